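# shells, PILR sampling, morphing, averaging

test_that("nuclear_centroid_coeffs builds the one-voxel centroid sphere", {
  nuc <- l0_coeffs(5, offset = c(1.5, -0.5, 0.25), voxel_size = 0.108333)
  nuc$coeffs[5] <- 0.3 # some l=1 content
  ctr <- nuclear_centroid_coeffs(nuc)
  expect_equal(she_mean_radius(ctr), 0.108333, tolerance = 1e-6)
  expect_equal(she_energy_fraction(ctr, 0), 1)
  expect_equal(ctr$centroid_offset, nuc$centroid_offset)
})

test_that("interpolate_shells is linear with exact endpoints", {
  inner <- l0_coeffs(2); outer <- l0_coeffs(10)
  outer$coeffs[3] <- 1.7
  sh <- interpolate_shells(inner, outer, 5)
  expect_equal(sh[[1]]$coeffs, inner$coeffs)
  expect_equal(sh[[5]]$coeffs, outer$coeffs)
  expect_equal(sh[[3]]$coeffs, (inner$coeffs + outer$coeffs) / 2)
  # concentric spheres: mean radii at the 5 fractions
  sh0 <- interpolate_shells(l0_coeffs(2), l0_coeffs(10), 5)
  expect_equal(vapply(sh0, she_mean_radius, numeric(1)), c(2, 4, 6, 8, 10),
               tolerance = 0.01)
  bad <- l0_coeffs(3, lmax = 8)
  expect_error(interpolate_shells(inner, bad, 3), "lmax mismatch")
})

test_that("shell family brackets nucleus and cell with monotone radii", {
  fx <- fx_default_cell()
  fam <- fx$fam
  expect_length(fam$shells, 96)
  expect_equal(she_mean_radius(fam$shells[[1]]), fam$voxel_size, tolerance = 1e-9)
  expect_equal(fam$shells[[fam$n_nuclear]]$coeffs, fx$nucleus$coeffs)
  expect_equal(fam$shells[[96]]$coeffs, fx$cell$coeffs)
  # radii non-decreasing along every grid direction (nested star-convex input)
  R <- cellorg:::shell_radii_matrix(fam)
  expect_true(all(apply(R, 1, function(r) all(diff(r) >= -1e-9))))
})

test_that("sample_pilr localizes structures in the correct shells", {
  fx <- fx_default_cell()
  cyto <- fx$images$cell & !fx$images$nucleus
  p <- sample_pilr(cyto, fx$fam)
  expect_equal(dim(p$values), c(96L, 32L * 64L))
  expect_lte(mean(p$values[seq_len(32), ]), 0.05) # nuclear rows empty
  expect_gte(mean(p$values[33:96, ]), 0.95)       # cytoplasmic rows filled
  expect_equal(p$compartment_split, 32L)

  empty <- array(FALSE, dim(fx$images$cell))
  expect_equal(sum(sample_pilr(empty, fx$fam)$values), 0)

  # intensity mode keeps raw values instead of binarizing
  graded <- array(0, dim(fx$images$cell))
  graded[cyto] <- 2.5
  pi_int <- sample_pilr(graded, fx$fam, mode = "intensity")
  expect_setequal(unique(as.numeric(pi_int$values)), c(0, 2.5))
  expect_true(all(sample_pilr(graded, fx$fam, mode = "binary")$values %in% c(0, 1)))
})

test_that("punctum lands at its analytic radial fraction", {
  d <- c(31, 31, 31); ctr <- c(16, 16, 16)
  cell <- sphere_mask(13, d, ctr); nuc <- sphere_mask(5, d, ctr)
  ccf <- compute_she(cell, 16, 1)
  ncf <- compute_she(nuc, 16, 1, reference_centroid = ccf$centroid_vox,
                     surface_label = "nucleus")
  fam <- shell_family(ccf, ncf)
  str <- array(FALSE, d); str[25, 16, 16] <- TRUE # radial fraction (9-5)/(13-5) = 0.5
  p <- sample_pilr(str, fam)
  rows <- which(rowSums(p$values) > 0)
  expect_true(all(rows > 32)) # cytoplasmic only
  frac <- (rows - fam$n_nuclear) / fam$n_cyto
  expect_true(all(frac >= 0.4 & frac <= 0.6))
})

test_that("morphing is a linear lookup and respects compartments", {
  fx <- fx_default_cell()
  set.seed(4)
  p1 <- sample_pilr(generate_structure(structure_pattern("punctate", 20, seed = 21),
                                       fx$images$cell, fx$images$nucleus), fx$fam)
  p2 <- sample_pilr(generate_structure(structure_pattern("punctate", 20, seed = 22),
                                       fx$images$cell, fx$images$nucleus), fx$fam)
  avg <- average_pilr(list(p1, p2))
  m_avg <- morph_pilr(avg, fx$fam)
  m1 <- morph_pilr(p1, fx$fam)
  m2 <- morph_pilr(p2, fx$fam)
  expect_lt(max(abs(m_avg$values - (m1$values + m2$values) / 2)), 1e-6)
  expect_true(all(m_avg$values[!m_avg$cell_mask] == 0))

  # compartment conservation into a different target shape
  nuc_pilr <- sample_pilr(generate_structure(structure_pattern("nuclear", 12, seed = 23),
                                             fx$images$cell, fx$images$nucleus), fx$fam)
  target <- shell_family(l0_coeffs(12), l0_coeffs(7, offset = c(1, 0, 0)))
  mn <- morph_pilr(nuc_pilr, target)
  inside_nuc <- sum(mn$values[mn$nucleus_mask])
  expect_gte(inside_nuc / sum(mn$values), 0.95)

  # incompatible discretization and invalid target are rejected
  small <- shell_family(fx$cell, fx$nucleus, n_nuclear = 8, n_cyto = 16)
  expect_error(morph_pilr(p1, small), "incompatible")
  bad_target <- shell_family(l0_coeffs(6), l0_coeffs(7))
  expect_error(morph_pilr(p1, bad_target), "not inside")
})

test_that("average_pilr is the elementwise mean with shape checking", {
  ones <- toy_pilr(matrix(1, 4, 8)); zeros <- toy_pilr(matrix(0, 4, 8))
  expect_true(all(average_pilr(list(ones, zeros))$values == 0.5))
  expect_equal(average_pilr(list(ones, ones, ones))$values, ones$values)
  set.seed(6)
  ps <- lapply(1:7, function(i) toy_pilr(matrix(rbinom(32, 1, 0.4), 4, 8)))
  oracle <- Reduce(`+`, lapply(ps, function(p) p$values)) / 7
  expect_equal(average_pilr(ps)$values, oracle)
  expect_error(average_pilr(list(ones, toy_pilr(matrix(0, 5, 8)))), "mismatch")
})

test_that("PILR is invariant to joint rigid rotation before alignment", {
  fx <- fx_default_cell()
  img <- fx$images
  str_mask <- generate_structure(structure_pattern("punctate", 25, seed = 31),
                                 img$cell, img$nucleus)
  build <- function(cell, nucleus, str) {
    al <- align_cell(cell, nucleus, str)
    ccf <- compute_she(al$cell, 16, 1)
    ncf <- compute_she(al$nucleus, 16, 1, reference_centroid = ccf$centroid_vox,
                       surface_label = "nucleus")
    sample_pilr(al$structure, shell_family(ccf, ncf))
  }
  rot90 <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  p0 <- build(img$cell, img$nucleus, str_mask)
  p90 <- build(rot90(img$cell), rot90(img$nucleus), rot90(str_mask))
  # 180-degree alignment ambiguity: compare against both orientations
  flip <- function(p) {
    v <- p$values
    idx <- matrix(seq_len(32L * 64L), nrow = 64, byrow = FALSE) # grid is 32 x 64
    # phi -> phi + pi is a shift of 32 in the longitude index within each ring
    perm <- as.integer(outer((seq_len(64) + 31L) %% 64L + 1L,
                             (seq_len(32) - 1L) * 64L, "+"))
    p$values <- v[, perm]
    p
  }
  d_direct <- mean(abs(p0$values - p90$values))
  d_flip <- mean(abs(p0$values - flip(p90)$values))
  expect_lte(min(d_direct, d_flip), 0.02)
})
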