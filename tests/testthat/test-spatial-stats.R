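# similarity, clustering, stereotypy/concordance, volume scaling

test_that("location_similarity matches the textbook correlation oracle", {
  set.seed(1)
  a <- toy_pilr(matrix(runif(96), 12, 8))
  b <- toy_pilr(matrix(runif(96), 12, 8))
  c3 <- toy_pilr(matrix(runif(96), 12, 8))
  sim <- location_similarity(list(A = a, B = b, C = c3))
  M <- cbind(pilr_flatten(a), pilr_flatten(b), pilr_flatten(c3))
  oracle <- cor(M)
  expect_equal(unname(sim), unname(oracle), tolerance = 1e-12)
  expect_equal(sim, t(sim))

  # identical -> 1; binary complement -> -1
  bin <- toy_pilr(matrix(rbinom(96, 1, 0.5), 12, 8))
  comp <- toy_pilr(1 - bin$values)
  s2 <- location_similarity(list(x = bin, y = bin, z = comp))
  expect_equal(s2["x", "y"], 1)
  expect_equal(s2["x", "z"], -1)

  flat <- toy_pilr(matrix(1, 12, 8))
  s3 <- location_similarity(list(x = bin, flat = flat))
  expect_true(is.na(s3["x", "flat"]))
  expect_match(attr(s3, "missing")[["flat"]], "zero-variance")
})

test_that("cluster_structures equals a brute-force average-linkage oracle", {
  set.seed(2)
  sim <- cor(matrix(rnorm(40), 10, 4))
  dimnames(sim) <- list(LETTERS[1:4], LETTERS[1:4])
  hc <- cluster_structures(sim)
  expect_length(hc$order, 4)
  expect_equal(nrow(hc$merge), 3)
  coph <- as.matrix(stats::cophenetic(hc))
  D <- as.matrix(dist(sim))
  oracle <- oracle_upgma_cophenetic(D)
  dimnames(oracle) <- dimnames(D)
  expect_equal(coph[rownames(D), colnames(D)], oracle, tolerance = 1e-10)

  # identical similarity rows merge first at height 0
  simA <- sim
  simA[1, ] <- c(1, 1, 0.3, 0.2); simA[, 1] <- simA[1, ]
  simA[2, ] <- c(1, 1, 0.3, 0.2); simA[, 2] <- simA[2, ]
  simA[1, 1] <- simA[2, 2] <- 1; simA[1, 2] <- simA[2, 1] <- 1
  hcA <- cluster_structures(simA)
  expect_equal(min(hcA$height), 0)
  expect_setequal(abs(hcA$merge[1, ]), c(1, 2))

  simNA <- sim; simNA[1, 3] <- NA
  expect_error(cluster_structures(simNA), "missing entries")
  n <- dendrogram_newick(hc)
  expect_match(n, "^\\(.*\\);$")
})

test_that("pairwise_cell_correlations matches an entry-by-entry oracle", {
  set.seed(3)
  ps <- stats::setNames(lapply(1:5, function(i) toy_pilr(matrix(runif(60), 6, 10))),
                        paste0("c", 1:5))
  ps$c5 <- ps$c1 # duplicated cell
  cc <- pairwise_cell_correlations(ps)
  expect_equal(unname(diag(cc)), rep(1, 5))
  expect_equal(cc["c1", "c5"], 1)
  M <- t(vapply(ps, pilr_flatten, numeric(60)))
  for (i in 1:5) for (j in 1:5)
    expect_equal(cc[i, j], cor(M[i, ], M[j, ]), tolerance = 1e-12)
  expect_error(pairwise_cell_correlations(ps["c1"]), "at least 2")
})

test_that("stereotypy and concordance follow the pair-enumeration semantics", {
  set.seed(4)
  # 2 structures x 2 cells, hand-enumerable
  M <- matrix(runif(4 * 20), 4, 20,
              dimnames = list(c("a1", "a2", "b1", "b2"), NULL))
  cc <- pairwise_cell_correlations(M)
  sc <- stereotypy_concordance(cc, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(sc$values["A", "A"], cc["a1", "a2"])
  conc_oracle <- mean(c(cc["a1", "b1"], cc["a1", "b2"], cc["a2", "b1"], cc["a2", "b2"]))
  expect_equal(sc$values["A", "B"], conc_oracle)
  expect_equal(sc$values["A", "B"], sc$values["B", "A"])
  expect_equal(sc$n_pairs["A", "B"], 4L)

  # identical PILRs within a structure -> stereotypy 1; across -> concordance 1
  M2 <- rbind(M[c(1, 1, 1), ], M[c(1, 1), ])
  rownames(M2) <- c("x1", "x2", "x3", "y1", "y2")
  cc2 <- pairwise_cell_correlations(M2)
  sc2 <- stereotypy_concordance(cc2, stats::setNames(c("X", "X", "X", "Y", "Y"),
                                                     rownames(M2)))
  expect_equal(sc2$values["X", "X"], 1)
  expect_equal(sc2$values["X", "Y"], 1)

  # single-cell structure: stereotypy missing with reason
  sc3 <- stereotypy_concordance(cc, c(a1 = "A", a2 = "A", b1 = "B", b2 = "C"))
  expect_true(is.na(sc3$values["B", "B"]))
  expect_match(sc3$missing[["B"]], "single cell")

  # permutation invariance
  perm <- c(3, 1, 4, 2)
  sc4 <- stereotypy_concordance(cc[perm, perm],
                                c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")[perm])
  expect_equal(sc4$values, sc$values)
})

test_that("per-map-point statistics are consistent with direct computation", {
  set.seed(5)
  n <- 30
  ids <- sprintf("c%02d", 1:n)
  pilrs <- stats::setNames(lapply(1:n, function(i) toy_pilr(matrix(runif(60), 6, 10))), ids)
  labels <- stats::setNames(rep(c("A", "B"), length.out = n), ids)
  coords <- matrix(0, n, 8, dimnames = list(ids, NULL))
  coords[, 1] <- rep(c(0, 0, 1, 1), length.out = n) + runif(n, -0.1, 0.1)
  pm <- per_mappoint_statistics(pilrs, labels, coords, "similarity",
                                modes = 1, min_cells = 5)
  centre <- pm$mode1[["0.0"]]
  members <- bin_cells(coords, 1)[["0.0"]]
  direct <- location_similarity(list(
    A = average_pilr(pilrs[members[labels[members] == "A"]]),
    B = average_pilr(pilrs[members[labels[members] == "B"]])))
  expect_equal(centre, direct)
  # a bin with too few cells is missing, not zero
  expect_false("2.0" %in% names(pm$mode1))
  expect_true("mode1@2.0" %in% names(attr(pm, "missing")))

  pm2 <- per_mappoint_statistics(pilrs, labels, coords, "stereotypy_concordance",
                                 modes = 1, min_cells = 5)
  cc <- pairwise_cell_correlations(pilrs[members])
  direct2 <- stereotypy_concordance(cc, labels[members])
  expect_equal(pm2$mode1[["0.0"]]$values, direct2$values)
})

test_that("volume scaling attributes variance with a leave-one-out refit oracle", {
  set.seed(6)
  n <- 40
  metrics <- data.frame(cell_volume = runif(n, 800, 2000),
                        cell_area = runif(n, 400, 900),
                        nuc_volume = runif(n, 200, 600))
  # exact linear dependence on cell volume
  v <- 0.1 * metrics$cell_volume
  res <- suppressWarnings(volume_scaling(v, metrics)) # lm warns on perfect fit
  expect_equal(res$total_r2, 1, tolerance = 1e-10)
  red <- summary(lm(v ~ cell_area + nuc_volume, data = metrics))$r.squared
  expect_equal(unname(res$unique_contribution["cell_volume"]), 1 - red,
               tolerance = 1e-8)

  # unique contributions match the brute-force refits on a noisy response
  v2 <- 0.05 * metrics$cell_volume + 0.2 * metrics$nuc_volume + rnorm(n, sd = 20)
  res2 <- volume_scaling(v2, metrics)
  full <- summary(lm(v2 ~ ., data = metrics))$r.squared
  for (m in names(metrics)) {
    r <- summary(lm(v2 ~ ., data = metrics[, setdiff(names(metrics), m), drop = FALSE]))$r.squared
    expect_equal(unname(res2$unique_contribution[m]), full - r, tolerance = 1e-8)
  }

  # independent noise: negligible R^2 at n = 1000
  set.seed(7)
  big <- data.frame(a = runif(1000, 1, 2), b = runif(1000, 1, 2),
                    c = runif(1000, 1, 2), d = runif(1000, 1, 2),
                    e = runif(1000, 1, 2))
  expect_lte(volume_scaling(rnorm(1000), big)$total_r2, 0.05)

  expect_error(volume_scaling(v[1:10], metrics[1:10, ]), ">= 30 cells")
  expect_error(volume_scaling(v, -metrics), "positive")
  collin <- metrics
  collin$dup <- 2 * collin$cell_volume
  expect_warning(volume_scaling(v2, collin), "collinear")
})
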