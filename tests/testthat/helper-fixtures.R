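# Shared fixtures and independent oracles. Everything is generated in code;
# expensive fixtures are memoised for the duration of the test run.

fx_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(fx_cache[[key]])) fx_cache[[key]] <- builder()
  fx_cache[[key]]
}

# --- simple geometric masks ------------------------------------------------

sphere_mask <- function(radius, dims = rep(2 * radius + 9, 3),
                        center = (dims + 1) / 2) {
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  r <- sqrt((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
              (idx[, 3] - center[3])^2)
  array(r <= radius, dims)
}

ellipsoid_mask <- function(semi, dims = 2 * ceiling(semi) + 9,
                           center = (dims + 1) / 2) {
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  e <- ((idx[, 1] - center[1]) / semi[1])^2 + ((idx[, 2] - center[2]) / semi[2])^2 +
    ((idx[, 3] - center[3]) / semi[3])^2
  array(e <= 1, dims)
}

# l = 0-only coefficient set describing a sphere of the given radius
l0_coeffs <- function(radius, lmax = 16L, offset = c(0, 0, 0), voxel_size = 1) {
  v <- numeric((lmax + 1)^2)
  v[1] <- radius * sqrt(4 * pi)
  cellorg:::new_she_coeffs(v, lmax, "sphere", offset, voxel_size = voxel_size)
}

# --- full single-cell pipeline on a synthetic cell -------------------------

# Build one synthetic cell record: images, aligned channels, SHE fits,
# shell family, PILR of the structure channel. `u` in [0,1] scales the base
# radius between 9 and 14 voxels.
make_cell_record <- function(seed, u = 0.5, pattern = NULL, base_range = c(9, 14),
                             aspect = c(1.3, 1, 0.9), noise = 0.04) {
  spec <- synthetic_cell_spec(
    cell_base_radius = base_range[1] + u * diff(base_range),
    aspect_ratios = aspect, shape_noise_amplitude = noise, seed = seed)
  shp <- generate_cell_shape(spec)
  if (is.null(pattern)) pattern <- structure_pattern("punctate", density = 25, seed = seed + 1)
  str_mask <- generate_structure(pattern, shp$cell, shp$nucleus)
  al <- align_cell(shp$cell, shp$nucleus, str_mask)
  ccf <- compute_she(al$cell, lmax = 16, voxel_size = 1)
  ncf <- compute_she(al$nucleus, lmax = 16, voxel_size = 1,
                     reference_centroid = ccf$centroid_vox,
                     surface_label = "nucleus")
  fam <- shell_family(ccf, ncf)
  list(images = shp, aligned = al, cell = ccf, nucleus = ncf, fam = fam,
       pilr = sample_pilr(al$structure, fam),
       descriptor = joint_descriptor(ccf, ncf))
}

# the default cached cell used across pilr tests
fx_default_cell <- function() memo("default_cell", function() {
  spec <- synthetic_cell_spec(seed = 3)
  shp <- generate_cell_shape(spec)
  ccf <- compute_she(shp$cell, lmax = 16, voxel_size = 1)
  ncf <- compute_she(shp$nucleus, lmax = 16, voxel_size = 1,
                     reference_centroid = ccf$centroid_vox,
                     surface_label = "nucleus")
  list(images = shp, cell = ccf, nucleus = ncf,
       fam = shell_family(ccf, ncf))
})

# a toy PILR with given values (for statistics tests that need no images)
toy_pilr <- function(values, n_nuclear = 2L, cell_id = NULL) {
  values <- as.matrix(values)
  structure(list(values = values, compartment_split = n_nuclear,
                 grid = c(1L, ncol(values)), n_nuclear = n_nuclear,
                 n_cyto = nrow(values) - n_nuclear, mode = "binary",
                 source_cell_id = cell_id, oob_count = 0L),
            class = "pilr")
}

# --- independent oracles ---------------------------------------------------

# brute-force PCA scores via eigendecomposition of the covariance matrix
oracle_pca_scores <- function(X, k) {
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(cov(X), symmetric = TRUE)
  Xc %*% ev$vectors[, seq_len(k), drop = FALSE]
}

# brute-force UPGMA (average linkage) cophenetic distance matrix
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  coph <- matrix(0, n, n)
  clusters <- as.list(seq_len(n))
  d <- D
  active <- seq_len(n)
  while (length(active) > 1) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- active[ij[1]]; b <- active[ij[2]]
    h <- d[a, b]
    for (x in clusters[[a]]) for (y in clusters[[b]]) {
      coph[x, y] <- h; coph[y, x] <- h
    }
    # average linkage: distance to merged cluster = size-weighted mean
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (c in setdiff(active, c(a, b)))
      d[a, c] <- d[c, a] <- (na * d[a, c] + nb * d[b, c]) / (na + nb)
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    active <- setdiff(active, b)
  }
  coph
}

# brute-force all-pairs nearest neighbour (lowest-id tie-break)
oracle_nearest_neighbour <- function(baseline, query) {
  bid <- rownames(baseline)
  ord <- order(bid)
  baseline <- baseline[ord, , drop = FALSE]; bid <- bid[ord]
  vapply(seq_len(nrow(query)), function(i) {
    d2 <- rowSums(sweep(baseline, 2, query[i, ])^2)
    bid[which.min(d2)]
  }, character(1))
}

# rank-based AUC of positions: P(score_pos > score_neg) with tie correction
rank_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# independent TOC classifier from the three prose rules
oracle_toc <- function(f1, f2, f3, measurable_any = TRUE) {
  if (!measurable_any) return("no_change")
  if (f1 && f3) return("stepwise")
  if (f1) return("m1_only")
  if (f3 || f2) return("m2_change")
  "no_change"
}
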