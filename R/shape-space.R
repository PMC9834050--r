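#' @title PCA cell and nuclear shape space
#' @description Fits the 8-mode PCA shape space on joint SHE descriptor
#'   vectors (578 values for cell + nucleus at lmax 16), maps cells in and out
#'   of it, bins cells at map points and selects the similarly-shaped
#'   population inside an 8-dimensional sphere.
#' @name shape_space
NULL

#' Stack cell and nucleus coefficients into one joint descriptor
#' @param cell,nucleus `she_coeffs` with the same lmax.
#' @return Numeric vector of length `2 * (lmax + 1)^2` (578 at lmax 16).
#' @export
joint_descriptor <- function(cell, nucleus) {
  stopifnot(cell$lmax == nucleus$lmax)
  c(stats::setNames(cell$coeffs, paste0("cell_", names(cell$coeffs))),
    stats::setNames(nucleus$coeffs, paste0("nuc_", names(nucleus$coeffs))))
}

#' Fit the PCA shape space
#'
#' PCA of the joint descriptor matrix, keeping `n_modes` components. Raw PC
#' scores are z-scored per mode by their standard deviation sigma, so shape
#' coordinates are in sigma units and the origin is the mean cell and nuclear
#' shape. Per-mode signs are flipped so each mode correlates positively with
#' `covariate` when given (e.g. cell volume), otherwise so each mode's score
#' skewness is non-negative. The PCA is fitted on all cells; cells outside the
#' (1st, 99th) percentile band of any raw PC are flagged `excluded` for
#' downstream statistics but not removed from the fit.
#'
#' @param X n x p descriptor matrix (rows = cells); n >= 9.
#' @param n_modes Number of shape modes (default 8).
#' @param covariate Optional numeric length-n interpretable covariate used to
#'   orient mode signs.
#' @return A `shape_space_model`.
#' @export
fit_shape_space <- function(X, n_modes = 8L, covariate = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 9) stop(sprintf("need at least 9 cells to fit a shape space, got %d", n))
  sds <- apply(X, 2, sd)
  kept <- which(sds > 0)
  if (length(kept) < ncol(X))
    warning(sprintf("dropping %d zero-variance descriptor column(s)",
                    ncol(X) - length(kept)))
  n_modes <- min(n_modes, length(kept), n - 1)
  pca <- prcomp(X[, kept, drop = FALSE], center = TRUE, scale. = FALSE)
  W <- pca$rotation[, seq_len(n_modes), drop = FALSE]
  scores <- pca$x[, seq_len(n_modes), drop = FALSE]
  flips <- vapply(seq_len(n_modes), function(k) {
    s <- 0
    if (!is.null(covariate)) {
      r <- suppressWarnings(cor(scores[, k], covariate))
      if (is.finite(r) && abs(r) > 1e-12) s <- sign(r)
    }
    if (s == 0) {
      sk <- mean((scores[, k] - mean(scores[, k]))^3)
      s <- if (sk < 0) -1 else 1
    }
    s
  }, numeric(1))
  W <- sweep(W, 2, flips, "*")
  scores <- sweep(scores, 2, flips, "*")
  sigma <- apply(scores, 2, sd)
  bounds <- apply(scores, 2, quantile, probs = c(0.01, 0.99), names = FALSE)
  excluded <- rowSums(sweep(scores, 2, bounds[1, ], "<") |
                        sweep(scores, 2, bounds[2, ], ">")) > 0
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(
    mean_kept = pca$center, kept = kept, p_full = ncol(X),
    full_colnames = colnames(X), col_means = colMeans(X),
    components = W, sigma = sigma, sign_flips = flips,
    percentile_bounds = bounds, n_fit = n, n_modes = n_modes,
    var_explained = ev[seq_len(n_modes)],
    excluded_fit = excluded
  ), class = "shape_space_model")
}

#' @export
print.shape_space_model <- function(x, ...) {
  cat(sprintf("shape_space_model: %d modes over %d descriptors (fit on %d cells)\n",
              x$n_modes, x$p_full, x$n_fit))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " "), "\n")
  invisible(x)
}

#' Map descriptors into shape coordinates (sigma units)
#'
#' @param model `shape_space_model`.
#' @param X Descriptor matrix or single descriptor vector of the fitted width.
#' @param apply_exclusion Flag cells outside the (1st, 99th) raw-PC band
#'   (attribute `"excluded"`). Second populations projected into a baseline
#'   space are mapped without exclusion (the default).
#' @return n x n_modes matrix of sigma-unit coordinates.
#' @export
shape_transform <- function(model, X, apply_exclusion = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$p_full)
    stop(sprintf("descriptor length %d does not match fitted width %d",
                 ncol(X), model$p_full))
  raw <- sweep(X[, model$kept, drop = FALSE], 2, model$mean_kept) %*% model$components
  Z <- sweep(raw, 2, model$sigma, "/")
  colnames(Z) <- paste0("mode", seq_len(model$n_modes))
  rownames(Z) <- rownames(X)
  if (apply_exclusion) {
    b <- model$percentile_bounds
    attr(Z, "excluded") <- rowSums(sweep(raw, 2, b[1, ], "<") |
                                     sweep(raw, 2, b[2, ], ">")) > 0
  }
  Z
}

#' Map shape coordinates back to descriptors (inverse PCA)
#'
#' The origin `(0, ..., 0)` maps to the mean descriptor, i.e. the mean cell
#' and nuclear shape. Dropped zero-variance columns are restored at their
#' fitted means.
#'
#' @param model `shape_space_model`.
#' @param Z Coordinate matrix or single sigma-unit coordinate vector.
#' @return n x p descriptor matrix.
#' @export
shape_inverse_transform <- function(model, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  Z <- as.matrix(Z)
  stopifnot(ncol(Z) == model$n_modes)
  raw <- sweep(Z, 2, model$sigma, "*")
  Xk <- sweep(raw %*% t(model$components), 2, model$mean_kept, "+")
  X <- matrix(rep(model$col_means, each = nrow(Z)), nrow = nrow(Z))
  X[, model$kept] <- Xk
  colnames(X) <- model$full_colnames
  X
}

#' Split a descriptor row back into cell and nucleus coefficient sets
#' @param descriptor Length `2 * (lmax+1)^2` joint vector.
#' @param lmax Expansion degree (default 16).
#' @param voxel_size Voxel edge, micrometres.
#' @return List with `she_coeffs` elements `cell` and `nucleus`.
#' @export
split_descriptor <- function(descriptor, lmax = 16L, voxel_size = DEFAULT_VOXEL_SIZE) {
  nc <- (lmax + 1)^2
  stopifnot(length(descriptor) == 2 * nc)
  list(cell = new_she_coeffs(unname(descriptor[seq_len(nc)]), lmax, "cell",
                             c(0, 0, 0), voxel_size = voxel_size),
       nucleus = new_she_coeffs(unname(descriptor[nc + seq_len(nc)]), lmax,
                                "nucleus", c(0, 0, 0), voxel_size = voxel_size))
}

map_point_centers <- function() seq(-2, 2, by = 0.5)

#' Bin cells at the nine map points of one shape mode
#'
#' Map point centers sit at -2 to 2 sigma in steps of 0.5 sigma. A cell is
#' assigned to the nearest center when within the bin half-width of it
#' (default 0.25 sigma, i.e. contiguous bins covering [-2.25, 2.25]).
#'
#' @param coords Sigma-unit coordinate matrix (cells x modes) with rownames
#'   as cell ids.
#' @param mode Mode index 1..n_modes.
#' @param half_width Bin half-width in sigma.
#' @return List of class `map_point_bins`: per center, the member cell ids;
#'   attribute `"assignment"` gives each cell's center (NA if unassigned).
#' @export
bin_cells <- function(coords, mode, half_width = 0.25) {
  coords <- as.matrix(coords)
  stopifnot(mode >= 1, mode <= ncol(coords))
  centers <- map_point_centers()
  x <- coords[, mode]
  nearest <- centers[pmax(1, pmin(length(centers), round(x / 0.5) + 5))]
  assign <- ifelse(abs(x - nearest) <= half_width, nearest, NA_real_)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
  bins <- lapply(centers, function(cc) ids[!is.na(assign) & assign == cc])
  names(bins) <- sprintf("%.1f", centers)
  structure(bins, assignment = stats::setNames(assign, ids),
            mode = mode, centers = centers, class = "map_point_bins")
}

#' Enumerate the 65 shape-space map points
#'
#' 8 modes x 9 centers with the center-0 bin shared across all modes: 65
#' distinct points.
#'
#' @param n_modes Number of shape modes.
#' @return data.frame with columns `point_id`, `mode` (NA for the shared
#'   origin) and `center`.
#' @export
enumerate_map_points <- function(n_modes = 8L) {
  centers <- map_point_centers()
  off <- expand.grid(mode = seq_len(n_modes), center = centers[centers != 0])
  off <- off[order(off$mode, off$center), ]
  out <- rbind(data.frame(mode = NA_integer_, center = 0), off)
  out$point_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("point_id", "mode", "center")]
}

#' Select cells inside the 8-dimensional sphere
#'
#' Cells whose sigma-unit coordinates have Euclidean norm at most `radius`
#' form the similarly-shaped reference population (the study used 2.1 sigma).
#'
#' @param coords Sigma-unit coordinate matrix with rownames as cell ids.
#' @param radius Sphere radius in sigma, > 0.
#' @return Character vector of selected cell ids.
#' @export
select_sphere <- function(coords, radius = 2.1) {
  if (radius <= 0) stop("radius must be > 0")
  coords <- as.matrix(coords)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
  ids[sqrt(rowSums(coords^2)) <= radius]
}
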