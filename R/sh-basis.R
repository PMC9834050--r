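#' Spherical harmonic index table
#'
#' Degrees and orders of the real spherical harmonic basis in the column order
#' used throughout the package: coefficient `(l, m)` sits at position
#' `l^2 + l + m + 1`, so a degree-`lmax` expansion has exactly
#' `(lmax + 1)^2` coefficients (289 for `lmax = 16`).
#'
#' @param lmax Maximum degree of the expansion.
#' @return A data.frame with columns `l` and `m`, one row per coefficient.
#' @export
sh_index_table <- function(lmax) {
  l <- rep.int(0:lmax, 2 * (0:lmax) + 1)
  m <- unlist(lapply(0:lmax, function(li) seq(-li, li)), use.names = FALSE)
  data.frame(l = l, m = m)
}

#' Names like "L3M-2" for the coefficient vector
#' @noRd
sh_coef_names <- function(lmax) {
  tb <- sh_index_table(lmax)
  paste0("L", tb$l, "M", tb$m)
}

#' Evaluate the real spherical harmonic basis
#'
#' Returns the design matrix of real, orthonormal spherical harmonics at the
#' supplied directions; a radius function is evaluated as `B %*% coeffs`.
#'
#' @param theta Polar angles in radians (0 at +z).
#' @param phi Azimuthal angles in radians.
#' @param lmax Maximum degree.
#' @return Numeric matrix, `length(theta)` x `(lmax + 1)^2`.
#' @export
sh_basis <- function(theta, phi, lmax) {
  cpp_sh_basis(as.numeric(theta), as.numeric(phi), as.integer(lmax))
}

# Equiangular fitting grid used for SHE least squares: 2(lmax+1) latitudes
# (cell centers, poles excluded) x 4(lmax+1) longitudes; oversamples the
# (lmax+1)^2 coefficients ~8-fold to stabilize the fit.
sh_fit_grid <- function(lmax) {
  nlat <- 2L * (lmax + 1L)
  nlon <- 4L * (lmax + 1L)
  theta <- (seq_len(nlat) - 0.5) * pi / nlat
  phi <- (seq_len(nlon) - 1) * 2 * pi / nlon
  list(
    theta = rep(theta, each = nlon),
    phi = rep(phi, times = nlat),
    nlat = nlat, nlon = nlon
  )
}

# Cached QR factorization of the fitting design matrix (one per lmax).
sh_fit_qr <- function(lmax) {
  key <- paste0("qr_", lmax)
  q <- .cellorg_cache[[key]]
  if (is.null(q)) {
    g <- sh_fit_grid(lmax)
    q <- qr(sh_basis(g$theta, g$phi, lmax))
    .cellorg_cache[[key]] <- q
  }
  q
}

# Cached basis on the radius-lookup-table grid: theta in [0, pi] inclusive,
# phi in [0, 2*pi] with the seam column duplicated, for bilinear interpolation.
sh_table_grid <- function(nlat_tab = 65L, nlon_tab = 129L) {
  theta <- seq(0, pi, length.out = nlat_tab)
  phi <- seq(0, 2 * pi, length.out = nlon_tab)
  list(theta = rep(theta, times = nlon_tab), phi = rep(phi, each = nlat_tab),
       nlat = nlat_tab, nlon = nlon_tab)
}

sh_table_basis <- function(lmax, nlat_tab = 65L, nlon_tab = 129L) {
  key <- paste0("tab_", lmax, "_", nlat_tab, "_", nlon_tab)
  B <- .cellorg_cache[[key]]
  if (is.null(B)) {
    g <- sh_table_grid(nlat_tab, nlon_tab)
    B <- sh_basis(g$theta, g$phi, lmax)
    .cellorg_cache[[key]] <- B
  }
  B
}

# Radius lookup table (nlat_tab x nlon_tab, micrometres) for one coefficient set.
sh_radius_table <- function(coeffs_vec, lmax, nlat_tab = 65L, nlon_tab = 129L) {
  B <- sh_table_basis(lmax, nlat_tab, nlon_tab)
  matrix(B %*% coeffs_vec, nrow = nlat_tab, ncol = nlon_tab)
}

# Bilinear interpolation of a radius table at arbitrary (theta, phi).
sh_table_lookup <- function(tab, theta, phi) {
  nlat <- nrow(tab); nlon <- ncol(tab)
  ti <- theta / pi * (nlat - 1) + 1
  pj <- (phi %% (2 * pi)) / (2 * pi) * (nlon - 1) + 1
  i0 <- pmin(pmax(floor(ti), 1), nlat - 1)
  j0 <- pmin(pmax(floor(pj), 1), nlon - 1)
  wi <- ti - i0
  wj <- pj - j0
  v00 <- tab[cbind(i0, j0)]
  v10 <- tab[cbind(i0 + 1, j0)]
  v01 <- tab[cbind(i0, j0 + 1)]
  v11 <- tab[cbind(i0 + 1, j0 + 1)]
  (1 - wi) * (1 - wj) * v00 + wi * (1 - wj) * v10 +
    (1 - wi) * wj * v01 + wi * wj * v11
}

# Evaluate a scoped expression under a fixed RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
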