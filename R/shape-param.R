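#' @title Spherical harmonic parameterization of cell and nuclear surfaces
#' @description Alignment of segmented cells in the xy plane, SHE fitting of
#'   star-convex surfaces, and mesh reconstruction from coefficients.
#' @name shape_param
NULL

DEFAULT_VOXEL_SIZE <- 0.108333 # micrometres, isotropic

mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  colMeans(idx)
}

mask_components <- function(mask) {
  lab <- cpp_label_components(as.logical(mask != 0), as.integer(dim(mask)))
  structure(array(lab, dim = dim(mask)), n = attr(lab, "n"))
}

#' Dice volume-overlap coefficient of two binary masks
#' @param a,b Logical/0-1 arrays of equal dimension.
#' @return `2|a & b| / (|a| + |b|)`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a != 0; b <- b != 0
  2 * sum(a & b) / (sum(a) + sum(b))
}

new_she_coeffs <- function(coeffs, lmax, surface_label, centroid_offset,
                           origin_vox = NULL, centroid_vox = NULL,
                           voxel_size = DEFAULT_VOXEL_SIZE, flags = character()) {
  names(coeffs) <- sh_coef_names(lmax)
  structure(
    list(coeffs = coeffs, lmax = as.integer(lmax),
         surface_label = surface_label,
         centroid_offset = as.numeric(centroid_offset),
         origin_vox = origin_vox, centroid_vox = centroid_vox,
         voxel_size = voxel_size, flags = flags),
    class = "she_coeffs"
  )
}

#' @export
print.she_coeffs <- function(x, ...) {
  cat(sprintf("SHE coefficients [%s], lmax = %d (%d coefficients)\n",
              x$surface_label, x$lmax, length(x$coeffs)))
  cat(sprintf("  mean radius %.3f um, centroid offset (%.3f, %.3f, %.3f) um\n",
              x$coeffs[1] / sqrt(4 * pi),
              x$centroid_offset[1], x$centroid_offset[2], x$centroid_offset[3]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Trilinear interpolation of a 3D array at arbitrary points (outside -> 0).
trilinear_sample <- function(img, px, py, pz) {
  d <- dim(img)
  x0 <- floor(px); y0 <- floor(py); z0 <- floor(pz)
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  val <- numeric(length(px))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xx <- x0 + dx; yy <- y0 + dy; zz <- z0 + dz
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    ok <- xx >= 1 & xx <= d[1] & yy >= 1 & yy <= d[2] & zz >= 1 & zz <= d[3] & w > 0
    if (any(ok)) {
      lin <- (xx[ok] - 1) + (yy[ok] - 1) * d[1] + (zz[ok] - 1) * d[1] * d[2] + 1
      val[ok] <- val[ok] + w[ok] * as.numeric(img[lin])
    }
  }
  val
}

# Radius function of a mask sampled by ray marching from `center` along the
# given directions. The binary occupancy is trilinearly interpolated along
# each ray and the surface placed at the 0.5 crossing (subvoxel accuracy).
# Also returns a star-convexity violation fraction (rays re-entering the mask
# beyond their first boundary crossing).
sample_radius_function <- function(mask, center, theta, phi, step = 0.5) {
  d <- dim(mask)
  rmax <- sqrt(sum(d^2)) / 2 + 2
  nstep <- ceiling(rmax / step)
  r <- seq_len(nstep) * step
  ux <- sin(theta) * cos(phi); uy <- sin(theta) * sin(phi); uz <- cos(theta)
  n <- length(theta)
  px <- outer(ux, r) + center[1]
  py <- outer(uy, r) + center[2]
  pz <- outer(uz, r) + center[3]
  occ <- matrix(trilinear_sample(mask, as.numeric(px), as.numeric(py),
                                 as.numeric(pz)), n, nstep)
  inside <- occ >= 0.5
  first_out <- apply(inside, 1, function(row) {
    k <- which(!row)
    if (length(k) == 0) length(row) + 1L else k[1]
  })
  ko <- pmin(first_out, nstep)
  ki <- pmax(ko - 1L, 1L)
  v_in <- occ[cbind(seq_len(n), ki)]
  v_out <- occ[cbind(seq_len(n), ko)]
  frac <- ifelse(v_in > v_out, (v_in - 0.5) / (v_in - v_out), 0.5)
  radius <- pmax((ki + pmin(pmax(frac, 0), 1)) * step, step / 2)
  radius[first_out == 1L] <- step / 2
  # star-convexity: inside samples beyond the first crossing
  beyond <- sweep(col(inside), 1, first_out, ">")
  viol <- rowSums(inside & beyond) > 0
  list(radius = radius, violation_fraction = mean(viol))
}

#' Fit a spherical harmonic expansion to a binary mask
#'
#' Samples the radius-versus-direction function of a star-convex mask about its
#' centroid on an oversampled equiangular grid and fits real spherical
#' harmonics of degree up to `lmax` by dense least squares. `lmax = 16` yields
#' `(16 + 1)^2 = 289` coefficients per surface. Coefficients are in
#' micrometres; the surface centroid relative to `reference_centroid` (e.g. the
#' cell centroid, for a nucleus) is carried as `centroid_offset` so meshes can
#' be placed back in the cell frame.
#'
#' Non-star-convex masks (sampled rays re-entering the mask beyond the first
#' boundary crossing on more than 1% of rays) are flagged
#' `"non_star_convex"` with a warning, not rejected. Masks with more than one
#' 6-connected component are rejected.
#'
#' @param mask 3D logical/0-1 array, a single star-convex component.
#' @param lmax Maximum expansion degree (default 16).
#' @param voxel_size Isotropic voxel edge in micrometres.
#' @param reference_centroid Voxel coordinates the `centroid_offset` is
#'   measured from; defaults to the mask's own centroid (offset zero).
#' @param surface_label `"cell"` or `"nucleus"`.
#' @return An object of class `she_coeffs`.
#' @export
compute_she <- function(mask, lmax = 16, voxel_size = DEFAULT_VOXEL_SIZE,
                        reference_centroid = NULL, surface_label = "cell") {
  comp <- mask_components(mask)
  ncomp <- attr(comp, "n")
  if (ncomp == 0) stop("mask is empty")
  if (ncomp > 1) stop(sprintf("mask has %d connected components; expected 1", ncomp))
  center <- mask_centroid(mask)
  g <- sh_fit_grid(lmax)
  rs <- sample_radius_function(mask, center, g$theta, g$phi)
  flags <- character()
  if (rs$violation_fraction > 0.01) {
    flags <- "non_star_convex"
    warning(sprintf("mask is not star-convex on %.1f%% of sampled rays",
                    100 * rs$violation_fraction))
  }
  coeffs <- qr.coef(sh_fit_qr(lmax), rs$radius * voxel_size)
  coeffs[is.na(coeffs)] <- 0
  if (is.null(reference_centroid)) reference_centroid <- center
  offset <- (center - reference_centroid) * voxel_size
  new_she_coeffs(coeffs, lmax, surface_label, offset,
                 origin_vox = as.numeric(reference_centroid),
                 centroid_vox = as.numeric(center),
                 voxel_size = voxel_size, flags = flags)
}

norm_angle <- function(a) ((a + 180) %% 360) - 180

rotate_image_xy <- function(img, theta_deg, center) {
  if (theta_deg == 0) return(img)
  d <- dim(img)
  th <- theta_deg * pi / 180
  # inverse mapping: content rotated CCW by theta -> sample source at -theta
  xs <- rep(seq_len(d[1]), times = d[2]) - center[1]
  ys <- rep(seq_len(d[2]), each = d[1]) - center[2]
  sx <- round(cos(th) * xs + sin(th) * ys + center[1])
  sy <- round(-sin(th) * xs + cos(th) * ys + center[2])
  ok <- sx >= 1 & sx <= d[1] & sy >= 1 & sy <= d[2]
  src <- (sx - 1) + (sy - 1) * d[1] + 1
  out <- array(if (is.logical(img)) FALSE else 0, dim = d)
  npix <- d[1] * d[2]
  for (z in seq_len(d[3])) {
    slice <- img[, , z]
    res <- slice
    res[] <- if (is.logical(img)) FALSE else 0
    res[ok] <- slice[src[ok]]
    out[, , z] <- res
  }
  out
}

xy_major_axis_angle <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  xy <- idx[, 1:2, drop = FALSE]
  cc <- cov(xy)
  ev <- eigen(cc, symmetric = TRUE)
  gap <- (ev$values[1] - ev$values[2]) / max(ev$values[1], .Machine$double.eps)
  if (!is.finite(gap) || gap < 1e-6) return(NA_real_) # rotationally symmetric
  v <- ev$vectors[, 1]
  atan2(v[2], v[1]) * 180 / pi
}

#' Align a segmented cell in the xy plane
#'
#' Rotates cell, nucleus and structure channels by the same angle
#' `theta_cell` about the cell centroid so that (mode `"longest_axis"`) the
#' longest in-plane cell axis lies along x, or (mode `"edge_axis"`) a supplied
#' outward direction maps onto +x. The z axis (apical-basal) is never rotated.
#'
#' The 180-degree ambiguity of the longest axis is resolved by requiring the
#' third central moment (skewness) of the rotated cell x coordinates to be
#' non-negative; rotationally symmetric cells keep `theta_cell = 0`.
#'
#' @param cell,nucleus 3D binary masks; `nucleus` may be `NULL`.
#' @param structure Optional structure mask or intensity image.
#' @param mode `"longest_axis"` or `"edge_axis"`.
#' @param outward_vector Length-2 or 3 outward direction (edge mode only).
#' @param voxel_size Voxel edge, micrometres.
#' @return List with rotated `cell`, `nucleus`, `structure` and an
#'   `alignment` record (`theta_cell` degrees in `[-180, 180)`, `mode`,
#'   `cell_centroid` in micrometres, lab frame).
#' @export
align_cell <- function(cell, nucleus = NULL, structure = NULL,
                       mode = c("longest_axis", "edge_axis"),
                       outward_vector = NULL,
                       voxel_size = DEFAULT_VOXEL_SIZE) {
  mode <- match.arg(mode)
  if (sum(cell != 0) == 0) stop("cell mask is empty")
  center <- mask_centroid(cell)
  if (mode == "edge_axis") {
    if (is.null(outward_vector)) stop("edge_axis mode requires an outward_vector")
    theta <- -atan2(outward_vector[2], outward_vector[1]) * 180 / pi
  } else {
    alpha <- xy_major_axis_angle(cell)
    theta <- if (is.na(alpha)) 0 else -alpha
    if (theta != 0 || !is.na(alpha)) {
      rot <- rotate_image_xy(cell, theta, center)
      xs <- which(rot != 0, arr.ind = TRUE)[, 1]
      skew <- mean((xs - mean(xs))^3)
      tol <- 1e-6 * max(1, sd(xs))^3
      if (skew < -tol) theta <- theta + 180
    }
  }
  theta <- norm_angle(theta)
  out <- list(
    cell = rotate_image_xy(cell, theta, center),
    nucleus = if (!is.null(nucleus)) rotate_image_xy(nucleus, theta, center),
    structure = if (!is.null(structure)) rotate_image_xy(structure, theta, center),
    alignment = list(theta_cell = theta, mode = mode,
                     cell_centroid = center * voxel_size)
  )
  out
}

#' Reconstruct a triangulated surface mesh from SHE coefficients
#'
#' Evaluates the SHE radius function on a latitude-longitude grid, adds pole
#' vertices, and triangulates. Vertices are in micrometres, translated by the
#' coefficient set's `centroid_offset` so nuclei land at their true position
#' relative to the cell centre.
#'
#' @param coeffs A `she_coeffs` object.
#' @param grid_resolution `c(nlat, nlon)` of the evaluation grid.
#' @return A `surface_mesh`: list with `vertices` (n x 3, micrometres,
#'   xyz), `faces` (m x 3 vertex indices), `provenance`.
#' @export
reconstruct_mesh <- function(coeffs, grid_resolution = c(32L, 64L)) {
  stopifnot(inherits(coeffs, "she_coeffs"))
  nlat <- as.integer(grid_resolution[1]); nlon <- as.integer(grid_resolution[2])
  theta <- (seq_len(nlat) - 0.5) * pi / nlat
  phi <- (seq_len(nlon) - 1) * 2 * pi / nlon
  th <- rep(theta, each = nlon)
  ph <- rep(phi, times = nlat)
  B <- sh_basis(c(th, 0, pi), c(ph, 0, 0), coeffs$lmax)
  r <- as.numeric(B %*% coeffs$coeffs)
  if (any(r <= 0)) stop("negative reconstructed radius: invalid coefficient set for radial parameterization")
  n <- nlat * nlon
  rg <- r[seq_len(n)]; r_np <- r[n + 1]; r_sp <- r[n + 2]
  verts <- cbind(rg * sin(th) * cos(ph), rg * sin(th) * sin(ph), rg * cos(th))
  verts <- rbind(verts, c(0, 0, r_np), c(0, 0, -r_sp))
  np <- n + 1L; sp <- n + 2L
  vid <- function(i, j) (i - 1L) * nlon + ((j - 1L) %% nlon) + 1L
  faces <- vector("list", 2 * n)
  k <- 0L
  for (i in seq_len(nlat - 1L)) {
    for (j in seq_len(nlon)) {
      a <- vid(i, j); b <- vid(i, j + 1L); cc <- vid(i + 1L, j); dd <- vid(i + 1L, j + 1L)
      k <- k + 1L; faces[[k]] <- c(a, cc, b)
      k <- k + 1L; faces[[k]] <- c(b, cc, dd)
    }
  }
  for (j in seq_len(nlon)) {
    k <- k + 1L; faces[[k]] <- c(np, vid(1L, j), vid(1L, j + 1L))
    k <- k + 1L; faces[[k]] <- c(sp, vid(nlat, j + 1L), vid(nlat, j))
  }
  verts <- sweep(verts, 2, coeffs$centroid_offset, "+")
  structure(list(vertices = verts, faces = do.call(rbind, faces[seq_len(k)]),
                 provenance = list(lmax = coeffs$lmax,
                                   surface_label = coeffs$surface_label,
                                   grid_resolution = c(nlat, nlon))),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces (%s, lmax %d)\n",
              nrow(x$vertices), nrow(x$faces),
              x$provenance$surface_label, x$provenance$lmax))
  invisible(x)
}

#' Voxelize a SHE surface into a binary mask
#'
#' A voxel is inside iff its radius about the surface centroid does not exceed
#' the SHE radius function in its direction (bilinearly interpolated from a
#' precomputed lookup table). The surface centroid is placed at
#' `origin_vox + centroid_offset / voxel_size`.
#'
#' @param coeffs `she_coeffs`.
#' @param dim Output array dimensions (x, y, z voxels).
#' @param origin_vox Voxel coordinates of the aligned-frame origin (the cell
#'   centroid); defaults to the coefficient set's recorded origin, else the
#'   box centre.
#' @return Logical 3D array.
#' @export
voxelize_coeffs <- function(coeffs, dim, origin_vox = NULL) {
  stopifnot(inherits(coeffs, "she_coeffs"))
  if (is.null(origin_vox)) {
    origin_vox <- if (!is.null(coeffs$origin_vox)) coeffs$origin_vox else (dim + 1) / 2
  }
  center <- origin_vox + coeffs$centroid_offset / coeffs$voxel_size
  tab <- sh_radius_table(coeffs$coeffs, coeffs$lmax) / coeffs$voxel_size # voxels
  dx <- seq_len(dim[1]) - center[1]
  dy <- seq_len(dim[2]) - center[2]
  dz <- seq_len(dim[3]) - center[3]
  X <- rep(dx, times = dim[2] * dim[3])
  Y <- rep(rep(dy, each = dim[1]), times = dim[3])
  Z <- rep(dz, each = dim[1] * dim[2])
  r <- sqrt(X^2 + Y^2 + Z^2)
  theta <- acos(pmin(pmax(ifelse(r > 0, Z / r, 1), -1), 1))
  phi <- atan2(Y, X)
  rad <- sh_table_lookup(tab, theta, phi)
  array(r <= rad, dim = dim)
}

#' Mean radius of a SHE surface (micrometres)
#' @param coeffs `she_coeffs`.
#' @export
she_mean_radius <- function(coeffs) {
  # l = 0 term is the spherical mean: c00 * Y00 = c00 / sqrt(4 pi)
  as.numeric(coeffs$coeffs[1]) / sqrt(4 * pi)
}

#' Fraction of squared coefficient energy in given degrees
#' @param coeffs `she_coeffs`.
#' @param degrees Integer vector of degrees l.
#' @export
she_energy_fraction <- function(coeffs, degrees) {
  tb <- sh_index_table(coeffs$lmax)
  e <- coeffs$coeffs^2
  sum(e[tb$l %in% degrees]) / sum(e)
}

#' Write a surface mesh as Wavefront OBJ
#' @param mesh `surface_mesh`.
#' @param path Output file.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' Write a surface mesh as legacy ASCII VTK polydata
#' @param mesh `surface_mesh`.
#' @param path Output file.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cellorg surface mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(mesh$vertices))), con)
  writeLines(sprintf("%.6f %.6f %.6f",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  nf <- nrow(mesh$faces)
  writeLines(sprintf("POLYGONS %d %d", nf, 4 * nf), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Serialize SHE coefficients to a data.frame / CSV
#' @param coeffs `she_coeffs`.
#' @param path Optional CSV path; when given the table is also written.
#' @return data.frame with columns surface, l, m, value.
#' @export
she_to_table <- function(coeffs, path = NULL) {
  tb <- sh_index_table(coeffs$lmax)
  df <- data.frame(surface = coeffs$surface_label, l = tb$l, m = tb$m,
                   value = as.numeric(coeffs$coeffs))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
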