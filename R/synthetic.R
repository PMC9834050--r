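#' @title Synthetic cells with planted geometry
#' @description Generator for epithelial-like star-convex cells with interior
#'   nuclei and organelle patterns (punctate, reticular, membrane shell,
#'   nuclear, polarized punctate). Surfaces are low-degree SHE shapes (l <= 4)
#'   voxelized onto an isotropic grid, so fixtures live in exactly the
#'   star-convex regime the radial SHE parameterization assumes.
#' @name fixtures
NULL

#' Specification of one synthetic cell
#'
#' @param cell_base_radius Geometric mean radius in voxels.
#' @param aspect_ratios Length-3 multiplier of the x, y, z semi-axes.
#' @param shape_noise_amplitude RMS random surface perturbation as a fraction
#'   of the base radius; must stay below 0.3 to preserve star-convexity.
#' @param nucleus_volume_fraction Nucleus/cell volume ratio, in (0, 1).
#' @param nucleus_offset Voxel offset of the nuclear centroid from the cell
#'   centroid.
#' @param seed Integer RNG seed; identical spec + seed gives voxel-identical
#'   output.
#' @return A `synthetic_cell_spec` list.
#' @export
synthetic_cell_spec <- function(cell_base_radius = 12,
                                aspect_ratios = c(1.4, 1.0, 0.9),
                                shape_noise_amplitude = 0.05,
                                nucleus_volume_fraction = 0.25,
                                nucleus_offset = c(0, 0, 0),
                                seed = 1L) {
  stopifnot(length(aspect_ratios) == 3, all(aspect_ratios > 0),
            cell_base_radius > 0, length(nucleus_offset) == 3)
  if (!(nucleus_volume_fraction > 0 && nucleus_volume_fraction < 1))
    stop("nucleus_volume_fraction must be in (0, 1)")
  if (shape_noise_amplitude >= 0.3)
    stop("shape_noise_amplitude must be < 0.3 (star-convexity)")
  structure(list(cell_base_radius = cell_base_radius,
                 aspect_ratios = as.numeric(aspect_ratios),
                 shape_noise_amplitude = shape_noise_amplitude,
                 nucleus_volume_fraction = nucleus_volume_fraction,
                 nucleus_offset = as.numeric(nucleus_offset),
                 seed = as.integer(seed)),
            class = "synthetic_cell_spec")
}

#' Description of one planted organelle pattern
#'
#' `kind` fixes the compartment: `punctate`, `reticular` and
#' `polarized_punctate` occupy the cytoplasm, `nuclear` the nucleus, and
#' `membrane_shell` a near-membrane band. For punctate kinds `density` is the
#' object count; for `reticular` and `membrane_shell` it is the volume
#' fraction of the compartment.
#'
#' @param kind Pattern class.
#' @param density Expected object count or volume fraction, >= 0.
#' @param polarization_bias Non-negative placement bias along +x
#'   (`polarized_punctate` only).
#' @param punct_radius Punctum radius in voxels.
#' @param seed Integer RNG seed.
#' @export
structure_pattern <- function(kind = c("punctate", "reticular", "membrane_shell",
                                       "nuclear", "polarized_punctate"),
                              density = 20, polarization_bias = 0,
                              punct_radius = 2, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(density >= 0, polarization_bias >= 0, punct_radius >= 1)
  structure(list(kind = kind, density = density,
                 polarization_bias = polarization_bias,
                 punct_radius = punct_radius, seed = as.integer(seed)),
            class = "structure_pattern")
}

# Low-degree SHE coefficient vector (micrometre radii) for the cell surface:
# LS projection of an ellipsoid radial function onto l <= 4, plus zero-mean
# random degree 1..4 perturbations with total RMS = noise * base radius.
synthetic_surface_coeffs <- function(spec, voxel_size = DEFAULT_VOXEL_SIZE) {
  lmax_gen <- 4L
  g <- sh_fit_grid(lmax_gen)
  a <- spec$cell_base_radius * spec$aspect_ratios
  r <- 1 / sqrt((sin(g$theta) * cos(g$phi) / a[1])^2 +
                (sin(g$theta) * sin(g$phi) / a[2])^2 +
                (cos(g$theta) / a[3])^2)
  coeffs <- qr.coef(sh_fit_qr(lmax_gen), r * voxel_size)
  coeffs[is.na(coeffs)] <- 0
  if (spec$shape_noise_amplitude > 0) {
    nterms <- (lmax_gen + 1)^2 - 1
    # orthonormal basis: radial variance = sum of squared coefficients / (4 pi)
    amp <- spec$shape_noise_amplitude * spec$cell_base_radius * voxel_size
    pert <- rnorm(nterms, sd = amp * sqrt(4 * pi / nterms))
    coeffs[-1] <- coeffs[-1] + pert
  }
  coeffs
}

#' Generate one synthetic cell and nucleus mask pair
#'
#' The cell surface is a randomized low-degree SHE shape; the nucleus is the
#' same shape scaled by `nucleus_volume_fraction^(1/3)` and shifted by
#' `nucleus_offset`, so the planted volume ratio is exact in the continuum.
#' An offset that would push the nucleus through the cell boundary is
#' rejected with an error.
#'
#' @param spec A [synthetic_cell_spec()].
#' @param voxel_size Voxel edge, micrometres.
#' @return List with logical arrays `cell` and `nucleus` (same dimensions,
#'   >= 2 voxel margin), `center` (cell-surface centre, voxels), and the true
#'   generating `cell_coeffs` / `nucleus_coeffs`.
#' @export
generate_cell_shape <- function(spec, voxel_size = DEFAULT_VOXEL_SIZE) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  with_seed(spec$seed, {
    cv <- synthetic_surface_coeffs(spec, voxel_size)
    s <- spec$nucleus_volume_fraction^(1 / 3)
    nv <- cv * s
    tab <- sh_radius_table(cv, 4L) / voxel_size # voxels
    ext <- apply(abs(cbind(
      tab * rep(sin(seq(0, pi, length.out = nrow(tab))), ncol(tab)) *
        cos(rep(seq(0, 2 * pi, length.out = ncol(tab)), each = nrow(tab))),
      tab * rep(sin(seq(0, pi, length.out = nrow(tab))), ncol(tab)) *
        sin(rep(seq(0, 2 * pi, length.out = ncol(tab)), each = nrow(tab))),
      tab * rep(cos(seq(0, pi, length.out = nrow(tab))), ncol(tab))
    )), 2, max)
    margin <- 4
    # square xy footprint so later in-plane rotations can never clip the cell
    ext_xy <- max(ext[1], ext[2]) + max(abs(spec$nucleus_offset[1:2]))
    dims <- 2 * ceiling(c(ext_xy, ext_xy, ext[3] + abs(spec$nucleus_offset[3]))) +
      2 * margin + 1
    center <- (dims + 1) / 2
    cell_sh <- new_she_coeffs(cv, 4L, "cell", c(0, 0, 0),
                              origin_vox = center, voxel_size = voxel_size)
    nuc_sh <- new_she_coeffs(nv, 4L, "nucleus", spec$nucleus_offset * voxel_size,
                             origin_vox = center, voxel_size = voxel_size)
    cell <- voxelize_coeffs(cell_sh, dims, origin_vox = center)
    nucleus <- voxelize_coeffs(nuc_sh, dims, origin_vox = center)
    if (any(nucleus & !cell))
      stop("nucleus would intersect the cell boundary given this offset/volume fraction")
    list(cell = cell, nucleus = nucleus, center = center,
         cell_coeffs = cell_sh, nucleus_coeffs = nuc_sh, spec = spec)
  })
}

# one-voxel-thick inner boundary layer of a mask, repeated `thickness` times
boundary_band <- function(mask, thickness = 2L) {
  d <- dim(mask)
  inner <- mask
  band <- array(FALSE, d)
  for (t in seq_len(thickness)) {
    shifted <- array(TRUE, d)
    layer <- array(FALSE, d)
    # voxel is boundary if any 6-neighbour is outside `inner`
    for (ax in 1:3) for (dir in c(-1L, 1L)) {
      nb <- array(FALSE, d)
      idx_src <- lapply(d, seq_len)
      idx_dst <- idx_src
      n <- d[ax]
      if (dir == 1L) { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
      else { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
      nb <- do.call(`[<-`, c(list(nb), idx_dst, list(do.call(`[`, c(list(inner), idx_src)))))
      # nb = neighbour-inside indicator; boundary where inner & !nb
      layer <- layer | (inner & !nb)
    }
    # faces touching the array edge count as boundary too
    edge <- array(FALSE, d)
    edge[c(1, d[1]), , ] <- TRUE; edge[, c(1, d[2]), ] <- TRUE; edge[, , c(1, d[3])] <- TRUE
    layer <- layer | (inner & edge)
    band <- band | layer
    inner <- inner & !layer
  }
  band
}

stamp_spheres <- function(dims, centers, radius) {
  out <- array(FALSE, dims)
  if (nrow(centers) == 0) return(out)
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius, dz = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= radius^2, ]
  for (k in seq_len(nrow(centers))) {
    px <- centers[k, 1] + off$dx; py <- centers[k, 2] + off$dy; pz <- centers[k, 3] + off$dz
    ok <- px >= 1 & px <= dims[1] & py >= 1 & py <= dims[2] & pz >= 1 & pz <= dims[3]
    out[cbind(px[ok], py[ok], pz[ok])] <- TRUE
  }
  out
}

#' Generate a planted structure mask inside a synthetic cell
#'
#' @param pattern A [structure_pattern()].
#' @param cell,nucleus Masks from [generate_cell_shape()].
#' @return Logical 3D array; structure voxels lie only in the compartment
#'   implied by `pattern$kind`.
#' @export
generate_structure <- function(pattern, cell, nucleus) {
  stopifnot(inherits(pattern, "structure_pattern"))
  dims <- dim(cell)
  cytoplasm <- cell & !nucleus
  compartment <- switch(pattern$kind,
    punctate = , polarized_punctate = , reticular = cytoplasm,
    nuclear = nucleus,
    membrane_shell = boundary_band(cell, 2L))
  if (sum(compartment) == 0)
    stop(sprintf("empty compartment for pattern kind '%s'", pattern$kind))
  if (pattern$density == 0) return(array(FALSE, dims))
  with_seed(pattern$seed, {
    vox <- which(compartment, arr.ind = TRUE)
    out <- switch(pattern$kind,
      punctate = , nuclear = , polarized_punctate = {
        n <- max(1L, round(pattern$density))
        w <- NULL
        if (pattern$kind == "polarized_punctate" && pattern$polarization_bias > 0) {
          x <- vox[, 1]
          sx <- max(sd(x), 1e-8)
          w <- exp(pattern$polarization_bias * (x - mean(x)) / sx)
        }
        pick <- sample.int(nrow(vox), size = n, replace = n > nrow(vox), prob = w)
        stamp_spheres(dims, vox[pick, , drop = FALSE], pattern$punct_radius) & compartment
      },
      membrane_shell = {
        frac <- min(pattern$density, 1)
        keep <- array(FALSE, dims)
        n <- round(frac * nrow(vox))
        if (n > 0) {
          pick <- if (frac >= 1) seq_len(nrow(vox)) else sample.int(nrow(vox), n)
          keep[vox[pick, , drop = FALSE]] <- TRUE
        }
        keep
      },
      reticular = {
        frac <- min(pattern$density, 1)
        target <- frac * nrow(vox)
        keep <- array(FALSE, dims)
        it <- 0L
        while (sum(keep) < target && it < 10000L) {
          it <- it + 1L
          start <- vox[sample.int(nrow(vox), 1), ]
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          len <- runif(1, 5, 15)
          tpts <- seq(0, len, by = 0.5)
          px <- round(start[1] + u[1] * tpts)
          py <- round(start[2] + u[2] * tpts)
          pz <- round(start[3] + u[3] * tpts)
          ok <- px >= 1 & px <= dims[1] & py >= 1 & py <= dims[2] & pz >= 1 & pz <= dims[3]
          pts <- cbind(px[ok], py[ok], pz[ok])
          inside <- compartment[pts]
          keep[pts[inside, , drop = FALSE]] <- TRUE
        }
        keep
      })
    out
  })
}

#' Generate a synthetic population with manifest
#'
#' Draws per-cell shape parameters uniformly from `spec_ranges`, assigns the
#' supplied patterns to cells round-robin (one tagged structure per cell, as
#' in real single-structure-tagged lines), writes one serialized mask per
#' channel plus a CSV manifest with paths relative to the manifest, and
#' returns the manifest. Fully reproducible under `seed`: rerunning into a
#' fresh directory produces byte-identical files.
#'
#' @param n Number of cells (>= 1).
#' @param dir Output directory (created if needed).
#' @param patterns List of [structure_pattern()]; each must be named via
#'   `names(patterns)` (the structure vocabulary) or default names are used.
#' @param spec_ranges Named list of `c(min, max)` ranges overriding
#'   [synthetic_cell_spec()] defaults for `cell_base_radius`,
#'   `shape_noise_amplitude`, `nucleus_volume_fraction`, `aspect_x`,
#'   `nucleus_offset_x/y/z`.
#' @param population Population label for all rows.
#' @param seed Master seed; all per-cell seeds derive from it.
#' @param keep_images Also return the in-memory images (for tests).
#' @return data.frame manifest (columns cell_id, population, structure_name,
#'   path_cell, path_nucleus, path_structure, seed), invisibly carrying the
#'   images in attribute `"images"` when `keep_images`.
#' @export
generate_population <- function(n, dir, patterns = list(punctate = structure_pattern()),
                                spec_ranges = list(), population = "baseline",
                                seed = 1L, keep_images = FALSE) {
  stopifnot(n >= 1)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop(sprintf("cannot create output directory '%s'", dir))
  }
  if (file.access(dir, 2) != 0) stop(sprintf("output directory '%s' is not writable", dir))
  if (is.null(names(patterns)))
    names(patterns) <- paste0("structure", seq_along(patterns))
  rng <- function(name, default) {
    r <- spec_ranges[[name]]
    if (is.null(r)) c(default, default) else r
  }
  rows <- vector("list", n)
  images <- if (keep_images) vector("list", n)
  with_seed(seed, {
    cell_seeds <- sample.int(.Machine$integer.max %/% 2, 2 * n)
    draws <- matrix(runif(7 * n), ncol = 7)
  })
  for (i in seq_len(n)) {
    u <- draws[i, ]
    lerp <- function(name, default, ui) {
      r <- rng(name, default); r[1] + ui * (r[2] - r[1])
    }
    spec <- synthetic_cell_spec(
      cell_base_radius = lerp("cell_base_radius", 12, u[1]),
      aspect_ratios = c(lerp("aspect_x", 1.4, u[2]), 1.0,
                        lerp("aspect_z", 0.9, u[3])),
      shape_noise_amplitude = lerp("shape_noise_amplitude", 0.05, u[4]),
      nucleus_volume_fraction = lerp("nucleus_volume_fraction", 0.25, u[5]),
      nucleus_offset = c(lerp("nucleus_offset_x", 0, u[6]),
                         lerp("nucleus_offset_y", 0, u[7]), 0),
      seed = cell_seeds[i])
    shp <- generate_cell_shape(spec)
    pat <- patterns[[(i - 1) %% length(patterns) + 1]]
    pat$seed <- cell_seeds[n + i]
    str_mask <- generate_structure(pat, shp$cell, shp$nucleus)
    cid <- sprintf("%s_cell%03d", population, i)
    paths <- sprintf("%s_%s.rds", cid, c("cell", "nucleus", "structure"))
    saveRDS(shp$cell, file.path(dir, paths[1]), version = 2)
    saveRDS(shp$nucleus, file.path(dir, paths[2]), version = 2)
    saveRDS(str_mask, file.path(dir, paths[3]), version = 2)
    rows[[i]] <- data.frame(
      cell_id = cid, population = population,
      structure_name = names(patterns)[(i - 1) %% length(patterns) + 1],
      path_cell = paths[1], path_nucleus = paths[2], path_structure = paths[3],
      seed = cell_seeds[i])
    if (keep_images)
      images[[i]] <- list(cell = shp$cell, nucleus = shp$nucleus,
                          structure = str_mask, spec = spec)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (keep_images) attr(manifest, "images") <- images
  invisible(manifest)
}

#' Read a mask written by the generator
#' @param path Path to a serialized mask.
#' @export
read_mask <- function(path) readRDS(path)
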