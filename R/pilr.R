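#' @title Parameterized intracellular location representation (PILR)
#' @description Interpolates SHE coefficients into concentric shells from the
#'   nuclear centroid to the nuclear boundary and on to the cell boundary,
#'   samples structure presence (or intensity) at every shell mesh point into
#'   a shells x grid matrix, morphs PILRs into arbitrary cell/nuclear shapes,
#'   and averages PILRs across cells.
#' @name pilr
NULL

#' Degenerate SHE set for the nuclear-centroid sphere
#'
#' The innermost shell of the family: a one-voxel-radius (0.108 um by
#' default) sphere centred at the nuclear centroid, expressed as an l = 0-only
#' coefficient set at the nucleus's lmax.
#'
#' @param nucleus `she_coeffs` of the nuclear surface.
#' @param radius Sphere radius in micrometres (default one voxel edge).
#' @return `she_coeffs` with `c00 = radius * sqrt(4 pi)` and the nuclear
#'   centroid offset.
#' @export
nuclear_centroid_coeffs <- function(nucleus, radius = nucleus$voxel_size) {
  stopifnot(inherits(nucleus, "she_coeffs"))
  coeffs <- numeric(length(nucleus$coeffs))
  coeffs[1] <- radius * sqrt(4 * pi)
  new_she_coeffs(coeffs, nucleus$lmax, "nuclear_centroid",
                 nucleus$centroid_offset, origin_vox = nucleus$origin_vox,
                 voxel_size = nucleus$voxel_size)
}

#' Interpolate between two SHE coefficient sets
#'
#' Linear interpolation in coefficient space (centroid offsets included) at
#' `n_shells` evenly spaced fractions in [0, 1]; the endpoints reproduce
#' `inner` and `outer` exactly.
#'
#' @param inner,outer `she_coeffs` sharing the same lmax.
#' @param n_shells Number of shells (>= 2).
#' @return List of `she_coeffs`, ordered inside-out.
#' @export
interpolate_shells <- function(inner, outer, n_shells) {
  stopifnot(inherits(inner, "she_coeffs"), inherits(outer, "she_coeffs"), n_shells >= 2)
  if (inner$lmax != outer$lmax)
    stop(sprintf("lmax mismatch: %d vs %d", inner$lmax, outer$lmax))
  fr <- seq(0, 1, length.out = n_shells)
  lapply(fr, function(t) {
    new_she_coeffs((1 - t) * inner$coeffs + t * outer$coeffs, inner$lmax,
                   sprintf("shell_%0.3f", t),
                   (1 - t) * inner$centroid_offset + t * outer$centroid_offset,
                   origin_vox = inner$origin_vox %||% outer$origin_vox,
                   voxel_size = inner$voxel_size)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the concentric shell family of one cell
#'
#' `n_nuclear` shells run from the one-voxel nuclear-centroid sphere (shell 1)
#' to the nuclear surface (shell `n_nuclear`); `n_cyto` further shells run
#' from just outside the nuclear surface to the cell surface (last shell).
#'
#' @param cell,nucleus `she_coeffs` of the two surfaces (same lmax; the
#'   nucleus carries its centroid offset relative to the cell centroid).
#' @param n_nuclear,n_cyto Shell counts (defaults 32 and 64).
#' @param grid `c(nlat, nlon)` angular grid per shell (default 32 x 64).
#' @return A `shell_family`.
#' @export
shell_family <- function(cell, nucleus, n_nuclear = 32L, n_cyto = 64L,
                         grid = c(32L, 64L)) {
  stopifnot(inherits(cell, "she_coeffs"), inherits(nucleus, "she_coeffs"))
  inner <- nuclear_centroid_coeffs(nucleus)
  nuc_shells <- interpolate_shells(inner, nucleus, n_nuclear)
  cyto_all <- interpolate_shells(nucleus, cell, n_cyto + 1L)
  shells <- c(nuc_shells, cyto_all[-1])
  structure(list(shells = shells, n_nuclear = as.integer(n_nuclear),
                 n_cyto = as.integer(n_cyto), grid = as.integer(grid),
                 cell = cell, nucleus = nucleus,
                 origin_vox = cell$origin_vox, voxel_size = cell$voxel_size),
            class = "shell_family")
}

pilr_grid_directions <- function(grid) {
  nlat <- grid[1]; nlon <- grid[2]
  theta <- (seq_len(nlat) - 0.5) * pi / nlat
  phi <- (seq_len(nlon) - 1) * 2 * pi / nlon
  list(theta = rep(theta, each = nlon), phi = rep(phi, times = nlat),
       nlat = nlat, nlon = nlon)
}

# radii (micrometres) of every shell at the PILR grid directions: G x S matrix
shell_radii_matrix <- function(fam, directions = pilr_grid_directions(fam$grid)) {
  lmax <- fam$cell$lmax
  B <- sh_basis(directions$theta, directions$phi, lmax)
  C <- vapply(fam$shells, function(s) as.numeric(s$coeffs),
              numeric((lmax + 1)^2))
  B %*% C
}

shell_offsets_matrix <- function(fam) {
  t(vapply(fam$shells, function(s) s$centroid_offset, numeric(3))) # S x 3, um
}

#' Sample a structure channel onto the shell family (build the PILR)
#'
#' `values[i, j]` is the structure value at the voxel nearest to mesh point j
#' of shell i in the aligned image frame. Mesh points falling outside the
#' image sample 0 and are counted in `oob_count`.
#'
#' @param structure Aligned 3D structure mask (binary mode) or intensity
#'   image (intensity mode).
#' @param fam `shell_family` of the same cell in the same aligned frame.
#' @param mode `"binary"` (presence/absence) or `"intensity"`.
#' @param cell_id Optional provenance id.
#' @return A `pilr` object: `values` (shells x grid points),
#'   `compartment_split` (= `n_nuclear`, last nuclear row), grid shape and
#'   metadata.
#' @export
sample_pilr <- function(structure, fam, mode = c("binary", "intensity"),
                        cell_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(fam, "shell_family"))
  if (is.null(fam$origin_vox))
    stop("shell family lacks an image-frame origin (origin_vox)")
  d <- dim(structure)
  dirs <- pilr_grid_directions(fam$grid)
  R <- shell_radii_matrix(fam, dirs) # G x S, um
  offs <- shell_offsets_matrix(fam) # S x 3, um
  S <- length(fam$shells); G <- length(dirs$theta)
  ux <- sin(dirs$theta) * cos(dirs$phi)
  uy <- sin(dirs$theta) * sin(dirs$phi)
  uz <- cos(dirs$theta)
  vs <- fam$voxel_size
  px <- round(sweep(R * ux, 2, offs[, 1], "+") / vs + fam$origin_vox[1])
  py <- round(sweep(R * uy, 2, offs[, 2], "+") / vs + fam$origin_vox[2])
  pz <- round(sweep(R * uz, 2, offs[, 3], "+") / vs + fam$origin_vox[3])
  ok <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] & pz >= 1 & pz <= d[3]
  vals <- matrix(0, G, S)
  lin <- (px[ok] - 1) + (py[ok] - 1) * d[1] + (pz[ok] - 1) * d[1] * d[2] + 1
  vals[ok] <- as.numeric(structure[lin])
  if (mode == "binary") vals <- (vals != 0) * 1
  structure(list(values = t(vals), compartment_split = fam$n_nuclear,
                 grid = fam$grid, n_nuclear = fam$n_nuclear,
                 n_cyto = fam$n_cyto, mode = mode,
                 source_cell_id = cell_id, oob_count = sum(!ok)),
            class = "pilr")
}

#' @export
print.pilr <- function(x, ...) {
  cat(sprintf("PILR: %d shells (%d nuclear + %d cytoplasmic) x %d grid points [%s]\n",
              nrow(x$values), x$n_nuclear, x$n_cyto, ncol(x$values), x$mode))
  if (x$oob_count > 0) cat("  out-of-bounds mesh points:", x$oob_count, "\n")
  invisible(x)
}

#' Average PILRs elementwise
#' @param pilrs List of `pilr` objects of identical discretization.
#' @return A `pilr` whose values are the elementwise mean (in [0, 1] for
#'   binary inputs).
#' @export
average_pilr <- function(pilrs) {
  stopifnot(length(pilrs) >= 1)
  ref <- pilrs[[1]]
  for (p in pilrs)
    if (!identical(dim(p$values), dim(ref$values)) ||
        p$compartment_split != ref$compartment_split)
      stop("PILR shape mismatch: all PILRs must share discretization")
  avg <- Reduce(`+`, lapply(pilrs, `[[`, "values")) / length(pilrs)
  out <- ref
  out$values <- avg
  out$mode <- paste0("average_", ref$mode)
  out$source_cell_id <- NULL
  out
}

#' Flatten a PILR to a numeric vector
#' @param pilr `pilr` object.
#' @export
pilr_flatten <- function(pilr) as.numeric(pilr$values)

# precomputed lookup machinery for inverse-mapped morphing
shell_lookup_tables <- function(fam, nlat_tab = 65L, nlon_tab = 129L) {
  lmax <- fam$cell$lmax
  B <- sh_table_basis(lmax, nlat_tab, nlon_tab)
  C <- vapply(fam$shells, function(s) as.numeric(s$coeffs), numeric((lmax + 1)^2))
  array(B %*% C, dim = c(nlat_tab, nlon_tab, length(fam$shells)))
}

#' Morph a PILR into a target cell and nuclear shape
#'
#' Inverse mapping: every voxel inside the target cell is assigned the PILR
#' value of its nearest (shell, grid point) coordinate under the target
#' shape's shell family, found by bisection over the nested shells. This is
#' hole-free and deterministic, and nuclear PILR rows land inside the target
#' nucleus while cytoplasmic rows land between the nuclear and cell surfaces.
#'
#' @param pilr `pilr` to morph.
#' @param target `shell_family` of the target shape (same shell counts and
#'   grid as the PILR).
#' @param dim Optional output array dimensions; computed from the target cell
#'   extent when missing.
#' @return A `morphed_cell`: `values` (3D numeric array, nonzero only inside
#'   the target cell mask), `cell_mask`, `nucleus_mask`, `origin_vox`.
#' @export
morph_pilr <- function(pilr, target, dim = NULL) {
  stopifnot(inherits(pilr, "pilr"), inherits(target, "shell_family"))
  if (pilr$n_nuclear != target$n_nuclear || pilr$n_cyto != target$n_cyto ||
      !identical(as.integer(pilr$grid), as.integer(target$grid)))
    stop("PILR discretization is incompatible with the target shell family")
  vs <- target$voxel_size
  if (is.null(dim)) {
    tab <- sh_radius_table(target$cell$coeffs, target$cell$lmax) / vs
    rmax <- max(tab) + max(abs(target$cell$centroid_offset)) / vs
    dim <- rep(2 * ceiling(rmax) + 7, 3)
  }
  origin <- (dim + 1) / 2
  cellc <- target$cell; nucc <- target$nucleus
  cell_mask <- voxelize_coeffs(cellc, dim, origin_vox = origin)
  nuc_mask <- voxelize_coeffs(nucc, dim, origin_vox = origin)
  outside <- nuc_mask & !cell_mask
  if (sum(outside) > 0.005 * max(1, sum(nuc_mask)))
    stop("target nucleus is not inside the target cell")
  nuc_mask <- nuc_mask & cell_mask
  S <- length(target$shells)
  radtab <- shell_lookup_tables(target) / vs # voxels
  offs <- shell_offsets_matrix(target) / vs # voxels
  nlat_tab <- nrow(radtab); nlon_tab <- dim(radtab)[2]
  vox <- which(cell_mask, arr.ind = TRUE)
  nv <- nrow(vox)
  lo <- rep(0L, nv); hi <- rep(S, nv) # invariant: inside shell hi, not inside lo
  while (any(hi - lo > 1L)) {
    mid <- (lo + hi) %/% 2L
    act <- which(hi - lo > 1L)
    for (m in unique(mid[act])) {
      sel <- act[mid[act] == m]
      sub <- inside_shell_subset(vox, sel, m, origin, offs, radtab, nlat_tab, nlon_tab)
      hi[sel[sub]] <- m
      lo[sel[!sub]] <- m
    }
  }
  shell_idx <- hi
  # grid point on the assigned shell
  dxa <- vox[, 1] - (origin[1] + offs[shell_idx, 1])
  dya <- vox[, 2] - (origin[2] + offs[shell_idx, 2])
  dza <- vox[, 3] - (origin[3] + offs[shell_idx, 3])
  ra <- sqrt(dxa^2 + dya^2 + dza^2)
  theta <- acos(pmin(pmax(ifelse(ra > 0, dza / ra, 1), -1), 1))
  phi <- atan2(dya, dxa) %% (2 * pi)
  nlat <- target$grid[1]; nlon <- target$grid[2]
  gi <- pmin(pmax(ceiling(theta / pi * nlat), 1), nlat)
  gj <- (floor(phi / (2 * pi) * nlon + 0.5) %% nlon) + 1
  gidx <- (gi - 1) * nlon + gj
  vals <- pilr$values[cbind(shell_idx, gidx)]
  out <- array(0, dim)
  out[vox] <- vals
  structure(list(values = out, cell_mask = cell_mask, nucleus_mask = nuc_mask,
                 origin_vox = origin,
                 provenance = list(source_cell_id = pilr$source_cell_id,
                                   mode = pilr$mode)),
            class = "morphed_cell")
}

# vectorized inside-shell test for a subset of voxels against one shell
inside_shell_subset <- function(vox, sel, shell_idx, origin, offs, radtab,
                                nlat_tab, nlon_tab) {
  dx <- vox[sel, 1] - (origin[1] + offs[shell_idx, 1])
  dy <- vox[sel, 2] - (origin[2] + offs[shell_idx, 2])
  dz <- vox[sel, 3] - (origin[3] + offs[shell_idx, 3])
  r <- sqrt(dx^2 + dy^2 + dz^2)
  theta <- acos(pmin(pmax(ifelse(r > 0, dz / r, 1), -1), 1))
  phi <- atan2(dy, dx) %% (2 * pi)
  ti <- pmin(pmax(round(theta / pi * (nlat_tab - 1)) + 1, 1), nlat_tab)
  pj <- pmin(pmax(round(phi / (2 * pi) * (nlon_tab - 1)) + 1, 1), nlon_tab)
  lin <- ti + (pj - 1) * nlat_tab + (shell_idx - 1) * nlat_tab * nlon_tab
  r <= radtab[lin]
}

#' @export
print.morphed_cell <- function(x, ...) {
  cat(sprintf("morphed_cell: %s, %d voxels in target cell, %d nonzero\n",
              paste(dim(x$values), collapse = "x"), sum(x$cell_mask),
              sum(x$values != 0)))
  invisible(x)
}

#' Binary structure mask of a morphed cell
#' @param morphed `morphed_cell`.
#' @param threshold Values > threshold count as structure (default 0.5 for
#'   averaged PILRs; use 0 for single-cell binary PILRs).
#' @export
morphed_mask <- function(morphed, threshold = 0) {
  morphed$values > threshold
}
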