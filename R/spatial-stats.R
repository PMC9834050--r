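#' @title Location similarity, stereotypy and concordance
#' @description Pixel-wise Pearson-correlation statistics over PILRs:
#'   average location similarity between structures (and its hierarchical
#'   clustering), per-cell pairwise correlations, location stereotypy
#'   (within-structure mean pairwise correlation) and location concordance
#'   (cross-structure mean pairwise correlation), per-map-point versions of
#'   each, and the structure-volume scaling analysis.
#' @name spatial_stats
NULL

#' Average location similarity matrix
#'
#' Entry (a, b) is the pixel-wise Pearson correlation between the flattened
#' average PILRs of structures a and b.
#'
#' @param avg_pilrs Named list of average `pilr` objects (one per structure).
#' @return Symmetric correlation matrix with unit diagonal; a zero-variance
#'   average PILR gives NA entries, with the reason recorded in attribute
#'   `"missing"`.
#' @export
location_similarity <- function(avg_pilrs) {
  stopifnot(length(avg_pilrs) >= 2, !is.null(names(avg_pilrs)))
  M <- vapply(avg_pilrs, pilr_flatten, numeric(length(pilr_flatten(avg_pilrs[[1]]))))
  sds <- apply(M, 2, sd)
  bad <- names(avg_pilrs)[sds == 0]
  sim <- suppressWarnings(cor(M))
  diag(sim) <- 1
  if (length(bad))
    attr(sim, "missing") <- stats::setNames(
      rep("zero-variance average PILR", length(bad)), bad)
  sim
}

#' Cluster structures by their average location similarity profiles
#'
#' Average-linkage agglomerative clustering of the similarity matrix, each
#' structure represented by its row of similarities to all structures
#' (Euclidean distance between profile rows).
#'
#' @param similarity Complete similarity matrix from [location_similarity()].
#' @return An `hclust` dendrogram with one leaf per structure.
#' @export
cluster_structures <- function(similarity) {
  if (any(is.na(similarity))) {
    bad <- which(is.na(similarity), arr.ind = TRUE)
    stop(sprintf("similarity matrix has missing entries: %s",
                 paste(unique(rownames(similarity)[bad[, 1]]), collapse = ", ")))
  }
  hclust(dist(similarity), method = "average")
}

#' Export a dendrogram as Newick
#' @param hc `hclust` from [cluster_structures()].
#' @param path Optional output file.
#' @return Newick string (invisibly when written to file).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tr <- ape::as.phylo(hc)
  if (!is.null(path)) {
    ape::write.tree(tr, file = path)
    return(invisible(ape::write.tree(tr)))
  }
  ape::write.tree(tr)
}

#' Pairwise PILR correlations between individual cells
#'
#' @param pilrs Named list of per-cell `pilr` objects, or a cells x pixels
#'   numeric matrix of flattened PILRs with rownames.
#' @return Symmetric n x n Pearson correlation matrix. Cells with
#'   zero-variance PILRs are excluded and reported in attribute
#'   `"excluded"`.
#' @export
pairwise_cell_correlations <- function(pilrs) {
  M <- if (is.matrix(pilrs)) pilrs else {
    stopifnot(!is.null(names(pilrs)))
    t(vapply(pilrs, pilr_flatten, numeric(length(pilr_flatten(pilrs[[1]])))))
  }
  sds <- apply(M, 1, sd)
  excluded <- rownames(M)[sds == 0]
  M <- M[sds > 0, , drop = FALSE]
  if (nrow(M) < 2) stop("need at least 2 cells with non-constant PILRs")
  cc <- cor(t(M))
  attr(cc, "excluded") <- excluded
  cc
}

#' Location stereotypy and concordance from a cell correlation matrix
#'
#' Averages the per-cell-pair PILR correlations within each pair of
#' structures. The diagonal is the location stereotypy of a structure (mean
#' over distinct unordered within-structure cell pairs, self-correlations
#' excluded); off-diagonals are the location concordance of two structures
#' (mean over all cross-structure cell pairs).
#'
#' @param cellcor Cell x cell correlation matrix from
#'   [pairwise_cell_correlations()].
#' @param labels Structure label per cell (named by cell id or aligned with
#'   `rownames(cellcor)`).
#' @return List of class `avg_correlation_matrix` with `values`
#'   (structure x structure), `n_pairs`, and `missing` reasons; a structure
#'   with a single cell has undefined stereotypy (NA).
#' @export
stereotypy_concordance <- function(cellcor, labels) {
  ids <- rownames(cellcor)
  if (!is.null(names(labels)) && !is.null(ids)) labels <- labels[ids]
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(cellcor))
  structs <- sort(unique(labels))
  k <- length(structs)
  vals <- matrix(NA_real_, k, k, dimnames = list(structs, structs))
  npairs <- matrix(0L, k, k, dimnames = list(structs, structs))
  missing <- character()
  for (i in seq_len(k)) for (j in i:k) {
    ai <- which(labels == structs[i]); aj <- which(labels == structs[j])
    if (i == j) {
      if (length(ai) < 2) {
        missing[structs[i]] <- "stereotypy undefined: structure has a single cell"
        next
      }
      block <- cellcor[ai, ai, drop = FALSE]
      ut <- block[upper.tri(block)]
      vals[i, i] <- mean(ut)
      npairs[i, i] <- length(ut)
    } else {
      block <- cellcor[ai, aj, drop = FALSE]
      vals[i, j] <- vals[j, i] <- mean(block)
      npairs[i, j] <- npairs[j, i] <- length(block)
    }
  }
  structure(list(values = vals, n_pairs = npairs, labels = structs,
                 missing = missing),
            class = "avg_correlation_matrix")
}

#' @export
print.avg_correlation_matrix <- function(x, ...) {
  cat(sprintf("avg_correlation_matrix over %d structures\n", length(x$labels)))
  print(round(x$values, 3))
  invisible(x)
}

#' Per-map-point statistics
#'
#' Recomputes a location statistic within every map point bin along every
#' requested shape mode. A bin where any involved structure has fewer than
#' `min_cells` cells (2 for stereotypy is still subject to `min_cells`) is
#' reported missing rather than zero.
#'
#' @param pilrs Named list of per-cell `pilr` objects.
#' @param labels Structure per cell (named by cell id).
#' @param coords Sigma-unit shape coordinates (rownames = cell ids).
#' @param statistic `"similarity"`, `"stereotypy_concordance"`.
#' @param modes Mode indices to sweep (default all).
#' @param min_cells Minimum cells per structure per bin (default 5).
#' @return Nested list `result[[mode]][[center]]`: the statistic matrix, or
#'   `NULL` with the reason in `attr(result, "missing")`.
#' @export
per_mappoint_statistics <- function(pilrs, labels, coords,
                                    statistic = c("similarity", "stereotypy_concordance"),
                                    modes = seq_len(ncol(coords)), min_cells = 5) {
  statistic <- match.arg(statistic)
  ids <- names(pilrs)
  labels <- labels[ids]
  out <- list()
  missing <- character()
  for (mode in modes) {
    bins <- bin_cells(coords, mode)
    res <- list()
    for (cname in names(bins)) {
      members <- intersect(bins[[cname]], ids)
      key <- sprintf("mode%d@%s", mode, trimws(cname))
      counts <- table(labels[members])
      usable <- names(counts)[counts >= min_cells]
      if (length(usable) < 2) {
        missing[key] <- sprintf("fewer than 2 structures with >= %d cells", min_cells)
        res[[cname]] <- NULL
        next
      }
      sel <- members[labels[members] %in% usable]
      if (statistic == "similarity") {
        avg <- lapply(stats::setNames(usable, usable), function(s)
          average_pilr(pilrs[sel[labels[sel] == s]]))
        res[[cname]] <- location_similarity(avg)
      } else {
        cc <- pairwise_cell_correlations(pilrs[sel])
        res[[cname]] <- stereotypy_concordance(cc, labels[sel])
      }
    }
    out[[paste0("mode", mode)]] <- res
  }
  attr(out, "missing") <- missing
  out
}

#' Structure-volume scaling against cell and nuclear size metrics
#'
#' Linear model of structure volume on the five size metrics (cell volume,
#' cell surface area, nuclear volume, nuclear surface area, cytoplasmic
#' volume, or any metric set supplied). Reports the total R-squared of the
#' all-metrics model and each metric's unique contribution, the drop in
#' R-squared when that metric is removed and the model refitted.
#'
#' @param structure_volume Numeric response vector (>= 30 cells).
#' @param metrics data.frame / matrix of positive size metrics (same rows).
#' @return List with `total_r2`, `unique_contribution` (named per metric)
#'   and `collinearity_warning`.
#' @export
volume_scaling <- function(structure_volume, metrics) {
  metrics <- as.data.frame(metrics)
  n <- length(structure_volume)
  stopifnot(nrow(metrics) == n)
  if (n < 30) stop(sprintf("need >= 30 cells for volume scaling, got %d", n))
  if (any(metrics <= 0)) stop("size metrics must be positive")
  dat <- cbind(v = structure_volume, metrics)
  full <- lm(v ~ ., data = dat)
  r2_full <- summary(full)$r.squared
  collinear <- qr(as.matrix(metrics))$rank < ncol(metrics)
  if (collinear)
    warning("size metrics are collinear; unique contributions are not well separated")
  uniq <- vapply(names(metrics), function(m) {
    red <- lm(v ~ ., data = dat[, c("v", setdiff(names(metrics), m))])
    r2_full - summary(red)$r.squared
  }, numeric(1))
  list(total_r2 = r2_full, unique_contribution = uniq,
       collinearity_warning = collinear)
}

#' Write a labeled statistic matrix as CSV
#' @param mat Matrix (or `avg_correlation_matrix`).
#' @param path Output CSV.
#' @export
write_stat_matrix <- function(mat, path) {
  if (inherits(mat, "avg_correlation_matrix")) mat <- mat$values
  write.csv(as.data.frame(mat), path, row.names = TRUE)
  invisible(path)
}
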