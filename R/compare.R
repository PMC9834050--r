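#' @title Shape-matched population comparison
#' @description Nearest-neighbour shape matching of a query population to a
#'   baseline in 8D shape space, the PCA+LDA average-location-phenotype axis
#'   over PILRs, and the stereotypy/concordance significance-flagging and
#'   timing-of-change (TOC) workflow across interphase -> prophase (m1) ->
#'   early prometaphase (m2).
#' @name population_compare
NULL

#' Shape-match a query population to a baseline
#'
#' For every query cell, the baseline cell at minimum Euclidean distance in
#' shape space is flagged (ties broken by the lexicographically lowest
#' baseline cell id). The shape-matched dataset is the unique set of flagged
#' baseline cells combined with the query cells.
#'
#' @param baseline,query Sigma-unit coordinate matrices (rownames = cell
#'   ids); the query must be projected with the baseline model, without
#'   percentile exclusion.
#' @return A `shape_matched_dataset`: `matched_baseline_ids` (unique),
#'   `nn_id` per query, `duplicate_flag_count` (queries whose nearest
#'   neighbour was already flagged), `combined_mean` coordinates.
#' @export
match_shapes <- function(baseline, query) {
  baseline <- as.matrix(baseline); query <- as.matrix(query)
  if (nrow(baseline) == 0) stop("baseline dataset is empty")
  bid <- rownames(baseline) %||% as.character(seq_len(nrow(baseline)))
  qid <- rownames(query) %||% as.character(seq_len(nrow(query)))
  ord <- order(bid)
  baseline <- baseline[ord, , drop = FALSE]; bid <- bid[ord]
  b2 <- rowSums(baseline^2)
  nn <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    d2 <- b2 - 2 * as.numeric(baseline %*% query[i, ]) + sum(query[i, ]^2)
    nn[i] <- bid[which.min(d2)] # first minimum = lowest id after sort
  }
  dup <- sum(duplicated(nn))
  uniq <- unique(nn)
  combined <- rbind(baseline[match(uniq, bid), , drop = FALSE], query)
  structure(list(query_cell_ids = qid, nn_id = stats::setNames(nn, qid),
                 matched_baseline_ids = uniq, duplicate_flag_count = dup,
                 combined_mean = colMeans(combined),
                 combined_ids = c(uniq, qid)),
            class = "shape_matched_dataset")
}

#' @export
print.shape_matched_dataset <- function(x, ...) {
  cat(sprintf(
    "shape_matched_dataset: %d query cells, %d unique matched baseline cells (%d duplicate flags, %.1f%%)\n",
    length(x$query_cell_ids), length(x$matched_baseline_ids),
    x$duplicate_flag_count,
    100 * x$duplicate_flag_count / max(1, length(x$query_cell_ids))))
  invisible(x)
}

#' Fit the PCA+LDA average-location-phenotype axis
#'
#' PILRs are reduced by PCA to `min(32, n)` dimensions (n = cells available),
#' then a two-class Fisher linear discriminant finds the direction in reduced
#' space that best separates the two populations. The discriminant direction
#' is unit-norm, oriented so the second population's mean is positive, and
#' axis positions are z-scored by the pooled projection standard deviation.
#'
#' @param pilrs Named list of `pilr` objects or cells x pixels matrix of
#'   flattened PILRs.
#' @param labels Two-level factor (or character) of population per cell;
#'   each population needs >= 3 cells.
#' @param max_dim Reduced dimensionality cap (default 32).
#' @return An `lda_axis_model` with `positions` (sigma units per fitted
#'   cell), `group_means`, `axis_scale`, the PCA basis and the discriminant.
#' @export
fit_lda_axis <- function(pilrs, labels, max_dim = 32L) {
  M <- if (is.matrix(pilrs)) pilrs else
    t(vapply(pilrs, pilr_flatten, numeric(length(pilr_flatten(pilrs[[1]])))))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two populations are required")
  tab <- table(labels)
  if (any(tab == 0)) stop("one population is empty")
  if (any(tab < 3)) stop("each population needs at least 3 cells")
  n <- nrow(M)
  ncomp <- min(max_dim, n, ncol(M))
  pca <- prcomp(M, center = TRUE, scale. = FALSE)
  ncomp <- min(ncomp, ncol(pca$rotation))
  Wp <- pca$rotation[, seq_len(ncomp), drop = FALSE]
  Z <- pca$x[, seq_len(ncomp), drop = FALSE]
  g <- levels(labels)
  z1 <- Z[labels == g[1], , drop = FALSE]
  z2 <- Z[labels == g[2], , drop = FALSE]
  Sw <- (crossprod(sweep(z1, 2, colMeans(z1))) +
           crossprod(sweep(z2, 2, colMeans(z2)))) / (n - 2)
  dm <- colMeans(z2) - colMeans(z1)
  w <- tryCatch(solve(Sw, dm), error = function(e) NULL)
  ridge_used <- FALSE
  if (is.null(w) || any(!is.finite(w))) {
    ridge_used <- TRUE
    warning("singular within-class scatter; applying ridge regularization")
    lam <- 1e-6 * mean(diag(Sw)) + 1e-12
    w <- solve(Sw + diag(lam, ncomp), dm)
  }
  w <- w / sqrt(sum(w^2))
  proj <- as.numeric(Z %*% w)
  if (mean(proj[labels == g[2]]) < mean(proj[labels == g[1]])) {
    w <- -w; proj <- -proj
  }
  center <- mean(proj)
  scale <- sd(proj)
  pos <- (proj - center) / scale
  names(pos) <- rownames(M)
  structure(list(
    pca_mean = pca$center, pca_basis = Wp, reduced_dim = ncomp,
    lda_weights = w, axis_scale = scale, axis_center = center,
    group_levels = g,
    group_means = c(mean(pos[labels == g[1]]), mean(pos[labels == g[2]])),
    positions = pos, ridge_used = ridge_used, n_fit = n
  ), class = "lda_axis_model")
}

#' @export
print.lda_axis_model <- function(x, ...) {
  cat(sprintf("lda_axis_model: %d cells, reduced dim %d, group means %.2f / %.2f sigma\n",
              x$n_fit, x$reduced_dim, x$group_means[1], x$group_means[2]))
  invisible(x)
}

#' Project PILRs onto a fitted location-phenotype axis
#' @param model `lda_axis_model`.
#' @param pilrs List of `pilr` objects or flattened matrix.
#' @return Axis positions in sigma units.
#' @export
project_cells <- function(model, pilrs) {
  M <- if (is.matrix(pilrs)) pilrs else {
    if (inherits(pilrs, "pilr")) pilrs <- list(pilrs)
    t(vapply(pilrs, pilr_flatten, numeric(length(model$pca_mean))))
  }
  Z <- sweep(M, 2, model$pca_mean) %*% model$pca_basis
  proj <- as.numeric(Z %*% model$lda_weights)
  (proj - model$axis_center) / model$axis_scale
}

#' Reconstruct PILRs at positions along the axis
#'
#' Inverse of the PCA transform evaluated on the discriminant line: position
#' p (sigma units) maps to the reduced-space point
#' `center + p * scale * w` and back to pixel space.
#'
#' @param model `lda_axis_model`.
#' @param positions Finite numeric axis positions.
#' @return Matrix, one reconstructed flattened PILR per row.
#' @export
reconstruct_along_axis <- function(model, positions) {
  if (any(!is.finite(positions))) stop("axis positions must be finite")
  red <- outer(positions * model$axis_scale + model$axis_center, model$lda_weights)
  sweep(red %*% t(model$pca_basis), 2, model$pca_mean, "+")
}

#' Flag significant stereotypy/concordance differences
#'
#' An entry is measurable iff its value in the reference (earlier-stage)
#' matrix reaches `rho_min`; a measurable entry is flagged iff the absolute
#' difference between the two matrices reaches `rho_diff_min`. Optionally a
#' relative-difference override suppresses flags whose relative change is
#' below 5% (the extremely-high-stereotypy exception); off by default.
#'
#' @param mat_a,mat_b `avg_correlation_matrix` or plain matrices with shared
#'   labels; `mat_a` is the reference unless `reference = "b"`.
#' @param rho_min Measurability cut-off on the reference value (default 0.03).
#' @param rho_diff_min Difference cut-off (default 0.02).
#' @param reference `"a"` or `"b"`.
#' @param relative_override Suppress flags with |diff|/reference < 5%.
#' @return List of class `difference_flags` with logical `flags` and
#'   `measurable` matrices and the `difference` matrix.
#' @export
flag_differences <- function(mat_a, mat_b, rho_min = 0.03, rho_diff_min = 0.02,
                             reference = c("a", "b"), relative_override = FALSE) {
  reference <- match.arg(reference)
  A <- if (inherits(mat_a, "avg_correlation_matrix")) mat_a$values else as.matrix(mat_a)
  B <- if (inherits(mat_b, "avg_correlation_matrix")) mat_b$values else as.matrix(mat_b)
  if (!identical(dimnames(A), dimnames(B)) || !identical(dim(A), dim(B)))
    stop("matrices must share dimensions and labels")
  ref <- if (reference == "a") A else B
  measurable <- !is.na(ref) & ref >= rho_min
  diffm <- A - B
  flags <- measurable & !is.na(diffm) & abs(diffm) >= rho_diff_min
  if (relative_override) {
    rel <- abs(diffm) / abs(ref)
    flags <- flags & !(is.finite(rel) & rel < 0.05)
  }
  structure(list(flags = flags, measurable = measurable, difference = diffm,
                 rho_min = rho_min, rho_diff_min = rho_diff_min),
            class = "difference_flags")
}

toc_levels <- c("m1_only", "stepwise", "m2_change", "no_change")

#' Timing-of-change categories across three stage comparisons
#'
#' Combines the flags of the three comparisons (interphase vs m1, interphase
#' vs m2, m1 vs m2) into one category per entry:
#' m1_only = flagged i1-m1 and not m1-m2; stepwise = flagged i1-m1 and m1-m2;
#' m2_change = not flagged i1-m1 but flagged m1-m2 or i2-m2; otherwise
#' no_change. Entries unmeasurable in all three comparisons are no_change
#' with an `undetermined` annotation.
#'
#' @param flags_i1m1,flags_i2m2,flags_m1m2 `difference_flags` (aligned labels).
#' @return List of class `toc_table` with `category` (character matrix),
#'   `undetermined` (logical matrix) and the input flags.
#' @export
toc_categories <- function(flags_i1m1, flags_i2m2, flags_m1m2) {
  f1 <- flags_i1m1$flags; f2 <- flags_i2m2$flags; f3 <- flags_m1m2$flags
  stopifnot(identical(dimnames(f1), dimnames(f2)),
            identical(dimnames(f1), dimnames(f3)))
  cat <- matrix("no_change", nrow(f1), ncol(f1), dimnames = dimnames(f1))
  cat[f1 & !f3] <- "m1_only"
  cat[f1 & f3] <- "stepwise"
  cat[!f1 & (f3 | f2)] <- "m2_change"
  undet <- !flags_i1m1$measurable & !flags_i2m2$measurable & !flags_m1m2$measurable
  cat[undet] <- "no_change"
  structure(list(category = cat, undetermined = undet,
                 flags = list(i1m1 = f1, i2m2 = f2, m1m2 = f3)),
            class = "toc_table")
}

# stage set at which a TOC category implies a change
toc_change_times <- function(category) {
  switch(category,
         m1_only = "m1", stepwise = c("m1", "m2"), m2_change = "m2",
         no_change = character(0))
}

#' Relationship between concordance and stereotypy timing of change
#'
#' Consolidates, per structure pair, the TOC of the pair's concordance and of
#' both members' stereotypies into: `"no_changes"` (nothing changed),
#' `"co_timed"` (every stage at which the concordance changed, at least one
#' member's stereotypy changed too; annotated `at_first_stereotypy_change`
#' when the first concordance change coincides with the earliest stereotypy
#' change), or `"independent"` (concordance and stereotypy changed at
#' different times, including stereotypy-only changes).
#'
#' @param stereotypy_toc Named character vector: TOC category per structure.
#' @param concordance_toc `toc_table` (or category matrix) over the same
#'   structures.
#' @return data.frame with one row per unordered structure pair: `category`
#'   and logical `at_first_stereotypy_change`.
#' @export
stereotypy_concordance_relationship <- function(stereotypy_toc, concordance_toc) {
  cmat <- if (inherits(concordance_toc, "toc_table")) concordance_toc$category
          else as.matrix(concordance_toc)
  structs <- rownames(cmat)
  stopifnot(all(structs %in% names(stereotypy_toc)))
  pairs <- which(upper.tri(cmat), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- structs[pairs[k, 1]]; b <- structs[pairs[k, 2]]
    tc <- toc_change_times(cmat[a, b])
    ta <- toc_change_times(stereotypy_toc[[a]])
    tb <- toc_change_times(stereotypy_toc[[b]])
    ts <- union(ta, tb)
    if (length(tc) == 0 && length(ts) == 0) {
      cat_k <- "no_changes"; first <- NA
    } else if (length(tc) > 0 && all(tc %in% ts)) {
      cat_k <- "co_timed"
      first <- min(tc) == min(ts)
    } else {
      cat_k <- "independent"; first <- NA
    }
    data.frame(structure_a = a, structure_b = b, category = cat_k,
               at_first_stereotypy_change = first)
  })
  do.call(rbind, res)
}
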