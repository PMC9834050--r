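# shape matching, LDA phenotype axis, flagging and TOC logic

test_that("match_shapes equals the exhaustive nearest-neighbour oracle", {
  set.seed(1)
  baseline <- matrix(rnorm(50 * 8), ncol = 8,
                     dimnames = list(sprintf("b%02d", 1:50), NULL))
  query <- matrix(rnorm(20 * 8), ncol = 8,
                  dimnames = list(sprintf("q%02d", 1:20), NULL))
  m <- match_shapes(baseline, query)
  oracle <- oracle_nearest_neighbour(baseline, query)
  expect_equal(unname(m$nn_id), oracle)
  expect_false(any(duplicated(m$matched_baseline_ids)))
  expect_equal(m$duplicate_flag_count, sum(duplicated(oracle)))
  expect_equal(length(m$combined_ids),
               length(unique(oracle)) + nrow(query))

  # identical query -> distance 0, that cell flagged
  m2 <- match_shapes(baseline, baseline[3, , drop = FALSE])
  expect_equal(unname(m2$nn_id), "b03")

  # exact tie broken by lowest baseline id
  tie_base <- rbind(z2 = c(1, rep(0, 7)), a1 = c(1, rep(0, 7)))
  m3 <- match_shapes(tie_base, matrix(c(1, rep(0, 7)), 1,
                                      dimnames = list("q", NULL)))
  expect_equal(unname(m3$nn_id), "a1")
  expect_error(match_shapes(baseline[0, ], query), "empty")
})

test_that("fit_lda_axis honours dimensionality and orientation contracts", {
  set.seed(2)
  M <- matrix(rnorm(40 * 200), 40, 200,
              dimnames = list(sprintf("c%02d", 1:40), NULL))
  M[21:40, 1:10] <- M[21:40, 1:10] + 2
  lab <- rep(c("g1", "g2"), each = 20)
  m <- fit_lda_axis(M, lab)
  expect_equal(m$reduced_dim, 32)
  expect_equal(sqrt(sum(m$lda_weights^2)), 1, tolerance = 1e-12)
  expect_gt(m$group_means[2], m$group_means[1]) # second population positive
  expect_equal(sd(m$positions), 1, tolerance = 1e-9)

  # swapping labels negates positions
  m_sw <- fit_lda_axis(M, rep(c("g2", "g1"), each = 20))
  expect_equal(unname(m_sw$positions), -unname(m$positions), tolerance = 1e-6)

  # n < 32 cells: reduced dimensionality = n (ridge kicks in for the
  # necessarily singular within-class scatter)
  expect_warning(m_small <- fit_lda_axis(M[1:10, ], rep(c("g1", "g2"), 5)),
                 "ridge")
  expect_equal(m_small$reduced_dim, 10)

  expect_error(fit_lda_axis(M, rep("g1", 40)), "two populations")
  expect_error(fit_lda_axis(M[1:5, ], c("a", "a", "a", "b", "b")), "at least 3")
})

test_that("projection and reconstruction along the axis are mutually linear", {
  set.seed(3)
  M <- matrix(rnorm(50 * 120), 50, 120)
  M[26:50, 1:15] <- M[26:50, 1:15] + 1.5
  lab <- rep(c("A", "B"), each = 25)
  m <- fit_lda_axis(M, lab)
  # projecting a population's mean PILR gives its mean axis position
  expect_equal(as.numeric(project_cells(m, matrix(colMeans(M[lab == "B", ]), 1))),
               m$group_means[2], tolerance = 1e-6)
  # project(reconstruct(p)) = p
  p <- c(-2, -0.5, 0, 1, 2)
  rec <- reconstruct_along_axis(m, p)
  expect_equal(as.numeric(project_cells(m, rec)), p, tolerance = 1e-6)
  # the planted block mean increases monotonically along the axis
  blockmean <- rowMeans(rec[, 1:15])
  expect_true(all(diff(blockmean) > 0))
  expect_error(reconstruct_along_axis(m, c(0, NA)), "finite")
})

test_that("flag_differences applies both cut-offs with monotone flagging", {
  lab <- list(c("s1", "s2"), c("s1", "s2"))
  A <- matrix(c(0.50, 0.02, 0.02, 0.50), 2, dimnames = lab)
  B <- matrix(c(0.40, 0.10, 0.10, 0.49), 2, dimnames = lab)
  f <- flag_differences(A, B)
  expect_true(f$flags["s1", "s1"])        # 0.50 vs 0.40: measurable, flagged
  expect_false(f$measurable["s1", "s2"])  # reference 0.02 < rho_min
  expect_false(f$flags["s1", "s2"])
  expect_false(f$flags["s2", "s2"])       # |0.50 - 0.49| < rho_diff
  expect_true(f$measurable["s2", "s2"])

  # monotone: growing |A - B| never un-flags
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1); d1 <- runif(1, 0, 0.3); d2 <- d1 + runif(1, 0, 0.3)
    A1 <- matrix(a, 1, dimnames = list("s", "s"))
    f1 <- flag_differences(A1, A1 - d1)$flags[1, 1]
    f2 <- flag_differences(A1, A1 - d2)$flags[1, 1]
    expect_true(!f1 || f2)
  }

  # relative override suppresses tiny relative changes
  Ahi <- matrix(0.99, 1, dimnames = list("pm", "pm"))
  Bhi <- matrix(0.95, 1, dimnames = list("pm", "pm"))
  expect_true(flag_differences(Ahi, Bhi)$flags[1, 1])
  expect_false(flag_differences(Ahi, Bhi, relative_override = TRUE)$flags[1, 1])

  C <- B; dimnames(C) <- list(c("x", "y"), c("x", "y"))
  expect_error(flag_differences(A, C), "labels")
})

test_that("TOC categories follow the three-comparison rule table", {
  mk <- function(v, meas = TRUE) {
    m <- matrix(v, 1, dimnames = list("s", "s"))
    structure(list(flags = m, measurable = matrix(meas, 1, dimnames = dimnames(m))),
              class = "difference_flags")
  }
  tt <- function(f1, f2, f3)
    toc_categories(mk(f1), mk(f2), mk(f3))$category[1, 1]
  expect_equal(tt(TRUE, FALSE, FALSE), "m1_only")
  expect_equal(tt(TRUE, TRUE, TRUE), "stepwise")
  expect_equal(tt(FALSE, FALSE, TRUE), "m2_change")
  expect_equal(tt(FALSE, TRUE, FALSE), "m2_change")
  expect_equal(tt(FALSE, FALSE, FALSE), "no_change")
  # unmeasurable everywhere -> undetermined no_change
  out <- toc_categories(mk(FALSE, FALSE), mk(FALSE, FALSE), mk(FALSE, FALSE))
  expect_equal(out$category[1, 1], "no_change")
  expect_true(out$undetermined[1, 1])
})

test_that("stereotypy/concordance relationship consolidates change timing", {
  lab <- c("X", "Y")
  cmat <- matrix("no_change", 2, 2, dimnames = list(lab, lab))
  st <- c(X = "no_change", Y = "no_change")
  r0 <- stereotypy_concordance_relationship(st, cmat)
  expect_equal(r0$category, "no_changes")

  cmat2 <- cmat; cmat2["X", "Y"] <- cmat2["Y", "X"] <- "m1_only"
  st2 <- c(X = "m1_only", Y = "no_change")
  r2 <- stereotypy_concordance_relationship(st2, cmat2)
  expect_equal(r2$category, "co_timed")
  expect_true(r2$at_first_stereotypy_change)

  st3 <- c(X = "m2_change", Y = "no_change")
  r3 <- stereotypy_concordance_relationship(st3, cmat2)
  expect_equal(r3$category, "independent")
})
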