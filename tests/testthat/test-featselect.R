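test_that("ANOVA F matches the hand-computed two-class example", {
  x <- matrix(c(0, 1, 2, 3), ncol = 1)
  lab <- c("A", "A", "B", "B")
  tb <- anova_f(x, lab)
  expect_equal(tb$score, 8, tolerance = 1e-12)  # SSB=4/df1, SSW=1/df2
  # equal means/variances: F ~ 0
  x0 <- matrix(c(1, 2, 1, 2), ncol = 1)
  expect_lt(anova_f(x0, lab)$score, 1e-9)
  # permutation invariance
  set.seed(3)
  xr <- matrix(rnorm(40), 20, 2)
  labr <- rep(c("A", "B"), each = 10)
  p <- sample(20)
  expect_equal(anova_f(xr, labr)$score, anova_f(xr[p, ], labr[p])$score)
  # cross-check against stats::aov on random data
  f_aov <- summary(stats::aov(xr[, 1] ~ factor(labr)))[[1]]$`F value`[1]
  expect_equal(anova_f(xr, labr)$score[1], f_aov, tolerance = 1e-9)
  # zero within-class variance -> Inf sentinel
  xi <- matrix(c(1, 1, 2, 2), ncol = 1)
  expect_identical(anova_f(xi, lab)$score, Inf)
  expect_error(anova_f(xr, rep(c("A", "B"), c(19, 1))),
               class = "oilauth_validation_error")
})

test_that("mutual information behaves like the label entropy at the extremes", {
  set.seed(42)
  n <- 2000
  lab <- rep(c("A", "B"), each = n / 2)
  # feature independent of label
  ind <- matrix(rnorm(n), ncol = 1)
  expect_lt(mutual_info(ind, lab)$score, 0.02)
  # feature that is a numeric copy of a balanced binary label: MI = ln 2
  copy <- matrix(as.numeric(lab == "B"), ncol = 1)
  expect_equal(mutual_info(copy, lab)$score, log(2), tolerance = 0.05)
  # constant feature scores 0
  expect_equal(mutual_info(matrix(1, n, 1), lab)$score, 0)
  # binned estimator agrees on the deterministic case
  expect_equal(mutual_info(copy, lab, estimator = "binned")$score,
               log(2), tolerance = 0.05)
})

test_that("random-forest importance normalises, ranks, and is reproducible", {
  set.seed(5)
  n <- 120
  lab <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 50), n, 50)
  x[, 7] <- ifelse(lab == "A", 0, 8) + rnorm(n, 0, 0.5)  # wide margin
  tb <- rf_importance(x, lab, seed = 42)
  expect_equal(sum(tb$score), 1, tolerance = 1e-9)
  expect_equal(which.max(tb$score), 7)
  tb2 <- rf_importance(x, lab, seed = 42)
  expect_equal(tb$score, tb2$score)
})

test_that("Pearson scores are exact for linear targets and guard constants", {
  x <- matrix(c(1, 2, 3), ncol = 1)
  expect_equal(pearson_scores(x, c(2, 4, 6))$score, 1)
  expect_equal(pearson_scores(x, c(6, 4, 2))$score, -1)
  expect_error(pearson_scores(x, c(1, 1, 1)), class = "oilauth_validation_error")
  # constant feature -> r = 0 by convention
  xc <- cbind(x, 5)
  expect_equal(pearson_scores(xc, c(2, 4, 6))$score[2], 0)
})

test_that("refine_bins merges windows like a brute-force interval union", {
  tb <- tibble::tibble(method = "m", mz = c(100.00, 100.04), score = c(5, 4))
  class(tb) <- c("score_table", class(tb))
  cfg <- refine_bins(tb, top_k = 5, window = 0.03)
  expect_equal(nrow(cfg), 1)
  expect_equal(cfg$start, 99.97)
  expect_equal(cfg$end, 100.07)
  # disjoint anchors stay disjoint
  tb2 <- tibble::tibble(method = "m", mz = c(100, 200), score = c(1, 2))
  class(tb2) <- c("score_table", class(tb2))
  expect_equal(nrow(refine_bins(tb2, window = 0.03)), 2)
  # duplicate tables are idempotent
  expect_equal(as.data.frame(refine_bins(list(tb, tb), window = 0.03)),
               as.data.frame(cfg))
  # property: merged set equals brute-force union membership on a fine grid
  set.seed(8)
  for (i in 1:10) {
    anchors <- sort(runif(12, 100, 101))
    tbp <- tibble::tibble(method = "m", mz = anchors, score = runif(12))
    class(tbp) <- c("score_table", class(tbp))
    cfgp <- refine_bins(tbp, top_k = 12, window = 0.03)
    grid <- seq(99.9, 101.1, by = 1e-3)
    in_union <- Reduce(`|`, lapply(anchors, function(a) {
      grid >= a - 0.03 - 1e-9 & grid <= a + 0.03 + 1e-9
    }))
    in_merged <- Reduce(`|`, lapply(seq_len(nrow(cfgp)), function(j) {
      grid >= cfgp$start[j] - 1e-9 & grid <= cfgp$end[j] + 1e-9
    }))
    expect_equal(in_merged, in_union)
    # disjoint, sorted, width bounded by the input total
    expect_true(all(diff(cfgp$start) > 0))
    expect_true(all(cfgp$start[-1] >= cfgp$end[-nrow(cfgp)]))
    expect_lte(sum(cfgp$end - cfgp$start), 12 * 0.06 + 1e-9)
    # idempotence: the same anchors refined again give the same set
    expect_equal(as.data.frame(refine_bins(tbp, top_k = 12, window = 0.03)),
                 as.data.frame(cfgp))
  }
  expect_error(refine_bins(list()), class = "oilauth_validation_error")
})

test_that("scores of correlation type rank by magnitude in refinement", {
  tb <- tibble::tibble(method = "pearson", mz = c(100, 200, 300),
                       score = c(-0.9, 0.5, 0.1))
  class(tb) <- c("score_table", class(tb))
  cfg <- refine_bins(tb, top_k = 1, window = 0.03)
  expect_equal(cfg$start, 100 - 0.03)
})
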