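test_that("bin expansion enumerates sub-bins with the half-open convention", {
  g <- tiny_grid()
  expect_equal(n_bins(g), 12)  # (75.11 - 74.99) / 0.01
  expect_equal(g$lo[1], 74.99)
  expect_equal(g$hi[12], 75.11)
  expect_equal(g$hi - g$lo, rep(0.01, 12), tolerance = 1e-9)
  # single sub-bin interval
  expect_equal(n_bins(expand_bins(bin_config(100, 101, 1))), 1)
  # non-multiple width: truncated final sub-bin
  gt <- expand_bins(bin_config(10, 11.05, 0.5))
  expect_equal(n_bins(gt), 3)
  expect_equal(gt$hi[3], 11.05)
  expect_equal(gt$hi[3] - gt$lo[3], 0.05, tolerance = 1e-12)
  # independently: count by repeated edge addition for random configs
  set.seed(9)
  for (i in 1:20) {
    s <- runif(1, 70, 900); w <- runif(1, 0.1, 5); st <- runif(1, 0.01, w)
    edges <- s
    while (max(edges) < s + w - 1e-9) edges <- c(edges, min(max(edges) + st, s + w))
    expect_equal(n_bins(expand_bins(bin_config(s, s + w, st))),
                 length(edges) - 1L)
  }
})

test_that("the packaged default configuration expands to 666 sub-bins over 92 intervals", {
  cfg <- default_bin_config()
  expect_equal(nrow(cfg), 92)
  g <- expand_bins(cfg)
  expect_equal(n_bins(g), 666)
  expect_equal(nrow(grid_summary(g)), 92)
  expect_equal(sum(grid_summary(g)$n_subbins), 666)
})

test_that("bin_scan places, sums, and conserves intensity mass", {
  g <- tiny_grid()
  expect_equal(bin_scan(numeric(0), numeric(0), g), rep(0, 12))
  v <- bin_scan(75.005, 10, g)
  expect_equal(v[2], 10)          # [75.00, 75.01)
  expect_equal(sum(v), 10)
  v2 <- bin_scan(c(75.001, 75.009), c(3, 4), g)
  expect_equal(v2[2], 7)
  # a peak exactly at the interval end is excluded
  expect_equal(sum(bin_scan(75.11, 5, g)), 0)
  # mass conservation and peak-order invariance on random scans
  big <- expand_bins(default_bin_config())
  set.seed(4)
  for (i in 1:5) {
    mz <- sort(runif(300, 70, 1005))
    int <- rexp(300)
    binned <- bin_scan(mz, int, big)
    inside <- rowSums(sapply(seq_len(nrow(default_bin_config())), function(j) {
      cfg <- default_bin_config()
      mz >= cfg$start[j] & mz < cfg$end[j]
    })) > 0
    expect_equal(sum(binned), sum(int[inside]), tolerance = 1e-12)
    perm <- sample(300)
    ord <- order(mz[perm])
    expect_equal(bin_scan(mz[perm][ord], int[perm][ord], big), binned)
  }
})

test_that("temporal aggregation computes the five statistics bin-major", {
  # bin constant at v over k scans -> (v, v, v, 0, k v)
  m <- matrix(3, nrow = 4, ncol = 2)
  expect_equal(aggregate_time(m), c(3, 3, 3, 0, 12, 3, 3, 3, 0, 12))
  # single scan: population SD = 0
  expect_equal(aggregate_time(matrix(c(1, 2), 1)), c(1, 1, 1, 0, 1, 2, 2, 2, 0, 2))
  # bin-major layout against a direct computation
  set.seed(11)
  m <- matrix(rexp(5 * 3), 5, 3)
  out <- aggregate_time(m)
  expect_length(out, 15)
  for (j in 1:3) {
    blk <- out[(j - 1) * 5 + 1:5]
    expect_equal(blk, c(max(m[, j]), mean(m[, j]), median(m[, j]),
                        sqrt(mean((m[, j] - mean(m[, j]))^2)), sum(m[, j])))
  }
})

test_that("TIC profile sums scans and scales homogeneously", {
  s <- tiny_series(n = 4)
  tp <- tic_profile(s)
  expect_equal(tp$tic, vapply(s$peaks, function(p) sum(p[, 2]), numeric(1)))
  s2 <- s
  s2$peaks <- lapply(s$peaks, function(p) { p[, 2] <- p[, 2] * 3; p })
  expect_equal(tic_profile(s2)$tic, 3 * tp$tic)
  empty <- scan_series("e", 1:3, replicate(3, NULL, simplify = FALSE))
  expect_equal(tic_profile(empty)$tic, rep(0, 3))
})

test_that("TIC descriptors: 8 features, symmetry, and degenerate rules", {
  s <- tiny_series(n = 5)
  f <- tic_features(tic_profile(s))
  expect_length(f, 8)
  expect_named(f, c("tic_area", "tic_main_time", "tic_snr", "tic_n_peaks",
                    "tic_skewness", "tic_kurtosis", "tic_main_height",
                    "tic_main_fwhm"))
  # symmetric triangular TIC on a uniform grid: skewness ~ 0, and the
  # weighted moments agree with a direct oracle
  y <- c(1, 2, 3, 4, 5, 4, 3, 2, 1)
  tp <- structure(tibble::tibble(time = as.double(1:9), tic = y),
                  class = c("tic_profile", "tbl_df", "tbl", "data.frame"))
  ft <- tic_features(tp)
  expect_lt(abs(ft[["tic_skewness"]]), 1e-9)
  w <- y / sum(y); mu <- sum(w * (1:9)); m2 <- sum(w * ((1:9) - mu)^2)
  oracle_kurt <- sum(w * ((1:9) - mu)^4) / m2^2 - 3
  expect_equal(ft[["tic_kurtosis"]], oracle_kurt, tolerance = 1e-12)
  expect_equal(ft[["tic_main_time"]], 5)
  expect_equal(ft[["tic_main_height"]], 5)
  expect_equal(ft[["tic_area"]], sum(diff(1:9) * (y[-1] + y[-9]) / 2))
  # constant TIC: shape stats zero, no local maxima, SNR finite
  cp <- structure(tibble::tibble(time = as.double(1:5), tic = rep(2, 5)),
                  class = c("tic_profile", "tbl_df", "tbl", "data.frame"))
  fc <- tic_features(cp)
  expect_equal(fc[["tic_skewness"]], 0)
  expect_equal(fc[["tic_kurtosis"]], 0)
  expect_equal(fc[["tic_n_peaks"]], 0)
  expect_true(is.finite(fc[["tic_snr"]]))
  expect_error(tic_features(structure(tibble::tibble(time = 1:2, tic = c(1, 2)),
                                      class = c("tic_profile", "tbl_df", "tbl",
                                                "data.frame"))),
               class = "oilauth_validation_error")
})

test_that("peak counting responds to prominence", {
  y <- c(0, 5, 0, 0.1, 0, 5, 0)
  tp <- structure(tibble::tibble(time = as.double(1:7), tic = y),
                  class = c("tic_profile", "tbl_df", "tbl", "data.frame"))
  expect_equal(tic_features(tp)[["tic_n_peaks"]], 2)          # 5% threshold
  expect_equal(tic_features(tp, peak_prominence = 0.01)[["tic_n_peaks"]], 3)
})

test_that("featurize_sample assembles the full vector with the fixed layout", {
  s <- tiny_series(n = 4)
  # 1-interval grid: 5 x 1 + 8 = 13 features
  f13 <- featurize_sample(s, bin_config(100, 101, 1))
  expect_equal(sum(grepl("^f", names(f13))), 13)
  # packaged grid: 3338
  full <- featurize_sample(s, default_bin_config())
  expect_equal(sum(grepl("^f", names(full))), 3338)
  expect_false(anyNA(as.numeric(full[-1])))
  # determinism on identical input
  expect_equal(featurize_sample(tiny_series(), tiny_grid()),
               featurize_sample(tiny_series(), tiny_grid()))
})

test_that("zero-noise mixture features are linear in composition", {
  lib <- fixture_library()
  zn <- zero_noise(n_scans = 4)
  g <- expand_bins(default_bin_config())
  pure <- pure_design(1)
  fpure <- sapply(oil_classes(), function(cl) {
    s <- simulate_scan_series(lib, pure[pure$label == cl, ], zn, seed = 1)
    as.numeric(featurize_sample(s, g)[-1])
  })
  des <- enumerate_design(systems = 2, levels = 30, replicates = 1)[1, ]
  mix <- simulate_scan_series(lib, des, zn, seed = 2)
  fmix <- as.numeric(featurize_sample(mix, g)[-1])
  fr <- as.numeric(des[fraction_cols_vec()])
  expected <- as.numeric(fpure %*% fr)
  bb <- seq_len(5 * 666)  # binned block
  expect_equal(fmix[bb], expected[bb], tolerance = 1e-9)
  # TIC area (feature 3331) is linear too
  expect_equal(fmix[3331], expected[3331], tolerance = 1e-9)
})
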