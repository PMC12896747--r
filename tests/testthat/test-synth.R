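test_that("the combinatorial design reproduces the published sample counts", {
  expect_equal(nrow(enumerate_design(systems = 2)), 198)  # ternary
  expect_equal(nrow(enumerate_design(systems = 3)), 132)  # quaternary
  expect_equal(nrow(enumerate_design(systems = 4)), 33)   # quinary
  # the stated combinatorics give 132 for the binary system (the printed
  # total of 165 is not reproducible from the stated design)
  expect_equal(nrow(enumerate_design(systems = 1)), 132)
  expect_equal(nrow(enumerate_design()), 132 + 198 + 132 + 33)
})

test_that("design fractions are conserved and adulterants share the level", {
  des <- enumerate_design()
  fr <- fraction_matrix(des)
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  expect_true(all(fr >= 0))
  expect_equal(des$adulteration_level / 100, 1 - des$frac_cao, tolerance = 1e-12)
  # quinary at 50%: (0.50, 0.125 x4)
  q50 <- des[des$system == "quinary" & des$adulteration_level == 50, ][1, ]
  expect_equal(as.numeric(q50[fraction_cols_vec()]),
               c(0.50, 0.125, 0.125, 0.125, 0.125))
  # nonzero adulterant fractions are equal within every design
  nz_equal <- apply(fr[, -1, drop = FALSE], 1, function(v) {
    v <- v[v > 0]
    length(unique(round(v, 12))) == 1L
  })
  expect_true(all(nz_equal))
  expect_error(enumerate_design(levels = numeric(0)),
               class = "oilauth_validation_error")
  expect_error(enumerate_design(levels = c(0, 50)),
               class = "oilauth_validation_error")
})

test_that("profile library is deterministic, complete, and class-separated", {
  lib1 <- make_profile_library(seed = 42)
  lib2 <- make_profile_library(seed = 42)
  expect_equal(as.data.frame(lib1), as.data.frame(lib2))
  expect_setequal(unique(lib1$oil), oil_classes())
  expect_true(all(lib1$mz >= 75 & lib1$mz <= 1000))
  expect_true(all(lib1$intensity > 0))
  disc <- lib1[lib1$role == "discriminative", ]
  for (cl in oil_classes()) {
    d <- disc[disc$oil == cl, ]
    expect_gte(sum(d$mz >= 100 & d$mz <= 300), 5)
    expect_gte(sum(d$mz >= 800 & d$mz <= 1000), 2)
    expect_true(all((d$mz >= 100 & d$mz <= 300) | (d$mz >= 800 & d$mz <= 1000)))
  }
  # pairwise profiles differ: cosine similarity of binned spectra < 0.99
  g <- expand_bins(default_bin_config())
  binned <- sapply(oil_classes(), function(cl) {
    p <- lib1[lib1$oil == cl, ]
    bin_scan(p$mz, p$intensity, g)
  })
  cs <- crossprod(apply(binned, 2, function(v) v / sqrt(sum(v^2))))
  expect_true(all(cs[upper.tri(cs)] < 0.99))
})

test_that("zero-noise simulation is exact and linear in composition", {
  lib <- fixture_library()
  zn <- zero_noise(n_scans = 4)
  pure <- pure_design(1)
  cao <- simulate_scan_series(lib, pure[pure$label == "CAO", ], zn, seed = 1)
  prof <- lib[lib$oil == "CAO", ]
  for (i in seq_len(n_scans(cao))) {
    expect_equal(cao$peaks[[i]][, "mz"], prof$mz, ignore_attr = TRUE)
    expect_equal(cao$peaks[[i]][, "intensity"], prof$intensity,
                 ignore_attr = TRUE)
  }
  # 50:50 CAO/COO: every peak intensity is the half-weighted profile value
  des <- enumerate_design(systems = 1, levels = 50, replicates = 1)
  mix <- des[des$adulterants == "COO", ]
  s <- simulate_scan_series(lib, mix, zn, seed = 3)
  expected <- sort(c(lib$intensity[lib$oil == "CAO"] * 0.5,
                     lib$intensity[lib$oil == "COO"] * 0.5))
  expect_equal(sort(s$peaks[[1]][, "intensity"]), expected, ignore_attr = TRUE)
})

test_that("simulation is deterministic for a fixed seed", {
  lib <- fixture_library()
  des <- enumerate_design(systems = 1, levels = 50, replicates = 1)[1, ]
  a <- simulate_scan_series(lib, des, noise_model(), seed = 7)
  b <- simulate_scan_series(lib, des, noise_model(), seed = 7)
  expect_equal(a$peaks, b$peaks)
  c <- simulate_scan_series(lib, des, noise_model(), seed = 8)
  expect_false(isTRUE(all.equal(a$peaks, c$peaks)))
})

test_that("simulate_dataset preserves counts, labels and id uniqueness", {
  lib <- fixture_library()
  des <- enumerate_design(systems = 2, levels = c(10, 50), replicates = 1)
  ds <- simulate_dataset(lib, des, zero_noise(), seed = 1)
  expect_length(ds, nrow(des))
  pures <- simulate_dataset(lib, NULL, zero_noise(), pure_replicates = 5,
                            seed = 1)
  expect_length(pures, 25)
  expect_equal(unname(table(dataset_design(pures)$label)), rep(5L, 5),
               ignore_attr = TRUE)
  ids <- vapply(pures, function(s) sample_id(s$series), character(1))
  expect_false(anyDuplicated(ids) > 0)
  dup <- des[c(1, 1), ]
  expect_error(simulate_dataset(lib, dup, zero_noise(), seed = 1),
               class = "oilauth_validation_error")
  expect_error(simulate_dataset(lib, NULL, zero_noise(), seed = 1),
               class = "oilauth_validation_error")
})

test_that("invalid fractions are rejected at simulation time", {
  lib <- fixture_library()
  row <- pure_design(1)[1, ]
  row$frac_cao <- 0.7
  expect_error(simulate_scan_series(lib, row, zero_noise(), seed = 1),
               class = "oilauth_validation_error")
})

test_that("pure-class feature vectors separate in PCA space under default noise", {
  skip_if_not_installed("cluster")
  ft <- fixture_full_features()
  pure <- ft[!startsWith(ft$label, "CAO-"), ]
  emb <- embed_fit(pure, embed_config("pca", n_components = 5))
  sil <- cluster::silhouette(as.integer(factor(pure$label)), dist(emb$x))
  expect_gt(mean(sil[, "sil_width"]), 0.3)
})
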