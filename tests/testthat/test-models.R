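make_separable <- function(n = 200, margin = 5, seed = 42) {
  with_seed <- asNamespace("oilauth")$with_seed
  with_seed(seed, {
    lab <- rep(c("pure", "adulterated"), each = n / 2)
    x <- matrix(rnorm(n * 10), n, 10)
    x[, 1] <- ifelse(lab == "pure", 0, margin) + rnorm(n, 0, 1)
    colnames(x) <- sprintf("f%04d", 1:10)
    tibble::tibble(sample_id = sprintf("s%03d", 1:n), label = lab) |>
      dplyr::bind_cols(tibble::as_tibble(as.data.frame(x)))
  })
}

test_that("the 8:2 split is stratified, exhaustive, and reproducible", {
  ft <- make_separable(100)
  sp <- split_data(ft, test_frac = 0.2, seed = 42)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), ft$sample_id)
  # class proportions preserved within one sample per class
  expect_equal(unname(table(sp$test$label)), c(10L, 10L), ignore_attr = TRUE)
  sp2 <- split_data(ft, test_frac = 0.2, seed = 42)
  expect_equal(sp$test$sample_id, sp2$test$sample_id)
  # singleton class falls back with a warning
  ft1 <- ft
  ft1$label[1] <- "oddity"
  expect_warning(split_data(ft1, 0.2, seed = 1), "unstratified")
})

test_that("seeded classifiers achieve perfect accuracy on a wide-margin task", {
  ft <- make_separable(200, margin = 5, seed = 42)
  sp <- split_data(ft, 0.2, seed = 42)
  for (kind in c("rf", "lr", "gbt")) {
    fit <- train_classifier(kind, sp$train)
    pred <- predict(fit, sp$test)
    expect_true(all(pred$.pred_class %in% unique(sp$train$label)))
    acc <- mean(pred$.pred_class == sp$test$label)
    expect_equal(acc, 1, info = kind)
  }
})

test_that("SVM decision scores discriminate the wide-margin task", {
  ft <- make_separable(200, margin = 5, seed = 42)
  sp <- split_data(ft, 0.2, seed = 42)
  fit <- train_classifier("svm", sp$train)
  pred <- predict(fit, sp$test)
  expect_equal(mean(pred$.pred_class == sp$test$label), 1)
  expect_equal(auc_roc(sp$test$label, pred$adulterated,
                       positive = "adulterated"), 1)
})

test_that("random forests are reproducible and single-class training fails", {
  ft <- make_separable(100)
  sp <- split_data(ft, 0.2, seed = 42)
  p1 <- predict(train_classifier("rf", sp$train), sp$test)
  p2 <- predict(train_classifier("rf", sp$train), sp$test)
  expect_equal(p1, p2)
  solo <- sp$train[sp$train$label == "pure", ]
  expect_error(train_classifier("rf", solo), class = "oilauth_validation_error")
})

test_that("prediction enforces the feature contract and handles empty input", {
  ft <- make_separable(100)
  fit <- train_classifier("rf", ft)
  expect_error(predict(fit, matrix(0, 2, 3)), class = "oilauth_contract_error")
  empty <- predict(fit, ft[0, ])
  expect_equal(nrow(empty), 0)
  p <- predict(fit, ft)
  expect_true(all(p$pure >= 0 & p$pure <= 1))
  expect_true(all(p$adulterated >= 0 & p$adulterated <= 1))
})

test_that("the CNN classifier trains on a small separable task", {
  ft <- make_separable(300, margin = 6, seed = 9)
  sp <- split_data(ft, 0.2, seed = 9)
  spec <- classifier_spec("cnn", epochs = 80, lr = 3e-3, filters = c(4, 8),
                          kernels = c(5, 3))
  fit <- train_classifier(spec, sp$train)
  pred <- predict(fit, sp$test)
  expect_gte(mean(pred$.pred_class == sp$test$label), 0.9)
  sums <- rowSums(as.matrix(pred[c("pure", "adulterated")]))
  expect_equal(sums, rep(1, nrow(pred)), tolerance = 1e-9)
})

test_that("quantifier predictions always lie on the 5-oil simplex", {
  set.seed(4)
  n <- 60
  fr <- t(apply(matrix(rexp(n * 5), n, 5), 1, function(v) v / sum(v)))
  x <- fr %*% matrix(rnorm(5 * 12), 5, 12) + rnorm(n * 12, 0, 0.01)
  colnames(x) <- sprintf("f%04d", 1:12)
  q <- train_quantifier(quantifier_spec(epochs = 15, filters = c(4, 6),
                                        kernels = c(5, 3)),
                        list(x = x, y = fr))
  # in-distribution and far out-of-distribution inputs both yield simplexes
  for (xx in list(x, x * 100 - 50)) {
    p <- as.matrix(predict(q, xx))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(rowSums(p), rep(1, n), tolerance = 1e-6)
  }
  expect_equal(nrow(predict(q, x[0, , drop = FALSE])), 0)
  # invalid fractions are rejected
  bad <- fr; bad[1, ] <- bad[1, ] * 2
  expect_error(train_quantifier(quantifier_spec(epochs = 1), list(x = x, y = bad)),
               class = "oilauth_validation_error")
})

test_that("a linear fit on zero-noise binned features recovers composition near-perfectly", {
  # upper-bound oracle for the quantifier: on the noiseless linear simulator
  # an ordinary least-squares fit must reach R2 >= 0.999
  lib <- fixture_library()
  des <- enumerate_design(systems = 1:2, levels = c(10, 30, 50, 70, 90),
                          replicates = 1)
  ds <- simulate_dataset(lib, des, zero_noise(n_scans = 3),
                         pure_replicates = 2, seed = 6)
  ft <- featurize_dataset(ds)
  emb <- embed_fit(ft, embed_config("pca"))
  df <- data.frame(y = ft$frac_cao, emb$x)
  fit <- lm(y ~ ., df)
  r2 <- suppressWarnings(summary(fit))$r.squared
  expect_gte(r2, 0.999)
})

test_that("tidy and glance expose the quantifier training curve", {
  set.seed(5)
  n <- 40
  fr <- t(apply(matrix(rexp(n * 5), n, 5), 1, function(v) v / sum(v)))
  x <- fr %*% matrix(rnorm(5 * 10), 5, 10)
  colnames(x) <- sprintf("f%04d", 1:10)
  q <- train_quantifier(quantifier_spec(epochs = 5, filters = c(3, 4),
                                        kernels = c(3, 3)),
                        list(x = x, y = fr))
  expect_s3_class(tidy(q), "tbl_df")
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(tidy(q))))
  expect_equal(nrow(glance(q)), 1)
})
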