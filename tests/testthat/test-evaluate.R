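test_that("the binary report matches the hand-worked confusion example", {
  # TP=2 FP=1 FN=0 TN=1 (positive = adulterated)
  truth <- c("adulterated", "adulterated", "pure", "pure")
  pred <- c("adulterated", "adulterated", "adulterated", "pure")
  rep <- classification_report(truth, pred)
  m <- setNames(rep$metrics$value, rep$metrics$metric)
  expect_equal(m[["accuracy"]], 0.75, tolerance = 1e-9)
  expect_equal(m[["precision"]], 2 / 3, tolerance = 1e-9)
  expect_equal(m[["recall"]], 1, tolerance = 1e-9)
  expect_equal(m[["f1"]], 0.8, tolerance = 1e-9)
  expect_equal(rep$misclassified, 1)
  expect_equal(sum(rep$confusion), 4)
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.vector(table(factor(truth)))))
})

test_that("perfect predictions score 1 on every metric", {
  truth <- rep(c("adulterated", "pure"), each = 5)
  scores <- c(runif(5, 0.6, 1), runif(5, 0, 0.4))
  rep <- classification_report(truth, truth, scores)
  m <- setNames(rep$metrics$value, rep$metrics$metric)
  expect_equal(unname(m[c("accuracy", "precision", "recall", "f1", "auc")]),
               rep(1, 5))
})

test_that("micro-averaged precision and recall equal accuracy in multiclass", {
  set.seed(2)
  truth <- sample(letters[1:4], 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(letters[1:4], 60, replace = TRUE))
  rep <- classification_report(truth, pred)
  m <- setNames(rep$metrics$value, rep$metrics$metric)
  expect_equal(m[["micro_precision"]], m[["accuracy"]], tolerance = 1e-12)
  expect_equal(m[["micro_recall"]], m[["accuracy"]], tolerance = 1e-12)
  # confusion-matrix structure: rows sum to class counts, trace = accuracy
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.vector(table(factor(truth, sort(unique(c(truth, pred))))))))
  expect_equal(sum(diag(rep$confusion)) / rep$n, m[["accuracy"]])
  expect_equal(rep$misclassified, sum(rep$confusion) - sum(diag(rep$confusion)))
})

test_that("AUC equals the all-pairs Mann-Whitney probability including ties", {
  expect_equal(auc_roc(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.8, 0.1, 0.2)), 1)
  expect_equal(auc_roc(c(TRUE, FALSE), c(0.7, 0.7)), 0.5)
  expect_error(auc_roc(c(TRUE, TRUE), c(1, 2)), class = "oilauth_validation_error")
  brute <- function(pos, neg) {
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(6)
  for (i in 1:25) {
    n1 <- sample(2:60, 1); n0 <- sample(2:60, 1)
    pos <- sample(seq(0, 1, by = 0.1), n1, replace = TRUE)  # heavy ties
    neg <- sample(seq(0, 1, by = 0.1), n0, replace = TRUE)
    lab <- c(rep(TRUE, n1), rep(FALSE, n0))
    expect_equal(auc_roc(lab, c(pos, neg)), brute(pos, neg), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  lab <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  sc <- rnorm(100) + lab
  ours <- auc_roc(lab, sc)
  theirs <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("label-independent scores give AUC near one half", {
  set.seed(12)
  n <- 2000
  lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
  expect_equal(auc_roc(lab, rnorm(n)), 0.5, tolerance = 0.03)
})

test_that("a scored multiclass report carries per-class and aggregate AUCs", {
  set.seed(21)
  n <- 90
  lab <- rep(c("CAO", "COO", "OLO"), each = n / 3)
  x <- matrix(rnorm(n * 6), n, 6)
  x[, 1] <- x[, 1] + 3 * (lab == "CAO")
  x[, 2] <- x[, 2] + 3 * (lab == "COO")
  colnames(x) <- sprintf("f%04d", 1:6)
  fit <- train_classifier("rf", list(x = x, y = lab))
  pred <- predict(fit, x)
  rep <- classification_report(lab, pred$.pred_class,
                               scores = as.matrix(pred[c("CAO", "COO", "OLO")]))
  m <- setNames(rep$metrics$value, rep$metrics$metric)
  expect_false(anyNA(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(nrow(rep$per_class), 3)
  expect_false(anyNA(rep$per_class$auc))
  # per-class OvR AUC agrees with direct binarised computation
  expect_equal(rep$per_class$auc[1], auc_roc(lab == "CAO", pred$CAO))
})

test_that("regression metrics match the worked example and direct formulas", {
  rep <- regression_report(c(0, 10, 20, 30), c(1, 9, 21, 29), "prediction")
  expect_equal(rep$rmse, 1, tolerance = 1e-9)
  expect_equal(rep$rpd, 12.9099, tolerance = 1e-4)
  expect_equal(rep$rpd, sd(c(0, 10, 20, 30)) / 1, tolerance = 1e-12)
  # perfect prediction
  p <- regression_report(1:5, 1:5, "prediction")
  expect_equal(p$r2, 1)
  expect_equal(p$rmse, 0)
  expect_identical(p$rpd, Inf)
  # predicting the mean gives R2 = 0
  m <- regression_report(1:5, rep(3, 5), "prediction")
  expect_equal(m$r2, 0)
  expect_error(regression_report(rep(2, 5), 1:5), class = "oilauth_validation_error")
  expect_error(regression_report(1:2, 1:2), class = "oilauth_validation_error")
  # random-instance agreement with direct formulas
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(30); yh <- y + rnorm(30, 0, 0.3)
    r <- regression_report(y, yh, "prediction")
    expect_equal(r$r2, 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    expect_equal(r$rmse, sqrt(mean((y - yh)^2)), tolerance = 1e-12)
    expect_equal(r$rpd, sd(y) / sqrt(mean((y - yh)^2)), tolerance = 1e-12)
  }
})

test_that("repeated runs aggregate per-metric means and flag single runs", {
  det <- function(seed) c(acc = 0.9, f1 = 0.8)
  rr <- repeated_runs(det, n_runs = 5, base_seed = 1)
  expect_equal(rr$summary$sd, c(0, 0))
  expect_equal(rr$summary$mean, c(0.9, 0.8), ignore_attr = TRUE)
  sto <- function(seed) c(x = asNamespace("oilauth")$with_seed(seed, rnorm(1)))
  rr2 <- repeated_runs(sto, n_runs = 10, base_seed = 7)
  expect_equal(nrow(rr2$runs), 10)
  expect_equal(rr2$summary$mean,
               mean(rr2$runs$value), tolerance = 1e-12)
  rr1 <- repeated_runs(det, n_runs = 1)
  expect_equal(rr1$summary$sd, c(0, 0))
  expect_match(attr(rr1, "note"), "single run")
  boom <- function(seed) if (seed > 0) stop("bad") else c(a = 1)
  expect_error(repeated_runs(boom, n_runs = 3), "run 1",
               class = "oilauth_run_error")
})

test_that("blind evaluation enforces id disjointness and ledgers mistakes", {
  ft <- fixture_binary_task()
  sp <- split_data(ft, 0.3, seed = 1)
  fit <- train_classifier("rf", sp$train)
  be <- blind_evaluation(fit, sp$test, train_ids = sp$train$sample_id)
  expect_s3_class(be$report, "class_report")
  expect_equal(nrow(be$ledger), be$report$misclassified)
  if (nrow(be$ledger)) {
    expect_true(all(be$ledger$truth != be$ledger$predicted))
  }
  expect_error(blind_evaluation(fit, sp$train[1, ], sp$train$sample_id),
               class = "oilauth_contract_error")
  expect_error(blind_evaluation(fit, sp$test[0, ], sp$train$sample_id),
               class = "oilauth_validation_error")
})
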