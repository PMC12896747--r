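#' ROC AUC (Mann-Whitney convention)
#'
#' Area under the ROC curve for binary labels, equal to the Mann-Whitney U
#' probability that a random positive scores above a random negative, with
#' ties counted half.
#'
#' @param truth Binary truth: logical, 0/1, or a factor/character with the
#'   positive class named by `positive`.
#' @param scores Numeric scores, higher meaning more positive.
#' @param positive Positive-class label when `truth` is not logical/0-1.
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(truth, scores, positive = NULL) {
  if (length(truth) != length(scores)) {
    stop_validation("truth and scores lengths differ")
  }
  pos <- if (is.logical(truth)) {
    truth
  } else if (is.numeric(truth)) {
    truth == 1
  } else {
    if (is.null(positive)) {
      lv <- sort(unique(as.character(truth)))
      if (length(lv) != 2L) stop_validation("truth must be binary")
      positive <- lv[2]
    }
    as.character(truth) == positive
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop_validation("both classes must be present to compute AUC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification report
#'
#' Standard qualitative-model metrics. Binary tasks report accuracy,
#' precision (positive predictive value), recall (sensitivity), F1 and ROC
#' AUC for the positive class. Multiclass tasks report per-class precision,
#' recall and F1 plus macro (unweighted mean) and micro (pooled) aggregates,
#' and one-versus-rest AUC (per class, macro and micro) when a score matrix
#' is given. Empty predicted or true classes contribute precision/recall 0
#' with a warning.
#'
#' @param truth True labels.
#' @param predicted Predicted labels, aligned with `truth`.
#' @param scores Optional numeric score vector (binary: scores of the
#'   positive class) or matrix with one column per class; AUC is omitted
#'   when absent.
#' @param positive Positive class for binary tasks (default
#'   `"adulterated"` when present, else the second sorted level).
#' @return An object of class `class_report`: metrics tibble, confusion
#'   matrix (true rows by predicted columns) and misclassification count.
#' @export
classification_report <- function(truth, predicted, scores = NULL,
                                  positive = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop_validation("truth and predicted lengths differ")
  }
  lev <- sort(union(truth, predicted))
  cm <- table(factor(truth, lev), factor(predicted, lev))
  names(dimnames(cm)) <- c("truth", "predicted")
  n <- length(truth)
  acc <- sum(diag(cm)) / n
  miscls <- n - sum(diag(cm))
  binary <- length(lev) == 2L
  if (!is.null(scores) && is.matrix(scores)) {
    if (is.null(colnames(scores)) || !all(lev %in% colnames(scores))) {
      stop_contract("score matrix must have one named column per class (%s)",
                    paste(lev, collapse = ", "))
    }
  }
  if (binary) {
    if (is.null(positive)) {
      positive <- if ("adulterated" %in% lev) "adulterated" else lev[2]
    }
    neg <- setdiff(lev, positive)
    tp <- cm[positive, positive]; fp <- cm[neg, positive]
    fn <- cm[positive, neg]; tn <- cm[neg, neg]
    prec <- if (tp + fp > 0) tp / (tp + fp) else { warn("no predicted positives"); 0 }
    rec <- if (tp + fn > 0) tp / (tp + fn) else { warn("no true positives"); 0 }
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    auc <- NA_real_
    if (!is.null(scores)) {
      sc <- if (is.matrix(scores)) scores[, positive] else scores
      auc <- auc_roc(truth, sc, positive = positive)
    }
    metrics <- tibble(metric = c("accuracy", "precision", "recall", "f1", "auc"),
                      value = c(acc, prec, rec, f1, auc))
    per_class <- NULL
  } else {
    per <- purrr::map(lev, function(cl) {
      tp <- cm[cl, cl]
      fp <- sum(cm[, cl]) - tp
      fn <- sum(cm[cl, ]) - tp
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      auc <- NA_real_
      if (!is.null(scores) && is.matrix(scores) && length(unique(truth == cl)) == 2L) {
        auc <- auc_roc(truth == cl, scores[, cl])
      }
      tibble(class = cl, tp = tp, fp = fp, fn = fn,
             precision = prec, recall = rec, f1 = f1, auc = auc)
    })
    per_class <- dplyr::bind_rows(per)
    if (any(per_class$tp + per_class$fp == 0) ||
        any(per_class$tp + per_class$fn == 0)) {
      warn("a class has no predictions or no true members; its precision/recall count as 0")
    }
    tp_tot <- sum(per_class$tp)
    fp_tot <- sum(per_class$fp)
    fn_tot <- sum(per_class$fn)
    micro_prec <- tp_tot / (tp_tot + fp_tot)
    micro_rec <- tp_tot / (tp_tot + fn_tot)
    micro_f1 <- 2 * micro_prec * micro_rec / (micro_prec + micro_rec)
    micro_auc <- NA_real_
    if (!is.null(scores) && is.matrix(scores)) {
      ind <- as.vector(outer(truth, lev, "=="))
      sc <- as.vector(scores[, lev])
      micro_auc <- auc_roc(ind, sc)
    }
    metrics <- tibble(
      metric = c("accuracy",
                 "macro_precision", "macro_recall", "macro_f1", "macro_auc",
                 "micro_precision", "micro_recall", "micro_f1", "micro_auc"),
      value = c(acc,
                mean(per_class$precision), mean(per_class$recall),
                mean(per_class$f1), mean(per_class$auc),
                micro_prec, micro_rec, micro_f1, micro_auc))
  }
  structure(list(metrics = metrics, confusion = cm, per_class = per_class,
                 misclassified = miscls, n = n, binary = binary),
            class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("<class_report> %d samples, %d misclassified (accuracy %.4f)\n",
              x$n, x$misclassified,
              x$metrics$value[x$metrics$metric == "accuracy"]))
  print(x$metrics, n = nrow(x$metrics))
  invisible(x)
}

#' @method tidy class_report
#' @export
tidy.class_report <- function(x, ...) x$metrics

#' @method glance class_report
#' @export
glance.class_report <- function(x, ...) {
  tidyr::pivot_wider(x$metrics, names_from = "metric", values_from = "value")
}

#' Regression report (chemometric validation statistics)
#'
#' Computes the coefficient of determination (R2 = 1 - SSres/SStot) and the
#' root mean square error for a calibration or prediction set. For the
#' prediction set the ratio of prediction to deviation is added:
#' RPD = SD / RMSEP, where SD is the standard deviation (sample convention,
#' n - 1) of the true values in the prediction set. A perfect prediction
#' reports RPD as `Inf`.
#'
#' @param truth True values (non-constant).
#' @param predicted Predicted values, aligned.
#' @param set `"calibration"` or `"prediction"`.
#' @return A tibble of class `reg_report`: `set`, `r2`, `rmse`, and `rpd`
#'   (NA for calibration).
#' @export
regression_report <- function(truth, predicted,
                              set = c("prediction", "calibration")) {
  set <- match.arg(set)
  if (length(truth) != length(predicted)) {
    stop_validation("truth and predicted lengths differ")
  }
  if (length(truth) < 3L) stop_validation("need at least 3 samples")
  if (sd(truth) == 0) {
    stop_validation("true values are constant; R2 and RPD are undefined")
  }
  ssres <- sum((truth - predicted)^2)
  sstot <- sum((truth - mean(truth))^2)
  r2 <- 1 - ssres / sstot
  rmse <- sqrt(mean((truth - predicted)^2))
  rpd <- NA_real_
  if (set == "prediction") {
    rpd <- if (rmse == 0) Inf else sd(truth) / rmse
  }
  out <- tibble(set = set, r2 = r2, rmse = rmse, rpd = rpd, n = length(truth))
  class(out) <- c("reg_report", class(out))
  out
}

#' Aggregate a metric pipeline over repeated runs
#'
#' Re-runs a pipeline closure with per-run seeds and reports each metric's
#' mean and standard deviation over the runs (the repeated-run protocol;
#' 10 runs by default). The closure receives a single integer seed and must
#' return a named numeric vector (or single-row data frame) of metrics.
#'
#' @param pipeline `function(seed) -> named numeric vector`.
#' @param n_runs Number of runs (default 10).
#' @param base_seed Seed from which per-run seeds are derived.
#' @return A list of class `repeated_runs`: `summary` (tibble metric, mean,
#'   sd) and `runs` (per-run tibble). With a single run the SD is 0 by
#'   convention and flagged in the `note` attribute.
#' @export
repeated_runs <- function(pipeline, n_runs = 10, base_seed = 42) {
  if (n_runs < 1) stop_validation("n_runs must be >= 1")
  runs <- purrr::map(seq_len(n_runs), function(i) {
    res <- tryCatch(pipeline(derive_seed(base_seed, i)), error = function(e) {
      rlang::abort(sprintf("repeated run %d failed: %s", i, conditionMessage(e)),
                   class = "oilauth_run_error")
    })
    if (is.data.frame(res)) res <- unlist(res[1, , drop = TRUE])
    tibble(run = i, metric = names(res), value = as.numeric(res))
  })
  runs <- dplyr::bind_rows(runs)
  summary <- dplyr::summarise(
    dplyr::group_by(runs, .data$metric),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1L) sd(.data$value) else 0,
    .groups = "drop"
  )
  out <- list(summary = summary, runs = runs, n_runs = n_runs)
  if (n_runs == 1L) attr(out, "note") <- "single run: SD is 0 by convention"
  class(out) <- "repeated_runs"
  out
}

#' @export
print.repeated_runs <- function(x, ...) {
  cat(sprintf("<repeated_runs> %d runs\n", x$n_runs))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' @method tidy repeated_runs
#' @export
tidy.repeated_runs <- function(x, ...) x$summary

#' Blind-set evaluation
#'
#' Evaluates a fitted classifier on blind samples that were never seen in
#' training (enforced by sample-id disjointness) and returns the confusion
#' matrix together with a per-sample misclassification ledger listing each
#' wrong call's true and predicted class.
#'
#' @param model A fitted `oil_classifier`.
#' @param blind A feature table of blind samples with `sample_id` and
#'   `label` columns.
#' @param train_ids Character vector of training sample ids used to enforce
#'   disjointness.
#' @return A list of class `blind_eval`: `report` (a `class_report`) and
#'   `ledger` (tibble sample_id, truth, predicted for each misclassified
#'   sample).
#' @export
blind_evaluation <- function(model, blind, train_ids = character(0)) {
  stopifnot(inherits(model, "oil_classifier"))
  if (!nrow(blind)) stop_validation("blind set is empty")
  overlap <- intersect(blind$sample_id, train_ids)
  if (length(overlap)) {
    stop_contract("blind set overlaps training ids (e.g. '%s')", overlap[1])
  }
  pred <- predict(model, blind)
  scores <- as.matrix(pred[model$levels[model$levels %in% names(pred)]])
  report <- classification_report(blind$label, pred$.pred_class,
                                  scores = if (ncol(scores)) scores else NULL)
  wrong <- which(blind$label != pred$.pred_class)
  ledger <- tibble(sample_id = blind$sample_id[wrong],
                   truth = blind$label[wrong],
                   predicted = pred$.pred_class[wrong])
  structure(list(report = report, ledger = ledger), class = "blind_eval")
}

#' @export
print.blind_eval <- function(x, ...) {
  cat(sprintf("<blind_eval> %d blind samples, %d misclassified\n",
              x$report$n, nrow(x$ledger)))
  if (nrow(x$ledger)) print(x$ledger, n = min(nrow(x$ledger), 20))
  invisible(x)
}
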