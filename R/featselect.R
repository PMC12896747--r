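# Feature-importance scoring and importance-driven bin refinement.

score_table <- function(method, mz, score) {
  ord <- order(mz)
  out <- tibble(method = method, mz = mz[ord], score = score[ord])
  if (anyDuplicated(out$mz)) stop_validation("score table m/z anchors must be unique")
  class(out) <- c("score_table", class(out))
  out
}

check_xy <- function(x, labels) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(labels)) {
    stop_validation("features (%d rows) and labels (%d) disagree",
                    nrow(x), length(labels))
  }
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop_validation("need at least 2 classes")
  }
  if (any(table(droplevels(labels)) < 2L)) {
    stop_validation("every class needs at least 2 samples")
  }
  list(x = x, y = droplevels(labels))
}

score_anchors <- function(x, mz) {
  if (is.null(mz)) {
    mz <- attr(x, "mz") %||% seq_len(ncol(as.matrix(x)))
  }
  as.double(mz)
}

#' One-way ANOVA F scores per feature
#'
#' Computes, for each feature, the one-way analysis-of-variance F statistic
#' of the class grouping: between-group mean square over within-group mean
#' square. Features with zero within-group variance but distinct group
#' means receive an `Inf` sentinel, which ranks above every finite score.
#'
#' @param x Numeric feature matrix, samples in rows.
#' @param labels Class labels (factor or character), one per row.
#' @param mz Optional m/z anchor per feature column (defaults to the
#'   column index, or an `mz` attribute of `x` when present).
#' @return A `score_table` tibble: `method`, `mz`, `score`.
#' @export
anova_f <- function(x, labels, mz = NULL) {
  d <- check_xy(x, labels)
  x <- d$x; y <- d$y
  n <- nrow(x); k <- nlevels(y)
  grand <- colMeans(x)
  ssb <- numeric(ncol(x))
  ssw <- numeric(ncol(x))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    m <- colMeans(x[idx, , drop = FALSE])
    ssb <- ssb + length(idx) * (m - grand)^2
    ssw <- ssw + colSums((x[idx, , drop = FALSE] -
                            matrix(m, length(idx), ncol(x), byrow = TRUE))^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  score_table("anova_f", score_anchors(x, mz), f)
}

#' Mutual information between each feature and the class label
#'
#' Nonparametric mutual-information estimate (in nats) between a continuous
#' feature and a discrete label. The default estimator is the k-nearest-
#' neighbour estimator for mixed continuous/discrete pairs (k = 3), with a
#' tiny deterministic jitter to break ties, as is standard for rank-based
#' neighbour estimators; a histogram ("binned") estimator is available as
#' an alternative. Constant features score 0. Estimates are clamped at 0.
#'
#' @inheritParams anova_f
#' @param k Neighbour count for the kNN estimator.
#' @param estimator `"knn"` (default) or `"binned"`.
#' @param n_bins Bin count for the binned estimator.
#' @return A `score_table`.
#' @export
mutual_info <- function(x, labels, mz = NULL, k = 3L,
                        estimator = c("knn", "binned"), n_bins = 10L) {
  estimator <- match.arg(estimator)
  d <- check_xy(x, labels)
  x <- d$x; y <- d$y
  n <- nrow(x)
  scores <- numeric(ncol(x))
  jit <- with_seed(20240101L, rnorm(n))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (diff(range(v)) == 0) {
      scores[j] <- 0
      next
    }
    scores[j] <- if (estimator == "knn") {
      vj <- v + 1e-10 * max(abs(v)) * jit
      mi_knn_1d(vj, y, k)
    } else {
      mi_binned_1d(v, y, n_bins)
    }
  }
  score_table(paste0("mutual_info_", estimator), score_anchors(x, mz),
              pmax(scores, 0))
}

# kNN mutual-information estimator for one continuous variable against a
# discrete label (Ross 2014): psi(N) - <psi(N_y)> + psi(k) - <psi(m_i)>,
# where m_i counts all samples within the distance to the k-th same-class
# neighbour of sample i.
mi_knn_1d <- function(v, y, k) {
  n <- length(v)
  ord <- order(v)
  vs <- v[ord]; ys <- y[ord]
  m <- numeric(n)
  ny <- as.numeric(table(y)[as.character(y)])
  kk <- pmin(k, ny[ord] - 1L)
  valid <- kk >= 1L
  for (i in which(valid)) {
    same <- which(ys == ys[i])
    dists <- abs(vs[same] - vs[i])
    dists <- sort(dists[same != i])
    r <- dists[kk[i]]
    # count of all samples strictly within r of vs[i] (excluding self);
    # vs is sorted, so use binary bounds
    lo <- findInterval(vs[i] - r, vs, left.open = TRUE)
    hi <- findInterval(vs[i] + r, vs, left.open = FALSE, rightmost.closed = FALSE)
    m[i] <- max(hi - lo - 1L, kk[i])
  }
  if (!any(valid)) return(0)
  mi <- digamma(n) - mean(digamma(ny[ord][valid])) +
    mean(digamma(kk[valid])) - mean(digamma(m[valid]))
  mi
}

mi_binned_1d <- function(v, y, n_bins) {
  br <- quantile(v, probs = seq(0, 1, length.out = n_bins + 1L), names = FALSE)
  br <- unique(br)
  if (length(br) < 2L) return(0)
  b <- cut(v, breaks = br, include.lowest = TRUE)
  tab <- table(b, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Random-forest impurity importance per feature
#'
#' Mean decrease in Gini impurity from a 100-tree random forest, normalised
#' to sum to 1. Deterministic for a fixed seed.
#'
#' @inheritParams anova_f
#' @param n_trees Number of trees (default 100).
#' @param seed RNG seed (default 42).
#' @return A `score_table`.
#' @export
rf_importance <- function(x, labels, mz = NULL, n_trees = 100, seed = 42) {
  d <- check_xy(x, labels)
  xm <- d$x
  colnames(xm) <- sprintf("v%d", seq_len(ncol(xm)))
  fit <- with_seed(seed,
    randomForest::randomForest(x = xm, y = d$y, ntree = n_trees)
  )
  imp <- as.numeric(fit$importance[, "MeanDecreaseGini"])
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  score_table("rf_importance", score_anchors(d$x, mz), imp)
}

#' Pearson correlation of each feature with a continuous target
#'
#' Correlates every feature with the adulteration fraction (or any other
#' continuous target). Constant features get r = 0 by convention; a
#' constant target is an error.
#'
#' @inheritParams anova_f
#' @param target Numeric target vector (e.g. total adulteration fraction).
#' @return A `score_table` (scores in [-1, 1]).
#' @export
pearson_scores <- function(x, target, mz = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(target)) {
    stop_validation("features (%d rows) and target (%d) disagree",
                    nrow(x), length(target))
  }
  if (nrow(x) < 3L) stop_validation("need at least 3 samples")
  if (sd(target) == 0) stop_validation("target is constant")
  r <- suppressWarnings(as.numeric(cor(x, target)))
  r[is.na(r)] <- 0
  score_table("pearson", score_anchors(x, mz), r)
}

#' Refine a bin configuration from importance score tables
#'
#' Implements the importance-driven interval selection: from each score
#' table keep the `top_k` highest-scoring m/z anchors (absolute value for
#' correlation scores; `Inf` sentinels rank first; ties broken by lower
#' m/z), expand each anchor to `[anchor - window, anchor + window]`, pool
#' the intervals from all tables, merge overlapping or touching ones, and
#' emit the merged set as a sorted bin configuration with a common step.
#' The procedure is idempotent: refining the merged anchors again with the
#' same window reproduces the same configuration.
#'
#' @param tables A `score_table` or list of them.
#' @param top_k Anchors retained per table (default 5).
#' @param window Half-width of the interval around each anchor in Da
#'   (default 0.03).
#' @param step Sub-bin step of the emitted configuration (default 0.01).
#' @return A [bin_config].
#' @export
refine_bins <- function(tables, top_k = 5, window = 0.03, step = 0.01) {
  if (inherits(tables, "score_table")) tables <- list(tables)
  if (!length(tables)) stop_validation("no score tables supplied")
  if (top_k < 1) stop_validation("top_k must be >= 1")
  if (window <= 0) stop_validation("window must be > 0")
  anchors <- unlist(lapply(tables, function(tb) {
    stopifnot(is.data.frame(tb), all(c("mz", "score") %in% names(tb)))
    s <- tb$score
    if (any(s < 0)) s <- abs(s)  # correlation-type scores rank by magnitude
    ord <- order(-s, tb$mz)
    tb$mz[ord][seq_len(min(top_k, nrow(tb)))]
  }))
  lo <- anchors - window
  hi <- anchors + window
  merged <- merge_intervals(lo, hi)
  bin_config(start = merged$lo, end = merged$hi, step = step)
}

# Merge overlapping or touching [lo, hi] intervals; returns sorted disjoint set.
merge_intervals <- function(lo, hi, tol = 1e-9) {
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  out_lo <- lo[1]; out_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= out_hi[length(out_hi)] + tol) {
      out_hi[length(out_hi)] <- max(out_hi[length(out_hi)], hi[i])
    } else {
      out_lo <- c(out_lo, lo[i])
      out_hi <- c(out_hi, hi[i])
    }
  }
  list(lo = out_lo, hi = out_hi)
}

#' @rdname refine_bins
#' @param table A `score_table`.
#' @param path Output CSV path.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  readr::write_csv(table, path)
  invisible(path)
}
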