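#' Feature-representation configuration
#'
#' The three comparative input representations: `"non"` (original features,
#' identity), `"pca"` (principal-component scores) and `"umap"` (uniform
#' manifold approximation and projection). Features are z-scored per column
#' before PCA/UMAP, using training-set statistics for new data.
#'
#' @param method `"non"`, `"pca"` or `"umap"`.
#' @param n_components Number of output dimensions. For PCA, `NULL` (the
#'   default) selects the smallest number of components retaining
#'   `var_retain` of the variance; UMAP defaults to 2.
#' @param var_retain PCA variance-retention fraction in (0, 1] (default
#'   0.95), used when `n_components` is `NULL`.
#' @param n_neighbors,min_dist UMAP graph size and embedding compactness
#'   (defaults 15 and 0.1).
#' @param seed RNG seed for UMAP layout optimisation.
#' @return A list of class `embed_config`.
#' @export
embed_config <- function(method = c("non", "pca", "umap"), n_components = NULL,
                         var_retain = 0.95, n_neighbors = 15, min_dist = 0.1,
                         seed = 42) {
  method <- match.arg(tolower(method[1]), c("non", "pca", "umap"))
  if (!is.null(n_components) && n_components < 1) {
    stop_validation("n_components must be >= 1")
  }
  if (var_retain <= 0 || var_retain > 1) {
    stop_validation("var_retain must lie in (0, 1]")
  }
  structure(list(method = method, n_components = n_components,
                 var_retain = var_retain, n_neighbors = n_neighbors,
                 min_dist = min_dist, seed = seed),
            class = "embed_config")
}

# z-score with guarded scale (constant columns get sd 1 so they map to 0)
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' Fit a feature representation and transform the data
#'
#' @param x Numeric matrix (samples in rows) or a feature table tibble, in
#'   which case the `f....` columns are used.
#' @param config An [embed_config()].
#' @return A list of class `oil_embed` with elements `x` (the transformed
#'   matrix, samples in the input order) and the fitted transformer state;
#'   use [predict()][predict.oil_embed] to project new samples.
#' @export
embed_fit <- function(x, config = embed_config("non")) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  if (nrow(x) < 2L) stop_validation("need at least 2 samples to fit")
  stopifnot(inherits(config, "embed_config"))
  out <- list(config = config)
  if (config$method == "non") {
    out$x <- x
  } else {
    scaler <- fit_scaler(x)
    z <- apply_scaler(x, scaler)
    out$scaler <- scaler
    if (config$method == "pca") {
      p <- prcomp(z, center = FALSE, scale. = FALSE)
      ev <- p$sdev^2
      frac <- ev / sum(ev)
      rank <- sum(p$sdev > max(p$sdev) * 1e-8)
      nc <- config$n_components
      if (is.null(nc)) {
        nc <- which(cumsum(frac) >= config$var_retain - 1e-12)[1]
      }
      if (nc > rank) {
        warn(sprintf("n_components (%d) exceeds rank (%d); truncating", nc, rank))
        nc <- rank
      }
      out$rotation <- p$rotation[, seq_len(nc), drop = FALSE]
      out$explained <- frac
      out$x <- p$x[, seq_len(nc), drop = FALSE]
    } else {
      nc <- config$n_components %||% 2L
      fit <- umap_fit(z, n_components = nc, n_neighbors = config$n_neighbors,
                      min_dist = config$min_dist, seed = config$seed)
      out$umap <- fit
      out$x <- fit$embedding
    }
  }
  rownames(out$x) <- rownames(x)
  class(out) <- "oil_embed"
  out
}

#' @rdname embed_fit
#' @param object A fitted `oil_embed`.
#' @param newdata Matrix or feature table of new samples.
#' @param ... Unused.
#' @export
predict.oil_embed <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- feature_matrix(newdata)
  cfg <- object$config
  if (cfg$method == "non") return(newdata)
  z <- apply_scaler(newdata, object$scaler)
  if (cfg$method == "pca") {
    z %*% object$rotation
  } else {
    umap_transform(object$umap, z)
  }
}

#' Per-component explained-variance fractions of a fitted PCA
#'
#' @param object An `oil_embed` fitted with `method = "pca"`.
#' @return Numeric vector of variance fractions, non-increasing, summing to
#'   at most 1 (all components, not only the retained ones).
#' @export
explained_variance <- function(object) {
  if (!inherits(object, "oil_embed") || object$config$method != "pca") {
    stop_contract("explained_variance() needs a PCA-fitted oil_embed")
  }
  object$explained
}

#' @export
print.oil_embed <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<oil_embed> method=%s: %d samples -> %d dimensions\n",
              cfg$method, nrow(x$x), ncol(x$x)))
  if (cfg$method == "pca") {
    cat(sprintf("  retained variance: %.1f%%\n",
                100 * sum(x$explained[seq_len(ncol(x$x))])))
  }
  invisible(x)
}
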