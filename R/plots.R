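# ggplot2 displays for the main result types.

#' Plot a scan series as a summed spectrum
#'
#' @param series A [scan_series].
#' @param top_n Annotate the `top_n` most intense summed peaks.
#' @return A ggplot object: summed intensity against m/z.
#' @export
plot_spectrum <- function(series, top_n = 0) {
  stopifnot(inherits(series, "scan_series"))
  df <- dplyr::bind_rows(purrr::map(series$peaks, function(p) {
    tibble(mz = p[, "mz"], intensity = p[, "intensity"])
  }))
  df <- dplyr::summarise(dplyr::group_by(df, mz = round(.data$mz, 2)),
                         intensity = sum(.data$intensity), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "summed intensity",
                  title = sprintf("Sample %s", sample_id(series))) +
    ggplot2::theme_minimal()
}

#' @method autoplot tic_profile
#' @export
autoplot.tic_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$tic)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "total ion current") +
    ggplot2::theme_minimal()
}

#' @method autoplot score_table
#' @export
autoplot.score_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mz, y = .data$score)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "importance score",
                  title = object$method[1]) +
    ggplot2::theme_minimal()
}

#' Two-dimensional embedding scatter
#'
#' @param embedding An `oil_embed` (2 or more output dimensions).
#' @param labels Optional class labels, one per sample.
#' @return A ggplot object of the first two embedding dimensions.
#' @export
plot_embedding <- function(embedding, labels = NULL) {
  stopifnot(inherits(embedding, "oil_embed"))
  x <- embedding$x
  if (ncol(x) < 2L) stop_validation("embedding has fewer than 2 dimensions")
  df <- tibble(d1 = x[, 1], d2 = x[, 2],
               label = labels %||% "sample")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d1, y = .data$d2,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  colour = NULL,
                  title = toupper(embedding$config$method)) +
    ggplot2::theme_minimal()
}

#' @method autoplot class_report
#' @export
autoplot.class_report <- function(object, ...) {
  cm <- as.data.frame(object$confusion)
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot oil_quantifier
#' @export
autoplot.oil_quantifier <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
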