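#' Build a scan series
#'
#' A scan series holds the time-ordered full-scan (MS1) spectra acquired for
#' one oil sample: one centroided peak list per scan together with its
#' acquisition time. It is the in-memory form of one mzXML file.
#'
#' @param sample_id Single string identifying the sample.
#' @param times Numeric vector of acquisition times in seconds, strictly
#'   increasing, one per scan.
#' @param peaks List of the same length as `times`; element `i` is a
#'   two-column matrix or data frame with columns `mz` (ascending) and
#'   `intensity` (non-negative) for scan `i`. Empty scans are allowed.
#'
#' @return An object of class `scan_series`: a tibble with one row per scan
#'   and columns `scan`, `time` and the list-column `peaks`, carrying the
#'   sample id as an attribute.
#' @export
#' @examples
#' s <- scan_series("s1", times = c(0, 1),
#'                  peaks = list(cbind(mz = c(100, 200), intensity = c(5, 1)),
#'                               cbind(mz = 150, intensity = 2)))
#' n_scans(s)
scan_series <- function(sample_id, times, peaks) {
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id)) {
    stop_validation("sample_id must be a single string")
  }
  if (length(times) < 1L) {
    stop_validation("a scan series needs at least one scan")
  }
  if (length(times) != length(peaks)) {
    stop_validation("times (%d) and peaks (%d) lengths differ",
                    length(times), length(peaks))
  }
  if (any(!is.finite(times))) stop_validation("scan times must be finite")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_validation("scan times must be strictly increasing")
  }
  peaks <- lapply(seq_along(peaks), function(i) {
    p <- peaks[[i]]
    if (is.data.frame(p)) p <- as.matrix(p[, c("mz", "intensity")])
    if (is.null(p) || length(p) == 0L) {
      p <- matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("mz", "intensity")))
    }
    if (!is.matrix(p) || ncol(p) != 2L) {
      stop_validation("scan %d: peaks must be a two-column (mz, intensity) matrix", i)
    }
    colnames(p) <- c("mz", "intensity")
    if (nrow(p) > 1L && is.unsorted(p[, "mz"])) {
      stop_validation("scan %d: m/z values must be sorted ascending", i)
    }
    if (any(p[, "intensity"] < 0)) {
      stop_validation("scan %d: negative intensity", i)
    }
    p
  })
  out <- tibble(scan = seq_along(times), time = as.double(times), peaks = peaks)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("scan_series", class(out))
  out
}

#' @rdname scan_series
#' @param x A `scan_series`.
#' @export
n_scans <- function(x) {
  stopifnot(inherits(x, "scan_series"))
  nrow(x)
}

#' @rdname scan_series
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' @export
print.scan_series <- function(x, ...) {
  cat(sprintf("<scan_series> sample '%s': %d MS1 scans, %.2f-%.2f s\n",
              sample_id(x), nrow(x), min(x$time), max(x$time)))
  npk <- vapply(x$peaks, nrow, integer(1))
  cat(sprintf("  peaks per scan: %d-%d\n", min(npk), max(npk)))
  invisible(x)
}
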