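#' Read an mzXML file into a scan series
#'
#' Reads all MS1 scans of an mzXML file in acquisition order. MS2
#' (data-dependent fragmentation) scans, when present, are skipped: the
#' authentication features are computed from full-scan data only. Peak lists
#' are decoded by the mzR backend (base64, 32/64-bit, optional zlib).
#'
#' @param path Path to an mzXML file.
#' @param sample_id Sample identifier to attach; defaults to the file name
#'   without extension.
#'
#' @return A [scan_series].
#' @export
read_mzxml <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop_io("mzXML file not found: %s", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  handle <- tryCatch(
    suppressWarnings(mzR::openMSfile(path, backend = "pwiz")),
    error = function(e) {
      stop_format("cannot parse '%s' as mzXML: %s", path, conditionMessage(e))
    }
  )
  on.exit(try(mzR::close(handle), silent = TRUE), add = TRUE)
  hdr <- tryCatch(mzR::header(handle), error = function(e) {
    stop_format("cannot read scan headers of '%s': %s", path, conditionMessage(e))
  })
  if (nrow(hdr) < 1L) stop_format("'%s' contains no scans", path)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) < 1L) stop_format("'%s' contains no MS1 scans", path)
  ms1 <- ms1[order(hdr$retentionTime[ms1])]
  pk <- tryCatch(mzR::peaks(handle, ms1), error = function(e) {
    stop_format("cannot decode peak data in '%s' (scan %s): %s",
                path, paste(ms1, collapse = ","), conditionMessage(e))
  })
  if (is.matrix(pk)) pk <- list(pk)
  pk <- lapply(seq_along(pk), function(i) {
    m <- pk[[i]]
    colnames(m) <- c("mz", "intensity")
    if (nrow(m) > 1L && is.unsorted(m[, "mz"])) m <- m[order(m[, "mz"]), , drop = FALSE]
    m
  })
  scan_series(sample_id, times = hdr$retentionTime[ms1], peaks = pk)
}

#' Write a scan series to mzXML
#'
#' Emits a standard-conforming mzXML file (via mzR/proteowizard) so that
#' simulated samples are interchangeable with instrument exports.
#' `read_mzxml(write_mzxml(x, f))` reproduces `x` up to float precision.
#'
#' @param series A [scan_series].
#' @param path Output file path (extension `.mzXML` recommended).
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(series, path) {
  if (!inherits(series, "scan_series")) {
    stop_validation("write_mzxml() needs a scan_series")
  }
  if (nrow(series) < 1L) stop_validation("cannot write an empty scan series")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("output directory does not exist: %s", dir)
  n <- nrow(series)
  pk <- lapply(series$peaks, function(p) {
    storage.mode(p) <- "double"
    p
  })
  npk <- vapply(pk, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npk,
    totIonCurrent = vapply(pk, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = series$time,
    basePeakMZ = vapply(pk, function(p) if (nrow(p)) p[which.max(p[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(p) if (nrow(p)) max(p[, 2]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pk, function(p) if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(pk, function(p) if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = 75, scanWindowUpperLimit = 1000
  )
  tryCatch(
    mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzxml"),
    error = function(e) stop_io("cannot write mzXML '%s': %s", path, conditionMessage(e))
  )
  invisible(path)
}

#' Bin configurations
#'
#' A bin configuration is the ordered list of m/z intervals used for dynamic
#' binning. Each interval is defined by a start value, an end value and a
#' step size; featurization subdivides it into contiguous sub-bins of width
#' `step`. Intervals must be non-overlapping; they are kept sorted by start.
#'
#' @param start,end,step Numeric vectors of equal length: interval start and
#'   end m/z and sub-bin width (Da).
#' @return A tibble of class `bin_config` with columns `start`, `end`, `step`.
#' @export
#' @examples
#' bin_config(start = 74.99, end = 75.11, step = 0.01)
bin_config <- function(start, end, step) {
  df <- tibble(start = as.double(start), end = as.double(end),
               step = as.double(step))
  validate_bin_config(df)
}

validate_bin_config <- function(df, where = "bin configuration") {
  need <- c("start", "end", "step")
  if (!all(need %in% names(df))) {
    stop_validation("%s must have columns start, end, step", where)
  }
  df <- as_tibble(df[need])
  if (nrow(df) < 1L) stop_validation("%s has no intervals", where)
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | !is.finite(df$step))
  if (length(bad)) stop_validation("%s: non-finite values at row %d", where, bad[1])
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop_validation("%s: start >= end at row %d (%g >= %g)",
                    where, bad[1], df$start[bad[1]], df$end[bad[1]])
  }
  bad <- which(df$step <= 0)
  if (length(bad)) stop_validation("%s: step <= 0 at row %d", where, bad[1])
  bad <- which(df$step > (df$end - df$start) + 1e-12)
  if (length(bad)) {
    stop_validation("%s: step wider than interval at row %d", where, bad[1])
  }
  ord <- order(df$start)
  df <- df[ord, ]
  if (nrow(df) > 1L) {
    overlap <- which(df$start[-1] < df$end[-nrow(df)] - 1e-12)
    if (length(overlap)) {
      stop_validation("%s: intervals overlap at sorted row %d", where, overlap[1] + 1L)
    }
  }
  class(df) <- c("bin_config", class(df))
  df
}

#' @rdname bin_config
#' @param path Path to a delimited text file with columns start, end, step
#'   (header optional).
#' @export
read_bin_config <- function(path) {
  if (!file.exists(path)) stop_io("bin configuration file not found: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header,
                        col.names = c("start", "end", "step"))
  validate_bin_config(df, where = sprintf("bin configuration '%s'", basename(path)))
}

#' @rdname bin_config
#' @param config A `bin_config`.
#' @export
write_bin_config <- function(config, path) {
  config <- validate_bin_config(config)
  readr::write_csv(config, path)
  invisible(path)
}

#' Packaged default bin configuration
#'
#' The 92-interval default configuration shipped with the package. It places
#' fine 0.01-Da sub-bins over the class-informative volatile region
#' (m/z 100-300) and the triglyceride region (m/z 800-1000) and coarse
#' sub-bins elsewhere, expanding to 666 sub-bins in total, so the complete
#' feature vector has 666 x 5 + 8 = 3338 dimensions.
#'
#' @return A `bin_config` with 92 intervals.
#' @export
default_bin_config <- function() {
  read_bin_config(system.file("extdata", "bins_default.csv",
                              package = "oilauth", mustWork = TRUE))
}

#' Read and write feature tables
#'
#' Feature tables are delimited text with one row per sample: `sample_id`,
#' `label`, the five composition columns `frac_cao` ... `frac_suo`, then the
#' feature columns `f0001` ... `fNNNN`.
#'
#' @param features A tibble as produced by [featurize_dataset()].
#' @param path File path (CSV).
#' @return `read_feature_table()` returns the tibble; `write_feature_table()`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(features, path) {
  need <- c("sample_id", "label", fraction_cols())
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    stop_validation("feature table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  fcols <- grep("^f[0-9]+$", names(features), value = TRUE)
  readr::write_csv(features[c(need, fcols)], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_io("feature table not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "label", fraction_cols())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_format("'%s' is not a feature table (missing %s)",
                path, paste(miss, collapse = ", "))
  }
  df
}

# Matrix of feature columns from a feature table, rows named by sample_id.
feature_matrix <- function(features) {
  fcols <- grep("^f[0-9]+$", names(features), value = TRUE)
  if (!length(fcols)) stop_validation("no feature columns (f0001...) present")
  m <- as.matrix(features[fcols])
  rownames(m) <- features$sample_id
  m
}
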