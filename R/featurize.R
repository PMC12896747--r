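#' Expand a bin configuration into the sub-bin grid
#'
#' Each configured interval is subdivided into contiguous half-open sub-bins
#' `[lo, lo + step)`. When the interval width is not an exact multiple of the
#' step, the final sub-bin is truncated at the interval end. A peak exactly
#' at an interval's end m/z falls outside the interval.
#'
#' @param config A [bin_config].
#' @return A tibble of class `subbin_grid` with one row per sub-bin:
#'   `interval` (source-interval index), `bin` (global index), `lo`, `hi`.
#' @export
#' @examples
#' expand_bins(bin_config(74.99, 75.11, 0.01))  # 12 sub-bins
expand_bins <- function(config) {
  config <- validate_bin_config(config)
  pieces <- lapply(seq_len(nrow(config)), function(i) {
    s <- config$start[i]; e <- config$end[i]; st <- config$step[i]
    ratio <- (e - s) / st
    n_exact <- round(ratio)
    n <- if (abs(ratio - n_exact) < 1e-6 * max(1, n_exact)) n_exact else ceiling(ratio)
    lo <- s + (seq_len(n) - 1) * st
    hi <- pmin(s + seq_len(n) * st, e)
    tibble(interval = i, lo = lo, hi = hi)
  })
  out <- dplyr::bind_rows(pieces)
  out$bin <- seq_len(nrow(out))
  out <- out[c("interval", "bin", "lo", "hi")]
  class(out) <- c("subbin_grid", class(out))
  out
}

#' @rdname expand_bins
#' @param grid A `subbin_grid`.
#' @export
n_bins <- function(grid) {
  stopifnot(inherits(grid, "subbin_grid"))
  nrow(grid)
}

# Precompute a break/slot lookup so repeated bin_scan calls are O(n log n).
# Breaks are every distinct sub-bin boundary; slots between breaks map either
# to a sub-bin index or to 0 (a gap between configured intervals).
grid_lookup <- function(grid) {
  breaks <- c(rbind(grid$lo, grid$hi))
  ub <- sort(unique(breaks))
  slot2bin <- integer(length(ub) - 1L)
  mid <- (ub[-length(ub)] + ub[-1]) / 2
  idx <- findInterval(mid, grid$lo)
  inside <- idx >= 1L & mid < grid$hi[pmax(idx, 1L)]
  slot2bin[inside] <- grid$bin[idx[inside]]
  list(breaks = ub, slot2bin = slot2bin)
}

#' Bin one scan onto a sub-bin grid
#'
#' Sums the intensities of all peaks whose m/z falls inside each half-open
#' sub-bin. Peaks outside every configured interval contribute nothing.
#'
#' @param mz Ascending numeric vector of peak m/z values (or a two-column
#'   peaks matrix, in which case `intensity` is taken from it).
#' @param intensity Peak intensities, same length as `mz`.
#' @param grid A `subbin_grid` from [expand_bins()].
#' @return Numeric vector of length `n_bins(grid)`.
#' @export
bin_scan <- function(mz, intensity = NULL, grid) {
  if (is.matrix(mz)) {
    intensity <- mz[, 2]
    mz <- mz[, 1]
  }
  stopifnot(length(mz) == length(intensity))
  out <- numeric(n_bins(grid))
  if (!length(mz)) return(out)
  lk <- attr(grid, "lookup")
  if (is.null(lk)) lk <- grid_lookup(grid)
  slot <- findInterval(mz, lk$breaks)
  ok <- slot >= 1L & slot < length(lk$breaks)
  bin <- rep(0L, length(mz))
  bin[ok] <- lk$slot2bin[slot[ok]]
  keep <- bin > 0L
  if (any(keep)) {
    sums <- rowsum(intensity[keep], group = bin[keep])
    out[as.integer(rownames(sums))] <- sums[, 1]
  }
  out
}

#' Aggregate binned scans along the time axis
#'
#' Collapses a scans-by-bins matrix into one vector by computing, per
#' sub-bin, five statistics across scans: maximum, mean, median, standard
#' deviation and sum. The output is laid out bin-major
#' (`bin1_max, bin1_mean, bin1_median, bin1_sd, bin1_sum, bin2_max, ...`);
#' models are layout-sensitive so this ordering is fixed. The standard
#' deviation uses the population convention (divide by n), so a single scan
#' yields 0.
#'
#' @param binned Numeric matrix, scans in rows, sub-bins in columns.
#' @return Numeric vector of length `5 * ncol(binned)`.
#' @export
aggregate_time <- function(binned) {
  if (!is.matrix(binned)) binned <- matrix(binned, nrow = 1L)
  if (nrow(binned) < 1L) stop_validation("aggregate_time() needs at least one scan")
  n <- nrow(binned)
  mx <- apply(binned, 2L, max)
  mn <- colMeans(binned)
  md <- apply(binned, 2L, median)
  s2 <- colMeans(binned^2) - mn^2
  sdv <- sqrt(pmax(s2, 0))
  sm <- mn * n
  out <- rbind(mx, mn, md, sdv, sm)
  as.vector(out)
}

agg_stat_names <- function() c("max", "mean", "median", "sd", "sum")

#' Total ion chromatogram of a scan series
#'
#' @param series A [scan_series].
#' @return A tibble of class `tic_profile` with columns `time` and `tic`
#'   (per-scan summed intensity).
#' @export
tic_profile <- function(series) {
  stopifnot(inherits(series, "scan_series"))
  out <- tibble(
    time = series$time,
    tic = vapply(series$peaks, function(p) sum(p[, "intensity"]), numeric(1))
  )
  class(out) <- c("tic_profile", class(out))
  out
}

# Local maxima of y with prominence >= prom_min. Prominence of a peak is its
# height minus the higher of the two valley minima separating it from the
# nearest higher ground (or the series edge). Plateaus count once.
local_peaks <- function(y, prom_min) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  r <- rle(y)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_max <- logical(k)
  for (i in seq_len(k)) {
    leftup <- if (i == 1L) -Inf else r$values[i - 1L]
    rightup <- if (i == k) -Inf else r$values[i + 1L]
    is_max[i] <- r$values[i] > leftup && r$values[i] > rightup &&
      !(i == 1L) && !(i == k)
  }
  peaks <- starts[is_max]
  heights <- r$values[is_max]
  keep <- logical(length(peaks))
  for (j in seq_along(peaks)) {
    p <- peaks[j]; h <- heights[j]
    left <- y[seq_len(p)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(left[max(higher_l):p]) else min(left)
    right <- y[p:n]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    prom <- h - max(lmin, rmin)
    keep[j] <- prom >= prom_min
  }
  peaks[keep]
}

#' TIC shape descriptors
#'
#' Computes the eight chromatographic features of a TIC, in fixed order:
#' total peak area (trapezoidal over time), retention time of the main peak
#' (time of the TIC maximum, first occurrence on ties), signal-to-noise
#' ratio (maximum over 1.4826 x median absolute deviation, denominator
#' floored for constant profiles), number of peaks (local maxima with
#' prominence at least `peak_prominence` of the TIC maximum),
#' intensity-weighted skewness and excess kurtosis of the time profile,
#' main-peak height, and main-peak full width at half maximum (linear
#' interpolation; window edges when the TIC never falls below half height).
#' A constant TIC has skewness and kurtosis defined as 0 and no local
#' maxima, hence a peak count of 0.
#'
#' @param tic A `tic_profile` from [tic_profile()].
#' @param peak_prominence Prominence threshold for peak counting, as a
#'   fraction of the TIC maximum (default 0.05).
#' @return Named numeric vector of length 8.
#' @export
tic_features <- function(tic, peak_prominence = 0.05) {
  stopifnot(inherits(tic, "tic_profile"))
  t <- tic$time; y <- tic$tic
  n <- length(y)
  if (n < 3L) stop_validation("TIC shape statistics need at least 3 scans")
  area <- sum(diff(t) * (y[-1] + y[-n]) / 2)
  imax <- which.max(y)
  t_main <- t[imax]
  h_main <- y[imax]
  noise <- mad(y, constant = 1.4826)
  denom <- max(noise, sqrt(.Machine$double.eps) * max(1, h_main))
  snr <- if (h_main == 0) 0 else h_main / denom
  npeaks <- length(local_peaks(y, prom_min = peak_prominence * max(y)))
  ytot <- sum(y)
  rng <- diff(range(y))
  if (ytot <= 0 || rng <= 1e-12 * max(abs(y), 1)) {
    skew <- 0; kurt <- 0
  } else {
    w <- y / ytot
    mu <- sum(w * t)
    m2 <- sum(w * (t - mu)^2)
    if (m2 <= 0) {
      skew <- 0; kurt <- 0
    } else {
      skew <- sum(w * (t - mu)^3) / m2^1.5
      kurt <- sum(w * (t - mu)^4) / m2^2 - 3
    }
  }
  half <- h_main / 2
  left_t <- t[1]
  if (imax > 1L) {
    below <- which(y[seq_len(imax - 1L)] < half)
    if (length(below)) {
      i <- max(below)
      left_t <- t[i] + (half - y[i]) * (t[i + 1] - t[i]) / (y[i + 1] - y[i])
    }
  }
  right_t <- t[n]
  if (imax < n) {
    below <- which(y[(imax + 1L):n] < half)
    if (length(below)) {
      i <- imax + min(below)
      right_t <- t[i - 1] + (half - y[i - 1]) * (t[i] - t[i - 1]) / (y[i] - y[i - 1])
    }
  }
  fwhm <- right_t - left_t
  c(tic_area = area, tic_main_time = t_main, tic_snr = snr,
    tic_n_peaks = npeaks, tic_skewness = skew, tic_kurtosis = kurt,
    tic_main_height = h_main, tic_main_fwhm = fwhm)
}

#' Featurize one scan series
#'
#' Runs the full feature-extraction chain for one sample: dynamic binning of
#' every scan onto the sub-bin grid, five-statistic temporal aggregation
#' (bin-major), TIC construction and its eight shape descriptors, then
#' concatenation. With the packaged 92-interval / 666-sub-bin default grid
#' the result has 666 x 5 + 8 = 3338 dimensions.
#'
#' @param series A [scan_series].
#' @param grid A `subbin_grid` (or a [bin_config], expanded on the fly).
#' @return A one-row tibble: `sample_id` then feature columns
#'   `f0001 ... fNNNN`.
#' @export
featurize_sample <- function(series, grid = default_bin_config()) {
  if (inherits(grid, "bin_config")) grid <- expand_bins(grid)
  stopifnot(inherits(series, "scan_series"), inherits(grid, "subbin_grid"))
  attr(grid, "lookup") <- grid_lookup(grid)
  binned <- t(vapply(series$peaks, function(p) bin_scan(p, grid = grid),
                     numeric(n_bins(grid))))
  if (n_bins(grid) == 1L) binned <- matrix(binned, ncol = 1L)
  agg <- aggregate_time(binned)
  tic8 <- tic_features(tic_profile(series))
  v <- c(agg, unname(tic8))
  names(v) <- sprintf("f%04d", seq_along(v))
  dplyr::bind_cols(tibble(sample_id = sample_id(series)), as_tibble(as.list(v)))
}

#' Featurize a simulated or loaded dataset
#'
#' @param samples A list of entries, each a list with elements `series`
#'   (a [scan_series]) and `design` (one-row [mixture_design] tibble), as
#'   produced by [simulate_dataset()]; or a bare list of scan series.
#' @param grid A `subbin_grid` or [bin_config].
#' @return A feature-table tibble: `sample_id`, `label`, the five
#'   composition columns, then feature columns.
#' @export
featurize_dataset <- function(samples, grid = default_bin_config()) {
  if (inherits(grid, "bin_config")) grid <- expand_bins(grid)
  rows <- purrr::map(samples, function(s) {
    if (inherits(s, "scan_series")) {
      featurize_sample(s, grid)
    } else {
      feats <- featurize_sample(s$series, grid)
      meta <- s$design
      dplyr::bind_cols(
        tibble(sample_id = feats$sample_id, label = meta$label),
        meta[fraction_cols()],
        feats[-1]
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' Summary of a sub-bin grid per source interval
#'
#' @param grid A `subbin_grid`.
#' @return Tibble with one row per configured interval: its bounds and its
#'   sub-bin count. Useful for auditing a refined configuration.
#' @export
grid_summary <- function(grid) {
  stopifnot(inherits(grid, "subbin_grid"))
  dplyr::summarise(dplyr::group_by(as_tibble(grid), .data$interval),
                   lo = min(.data$lo), hi = max(.data$hi),
                   n_subbins = dplyr::n(), .groups = "drop")
}
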