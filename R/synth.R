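#' Enumerate the adulteration mixture design
#'
#' Builds the full combinatorial design of adulterated camellia-oil (CAO)
#' samples: for a system with k adulterants, every size-k subset of the
#' adulterant set is blended 1:1 (equal volumes), then added to CAO at each
#' gradient level, with the requested number of replicates. The gradient
#' levels are the adulteration percentages of the total volume, so the CAO
#' fraction is `1 - level/100` and each adulterant carries `level/100 / k`.
#' With 4 adulterants, 11 levels and 3 replicates this yields 132 binary,
#' 198 ternary, 132 quaternary and 33 quinary designs.
#'
#' @param systems Integer vector of adulterant counts to enumerate
#'   (1 = binary system ... 4 = quinary); default all four.
#' @param adulterants Character vector of adulterant oil codes
#'   (default COO, OLO, SOO, SUO).
#' @param levels Adulteration percentages in (0, 100); default the gradient
#'   3, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90.
#' @param replicates Replicates per gradient point (default 3).
#'
#' @return A tibble of class `mixture_design`: `sample_id`, `system`
#'   (binary/ternary/quaternary/quinary), `adulterants`, `adulteration_level`
#'   (percent), `replicate`, `label` (composition class, e.g.
#'   `CAO-B2(COO,OLO)`), and the five volume-fraction columns
#'   `frac_cao ... frac_suo` (each row sums to 1).
#' @export
#' @examples
#' nrow(enumerate_design(systems = 2))  # 198 ternary designs
enumerate_design <- function(systems = 1:4,
                             adulterants = setdiff(oil_classes(), "CAO"),
                             levels = c(3, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90),
                             replicates = 3) {
  if (!length(levels)) stop_validation("empty adulteration level list")
  if (any(levels <= 0 | levels >= 100)) {
    stop_validation("adulteration levels must lie strictly between 0 and 100")
  }
  if (replicates < 1) stop_validation("replicates must be >= 1")
  if (!all(systems %in% seq_along(adulterants))) {
    stop_validation("systems must be between 1 and the number of adulterants")
  }
  if (!all(adulterants %in% oil_classes()) || "CAO" %in% adulterants) {
    stop_validation("adulterants must be drawn from %s",
                    paste(setdiff(oil_classes(), "CAO"), collapse = ", "))
  }
  sysname <- c("binary", "ternary", "quaternary", "quinary")
  rows <- list()
  for (k in sort(systems)) {
    subsets <- utils::combn(adulterants, k, simplify = FALSE)
    for (sub in subsets) {
      for (lev in levels) {
        for (r in seq_len(replicates)) {
          fr <- setNames(numeric(5), oil_classes())
          fr["CAO"] <- 1 - lev / 100
          fr[sub] <- (lev / 100) / k
          rows[[length(rows) + 1L]] <- dplyr::bind_cols(
            tibble(
              system = sysname[k],
              adulterants = paste(sub, collapse = ","),
              adulteration_level = lev,
              replicate = r,
              label = sprintf("CAO-B%d(%s)", k, paste(sub, collapse = ","))
            ),
            as_tibble(as.list(setNames(fr, fraction_cols())))
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(
    out,
    sample_id = sprintf("%s_%s_L%02d_r%d",
                        substr(.data$system, 1, 3),
                        gsub(",", "-", .data$adulterants),
                        match(.data$adulteration_level, sort(unique(levels))),
                        .data$replicate),
    .before = 1
  )
  class(out) <- c("mixture_design", class(out))
  out
}

#' Pure-oil designs
#'
#' Design rows for unadulterated samples of each oil class (unit fraction
#' vectors), used for the pure-class arms of the classification tasks.
#'
#' @param replicates Pure replicates per oil class.
#' @param classes Oil classes to include (default all five).
#' @return A `mixture_design` tibble; `label` is the oil code and
#'   `adulteration_level` is 0 (100 for pure non-CAO oils' own level is not
#'   meaningful, so 0 denotes "no CAO adulteration design").
#' @export
pure_design <- function(replicates = 3, classes = oil_classes()) {
  if (replicates < 1) stop_validation("replicates must be >= 1")
  rows <- purrr::map(classes, function(cl) {
    fr <- setNames(as.numeric(oil_classes() == cl), fraction_cols())
    dplyr::bind_cols(
      tibble(
        sample_id = sprintf("pure_%s_r%d", cl, seq_len(replicates)),
        system = "pure", adulterants = "",
        adulteration_level = 0, replicate = seq_len(replicates), label = cl
      ),
      as_tibble(as.list(fr))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mixture_design", class(out))
  out
}

validate_design_row <- function(design) {
  fr <- as.numeric(design[1, fraction_cols()])
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop_validation("design '%s': fractions must be >= 0 and sum to 1",
                    design$sample_id[1])
  }
  fr
}

#' Build a synthetic oil profile library
#'
#' Constructs per-class reference spectra for the five oils. All classes
#' share a common peak backbone across m/z 75-1000 (volatile region plus a
#' triglyceride envelope); each class additionally carries discriminative
#' peaks concentrated in the volatile m/z 100-300 region (8 peaks) and,
#' secondarily, in the triglyceride m/z 800-1000 region (3 peaks), plus
#' class-specific intensity modulation of part of the shared backbone. The
#' discriminative peaks are placed near the anchor m/z values that the
#' packaged default bin configuration covers with fine sub-bins, emulating
#' a configuration designed around characteristic lipid compounds.
#'
#' @param seed Integer seed; the library is deterministic given the seed.
#' @param n_shared Number of shared backbone peaks (default 80).
#' @return A tibble of class `oil_profile_library`: columns `oil`, `mz`,
#'   `intensity` (mean), `rel_sd` (within-class relative standard deviation),
#'   `role` (shared/discriminative); seed stored as an attribute.
#' @export
make_profile_library <- function(seed = 42, n_shared = 80) {
  anchors_low <- seq(102, 297, by = 5)
  anchors_high <- seq(810, 990, by = 20)
  with_seed(seed, {
    # Shared backbone: identical across classes so mixtures conserve it.
    sh_mz <- sort(c(
      runif(ceiling(n_shared * 0.55), 76, 700),       # volatile/semi-volatile
      runif(floor(n_shared * 0.2), 300, 800),          # mid-range lipids
      runif(n_shared - ceiling(n_shared * 0.55) - floor(n_shared * 0.2),
            800, 1000)                                 # triglyceride envelope
    ))
    sh_int <- exp(rnorm(n_shared, mean = log(500), sd = 0.9))
    shared <- tibble(mz = sh_mz, intensity = sh_int,
                     rel_sd = runif(n_shared, 0.05, 0.15), role = "shared")
    # A subset of the backbone is class-modulated: same m/z, class-specific
    # intensity factor (oils share compounds at different abundances).
    mod_idx <- sample(n_shared, size = round(n_shared * 0.3))
    rows <- purrr::map(oil_classes(), function(cl) {
      base <- shared
      factor_cl <- exp(rnorm(length(mod_idx), 0, 0.35))
      base$intensity[mod_idx] <- base$intensity[mod_idx] * factor_cl
      low <- sample(anchors_low, 8)
      high <- sample(anchors_high, 3)
      disc <- tibble(
        mz = c(low + runif(8, -0.04, 0.04), high + runif(3, -0.03, 0.03)),
        intensity = exp(rnorm(11, mean = log(1500), sd = 0.5)),
        rel_sd = runif(11, 0.05, 0.15),
        role = "discriminative"
      )
      out <- dplyr::bind_rows(base, disc)
      out$oil <- cl
      dplyr::arrange(out[c("oil", "mz", "intensity", "rel_sd", "role")], .data$mz)
    })
    lib <- dplyr::bind_rows(rows)
    attr(lib, "seed") <- seed
    class(lib) <- c("oil_profile_library", class(lib))
    lib
  })
}

#' Instrument noise model
#'
#' Parameters of the simulated SICRIT-HRMS acquisition: per-scan
#' multiplicative intensity noise (lognormal, coefficient of variation
#' `cv`), an additive baseline (fraction of the library's maximum peak),
#' Gaussian m/z jitter, the per-scan intensity envelope over the sampling
#' window, and the scan count. Defaults emulate a 5-second ambient-source
#' exposure sampled by 20 full scans with a smooth rise-plateau-fall
#' intensity envelope, 5% intensity CV, 0.1% baseline and 0.002 Da jitter.
#' The library's within-class relative SD is drawn once per sample and
#' peak; it is active only when `cv > 0`, so a zero-noise model is fully
#' deterministic.
#'
#' @param cv Multiplicative intensity coefficient of variation (>= 0).
#' @param baseline_frac Additive baseline as a fraction of the maximum
#'   library peak intensity.
#' @param mz_jitter_sd Gaussian m/z jitter SD in Da.
#' @param n_scans Number of scans across the window (>= 1).
#' @param window Acquisition window length in seconds.
#' @param envelope Per-scan intensity scale; `"rise_fall"` (default) or
#'   `"flat"`, or a numeric vector of length `n_scans`.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(cv = 0.05, baseline_frac = 0.001, mz_jitter_sd = 0.002,
                        n_scans = 20, window = 5, envelope = "rise_fall") {
  if (cv < 0 || baseline_frac < 0 || mz_jitter_sd < 0) {
    stop_validation("noise SDs must be >= 0")
  }
  if (n_scans < 1) stop_validation("n_scans must be >= 1")
  if (is.character(envelope)) {
    envelope <- match.arg(envelope, c("rise_fall", "flat"))
    env <- if (envelope == "flat") {
      rep(1, n_scans)
    } else {
      # smooth rise-plateau-fall: raised cosine edges over the outer thirds
      u <- seq(0, 1, length.out = n_scans)
      e <- rep(1, n_scans)
      e[u < 1 / 3] <- (1 - cos(pi * u[u < 1 / 3] / (1 / 3))) / 2
      e[u > 2 / 3] <- (1 - cos(pi * (1 - u[u > 2 / 3]) / (1 / 3))) / 2
      0.05 + 0.95 * e
    }
  } else {
    if (length(envelope) != n_scans) {
      stop_validation("numeric envelope must have length n_scans")
    }
    env <- envelope
  }
  structure(list(cv = cv, baseline_frac = baseline_frac,
                 mz_jitter_sd = mz_jitter_sd, n_scans = as.integer(n_scans),
                 window = window, envelope = env),
            class = "noise_model")
}

#' Zero-noise model (deterministic simulation)
#'
#' @param n_scans,window,envelope As in [noise_model()]; envelope defaults
#'   to flat so every scan equals the expected spectrum exactly.
#' @return A `noise_model` with all stochastic components off.
#' @export
zero_noise <- function(n_scans = 5, window = 5, envelope = "flat") {
  noise_model(cv = 0, baseline_frac = 0, mz_jitter_sd = 0,
              n_scans = n_scans, window = window, envelope = envelope)
}

# Expected (noise-free) peak list of a mixture: the union of the profiles of
# all oils with nonzero fraction, each scaled by its volume fraction.
mixture_profile <- function(library, fractions) {
  stopifnot(inherits(library, "oil_profile_library"))
  pieces <- purrr::map(which(fractions > 0), function(i) {
    cl <- oil_classes()[i]
    p <- library[library$oil == cl, ]
    tibble(mz = p$mz, intensity = p$intensity * fractions[i], rel_sd = p$rel_sd)
  })
  out <- dplyr::bind_rows(pieces)
  dplyr::arrange(out, .data$mz)
}

#' Simulate the scan series of one mixture sample
#'
#' The expected spectrum is the fraction-weighted sum of the pure-oil
#' profiles (spectral linear mixing by volume). Per scan, each peak's
#' intensity is scaled by the acquisition envelope and a mean-one lognormal
#' multiplier (CV from the noise model plus the peak's within-class relative
#' SD, drawn once per sample), an additive baseline is applied, and the m/z
#' is jittered with Gaussian noise. With a zero-noise model every scan
#' equals the expected spectrum exactly.
#'
#' @param library An [make_profile_library()] result.
#' @param design One-row `mixture_design` tibble.
#' @param noise A [noise_model()].
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return A [scan_series].
#' @export
simulate_scan_series <- function(library, design, noise = noise_model(),
                                 seed = 1) {
  fr <- validate_design_row(design)
  prof <- mixture_profile(library, fr)
  base_level <- noise$baseline_frac * max(library$intensity)
  times <- seq(0, noise$window, length.out = noise$n_scans + 1L)[-1L]
  np <- nrow(prof)
  with_seed(seed, {
    # Within-class biological variability: one draw per peak per sample,
    # active only under a stochastic acquisition (cv > 0).
    samp_fac <- if (noise$cv > 0) {
      exp(rnorm(np, 0, prof$rel_sd) - prof$rel_sd^2 / 2)
    } else {
      rep(1, np)
    }
    sigma <- sqrt(log(1 + noise$cv^2))
    peaks <- purrr::map(seq_len(noise$n_scans), function(s) {
      fac <- if (noise$cv > 0) {
        exp(rnorm(np, 0, sigma) - sigma^2 / 2)
      } else {
        rep(1, np)
      }
      inten <- noise$envelope[s] * (prof$intensity * samp_fac * fac + base_level)
      mz <- prof$mz + if (noise$mz_jitter_sd > 0) {
        rnorm(np, 0, noise$mz_jitter_sd)
      } else {
        0
      }
      ord <- order(mz)
      cbind(mz = mz[ord], intensity = inten[ord])
    })
    scan_series(design$sample_id[1], times = times, peaks = peaks)
  })
}

#' Simulate a full dataset
#'
#' One scan series per design row, plus optional pure-oil replicates for
#' every class. Sample ids must be unique.
#'
#' @param library An [make_profile_library()] result.
#' @param designs A `mixture_design` tibble (may be empty, `NULL`, or have
#'   zero rows).
#' @param noise A [noise_model()].
#' @param pure_replicates Pure samples per oil class to append (default 0).
#' @param seed Base seed; each sample uses a derived per-sample seed.
#' @return A list of class `oil_dataset`; each element is
#'   `list(series = scan_series, design = one-row design tibble)`.
#' @export
simulate_dataset <- function(library, designs = NULL, noise = noise_model(),
                             pure_replicates = 0, seed = 1) {
  all_designs <- list()
  if (!is.null(designs) && nrow(designs)) all_designs <- c(all_designs, list(designs))
  if (pure_replicates > 0) {
    all_designs <- c(all_designs, list(pure_design(pure_replicates)))
  }
  if (!length(all_designs)) stop_validation("nothing to simulate")
  design <- dplyr::bind_rows(all_designs)
  if (anyDuplicated(design$sample_id)) {
    stop_validation("duplicate sample_id in design: %s",
                    design$sample_id[duplicated(design$sample_id)][1])
  }
  out <- purrr::map(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    list(series = simulate_scan_series(library, row, noise,
                                       seed = derive_seed(seed, i)),
         design = row)
  })
  class(out) <- c("oil_dataset", class(out))
  out
}

#' @export
print.oil_dataset <- function(x, ...) {
  labs <- vapply(x, function(s) s$design$label, character(1))
  cat(sprintf("<oil_dataset> %d samples across %d composition classes\n",
              length(x), length(unique(labs))))
  invisible(x)
}

#' Design table of a simulated dataset
#'
#' @param dataset An `oil_dataset`.
#' @return The stacked `mixture_design` tibble, one row per sample.
#' @export
dataset_design <- function(dataset) {
  stopifnot(inherits(dataset, "oil_dataset"))
  dplyr::bind_rows(purrr::map(dataset, "design"))
}
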