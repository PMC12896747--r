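# Shared fixtures, built in code. The expensive seeded simulation used by
# the separability/recovery checks is computed lazily once per session.

tiny_series <- function(id = "s1", n = 3) {
  scan_series(id,
              times = seq_len(n),
              peaks = lapply(seq_len(n), function(i) {
                cbind(mz = c(100.005, 200.5, 750.2),
                      intensity = c(10, 5, 2) * i)
              }))
}

tiny_grid <- function() expand_bins(bin_config(74.99, 75.11, 0.01))

.fixture_env <- new.env(parent = emptyenv())

fixture_library <- function() {
  if (is.null(.fixture_env$lib)) .fixture_env$lib <- make_profile_library(seed = 101)
  .fixture_env$lib
}

# Seeded default-noise dataset at the study conditions: the full
# adulteration design (495 mixtures across the four systems) plus 15 pure
# replicates per oil class, featurized with the packaged grid. Built once
# per session; shared by the classifier, embedding and recovery checks.
fixture_full_features <- function() {
  if (is.null(.fixture_env$full_features)) {
    lib <- fixture_library()
    ds <- simulate_dataset(lib, enumerate_design(), noise_model(),
                           pure_replicates = 15, seed = 11)
    .fixture_env$full_features <- featurize_dataset(ds)
  }
  .fixture_env$full_features
}

# Pure-vs-adulterated relabelling of the full dataset (drops pure
# adulterant-oil samples).
fixture_binary_task <- function() {
  ft <- fixture_full_features()
  keep <- ft$label == "CAO" | startsWith(ft$label, "CAO-")
  ft <- ft[keep, ]
  ft$label <- ifelse(ft$label == "CAO", "pure", "adulterated")
  ft
}

fraction_matrix <- function(features) as.matrix(features[fraction_cols_vec()])

fraction_cols_vec <- function() paste0("frac_", c("cao", "coo", "olo", "soo", "suo"))
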