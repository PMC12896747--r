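# Internal helpers shared across the pipeline.

# Condition helpers: every user-facing validation failure is signalled with a
# classed condition so callers (and the command-line wrapper) can branch on it.
stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "oilauth_validation_error")
}

stop_io <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "oilauth_io_error")
}

stop_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "oilauth_format_error")
}

stop_contract <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "oilauth_contract_error")
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying inside
# the 32-bit signed-integer range R requires of set.seed().
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483629L)
}

#' Canonical oil class codes
#'
#' The five oil classes of the adulteration design: camellia oil (CAO) and
#' the four adulterants corn (COO), olive (OLO), soybean (SOO) and
#' sunflower (SUO) oil.
#'
#' @return Character vector of the five oil codes, CAO first.
#' @export
oil_classes <- function() c("CAO", "COO", "OLO", "SOO", "SUO")

fraction_cols <- function() paste0("frac_", tolower(oil_classes()))

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
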