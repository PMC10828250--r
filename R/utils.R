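## Internal helpers: classed conditions and seeded sub-streams.

abort_range <- function(msg, ...) abort(msg, class = "agecovar_error_range", ...)
abort_domain <- function(msg, ...) abort(msg, class = "agecovar_error_domain", ...)
abort_config <- function(msg, ...) abort(msg, class = "agecovar_error_config", ...)
abort_parse <- function(msg, ...) abort(msg, class = "agecovar_error_parse", ...)
abort_contract <- function(msg, ...) abort(msg, class = "agecovar_error_contract", ...)

#' Derive independent sub-stream seeds from one master seed
#'
#' One master seed drives one generator; each simulation stage (baselines,
#' slopes, observation ages, measurement noise) consumes its own derived
#' sub-seed so that, e.g., switching noise on does not perturb the baseline
#' draws.
#'
#' @param seed Master seed (single integer).
#' @param n_streams Number of sub-seeds to derive.
#' @return Integer vector of length `n_streams`, each in `[1, 2^31 - 1]`.
#' @keywords internal
#' @noRd
substream_seeds <- function(seed, n_streams = 4L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n_streams)
}

## Run `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
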