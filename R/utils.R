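# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's `.Random.seed`, so
#' package functions never clobber user-level random streams.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(as.integer(seed))
  force(code)
}

# Derive n reproducible sub-seeds from one master seed (splittable contract:
# every stochastic stage consumes its own stream).
split_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# quantile() type 7 everywhere; named wrapper so the convention is explicit
qtile <- function(x, p) stats::quantile(x, p, names = FALSE, type = 7)

stop_ns <- function(...) stop(..., call. = FALSE)
warn_ns <- function(...) warning(..., call. = FALSE)
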