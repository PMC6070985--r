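#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded internals (fit restarts, permutation
#' p-values) never disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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
  })
  set.seed(seed)
  expr
}

# Validate a vector of event times: finite, non-negative, strictly increasing.
check_event_times <- function(times, what = "response_times") {
  if (length(times) == 0L) {
    return(invisible(numeric(0)))
  }
  if (!is.numeric(times) || anyNA(times) || any(!is.finite(times))) {
    stop(what, " must be finite numeric values", call. = FALSE)
  }
  if (any(times < 0)) {
    stop(what, " must be non-negative", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop(what, " must be strictly increasing", call. = FALSE)
  }
  invisible(times)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a finite numeric scalar", call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(name, " out of range [", lower, ", ", upper, "]", call. = FALSE)
  }
  invisible(x)
}

# Small deterministic sub-seed derivation (keeps results < 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + 104729 * as.numeric(k)) %% 2147483629) + 1L
}
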