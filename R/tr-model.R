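#' Temporal-regulation mixture parameters
#'
#' Parameter vector of the shifted three-component inter-response-time (IRT)
#' mixture used to characterise DRL responding.  With probability `p` an IRT
#' is a *timed* response, gamma-distributed with shape `N` and scale `c`
#' (mean `N * c`, centred near the schedule criterion in trained animals);
#' with probability `q * (1 - p)` it is a *burst* response, exponential with
#' decay rate `L` (fast, sub-second); with probability `(1 - q) * (1 - p)`
#' it is a *long* (task-delinquent) pause, exponential with the slow decay
#' rate `Lprime`.  All components are shifted right by `delta`, the smallest
#' IRT the subject can emit.
#'
#' @param p Proportion of timed IRTs, in `[0, 1]`.
#' @param q Proportion of bursts among non-timed IRTs, in `[0, 1]`.
#' @param N Gamma shape of the timed component, positive.
#' @param c Gamma scale of the timed component, seconds, positive.
#' @param L Burst decay rate, 1/seconds, positive.
#' @param Lprime Long-pause decay rate, 1/seconds, positive.
#' @param delta Shift (smallest elicitable IRT), seconds, non-negative.
#' @return A list of class `tr_params`.
#' @examples
#' tr_params(p = 0.7, q = 0.6, N = 6, c = 2.67, L = 2, Lprime = 0.05,
#'           delta = 0.3)
#' @export
tr_params <- function(p, q, N, c, L, Lprime, delta = 0) {
  check_scalar(p, "p", lower = 0, upper = 1)
  check_scalar(q, "q", lower = 0, upper = 1)
  check_scalar(N, "N", lower = 0, strict_lower = TRUE)
  check_scalar(c, "c", lower = 0, strict_lower = TRUE)
  check_scalar(L, "L", lower = 0, strict_lower = TRUE)
  check_scalar(Lprime, "Lprime", lower = 0, strict_lower = TRUE)
  check_scalar(delta, "delta", lower = 0)
  structure(
    list(p = p, q = q, N = N, c = c, L = L, Lprime = Lprime, delta = delta),
    class = "tr_params"
  )
}

#' @export
print.tr_params <- function(x, ...) {
  cat("<tr_params>\n")
  cat(sprintf("  p = %.4g, q = %.4g, N = %.4g, c = %.4g\n",
              x$p, x$q, x$N, x$c))
  cat(sprintf("  L = %.4g, L' = %.4g, delta = %.4g\n",
              x$L, x$Lprime, x$delta))
  pr <- derived_proportions(x$p, x$q)
  cat(sprintf("  proportions: timed %.3f, burst %.3f, long %.3f; mean timed IRT %.3g s\n",
              pr[["prop_timed"]], pr[["prop_burst"]], pr[["prop_long"]],
              x$N * x$c))
  invisible(x)
}

#' Mixture density, distribution function and likelihood
#'
#' `tr_pdf()` evaluates the density of the timing mixture
#' `p * dgamma(t - delta; N, c) + q(1-p) * L * exp(-L (t - delta)) +
#' (1-q)(1-p) * Lprime * exp(-Lprime (t - delta))` (zero below `delta`);
#' `tr_cdf()` the corresponding distribution function; `tr_nll()` the
#' negative log-likelihood of a sample of IRTs.  IRTs at or below `delta`
#' (possible after rounding) contribute a floor density of `1e-12` so the
#' log-likelihood stays finite.
#'
#' @param t Evaluation times, seconds.
#' @param params A [tr_params()] object.
#' @param irts Non-negative IRTs in seconds, at least 2.
#' @return `tr_pdf`/`tr_cdf`: numeric vector the length of `t`.
#'   `tr_nll`: a scalar negative log-likelihood.
#' @examples
#' pars <- tr_params(0.7, 0.6, 6, 2.67, 2, 0.05, 0.3)
#' tr_pdf(c(0.5, 5, 16), pars)
#' tr_cdf(15, pars)
#' @export
tr_pdf <- function(t, params) {
  stopifnot(inherits(params, "tr_params"))
  x <- t - params$delta
  w_burst <- params$q * (1 - params$p)
  w_long <- (1 - params$q) * (1 - params$p)
  out <- params$p * dgamma(x, shape = params$N, scale = params$c) +
    w_burst * dexp(x, rate = params$L) +
    w_long * dexp(x, rate = params$Lprime)
  out[x < 0] <- 0
  out
}

#' @rdname tr_pdf
#' @export
tr_cdf <- function(t, params) {
  stopifnot(inherits(params, "tr_params"))
  x <- pmax(t - params$delta, 0)
  w_burst <- params$q * (1 - params$p)
  w_long <- (1 - params$q) * (1 - params$p)
  params$p * pgamma(x, shape = params$N, scale = params$c) +
    w_burst * pexp(x, rate = params$L) +
    w_long * pexp(x, rate = params$Lprime)
}

#' @rdname tr_pdf
#' @export
tr_nll <- function(irts, params) {
  if (length(irts) < 2L) {
    stop("at least 2 IRTs are required for a likelihood", call. = FALSE)
  }
  if (any(irts < 0)) {
    stop("IRTs must be non-negative", call. = FALSE)
  }
  dens <- tr_pdf(irts, params)
  -sum(log(pmax(dens, 1e-12)))
}

#' Derived response-inhibition indices
#'
#' `response_threshold()` is the mean timed IRT relative to the DRL
#' criterion, `theta = N * c / criterion`; values below 1 mark premature
#' (low-accuracy) timing and carry a `"low_accuracy"` attribute.
#' `derived_proportions()` maps the mixing parameters to the proportions of
#' timed, burst and long IRTs, which sum to one exactly.
#' `weber_fraction()` is the relative precision of the timed component,
#' `omega = 1 / sqrt(N)` (the coefficient of variation of a gamma with
#' shape `N`).
#'
#' @param N,c Gamma shape and scale of the timed component.
#' @param criterion DRL criterion in seconds (default 15).
#' @param p,q Mixing parameters in `[0, 1]`.
#' @return `response_threshold`: scalar theta with a logical
#'   `"low_accuracy"` attribute.  `derived_proportions`: named vector
#'   `(prop_timed, prop_burst, prop_long)`.  `weber_fraction`: scalar omega.
#' @examples
#' response_threshold(6, 2.5)        # exactly 1
#' derived_proportions(0.67, 0.485)  # sums to 1
#' weber_fraction(4)                 # 0.5
#' @export
response_threshold <- function(N, c, criterion = 15) {
  check_scalar(N, "N", lower = 0, strict_lower = TRUE)
  check_scalar(c, "c", lower = 0, strict_lower = TRUE)
  check_scalar(criterion, "criterion", lower = 0, strict_lower = TRUE)
  theta <- N * c / criterion
  attr(theta, "low_accuracy") <- theta < 1
  theta
}

#' @rdname response_threshold
#' @export
derived_proportions <- function(p, q) {
  check_scalar(p, "p", lower = 0, upper = 1)
  check_scalar(q, "q", lower = 0, upper = 1)
  c(prop_timed = p,
    prop_burst = q * (1 - p),
    prop_long = (1 - q) * (1 - p))
}

#' @rdname response_threshold
#' @export
weber_fraction <- function(N) {
  check_scalar(N, "N", lower = 0, strict_lower = TRUE)
  1 / sqrt(N)
}
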