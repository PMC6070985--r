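#' Effect sizes from an independent-samples t statistic
#'
#' `cohen_d_from_t()` converts a two-sample t statistic to Cohen's d via
#' `d = t * sqrt(1/n1 + 1/n2)`; `effect_r_from_d()` maps d to the
#' point-biserial correlation `r = d / sqrt(d^2 + 4)`.
#'
#' @param t Observed t statistic.
#' @param n1,n2 Group sizes (each at least 2).
#' @param d Cohen's d.
#' @return Scalar effect size.
#' @examples
#' d <- cohen_d_from_t(2.27, 7, 7)  # 1.213
#' effect_r_from_d(d)               # 0.52
#' @export
cohen_d_from_t <- function(t, n1, n2) {
  check_scalar(t, "t")
  if (n1 < 2 || n2 < 2) {
    stop("group sizes must be at least 2", call. = FALSE)
  }
  t * sqrt(1 / n1 + 1 / n2)
}

#' @rdname cohen_d_from_t
#' @export
effect_r_from_d <- function(d) {
  check_scalar(d, "d")
  d / sqrt(d^2 + 4)
}

#' Exact two-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup_x |ECDF_x(x) - ECDF_y(x)|`, evaluated exactly over the pooled
#' sample points (ties handled correctly).  No asymptotic p-value is
#' attached by default; with `n_perm > 0` a permutation p-value is computed
#' by reshuffling group labels, which suits the small group sizes of
#' cumulative progressive-ratio comparisons.
#'
#' @param x,y Non-empty numeric samples.
#' @param n_perm Number of label permutations for the p-value (0 = none).
#' @param seed Seed for the permutation draw.
#' @return A list of class `ks_result`: `statistic` (D), `n_x`, `n_y`,
#'   `p_value` (`NA` unless `n_perm > 0`).
#' @examples
#' ks_two_sample(c(1, 3), 2)$statistic  # 0.5
#' @export
ks_two_sample <- function(x, y, n_perm = 0, seed = 1) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("samples must not contain missing values", call. = FALSE)
  }
  d_stat <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    fa <- vapply(pts, function(v) mean(a <= v), numeric(1))
    fb <- vapply(pts, function(v) mean(b <= v), numeric(1))
    max(abs(fa - fb))
  }
  d_obs <- d_stat(x, y)
  p_val <- NA_real_
  if (n_perm > 0) {
    pooled <- c(x, y)
    nx <- length(x)
    p_val <- with_seed(seed, {
      hits <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(pooled), nx)
        d_stat(pooled[idx], pooled[-idx]) >= d_obs - 1e-12
      }, logical(1))
      (sum(hits) + 1) / (n_perm + 1)
    })
  }
  structure(
    list(statistic = d_obs, n_x = length(x), n_y = length(y),
         p_value = p_val, n_perm = n_perm),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f (n = %d, %d)", x$statistic, x$n_x, x$n_y))
  if (!is.na(x$p_value)) {
    cat(sprintf(", permutation p = %.4g (%d perms)", x$p_value, x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' Blood ethanol concentration utilities
#'
#' `bec_correct()` subtracts the instrument noise floor estimated from
#' ethanol-naive plasma (3.9 mg/dL) and clamps at zero.  `bec_in_range()`
#' checks the corrected value against the vapor-titration target range
#' (125-250 mg/dL, bounds inclusive) and reports which way to adjust vapor
#' when outside it.  `bec_mgdl_to_mm()` converts mg/dL to mM using the
#' molar mass of ethanol (46.07 g/mol); the conversion is provided for
#' convenience and is not a validated output.
#'
#' @param raw_mgdl Raw BEC in mg/dL, non-negative.
#' @param noise_floor Instrument noise floor in mg/dL.
#' @param corrected_mgdl Corrected BEC in mg/dL.
#' @param lo,hi Target range bounds in mg/dL.
#' @param mgdl BEC in mg/dL.
#' @param mw Molar mass of ethanol in g/mol.
#' @return `bec_correct`: corrected mg/dL.  `bec_in_range`: a list with
#'   `in_target` (logical) and `adjust` (`"none"`, `"up"` when below range,
#'   `"down"` when above).  `bec_mgdl_to_mm`: mM.
#' @examples
#' bec_correct(150)          # 146.1
#' bec_in_range(100)$adjust  # "up"
#' @export
bec_correct <- function(raw_mgdl, noise_floor = 3.9) {
  if (any(raw_mgdl < 0) || anyNA(raw_mgdl)) {
    stop("raw BEC must be non-negative", call. = FALSE)
  }
  pmax(0, raw_mgdl - noise_floor)
}

#' @rdname bec_correct
#' @export
bec_in_range <- function(corrected_mgdl, lo = 125, hi = 250) {
  check_scalar(corrected_mgdl, "corrected_mgdl", lower = 0)
  if (corrected_mgdl < lo) {
    list(in_target = FALSE, adjust = "up")
  } else if (corrected_mgdl > hi) {
    list(in_target = FALSE, adjust = "down")
  } else {
    list(in_target = TRUE, adjust = "none")
  }
}

#' @rdname bec_correct
#' @export
bec_mgdl_to_mm <- function(mgdl, mw = 46.07) {
  mgdl * 10 / mw
}
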