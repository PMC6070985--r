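#' Inter-response times of a session
#'
#' Differences of consecutive response times; the first IRT is measured
#' from session start (time 0).
#'
#' @param session A `drl_session` object.
#' @return Numeric vector of IRTs, one per response.
#' @examples
#' s <- simulate_session(default_tr_params())
#' length(compute_irts(s)) == length(s$response_times_s)
#' @export
compute_irts <- function(session) {
  stopifnot(inherits(session, "drl_session"))
  diff(c(0, session$response_times_s))
}

#' Efficiency of reinforcement
#'
#' The inverse impulsivity index: `100 * reinforcers / responses`.  Sessions
#' with zero responses have undefined efficiency and return `NA` with a
#' warning; weekly averaging excludes them.
#'
#' @param session A `drl_session` object.
#' @return Percent efficiency in `[0, 100]`, or `NA` for empty sessions.
#' @export
efficiency <- function(session) {
  stopifnot(inherits(session, "drl_session"))
  n <- length(session$response_times_s)
  if (n == 0L) {
    warning("session ", session$subject_id, " week ", session$week, " ",
            session$day, " has zero responses; efficiency undefined",
            call. = FALSE)
    return(NA_real_)
  }
  100 * sum(session$reinforced) / n
}

#' Bin an IRT sample into the standard half-second distribution
#'
#' 120 half-open bins of 0.5 s (`[0, 0.5), [0.5, 1), ..., [59.5, 60)`);
#' IRTs of 60 s or more are counted in an explicit overflow bucket.
#' Percentages are relative to all IRTs including overflow, so the bins sum
#' to 100 only when nothing overflows.
#'
#' @param irts Non-negative IRTs in seconds; must be non-empty.
#' @param bin_width Bin width in seconds.
#' @param n_bins Number of bins.
#' @return A list of class `binned_irt`: `bin_lo` (lower edges), `counts`,
#'   `percent`, `n_irts`, `overflow_count`, `bin_width_s`.
#' @examples
#' b <- bin_irt_distribution(c(0.6, 0.7, 14.9))
#' b$percent[b$bin_lo == 0.5]  # 66.67
#' @export
bin_irt_distribution <- function(irts, bin_width = 0.5, n_bins = 120) {
  if (length(irts) == 0L) {
    stop("cannot bin an empty IRT sample", call. = FALSE)
  }
  if (any(irts < 0) || anyNA(irts)) {
    stop("IRTs must be non-negative and non-missing", call. = FALSE)
  }
  idx <- floor(irts / bin_width)
  counts <- vapply(seq_len(n_bins) - 1L, function(k) sum(idx == k), integer(1))
  overflow <- sum(idx >= n_bins)
  structure(
    list(bin_lo = (seq_len(n_bins) - 1L) * bin_width,
         counts = counts,
         percent = 100 * counts / length(irts),
         n_irts = length(irts),
         overflow_count = overflow,
         bin_width_s = bin_width),
    class = "binned_irt"
  )
}

#' @export
print.binned_irt <- function(x, ...) {
  cat("<binned_irt> ", x$n_irts, " IRTs in ", length(x$bin_lo), " x ",
      x$bin_width_s, " s bins (", x$overflow_count, " overflow)\n", sep = "")
  invisible(x)
}

#' Weekly summary with day exclusion
#'
#' Averages per-session efficiency and reinforcer counts over the sessions
#' of one subject-week, restricted to the included days (Tuesday-Thursday
#' by default; Monday and Friday are excluded to avoid weekend-gap and
#' blood-draw confounds).  If no included day is present the means are `NA`
#' (missing, never a silent zero).
#'
#' @param sessions List of `drl_session` objects from one subject and week.
#' @param included_days Character vector of day labels to average over.
#' @return A one-row tibble: `subject_id`, `week`, `mean_efficiency`,
#'   `mean_reinforcers`, `mean_responses`, `n_sessions_used`,
#'   `sessions_used`.
#' @export
weekly_summary <- function(sessions, included_days = c("Tue", "Wed", "Thu")) {
  stopifnot(length(sessions) > 0,
            all(vapply(sessions, inherits, logical(1), "drl_session")))
  ids <- unique(vapply(sessions, `[[`, character(1), "subject_id"))
  wks <- unique(vapply(sessions, `[[`, integer(1), "week"))
  if (length(ids) != 1L || length(wks) != 1L) {
    stop("sessions must come from a single subject and week", call. = FALSE)
  }
  days <- vapply(sessions, `[[`, character(1), "day")
  keep <- sessions[days %in% included_days]
  if (length(keep) == 0L) {
    return(tibble::tibble(subject_id = ids, week = wks,
                          mean_efficiency = NA_real_,
                          mean_reinforcers = NA_real_,
                          mean_responses = NA_real_,
                          n_sessions_used = 0L,
                          sessions_used = ""))
  }
  effs <- vapply(keep, function(s) suppressWarnings(efficiency(s)), numeric(1))
  reinf <- vapply(keep, function(s) sum(s$reinforced), numeric(1))
  resp <- vapply(keep, function(s) length(s$response_times_s), numeric(1))
  tibble::tibble(
    subject_id = ids, week = wks,
    mean_efficiency = mean(effs, na.rm = TRUE),
    mean_reinforcers = mean(reinf),
    mean_responses = mean(resp),
    n_sessions_used = length(keep),
    sessions_used = paste(sort(vapply(keep, `[[`, character(1), "day")),
                          collapse = ",")
  )
}

#' Stability of session-to-session efficiency
#'
#' Performance is stable when some run of `window` consecutive sessions
#' varies by less than `threshold`, with variation measured as range over
#' mean (`(max - min) / mean`).  Returns `NA` when fewer than `window`
#' sessions are available (not assessable).
#'
#' @param efficiencies Ordered per-session efficiencies (percent).
#' @param window Run length (default 3 consecutive sessions).
#' @param threshold Relative variation bound (default 0.10, i.e. <10%).
#' @return `TRUE`, `FALSE`, or `NA` if not assessable.
#' @examples
#' stability_check(c(40, 80, 58, 59, 60))  # TRUE: last three vary ~3.4%
#' @export
stability_check <- function(efficiencies, window = 3, threshold = 0.10) {
  stopifnot(window >= 2)
  if (anyNA(efficiencies)) {
    efficiencies <- efficiencies[!is.na(efficiencies)]
  }
  n <- length(efficiencies)
  if (n < window) {
    return(NA)
  }
  for (i in seq_len(n - window + 1L)) {
    run <- efficiencies[i:(i + window - 1L)]
    m <- mean(run)
    if (m > 0 && (max(run) - min(run)) / m < threshold) {
      return(TRUE)
    }
  }
  FALSE
}

#' Compare a DRL20 challenge session with the week's DRL15 average
#'
#' Pairs the weekly mean efficiency and reinforcer count under the trained
#' criterion with the values from the single raised-criterion challenge
#' session, for downstream paired statistics.
#'
#' @param week_sessions List of `drl_session` objects under the trained
#'   (DRL15) criterion from one subject-week.
#' @param challenge_session The single challenge `drl_session` (criterion
#'   20 s).
#' @param included_days Days included in the weekly average.
#' @return A one-row tibble: `subject_id`, `drl15_efficiency`,
#'   `challenge_efficiency`, `efficiency_diff` (challenge minus weekly),
#'   `drl15_reinforcers`, `challenge_reinforcers`.
#' @export
challenge_comparison <- function(week_sessions, challenge_session,
                                 included_days = c("Tue", "Wed", "Thu")) {
  if (missing(challenge_session) || !inherits(challenge_session, "drl_session")) {
    stop("a challenge session is required", call. = FALSE)
  }
  if (challenge_session$schedule$kind != "DRL" ||
      challenge_session$schedule$criterion_s <= 15) {
    stop("challenge session must use a raised DRL criterion (e.g. 20 s)",
         call. = FALSE)
  }
  wk <- weekly_summary(week_sessions, included_days = included_days)
  ch_eff <- suppressWarnings(efficiency(challenge_session))
  tibble::tibble(
    subject_id = wk$subject_id,
    drl15_efficiency = wk$mean_efficiency,
    challenge_efficiency = ch_eff,
    efficiency_diff = ch_eff - wk$mean_efficiency,
    drl15_reinforcers = wk$mean_reinforcers,
    challenge_reinforcers = sum(challenge_session$reinforced)
  )
}
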