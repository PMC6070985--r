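#' Schedule configurations
#'
#' Constructors for the three reinforcement schedules used in DRL response
#' inhibition experiments: plain DRL-N (a response is reinforced only when
#' the inter-response time exceeds the criterion), adjusting DRL (the
#' criterion grows by a fixed fraction after every reinforced response until
#' it reaches the target, carrying over between sessions), and progressive
#' ratio (the response cost of each successive reinforcer climbs through a
#' progression until the subject pauses for the hang limit).
#'
#' @param criterion_s DRL criterion in seconds (15 for DRL15, 20 for the
#'   DRL20 challenge).  For adjusting DRL this is the target criterion at
#'   which the schedule saturates.
#' @param session_duration_s Session length in seconds (30-min sessions by
#'   default).
#' @param start_criterion_s Adjusting DRL only: the criterion at the start of
#'   training (2 s).
#' @param increment_fraction Adjusting DRL only: fractional criterion
#'   increase applied after each reinforced response (0.0075 = 0.75%).
#' @param progression Progressive ratio only: ordered response requirements
#'   per successive reinforcer; must be positive and non-decreasing.  The
#'   default is a test scaffold, not an empirical schedule.
#' @param hang_limit_s Progressive ratio only: length of the response pause
#'   that terminates the session (the breakpoint rule), 15 min by default.
#'
#' @return A list of class `drl_schedule` with a `kind` field (`"DRL"`,
#'   `"ADJUSTING_DRL"` or `"PR"`) and the schedule parameters.
#' @examples
#' drl_schedule(15)
#' adjusting_drl_schedule()
#' pr_schedule(progression = c(1, 2, 3))
#' @export
drl_schedule <- function(criterion_s = 15, session_duration_s = 1800) {
  check_scalar(criterion_s, "criterion_s", lower = 0, strict_lower = TRUE)
  check_scalar(session_duration_s, "session_duration_s",
               lower = 0, strict_lower = TRUE)
  structure(
    list(kind = "DRL", criterion_s = criterion_s,
         session_duration_s = session_duration_s),
    class = "drl_schedule"
  )
}

#' @rdname drl_schedule
#' @export
adjusting_drl_schedule <- function(criterion_s = 15, start_criterion_s = 2,
                                   increment_fraction = 0.0075,
                                   session_duration_s = 1800) {
  check_scalar(criterion_s, "criterion_s", lower = 0, strict_lower = TRUE)
  check_scalar(start_criterion_s, "start_criterion_s",
               lower = 0, strict_lower = TRUE)
  check_scalar(increment_fraction, "increment_fraction",
               lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(session_duration_s, "session_duration_s",
               lower = 0, strict_lower = TRUE)
  if (start_criterion_s > criterion_s) {
    stop("start_criterion_s must not exceed criterion_s", call. = FALSE)
  }
  structure(
    list(kind = "ADJUSTING_DRL", criterion_s = criterion_s,
         start_criterion_s = start_criterion_s,
         increment_fraction = increment_fraction,
         session_duration_s = session_duration_s),
    class = "drl_schedule"
  )
}

#' @rdname drl_schedule
#' @export
pr_schedule <- function(progression = c(1, 2, 4, 6, 9, 12, 15, 20, 25, 32, 40, 50),
                        hang_limit_s = 900, session_duration_s = 3600) {
  if (length(progression) == 0L || any(progression <= 0) ||
      is.unsorted(progression)) {
    stop("progression must be positive and non-decreasing", call. = FALSE)
  }
  check_scalar(hang_limit_s, "hang_limit_s", lower = 0, strict_lower = TRUE)
  check_scalar(session_duration_s, "session_duration_s",
               lower = 0, strict_lower = TRUE)
  structure(
    list(kind = "PR", progression = as.numeric(progression),
         hang_limit_s = hang_limit_s,
         session_duration_s = session_duration_s),
    class = "drl_schedule"
  )
}

#' @export
print.drl_schedule <- function(x, ...) {
  cat("<drl_schedule:", x$kind, ">\n")
  for (f in setdiff(names(x), "kind")) {
    cat("  ", f, ": ", paste(x[[f]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Score a response stream under a fixed DRL criterion
#'
#' A response is reinforced when its inter-response time (IRT) strictly
#' exceeds the criterion.  The first response of a session is timed from
#' session start (time 0), matching the timer-since-last-event behaviour of
#' operant chambers.
#'
#' @param response_times Strictly increasing, non-negative response times in
#'   seconds.
#' @param criterion DRL criterion in seconds.
#' @return A list with `reinforced` (logical per response), `n_responses`
#'   and `n_reinforcers`.
#' @examples
#' score_drl_session(c(16, 40, 45), 15)  # IRTs 16, 24, 5 -> T, T, F
#' @export
score_drl_session <- function(response_times, criterion) {
  check_event_times(response_times)
  check_scalar(criterion, "criterion", lower = 0)
  irts <- diff(c(0, response_times))
  reinforced <- irts > criterion
  list(reinforced = reinforced,
       n_responses = length(response_times),
       n_reinforcers = sum(reinforced))
}

#' Run the adjusting-DRL criterion trajectory over a response stream
#'
#' Training starts at a low criterion (2 s) which is multiplied by
#' `1 + increment_fraction` after every reinforced response, saturating at
#' the target criterion (15 s).  The criterion reached at the end of a
#' session carries over to the next session via `carry_in_s`.
#'
#' @param response_times Strictly increasing response times in seconds.
#' @param cfg An `adjusting_drl_schedule()` configuration.
#' @param carry_in_s Optional criterion carried over from the previous
#'   session; defaults to `cfg$start_criterion_s`.
#' @return A list with `criterion_trajectory` (criterion in force at each
#'   response), `reinforced` flags, `n_reinforcers` and `final_criterion_s`.
#' @export
run_adjusting_drl <- function(response_times, cfg, carry_in_s = NULL) {
  stopifnot(inherits(cfg, "drl_schedule"))
  if (cfg$kind != "ADJUSTING_DRL") {
    stop("cfg must be an adjusting DRL schedule", call. = FALSE)
  }
  check_event_times(response_times)
  crit <- if (is.null(carry_in_s)) cfg$start_criterion_s else carry_in_s
  check_scalar(crit, "carry_in_s", lower = 0, strict_lower = TRUE)
  n <- length(response_times)
  trajectory <- numeric(n)
  reinforced <- logical(n)
  prev <- 0
  for (i in seq_len(n)) {
    trajectory[i] <- crit
    irt <- response_times[i] - prev
    if (irt > crit) {
      reinforced[i] <- TRUE
      crit <- min(crit * (1 + cfg$increment_fraction), cfg$criterion_s)
    }
    prev <- response_times[i]
  }
  list(criterion_trajectory = trajectory, reinforced = reinforced,
       n_reinforcers = sum(reinforced), final_criterion_s = crit)
}

#' Reinforced responses needed to raise an adjusting-DRL criterion
#'
#' Closed form of the multiplicative progression: the smallest integer `k`
#' with `start_s * (1 + increment_fraction)^k >= target_s`.  With the
#' conventional 2 s start, 15 s target and 0.75% increments this is 270.
#'
#' @param start_s Starting criterion, seconds.
#' @param target_s Target criterion, seconds; must be `>= start_s`.
#' @param increment_fraction Fractional increment per reinforced response.
#' @return Integer count of reinforced responses.
#' @examples
#' reinforcers_to_reach(2, 15, 0.0075)  # 270
#' @export
reinforcers_to_reach <- function(start_s, target_s, increment_fraction = 0.0075) {
  check_scalar(start_s, "start_s", lower = 0, strict_lower = TRUE)
  check_scalar(target_s, "target_s", lower = 0, strict_lower = TRUE)
  check_scalar(increment_fraction, "increment_fraction",
               lower = 0, strict_lower = TRUE)
  if (target_s < start_s) {
    stop("target_s must be at least start_s", call. = FALSE)
  }
  if (target_s == start_s) {
    return(0L)
  }
  k <- ceiling(log(target_s / start_s) / log1p(increment_fraction))
  # guard float rounding at the boundary
  while (k > 0 && start_s * (1 + increment_fraction)^(k - 1) >= target_s) {
    k <- k - 1
  }
  while (start_s * (1 + increment_fraction)^k < target_s) {
    k <- k + 1
  }
  as.integer(k)
}

#' Score a lever-press stream under a progressive-ratio schedule
#'
#' Each reinforcer requires the number of presses given by the next entry of
#' the progression.  The session terminates at the first inter-press gap of
#' at least the hang limit (measured between consecutive presses, and from
#' session start to the first press); presses after that gap are not
#' counted.  The breakpoint is the last ratio requirement completed.
#'
#' @param press_times Strictly increasing press times in seconds.
#' @param cfg A `pr_schedule()` configuration.
#' @return A list of class `pr_result`: `reinforcers_earned`,
#'   `breakpoint_ratio`, `total_responses`, `press_times` (counted presses),
#'   `reinforced` flags, `cumulative_curve` (cumulative presses at each
#'   1-min boundary up to termination) and `termination_time_s`.
#' @examples
#' run_progressive_ratio(1:6, pr_schedule(progression = c(1, 2, 3)))
#' @export
run_progressive_ratio <- function(press_times, cfg) {
  stopifnot(inherits(cfg, "drl_schedule"))
  if (cfg$kind != "PR") {
    stop("cfg must be a progressive-ratio schedule", call. = FALSE)
  }
  check_event_times(press_times, "press_times")

  # truncate at the first hang-limit gap
  gaps <- diff(c(0, press_times))
  hang <- which(gaps >= cfg$hang_limit_s)
  if (length(hang) > 0L) {
    press_times <- press_times[seq_len(hang[1] - 1L)]
  }
  press_times <- press_times[press_times <= cfg$session_duration_s]

  n <- length(press_times)
  reinforced <- logical(n)
  earned <- 0L
  since_last <- 0L
  for (i in seq_len(n)) {
    since_last <- since_last + 1L
    req <- if (earned < length(cfg$progression)) {
      cfg$progression[earned + 1L]
    } else {
      Inf
    }
    if (since_last >= req) {
      reinforced[i] <- TRUE
      earned <- earned + 1L
      since_last <- 0L
    }
  }
  breakpoint <- if (earned > 0L) cfg$progression[earned] else 0
  termination <- if (n == 0L) {
    cfg$hang_limit_s
  } else if (length(hang) > 0L || n < length(gaps)) {
    press_times[n] + cfg$hang_limit_s
  } else {
    max(press_times[n], 0)
  }
  termination <- min(termination, cfg$session_duration_s)
  n_bins <- max(1L, ceiling(termination / 60))
  counts <- vapply(seq_len(n_bins) * 60,
                   function(b) sum(press_times <= b), integer(1))
  counts[n_bins] <- n  # last (possibly partial) minute closes the record
  structure(
    list(reinforcers_earned = earned,
         breakpoint_ratio = breakpoint,
         total_responses = n,
         press_times = press_times,
         reinforced = reinforced,
         cumulative_curve = counts,
         termination_time_s = termination),
    class = "pr_result"
  )
}

#' @export
print.pr_result <- function(x, ...) {
  cat("<pr_result> ", x$total_responses, " presses, ",
      x$reinforcers_earned, " reinforcers, breakpoint ratio ",
      x$breakpoint_ratio, ", terminated at ",
      round(x$termination_time_s, 1), " s\n", sep = "")
  invisible(x)
}
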