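#' Default baseline timing parameters for synthetic subjects
#'
#' A DRL15-trained responder: 70% timed IRTs with mean `6 * 2.67 = 16.02` s
#' (response threshold ~1.07, just above the criterion), bursts decaying at
#' 2/s, long pauses at 0.05/s, smallest IRT 0.3 s.  The derived proportions
#' (timed 0.70, burst 0.18, long 0.12) bracket values typical of trained
#' rats.
#'
#' @return A [tr_params()] object.
#' @export
default_tr_params <- function() {
  tr_params(p = 0.7, q = 0.6, N = 6, c = 2.67, L = 2, Lprime = 0.05,
            delta = 0.3)
}

#' Sample inter-response times from the timing mixture
#'
#' Draws `n` IRTs: with probability `p` a shifted gamma (timed), with
#' probability `q (1 - p)` a shifted fast exponential (burst), otherwise a
#' shifted slow exponential (long pause).
#'
#' @param n Number of draws.
#' @param params A [tr_params()] object.
#' @return Numeric vector of `n` IRTs, all `>= params$delta`.
#' @examples
#' mean(sample_irt(1000, default_tr_params()))
#' @export
sample_irt <- function(n, params) {
  stopifnot(inherits(params, "tr_params"))
  if (n == 0L) return(numeric(0))
  u <- runif(n)
  p_timed <- params$p
  p_burst <- params$q * (1 - params$p)
  x <- numeric(n)
  timed <- u < p_timed
  burst <- !timed & u < p_timed + p_burst
  long <- !timed & !burst
  x[timed] <- rgamma(sum(timed), shape = params$N, scale = params$c)
  x[burst] <- rexp(sum(burst), rate = params$L)
  x[long] <- rexp(sum(long), rate = params$Lprime)
  params$delta + x
}

#' Simulate one operant session as a renewal process of sampled IRTs
#'
#' Response times are cumulative sums of IRTs drawn i.i.d. from the mixture,
#' truncated at the session duration; reinforced flags come from the
#' schedule engine (plain or adjusting DRL).
#'
#' @param params A [tr_params()] object.
#' @param schedule A [drl_schedule()] or [adjusting_drl_schedule()] config.
#' @param subject_id,group,reinforcer_type,week,day Session metadata.
#' @param carry_in_s Adjusting DRL only: carried-over criterion.
#' @return A list of class `drl_session` with `response_times_s`,
#'   `reinforced`, the metadata fields and the schedule; for adjusting DRL
#'   also `final_criterion_s`.
#' @export
simulate_session <- function(params, schedule = drl_schedule(),
                             subject_id = "s1", group = "CON",
                             reinforcer_type = "ETHANOL",
                             week = 0L, day = "Tue", carry_in_s = NULL) {
  stopifnot(inherits(params, "tr_params"), inherits(schedule, "drl_schedule"))
  dur <- schedule$session_duration_s
  times <- numeric(0)
  total <- 0
  repeat {
    chunk <- sample_irt(64L, params)
    times <- c(times, total + cumsum(chunk))
    total <- times[length(times)]
    if (total > dur) break
  }
  times <- times[times <= dur]
  new_session(times, params = params, schedule = schedule,
              subject_id = subject_id, group = group,
              reinforcer_type = reinforcer_type, week = week, day = day,
              carry_in_s = carry_in_s)
}

# Internal constructor: score a response stream and attach metadata.
new_session <- function(times, params = NULL, schedule,
                        subject_id, group, reinforcer_type, week, day,
                        carry_in_s = NULL, reinforced = NULL) {
  final_criterion <- NULL
  if (is.null(reinforced)) {
    if (schedule$kind == "DRL") {
      reinforced <- score_drl_session(times, schedule$criterion_s)$reinforced
    } else if (schedule$kind == "ADJUSTING_DRL") {
      res <- run_adjusting_drl(times, schedule, carry_in_s = carry_in_s)
      reinforced <- res$reinforced
      final_criterion <- res$final_criterion_s
    } else {
      stop("use run_progressive_ratio() for PR streams", call. = FALSE)
    }
  }
  structure(
    list(subject_id = subject_id, group = group,
         reinforcer_type = reinforcer_type,
         week = as.integer(week), day = day,
         response_times_s = times, reinforced = reinforced,
         schedule = schedule, final_criterion_s = final_criterion,
         true_params = params),
    class = "drl_session"
  )
}

#' @export
print.drl_session <- function(x, ...) {
  cat("<drl_session> ", x$subject_id, " (", x$group, ", ",
      x$reinforcer_type, ") week ", x$week, " ", x$day, ": ",
      length(x$response_times_s), " responses, ",
      sum(x$reinforced), " reinforcers\n", sep = "")
  invisible(x)
}

#' Week-by-week CIE effect multipliers
#'
#' Multipliers applied to a CIE subject's baseline parameters per week.
#' The default encodes the protracted-abstinence phenotype: during
#' abstinence weeks 9-11 the burst decay rate `L` is halved (a shallower
#' decay of burst responding) and the timed mean `N * c` shifts right by 5%
#' (applied to the scale `c`); `p` is untouched.
#'
#' @param weeks Weeks at which the effect is active.
#' @param L_mult,Nc_mult,p_mult Multipliers on `L`, on the timed mean
#'   `N * c` and on `p` for those weeks.
#' @return A tibble with columns `week`, `L_mult`, `Nc_mult`, `p_mult`.
#' @export
cie_effects <- function(weeks = 9:11, L_mult = 0.5, Nc_mult = 1.05,
                        p_mult = 1) {
  tibble::tibble(week = as.integer(weeks), L_mult = L_mult,
                 Nc_mult = Nc_mult, p_mult = p_mult)
}

#' Cohort design for synthetic CIE vs control experiments
#'
#' Describes a subjects x groups x weeks design emulating a
#' chronic-intermittent-ethanol timeline: week 0 pre-vapor, weeks 1-6 CIE
#' (or air for controls), weeks 7-11 forced abstinence, 5 sessions per week
#' (Mon-Fri), 30-min DRL15 sessions, 8 subjects per group.  Control
#' subjects keep the baseline parameters throughout; CIE subjects get the
#' `effects` multipliers in the scheduled weeks.  Log-normal subject-level
#' heterogeneity multiplies the timed mean and burst rate.
#'
#' @param n_per_group Subjects per group.
#' @param baseline_params Baseline [tr_params()].
#' @param effects A [cie_effects()] tibble.
#' @param weeks Week indices simulated.
#' @param sessions_per_week Sessions per week (1-5, labelled Mon..Fri).
#' @param schedule Session schedule config.
#' @param reinforcer_type `"ETHANOL"` or `"SUCROSE"` label.
#' @param subject_sdlog Log-normal sd of per-subject multipliers on
#'   `N * c` and `L` (0 disables heterogeneity).
#' @param seed Integer master seed; each subject gets its own derived
#'   stream, so cohorts are reproducible.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 8,
                        baseline_params = default_tr_params(),
                        effects = cie_effects(),
                        weeks = 0:11,
                        sessions_per_week = 5,
                        schedule = drl_schedule(15, 1800),
                        reinforcer_type = "ETHANOL",
                        subject_sdlog = 0.1,
                        seed = 1) {
  stopifnot(n_per_group >= 1, sessions_per_week >= 1, sessions_per_week <= 5,
            inherits(baseline_params, "tr_params"),
            inherits(schedule, "drl_schedule"))
  structure(
    list(n_per_group = as.integer(n_per_group),
         baseline_params = baseline_params,
         effects = effects, weeks = as.integer(weeks),
         sessions_per_week = as.integer(sessions_per_week),
         schedule = schedule, reinforcer_type = reinforcer_type,
         subject_sdlog = subject_sdlog, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Internal: parameters in force for one subject in one week.
subject_week_params <- function(baseline, group, week, effects,
                                nc_mult_subj = 1, l_mult_subj = 1) {
  p <- baseline$p
  c_ <- baseline$c * nc_mult_subj
  L <- baseline$L * l_mult_subj
  if (group == "CIE") {
    row <- effects[effects$week == week, ]
    if (nrow(row) == 1L) {
      L <- L * row$L_mult
      c_ <- c_ * row$Nc_mult
      p <- min(p * row$p_mult, 0.999)
    }
  }
  tr_params(p = p, q = baseline$q, N = baseline$N, c = c_, L = L,
            Lprime = baseline$Lprime, delta = baseline$delta)
}

#' Simulate a full cohort of DRL sessions
#'
#' Generates every subject x week x day session of the design.  Each
#' subject runs on its own pseudo-random stream derived from
#' `(seed, subject index)`, so the cohort is reproducible and insensitive
#' to generation order.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `group`, `reinforcer_type`,
#'   `week`, `day` and a list-column `session` of `drl_session` objects.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_per_group = 2, weeks = 0:1, seed = 7))
#' nrow(coh)  # 2 groups x 2 subjects x 2 weeks x 5 days
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  days <- c("Mon", "Tue", "Wed", "Thu", "Fri")[seq_len(spec$sessions_per_week)]
  subjects <- expand.grid(idx = seq_len(spec$n_per_group),
                          group = c("CON", "CIE"),
                          stringsAsFactors = FALSE)
  subjects$subject_id <- sprintf("%s%02d", subjects$group, subjects$idx)
  subjects$seed <- vapply(seq_len(nrow(subjects)),
                          function(i) derive_seed(spec$seed, i), integer(1))

  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    sub <- subjects[i, ]
    with_seed(sub$seed, {
      nc_mult <- if (spec$subject_sdlog > 0) {
        rlnorm(1, sdlog = spec$subject_sdlog)
      } else 1
      l_mult <- if (spec$subject_sdlog > 0) {
        rlnorm(1, sdlog = spec$subject_sdlog)
      } else 1
      out <- list()
      for (wk in spec$weeks) {
        pars <- subject_week_params(spec$baseline_params, sub$group, wk,
                                    spec$effects, nc_mult, l_mult)
        for (d in days) {
          ses <- simulate_session(pars, spec$schedule,
                                  subject_id = sub$subject_id,
                                  group = sub$group,
                                  reinforcer_type = spec$reinforcer_type,
                                  week = wk, day = d)
          out[[length(out) + 1L]] <- ses
        }
      }
      out
    })
  })
  sessions <- unlist(rows, recursive = FALSE)
  tibble::tibble(
    subject_id = vapply(sessions, `[[`, character(1), "subject_id"),
    group = vapply(sessions, `[[`, character(1), "group"),
    reinforcer_type = vapply(sessions, `[[`, character(1), "reinforcer_type"),
    week = vapply(sessions, `[[`, integer(1), "week"),
    day = vapply(sessions, `[[`, character(1), "day"),
    session = sessions
  )
}

#' Simulate a progressive-ratio session
#'
#' Press times follow the same renewal mixture as DRL responding (trained
#' subjects keep their timing phenotype); the stream is cut by the
#' progressive-ratio engine at the first hang-limit pause.
#'
#' @param params A [tr_params()] object.
#' @param cfg A [pr_schedule()] config.
#' @inheritParams simulate_session
#' @return A `pr_result` (see [run_progressive_ratio()]) with the session
#'   metadata attached as attributes.
#' @export
simulate_pr_session <- function(params, cfg = pr_schedule(),
                                subject_id = "s1", group = "CON") {
  stopifnot(inherits(params, "tr_params"), inherits(cfg, "drl_schedule"),
            cfg$kind == "PR")
  total <- 0
  times <- numeric(0)
  repeat {
    chunk <- sample_irt(64L, params)
    times <- c(times, total + cumsum(chunk))
    total <- times[length(times)]
    if (total > cfg$session_duration_s) break
  }
  res <- run_progressive_ratio(times[times <= cfg$session_duration_s], cfg)
  attr(res, "subject_id") <- subject_id
  attr(res, "group") <- group
  res
}
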