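# Internal: pick a non-clobbering output directory ("runs never silently
# overwrite"): if `path` exists and is non-empty, append _1, _2, ...
next_out_dir <- function(path) {
  if (!dir.exists(path) || length(list.files(path)) == 0L) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    return(path)
  }
  k <- 1L
  repeat {
    cand <- paste0(path, "_", k)
    if (!dir.exists(cand)) {
      dir.create(cand, recursive = TRUE)
      return(cand)
    }
    k <- k + 1L
  }
}

# Internal: run manifest (config echo + seed + version; no timestamps, so
# reruns with the same config are byte-identical).
write_manifest <- function(out_dir, step, config) {
  manifest <- list(
    step = step,
    package = "drlmix",
    version = as.character(utils::packageVersion("drlmix")),
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a cohort and write its event logs
#'
#' Writes `events.csv` (the DRL sessions of the whole design),
#' `pr_events.csv` (one post-abstinence progressive-ratio session per
#' subject, simulated from each subject's final-week parameters) and a
#' `manifest.json` echoing the configuration and seed.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (suffixed `_1`, `_2`, ... if it already
#'   has content, so reruns never silently overwrite).
#' @param pr_config A [pr_schedule()] for the progressive-ratio session, or
#'   `NULL` to skip it.
#' @return The output directory used, invisibly.
#' @export
drl_simulate <- function(spec, out_dir, pr_config = pr_schedule()) {
  stopifnot(inherits(spec, "cohort_spec"))
  out_dir <- next_out_dir(out_dir)
  cohort <- simulate_cohort(spec)
  write_event_log(cohort, file.path(out_dir, "events.csv"))

  if (!is.null(pr_config)) {
    last_week <- max(spec$weeks)
    subjects <- unique(cohort[, c("subject_id", "group")])
    pr_rows <- lapply(seq_len(nrow(subjects)), function(i) {
      sid <- subjects$subject_id[i]
      grp <- subjects$group[i]
      pars <- subject_week_params(spec$baseline_params, grp, last_week,
                                  spec$effects)
      res <- with_seed(derive_seed(spec$seed, 10000L + i),
                       simulate_pr_session(pars, pr_config,
                                           subject_id = sid, group = grp))
      n <- res$total_responses
      if (n == 0L) return(NULL)
      t_resp <- sprintf("%.3f", res$press_times)
      tibble::tibble(
        subject_id = sid, group = grp,
        reinforcer_type = spec$reinforcer_type,
        week = last_week + 1L, day = "PR",
        event_time_s = c(t_resp, t_resp[res$reinforced]),
        event_kind = c(rep("response", n),
                       rep("reinforcer", sum(res$reinforced)))
      )
    })
    readr::write_csv(dplyr::bind_rows(pr_rows),
                     file.path(out_dir, "pr_events.csv"))
  }
  write_manifest(out_dir, "simulate", spec_to_config(spec))
  invisible(out_dir)
}

# Internal: plain-list echo of a cohort_spec for the manifest / YAML config.
spec_to_config <- function(spec) {
  list(
    n_per_group = spec$n_per_group,
    baseline_params = unclass(spec$baseline_params),
    cie_effects = as.list(spec$effects),
    weeks = spec$weeks,
    sessions_per_week = spec$sessions_per_week,
    schedule = unclass(spec$schedule),
    reinforcer_type = spec$reinforcer_type,
    subject_sdlog = spec$subject_sdlog,
    seed = spec$seed
  )
}

#' Fit the timing mixture per subject-week and write a parameter table
#'
#' Pools each subject's IRTs over the included days of each week (the
#' Tuesday-Thursday sessions by default) and fits the mixture, producing
#' one row per subject x week with the estimated parameters and derived
#' indices (proportion timed, response threshold, proportion burst, decay
#' rates, Weber fraction, shift, objective, convergence).
#'
#' @param cohort A cohort tibble (from [simulate_cohort()] or
#'   [read_event_log()]).
#' @param mode Fit objective, `"mle"` or `"cdf_lsq"`.
#' @param criterion DRL criterion in seconds.
#' @param included_days Days pooled per week.
#' @param seed Seed for fit restarts.
#' @param min_irts Subject-weeks with fewer pooled IRTs are skipped.
#' @return A tibble, one row per subject x week.
#' @export
drl_fit_table <- function(cohort, mode = "mle", criterion = 15,
                          included_days = c("Tue", "Wed", "Thu"),
                          seed = 1, min_irts = 30) {
  stopifnot(is.data.frame(cohort), "session" %in% names(cohort))
  keep <- cohort[cohort$day %in% included_days, ]
  groups <- split(keep, list(keep$subject_id, keep$week), drop = TRUE)
  rows <- lapply(groups, function(g) {
    irts <- unlist(lapply(g$session, compute_irts))
    if (length(irts) < min_irts) return(NULL)
    fit <- fit_tr_model(irts, mode = mode, criterion = criterion,
                        seed = derive_seed(seed, g$week[1] * 1000L +
                                             sum(utf8ToInt(g$subject_id[1]))))
    dplyr::bind_cols(
      tibble::tibble(subject_id = g$subject_id[1], group = g$group[1],
                     reinforcer_type = g$reinforcer_type[1],
                     week = g$week[1]),
      tr_fit_row(fit)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, subject_id, week)
}

#' Run the fit stage on an event log
#'
#' @param events_path Event-log CSV (see [read_event_log()]).
#' @param out_dir Output directory.
#' @param schedule Schedule the sessions ran under.
#' @inheritParams drl_fit_table
#' @return The output directory used, invisibly; writes `fit_params.csv`
#'   and `manifest.json`.
#' @export
drl_fit <- function(events_path, out_dir, schedule = drl_schedule(),
                    mode = "mle", included_days = c("Tue", "Wed", "Thu"),
                    seed = 1) {
  out_dir <- next_out_dir(out_dir)
  cohort <- read_event_log(events_path, schedule = schedule)
  tab <- drl_fit_table(cohort, mode = mode,
                       criterion = schedule$criterion_s,
                       included_days = included_days, seed = seed)
  readr::write_csv(tab, file.path(out_dir, "fit_params.csv"))
  write_manifest(out_dir, "fit",
                 list(events = basename(events_path), mode = mode,
                      criterion = schedule$criterion_s,
                      included_days = included_days, seed = seed))
  invisible(out_dir)
}

#' Run the descriptive analysis stage on an event log
#'
#' Writes `session_metrics.csv` (per-session responses, reinforcers,
#' efficiency), `weekly_summary.csv` (Tuesday-Thursday weekly averages) and
#' `binned_irt.csv` (the half-second binned IRT distribution per
#' subject-week in long format).
#'
#' @inheritParams drl_fit
#' @param included_days Days included in weekly averages.
#' @return The output directory used, invisibly.
#' @export
drl_analyze <- function(events_path, out_dir, schedule = drl_schedule(),
                        included_days = c("Tue", "Wed", "Thu")) {
  out_dir <- next_out_dir(out_dir)
  cohort <- read_event_log(events_path, schedule = schedule)

  metrics <- dplyr::bind_rows(lapply(cohort$session, function(s) {
    tibble::tibble(subject_id = s$subject_id, group = s$group,
                   reinforcer_type = s$reinforcer_type,
                   week = s$week, day = s$day,
                   n_responses = length(s$response_times_s),
                   n_reinforcers = sum(s$reinforced),
                   efficiency = suppressWarnings(efficiency(s)))
  }))
  readr::write_csv(dplyr::arrange(metrics, subject_id, week, day),
                   file.path(out_dir, "session_metrics.csv"))

  wk_groups <- split(cohort, list(cohort$subject_id, cohort$week), drop = TRUE)
  weekly <- dplyr::bind_rows(lapply(wk_groups, function(g) {
    dplyr::bind_cols(
      weekly_summary(g$session, included_days = included_days),
      tibble::tibble(group = g$group[1], reinforcer_type = g$reinforcer_type[1])
    )
  }))
  readr::write_csv(dplyr::arrange(weekly, subject_id, week),
                   file.path(out_dir, "weekly_summary.csv"))

  binned <- dplyr::bind_rows(lapply(wk_groups, function(g) {
    keep <- g$session[g$day %in% included_days]
    irts <- unlist(lapply(keep, compute_irts))
    if (length(irts) == 0L) return(NULL)
    b <- bin_irt_distribution(irts)
    tibble::tibble(subject_id = g$subject_id[1], group = g$group[1],
                   week = g$week[1], bin_lo = b$bin_lo,
                   percent = b$percent, n_irts = b$n_irts,
                   overflow_count = b$overflow_count)
  }))
  readr::write_csv(dplyr::arrange(binned, subject_id, week, bin_lo),
                   file.path(out_dir, "binned_irt.csv"))

  write_manifest(out_dir, "analyze",
                 list(events = basename(events_path),
                      criterion = schedule$criterion_s,
                      included_days = included_days))
  invisible(out_dir)
}

#' Run the report stage: effect sizes and PR curve comparison
#'
#' From the weekly summaries, compares CIE vs control efficiency at the
#' final week with a Welch t-test and reports the t-to-d-to-r effect-size
#' chain.  If a progressive-ratio event log is given, pools the press times
#' per group and reports the exact two-sample Kolmogorov-Smirnov D between
#' the groups' cumulative response records (optionally with a permutation
#' p-value and a cumulative-curve figure).
#'
#' @param analyze_dir Directory produced by [drl_analyze()].
#' @param out_dir Output directory.
#' @param pr_events_path Optional `pr_events.csv` from [drl_simulate()].
#' @param week Week to compare (default: last week present).
#' @param n_perm Permutations for the KS p-value (0 = exact D only).
#' @param figures If `TRUE`, also writes `pr_curves.pdf`.
#' @return The output directory used, invisibly; writes
#'   `effect_sizes.csv` and (with PR data) `ks_pr.csv`.
#' @export
drl_report <- function(analyze_dir, out_dir, pr_events_path = NULL,
                       week = NULL, n_perm = 0, figures = FALSE) {
  out_dir <- next_out_dir(out_dir)
  weekly <- readr::read_csv(file.path(analyze_dir, "weekly_summary.csv"),
                            show_col_types = FALSE, progress = FALSE)
  if (is.null(week)) week <- max(weekly$week)
  wk <- weekly[weekly$week == week & !is.na(weekly$mean_efficiency), ]
  eff_cie <- wk$mean_efficiency[wk$group == "CIE"]
  eff_con <- wk$mean_efficiency[wk$group == "CON"]
  es <- if (length(eff_cie) >= 2 && length(eff_con) >= 2) {
    tt <- t.test(eff_cie, eff_con)
    d <- cohen_d_from_t(unname(tt$statistic),
                        length(eff_cie), length(eff_con))
    tibble::tibble(week = week, measure = "mean_efficiency",
                   mean_cie = mean(eff_cie), mean_con = mean(eff_con),
                   t_value = unname(tt$statistic), df = unname(tt$parameter),
                   n_cie = length(eff_cie), n_con = length(eff_con),
                   cohen_d = d, effect_r = effect_r_from_d(d),
                   p_value = tt$p.value)
  } else {
    tibble::tibble(week = week, measure = "mean_efficiency",
                   mean_cie = NA_real_, mean_con = NA_real_,
                   t_value = NA_real_, df = NA_real_,
                   n_cie = length(eff_cie), n_con = length(eff_con),
                   cohen_d = NA_real_, effect_r = NA_real_,
                   p_value = NA_real_)
  }
  readr::write_csv(es, file.path(out_dir, "effect_sizes.csv"))

  if (!is.null(pr_events_path) && file.exists(pr_events_path)) {
    pr <- readr::read_csv(pr_events_path, show_col_types = FALSE,
                          progress = FALSE)
    presses <- pr[pr$event_kind == "response", ]
    x <- presses$event_time_s[presses$group == "CIE"]
    y <- presses$event_time_s[presses$group == "CON"]
    if (length(x) > 0 && length(y) > 0) {
      ks <- ks_two_sample(x, y, n_perm = n_perm)
      readr::write_csv(
        tibble::tibble(comparison = "pr_cumulative_presses_CIE_vs_CON",
                       D = ks$statistic, n_cie = ks$n_x, n_con = ks$n_y,
                       p_perm = ks$p_value, n_perm = n_perm),
        file.path(out_dir, "ks_pr.csv"))
      if (isTRUE(figures)) {
        fig <- plot_pr_curves(presses)
        ggplot2::ggsave(file.path(out_dir, "pr_curves.pdf"), fig,
                        width = 6, height = 4)
      }
    }
  }
  write_manifest(out_dir, "report",
                 list(analyze_dir = basename(analyze_dir), week = week,
                      n_perm = n_perm))
  invisible(out_dir)
}

#' Cumulative progressive-ratio response curves by group
#'
#' @param presses A data frame of press events with `group` and
#'   `event_time_s` columns (the `response` rows of `pr_events.csv`).
#' @return A ggplot object: cumulative presses (averaged per subject within
#'   group) against session time.
#' @export
plot_pr_curves <- function(presses) {
  df <- dplyr::arrange(presses, group, event_time_s)
  df <- dplyr::mutate(
    dplyr::group_by(df, group),
    cum_presses = dplyr::row_number() /
      length(unique(subject_id))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = event_time_s / 60, y = cum_presses,
                                   colour = group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Session time (min)",
                  y = "Cumulative presses per subject",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Small packaged fixture design
#'
#' A down-scaled cohort (2 subjects/group, pre-vapor week 0 and final
#' abstinence week 11, 5 sessions/week, 10-min sessions) used by the
#' end-to-end pipeline tests and the `fixtures` CLI subcommand.
#'
#' @param seed Master seed.
#' @return A [cohort_spec()].
#' @export
drl_fixture_spec <- function(seed = 42) {
  cohort_spec(n_per_group = 2, weeks = c(0L, 11L), sessions_per_week = 5,
              schedule = drl_schedule(15, 600), seed = seed)
}

#' Run the full simulate -> fit -> analyze -> report pipeline
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Root output directory; stages write to `simulate/`,
#'   `fit/`, `analyze/`, `report/` beneath it.
#' @param mode Fit objective.
#' @return A list of the four stage directories, invisibly.
#' @export
drl_pipeline <- function(spec, out_dir, mode = "mle") {
  sim <- drl_simulate(spec, file.path(out_dir, "simulate"))
  fit <- drl_fit(file.path(sim, "events.csv"), file.path(out_dir, "fit"),
                 schedule = spec$schedule, mode = mode, seed = spec$seed)
  ana <- drl_analyze(file.path(sim, "events.csv"),
                     file.path(out_dir, "analyze"),
                     schedule = spec$schedule)
  rep <- drl_report(ana, file.path(out_dir, "report"),
                    pr_events_path = file.path(sim, "pr_events.csv"))
  invisible(list(simulate = sim, fit = fit, analyze = ana, report = rep))
}
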