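#' Write a cohort of sessions as a delimited event log
#'
#' One row per event: every response, plus a reinforcer row at the same
#' timestamp for reinforced responses.  Columns are `subject_id, group,
#' reinforcer_type, week, day, event_time_s, event_kind` with times at
#' 3-decimal fixed precision, so a write/read round trip is lossless at
#' millisecond resolution.
#'
#' @param cohort A cohort tibble from [simulate_cohort()] (or any tibble
#'   with a `session` list-column of `drl_session` objects).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(cohort, path) {
  stopifnot(is.data.frame(cohort), "session" %in% names(cohort))
  rows <- lapply(cohort$session, function(s) {
    n <- length(s$response_times_s)
    if (n == 0L) return(NULL)
    t_resp <- sprintf("%.3f", s$response_times_s)
    t_reinf <- t_resp[s$reinforced]
    tibble::tibble(
      subject_id = s$subject_id,
      group = s$group,
      reinforcer_type = s$reinforcer_type,
      week = s$week,
      day = s$day,
      event_time_s = c(t_resp, t_reinf),
      event_kind = c(rep("response", n), rep("reinforcer", length(t_reinf))),
      .ord = c(seq_len(n), which(s$reinforced) + 0.5)
    )
  })
  df <- dplyr::bind_rows(rows)
  if (nrow(df) > 0) {
    df <- dplyr::arrange(df, subject_id, week, day, .ord)
    df$.ord <- NULL
  } else {
    df <- tibble::tibble(subject_id = character(), group = character(),
                         reinforcer_type = character(), week = integer(),
                         day = character(), event_time_s = character(),
                         event_kind = character())
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Read an event log back into sessions
#'
#' Validates the schema and the causal structure of each session
#' (timestamps strictly increasing within a session's responses, every
#' reinforcer matching a response at the same 3-decimal timestamp, no
#' reinforcer before the first response) and reports offending rows by
#' line number.  The schedule configuration is supplied by the caller
#' because it is not recoverable from the event rows.
#'
#' @param path Event-log CSV path.
#' @param schedule The [drl_schedule()] under which the sessions ran.
#' @return A cohort tibble (`subject_id`, `group`, `reinforcer_type`,
#'   `week`, `day`, `session` list-column).  An empty file with a valid
#'   header returns a zero-row tibble with a warning.
#' @export
read_event_log <- function(path, schedule = drl_schedule()) {
  if (!file.exists(path)) {
    stop("event log not found: ", path, call. = FALSE)
  }
  wanted <- c("subject_id", "group", "reinforcer_type", "week", "day",
              "event_time_s", "event_kind")
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    reinforcer_type = readr::col_character(),
    week = readr::col_integer(),
    day = readr::col_character(),
    event_time_s = readr::col_double(),
    event_kind = readr::col_character()
  ), progress = FALSE)
  if (!identical(names(df), wanted)) {
    stop("event log header mismatch; expected columns: ",
         paste(wanted, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("event log is empty: ", path, call. = FALSE)
    return(tibble::tibble(subject_id = character(), group = character(),
                          reinforcer_type = character(), week = integer(),
                          day = character(), session = list()))
  }
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_kind <- df$.line[!df$event_kind %in% c("response", "reinforcer")]
  bad_time <- df$.line[is.na(df$event_time_s) | df$event_time_s < 0]
  bad <- sort(c(bad_kind, bad_time))
  if (length(bad) > 0) {
    stop("malformed event rows at line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  keys <- split(df, list(df$subject_id, df$week, df$day), drop = TRUE)
  sessions <- lapply(keys, function(g) {
    resp <- g[g$event_kind == "response", ]
    reinf <- g[g$event_kind == "reinforcer", ]
    if (nrow(resp) == 0L && nrow(reinf) > 0L) {
      stop("reinforcer event(s) with no responses at line(s): ",
           paste(reinf$.line, collapse = ", "), call. = FALSE)
    }
    if (is.unsorted(resp$event_time_s, strictly = TRUE)) {
      stop("non-monotone response times in session ", resp$subject_id[1],
           " week ", resp$week[1], " ", resp$day[1], " (lines ",
           min(resp$.line), "-", max(resp$.line), ")", call. = FALSE)
    }
    if (nrow(reinf) > 0L && min(reinf$event_time_s) < min(resp$event_time_s)) {
      stop("reinforcer precedes first response at line(s): ",
           paste(reinf$.line[reinf$event_time_s < min(resp$event_time_s)],
                 collapse = ", "), call. = FALSE)
    }
    key <- sprintf("%.3f", resp$event_time_s)
    rkey <- sprintf("%.3f", reinf$event_time_s)
    if (!all(rkey %in% key)) {
      stop("reinforcer without a matching response at line(s): ",
           paste(reinf$.line[!rkey %in% key], collapse = ", "),
           call. = FALSE)
    }
    new_session(resp$event_time_s, schedule = schedule,
                subject_id = resp$subject_id[1], group = resp$group[1],
                reinforcer_type = resp$reinforcer_type[1],
                week = resp$week[1], day = resp$day[1],
                reinforced = key %in% rkey)
  })
  out <- tibble::tibble(
    subject_id = vapply(sessions, `[[`, character(1), "subject_id"),
    group = vapply(sessions, `[[`, character(1), "group"),
    reinforcer_type = vapply(sessions, `[[`, character(1), "reinforcer_type"),
    week = vapply(sessions, `[[`, integer(1), "week"),
    day = vapply(sessions, `[[`, character(1), "day"),
    session = unname(sessions)
  )
  dplyr::arrange(out, subject_id, week, day)
}
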