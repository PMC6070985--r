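# Shared fixtures: the default synthetic responder and small hand-built
# sessions.  Everything is generated in code; no data files.

fixture_params <- function() {
  tr_params(p = 0.7, q = 0.6, N = 6, c = 2.67, L = 2, Lprime = 0.05,
            delta = 0.3)
}

# A session built directly from response times (DRL scoring applied).
make_session <- function(times, criterion = 15, duration = 1800,
                         subject_id = "s1", group = "CON", week = 0L,
                         day = "Tue") {
  sched <- drl_schedule(criterion, duration)
  flags <- score_drl_session(times, criterion)$reinforced
  structure(
    list(subject_id = subject_id, group = group,
         reinforcer_type = "ETHANOL", week = as.integer(week), day = day,
         response_times_s = times, reinforced = flags, schedule = sched,
         final_criterion_s = NULL, true_params = NULL),
    class = "drl_session"
  )
}

# Deterministic draw of a random valid parameter vector, used by the
# normalization property sweeps.
random_params <- function() {
  tr_params(p = runif(1, 0.05, 0.95), q = runif(1, 0.05, 0.95),
            N = runif(1, 0.5, 10), c = runif(1, 0.2, 5),
            L = runif(1, 0.5, 8), Lprime = runif(1, 0.01, 0.5),
            delta = runif(1, 0, 1))
}

# Independent O(n*m) ECDF comparison used as the KS oracle: explicit loops,
# no vectorised shortcuts shared with the implementation.
ks_brute_force <- function(x, y) {
  pooled <- c(x, y)
  best <- 0
  for (v in pooled) {
    cx <- 0
    for (xi in x) if (xi <= v) cx <- cx + 1
    cy <- 0
    for (yi in y) if (yi <= v) cy <- cy + 1
    d <- abs(cx / length(x) - cy / length(y))
    if (d > best) best <- d
  }
  best
}
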