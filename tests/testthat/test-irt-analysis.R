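test_that("IRTs are differences of response times with the first timed from session start", {
  expect_equal(compute_irts(make_session(c(16, 40, 45))), c(16, 24, 5))
  expect_equal(compute_irts(make_session(7)), 7)
  expect_equal(compute_irts(make_session(numeric(0))), numeric(0))
})

test_that("efficiency is the percentage of reinforced responses", {
  s <- make_session(c(16, 40, 45))          # 2 of 3 reinforced under DRL15
  expect_equal(efficiency(s), 100 * 2 / 3)
  all_r <- make_session(c(20, 40, 60, 80))  # every IRT > 15
  expect_equal(efficiency(all_r), 100)
  expect_warning(e <- efficiency(make_session(numeric(0))), "zero responses")
  expect_true(is.na(e))

  # flag identity: efficiency equals 100 * sum(flags) / n on random streams
  set.seed(61)
  for (rep in 1:10) {
    times <- cumsum(runif(40, 0.5, 30))
    s <- make_session(times)
    expect_equal(efficiency(s),
                 100 * sum(s$reinforced) / length(s$reinforced))
  }
})

test_that("half-second binning is half-open with an explicit overflow bucket", {
  b <- bin_irt_distribution(c(0.6, 0.7, 14.9))
  expect_equal(b$percent[2], 100 * 2 / 3)   # bin [0.5, 1)
  expect_equal(b$percent[30], 100 * 1 / 3)  # bin [14.5, 15)
  expect_equal(sum(b$percent > 0), 2)

  one <- bin_irt_distribution(rep(3.1, 5))
  expect_equal(one$percent[7], 100)

  over <- bin_irt_distribution(c(70, 80))
  expect_equal(over$overflow_count, 2L)
  expect_true(all(over$percent == 0))

  # boundary IRTs fall in the upper bin; 60 s exactly overflows
  edge <- bin_irt_distribution(c(0.5, 59.999, 60))
  expect_equal(edge$counts[2], 1L)
  expect_equal(edge$counts[120], 1L)
  expect_equal(edge$overflow_count, 1L)

  expect_error(bin_irt_distribution(numeric(0)), "empty")
})

test_that("binning conserves counts and converges to the mixture bin masses", {
  set.seed(62)
  irts <- sample_irt(5e4, fixture_params())
  b <- bin_irt_distribution(irts)
  expect_equal(sum(b$counts) + b$overflow_count, b$n_irts)
  expect_equal(sum(b$percent) + 100 * b$overflow_count / b$n_irts, 100,
               tolerance = 1e-9)
  model_mass <- tr_cdf(b$bin_lo + 0.5, fixture_params()) -
    tr_cdf(b$bin_lo, fixture_params())
  expect_lt(max(abs(b$percent / 100 - model_mass)), 0.01)
})

test_that("weekly averages use only the included days and flag missing weeks", {
  effs <- c(Mon = 10, Tue = 50, Wed = 60, Thu = 70, Fri = 90)
  sessions <- lapply(names(effs), function(d) {
    # 10 responses, efficiency/10 of them reinforced, built by spacing IRTs
    n_r <- effs[[d]] / 10
    times <- cumsum(c(rep(20, n_r), rep(1, 10 - n_r)))
    make_session(times, day = d, week = 3L)
  })
  wk <- weekly_summary(sessions)
  expect_equal(wk$mean_efficiency, 60)
  expect_equal(wk$n_sessions_used, 3L)
  expect_equal(wk$sessions_used, "Thu,Tue,Wed")

  # invariant to session order within the week
  wk_rev <- weekly_summary(rev(sessions))
  expect_equal(wk_rev$mean_efficiency, wk$mean_efficiency)

  # only excluded days present -> missing marker, not zero
  mon_fri <- sessions[c(1, 5)]
  wk_mf <- weekly_summary(mon_fri)
  expect_true(is.na(wk_mf$mean_efficiency))
  expect_equal(wk_mf$n_sessions_used, 0L)

  expect_error(weekly_summary(list(make_session(5, week = 1),
                                   make_session(5, week = 2))),
               "single subject and week")
})

test_that("stability rule: <10% range-over-mean across 3 consecutive sessions", {
  expect_true(stability_check(c(50, 50, 50)))
  expect_false(stability_check(c(50, 60, 70)))   # (70-50)/60 = 33%
  expect_true(stability_check(c(40, 80, 58, 59, 60)))  # last three ~3.4%
  expect_true(is.na(stability_check(c(50, 51))))  # not assessable
})

test_that("the DRL20 challenge comparison pairs weekly and challenge values", {
  week_sessions <- lapply(c("Tue", "Wed", "Thu"), function(d) {
    make_session(cumsum(rep(c(20, 1), 5)), criterion = 15, day = d, week = 10L)
  })
  challenge <- make_session(cumsum(rep(c(21, 1), 5)), criterion = 20,
                            day = "Fri", week = 10L)
  cmp <- challenge_comparison(week_sessions, challenge)
  expect_equal(cmp$drl15_efficiency, 50)
  expect_equal(cmp$challenge_efficiency, 50)
  expect_equal(cmp$efficiency_diff, 0)

  # identical sessions for both sides give a zero difference
  same <- make_session(cumsum(rep(c(25, 1), 5)), criterion = 20, week = 10L)
  cmp0 <- challenge_comparison(list(same), same)
  expect_equal(cmp0$efficiency_diff, 0)

  expect_error(challenge_comparison(week_sessions,
                                    make_session(c(16, 40), criterion = 15)),
               "raised DRL criterion")
})
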