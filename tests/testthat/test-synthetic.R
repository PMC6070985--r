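test_that("sampled IRTs respect the support and converge to the mixture moments", {
  truth <- fixture_params()
  set.seed(51)
  x <- sample_irt(1e5, truth)
  expect_true(all(x >= truth$delta))

  mix_mean <- truth$delta + truth$p * truth$N * truth$c +
    truth$q * (1 - truth$p) / truth$L +
    (1 - truth$q) * (1 - truth$p) / truth$Lprime
  expect_lt(abs(mean(x) - mix_mean) / mix_mean, 0.02)

  # pure components: gamma mean and exponential mean
  set.seed(52)
  g <- sample_irt(1e5, tr_params(1, 0.5, 6, 2.5, 1, 1, delta = 0.3))
  expect_lt(abs(mean(g) - 15.3) / 15.3, 0.02)
  set.seed(53)
  e <- sample_irt(1e5, tr_params(0, 1, 1, 1, 2, 1, delta = 0))
  expect_lt(abs(mean(e) - 0.5) / 0.5, 0.02)
})

test_that("component fractions converge to (p, q(1-p), (1-q)(1-p)) and the sample passes a GOF check", {
  truth <- fixture_params()
  set.seed(54)
  x <- sample_irt(1e5, truth)
  # empirical mass below several cuts matches the mixture CDF (binomial error)
  for (cut in c(2, 10, 20, 60)) {
    expect_lt(abs(mean(x <= cut) - tr_cdf(cut, truth)), 0.01)
  }
  # one-sample Kolmogorov-Smirnov against the model CDF at alpha = 0.01
  ks <- suppressWarnings(stats::ks.test(x, function(t) tr_cdf(t, truth)))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated sessions are truncated renewal processes and reproducible", {
  pars <- fixture_params()
  set.seed(55)
  s1 <- simulate_session(pars, drl_schedule(15, 1800))
  set.seed(55)
  s2 <- simulate_session(pars, drl_schedule(15, 1800))
  expect_identical(s1$response_times_s, s2$response_times_s)
  expect_identical(s1$reinforced, s2$reinforced)
  expect_true(all(s1$response_times_s <= 1800))
  expect_true(all(diff(s1$response_times_s) > 0))

  # a shift longer than the session yields at most one response
  big_delta <- tr_params(0.7, 0.6, 6, 2.67, 2, 0.05, delta = 2000)
  set.seed(56)
  s3 <- simulate_session(big_delta, drl_schedule(15, 1800))
  expect_lte(length(s3$response_times_s), 1)
})

test_that("a timer responder beats a bursty responder on DRL15 efficiency", {
  timer <- tr_params(p = 1, q = 0.5, N = 100, c = 0.16, L = 2,
                     Lprime = 0.05, delta = 0.3)
  bursty <- tr_params(p = 0.5, q = 1, N = 100, c = 0.16, L = 2,
                      Lprime = 0.05, delta = 0.3)
  set.seed(57)
  eff <- function(p) {
    mean(replicate(20, suppressWarnings(
      efficiency(simulate_session(p, drl_schedule(15, 1800))))), na.rm = TRUE)
  }
  expect_gt(eff(timer), eff(bursty))
})

test_that("cohort generation is seed-reproducible with per-subject streams", {
  spec <- cohort_spec(n_per_group = 2, weeks = 0:1, sessions_per_week = 3,
                      seed = 58)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_equal(nrow(c1), 2 * 2 * 2 * 3)
  expect_identical(lapply(c1$session, `[[`, "response_times_s"),
                   lapply(c2$session, `[[`, "response_times_s"))
  expect_setequal(unique(c1$group), c("CIE", "CON"))
  expect_setequal(unique(c1$day), c("Mon", "Tue", "Wed"))
})

test_that("CIE effect multipliers apply only to CIE subjects in scheduled weeks", {
  base <- fixture_params()
  eff <- cie_effects(weeks = 9:11, L_mult = 0.5, Nc_mult = 1.05)
  con <- drlmix:::subject_week_params(base, "CON", 11, eff)
  cie <- drlmix:::subject_week_params(base, "CIE", 11, eff)
  cie_off <- drlmix:::subject_week_params(base, "CIE", 5, eff)
  expect_identical(con, base)
  expect_identical(cie_off, base)
  expect_equal(cie$L, base$L * 0.5)
  expect_equal(cie$N * cie$c, base$N * base$c * 1.05)
  expect_equal(cie$p, base$p)

  # null effects leave CIE and CON subjects identically distributed
  null_eff <- cie_effects(weeks = 9:11, L_mult = 1, Nc_mult = 1, p_mult = 1)
  expect_identical(drlmix:::subject_week_params(base, "CIE", 11, null_eff),
                   drlmix:::subject_week_params(base, "CON", 11, null_eff))
})

test_that("simulated PR sessions terminate and score under the progression", {
  slow <- tr_params(p = 0.2, q = 0.1, N = 6, c = 2.67, L = 2,
                    Lprime = 0.01, delta = 0.3)
  set.seed(59)
  res <- simulate_pr_session(slow, pr_schedule(hang_limit_s = 120,
                                               session_duration_s = 1800))
  expect_s3_class(res, "pr_result")
  expect_lte(res$termination_time_s, 1800)
  expect_equal(res$cumulative_curve[length(res$cumulative_curve)],
               res$total_responses)
})
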