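test_that("DRL scoring reinforces responses whose IRT strictly exceeds the criterion", {
  res <- score_drl_session(c(16, 40, 45), 15)  # IRTs 16, 24, 5
  expect_equal(res$reinforced, c(TRUE, TRUE, FALSE))
  expect_equal(res$n_responses, 3L)
  expect_equal(res$n_reinforcers, 2L)

  expect_equal(score_drl_session(numeric(0), 15),
               list(reinforced = logical(0), n_responses = 0L,
                    n_reinforcers = 0L))
  expect_equal(score_drl_session(c(1, 2, 3), 15)$n_reinforcers, 0L)

  # strict inequality at the boundary: IRT == criterion is not reinforced
  expect_false(score_drl_session(c(15), 15)$reinforced[1])
  expect_true(score_drl_session(c(15.001), 15)$reinforced[1])
})

test_that("DRL scoring rejects invalid response streams", {
  expect_error(score_drl_session(c(5, 4), 15), "strictly increasing")
  expect_error(score_drl_session(c(-1, 4), 15), "non-negative")
  expect_error(score_drl_session(c(1, NA), 15), "finite")
})

test_that("criterion 0 reinforces every response and raising it never adds reinforcers", {
  set.seed(11)
  for (rep in 1:20) {
    times <- cumsum(runif(30, 0.1, 30))
    expect_equal(score_drl_session(times, 0)$n_reinforcers, 30L)
    counts <- vapply(c(0, 5, 10, 15, 20, 40),
                     function(k) score_drl_session(times, k)$n_reinforcers,
                     integer(1))
    expect_true(all(diff(counts) <= 0))
    expect_lte(score_drl_session(times, 15)$n_reinforcers, length(times))
  }
})

test_that("adjusting DRL multiplies the criterion after reinforced responses and caps at the target", {
  cfg <- adjusting_drl_schedule()
  # one reinforced response starting at 2 s
  res <- run_adjusting_drl(3, cfg)
  expect_equal(res$criterion_trajectory, 2)
  expect_true(res$reinforced)
  expect_equal(res$final_criterion_s, 2 * 1.0075)

  # zero reinforced responses leave the criterion unchanged
  res0 <- run_adjusting_drl(c(1, 2, 3), cfg)
  expect_equal(res0$n_reinforcers, 0L)
  expect_equal(res0$final_criterion_s, 2)

  # carry-over continues from the previous session's criterion
  res1 <- run_adjusting_drl(3, cfg, carry_in_s = res$final_criterion_s)
  expect_equal(res1$criterion_trajectory, 2 * 1.0075)

  # trajectory is non-decreasing and never exceeds the cap
  set.seed(3)
  times <- cumsum(runif(400, 0.5, 40))
  traj <- run_adjusting_drl(times, cfg)$criterion_trajectory
  expect_true(all(diff(traj) >= 0))
  expect_true(all(traj <= 15))
})

test_that("the 2 s -> 15 s progression at 0.75% needs 270 reinforced responses", {
  expect_identical(reinforcers_to_reach(2, 15, 0.0075), 270L)
  expect_identical(reinforcers_to_reach(15, 15, 0.0075), 0L)
  expect_identical(reinforcers_to_reach(2, 4, 1), 1L)
  expect_error(reinforcers_to_reach(15, 2, 0.0075), "at least")

  # criterion first reaches 15 s on reinforced response #270 of a stream
  times <- cumsum(rep(16, 275))
  res <- run_adjusting_drl(times, adjusting_drl_schedule())
  expect_true(all(res$reinforced))
  expect_lt(res$criterion_trajectory[270], 15)
  expect_equal(res$criterion_trajectory[271], 15)
})

test_that("progressive ratio delivers reinforcers per the progression and stops at the hang limit", {
  cfg <- pr_schedule(progression = c(1, 2, 3))
  res <- run_progressive_ratio(1:6, cfg)
  expect_equal(res$reinforcers_earned, 3L)
  expect_equal(res$breakpoint_ratio, 3)
  expect_equal(res$total_responses, 6L)

  empty <- run_progressive_ratio(numeric(0), cfg)
  expect_equal(empty$reinforcers_earned, 0L)
  expect_equal(empty$breakpoint_ratio, 0)

  # a 900 s pause terminates the session; later presses are not counted
  gap <- run_progressive_ratio(c(1, 950), pr_schedule(progression = c(1, 2)))
  expect_equal(gap$total_responses, 1L)
  # the hang limit also applies from session start to the first press
  late <- run_progressive_ratio(c(950, 951), pr_schedule(progression = c(1, 2)))
  expect_equal(late$total_responses, 0L)
})

test_that("PR cumulative curve is non-decreasing and closes at the total count", {
  set.seed(5)
  for (rep in 1:10) {
    presses <- cumsum(rexp(80, rate = 0.2))
    res <- run_progressive_ratio(presses, pr_schedule())
    expect_true(all(diff(res$cumulative_curve) >= 0))
    expect_equal(res$cumulative_curve[length(res$cumulative_curve)],
                 res$total_responses)
    expect_lte(res$reinforcers_earned, length(pr_schedule()$progression))
  }
})

test_that("schedule constructors validate their parameters", {
  expect_error(drl_schedule(-1), "out of range")
  expect_error(adjusting_drl_schedule(increment_fraction = 1.5), "out of range")
  expect_error(adjusting_drl_schedule(criterion_s = 1, start_criterion_s = 2),
               "must not exceed")
  expect_error(pr_schedule(progression = c(3, 2, 1)), "non-decreasing")
})
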