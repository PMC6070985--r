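test_that("mixture density matches its analytic components", {
  # pure fast exponential: f(1) = exp(-1)
  pars <- tr_params(p = 0, q = 1, N = 1, c = 1, L = 1, Lprime = 1, delta = 0)
  expect_equal(tr_pdf(1, pars), exp(-1), tolerance = 1e-12)
  # zero below the shift
  fx <- fixture_params()
  expect_equal(tr_pdf(c(0, 0.1, 0.29), fx), c(0, 0, 0))
  # pure gamma reduction
  pg <- tr_params(p = 1, q = 0, N = 6, c = 2.5, L = 1, Lprime = 1, delta = 0.3)
  t <- c(1, 5, 16, 40)
  expect_equal(tr_pdf(t, pg), dgamma(t - 0.3, shape = 6, scale = 2.5),
               tolerance = 1e-12)
})

test_that("mixture density integrates to one over its support", {
  set.seed(21)
  for (rep in 1:20) {
    pars <- random_params()
    val <- integrate(function(t) tr_pdf(t, pars), pars$delta, Inf,
                     rel.tol = 1e-9, abs.tol = 1e-10,
                     subdivisions = 500L)$value
    expect_lt(abs(val - 1), 1e-6)
  }
})

test_that("mixture CDF is a proper distribution function agreeing with quadrature", {
  pars <- tr_params(p = 0, q = 1, N = 1, c = 1, L = 1, Lprime = 1, delta = 0)
  expect_equal(tr_cdf(log(2), pars), 0.5, tolerance = 1e-12)

  fx <- fixture_params()
  expect_equal(tr_cdf(fx$delta, fx), 0)
  grid <- seq(0, 200, by = 0.25)
  vals <- tr_cdf(grid, fx)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_lt(1 - tr_cdf(1e4, fx), 1e-6)

  for (t in c(1, 5, 15, 60)) {
    quad <- integrate(function(u) tr_pdf(u, fx), fx$delta, t,
                      rel.tol = 1e-10, abs.tol = 1e-12)$value
    expect_equal(tr_cdf(t, fx), quad, tolerance = 1e-8)
  }
})

test_that("negative log-likelihood reduces to the shifted-gamma form and obeys Gibbs' inequality", {
  pg <- tr_params(p = 1, q = 0, N = 6, c = 2.5, L = 1, Lprime = 1, delta = 0.3)
  set.seed(31)
  irts <- 0.3 + rgamma(400, shape = 6, scale = 2.5)
  closed_form <- -sum(dgamma(irts - 0.3, shape = 6, scale = 2.5, log = TRUE))
  expect_equal(tr_nll(irts, pg), closed_form, tolerance = 1e-9)

  expect_error(tr_nll(numeric(0), pg), "at least 2")
  expect_error(tr_nll(1.5, pg), "at least 2")

  # generator parameters beat a perturbed vector in expected NLL
  truth <- fixture_params()
  other <- tr_params(p = 0.5, q = 0.3, N = 4, c = 4, L = 1, Lprime = 0.1,
                     delta = 0.3)
  set.seed(32)
  diffs <- replicate(10, {
    x <- sample_irt(500, truth)
    tr_nll(x, other) - tr_nll(x, truth)
  })
  expect_gt(mean(diffs), 0)
})

test_that("derived indices follow their defining formulas", {
  expect_equal(as.numeric(response_threshold(6, 2.5)), 1)
  th <- response_threshold(3, 2)
  expect_equal(as.numeric(th), 0.4)
  expect_true(attr(th, "low_accuracy"))
  expect_equal(as.numeric(response_threshold(7.02, 2.5)), 1.17)
  expect_error(response_threshold(-1, 2), "out of range")

  expect_equal(unname(derived_proportions(1, 0.5)), c(1, 0, 0))
  expect_equal(unname(derived_proportions(0, 0)), c(0, 0, 1))
  pr <- derived_proportions(0.67, 0.485)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_equal(unname(pr["prop_burst"]), 0.485 * 0.33, tolerance = 1e-12)
  expect_error(derived_proportions(1.2, 0.5), "out of range")

  expect_equal(weber_fraction(4), 0.5)
  expect_equal(weber_fraction(1), 1)
  ns <- seq(0.5, 20, by = 0.5)
  expect_true(all(diff(weber_fraction_vec <- sapply(ns, weber_fraction)) < 0))
})

test_that("parameter constructor enforces the valid domain", {
  expect_error(tr_params(1.5, 0.5, 6, 2, 2, 0.05), "out of range")
  expect_error(tr_params(0.5, 0.5, -6, 2, 2, 0.05), "out of range")
  expect_error(tr_params(0.5, 0.5, 6, 2, 0, 0.05), "out of range")
  expect_error(tr_params(0.5, 0.5, 6, 2, 2, 0.05, delta = -1), "out of range")
})
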