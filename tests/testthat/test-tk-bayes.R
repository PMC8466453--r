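test_that("scaled posterior objective reduces to the likelihood under flat priors", {
  s <- test_sample(seed = 31, m = 20)
  n <- s$scheme$n
  pr <- gamma_priors()      # shape 1, rate 1e-4: log prior ~ -1e-4 * sum(theta)
  for (th in list(c(1.5, 1, 0.5), c(0.8, 2, 0.3))) {
    gap <- n * ipl_log_q(th, s, pr) - ipl_loglik(th, s)
    expect_equal(gap, -1e-4 * sum(th), tolerance = 1e-10)
  }
})

test_that("objective gradient and Hessian match finite differences, including the Q* correction", {
  s <- test_sample(seed = 32, m = 20)
  pr <- gamma_priors(1.5, 1, 1, 1, 1, 2)
  for (spec in list(list(w = 0, j = 0L), list(w = 1, j = 1L),
                    list(w = -1, j = 3L))) {
    obj <- iplcens:::q_objective(s, pr, extra_w = spec$w, extra_j = spec$j)
    th <- c(1.2, 1.1, 0.6)
    f <- obj(th)
    expect_equal(unname(f$grad), fd_grad(function(t) obj(t)$value, th),
                 tolerance = 1e-5)
    expect_equal(unname(f$hess), fd_hess(function(t) obj(t)$value, th),
                 tolerance = 1e-4)
  }
})

test_that("posterior mode under near-flat priors coincides with the MLE", {
  s <- test_sample(seed = 33, m = 30)
  fit <- fit_ipl_mle(s)
  tk <- tk_estimate(s, gamma_priors(), "sel", init = fit$params_hat)
  # the rate-1e-4 prior displaces the mode by O(b * Var), so agreement is to
  # a couple of percent, not machine precision
  expect_equal(unname(tk$q_max), unname(fit$params_hat), tolerance = 0.02)
})

test_that("entropy loss with q = -1 recovers the squared-error estimate", {
  s <- test_sample(seed = 34, m = 20)
  pr <- gamma_priors(1.5, 1, 1, 1, 1, 2)
  sel <- tk_estimate(s, pr, "sel")
  gel <- tk_estimate(s, pr, "gel", q = -1)
  expect_equal(gel$estimates, sel$estimates, tolerance = 1e-6)
})

test_that("entropy-loss estimates vary continuously in q", {
  # for exact posterior expectations E[theta^-q]^(-1/q) is nonincreasing in
  # q (power-mean inequality); the Laplace-ratio approximation tracks it
  # closely but not exactly, so only near-continuity is asserted
  s <- rpffc(1.5, 1, 0.5, complete_scheme(25), seed = 35)
  pr <- gamma_priors(1.5, 1, 1, 1, 1, 2)
  qs <- c(-1, -0.5, 0.5, 1)
  ests <- vapply(qs, function(qv)
    tk_estimate(s, pr, "gel", q = qv)$estimates, numeric(3))
  for (i in 1:3)
    expect_true(all(abs(diff(ests[i, ])) < 0.25 * ests[i, 1] * diff(qs)))
})

test_that("loss specification is validated", {
  s <- test_sample(seed = 36, m = 10)
  expect_error(tk_estimate(s, gamma_priors(), "gel"), "nonzero")
  expect_error(tk_estimate(s, gamma_priors(), "gel", q = 0), "nonzero")
  expect_error(gamma_priors(a1 = -1), "positive")
})

test_that("determinants at valid maximizers are positive (negative definite Hessians)", {
  s <- test_sample(seed = 37, m = 30)
  pr <- gamma_priors(1.5, 1, 1, 1, 1, 2)
  tk <- tk_estimate(s, pr, "sel")
  expect_true(all(tk$converged))
  expect_true(is.finite(tk$logdet_sigma))
  expect_true(all(is.finite(tk$logdet_sigma_star)))
})
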