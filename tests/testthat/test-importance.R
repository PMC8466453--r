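test_that("weights are a normalized probability vector and draws are reproducible", {
  s <- test_sample(seed = 41, m = 20)
  pr <- gamma_priors(1.5, 1, 1, 1, 1, 2)
  wp <- ipl_posterior_draws(s, pr, N = 500, seed = 2)
  expect_equal(sum(wp$weights), 1, tolerance = 1e-12)
  expect_true(all(wp$weights >= 0))
  expect_true(all(wp$draws > 0))
  expect_gte(wp$ess, 1)
  wp2 <- ipl_posterior_draws(s, pr, N = 500, seed = 2)
  expect_identical(wp$draws, wp2$draws)
  expect_identical(wp$weights, wp2$weights)
  expect_error(ipl_posterior_draws(s, pr, N = 50), "at least 100")
})

test_that("posterior-mean estimates are stable in N and agree between independent runs", {
  s <- test_sample(seed = 43, m = 20)
  pr <- gamma_priors(1.5, 1, 1, 1, 1, 2)
  m1 <- colSums(ipl_posterior_draws(s, pr, N = 2000, seed = 1)$weights *
                ipl_posterior_draws(s, pr, N = 2000, seed = 1)$draws)
  m2 <- colSums(ipl_posterior_draws(s, pr, N = 4000, seed = 9)$weights *
                ipl_posterior_draws(s, pr, N = 4000, seed = 9)$draws)
  expect_equal(unname(m1), unname(m2), tolerance = 0.1)
})

test_that("HPD intervals are never wider than equal-tail intervals", {
  pr <- gamma_priors(1.5, 1, 1, 1, 1, 2)
  for (sd in c(51, 52, 53)) {
    s <- test_sample(seed = sd, m = 20)
    wp <- ipl_posterior_draws(s, pr, N = 1000, seed = sd)
    for (par in c("alpha", "beta", "lambda")) {
      h <- hpd_interval(wp, par, 0.95)
      et <- equal_tail_interval(wp, par, 0.95)
      expect_lte(h$upper - h$lower, et["upper"] - et["lower"] + 1e-12)
      expect_lt(h$lower, h$upper)
    }
  }
})

test_that("HPD construction behaves correctly on hand-built weighted samples", {
  # equal weights, symmetric draws: HPD approximately equals equal tails
  set.seed(6)
  N <- 4000
  g <- rnorm(N)
  wp <- structure(list(
    draws = cbind(alpha = g, beta = g, lambda = abs(g) + 0.1),
    weights = rep(1 / N, N), ess = N, N = N),
    class = "weighted_posterior")
  h <- hpd_interval(wp, "alpha", 0.95)
  et <- equal_tail_interval(wp, "alpha", 0.95)
  expect_lt(abs(h$lower - et["lower"]), 2 / sqrt(N) * 3)
  expect_lt(abs(h$upper - et["upper"]), 2 / sqrt(N) * 3)

  # level close to 1 returns nearly the full range of the draws
  h99 <- hpd_interval(wp, "alpha", 1 - 1 / N)
  expect_equal(h99$lower, min(g))
  expect_gte(h99$upper, sort(g)[N - 1])

  # a deliberately skewed weighted sample: HPD must hug the heavy side
  gs <- sort(rexp(N))
  wps <- structure(list(draws = cbind(alpha = gs, beta = gs, lambda = gs),
                        weights = rep(1 / N, N), ess = N, N = N),
                   class = "weighted_posterior")
  hs <- hpd_interval(wps, "alpha", 0.9)
  ets <- equal_tail_interval(wps, "alpha", 0.9)
  expect_lt(hs$lower, ets["lower"])
  expect_lt(hs$upper, ets["upper"])

  expect_warning(hpd_interval(wp, "alpha", 0.001), "unstable")
})

test_that("accumulated weight inside the HPD interval reaches the nominal level", {
  s <- test_sample(seed = 55, m = 20)
  pr <- gamma_priors(1.5, 1, 1, 1, 1, 2)
  wp <- ipl_posterior_draws(s, pr, N = 1500, seed = 3)
  h <- hpd_interval(wp, "alpha", 0.9)
  inside <- wp$draws[, "alpha"] >= h$lower & wp$draws[, "alpha"] <= h$upper
  # the floor-indexed quantile construction can undershoot the nominal mass
  # by at most the largest single weight
  expect_gte(sum(wp$weights[inside]), 0.9 - max(wp$weights) - 1e-9)
})
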