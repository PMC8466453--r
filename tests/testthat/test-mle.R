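test_that("Newton fit satisfies first-order conditions and beats a local grid", {
  s <- test_sample(seed = 8, m = 10)
  fit <- fit_ipl_mle(s)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$score)), 1e-3)
  # no point on a coarse grid around the solution does better
  th <- fit$params_hat
  fac <- exp(seq(-0.4, 0.4, length.out = 5))
  for (i in fac) for (j in fac) for (k in fac)
    expect_lte(ipl_loglik(c(th[1] * i, th[2] * j, th[3] * k), s), fit$loglik)
})

test_that("restarting at the maximizer stays there", {
  s <- test_sample(seed = 12, m = 20)
  fit <- fit_ipl_mle(s)
  refit <- fit_ipl_mle(s, init = fit$params_hat)
  expect_lte(refit$n_iter, 2)
  expect_equal(refit$params_hat, fit$params_hat, tolerance = 1e-6)
})

test_that("fit is invariant to observation order and additive likelihood constants", {
  x <- guinea_pigs()
  f1 <- fit_ipl_complete(x)
  f2 <- fit_ipl_complete(sample(x))
  expect_equal(f1$params_hat, f2$params_hat, tolerance = 1e-8)
})

test_that("covariance is the inverse observed information, and the information is negative of the Hessian", {
  s <- test_sample(seed = 21, m = 30)
  fit <- fit_ipl_mle(s)
  expect_equal(fit$observed_info, -ipl_hessian(fit$params_hat, s))
  expect_equal(fit$covariance %*% fit$observed_info, diag(3),
               tolerance = 1e-8, ignore_attr = TRUE)
  # negative definite Hessian at an interior maximum
  expect_true(all(eigen(fit$observed_info, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("Wald intervals have the textbook geometry", {
  s <- test_sample(seed = 21, m = 30)
  fit <- fit_ipl_mle(s)
  ci <- asymptotic_ci(fit, 0.95)
  expect_true(all(ci[, "lower"] < fit$params_hat))
  expect_true(all(ci[, "upper"] > fit$params_hat))
  # half-width = z * se, and width scales as sqrt(variance)
  se <- sqrt(diag(fit$covariance))
  expect_equal(unname(ci[, "upper"] - fit$params_hat),
               unname(qnorm(0.975) * se), tolerance = 1e-10)
  wide <- asymptotic_ci(fit, 0.99)
  expect_true(all(wide[, "upper"] - wide[, "lower"] >
                  ci[, "upper"] - ci[, "lower"]))
  # identity covariance: half-width is the standard normal quantile
  fake <- fit
  fake$covariance <- diag(3)
  hw <- asymptotic_ci(fake, 0.95)[, "upper"] - fake$params_hat
  expect_equal(unname(hw), rep(qnorm(0.975), 3), tolerance = 1e-12)
})

test_that("parameter recovery at the reference design is unbiased within Monte Carlo error", {
  # k=2, n=m=30, truth (1.5, 1, 0.5): median of the ML estimates should
  # bracket the truth (the mean is distorted by boundary-ridge samples,
  # which is why the study driver reports dropped replicates)
  sch <- censoring_scheme(2, 30, 30, "(0*30)")
  est <- t(vapply(1:120, function(i) {
    s <- rpffc(1.5, 1, 0.5, sch, seed = 700000 + i)
    fit_ipl_mle(s, init = c(1.4, 0.9, 0.4))$params_hat
  }, numeric(3)))
  med <- apply(est, 2, median)
  expect_lt(abs(med[1] - 1.5), 0.45)
  expect_lt(abs(med[2] - 1.0), 0.3)
  expect_lt(abs(med[3] - 0.5), 0.3)
})
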