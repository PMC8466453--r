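# Shared test utilities: finite-difference derivatives and small canonical
# samples. The heavier quadrature oracle values used in test-acceptance.R
# were computed once with a 3-D tensor Gauss-Legendre rule (pracma nodes,
# 64 and 80 points per dimension agreeing to ~1e-5) and frozen there.

fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h * max(1, abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, 0)
}

fd_hess <- function(f, x) {
  # central differences of the analytic gradient would not be independent;
  # use second differences of f itself
  k <- length(x)
  H <- matrix(0, k, k)
  h <- 1e-4 * pmax(1, abs(x))
  for (i in 1:k) for (j in i:k) {
    ei <- numeric(k); ei[i] <- h[i]
    ej <- numeric(k); ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h[i] * h[j])
  }
  H
}

# a small complete sample and a censored sample reused across tests
complete_scheme <- function(n) censoring_scheme(1, n, n, rep(0L, n))

test_sample <- function(seed = 42, m = 20) {
  sch <- censoring_scheme(2, 30, m, c(rep(0L, m - 1L), 30L - m))
  rpffc(1.5, 1, 0.5, sch, seed = seed)
}
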