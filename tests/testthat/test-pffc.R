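test_that("scheme strings expand correctly", {
  expect_identical(parse_scheme("(0*4)", 4), rep(0L, 4))
  expect_identical(parse_scheme("((2,0)*3)", 6), c(2L, 0L, 2L, 0L, 2L, 0L))
  expect_identical(parse_scheme("(1, 0)*10", 20), rep(c(1L, 0L), 10))
  R <- parse_scheme("(10, 0*19)", 20)
  expect_identical(sum(R), 10L)           # n = 30 with m = 20
  expect_identical(parse_scheme("(0*11, 3,4,3, 0*12)", 26),
                   c(rep(0L, 11), 3L, 4L, 3L, rep(0L, 12)))
  expect_identical(parse_scheme("0,1,2", 3), c(0L, 1L, 2L))

  expect_error(parse_scheme("(0*4)", 5), "length")
  expect_error(parse_scheme("(-1, 0)", 2), "nonnegative")
  expect_error(parse_scheme("(1*", 1), "scheme|repeat")
})

test_that("censoring scheme validates its accounting identity", {
  sc <- censoring_scheme(2, 36, 26, "(10, 0*25)")
  expect_identical(sc$n, 26L + sum(sc$R))
  expect_error(censoring_scheme(2, 35, 26, "(10, 0*25)"), "inconsistent")
  expect_error(censoring_scheme(0, 36, 26, "(10, 0*25)"), "k")
  expect_error(pffc_sample(1:5, sc), "expected 26")
})

test_that("uniform-spacings construction reproduces the worked example", {
  # Z = (0.25, 0.25), R = (0, 0): exponents (1, 2), xi = (0.25, 0.5),
  # U = (1 - xi2, 1 - xi2 xi1) = (0.5, 0.875)
  U <- iplcens:::pffc_uniforms(c(0.25, 0.25), c(0, 0))
  expect_equal(U, c(0.5, 0.875))

  # U strictly increasing for arbitrary Z and removals
  set.seed(3)
  for (i in 1:20) {
    m <- sample(2:10, 1)
    R <- sample(0:3, m, replace = TRUE)
    U <- iplcens:::pffc_uniforms(runif(m), R)
    expect_true(all(diff(U) > 0))
    expect_true(all(U > 0 & U < 1))
  }
})

test_that("generated samples have length m, are sorted, and are reproducible", {
  sc <- censoring_scheme(3, 12, 6, c(2, 0, 1, 0, 3, 0))
  s1 <- rpffc(1.5, 1, 0.5, sc, seed = 9)
  s2 <- rpffc(1.5, 1, 0.5, sc, seed = 9)
  expect_identical(s1$times, s2$times)
  expect_length(s1$times, 6)
  expect_true(all(diff(s1$times) >= 0))
  # a private seed must not disturb the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(rpffc(1.5, 1, 0.5, sc, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("first observed failure follows the group-minimum law 1-(1-F)^(nk)", {
  sc <- censoring_scheme(2, 10, 5, c(3, 1, 0, 0, 1))
  x1 <- vapply(1:8000, function(i)
    rpffc(1.5, 1, 0.5, sc, seed = 100000 + i)$times[1], 0)
  xs <- sort(x1)
  Fx <- 1 - (1 - pipl(xs, 1.5, 1, 0.5))^(sc$n * sc$k)
  ks <- max(abs(seq_along(xs) / length(xs) - Fx))
  expect_lt(ks, 0.02)
})

test_that("k=1 complete design reduces to iid sampling; Type-II design to truncated order statistics", {
  # k = 1, R = 0, m = n: pooled draws are iid from the base distribution
  sc <- censoring_scheme(1, 8, 8, rep(0, 8))
  pool <- unlist(lapply(1:1500, function(i)
    rpffc(1.5, 1, 0.5, sc, seed = 300000 + i)$times))
  xs <- sort(pool)
  ks <- max(abs(seq_along(xs) / length(xs) - pipl(xs, 1.5, 1, 0.5)))
  expect_lt(ks, 0.02)

  # k = 1, R = (0,...,0,n-m): marginal of the m-th entry equals the m-th
  # order statistic of n iid draws
  scT2 <- censoring_scheme(1, 10, 6, c(rep(0, 5), 4))
  a <- vapply(1:3000, function(i)
    rpffc(1.5, 1, 0.5, scT2, seed = 500000 + i)$times[6], 0)
  withr::with_seed(99, {
    b <- replicate(3000, sort(ripl(10, 1.5, 1, 0.5))[6])
  })
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)
})
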