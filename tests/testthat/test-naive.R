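# Naive conversion formulas and the comparison report.

test_that("the simple formula reproduces the published counterexample", {
  Q <- rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0)))
  p <- simple_probabilities(Q, 1)
  expect_equal(round(p[1, 2], 3), 0.632)
  expect_equal(round(p[1, 3], 3), 0.632)
  expect_equal(round(p[1, 1], 3), -0.264)
  # rows still sum to one by construction
  expect_equal(rowSums(p), rep(1, 3), ignore_attr = TRUE)
  # it is exact for the single-exit-to-death row (2 -> 3)
  exact <- probabilities_series(Q, 1)$p
  expect_equal(p[2, 3], exact[2, 3], tolerance = 1e-12)
  # zero generator: identity
  expect_equal(simple_probabilities(rate_matrix(matrix(0, 2, 2)), 1),
               diag(2), ignore_attr = TRUE)
})

test_that("the competing-risks decomposition is exact exactly where valid", {
  # two competing absorbing exits: matches the published 0.432 / 0.135
  Q <- rate_matrix(rbind(c(-2, 1, 1), c(0, 0, 0), c(0, 0, 0)))
  p <- competing_risks_probabilities(Q, 1)
  expect_equal(round(p[1, 2], 3), 0.432)
  expect_equal(round(p[1, 3], 3), 0.432)
  expect_equal(round(p[1, 1], 3), 0.135)
  exact <- probabilities_series(Q, 1)$p
  expect_lt(max(abs(p - exact)), 1e-12)
  # single exit reduces to 1 - exp(-rt)
  Q2 <- rate_matrix(rbind(c(-0.7, 0.7), c(0, 0)))
  expect_equal(competing_risks_probabilities(Q2, 2)[1, 2], 1 - exp(-1.4),
               tolerance = 1e-14)
  # a non-absorbing successor invalidates the decomposition
  Q3 <- rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0)))
  expect_error(competing_risks_probabilities(Q3, 1),
               class = "rtp_invalid_structure")
  # exactness across random competing-absorbing fixtures
  set.seed(21)
  for (i in 1:10) {
    r <- runif(3, 0.1, 2)
    Q4 <- rate_matrix(rbind(c(-sum(r), r), rep(0, 4), rep(0, 4), rep(0, 4)))
    t <- runif(1, 0.2, 3)
    expect_lt(max(abs(competing_risks_probabilities(Q4, t) -
                      probabilities_series(Q4, t)$p)), 1e-12)
  }
})

test_that("compare_methods aggregates errors and bounds violations", {
  Q <- rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0)))
  cmp <- compare_methods(Q, 1)
  v <- cmp$bounds_violations
  expect_true(any(v$row == 1 & v$col == 1 &
                  abs(v$value - (-0.264)) < 5e-4))
  expect_null(cmp$competing)  # q23 > 0 forbids the decomposition
  # short-cycle regime: the simple formula becomes accurate
  Qs <- rate_matrix(Q$q * 1e-4)
  expect_lt(compare_methods(Qs, 1)$max_abs_error_simple, 1e-7)
  # zero generator: all methods identical
  cmp0 <- compare_methods(rate_matrix(matrix(0, 2, 2)), 1)
  expect_equal(cmp0$max_abs_error_simple, 0)
  expect_equal(cmp0$max_abs_error_competing, 0)
})

test_that("the simple-formula error decays quadratically in cycle length", {
  Q <- rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0)))
  ts <- 2^-(0:20)  # halving over six decades
  err <- vapply(ts, function(t)
    max(abs(simple_probabilities(Q, t) - probabilities_series(Q, t)$p)), 0)
  slope <- coef(lm(log(err) ~ log(ts)))[[2]]
  expect_gt(slope, 1.8)
  expect_lt(slope, 2.2)
})
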