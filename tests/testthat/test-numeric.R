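# Numeric engine: eigen route, series oracle, diagnostics, fallback.

test_that("the worked three-state conversion matches its known values", {
  Q <- rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0)))
  res <- probabilities_eigen(Q, 1)
  # closed form: p11 = e^-2t, p22 = e^-t, p12 = e^-t - e^-2t
  expect_equal(res$P$p[1, 1], exp(-2), tolerance = 1e-12)
  expect_equal(res$P$p[1, 2], exp(-1) - exp(-2), tolerance = 1e-12)
  expect_equal(res$P$p[2, 3], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(round(res$P$p[1, 1], 3), 0.135)
  expect_equal(round(res$P$p[1, 2], 3), 0.233)
  expect_equal(round(res$P$p[2, 3], 3), 0.632)
  expect_false(res$report$near_degenerate)
  expect_false(res$report$complex_eigenvalues)
})

test_that("series and eigen routes agree on random fixtures", {
  set.seed(101)
  structs <- canonical_structs()
  for (rep in 1:25) {
    st <- structs[[1 + rep %% length(structs)]]
    Q <- generate_fixture(st, seed = 1000 + rep)
    t <- runif(1, 0.1, 3)
    Pe <- probabilities_eigen(Q, t)$P$p
    Ps <- probabilities_series(Q, t)$p
    expect_lt(max(abs(Pe - Ps)), 1e-9)
  }
})

test_that("series conversion matches closed forms and the identity limit", {
  # single transition to an absorbing state: p12 = 1 - exp(-rt)
  Q <- rate_matrix(rbind(c(-0.7, 0.7), c(0, 0)))
  expect_equal(probabilities_series(Q, 2)$p[1, 2], 1 - exp(-1.4),
               tolerance = 1e-14)
  # zero generator: P = I exactly
  expect_equal(probabilities_series(rate_matrix(matrix(0, 3, 3)), 1)$p,
               diag(3), ignore_attr = TRUE)
  # t -> 0: P -> I
  Q3 <- rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0)))
  expect_lt(max(abs(probabilities_eigen(Q3, 1e-12)$P$p - diag(3))), 1e-10)
})

test_that("series route agrees with an independent matrix exponential", {
  skip_if_not_installed("Matrix")
  set.seed(5)
  for (i in 1:5) {
    Q <- generate_fixture(struct_backward4(), seed = 60 + i)
    t <- runif(1, 0.2, 2)
    ref <- as.matrix(Matrix::expm(Matrix::Matrix(Q$q * t)))
    expect_lt(max(abs(probabilities_series(Q, t)$p - ref)), 1e-12)
  }
})

test_that("row sums, Chapman-Kolmogorov and the absorbing limit hold", {
  set.seed(202)
  structs <- canonical_structs()
  for (rep in 1:40) {
    st <- structs[[1 + rep %% length(structs)]]
    Q <- generate_fixture(st, seed = 2000 + rep)
    s <- runif(1, 0.05, 5); t <- runif(1, 0.05, 5)
    Ps <- probabilities_series(Q, s)$p
    Pt <- probabilities_series(Q, t)$p
    Pst <- probabilities_series(Q, s + t)$p
    expect_lt(max(abs(rowSums(Pst) - 1)), 1e-10)
    expect_lt(max(abs(Ps %*% Pt - Pst)), 1e-9)
  }
  # all mass ends in the absorbing state
  Q <- generate_fixture(struct_forward3(), seed = 8)
  Pinf <- probabilities_series(Q, 1e3)$p
  expect_lt(max(abs(Pinf[, 3] - 1)), 1e-9)
})

test_that("triangular generators get their eigenvalues read off exactly", {
  set.seed(303)
  for (i in 1:10) {
    Q <- generate_fixture(struct_forward4(), seed = 300 + i)
    ed <- eigen_decompose(Q)
    expect_identical(Re(ed$values), unname(diag(Q$q)))
    expect_identical(Im(ed$values), rep(0, 4))
  }
})

test_that("defective generators raise NotDiagonalizable and trigger the series fallback", {
  # repeated eigenvalue -1 with a coupling makes this triangular Q defective;
  # independent check: rank(Q + I) = 2, so the eigenspace of -1 is
  # 1-dimensional while the algebraic multiplicity is 2
  q <- rbind(c(-1, 1, 0), c(0, -1, 1), c(0, 0, 0))
  expect_equal(qr(q + diag(3))$rank, 2L)
  Q <- rate_matrix(q)
  expect_error(eigen_decompose(Q), class = "rtp_not_diagonalizable")
  res <- rates_to_probs(Q, 1)
  expect_true(res$report$fallback_series)
  # the fallback result is the true exponential: closed form for this chain
  expect_equal(res$P$p[1, 2], exp(-1), tolerance = 1e-12)  # t e^-t at t=1
  # zero matrix is diagonal already: no error, degenerate flagged
  rep0 <- diagnose(rate_matrix(matrix(0, 2, 2)), 1)
  expect_true(rep0$degenerate)
  expect_true(rep0$near_degenerate)
  expect_false(rep0$fallback_series)
})

test_that("diagnose flags near-degenerate and complex-eigenvalue generators", {
  # near-equal eigenvalue pair in a backward model: a = g, b*f tiny
  q <- matrix(0, 4, 4)
  q[1, 2] <- 1e-9; q[1, 3] <- 0.5; q[1, 4] <- 0.5
  q[2, 1] <- 1e-9; q[2, 3] <- 0.5; q[2, 4] <- 0.5
  q[3, 4] <- 0.4
  diag(q) <- -rowSums(q)
  rep <- diagnose(rate_matrix(q), 1)
  expect_true(rep$near_degenerate)
  expect_false(rep$degenerate)
  expect_gt(rep$min_gap_sigfigs, 8)
  # strong cyclic backward rates give a complex-conjugate pair, but the
  # imaginary parts cancel in P (series route confirms)
  qc <- rbind(c(-1, 1, 0), c(0, -1, 1), c(1, 0, -1))
  repc <- diagnose(rate_matrix(qc), 1)
  expect_true(repc$complex_eigenvalues)
  expect_lt(repc$imag_residual, 1e-10)
  expect_lt(repc$max_route_diff, 1e-9)
  # the well-conditioned worked example raises no flags
  rep1 <- diagnose(rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0))), 1)
  expect_false(rep1$near_degenerate)
  expect_false(rep1$complex_eigenvalues)
  expect_false(rep1$fallback_series)
})
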