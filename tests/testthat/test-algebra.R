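# Exact-arithmetic layer: polynomials, GCDs, fractions, sqrt extensions.
# Expected values are computed by hand on small cases.

qp_var <- ratetoprob:::qp_var
qp_add <- ratetoprob:::qp_add
qp_sub <- ratetoprob:::qp_sub
qp_mul <- ratetoprob:::qp_mul
qp_pow <- ratetoprob:::qp_pow
qp_gcd <- ratetoprob:::qp_gcd
qp_const <- ratetoprob:::qp_const
qp_scale <- ratetoprob:::qp_scale
qp_divexact <- ratetoprob:::qp_divexact
qp_equal <- ratetoprob:::qp_equal
qp_eval <- ratetoprob:::qp_eval
qf_new <- ratetoprob:::qf_new
qf_mul <- ratetoprob:::qf_mul
qf_div <- ratetoprob:::qf_div
qf_sub <- ratetoprob:::qf_sub
qf_equal <- ratetoprob:::qf_equal
qf_eval <- ratetoprob:::qf_eval
qf_const <- ratetoprob:::qf_const
qf_from_poly <- ratetoprob:::qf_from_poly

test_that("polynomial arithmetic expands and cancels exactly", {
  a <- qp_var("a"); b <- qp_var("b")
  # (a+b)^2 = a^2 + 2ab + b^2
  sq <- qp_pow(qp_add(a, b), 2)
  expect_equal(sort(unname(unclass(sq))), c(1, 1, 2))
  # (a+b)(a-b) = a^2 - b^2 and its gcd with (a+b)^2 is a+b
  dif <- qp_mul(qp_add(a, b), qp_sub(a, b))
  expect_true(qp_equal(qp_gcd(dif, sq), qp_add(a, b)))
  # exact division recovers the cofactor
  expect_true(qp_equal(qp_divexact(sq, qp_add(a, b)), qp_add(a, b)))
  # integer contents participate in the gcd: gcd(6ab, 4a^2) = 2a
  g <- qp_gcd(qp_scale(qp_mul(a, b), 6), qp_scale(qp_pow(a, 2), 4))
  expect_true(qp_equal(g, qp_scale(a, 2)))
})

test_that("rational functions cancel common polynomial factors", {
  a <- qp_var("a"); b <- qp_var("b")
  f <- qf_new(qp_mul(qp_add(a, b), qp_sub(a, b)), qp_add(a, b))
  expect_true(qf_equal(f, qf_from_poly(qp_sub(a, b))))
  # sign convention: denominator has a positive leading coefficient
  g <- qf_new(a, qp_scale(qp_add(a, b), -1))
  expect_true(all(unclass(g$den) > 0))
  env <- list(a = 0.7, b = 0.2)
  expect_equal(qf_eval(g, env), 0.7 / (-0.9))
})

test_that("square-root extension arithmetic reduces s^2 to the discriminant", {
  a <- qp_var("a"); g <- qp_var("g"); b <- qp_var("b"); f <- qp_var("f")
  disc <- qp_add(qp_pow(qp_sub(a, g), 2), qp_scale(qp_mul(b, f), 4))
  ext <- list(".s1" = disc)
  s <- qp_var(".s1")
  # the quadratic-root pair multiplies back to the determinant ag - bf
  k <- qf_new(qp_add(qp_add(a, g), s), qp_const(2), ext)
  l <- qf_new(qp_sub(qp_add(a, g), s), qp_const(2), ext)
  prod <- qf_mul(k, l, ext)
  det <- qf_sub(qf_from_poly(qp_mul(a, g)), qf_from_poly(qp_mul(b, f)))
  expect_true(qf_equal(prod, det, ext))
  # ... and sums to the trace
  tr <- ratetoprob:::qf_add(k, l, ext)
  expect_true(qf_equal(tr, qf_from_poly(qp_add(a, g)), ext))
  # denominators are rationalized: 1/(a+s) has an s-free denominator
  r <- qf_div(qf_const(1), qf_new(qp_add(a, s), qp_const(1), ext), ext)
  expect_false(".s1" %in% ratetoprob:::qp_vars(r$den))
  env <- list(a = -2, g = -3, b = 0.5, f = 0.7)
  env$.s1 <- sqrt(qp_eval(disc, env))
  expect_equal(qf_eval(r, env), 1 / (env$a + env$.s1), tolerance = 1e-14)
})

test_that("polynomial evaluation matches direct computation on random points", {
  set.seed(42)
  a <- qp_var("a"); b <- qp_var("b"); c <- qp_var("c")
  # p = (a + 2b)(b - c) + c^3
  p <- qp_add(qp_mul(qp_add(a, qp_scale(b, 2)), qp_sub(b, c)),
              qp_pow(c, 3))
  for (i in 1:20) {
    env <- list(a = rnorm(1), b = rnorm(1), c = rnorm(1))
    expect_equal(qp_eval(p, env),
                 (env$a + 2 * env$b) * (env$b - env$c) + env$c^3,
                 tolerance = 1e-12)
  }
})
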