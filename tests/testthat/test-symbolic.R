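# Symbolic derivation engine: golden structures, intermediate-variable
# bookkeeping, and end-to-end equivalence with the series oracle.

sx_render <- ratetoprob:::sx_render
sm_entry <- ratetoprob:::sm_entry
qf_equal <- ratetoprob:::qf_equal
qf_var <- ratetoprob:::qf_var
qf_neg <- ratetoprob:::qf_neg
qf_is_zero <- ratetoprob:::qf_is_zero

test_that("the symbolic generator is written with the documented conventions", {
  Qs <- build_symbolic_Q(struct_forward3(), naming = "qij")
  r <- ratetoprob:::sm_render(Qs)
  expect_equal(unname(r[1, ]), c("q11", "q12", "q13"))
  # single-exit row collapses its diagonal to the negated exit symbol
  expect_equal(unname(r[2, ]), c("0", "-q23", "q23"))
  expect_equal(unname(r[3, ]), c("0", "0", "0"))
  expect_equal(Qs$diag_defs, list(q11 = c("q12", "q13")))
  # single-transition two-state structure
  Q2 <- build_symbolic_Q(model_structure(2, rbind(c(1, 2))), naming = "qij")
  expect_equal(unname(ratetoprob:::sm_render(Q2)[1, ]), c("-q12", "q12"))
  # backward model in letter naming: f sits at position (2,1)
  Qb <- build_symbolic_Q(struct_backward4())
  expect_equal(ratetoprob:::sm_render(Qb)[2, 1], "f")
})

test_that("eigenvalues are read off or solved per structure (golden sets)", {
  d1 <- vapply(derive_formulas(struct_forward3(), naming = "qij")$D_entries,
               sx_render, "")
  expect_equal(d1, c("q11", "-q23", "0"))
  d2 <- vapply(derive_formulas(struct_forward4())$D_entries, sx_render, "")
  expect_equal(d2, c("a", "f", "-i", "0"))
  fs3 <- derive_formulas(struct_backward4())
  d3 <- vapply(fs3$D_entries, sx_render, "")
  expect_equal(d3, c("k", "l", "-j", "0"))
  # the quadratic pair carries the discriminant (a-g)^2 + 4bf
  kdef <- Filter(function(iv) iv$name == "k", fs3$intermediates)[[1]]$expr
  expect_match(sx_render(kdef), "sqrt", fixed = TRUE)
  disc <- ratetoprob:::characteristic_roots(
    build_symbolic_Q(struct_backward4()))$ext[[1]]
  a <- ratetoprob:::qp_var("a"); g <- ratetoprob:::qp_var("g")
  b <- ratetoprob:::qp_var("b"); f <- ratetoprob:::qp_var("f")
  expected <- ratetoprob:::qp_add(
    ratetoprob:::qp_pow(ratetoprob:::qp_sub(a, g), 2),
    ratetoprob:::qp_scale(ratetoprob:::qp_mul(b, f), 4))
  expect_true(ratetoprob:::qp_equal(disc, expected))
  d4 <- vapply(derive_formulas(struct_twodeath5())$D_entries, sx_render, "")
  expect_equal(d4, c("a", "g", "k", "0", "0"))
})

test_that("a residual characteristic factor of degree >= 3 is refused", {
  # three mutually-backward states form an irreducible 3x3 block
  s <- model_structure(5, rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2),
                                c(1, 3), c(3, 1), c(3, 4), c(4, 5)))
  expect_error(derive_formulas(s), class = "rtp_unsolvable_characteristic")
  expect_error(derive_formulas(s), "impossible to find an algebraic solution")
})

test_that("the derived eigenvector matrix matches the classical three-state result", {
  fs <- derive_formulas(struct_forward3(), naming = "qij")
  U <- fs$U_entries
  # column for the first eigenvalue is e1; column two is the published
  # (q12, -q11-q23, 0) up to scale -- here exactly
  expect_true(qf_equal(sm_entry(U, 1, 1), ratetoprob:::qf_const(1)))
  expect_true(qf_is_zero(sm_entry(U, 2, 1)))
  expect_true(qf_equal(sm_entry(U, 1, 2), qf_var("q12")))
  b <- Filter(function(iv) iv$name == "b", fs$intermediates)[[1]]
  expect_equal(sx_render(b$expr), "-q11-q23")
  # column three equals (1,1,1) once the diagonal definition
  # q11 = -(q12+q13) is substituted: check proportionality numerically on
  # the raw (pre-intermediation) eigenvector matrix
  Qs <- build_symbolic_Q(struct_forward3(), naming = "qij")
  roots <- ratetoprob:::characteristic_roots(Qs)
  Uraw <- symbolic_eigenvectors(Qs, roots)
  set.seed(9)
  for (i in 1:10) {
    r <- runif(3, 0.1, 2)
    vals <- list(q12 = r[1], q13 = r[2], q23 = r[3], q11 = -(r[1] + r[2]))
    col3 <- vapply(1:3, function(row)
      ratetoprob:::qf_eval(sm_entry(Uraw, row, 3), vals), 0)
    expect_lt(max(abs(col3 / col3[1] - 1)), 1e-12)
  }
})

test_that("intermediates reproduce the published four-state bookkeeping", {
  fs <- derive_formulas(struct_forward4())
  # U-stage letters continue after the rate symbols: j, k, l, ...
  unames <- vapply(Filter(function(iv) iv$stage == "U", fs$intermediates),
                   `[[`, "", "name")
  expect_equal(unames[1:3], c("j", "k", "l"))
  # U(2,2) is the eigenvector scale factor f - a
  l <- Filter(function(iv) iv$name == "l", fs$intermediates)[[1]]
  env <- new.env(parent = emptyenv())
  vals <- list(a = -1.5, f = -0.9)
  for (nm in names(vals)) assign(nm, vals[[nm]], envir = env)
  expect_equal(ratetoprob:::sx_eval(l$expr, env), vals$f - vals$a)
  # golden inverse entry: U^-1[1,2] = -b/l
  ap <- Filter(function(iv) iv$name == "a'", fs$intermediates)[[1]]
  expect_equal(sx_render(ap$expr), "(-b)/l")
  expect_equal(ratetoprob:::qf_atom_info(
    sm_entry(fs$Uinv_entries, 1, 2))$name, "a'")
  # shared entries share one intermediate: U(3,4) and U(4,4) are both a*f
  expect_true(qf_equal(sm_entry(fs$U_entries, 3, 4),
                       sm_entry(fs$U_entries, 4, 4)))
})

test_that("the intermediate list is a DAG evaluated in dependency order", {
  for (st in canonical_structs()) {
    fs <- suppressMessages(derive_formulas(st))
    known <- c(names(fs$base_symbols), "t")
    for (iv in fs$intermediates) {
      deps <- ratetoprob:::sx_syms(iv$expr)
      expect_true(all(deps %in% known),
                  info = sprintf("%s depends on undefined %s", iv$name,
                                 paste(setdiff(deps, known), collapse = ",")))
      known <- c(known, iv$name)
    }
    for (i in seq_len(fs$n)) for (j in seq_len(fs$n))
      expect_true(all(ratetoprob:::sx_syms(fs$P_entries[[i, j]]) %in% known))
  }
})

test_that("derived formulas agree with the series oracle across structures", {
  set.seed(77)
  for (st in canonical_structs()) {
    fs <- suppressMessages(derive_formulas(st))
    for (rep in 1:10) {
      rates <- random_rates(fs)
      Q <- q_from_rates(fs, rates)
      t <- runif(1, 0.2, 2)
      P1 <- evaluate_formula_set(fs, rates, t)
      P2 <- probabilities_series(Q, t)
      expect_lt(max(abs(P1$p - P2$p)), 1e-9)
      expect_lt(max(abs(rowSums(P1$p) - 1)), 1e-10)
    }
  }
})

test_that("row-sum replacement preserves the evaluated probabilities", {
  fs <- derive_formulas(struct_forward4(), row_sum_replace = TRUE)
  fs0 <- derive_formulas(struct_forward4())
  set.seed(12)
  rates <- random_rates(fs)
  P1 <- evaluate_formula_set(fs, rates, 0.7)
  P0 <- evaluate_formula_set(fs0, rates, 0.7)
  expect_lt(max(abs(P1$p - P0$p)), 1e-10)
  expect_lt(max(abs(rowSums(P1$p) - 1)), 1e-10)
})

test_that("evaluation errors are classed and informative", {
  fs <- derive_formulas(struct_forward4())
  set.seed(3)
  rates <- random_rates(fs)
  expect_error(evaluate_formula_set(fs, rates[-1], 1),
               class = "rtp_unbound_symbol")
  # equal eigenvalues at the evaluation point: division by zero in the
  # formulas (a == f exactly makes the factor l = f - a vanish; dyadic
  # rates keep the sums exact in floating point)
  rates_eq <- rates
  rates_eq[c("b", "c", "d")] <- c(0.25, 0.25, 0.5)
  rates_eq[c("g", "h")] <- c(0.5, 0.5)
  expect_error(evaluate_formula_set(fs, rates_eq, 1),
               class = "rtp_degenerate_evaluation")
})

test_that("absorbing rows are identity rows in every derived set", {
  for (st in canonical_structs()) {
    fs <- suppressMessages(derive_formulas(st))
    for (i in st$absorbing) for (j in seq_len(fs$n)) {
      e <- fs$P_entries[[i, j]]
      expect_true(ratetoprob:::sx_is_num(e, as.numeric(i == j)))
    }
  }
})
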