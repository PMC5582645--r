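# Rate schedules, cohort traces and probabilistic sensitivity analysis.

test_that("schedules convert per cycle and keep per-cycle diagnostics", {
  q1 <- rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0))
  S <- rate_schedule(list(young = rate_matrix(q1),
                          old = rate_matrix(q1 / 2)), t = 1)
  out <- convert_schedule(S)
  expect_length(out, 2)
  expect_equal(out[[1]]$P$p[1, 1], exp(-2), tolerance = 1e-12)
  expect_equal(out[[2]]$P$p[1, 1], exp(-1), tolerance = 1e-12)
  expect_s3_class(out[[1]]$report, "diagnostics_report")
  # identical matrices give identical conversions
  S2 <- rate_schedule(list(rate_matrix(q1), rate_matrix(q1)), t = 1)
  out2 <- convert_schedule(S2)
  expect_equal(out2[[1]]$P$p, out2[[2]]$P$p)
  # one defective cycle must not abort the others
  qd <- rbind(c(-1, 1, 0), c(0, -1, 1), c(0, 0, 0))
  S3 <- rate_schedule(list(rate_matrix(q1), rate_matrix(qd)), t = 1)
  out3 <- convert_schedule(S3)
  expect_false(is.null(out3[[1]]$P))
  expect_false(is.null(out3[[2]]$P))  # series fallback still converts
  expect_true(out3[[2]]$report$fallback_series)
  # rising mortality gives nondecreasing death probabilities
  cyc <- lapply(1:10, function(k) {
    q <- rbind(c(-(0.1 + 0.05 * k) - 0.2, 0.2, 0.1 + 0.05 * k),
               c(0, -(0.2 + 0.1 * k), 0.2 + 0.1 * k),
               c(0, 0, 0))
    rate_matrix(q)
  })
  outm <- convert_schedule(rate_schedule(cyc, t = 1))
  pdeath <- vapply(outm, function(x) x$P$p[1, 3], 0)
  expect_true(all(diff(pdeath) > 0))
})

test_that("the cohort trace obeys conservation and the absorbing limit", {
  Q <- rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0)))
  P <- rates_to_probs(Q, 1)$P
  tr <- markov_trace(P, c(1, 0, 0), n_cycles = 1)
  expect_equal(round(tr[2, ], 3), c(0.135, 0.233, 0.632),
               ignore_attr = TRUE)
  # identity transitions leave the occupancy constant
  trI <- markov_trace(prob_matrix(diag(3), 1), c(0.3, 0.3, 0.4),
                      n_cycles = 5)
  expect_true(all(apply(trI, 2, function(col) all(col == col[1]))))
  # 100 cycles: death occupancy is monotone and tends to 1
  tr100 <- markov_trace(P, c(1, 0, 0), n_cycles = 100)
  expect_lt(max(abs(rowSums(tr100) - 1)), 1e-10)
  expect_true(all(diff(tr100[, 3]) >= -1e-14))
  expect_gt(tr100[101, 3], 1 - 1e-9)
  expect_error(markov_trace(P, c(1, 0)), class = "rtp_dimension_mismatch")
})

psa_tr <- function(se = 0.1) {
  data.frame(from = c(1, 1, 2), to = c(2, 3, 3),
             rate = c(1, 1, 1), se = se)
}

test_that("PSA draws are reproducible and recover the point estimate at SE = 0", {
  st <- struct_forward3()
  d1 <- psa_draws(psa_spec(psa_tr(), n_draws = 50, seed = 42), st)
  d2 <- psa_draws(psa_spec(psa_tr(), n_draws = 50, seed = 42), st)
  expect_identical(lapply(d1, `[[`, "q"), lapply(d2, `[[`, "q"))
  d3 <- psa_draws(psa_spec(psa_tr(), n_draws = 50, seed = 43), st)
  expect_false(identical(d1[[1]]$q, d3[[1]]$q))
  # SE = 0: every draw equals the point estimate, conversions identical
  d0 <- psa_draws(psa_spec(psa_tr(se = 0), n_draws = 5, seed = 1), st)
  Qpoint <- rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0)),
                        states = st$states)
  for (d in d0) expect_equal(d$q, Qpoint$q)
  res <- psa_convert(d0, 1)
  for (P in res$P) expect_equal(P$p, rates_to_probs(Qpoint, 1)$P$p)
})

test_that("moment matching holds for both families", {
  st <- struct_forward3()
  for (dist in c("lognormal", "gamma")) {
    tr <- psa_tr(se = 0.3)
    tr$dist <- dist
    draws <- psa_draws(psa_spec(tr, n_draws = 4000, seed = 7), st)
    r12 <- vapply(draws, function(d) d$q[1, 2], 0)
    expect_true(all(r12 > 0))
    mc_se <- 0.3 / sqrt(4000)
    expect_lt(abs(mean(r12) - 1), 2.5 * mc_se)
    expect_lt(abs(sd(r12) - 0.3), 0.03)
  }
})

test_that("PSA spec coverage and distribution names are checked", {
  st <- struct_forward3()
  expect_error(psa_draws(psa_spec(psa_tr()[-3, ], n_draws = 2), st),
               "missing")
  bad <- psa_tr(); bad$dist <- "beta"
  expect_error(psa_spec(bad), class = "rtp_unknown_distribution")
})

test_that("degenerate draws are flagged, never dropped", {
  # backward-model draws built so the eigenvalue pair nearly coincides
  st <- struct_backward4()
  tr <- data.frame(from = c(1, 1, 1, 2, 2, 2, 3),
                   to = c(2, 3, 4, 1, 3, 4, 4),
                   rate = c(1e-9, 0.5, 0.5, 1e-9, 0.5, 0.5, 0.4),
                   se = 0)
  draws <- psa_draws(psa_spec(tr, n_draws = 5, seed = 1), st)
  res <- psa_convert(draws, 1)
  expect_equal(res$flagged_fraction, 1)
  expect_length(res$P, 5)
  expect_false(any(vapply(res$P, is.null, TRUE)))
  # well-separated draws are not flagged
  tr2 <- data.frame(from = c(1, 1, 1, 2, 2, 3),
                    to = c(2, 3, 4, 3, 4, 4),
                    rate = c(0.9, 0.4, 0.2, 0.7, 0.3, 0.5), se = 0.05)
  draws2 <- psa_draws(psa_spec(tr2, n_draws = 200, seed = 2),
                      struct_forward4())
  res2 <- psa_convert(draws2, 1)
  expect_equal(res2$flagged_fraction, 0)
  # scatter data is tidy: one row per draw and quantity
  expect_equal(nrow(res2$scatter), 200 * (2 + 16))
  expect_named(res2$scatter, c("draw", "quantity", "value"))
})
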