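# Probabilistic sensitivity analysis on transition rates.
#
# Each transition rate carries a point estimate and a standard error; PSA
# draws rate matrices from per-transition uncertainty distributions and
# converts every draw, so that parameter uncertainty propagates directly
# into the transition probabilities.  Distributions are parameterized by
# moment matching on the rate scale; the default lognormal (and the gamma
# alternative) keep draws strictly positive.  Draws whose conversion shows
# warning signs (nearly equal eigenvalues, bounds excursions) are flagged,
# never silently discarded: with only a few flagged draws the user may
# reasonably drop them, but that decision is theirs.

#' Specify a PSA over transition rates
#'
#' @param transitions data frame with columns `from`, `to`, `rate` (point
#'   estimate, >= 0), `se` (standard error on the rate scale, >= 0) and
#'   optionally `dist` (`"lognormal"` or `"gamma"`, default lognormal).
#' @param n_draws number of draws, >= 1.
#' @param seed integer seed; the draw sequence is reproducible bit for bit.
#' @return object of class `psa_spec`.
#' @export
psa_spec <- function(transitions, n_draws = 1000L, seed = 1L) {
  stopifnot(is.data.frame(transitions),
            all(c("from", "to", "rate", "se") %in% names(transitions)),
            n_draws >= 1L)
  if (is.null(transitions$dist)) transitions$dist <- "lognormal"
  bad <- !transitions$dist %in% c("lognormal", "gamma")
  if (any(bad))
    rtp_error("rtp_unknown_distribution",
              sprintf("unknown distribution '%s'", transitions$dist[bad][1L]))
  stopifnot(all(transitions$rate >= 0), all(transitions$se >= 0))
  structure(list(transitions = transitions,
                 n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "psa_spec")
}

# one vector of n draws for a single transition, by moment matching
draw_rates <- function(dist, n, m, s) {
  if (s == 0 || m == 0) return(rep(m, n))
  switch(dist,
    lognormal = {
      sigma2 <- log(1 + (s / m)^2)
      mu <- log(m) - sigma2 / 2
      stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
    },
    gamma = {
      shape <- (m / s)^2
      stats::rgamma(n, shape = shape, rate = m / s^2)
    },
    rtp_error("rtp_unknown_distribution",
              sprintf("unknown distribution '%s'", dist))
  )
}

#' Draw rate matrices for a PSA
#'
#' Samples every allowed transition independently from its stated
#' distribution and rebuilds a valid [rate_matrix()] per draw (diagonal
#' recomputed as minus the row sum).  The spec must cover exactly the
#' transitions allowed by the structure.
#'
#' @param spec a [psa_spec()].
#' @param structure a [model_structure()].
#' @return list of `spec$n_draws` [rate_matrix()] objects.
#' @export
psa_draws <- function(spec, structure) {
  stopifnot(inherits(spec, "psa_spec"), inherits(structure, "model_structure"))
  tr <- spec$transitions
  key <- function(m) paste(m[, 1L], m[, 2L])
  want <- key(structure$allowed)
  have <- paste(tr$from, tr$to)
  if (!setequal(want, have) || anyDuplicated(have))
    stop("PSA spec must cover exactly the structure's allowed transitions; ",
         "missing: ", paste(setdiff(want, have), collapse = ", "),
         "; extra: ", paste(setdiff(have, want), collapse = ", "))
  n <- structure$n
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  samples <- lapply(seq_len(nrow(tr)), function(k)
    draw_rates(tr$dist[k], spec$n_draws, tr$rate[k], tr$se[k]))
  lapply(seq_len(spec$n_draws), function(d) {
    q <- matrix(0, n, n, dimnames = list(structure$states, structure$states))
    for (k in seq_len(nrow(tr))) q[tr$from[k], tr$to[k]] <- samples[[k]][d]
    diag(q) <- -rowSums(q)
    rate_matrix(q, structure$states)
  })
}

#' Convert every PSA draw and collect diagnostics
#'
#' Converts each drawn rate matrix through [rates_to_probs()], recording
#' per-draw diagnostics.  Draws flagged as (near-)degenerate or carrying a
#' bounds violation are marked in the summary, not removed.  Scatter data
#' (one row per draw and quantity: eigenvalue gap depth, bounds excursion,
#' and every transition probability) are returned in long format for
#' plotting or export with [write_scatter_csv()].
#'
#' @param draws list of [rate_matrix()] (from [psa_draws()]).
#' @param t cycle length.
#' @return object of class `psa_result`: `P` (list of [prob_matrix()], one
#'   per draw; `NULL` where conversion failed), `flags` (data frame with
#'   per-draw diagnostic columns), `flagged_fraction`, `scatter` (long data
#'   frame `draw`, `quantity`, `value`).
#' @export
psa_convert <- function(draws, t) {
  stopifnot(length(draws) >= 1L, all(vapply(draws, is_rate_matrix, TRUE)))
  n <- draws[[1L]]$n
  P <- vector("list", length(draws))
  flags <- data.frame(draw = seq_along(draws), near_degenerate = FALSE,
                      degenerate = FALSE, fallback = FALSE,
                      bounds_violation = 0, min_gap_sigfigs = NA_real_,
                      failed = FALSE)
  scat <- vector("list", length(draws))
  for (d in seq_along(draws)) {
    res <- tryCatch(rates_to_probs(draws[[d]], t), rtp_error = function(e) e)
    if (inherits(res, "rtp_error")) {
      flags$failed[d] <- TRUE
      next
    }
    P[[d]] <- res$P
    rep <- res$report
    flags$near_degenerate[d] <- rep$near_degenerate
    flags$degenerate[d] <- rep$degenerate
    flags$fallback[d] <- rep$fallback_series
    flags$bounds_violation[d] <- rep$bounds_violation
    flags$min_gap_sigfigs[d] <- rep$min_gap_sigfigs
    p <- res$P$p
    qty <- c("eigen_gap_sigfigs", "bounds_violation",
             sprintf("p%d%d", row(p), col(p)))
    val <- c(rep$min_gap_sigfigs, rep$bounds_violation, as.vector(p))
    scat[[d]] <- data.frame(draw = d, quantity = qty, value = val)
  }
  marked <- flags$near_degenerate | flags$degenerate | flags$failed |
    flags$bounds_violation > 1e-10
  structure(list(P = P, flags = flags,
                 flagged_fraction = mean(marked),
                 scatter = do.call(rbind, scat)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA conversion: %d draws, %.2f%% flagged\n",
              nrow(x$flags), 100 * x$flagged_fraction))
  if (any(x$flags$failed))
    cat(sprintf("  %d draws failed to convert\n", sum(x$flags$failed)))
  invisible(x)
}

#' Write PSA scatter data as tidy CSV
#'
#' One row per draw and quantity (`draw`, `quantity`, `value`), suitable
#' for scatter-plotting intermediate diagnostics and probabilities to spot
#' extreme draws.
#'
#' @param result a `psa_result` from [psa_convert()].
#' @param path output file.
#' @export
write_scatter_csv <- function(result, path) {
  stopifnot(inherits(result, "psa_result"))
  utils::write.csv(result$scatter, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
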