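# Canonical transition structures and the synthetic rate-matrix generator.
#
# The structure factories cover the model shapes that recur throughout
# health-economic decision modelling: the three-state forward
# (well/ill/dead) model, four-state forward and forward-plus-one-backward
# models, a five-state forward model with two competing death states, and
# the chain-shaped disease progression model (stay, progress one step, or
# die).

#' Canonical model structures
#'
#' @return a [model_structure()].
#' @name canonical_structures
NULL

#' @describeIn canonical_structures three states, forward only
#'   (1->2, 1->3, 2->3).
#' @export
struct_forward3 <- function() {
  model_structure(3, rbind(c(1, 2), c(1, 3), c(2, 3)),
                  states = c("well", "ill", "dead"))
}

#' @describeIn canonical_structures four states, forward only
#'   (1->2,3,4; 2->3,4; 3->4), e.g. healthy / minor event / major event /
#'   dead.
#' @export
struct_forward4 <- function() {
  model_structure(4, rbind(c(1, 2), c(1, 3), c(1, 4),
                           c(2, 3), c(2, 4), c(3, 4)))
}

#' @describeIn canonical_structures four states with one backward
#'   transition (2->1 added to the forward set minus nothing).
#' @export
struct_backward4 <- function() {
  model_structure(4, rbind(c(1, 2), c(1, 3), c(1, 4),
                           c(2, 1), c(2, 3), c(2, 4), c(3, 4)))
}

#' @describeIn canonical_structures five states, forward only, two
#'   absorbing death states (4 and 5).
#' @export
struct_twodeath5 <- function() {
  model_structure(5, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                           c(2, 3), c(2, 4), c(2, 5),
                           c(3, 4), c(3, 5)))
}

#' @describeIn canonical_structures disease progression chain with `n`
#'   states: from state `i < n` either progress to `i + 1` or die
#'   (state `n`); no backward transitions.
#' @param n total number of states including the death state (>= 3).
#' @export
struct_progression <- function(n = 6) {
  stopifnot(n >= 3)
  fwd <- cbind(seq_len(n - 2L), seq_len(n - 2L) + 1L)
  die <- cbind(seq_len(n - 1L), n)
  model_structure(n, rbind(fwd, die))
}

#' Generate a random rate matrix for a given structure
#'
#' Draws every allowed transition rate uniformly from `rate_range` under
#' the given seed.  By default the draw is rejected and redrawn (up to
#' `max_tries` times) while the conversion diagnostics flag near-degenerate
#' eigenvalues, so that default fixtures are well-conditioned;
#' `avoid_degenerate = FALSE` disables the redraw to produce stress
#' fixtures.
#'
#' @param structure a [model_structure()].
#' @param seed integer seed (same seed, same matrix).
#' @param rate_range positive range `c(lo, hi)`, `lo > 0`.
#' @param avoid_degenerate redraw while flagged (default `TRUE`).
#' @param max_tries redraw budget.
#' @return a [rate_matrix()].
#' @export
generate_fixture <- function(structure, seed, rate_range = c(0.1, 2),
                             avoid_degenerate = TRUE, max_tries = 100L) {
  stopifnot(inherits(structure, "model_structure"),
            length(rate_range) == 2L, rate_range[1L] > 0,
            rate_range[2L] >= rate_range[1L])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  n <- structure$n
  m <- nrow(structure$allowed)
  for (try in seq_len(max_tries)) {
    q <- matrix(0, n, n, dimnames = list(structure$states, structure$states))
    r <- stats::runif(m, rate_range[1L], rate_range[2L])
    for (k in seq_len(m))
      q[structure$allowed[k, 1L], structure$allowed[k, 2L]] <- r[k]
    diag(q) <- -rowSums(q)
    Q <- rate_matrix(q, structure$states)
    if (!avoid_degenerate) return(Q)
    rep <- diagnose(Q, t = 1)
    if (!rep$near_degenerate && !rep$fallback_series) return(Q)
  }
  rtp_error("rtp_cannot_avoid_degeneracy",
            sprintf("no well-conditioned fixture found in %d attempts",
                    max_tries))
}
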