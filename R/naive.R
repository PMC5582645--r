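# The "simple formula" and the competing-risks decomposition.
#
# Both are popular shortcuts for converting rates to probabilities.  The
# simple formula p = 1 - exp(-q t) applied per transition ignores the
# possibility of two events in one cycle and is exact only when a row has a
# single exit into an absorbing state; applied to a row with competing
# exits it can push the diagonal below zero.  The competing-risks
# decomposition allocates the total exit probability proportionally to the
# rates and is exact precisely when every successor of a transient state is
# absorbing.  These are kept here, bounds violations and all, so they can
# be compared against the exact conversion.

#' Naive per-transition exponential conversion
#'
#' Applies `p[i,j] = 1 - exp(-q[i,j] t)` to every structurally allowed
#' transition (rate > 0), leaves disallowed transitions at 0, and sets each
#' diagonal to the row complement `1 - sum(off-diagonal)`.  Bounds are
#' deliberately not enforced: with competing exits the diagonal can fall
#' below 0, and returning the out-of-range value as computed is the point
#' of the comparison.
#'
#' @param Q a [rate_matrix()].
#' @param t cycle length, positive.
#' @return a plain numeric matrix (rows sum to 1 by construction, entries
#'   may leave `[0, 1]`).
#' @examples
#' Q <- rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0)))
#' simple_probabilities(Q, 1)  # diagonal entry 1 is -0.264
#' @export
simple_probabilities <- function(Q, t) {
  stopifnot(is_rate_matrix(Q), t > 0)
  p <- matrix(0, Q$n, Q$n, dimnames = dimnames(Q$q))
  off <- Q$q > 0 & row(Q$q) != col(Q$q)
  p[off] <- 1 - exp(-Q$q[off] * t)
  diag(p) <- 0
  diag(p) <- 1 - rowSums(p)
  p
}

#' Competing-risks (conditional two-way node) conversion
#'
#' For a transient state `i` with total exit rate `q_i = -q[i,i]`, the exit
#' probability `1 - exp(-q_i t)` is allocated to the destinations in
#' proportion to their rates: `p[i,j] = (1 - exp(q[i,i] t)) q[i,j] / q_i`.
#' This is exact only when every destination reachable from a transient
#' state is absorbing, so that no second transition can follow within the
#' cycle; the function refuses other structures.  The classical
#' presentation covers a single state with two competing absorbing exits;
#' the formula extends unchanged to any number of competing absorbing
#' exits, and that generalization is what is implemented here.
#'
#' @param Q a [rate_matrix()].
#' @param t cycle length, positive.
#' @return a plain numeric matrix.
#' @examples
#' Q <- rate_matrix(rbind(c(-2, 1, 1), c(0, 0, 0), c(0, 0, 0)))
#' competing_risks_probabilities(Q, 1)
#' @export
competing_risks_probabilities <- function(Q, t) {
  stopifnot(is_rate_matrix(Q), t > 0)
  n <- Q$n
  absorbing <- which(rowSums(Q$q != 0) == 0)
  for (i in setdiff(seq_len(n), absorbing)) {
    succ <- which(Q$q[i, ] > 0 & seq_len(n) != i)
    bad <- setdiff(succ, absorbing)
    if (length(bad))
      rtp_error("rtp_invalid_structure",
                sprintf(paste0("state %d is reachable from %d but is not ",
                               "absorbing (it has outgoing transitions): the ",
                               "competing-risks decomposition is not valid"),
                        bad[1L], i))
  }
  p <- diag(n)
  dimnames(p) <- dimnames(Q$q)
  for (i in setdiff(seq_len(n), absorbing)) {
    qi <- -Q$q[i, i]
    exit <- 1 - exp(Q$q[i, i] * t)
    p[i, ] <- exit * Q$q[i, ] / qi
    p[i, i] <- exp(Q$q[i, i] * t)
  }
  p
}

#' Compare exact, simple and competing-risks conversions
#'
#' Runs the exact conversion (eigen route with automatic series fallback),
#' the naive per-transition formula, and -- when the structure permits --
#' the competing-risks decomposition, and summarises the discrepancies.
#'
#' @param Q a [rate_matrix()].
#' @param t cycle length, positive.
#' @return object of class `method_comparison`: `exact` (a
#'   [prob_matrix()]), `simple` and `competing` (plain matrices; `competing`
#'   is `NULL` when the structure does not permit it),
#'   `max_abs_error_simple`, `max_abs_error_competing`, and
#'   `bounds_violations` (violation table for the simple formula).
#' @export
compare_methods <- function(Q, t) {
  stopifnot(is_rate_matrix(Q), t > 0)
  exact <- rates_to_probs(Q, t)
  simple <- simple_probabilities(Q, t)
  competing <- tryCatch(competing_risks_probabilities(Q, t),
                        rtp_invalid_structure = function(e) NULL)
  structure(list(
    exact = exact$P,
    report = exact$report,
    simple = simple,
    competing = competing,
    max_abs_error_simple = max(abs(simple - exact$P$p)),
    max_abs_error_competing = if (is.null(competing)) NA_real_ else
      max(abs(competing - exact$P$p)),
    bounds_violations = validate_prob_matrix(simple)
  ), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, digits = 4, ...) {
  cat("Exact conversion (eigen route",
      if (x$report$fallback_series) ", series fallback" else "", "):\n",
      sep = "")
  print(round(x$exact$p, digits))
  cat(sprintf("\nSimple formula (max |error| = %.4g):\n",
              x$max_abs_error_simple))
  print(round(x$simple, digits))
  if (!is.null(x$competing)) {
    cat(sprintf("\nCompeting-risks decomposition (max |error| = %.4g):\n",
                x$max_abs_error_competing))
    print(round(x$competing, digits))
  }
  if (nrow(x$bounds_violations)) {
    cat("\nSimple-formula bounds violations:\n")
    print(x$bounds_violations)
  }
  invisible(x)
}
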