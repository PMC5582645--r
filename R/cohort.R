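# Per-cycle rate schedules and Markov cohort traces.
#
# Transition rates commonly vary with an external clock (patient age,
# treatment phase), so the rate-to-probability conversion has to be
# repeated for each age-group or cycle; a schedule bundles the per-cycle
# rate matrices and converts them independently, and the cohort trace then
# propagates a state-occupancy distribution through the per-cycle
# probability matrices.

#' Bundle per-cycle (age-group) rate matrices
#'
#' @param cycles list of [rate_matrix()] objects, one per cycle or
#'   age-group, all sharing the same states; names are used as cycle
#'   labels.
#' @param t common cycle length.
#' @return object of class `rate_schedule`.
#' @export
rate_schedule <- function(cycles, t) {
  stopifnot(is.list(cycles), length(cycles) >= 1L, t > 0)
  stopifnot(all(vapply(cycles, is_rate_matrix, TRUE)))
  s1 <- cycles[[1L]]$states
  for (Q in cycles)
    if (!identical(Q$states, s1) || Q$n != cycles[[1L]]$n)
      stop("all matrices in a schedule must share states and dimension")
  if (is.null(names(cycles)))
    names(cycles) <- paste0("cycle", seq_along(cycles))
  structure(list(cycles = cycles, t = t), class = "rate_schedule")
}

#' Convert every cycle of a rate schedule
#'
#' Each cycle is converted independently through [rates_to_probs()].  A
#' conversion failure in one age-band is recorded in that cycle's slot and
#' must not abort the remaining cycles.
#'
#' @param S a [rate_schedule()].
#' @return list with one element per cycle: `label`, `P` (a
#'   [prob_matrix()], or `NULL` on failure), `report` (diagnostics, or the
#'   error condition on failure).
#' @export
convert_schedule <- function(S) {
  stopifnot(inherits(S, "rate_schedule"))
  lapply(seq_along(S$cycles), function(i) {
    res <- tryCatch(rates_to_probs(S$cycles[[i]], S$t),
                    rtp_error = function(e) e)
    if (inherits(res, "rtp_error")) {
      list(label = names(S$cycles)[i], P = NULL, report = res)
    } else {
      list(label = names(S$cycles)[i], P = res$P, report = res$report)
    }
  })
}

#' Propagate a cohort through per-cycle probability matrices
#'
#' Standard cohort-model recursion with a row-distribution convention:
#' occupancy row `k` equals row `k-1` times the cycle-`k` transition
#' matrix.
#'
#' @param P_list a single [prob_matrix()] (used for every cycle), or a list
#'   of them, one per cycle; or the output of [convert_schedule()].
#' @param init initial state-occupancy distribution (nonnegative, sums
#'   to 1).
#' @param n_cycles number of cycles when `P_list` is a single matrix;
#'   otherwise taken from its length.
#' @return numeric matrix with `n_cycles + 1` rows (row 1 = `init`) and one
#'   column per state; every row sums to 1.
#' @export
markov_trace <- function(P_list, init, n_cycles = NULL) {
  if (inherits(P_list, "prob_matrix")) {
    n_cycles <- n_cycles %||% 1L
    P_list <- rep(list(P_list), n_cycles)
  }
  if (length(P_list) && is.list(P_list[[1L]]) &&
      !inherits(P_list[[1L]], "prob_matrix")) {
    # convert_schedule() output
    P_list <- lapply(P_list, function(x) {
      if (is.null(x$P)) stop("schedule cycle '", x$label, "' failed to convert")
      x$P
    })
  }
  stopifnot(all(vapply(P_list, inherits, TRUE, "prob_matrix")))
  n <- P_list[[1L]]$n
  if (length(init) != n)
    rtp_error("rtp_dimension_mismatch",
              sprintf("init has length %d but the model has %d states",
                      length(init), n))
  stopifnot(all(init >= 0), abs(sum(init) - 1) < 1e-10)
  out <- matrix(0, length(P_list) + 1L, n,
                dimnames = list(0:length(P_list), P_list[[1L]]$states))
  out[1L, ] <- init
  for (k in seq_along(P_list)) {
    if (P_list[[k]]$n != n)
      rtp_error("rtp_dimension_mismatch", "cycle matrices differ in dimension")
    out[k + 1L, ] <- out[k, ] %*% P_list[[k]]$p
  }
  out
}
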