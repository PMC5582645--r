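#' Validate and construct a transition-rate matrix
#'
#' A transition-rate (intensity, generator) matrix `Q` of a continuous-time
#' Markov chain has nonnegative off-diagonal entries `q[i,j]` (the
#' instantaneous rate of moving from state `i` to state `j`, in events per
#' unit time), non-positive diagonal entries, and zero row sums.  Input row
#' sums within a small relative tolerance of zero are treated as rounding
#' noise from upstream software: the diagonal is recomputed as minus the sum
#' of the off-diagonal entries so that downstream algebra sees exact zero
#' row sums.  Row sums beyond the tolerance signal a malformed input and
#' raise an error.
#'
#' @param q numeric square matrix of rates (n >= 2).
#' @param states character vector of state labels; defaults to the dimnames
#'   of `q` or `S1 ... Sn`.
#' @param tol relative row-sum tolerance, scaled by `max(1, max(abs(q)))`.
#' @return an object of class `rate_matrix` with fields `states`, `q`
#'   (the validated matrix, exact zero row sums) and `n`.
#' @examples
#' q <- rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0))
#' rate_matrix(q, states = c("well", "ill", "dead"))
#' @export
rate_matrix <- function(q, states = NULL, tol = 1e-12) {
  q <- as.matrix(q)
  if (nrow(q) != ncol(q) || nrow(q) < 2L)
    rtp_error("rtp_non_square",
              sprintf("rate matrix must be square with n >= 2, got %d x %d",
                      nrow(q), ncol(q)))
  if (!is.numeric(q) || any(!is.finite(q)))
    rtp_error("rtp_non_square", "rate matrix must be finite numeric")
  n <- nrow(q)
  if (is.null(states)) states <- rownames(q) %||% paste0("S", seq_len(n))
  stopifnot(length(states) == n)
  off <- q; diag(off) <- 0
  if (any(off < 0)) {
    bad <- which(off < 0, arr.ind = TRUE)[1L, ]
    rtp_error("rtp_negative_offdiag",
              sprintf("negative off-diagonal rate q[%d,%d] = %g",
                      bad[1L], bad[2L], q[bad[1L], bad[2L]]))
  }
  scale <- max(1, max(abs(q)))
  rs <- rowSums(q)
  if (any(abs(rs) > tol * scale)) {
    bad <- which.max(abs(rs))
    rtp_error("rtp_row_sum",
              sprintf("row %d sums to %g (beyond tolerance %g); input looks malformed",
                      bad, rs[bad], tol * scale))
  }
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  dimnames(q) <- list(states, states)
  structure(list(states = states, q = q, n = n), class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("Transition-rate matrix (%d states)\n", x$n))
  print(x$q, ...)
  invisible(x)
}

#' @export
as.matrix.rate_matrix <- function(x, ...) x$q

is_rate_matrix <- function(x) inherits(x, "rate_matrix")

#' Describe the allowed-transition structure of a model
#'
#' A `model_structure` records which off-diagonal transitions a multistate
#' model permits, independently of the numeric rates.  Absorbing (death)
#' states are those with no outgoing transitions, and the structure is
#' upper-triangular when every allowed transition goes from a lower to a
#' higher state index (forward-only models).
#'
#' @param n number of states (>= 2).
#' @param allowed two-column integer matrix (or list of pairs) of allowed
#'   ordered transitions `(from, to)`, `from != to`.
#' @param states optional state labels.
#' @return an object of class `model_structure` with fields `n`, `allowed`,
#'   `absorbing` (integer vector) and `upper_triangular`.
#' @examples
#' model_structure(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
#' @export
model_structure <- function(n, allowed, states = NULL) {
  if (is.list(allowed)) allowed <- do.call(rbind, allowed)
  if (length(allowed) == 0L) {
    allowed <- matrix(integer(0), ncol = 2L)
  }
  allowed <- matrix(as.integer(allowed), ncol = 2L,
                    dimnames = list(NULL, c("from", "to")))
  stopifnot(n >= 2L, all(allowed >= 1L), all(allowed <= n),
            all(allowed[, 1L] != allowed[, 2L]))
  allowed <- allowed[order(allowed[, 1L], allowed[, 2L]), , drop = FALSE]
  allowed <- unique(allowed)
  if (is.null(states)) states <- paste0("S", seq_len(n))
  absorbing <- setdiff(seq_len(n), unique(allowed[, 1L]))
  structure(list(n = as.integer(n), allowed = allowed,
                 absorbing = as.integer(absorbing),
                 upper_triangular = all(allowed[, 1L] < allowed[, 2L]),
                 states = states),
            class = "model_structure")
}

#' @export
print.model_structure <- function(x, ...) {
  cat(sprintf("Model structure: %d states, %d transitions%s\n", x$n,
              nrow(x$allowed),
              if (x$upper_triangular) " (forward only)" else ""))
  if (nrow(x$allowed))
    cat("  transitions:",
        paste(sprintf("%d->%d", x$allowed[, 1], x$allowed[, 2]),
              collapse = ", "), "\n")
  cat("  absorbing:",
      if (length(x$absorbing)) paste(x$absorbing, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Infer the transition structure from a rate matrix
#'
#' A transition is considered allowed when its rate exceeds `threshold`.
#' The default threshold is exactly 0: a stored rate of 0 means the
#' transition is structurally disallowed.
#'
#' @param Q a [rate_matrix()].
#' @param threshold nonnegative rate below or at which a transition is
#'   treated as absent.
#' @return a [model_structure()].
#' @export
infer_structure <- function(Q, threshold = 0) {
  stopifnot(is_rate_matrix(Q), threshold >= 0)
  idx <- which(Q$q > threshold & row(Q$q) != col(Q$q), arr.ind = TRUE)
  model_structure(Q$n, unname(idx), states = Q$states)
}

#' Construct a transition-probability matrix object
#'
#' Wraps an `n x n` matrix of per-cycle transition probabilities together
#' with its cycle length.  Entries a hair outside `[0, 1]` (within `tol`,
#' default 1e-10) are clipped and rows renormalized; anything worse is left
#' untouched so that [validate_prob_matrix()] can report it.
#'
#' @param p numeric square matrix.
#' @param t cycle length (same time unit as the rates).
#' @param states state labels.
#' @param tol clipping tolerance.
#' @return object of class `prob_matrix` with fields `states`, `p`, `t`.
#' @export
prob_matrix <- function(p, t, states = NULL, tol = 1e-10) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (is.null(states)) states <- rownames(p) %||% paste0("S", seq_len(n))
  # clip rounding-level excursions only
  lo <- p < 0 & p > -tol
  hi <- p > 1 & p < 1 + tol
  p[lo] <- 0; p[hi] <- 1
  rs <- rowSums(p)
  fix <- abs(rs - 1) < tol & rs > 0
  p[fix, ] <- p[fix, , drop = FALSE] / rs[fix]
  dimnames(p) <- list(states, states)
  structure(list(states = states, p = p, t = t, n = n),
            class = "prob_matrix")
}

#' @export
print.prob_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Transition-probability matrix, cycle length t = %g\n", x$t))
  print(round(x$p, digits), ...)
  invisible(x)
}

#' @export
as.matrix.prob_matrix <- function(x, ...) x$p

#' Check a probability matrix against its invariants
#'
#' Verifies that all entries lie in `[0, 1]` and all row sums equal 1
#' (within `tol`), and that absorbing states (zero off-diagonal rows) have
#' a diagonal entry of 1.  Violations are returned, not raised, because an
#' out-of-bounds "probability" is a diagnostic finding of interest (the
#' naive conversion formula produces them).
#'
#' @param P a [prob_matrix()] or plain matrix.
#' @param tol tolerance, default 1e-10.
#' @return data frame with columns `row`, `col`, `value`, `bound`,
#'   `message`; zero rows when all invariants hold.
#' @export
validate_prob_matrix <- function(P, tol = 1e-10) {
  p <- if (inherits(P, "prob_matrix")) P$p else as.matrix(P)
  n <- nrow(p)
  out <- data.frame(row = integer(0), col = integer(0), value = numeric(0),
                    bound = numeric(0), message = character(0))
  add <- function(i, j, v, b, msg) {
    rbind(out, data.frame(row = i, col = j, value = v, bound = b,
                          message = msg))
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (p[i, j] < -tol)
      out <- add(i, j, p[i, j], 0, sprintf("p[%d,%d] = %.6g below 0", i, j,
                                           p[i, j]))
    if (p[i, j] > 1 + tol)
      out <- add(i, j, p[i, j], 1, sprintf("p[%d,%d] = %.6g above 1", i, j,
                                           p[i, j]))
  }
  rs <- rowSums(p)
  for (i in seq_len(n)) {
    if (abs(rs[i] - 1) > tol)
      out <- add(i, NA_integer_, rs[i], 1,
                 sprintf("row %d sums to %.6g, not 1", i, rs[i]))
    off <- p[i, -i]
    if (all(abs(off) <= tol) && abs(p[i, i] - 1) > tol && abs(rs[i] - 1) <= tol)
      out <- add(i, i, p[i, i], 1,
                 sprintf("absorbing state %d has p[i,i] != 1", i))
  }
  out
}
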