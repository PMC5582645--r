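# Numeric conversion of a rate matrix Q to P(t) = Exp(Qt).
#
# Two independent routes are provided.  The eigen route computes
# U Exp(Dt) U^-1 from the spectral decomposition Q = U D U^-1 and is the
# numeric mirror of the derived algebraic formulas, sharing their failure
# modes (defective Q, nearly equal eigenvalues).  The series route computes
# Exp(Qt) by scaling-and-squaring of a truncated Taylor sum and has none of
# those failure modes; it serves as the independent oracle throughout the
# test-suite and as the automatic fallback of the public entry point.

#' Eigen-decomposition of a rate matrix
#'
#' Computes eigenvalues and eigenvectors of `Q` with metadata used by the
#' failure-mode diagnostics: the agreement depth (in significant figures) of
#' the closest eigenvalue pair, whether any eigenvalue is complex, and the
#' condition number of the eigenvector matrix `U`.
#'
#' For an exactly triangular `Q` the eigenvalues are read off the diagonal
#' exactly and the eigenvectors obtained by back-substitution, mirroring the
#' algebraic shortcut for forward-only models; otherwise LAPACK's general
#' eigensolver is used.
#'
#' @param Q a [rate_matrix()].
#' @return object of class `eigen_decomp`: `values` (complex vector, the
#'   diagonal of `D`; `values[i]` corresponds to column `i` of `U`), `U`,
#'   `U_inv`, `min_gap_sigfigs`, `has_complex`, `condition_U`.
#' @export
eigen_decompose <- function(Q) {
  stopifnot(is_rate_matrix(Q))
  q <- Q$q
  n <- Q$n
  lower <- all(q[upper.tri(q)] == 0)
  upper <- all(q[lower.tri(q)] == 0)
  if (upper || lower) {
    ed <- eigen_triangular(q, upper = upper)
  } else {
    e <- eigen(q)
    ed <- list(values = as.complex(e$values), U = as.complex(e$vectors))
    dim(ed$U) <- dim(q)
  }
  vals <- ed$values
  U <- ed$U
  U_inv <- tryCatch(solve(U), error = function(e) NULL)
  cond <- if (is.null(U_inv)) Inf else
    norm(abs(U), "1") * norm(abs(U_inv), "1")
  if (!is.finite(cond) || cond > 1e12)
    rtp_error("rtp_not_diagonalizable",
              sprintf(paste0("eigenvector matrix is numerically singular ",
                             "(condition %.3g): Q is defective or nearly so; ",
                             "use the series conversion instead"), cond))
  scale <- max(1, max(Mod(vals)))
  # a repeated zero eigenvalue from several absorbing states is structural:
  # the derived formulas never divide by that difference, so zero-zero
  # pairs are excluded from the gap metric (an all-zero spectrum still
  # counts as exactly repeated)
  zero <- Mod(vals) <= 1e-12 * scale
  gaps <- Mod(outer(vals, vals, `-`))
  keep <- upper.tri(gaps) & !outer(zero, zero, `&`)
  if (any(keep)) {
    min_gap <- min(gaps[keep]) / scale
    exact_repeat <- any(gaps[keep] == 0)
  } else {
    min_gap <- 0
    exact_repeat <- Q$n > 1
  }
  structure(list(
    values = vals, U = U, U_inv = U_inv,
    exact_repeat = exact_repeat,
    min_gap_sigfigs = if (min_gap == 0) Inf else -log10(min_gap),
    has_complex = any(abs(Im(vals)) > 1e-12 * pmax(1, Mod(vals))),
    condition_U = cond,
    states = Q$states
  ), class = "eigen_decomp")
}

# exact eigenpairs of a triangular generator by back-substitution
eigen_triangular <- function(q, upper = TRUE) {
  n <- nrow(q)
  vals <- diag(q)
  U <- diag(n) * (1 + 0i)
  ord_target <- if (upper) seq_len(n) else rev(seq_len(n))
  for (i in ord_target) {
    lam <- vals[i]
    x <- complex(n)
    x[i] <- 1
    js <- if (upper) rev(seq_len(max(i - 1L, 0L))) else
      (if (i < n) (i + 1L):n else integer(0))
    for (j in js) {
      later <- if (upper) (j + 1L):i else i:(j - 1L)
      rhs <- -sum(q[j, later] * x[later])
      dd <- q[j, j] - lam
      if (dd == 0) {
        if (Mod(rhs) == 0) { x[j] <- 0 } else {
          rtp_error("rtp_not_diagonalizable",
                    sprintf(paste0("repeated eigenvalue %g on the diagonal ",
                                   "makes Q defective"), Re(lam)))
        }
      } else {
        x[j] <- rhs / dd
      }
    }
    U[, i] <- x / max(Mod(x))
  }
  list(values = as.complex(vals), U = U)
}

#' Convert rates to probabilities via the eigen-decomposition
#'
#' Computes `P(t) = U Exp(Dt) U^-1` in complex arithmetic and returns the
#' real part, together with a [diagnostics report][diagnose] recording the
#' residual imaginary magnitude, eigenvalue-gap warnings and any excursion
#' of the probabilities outside `[0, 1]`.
#'
#' @param Q a [rate_matrix()].
#' @param t cycle length, positive.
#' @return list with components `P` (a [prob_matrix()]) and `report`
#'   (a `diagnostics_report`).
#' @examples
#' Q <- rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0)))
#' probabilities_eigen(Q, t = 1)$P
#' @export
probabilities_eigen <- function(Q, t) {
  stopifnot(is_rate_matrix(Q), t > 0)
  ed <- eigen_decompose(Q)
  degenerate <- ed$exact_repeat
  if (degenerate && ed$condition_U > 1e8)
    rtp_error("rtp_degenerate_eigenvalues",
              paste0("two eigenvalues are exactly equal: the eigen-route ",
                     "formulas divide by their difference"))
  Pc <- ed$U %*% diag(exp(ed$values * t), Q$n) %*% ed$U_inv
  imag_residual <- max(abs(Im(Pc)))
  P <- Re(Pc)
  report <- build_report(ed, P, imag_residual, fallback = FALSE,
                         degenerate = degenerate)
  list(P = prob_matrix(P, t, Q$states), report = report)
}

build_report <- function(ed, P, imag_residual, fallback, degenerate,
                         messages = character(0)) {
  near <- !is.null(ed) && ed$min_gap_sigfigs > 8
  bounds <- max(0, max(-P), max(P - 1))
  msg <- messages
  if (degenerate)
    msg <- c(msg, "exactly equal eigenvalues detected")
  if (near && !degenerate)
    msg <- c(msg, sprintf(
      "two eigenvalues agree to %.1f significant figures; derived formulas divide by their difference",
      ed$min_gap_sigfigs))
  if (!is.null(ed) && ed$has_complex)
    msg <- c(msg, "complex eigenvalue pair present; handled in complex arithmetic")
  if (bounds > 1e-10)
    msg <- c(msg, sprintf("probability out of [0,1] by %.3g", bounds))
  if (fallback)
    msg <- c(msg, "eigen route unusable; fell back to series summation")
  structure(list(
    degenerate = isTRUE(degenerate),
    near_degenerate = isTRUE(degenerate) || isTRUE(near),
    complex_eigenvalues = !is.null(ed) && ed$has_complex,
    imag_residual = imag_residual,
    bounds_violation = bounds,
    min_gap_sigfigs = if (is.null(ed)) NA_real_ else ed$min_gap_sigfigs,
    condition_U = if (is.null(ed)) NA_real_ else ed$condition_U,
    fallback_series = fallback,
    messages = msg
  ), class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Conversion diagnostics:\n")
  flags <- c(degenerate = x$degenerate, near_degenerate = x$near_degenerate,
             complex_eigenvalues = x$complex_eigenvalues,
             series_fallback = x$fallback_series)
  cat(sprintf("  flags: %s\n",
              if (any(flags)) paste(names(flags)[flags], collapse = ", ")
              else "none"))
  cat(sprintf("  imaginary residual: %.3g; bounds violation: %.3g\n",
              x$imag_residual, x$bounds_violation))
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

#' Convert rates to probabilities by series summation
#'
#' Computes the matrix exponential `Exp(Qt)` from its defining infinite sum,
#' using scaling-and-squaring: `Qt` is scaled by `2^-s` until its 1-norm is
#' at most 0.5, the Taylor series is summed until the next term's norm drops
#' below `tol`, and the result is squared `s` times.  Naive Taylor summation
#' loses accuracy for large `|Qt|`; the scaling step avoids that.  This
#' route is independent of the eigen-decomposition and has no
#' division-by-eigenvalue-difference failure mode, so it serves as the
#' oracle against which the other conversion paths are checked.
#'
#' @param Q a [rate_matrix()].
#' @param t cycle length, positive.
#' @param tol truncation tolerance for the scaled series, default 1e-14.
#' @return a [prob_matrix()].
#' @export
probabilities_series <- function(Q, t, tol = 1e-14) {
  stopifnot(is_rate_matrix(Q), t > 0, tol > 0)
  A <- Q$q * t
  s <- 0L
  while (norm(A, "1") > 0.5) { A <- A / 2; s <- s + 1L }
  n <- Q$n
  P <- diag(n)
  term <- diag(n)
  k <- 0L
  while (norm(term, "1") >= tol) {
    k <- k + 1L
    if (k > 200L)
      rtp_error("rtp_non_convergence",
                "series summation did not converge in 200 terms")
    term <- term %*% A / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  prob_matrix(P, t, Q$states)
}

#' Run the failure-mode diagnostics for a conversion
#'
#' Attempts the eigen-decomposition, converts by both the eigen and series
#' routes, compares them, and aggregates all diagnostic flags.  Never raises:
#' failures are recorded as findings in the returned report.
#'
#' @param Q a [rate_matrix()].
#' @param t cycle length.
#' @return a `diagnostics_report` with an extra field `max_route_diff`, the
#'   largest elementwise difference between the eigen and series routes.
#' @export
diagnose <- function(Q, t = 1) {
  stopifnot(is_rate_matrix(Q))
  Pser <- probabilities_series(Q, t)
  res <- tryCatch(probabilities_eigen(Q, t), rtp_error = function(e) e)
  if (inherits(res, "rtp_error")) {
    ed <- tryCatch(eigen_decompose(Q), rtp_error = function(e) NULL)
    rep <- build_report(ed, Pser$p, imag_residual = 0, fallback = TRUE,
                        degenerate = inherits(res, "rtp_degenerate_eigenvalues"),
                        messages = conditionMessage(res))
    rep$max_route_diff <- NA_real_
    return(rep)
  }
  rep <- res$report
  rep$max_route_diff <- max(abs(res$P$p - Pser$p))
  if (rep$max_route_diff > 1e-9)
    rep$messages <- c(rep$messages,
                      sprintf("eigen and series routes differ by %.3g",
                              rep$max_route_diff))
  rep
}

#' Convert a rate matrix to a probability matrix (public entry point)
#'
#' Uses the eigen-decomposition route and falls back automatically to the
#' series summation when the eigen route is unusable (defective `Q` or
#' exactly equal eigenvalues); the fallback is recorded in the report.
#'
#' @param Q a [rate_matrix()] or plain numeric generator matrix.
#' @param t cycle length, positive.
#' @return list with `P` (a [prob_matrix()]) and `report`.
#' @examples
#' Q <- rate_matrix(rbind(c(-2, 1, 1), c(0, -1, 1), c(0, 0, 0)))
#' rates_to_probs(Q, t = 1)$P
#' @export
rates_to_probs <- function(Q, t) {
  if (!is_rate_matrix(Q)) Q <- rate_matrix(Q)
  res <- tryCatch(probabilities_eigen(Q, t), rtp_error = function(e) e)
  if (inherits(res, "rtp_error")) {
    P <- probabilities_series(Q, t)
    ed <- tryCatch(eigen_decompose(Q), rtp_error = function(e) NULL)
    report <- build_report(ed, P$p, imag_residual = 0, fallback = TRUE,
                           degenerate = inherits(res, "rtp_degenerate_eigenvalues"),
                           messages = conditionMessage(res))
    return(list(P = P, report = report))
  }
  res
}
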