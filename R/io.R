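# Reading and writing rate and probability matrices.
#
# CSV layout: a header row of state labels, a first column of state
# labels, numeric cells.  The diagonal may be left blank (it is then
# filled as minus the row sum) or given explicitly (it is then checked).
# JSON layout: {"states": [...], "q": [[...], ...]}.  Numbers are written
# with 17 significant digits, which round-trips IEEE doubles exactly.

#' Read a rate matrix from CSV or JSON
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return a [rate_matrix()].
#' @export
read_rate_matrix <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path))
    rtp_error("rtp_parse_error", sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                      rtp_error("rtp_parse_error",
                                sprintf("cannot parse %s: %s", path,
                                        conditionMessage(e))))
    if (is.null(obj$q))
      rtp_error("rtp_parse_error", "JSON must contain a 'q' matrix")
    q <- as.matrix(obj$q)
    states <- obj$states %||% paste0("S", seq_len(nrow(q)))
  } else {
    df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                   stringsAsFactors = FALSE),
                   error = function(e)
                     rtp_error("rtp_parse_error",
                               sprintf("cannot parse %s: %s", path,
                                       conditionMessage(e))))
    states <- as.character(df[[1L]])
    q <- suppressWarnings(as.matrix(
      as.data.frame(lapply(df[-1L], as.numeric))))
    if (nrow(q) != ncol(q))
      rtp_error("rtp_parse_error",
                sprintf("%s: %d rows but %d numeric columns", path,
                        nrow(q), ncol(q)))
  }
  # blank/NA diagonal cells: fill each as minus its row's off-diagonal sum
  if (any(is.na(q))) {
    bad <- which(is.na(q) & row(q) != col(q), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      rtp_error("rtp_parse_error",
                sprintf("non-numeric off-diagonal cell at row %d, column %d",
                        bad[1L, 1L], bad[1L, 2L]))
    for (i in which(is.na(diag(q))))
      q[i, i] <- -sum(q[i, -i])
  }
  rate_matrix(q, states)
}

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Write a rate matrix to CSV or JSON
#'
#' @param Q a [rate_matrix()].
#' @param path output file.
#' @param format `"auto"`, `"csv"` or `"json"`.
#' @export
write_rate_matrix <- function(Q, path, format = c("auto", "csv", "json")) {
  stopifnot(is_rate_matrix(Q))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(list(states = Q$states, q = Q$q), path,
                         digits = I(17), auto_unbox = FALSE)
  } else {
    write_matrix_csv(Q$q, Q$states, path)
  }
  invisible(path)
}

write_matrix_csv <- function(m, states, path) {
  lines <- c(paste(c("state", states), collapse = ","),
             vapply(seq_along(states), function(i)
               paste(c(states[i], fmt17(m[i, ])), collapse = ","), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write a probability matrix (and optional diagnostics) to CSV
#'
#' The matrix file stays purely numeric and machine-readable; diagnostics,
#' when given, go to a companion text file `<path>.diagnostics.txt`.
#'
#' @param P a [prob_matrix()].
#' @param path output CSV.
#' @param report optional `diagnostics_report` to write alongside.
#' @export
write_prob_matrix <- function(P, path, report = NULL) {
  stopifnot(inherits(P, "prob_matrix"))
  write_matrix_csv(P$p, P$states, path)
  if (!is.null(report)) {
    con <- file(paste0(path, ".diagnostics.txt"), "w")
    on.exit(close(con))
    sink(con); print(report); sink()
  }
  invisible(path)
}

#' Read a model structure from JSON
#'
#' Layout: `{"n": 4, "allowed": [[1,2], [1,3], ...], "states": [...]}`.
#'
#' @param path input file.
#' @return a [model_structure()].
#' @export
read_structure <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    rtp_error("rtp_parse_error",
                              sprintf("cannot parse %s: %s", path,
                                      conditionMessage(e))))
  if (is.null(obj$n) || is.null(obj$allowed))
    rtp_error("rtp_parse_error", "structure JSON needs 'n' and 'allowed'")
  model_structure(obj$n, as.matrix(obj$allowed), states = obj$states)
}
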