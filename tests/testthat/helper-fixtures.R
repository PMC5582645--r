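# Shared test helpers: random rate assignments for a derived formula set,
# the matching rate_matrix, and a small A1-formula CSV evaluator used to
# round-trip the spreadsheet export independently of the exporter.

# random named rates for every base symbol of a formula set
random_rates <- function(fs, lo = 0.2, hi = 1.5) {
  r <- stats::runif(length(fs$base_symbols), lo, hi)
  stats::setNames(r, names(fs$base_symbols))
}

# rate_matrix matching a formula set's structure and a named rate vector
q_from_rates <- function(fs, rates) {
  n <- fs$n
  q <- matrix(0, n, n)
  for (nm in names(fs$base_symbols)) {
    pos <- fs$base_symbols[[nm]]
    q[pos[1], pos[2]] <- rates[[nm]]
  }
  diag(q) <- -rowSums(q)
  rate_matrix(q, fs$states)
}

# the five canonical structures used across the equivalence tests
canonical_structs <- function() {
  list(forward3 = struct_forward3(),
       forward4 = struct_forward4(),
       backward4 = struct_backward4(),
       twodeath5 = struct_twodeath5(),
       progression6 = struct_progression(6))
}

# --- independent spreadsheet-formula evaluator ------------------------------
# Parses a CSV of cells where formulas start with "=", translates EXP/SQRT
# and A1 references, and evaluates cells iteratively until stable.  This is
# deliberately independent of the exporter: it knows nothing about layouts,
# only about A1 arithmetic.
eval_sheet_csv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  nr <- length(rows)
  nc <- max(vapply(rows, length, 1L))
  cell <- matrix("", nr, nc)
  for (i in seq_len(nr)) cell[i, seq_along(rows[[i]])] <- rows[[i]]
  val <- matrix(NA_real_, nr, nc)
  addr_of <- function(i, j) {
    col <- ""
    k <- j
    while (k > 0) { r <- (k - 1) %% 26; col <- paste0(LETTERS[r + 1], col)
      k <- (k - 1) %/% 26 }
    paste0(col, i)
  }
  col_num <- function(s) {
    v <- 0
    for (ch in strsplit(s, "")[[1]]) v <- v * 26 + match(ch, LETTERS)
    v
  }
  # literal numbers first
  suppress <- function(x) suppressWarnings(as.numeric(x))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!startsWith(cell[i, j], "=")) val[i, j] <- suppress(cell[i, j])
  }
  for (pass in 1:50) {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      f <- cell[i, j]
      if (!startsWith(f, "=") || !is.na(val[i, j])) next
      body <- substr(f, 2, nchar(f))
      body <- gsub("EXP(", "exp(", body, fixed = TRUE)
      body <- gsub("SQRT(", "sqrt(", body, fixed = TRUE)
      refs <- regmatches(body, gregexpr("[A-Z]+[0-9]+", body))[[1]]
      ok <- TRUE
      refs <- unique(refs)
      refs <- refs[order(-nchar(refs))]  # B21 before B2: avoid partial hits
      for (ref in refs) {
        rc <- regmatches(ref, regexec("([A-Z]+)([0-9]+)", ref))[[1]]
        ri <- as.integer(rc[3]); rj <- col_num(rc[2])
        v <- val[ri, rj]
        if (is.na(v)) { ok <- FALSE; break }
        body <- gsub(ref, sprintf("(%.17g)", v), body, fixed = TRUE)
      }
      if (!ok) next
      val[i, j] <- eval(parse(text = body), envir = baseenv())
      changed <- TRUE
    }
    if (!changed) break
  }
  list(cells = cell, values = val)
}
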