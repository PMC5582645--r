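# Spreadsheet-formula export of a derived formula set.
#
# The exported file is a plain-text CSV whose cells contain live A1-style
# spreadsheet formulas (leading "="), using only arithmetic, EXP and SQRT
# -- no macros.  Opened in Excel or LibreOffice the sheet computes P(t)
# from the rate cells.  Two layouts are offered: `matrix_blocks` places
# the six matrices Q, D, U, U^-1, Exp(Dt), P(t) side by side, and
# `single_row` puts rate inputs, every intermediate variable and every
# probability in one row of formulas designed for copying down, one row
# per age-group or cycle.

col_letter <- function(j) {
  out <- ""
  while (j > 0L) {
    r <- (j - 1L) %% 26L
    out <- paste0(LETTERS[r + 1L], out)
    j <- (j - 1L) %/% 26L
  }
  out
}

a1 <- function(row, col) paste0(col_letter(col), row)

sheet_funs <- c(exp = "EXP", sqrt = "SQRT")

# classify an atomic rational-function entry
qf_atom_info <- function(f) {
  if (qf_is_const(f)) return(list(kind = "num", val = qf_const_val(f)))
  stopifnot(length(f$num) == 1L)
  ex <- mono_parse(names(f$num)[1L])
  nm <- names(ex)[1L]
  if (f$num[[1L]] > 0) list(kind = "sym", name = nm)
  else list(kind = "negsym", name = nm)
}

#' Export a formula set as live spreadsheet formulas
#'
#' Writes a CSV of A1-style formulas implementing the derived conversion.
#' If `rates` are supplied the input cells are pre-filled so the opened
#' sheet immediately shows numeric probabilities; the export refuses with
#' `rtp_complex_formula` if those rates make an eigenvalue discriminant
#' negative, since `SQRT` of a negative number is a spreadsheet error and
#' complex arithmetic belongs to the numeric engine.
#'
#' @param F a `formula_set` from [derive_formulas()].
#' @param path output file (CSV of formulas).
#' @param layout `"matrix_blocks"` or `"single_row"`.
#' @param rates optional named numeric vector (by base rate symbol) or
#'   [rate_matrix()] used to pre-fill the input cells.
#' @param t cycle length written to the sheet's t cell.
#' @return `path`, invisibly.
#' @export
export_spreadsheet <- function(F, path, layout = c("matrix_blocks",
                                                   "single_row"),
                               rates = NULL, t = 1) {
  stopifnot(inherits(F, "formula_set"))
  layout <- match.arg(layout)
  rate_vals <- NULL
  if (!is.null(rates)) {
    if (is_rate_matrix(rates)) {
      rate_vals <- vapply(F$base_symbols, function(pos)
        rates$q[pos[1L], pos[2L]], 0)
    } else {
      rate_vals <- vapply(names(F$base_symbols), function(nm) {
        if (is.null(rates[[nm]]))
          rtp_error("rtp_unbound_symbol", sprintf("no rate for '%s'", nm))
        rates[[nm]]
      }, 0)
    }
    # refuse complex eigenvalues: SQRT(negative) breaks the sheet
    env <- new.env(parent = emptyenv())
    for (nm in names(rate_vals)) assign(nm, rate_vals[[nm]], envir = env)
    assign("t", t, envir = env)
    for (iv in F$intermediates) {
      v <- sx_eval(iv$expr, env)
      if (iv$stage == "D" && is.complex(v) && abs(Im(v)) > 0)
        rtp_error("rtp_complex_formula",
                  sprintf(paste0("eigenvalue '%s' is complex at these rates; ",
                                 "the spreadsheet export cannot represent it ",
                                 "-- use the numeric conversion"), iv$name))
      assign(iv$name, v, envir = env)
    }
  }
  defs <- stats::setNames(lapply(F$intermediates, `[[`, "expr"),
                          vapply(F$intermediates, `[[`, "", "name"))
  cells <- if (layout == "single_row")
    sheet_single_row(F, rate_vals, t, defs)
  else
    sheet_matrix_blocks(F, rate_vals, t, defs)
  lines <- apply(cells, 1L, function(r) paste(r, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

sheet_single_row <- function(F, rate_vals, t, defs) {
  base <- names(F$base_symbols)
  inames <- names(defs)
  n <- F$n
  pnames <- as.vector(t(outer(seq_len(n), seq_len(n),
                              function(i, j) sprintf("p%d%d", i, j))))
  headers <- c(base, "t", inames, pnames)
  addr <- stats::setNames(vapply(seq_along(headers), function(k) a1(2L, k), ""),
                          headers)
  ref <- function(nm) addr[[nm]]
  row2 <- character(length(headers))
  for (k in seq_along(base))
    row2[k] <- fmt17(if (is.null(rate_vals)) 0 else rate_vals[[base[k]]])
  row2[length(base) + 1L] <- fmt17(t)
  off <- length(base) + 1L
  for (k in seq_along(inames))
    row2[off + k] <- paste0("=", sx_render(defs[[k]], sym_fmt = ref,
                                           fun_names = sheet_funs))
  off <- off + length(inames)
  k <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k <- k + 1L
    e <- F$P_entries[[i, j]]
    row2[off + k] <- if (sx_is_num(e)) fmt17(e$v)
    else paste0("=", sx_render(e, sym_fmt = ref, fun_names = sheet_funs))
  }
  rbind(headers, row2)
}

sheet_matrix_blocks <- function(F, rate_vals, t, defs) {
  n <- F$n
  blocks <- c("Q", "D", "U", "Uinv", "ExpDt", "P")
  sc <- function(b) (b - 1L) * (n + 1L) + 1L
  nrows <- n + 3L
  ncols <- sc(6L) + n - 1L
  cells <- matrix("", nrows, ncols)
  titles <- c("Q", "D", "U", "U^-1", "Exp(Dt)", "P(t)")
  for (b in seq_along(blocks)) cells[1L, sc(b)] <- titles[b]
  trow <- n + 3L
  cells[trow, 1L] <- "t"
  cells[trow, 2L] <- fmt17(t)
  taddr <- a1(trow, 2L)

  cell_at <- function(b, i, j) c(i + 1L, sc(b) + j - 1L)
  addr_at <- function(b, i, j) a1(i + 1L, sc(b) + j - 1L)

  # home addresses of every symbol
  home <- list(t = taddr)
  for (nm in names(F$base_symbols)) {
    pos <- F$base_symbols[[nm]]
    home[[nm]] <- addr_at(1L, pos[1L], pos[2L])
  }
  for (nm in names(F$Qsym$diag_defs)) {
    i <- which(vapply(seq_len(n), function(i) {
      info <- qf_atom_info(sm_entry(F$Qsym, i, i))
      info$kind %in% c("sym", "negsym") && info$name == nm
    }, TRUE))[1L]
    home[[nm]] <- addr_at(1L, i, i)
  }
  dstage <- vapply(Filter(function(iv) iv$stage == "D", F$intermediates),
                   `[[`, "", "name")
  for (k in seq_len(n)) {
    e <- F$D_entries[[k]]
    if (e$k == "sym" && e$name %in% dstage && is.null(home[[e$name]]))
      home[[e$name]] <- addr_at(2L, k, k)
  }
  set_homes <- function(M, b) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      info <- qf_atom_info(sm_entry(M, i, j))
      if (info$kind %in% c("sym", "negsym") && info$name %in% names(defs) &&
          is.null(home[[info$name]]))
        home[[info$name]] <<- addr_at(b, i, j)
    }
  }
  set_homes(F$U_entries, 3L)
  set_homes(F$Uinv_entries, 4L)
  ref <- function(nm) {
    if (is.null(home[[nm]])) stop("no home cell for symbol ", nm)
    home[[nm]]
  }
  put <- function(b, i, j, s) {
    rc <- cell_at(b, i, j)
    cells[rc[1L], rc[2L]] <<- s
  }
  fml <- function(expr) paste0("=", sx_render(expr, sym_fmt = ref,
                                              fun_names = sheet_funs))
  # an atomic entry becomes: its definition formula at its home cell, a
  # reference elsewhere, an input value for base rates, a literal number
  atom_cell <- function(info, here) {
    if (info$kind == "num") return(fmt17(info$val))
    nm <- info$name
    neg <- info$kind == "negsym"
    s <- if (nm %in% names(F$base_symbols) && identical(here, home[[nm]])) {
      fmt17(if (is.null(rate_vals)) 0 else rate_vals[[nm]])
    } else if (nm %in% names(defs) && identical(here, home[[nm]])) {
      fml(defs[[nm]])
    } else if (nm %in% names(F$Qsym$diag_defs) && identical(here, home[[nm]])) {
      paste0("=-(", paste(vapply(F$Qsym$diag_defs[[nm]], ref, ""),
                          collapse = "+"), ")")
    } else {
      paste0("=", ref(nm))
    }
    if (neg) {
      if (startsWith(s, "=")) paste0("=-(", substr(s, 2L, nchar(s)), ")")
      else paste0("=-", s)
    } else s
  }
  # Q block
  for (i in seq_len(n)) for (j in seq_len(n))
    put(1L, i, j, atom_cell(qf_atom_info(sm_entry(F$Qsym, i, j)),
                            addr_at(1L, i, j)))
  # D block (diagonal)
  for (k in seq_len(n)) for (j in seq_len(n)) {
    if (k != j) { put(2L, k, j, "0"); next }
    e <- F$D_entries[[k]]
    s <- if (sx_is_num(e)) fmt17(e$v)
    else if (e$k == "sym" && e$name %in% dstage &&
             identical(addr_at(2L, k, k), home[[e$name]])) fml(defs[[e$name]])
    else fml(e)
    put(2L, k, k, s)
  }
  # U and Uinv blocks
  for (b in c(3L, 4L)) {
    M <- if (b == 3L) F$U_entries else F$Uinv_entries
    for (i in seq_len(n)) for (j in seq_len(n))
      put(b, i, j, atom_cell(qf_atom_info(sm_entry(M, i, j)),
                             addr_at(b, i, j)))
  }
  # Exp(Dt) block
  for (k in seq_len(n)) for (j in seq_len(n)) {
    if (k != j) { put(5L, k, j, "0"); next }
    put(5L, k, k, paste0("=EXP(", addr_at(2L, k, k), "*", taddr, ")"))
  }
  # P block: row of U times Exp(Dt) times column of Uinv
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i %in% F$structure$absorbing) {
      put(6L, i, j, if (i == j) "1" else "0")
      next
    }
    terms <- character(0)
    for (k in seq_len(n)) {
      if (qf_is_zero(sm_entry(F$U_entries, i, k)) ||
          qf_is_zero(sm_entry(F$Uinv_entries, k, j))) next
      terms <- c(terms, paste0(addr_at(3L, i, k), "*", addr_at(5L, k, k),
                               "*", addr_at(4L, k, j)))
    }
    put(6L, i, j, if (length(terms)) paste0("=", paste(terms, collapse = "+"))
        else "0")
  }
  cells
}
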