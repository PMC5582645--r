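# Symbolic derivation of rate-to-probability conversion formulas.
#
# Given only the allowed-transition structure of a multistate model, this
# engine carries out the five-step derivation: (1) write the symbolic
# generator Q, (2) solve the characteristic equation for the eigenvalues,
# (3) solve (Q - lambda I)x = 0 for the eigenvectors, (4) invert the
# eigenvector matrix, (5) multiply out P(t) = U Exp(Dt) U^-1 -- introducing
# named intermediate variables after steps 2-4 so that every individual
# formula stays short enough for one spreadsheet cell.
#
# Eigenvalues are found structurally: the strongly connected components of
# the transition graph make Q block-triangular, so each size-1 block
# contributes its diagonal entry and each size-2 block a quadratic-formula
# pair.  An irreducible block of size 3 or more leaves a residual
# characteristic factor of degree >= 3, which has no usable algebraic
# solution; the engine refuses and directs the user to the numeric route.

new_symbolic_matrix <- function(n, entries, symbols, sym_pos, diag_defs,
                                states, structure = NULL, ext = list()) {
  structure(list(n = n, entries = entries, symbols = symbols,
                 sym_pos = sym_pos, diag_defs = diag_defs, states = states,
                 structure = structure, ext = ext),
            class = "symbolic_matrix")
}

sm_entry <- function(M, i, j) M$entries[[(i - 1L) * M$n + j]]

sm_render <- function(M) {
  out <- matrix("", M$n, M$n)
  for (i in seq_len(M$n)) for (j in seq_len(M$n))
    out[i, j] <- sx_render(sx_from_qfrac(sm_entry(M, i, j), M$ext))
  dimnames(out) <- list(M$states, M$states)
  out
}

#' @export
print.symbolic_matrix <- function(x, ...) {
  cat(sprintf("Symbolic matrix (%d x %d) over symbols: %s\n", x$n, x$n,
              paste(x$symbols, collapse = ", ")))
  print(sm_render(x), quote = FALSE, ...)
  for (nm in names(x$diag_defs))
    cat(sprintf("  where %s = -(%s)\n", nm,
                paste(x$diag_defs[[nm]], collapse = " + ")))
  invisible(x)
}

# letter supply for rate symbols and intermediates; e (exponential) and
# t (cycle length) are never used
make_namer <- function(reserved = character(0), primed = FALSE) {
  pool <- setdiff(letters, c("e", "t", reserved))
  idx <- 0L
  warned <- FALSE
  function() {
    idx <<- idx + 1L
    if (idx <= length(pool)) {
      if (primed) paste0(pool[[idx]], "'") else pool[[idx]]
    } else {
      if (!warned) {
        message("single-letter name supply exhausted; switching to indexed names")
        warned <<- TRUE
      }
      paste0(if (primed) "y" else "x", idx - length(pool))
    }
  }
}

#' Write down the symbolic generator matrix for a transition structure
#'
#' Step 1 of the derivation.  Allowed off-diagonal transitions get named
#' rate symbols; disallowed ones are structural zeros; the diagonal of each
#' row is minus the sum of the row's rate symbols, written as its own named
#' symbol whose definition is recorded.  When a row has exactly one exit
#' and `collapse_single_exit` is `TRUE`, the diagonal is written directly
#' as the negated exit symbol instead of introducing a diagonal symbol.
#'
#' @param structure a [model_structure()].
#' @param collapse_single_exit write `-q` instead of a named diagonal
#'   symbol for single-exit rows (default `TRUE`).
#' @param naming `"letters"` for single roman letters in row-major order
#'   (skipping `e` and `t`), or `"qij"` for subscripted names like `q12`
#'   (requires n <= 9).
#' @return a `symbolic_matrix`.
#' @examples
#' s3 <- model_structure(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
#' build_symbolic_Q(s3, naming = "qij")
#' @export
build_symbolic_Q <- function(structure, collapse_single_exit = TRUE,
                             naming = c("letters", "qij")) {
  naming <- match.arg(naming)
  n <- structure$n
  if (naming == "qij" && n > 9L)
    stop("'qij' naming needs n <= 9; use naming = \"letters\"")
  namer <- make_namer()
  entries <- rep(list(qf_const(0)), n * n)
  set <- function(i, j, v) entries[[(i - 1L) * n + j]] <<- v
  symbols <- character(0)
  sym_pos <- list()
  diag_defs <- list()
  exits_of <- function(i) sort(structure$allowed[structure$allowed[, 1L] == i, 2L])
  for (i in seq_len(n)) {
    exits <- exits_of(i)
    if (length(exits) == 0L) next
    if (length(exits) == 1L && collapse_single_exit) {
      nm <- if (naming == "qij") paste0("q", i, exits) else namer()
      symbols <- c(symbols, nm)
      sym_pos[[nm]] <- c(i, exits)
      set(i, exits, qf_var(nm))
      set(i, i, qf_neg(qf_var(nm)))
      next
    }
    row_syms <- character(0)
    dnm <- NULL
    for (j in seq_len(n)) {
      if (j == i) {
        dnm <- if (naming == "qij") paste0("q", i, i) else namer()
        set(i, i, qf_var(dnm))
      } else if (j %in% exits) {
        nm <- if (naming == "qij") paste0("q", i, j) else namer()
        symbols <- c(symbols, nm)
        sym_pos[[nm]] <- c(i, j)
        row_syms <- c(row_syms, nm)
        set(i, j, qf_var(nm))
      }
    }
    diag_defs[[dnm]] <- row_syms
    symbols <- c(symbols, dnm)
  }
  new_symbolic_matrix(n, entries, symbols, sym_pos, diag_defs,
                      structure$states, structure)
}

# strongly connected components (Kosaraju); returns component id per state
scc_components <- function(adj) {
  n <- nrow(adj)
  visited <- logical(n); ord <- integer(0)
  dfs1 <- function(v) {
    visited[v] <<- TRUE
    for (w in which(adj[v, ])) if (!visited[w]) dfs1(w)
    ord <<- c(ord, v)
  }
  for (v in seq_len(n)) if (!visited[v]) dfs1(v)
  comp <- integer(n); cur <- 0L; seen <- logical(n)
  dfs2 <- function(v) {
    seen[v] <<- TRUE; comp[v] <<- cur
    for (w in which(adj[, v])) if (!seen[w]) dfs2(w)
  }
  for (v in rev(ord)) if (!seen[v]) { cur <- cur + 1L; dfs2(v) }
  comp
}

#' Solve the characteristic equation of a symbolic generator
#'
#' Step 2.  The strongly connected components of the transition graph give
#' a block-triangular form of `Q`, so `det(Q - lambda I)` factors over the
#' diagonal blocks: size-1 blocks contribute their diagonal entry as a
#' root, and size-2 blocks contribute the quadratic-formula pair
#' `(tr +/- sqrt(tr^2 - 4 det)) / 2`.  An irreducible block of size >= 3
#' leaves a residual polynomial of degree >= 3 and raises
#' `rtp_unsolvable_characteristic`: the algebraic route is impossible and
#' numeric conversion must be used.
#'
#' Roots are ordered with nonzero eigenvalues first (by the lowest state
#' index of the contributing block, `+sqrt` before `-sqrt`) and zero
#' eigenvalues last.
#'
#' @param Qsym a `symbolic_matrix` from [build_symbolic_Q()].
#' @return object of class `char_roots`: `roots` (list of exact
#'   expressions), `ext` (square-root extension definitions), `state`
#'   (contributing state per root).
#' @export
characteristic_roots <- function(Qsym) {
  n <- Qsym$n
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && !qf_is_zero(sm_entry(Qsym, i, j))) adj[i, j] <- TRUE
  comp <- scc_components(adj)
  ext <- Qsym$ext
  roots <- list()
  state <- integer(0)
  nsqrt <- 0L
  comp_ids <- unique(comp)
  comp_min <- vapply(comp_ids, function(cid) min(which(comp == cid)), 1L)
  for (cid in comp_ids[order(comp_min)]) {
    m <- which(comp == cid)
    if (length(m) == 1L) {
      roots <- c(roots, list(sm_entry(Qsym, m, m)))
      state <- c(state, m)
    } else if (length(m) == 2L) {
      i <- m[1L]; j <- m[2L]
      e_ii <- sm_entry(Qsym, i, i)$num; e_jj <- sm_entry(Qsym, j, j)$num
      e_ij <- sm_entry(Qsym, i, j)$num; e_ji <- sm_entry(Qsym, j, i)$num
      tr <- qp_add(e_ii, e_jj)
      det2 <- qp_sub(qp_mul(e_ii, e_jj), qp_mul(e_ij, e_ji))
      disc <- qp_sub(qp_pow(tr, 2), qp_scale(det2, 4))
      nsqrt <- nsqrt + 1L
      sname <- paste0(".sqrt", nsqrt)
      ext[[sname]] <- disc
      s <- qp_var(sname)
      roots <- c(roots,
                 list(qf_new(qp_add(tr, s), qp_const(2), ext),
                      qf_new(qp_sub(tr, s), qp_const(2), ext)))
      state <- c(state, i, i)
    } else {
      rtp_error("rtp_unsolvable_characteristic",
                sprintf(paste0("states {%s} are mutually reachable: the ",
                               "residual characteristic factor has degree %d ",
                               ">= 3, so it is impossible to find an algebraic ",
                               "solution; use the numeric conversion instead"),
                        paste(m, collapse = ","), length(m)))
    }
  }
  is_zero <- vapply(roots, qf_is_zero, TRUE)
  ord <- c(which(!is_zero)[order(state[!is_zero])], which(is_zero))
  structure(list(roots = roots[ord], ext = ext, state = state[ord],
                 n = n), class = "char_roots")
}

#' @export
print.char_roots <- function(x, ...) {
  cat("Eigenvalues of the symbolic generator:\n")
  for (r in x$roots)
    cat("  ", sx_render(sx_from_qfrac(r, x$ext)), "\n", sep = "")
  invisible(x)
}

# nullspace basis of a square symbolic matrix, by Gaussian elimination over
# the rational-function field (pivot = fewest-term nonzero candidate)
qf_nullspace <- function(E, n, ext) {
  R <- E
  get <- function(i, j) R[[(i - 1L) * n + j]]
  set <- function(i, j, v) R[[(i - 1L) * n + j]] <<- v
  row_used <- logical(n)
  pivots <- list()
  for (col in seq_len(n)) {
    cand <- which(!row_used &
                  !vapply(seq_len(n), function(r) qf_is_zero(get(r, col)), TRUE))
    if (length(cand) == 0L) next
    size <- vapply(cand, function(r) {
      e <- get(r, col); length(e$num) + length(e$den)
    }, 1)
    prow <- cand[[which.min(size)]]
    piv <- get(prow, col)
    for (j in seq_len(n)) set(prow, j, qf_div(get(prow, j), piv, ext))
    for (r in seq_len(n)) {
      if (r == prow) next
      fac <- get(r, col)
      if (qf_is_zero(fac)) next
      for (j in seq_len(n))
        set(r, j, qf_sub(get(r, j), qf_mul(fac, get(prow, j), ext), ext))
    }
    row_used[prow] <- TRUE
    pivots <- c(pivots, list(c(prow, col)))
  }
  pcols <- vapply(pivots, `[[`, 1L, 2L)
  free <- setdiff(seq_len(n), pcols)
  lapply(free, function(f) {
    x <- rep(list(qf_const(0)), n)
    x[[f]] <- qf_const(1)
    for (p in pivots) x[[p[2L]]] <- qf_neg(get(p[1L], f))
    x
  })
}

# scale a vector of rational functions to coprime polynomials with a
# positive-leading first entry (deterministic eigenvector normalization)
clear_denominators <- function(vec, ext) {
  nz <- which(!vapply(vec, qf_is_zero, TRUE))
  if (length(nz) == 0L) return(rep(list(qp_zero()), length(vec)))
  L <- qp_const(1)
  for (i in nz) L <- qp_lcm(L, vec[[i]]$den)
  nums <- lapply(seq_along(vec), function(i) {
    if (qf_is_zero(vec[[i]])) return(qp_zero())
    qp_mul(vec[[i]]$num, qp_divexact(L, vec[[i]]$den), ext)
  })
  parts <- list()
  for (i in nz) {
    p <- nums[[i]]
    for (s in names(ext)) {
      sp <- qp_split_ext(p, s)
      parts <- c(parts, list(sp[[2L]]))
      p <- sp[[1L]]
    }
    parts <- c(parts, list(p))
  }
  g <- qp_zero()
  for (p in parts) g <- qp_gcd(g, p)
  if (!qp_is_zero(g) && !(qp_is_const(g) && qp_const_val(g) == 1))
    nums <- lapply(nums, function(p) qp_divexact_ext(p, g, ext))
  u <- qp_lead_sign(nums[[nz[[1L]]]])
  lapply(nums, function(p) qp_scale(p, u))
}

#' Derive the symbolic eigenvector matrix
#'
#' Step 3.  For each distinct eigenvalue the nullspace of `(Q - lambda I)`
#' is computed by symbolic Gaussian elimination; a repeated eigenvalue
#' (e.g. the zero eigenvalue of a model with several absorbing states) must
#' yield a nullspace of matching dimension, otherwise the symbolic
#' generator is defective and `rtp_symbolic_rank` is raised.  Each column
#' is rescaled deterministically: denominators are cleared by their least
#' common multiple, the entries divided by their common polynomial divisor,
#' and the sign fixed so the first nonzero entry has a positive leading
#' coefficient.
#'
#' @param Qsym a `symbolic_matrix`.
#' @param roots a `char_roots` object from [characteristic_roots()].
#' @return a `symbolic_matrix` whose columns are eigenvectors, column `i`
#'   matching `roots$roots[[i]]`.
#' @export
symbolic_eigenvectors <- function(Qsym, roots) {
  n <- Qsym$n
  ext <- roots$ext
  k <- length(roots$roots)
  stopifnot(k == n)
  # group equal roots
  gid <- integer(k)
  for (i in seq_len(k)) {
    gid[i] <- i
    for (j in seq_len(i - 1L)) {
      if (qf_equal(roots$roots[[i]], roots$roots[[j]], ext)) {
        gid[i] <- gid[j]; break
      }
    }
  }
  cols <- vector("list", k)
  for (g in unique(gid)) {
    members <- which(gid == g)
    lam <- roots$roots[[g]]
    E <- Qsym$entries
    for (i in seq_len(n)) {
      idx <- (i - 1L) * n + i
      E[[idx]] <- qf_sub(E[[idx]], lam, ext)
    }
    basis <- qf_nullspace(E, n, ext)
    if (length(basis) != length(members))
      rtp_error("rtp_symbolic_rank",
                sprintf(paste0("eigenvalue %s has multiplicity %d but a ",
                               "nullspace of dimension %d: the symbolic ",
                               "generator is defective"),
                        sx_render(sx_from_qfrac(lam, ext)),
                        length(members), length(basis)))
    for (m in seq_along(members)) {
      v <- clear_denominators(basis[[m]], ext)
      cols[[members[[m]]]] <- lapply(v, qf_from_poly)
    }
  }
  entries <- rep(list(qf_const(0)), n * n)
  for (j in seq_len(k)) for (i in seq_len(n))
    entries[[(i - 1L) * n + j]] <- cols[[j]][[i]]
  new_symbolic_matrix(n, entries, Qsym$symbols, Qsym$sym_pos, Qsym$diag_defs,
                      Qsym$states, Qsym$structure, ext)
}

# determinant by cofactor expansion along the column with most zeros
qf_det <- function(M, rows, cols, ext) {
  m <- length(rows)
  if (m == 1L) return(M[[rows[1L]]][[cols[1L]]])
  nz <- vapply(cols, function(j)
    sum(!vapply(rows, function(i) qf_is_zero(M[[i]][[j]]), TRUE)), 1L)
  jbest <- which.min(nz)
  j <- cols[jbest]
  tot <- qf_const(0)
  for (ii in seq_along(rows)) {
    e <- M[[rows[ii]]][[j]]
    if (qf_is_zero(e)) next
    minor <- qf_det(M, rows[-ii], cols[-jbest], ext)
    term <- qf_mul(e, minor, ext)
    if ((ii + jbest) %% 2L == 1L) term <- qf_neg(term)
    tot <- qf_add(tot, term, ext)
  }
  tot
}

#' Invert a symbolic matrix via the adjugate
#'
#' Step 4.  `U^-1 = adj(U) / det(U)` using the matrix of cofactors, with
#' every entry simplified by exact polynomial cancellation.  Intended to be
#' applied to the intermediated `U`, whose entries are single symbols, so
#' that the inverse entries stay compact.  Raises `rtp_singular_symbolic`
#' when the determinant simplifies to zero.
#'
#' @param U a `symbolic_matrix`.
#' @return a `symbolic_matrix` holding `U^-1`.
#' @export
symbolic_inverse <- function(U) {
  n <- U$n
  ext <- U$ext
  M <- lapply(seq_len(n), function(i)
    lapply(seq_len(n), function(j) sm_entry(U, i, j)))
  det <- qf_det(M, seq_len(n), seq_len(n), ext)
  if (qf_is_zero(det))
    rtp_error("rtp_singular_symbolic",
              "the symbolic determinant simplifies to zero; U is singular")
  entries <- rep(list(qf_const(0)), n * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cof <- qf_det(M, setdiff(seq_len(n), j), setdiff(seq_len(n), i), ext)
    if ((i + j) %% 2L == 1L) cof <- qf_neg(cof)
    entries[[(i - 1L) * n + j]] <- qf_div(cof, det, ext)
  }
  new_symbolic_matrix(n, entries, U$symbols, U$sym_pos, U$diag_defs,
                      U$states, U$structure, ext)
}

qf_is_atom <- function(f) {
  if (qf_is_const(f)) return(TRUE)
  if (!(qp_is_const(f$den) && qp_const_val(f$den) == 1)) return(FALSE)
  if (length(f$num) != 1L) return(FALSE)
  if (abs(f$num[[1L]]) != 1) return(FALSE)
  ex <- mono_parse(names(f$num)[1L])
  length(ex) == 1L && ex[[1L]] == 1L
}

qf_key <- function(f) {
  paste(paste(names(f$num), unclass(f$num), collapse = ";"), "/",
        paste(names(f$den), unclass(f$den), collapse = ";"))
}

#' Replace composite matrix entries by named intermediate variables
#'
#' Every entry that is neither a fixed number nor a (possibly negated)
#' single symbol is replaced by a fresh single-letter name, scanning in
#' row-major order; identical entries share one name.  Unprimed letters are
#' used for the eigenvalue/eigenvector stages and primed letters (`a'`,
#' `b'`, ...) for the inverse stage; `e` and `t` are never used, and when
#' the letter supply runs out, indexed names (`x1`, `x2`, ...) are used
#' instead.
#'
#' @param M a `symbolic_matrix` (or list of entries for a diagonal stage).
#' @param namer a name generator from an earlier stage, or `NULL` to start
#'   a fresh one with `reserved` names skipped.
#' @param reserved names that must not be generated (the base rate
#'   symbols).
#' @param primed use primed letters (inverse stage).
#' @return list with `matrix` (entries rewritten to atoms),
#'   `intermediates` (list of `(name, expr)` definitions in order) and
#'   `namer` (to continue the sequence in a later stage).
#' @export
introduce_intermediates <- function(M, namer = NULL,
                                    reserved = character(0), primed = FALSE) {
  if (is.null(namer)) namer <- make_namer(reserved, primed = primed)
  seen <- new.env(parent = emptyenv())
  defs <- list()
  rewrite <- function(e) {
    if (qf_is_atom(e)) return(e)
    key <- qf_key(e)
    nm <- seen[[key]]
    if (is.null(nm)) {
      nm <- namer()
      seen[[key]] <- nm
      defs[[length(defs) + 1L]] <<- list(name = nm,
                                         expr = sx_from_qfrac(e, M$ext),
                                         frac = e)
    }
    qf_var(nm)
  }
  n <- M$n
  entries <- M$entries
  for (i in seq_len(n)) for (j in seq_len(n)) {
    idx <- (i - 1L) * n + j
    entries[[idx]] <- rewrite(entries[[idx]])
  }
  out <- M
  out$entries <- entries
  list(matrix = out, intermediates = defs, namer = namer)
}

# same rewriting for the diagonal (eigenvalue) stage, which is a list of
# root expressions rather than a matrix
intermediates_for_roots <- function(roots, namer) {
  seen <- new.env(parent = emptyenv())
  defs <- list()
  atoms <- lapply(roots$roots, function(r) {
    if (qf_is_atom(r)) return(r)
    key <- qf_key(r)
    nm <- seen[[key]]
    if (is.null(nm)) {
      nm <- namer()
      seen[[key]] <- nm
      defs[[length(defs) + 1L]] <<- list(name = nm,
                                         expr = sx_from_qfrac(r, roots$ext),
                                         frac = r)
    }
    qf_var(nm)
  })
  list(atoms = atoms, intermediates = defs, namer = namer)
}

#' Assemble the transition-probability formulas
#'
#' Step 5.  `p[i,j](t) = sum_k U[i,k] e^(lambda_k t) U^-1[k,j]`, with zero
#' terms dropped and `e^(0 t)` simplified away.  Rows of absorbing states
#' are identity rows (`p[i,i] = 1`).  With `row_sum_replace` one entry per
#' non-absorbing row (the one with the most terms) is replaced by one minus
#' the sum of the others, which shortens that formula at the cost of making
#' it depend on the rest of its row.
#'
#' @param D_atoms list of eigenvalue atoms (after intermediation).
#' @param U,Uinv intermediated `symbolic_matrix` objects.
#' @param absorbing integer vector of absorbing states.
#' @param row_sum_replace logical, default `FALSE`.
#' @return n x n list-matrix of expression trees for the entries of `P(t)`.
#' @export
assemble_probabilities <- function(D_atoms, U, Uinv, absorbing = integer(0),
                                   row_sum_replace = FALSE) {
  n <- U$n
  P <- matrix(list(), n, n)
  tsym <- sx_sym("t")
  for (i in seq_len(n)) {
    if (i %in% absorbing) {
      for (j in seq_len(n)) P[[i, j]] <- sx_num(as.numeric(i == j))
      next
    }
    for (j in seq_len(n)) {
      terms <- list()
      for (k in seq_len(n)) {
        u <- sm_entry(U, i, k)
        v <- sm_entry(Uinv, k, j)
        if (qf_is_zero(u) || qf_is_zero(v)) next
        lam <- D_atoms[[k]]
        factors <- list(sx_from_qfrac(u, U$ext))
        if (!qf_is_zero(lam))
          factors <- c(factors,
                       list(sx_exp(sx_mul(list(sx_from_qfrac(lam, U$ext),
                                               tsym)))))
        factors <- c(factors, list(sx_from_qfrac(v, U$ext)))
        terms <- c(terms, list(sx_mul(factors)))
      }
      P[[i, j]] <- sx_add(terms)
    }
    if (row_sum_replace) {
      sizes <- vapply(seq_len(n), function(j) sx_nterms(P[[i, j]]), 1L)
      jrep <- max(which(sizes == max(sizes)))
      others <- setdiff(seq_len(n), jrep)
      P[[i, jrep]] <- sx_add(c(list(sx_num(1)),
                               lapply(others, function(j) sx_neg(P[[i, j]]))))
    }
  }
  P
}

#' Derive the complete conversion formula set for a transition structure
#'
#' Runs the whole five-step derivation and returns a `formula_set` holding
#' the eigenvalue expressions, the intermediated `U` and `U^-1`, the
#' per-entry formulas for `P(t)`, and all intermediate-variable definitions
#' in dependency order (diagonal rate definitions first, then the
#' eigenvalue, eigenvector and inverse stages).
#'
#' @inheritParams build_symbolic_Q
#' @param row_sum_replace see [assemble_probabilities()].
#' @return object of class `formula_set`.
#' @examples
#' s3 <- model_structure(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
#' fs <- derive_formulas(s3, naming = "qij")
#' fs
#' @export
derive_formulas <- function(structure, naming = c("letters", "qij"),
                            collapse_single_exit = TRUE,
                            row_sum_replace = FALSE) {
  naming <- match.arg(naming)
  Qsym <- build_symbolic_Q(structure, collapse_single_exit, naming)
  roots <- characteristic_roots(Qsym)
  Uraw <- symbolic_eigenvectors(Qsym, roots)
  namer <- make_namer(Qsym$symbols)
  dstage <- intermediates_for_roots(roots, namer)
  ustage <- introduce_intermediates(Uraw, dstage$namer)
  Uinv_raw <- symbolic_inverse(ustage$matrix)
  vstage <- introduce_intermediates(Uinv_raw, primed = TRUE)
  P <- assemble_probabilities(dstage$atoms, ustage$matrix, vstage$matrix,
                              absorbing = structure$absorbing,
                              row_sum_replace = row_sum_replace)
  inter <- list()
  for (nm in names(Qsym$diag_defs))
    inter[[length(inter) + 1L]] <- list(
      name = nm,
      expr = sx_neg(sx_add(lapply(Qsym$diag_defs[[nm]], sx_sym))),
      stage = "Q")
  for (d in dstage$intermediates)
    inter[[length(inter) + 1L]] <- list(name = d$name, expr = d$expr,
                                        stage = "D")
  for (d in ustage$intermediates)
    inter[[length(inter) + 1L]] <- list(name = d$name, expr = d$expr,
                                        stage = "U")
  for (d in vstage$intermediates)
    inter[[length(inter) + 1L]] <- list(name = d$name, expr = d$expr,
                                        stage = "Uinv")
  structure(list(
    n = structure$n,
    states = structure$states,
    structure = structure,
    Qsym = Qsym,
    D_entries = lapply(dstage$atoms, function(a) sx_from_qfrac(a, roots$ext)),
    D_raw = roots,
    U_entries = ustage$matrix,
    Uinv_entries = vstage$matrix,
    P_entries = P,
    intermediates = inter,
    base_symbols = Qsym$sym_pos,
    naming_scheme = naming,
    row_sum_replace = row_sum_replace
  ), class = "formula_set")
}

#' @export
print.formula_set <- function(x, ...) {
  cat(sprintf("Conversion formula set: %d states, %d intermediates\n",
              x$n, length(x$intermediates)))
  cat("Eigenvalues:\n")
  for (d in x$D_entries) cat("  ", sx_render(d), "\n", sep = "")
  if (length(x$intermediates)) {
    cat("Intermediate variables:\n")
    for (iv in x$intermediates)
      cat(sprintf("  %-4s = %s\n", iv$name, sx_render(iv$expr)))
  }
  cat("Transition probabilities:\n")
  for (i in seq_len(x$n)) for (j in seq_len(x$n)) {
    f <- x$P_entries[[i, j]]
    if (sx_is_num(f) && i != j) next
    cat(sprintf("  p%d%d(t) = %s\n", i, j, sx_render(f)))
  }
  invisible(x)
}

#' Evaluate a derived formula set at numeric rates
#'
#' Binds the base rate symbols, evaluates every intermediate variable in
#' dependency order and then the probability formulas.  Square roots of
#' negative discriminants are evaluated in complex arithmetic and the real
#' part returned (after checking the imaginary residual).  Raises
#' `rtp_unbound_symbol` if a rate is missing and
#' `rtp_degenerate_evaluation` if a division by zero occurs, which happens
#' exactly when two eigenvalues coincide at the supplied rates.
#'
#' @param F a `formula_set`.
#' @param rates named numeric vector keyed by base rate symbol, or a
#'   [rate_matrix()] whose entries are read off at the structure's
#'   transitions.
#' @param t cycle length, positive.
#' @return a [prob_matrix()].
#' @examples
#' s3 <- model_structure(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
#' fs <- derive_formulas(s3, naming = "qij")
#' evaluate_formula_set(fs, c(q12 = 1, q13 = 1, q23 = 1), t = 1)
#' @export
evaluate_formula_set <- function(F, rates, t) {
  stopifnot(inherits(F, "formula_set"), t > 0)
  env <- new.env(parent = emptyenv())
  if (is_rate_matrix(rates)) {
    for (nm in names(F$base_symbols)) {
      pos <- F$base_symbols[[nm]]
      assign(nm, rates$q[pos[1L], pos[2L]], envir = env)
    }
  } else {
    stopifnot(!is.null(names(rates)))
    for (nm in names(rates)) assign(nm, rates[[nm]], envir = env)
  }
  assign("t", t, envir = env)
  for (iv in F$intermediates)
    assign(iv$name, sx_eval(iv$expr, env), envir = env)
  n <- F$n
  P <- matrix(0, n, n)
  imag_res <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- sx_eval(F$P_entries[[i, j]], env)
    if (is.complex(v)) {
      imag_res <- max(imag_res, abs(Im(v)))
      v <- Re(v)
    }
    P[i, j] <- v
  }
  if (imag_res > 1e-10 * n)
    warning(sprintf("imaginary residual %.3g in evaluated probabilities",
                    imag_res))
  prob_matrix(P, t, F$states)
}
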