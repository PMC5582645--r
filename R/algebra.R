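# Exact multivariate polynomial / rational-function arithmetic.
#
# This is the minimal computer-algebra layer behind the symbolic derivation
# engine.  Polynomials are stored as named numeric vectors: names are
# monomial keys ("" for the constant term, otherwise "a^1|b^2" with variable
# names radix-sorted), values are coefficients.  All arithmetic arising in
# the derivations keeps coefficients as integers or dyadic rationals, which
# doubles represent exactly; exact zero tests are therefore plain `== 0`.
#
# Square roots entering through the quadratic formula are handled as
# extension symbols s with a defining polynomial s^2 = disc; `ext` is a
# named list mapping extension-symbol names to their (extension-free)
# discriminant polynomials, and every product is reduced so extension
# exponents stay <= 1.

MONO_SEP <- "|"
MONO_ONE <- "1"  # constant-term key ("" cannot be used as an R name)

qp_norm <- function(v) {
  v <- v[v != 0]
  if (length(v) == 0L) v <- stats::setNames(numeric(0), character(0))
  v <- v[order(names(v), method = "radix")]
  class(v) <- "qpoly"
  v
}

qp_zero <- function() qp_norm(stats::setNames(numeric(0), character(0)))

qp_const <- function(x) {
  if (x == 0) return(qp_zero())
  qp_norm(stats::setNames(x, MONO_ONE))
}

qp_var <- function(name) {
  stopifnot(!grepl("[|^]", name))
  qp_norm(stats::setNames(1, paste0(name, "^1")))
}

qp_is_zero <- function(p) length(p) == 0L

qp_is_const <- function(p) {
  length(p) == 0L || (length(p) == 1L && names(p) == MONO_ONE)
}

qp_const_val <- function(p) {
  if (qp_is_zero(p)) 0 else unname(p[[MONO_ONE]])
}

mono_parse <- function(key) {
  if (key == MONO_ONE) return(stats::setNames(integer(0), character(0)))
  parts <- strsplit(key, MONO_SEP, fixed = TRUE)[[1L]]
  bits <- strsplit(parts, "^", fixed = TRUE)
  stats::setNames(vapply(bits, function(b) as.integer(b[[2L]]), 1L),
                  vapply(bits, `[[`, "", 1L))
}

mono_key <- function(ex) {
  ex <- ex[ex != 0L]
  if (length(ex) == 0L) return(MONO_ONE)
  ex <- ex[order(names(ex), method = "radix")]
  paste(paste0(names(ex), "^", ex), collapse = MONO_SEP)
}

mono_mul <- function(k1, k2) {
  if (k1 == MONO_ONE) return(k2)
  if (k2 == MONO_ONE) return(k1)
  e1 <- mono_parse(k1); e2 <- mono_parse(k2)
  all_v <- union(names(e1), names(e2))
  ex <- stats::setNames(integer(length(all_v)), all_v)
  ex[names(e1)] <- e1
  ex[names(e2)] <- ex[names(e2)] + e2
  mono_key(ex)
}

qp_add <- function(p, q) {
  if (qp_is_zero(p)) return(q)
  if (qp_is_zero(q)) return(p)
  v <- c(unclass(p), unclass(q))
  s <- vapply(split(unname(v), names(v)), sum, 0)
  qp_norm(s)
}

qp_neg <- function(p) qp_norm(-unclass(p))

qp_sub <- function(p, q) qp_add(p, qp_neg(q))

qp_scale <- function(p, s) {
  if (s == 0) return(qp_zero())
  qp_norm(unclass(p) * s)
}

# Reduce extension-symbol exponents >= 2 via s^2 -> disc.
qp_reduce <- function(p, ext) {
  if (length(ext) == 0L || qp_is_zero(p)) return(p)
  repeat {
    changed <- FALSE
    out <- qp_zero()
    for (i in seq_along(p)) {
      key <- names(p)[i]
      ex <- mono_parse(key)
      hit <- intersect(names(ex)[ex >= 2L], names(ext))
      if (length(hit) == 0L) {
        out <- qp_add(out, qp_norm(stats::setNames(p[[i]], key)))
      } else {
        changed <- TRUE
        s <- hit[[1L]]
        k <- ex[[s]] %/% 2L
        ex[[s]] <- ex[[s]] %% 2L
        term <- qp_norm(stats::setNames(p[[i]], mono_key(ex)))
        for (r in seq_len(k)) term <- qp_mul(term, ext[[s]], ext = NULL)
        out <- qp_add(out, term)
      }
    }
    p <- out
    if (!changed) return(p)
  }
}

qp_mul <- function(p, q, ext = NULL) {
  if (qp_is_zero(p) || qp_is_zero(q)) return(qp_zero())
  acc <- new.env(parent = emptyenv())
  np <- names(p); nq <- names(q)
  for (i in seq_along(p)) {
    ci <- p[[i]]
    for (j in seq_along(q)) {
      key <- mono_mul(np[i], nq[j])
      prev <- if (is.null(acc[[key]])) 0 else acc[[key]]
      acc[[key]] <- prev + ci * q[[j]]
    }
  }
  keys <- ls(acc, all.names = TRUE)
  out <- qp_norm(stats::setNames(
    vapply(keys, function(k) acc[[k]], 0), keys))
  if (!is.null(ext)) out <- qp_reduce(out, ext)
  out
}

qp_pow <- function(p, n, ext = NULL) {
  out <- qp_const(1)
  for (i in seq_len(n)) out <- qp_mul(out, p, ext)
  out
}

qp_equal <- function(p, q) qp_is_zero(qp_sub(p, q))

qp_vars <- function(p) {
  if (qp_is_zero(p)) return(character(0))
  vs <- unique(unlist(lapply(names(p), function(k) names(mono_parse(k)))))
  sort(vs %||% character(0), method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer content: largest positive rational c such that p / c has integer,
# setwise-coprime coefficients.  Coefficients are dyadic, so first scale by a
# power of two to reach integers.
num_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { r <- a %% b; a <- b; b <- r }
  a
}

qp_icontent <- function(p) {
  if (qp_is_zero(p)) return(1)
  co <- unname(unclass(p))
  pow2 <- 1
  it <- 0L
  while (any(co %% 1 != 0)) {
    co <- co * 2; pow2 <- pow2 * 2
    it <- it + 1L
    if (it > 80L) stop("non-dyadic coefficient encountered")
  }
  g <- 0
  for (x in co) g <- num_gcd(g, x)
  g / pow2
}

qp_lead_sign <- function(p) {
  if (qp_is_zero(p)) return(1)
  # leading term: first key in radix order (terms are stored sorted)
  if (p[[1L]] >= 0) 1 else -1
}

# primitive part with positive leading coefficient; returns poly
qp_primitive <- function(p) {
  if (qp_is_zero(p)) return(p)
  qp_scale(p, qp_lead_sign(p) / qp_icontent(p))
}

# --- univariate (in x) views with polynomial coefficients -------------------

qp_deg_in <- function(p, x) {
  if (qp_is_zero(p)) return(-1L)
  d <- 0L
  for (k in names(p)) {
    ex <- mono_parse(k)
    if (x %in% names(ex)) d <- max(d, ex[[x]])
  }
  d
}

# list of qpoly coefficients, index = degree + 1
qp_coeflist <- function(p, x) {
  d <- qp_deg_in(p, x)
  if (d < 0L) return(list())
  out <- rep(list(qp_zero()), d + 1L)
  for (i in seq_along(p)) {
    ex <- mono_parse(names(p)[i])
    dx <- if (x %in% names(ex)) ex[[x]] else 0L
    ex <- ex[names(ex) != x]
    out[[dx + 1L]] <- qp_add(out[[dx + 1L]],
                             qp_norm(stats::setNames(p[[i]], mono_key(ex))))
  }
  out
}

qp_from_coeflist <- function(cl, x) {
  out <- qp_zero()
  xv <- qp_var(x)
  for (d in seq_along(cl)) {
    if (qp_is_zero(cl[[d]])) next
    out <- qp_add(out, qp_mul(cl[[d]], qp_pow(xv, d - 1L)))
  }
  out
}

up_deg <- function(cl) length(cl) - 1L

up_trim <- function(cl) {
  while (length(cl) > 0L && qp_is_zero(cl[[length(cl)]]))
    cl[[length(cl)]] <- NULL
  cl
}

# pseudo-remainder of A by B (coefficient lists in the same main variable)
up_prem <- function(A, B) {
  A <- up_trim(A); B <- up_trim(B)
  dB <- up_deg(B)
  stopifnot(dB >= 0L)
  lcB <- B[[dB + 1L]]
  R <- A
  guard <- 0L
  while (up_deg(R) >= dB && length(R) > 0L) {
    guard <- guard + 1L
    if (guard > 200L) stop("pseudo-division failed to terminate")
    dR <- up_deg(R)
    lcR <- R[[dR + 1L]]
    newR <- rep(list(qp_zero()), dR)
    for (d in seq_len(dR) - 1L) {
      term <- qp_mul(lcB, R[[d + 1L]])
      shift <- d - (dR - dB)
      if (shift >= 0L && shift <= dB)
        term <- qp_sub(term, qp_mul(lcR, B[[shift + 1L]]))
      newR[[d + 1L]] <- term
    }
    R <- up_trim(newR)
  }
  R
}

up_content <- function(cl) {
  g <- qp_zero()
  for (co in cl) g <- qp_gcd(g, co)
  g
}

# --- multivariate GCD (primitive PRS); inputs must be extension-free --------

qp_gcd <- function(A, B) {
  if (qp_is_zero(A)) return(qp_primitive_with_content(B))
  if (qp_is_zero(B)) return(qp_primitive_with_content(A))
  if (qp_is_const(A) || qp_is_const(B))
    return(qp_const(num_gcd(qp_icontent(A), qp_icontent(B))))
  vars <- union(qp_vars(A), qp_vars(B))
  x <- sort(vars, method = "radix")[[1L]]
  clA <- qp_coeflist(A, x)
  clB <- qp_coeflist(B, x)
  contA <- up_content(clA)
  contB <- up_content(clB)
  contG <- qp_gcd(contA, contB)
  if (qp_deg_in(A, x) == 0L || qp_deg_in(B, x) == 0L) {
    # x absent from one argument: gcd cannot involve x
    return(contG)
  }
  pA <- lapply(clA, function(co) qp_divexact(co, contA))
  pB <- lapply(clB, function(co) qp_divexact(co, contB))
  if (up_deg(pA) < up_deg(pB)) { tmp <- pA; pA <- pB; pB <- tmp }
  guard <- 0L
  while (TRUE) {
    guard <- guard + 1L
    if (guard > 100L) stop("gcd iteration failed to terminate")
    R <- up_prem(pA, pB)
    if (length(R) == 0L) break
    contR <- up_content(R)
    R <- lapply(R, function(co) qp_divexact(co, contR))
    pA <- pB
    pB <- R
  }
  g <- qp_from_coeflist(pB, x)
  g <- qp_scale(g, qp_lead_sign(g) / qp_icontent(g))
  qp_mul(contG, g)
}

qp_primitive_with_content <- function(p) {
  if (qp_is_zero(p)) return(p)
  qp_scale(p, qp_lead_sign(p))
}

# exact division A / B; stops if not exact
qp_divexact <- function(A, B) {
  if (qp_is_zero(A)) return(qp_zero())
  stopifnot(!qp_is_zero(B))
  if (qp_is_const(B)) return(qp_scale(A, 1 / qp_const_val(B)))
  x <- sort(qp_vars(B), method = "radix")[[1L]]
  clA <- qp_coeflist(A, x)
  clB <- up_trim(qp_coeflist(B, x))
  dB <- up_deg(clB)
  lcB <- clB[[dB + 1L]]
  Q <- list()
  R <- clA
  guard <- 0L
  while (up_deg(up_trim(R)) >= dB) {
    guard <- guard + 1L
    if (guard > 500L) stop("exact division failed to terminate")
    R <- up_trim(R)
    dR <- up_deg(R)
    qc <- qp_divexact(R[[dR + 1L]], lcB)
    Q[[dR - dB + 1L]] <- qc
    for (d in 0:dB) {
      idx <- dR - dB + d + 1L
      R[[idx]] <- qp_sub(R[[idx]], qp_mul(qc, clB[[d + 1L]]))
    }
  }
  R <- up_trim(R)
  if (length(R) > 0L) stop("internal error: division not exact")
  for (i in seq_along(Q)) if (is.null(Q[[i]])) Q[[i]] <- qp_zero()
  qp_from_coeflist(Q, x)
}

qp_lcm <- function(A, B) {
  if (qp_is_zero(A) || qp_is_zero(B)) return(qp_zero())
  qp_divexact(qp_mul(A, B), qp_gcd(A, B))
}

qp_eval <- function(p, env) {
  if (qp_is_zero(p)) return(0)
  tot <- 0
  for (i in seq_along(p)) {
    ex <- mono_parse(names(p)[i])
    v <- p[[i]]
    for (nm in names(ex)) v <- v * env[[nm]]^ex[[nm]]
    tot <- tot + v
  }
  tot
}

# --- rational functions -----------------------------------------------------

# split p into (s-free part, coefficient of s) for extension symbol s
qp_split_ext <- function(p, s) {
  p0 <- qp_zero(); p1 <- qp_zero()
  for (i in seq_along(p)) {
    ex <- mono_parse(names(p)[i])
    if (s %in% names(ex)) {
      ex <- ex[names(ex) != s]
      p1 <- qp_add(p1, qp_norm(stats::setNames(p[[i]], mono_key(ex))))
    } else {
      p0 <- qp_add(p0, qp_norm(stats::setNames(p[[i]], names(p)[i])))
    }
  }
  list(p0, p1)
}

qf_new <- function(num, den, ext = NULL) {
  stopifnot(!qp_is_zero(den))
  if (qp_is_zero(num)) return(structure(list(num = qp_zero(), den = qp_const(1)),
                                        class = "qfrac"))
  # rationalize: clear extension symbols from the denominator
  if (!is.null(ext) && length(ext) > 0L) {
    for (s in names(ext)) {
      sp <- qp_split_ext(den, s)
      if (!qp_is_zero(sp[[2L]])) {
        conj <- qp_sub(sp[[1L]], qp_mul(qp_var(s), sp[[2L]], ext))
        num <- qp_mul(num, conj, ext)
        den <- qp_mul(den, conj, ext)
      }
    }
  }
  # cancel: gcd over the extension-free components of num and den
  parts <- list(num)
  if (!is.null(ext)) {
    for (s in names(ext)) {
      parts <- unlist(lapply(parts, function(p) qp_split_ext(p, s)),
                      recursive = FALSE)
    }
  }
  g <- qp_zero()
  for (p in parts) g <- qp_gcd(g, p)
  g <- qp_gcd(g, den)
  if (!qp_is_zero(g) && !(qp_is_const(g) && qp_const_val(g) == 1)) {
    num <- qp_divexact_ext(num, g, ext)
    den <- qp_divexact(den, g)
  }
  u <- qp_lead_sign(den)
  structure(list(num = qp_scale(num, u), den = qp_scale(den, u)),
            class = "qfrac")
}

# exact division where A may contain extension symbols but B may not
qp_divexact_ext <- function(A, B, ext = NULL) {
  if (is.null(ext) || length(ext) == 0L) return(qp_divexact(A, B))
  parts <- list(A)
  syms <- character(0)
  for (s in names(ext)) {
    if (any(vapply(names(A), function(k) s %in% names(mono_parse(k)), TRUE))) {
      syms <- c(syms, s)
    }
  }
  if (length(syms) == 0L) return(qp_divexact(A, B))
  s <- syms[[1L]]
  sp <- qp_split_ext(A, s)
  qp_add(qp_divexact_ext(sp[[1L]], B, ext),
         qp_mul(qp_var(s), qp_divexact_ext(sp[[2L]], B, ext), ext))
}

qf_from_poly <- function(p) structure(list(num = p, den = qp_const(1)),
                                      class = "qfrac")
qf_const <- function(x) qf_from_poly(qp_const(x))
qf_var <- function(name) qf_from_poly(qp_var(name))
qf_is_zero <- function(f) qp_is_zero(f$num)

qf_add <- function(f, g, ext = NULL) {
  qf_new(qp_add(qp_mul(f$num, g$den, ext), qp_mul(g$num, f$den, ext)),
         qp_mul(f$den, g$den, ext), ext)
}
qf_neg <- function(f) structure(list(num = qp_neg(f$num), den = f$den),
                                class = "qfrac")
qf_sub <- function(f, g, ext = NULL) qf_add(f, qf_neg(g), ext)
qf_mul <- function(f, g, ext = NULL)
  qf_new(qp_mul(f$num, g$num, ext), qp_mul(f$den, g$den, ext), ext)
qf_div <- function(f, g, ext = NULL) {
  stopifnot(!qf_is_zero(g))
  qf_new(qp_mul(f$num, g$den, ext), qp_mul(f$den, g$num, ext), ext)
}
qf_scale <- function(f, s, ext = NULL) qf_mul(f, qf_const(s), ext)

qf_equal <- function(f, g, ext = NULL) {
  qp_is_zero(qp_sub(qp_mul(f$num, g$den, ext), qp_mul(g$num, f$den, ext)))
}

qf_is_const <- function(f) qp_is_const(f$num) && qp_is_const(f$den)
qf_const_val <- function(f) qp_const_val(f$num) / qp_const_val(f$den)

qf_eval <- function(f, env) qp_eval(f$num, env) / qp_eval(f$den, env)

qf_vars <- function(f) sort(union(qp_vars(f$num), qp_vars(f$den)),
                            method = "radix")
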