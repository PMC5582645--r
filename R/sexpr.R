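# Lightweight expression trees for derived formulas.
#
# The exact-arithmetic layer (algebra.R) does the mathematics; these trees
# are the human-facing form: they render as plain text ("(a+g+sqrt((a-g)^2+
# 4*b*f))/2"), as spreadsheet formulas ("=(B2+C2+SQRT(...))/2"), and they
# evaluate numerically (in complex arithmetic when a discriminant goes
# negative).  Intermediate-variable names are free-form strings (primed
# names like "a'" are legal), so evaluation uses an environment keyed by
# those strings rather than parsed R code.

sx_num <- function(v) list(k = "num", v = v)
sx_sym <- function(name) list(k = "sym", name = name)
sx_sqrt <- function(a) list(k = "sqrt", a = a)
sx_exp <- function(a) list(k = "exp", a = a)
sx_pow <- function(a, n) {
  if (n == 1) a else list(k = "pow", a = a, n = n)
}

sx_is_num <- function(x, v = NULL) {
  x$k == "num" && (is.null(v) || x$v == v)
}

sx_neg <- function(a) {
  if (sx_is_num(a)) return(sx_num(-a$v))
  if (a$k == "neg") return(a$a)
  list(k = "neg", a = a)
}

sx_add <- function(args) {
  args <- Filter(function(x) !sx_is_num(x, 0), args)
  if (length(args) == 0L) return(sx_num(0))
  if (length(args) == 1L) return(args[[1L]])
  list(k = "add", args = args)
}

sx_mul <- function(args) {
  if (any(vapply(args, sx_is_num, TRUE, v = 0))) return(sx_num(0))
  args <- Filter(function(x) !sx_is_num(x, 1), args)
  if (length(args) == 0L) return(sx_num(1))
  if (length(args) == 1L) return(args[[1L]])
  # pull unary minus signs out front
  neg <- FALSE
  args <- lapply(args, function(x) {
    if (x$k == "neg") { neg <<- !neg; x$a } else x
  })
  out <- list(k = "mul", args = args)
  if (neg) sx_neg(out) else out
}

sx_div <- function(a, b) {
  if (sx_is_num(b, 1)) return(a)
  if (sx_is_num(a, 0)) return(sx_num(0))
  list(k = "div", a = a, b = b)
}

# --- conversion from the exact layer ---------------------------------------

# one monomial term -> AST
sx_from_term <- function(coef, key, ext) {
  ex <- mono_parse(key)
  factors <- list()
  for (nm in names(ex)) {
    base <- if (nm %in% names(ext)) {
      sx_sqrt(sx_from_qpoly(ext[[nm]], ext))
    } else {
      sx_sym(nm)
    }
    factors <- c(factors, list(sx_pow(base, ex[[nm]])))
  }
  if (length(factors) == 0L) return(sx_num(coef))
  if (coef == 1) return(sx_mul(factors))
  if (coef == -1) return(sx_neg(sx_mul(factors)))
  sx_mul(c(list(sx_num(coef)), factors))
}

sx_from_qpoly <- function(p, ext = NULL) {
  if (qp_is_zero(p)) return(sx_num(0))
  ext <- ext %||% list()
  # positive-leading terms first so rendered sums rarely start with a minus
  ord <- order(qp_lead_sign(p) * unclass(p) < 0, names(p), method = "radix")
  terms <- lapply(ord, function(i) sx_from_term(p[[i]], names(p)[i], ext))
  sx_add(terms)
}

sx_from_qfrac <- function(f, ext = NULL) {
  num <- sx_from_qpoly(f$num, ext)
  if (qp_is_const(f$den) && qp_const_val(f$den) == 1) return(num)
  sx_div(num, sx_from_qpoly(f$den, ext))
}

# --- rendering --------------------------------------------------------------

# precedence: add 1, mul/div 2, neg 1.5, pow 3, atom 4
sx_render <- function(x, sym_fmt = identity, fun_names = c(exp = "exp",
                      sqrt = "sqrt")) {
  rnd <- function(x) {
    switch(x$k,
      num = list(s = format(x$v, digits = 17), p = if (x$v < 0) 1.5 else 4),
      sym = list(s = sym_fmt(x$name), p = 4),
      neg = {
        a <- rnd(x$a)
        list(s = paste0("-", wrap(a, 2)), p = 1.5)
      },
      add = {
        parts <- lapply(x$args, rnd)
        s <- wrap(parts[[1L]], 1)
        for (pp in parts[-1L]) {
          if (substr(pp$s, 1, 1) == "-" && pp$p >= 1.5) {
            s <- paste0(s, pp$s)
          } else {
            s <- paste0(s, "+", wrap(pp, 1))
          }
        }
        list(s = s, p = 1)
      },
      mul = {
        parts <- vapply(x$args, function(a) wrap(rnd(a), 2), "")
        list(s = paste(parts, collapse = "*"), p = 2)
      },
      div = list(s = paste0(wrap(rnd(x$a), 2), "/",
                            wrap2(rnd(x$b), 2)), p = 2),
      pow = list(s = paste0(wrap2(rnd(x$a), 3), "^", x$n), p = 3),
      sqrt = list(s = paste0(fun_names[["sqrt"]], "(", rnd(x$a)$s, ")"),
                  p = 4),
      exp = list(s = paste0(fun_names[["exp"]], "(", rnd(x$a)$s, ")"),
                 p = 4),
      stop("unknown node kind: ", x$k)
    )
  }
  wrap <- function(part, need) {
    if (part$p < need) paste0("(", part$s, ")") else part$s
  }
  wrap2 <- function(part, need) {   # strict: parenthesize equal precedence
    if (part$p <= need) paste0("(", part$s, ")") else part$s
  }
  rnd(x)$s
}

# --- evaluation -------------------------------------------------------------

rtp_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "rtp_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

sx_eval <- function(x, env) {
  switch(x$k,
    num = x$v,
    sym = {
      v <- env[[x$name]]
      if (is.null(v))
        rtp_error("rtp_unbound_symbol",
                  sprintf("symbol '%s' is not bound", x$name))
      v
    },
    neg = -sx_eval(x$a, env),
    add = {
      tot <- 0
      for (a in x$args) tot <- tot + sx_eval(a, env)
      tot
    },
    mul = {
      tot <- 1
      for (a in x$args) tot <- tot * sx_eval(a, env)
      tot
    },
    div = {
      den <- sx_eval(x$b, env)
      if (all(Mod(den) == 0))
        rtp_error("rtp_degenerate_evaluation",
                  "division by zero while evaluating a derived formula")
      sx_eval(x$a, env) / den
    },
    pow = sx_eval(x$a, env)^x$n,
    sqrt = {
      v <- sx_eval(x$a, env)
      if (is.complex(v) || v < 0) sqrt(as.complex(v)) else sqrt(v)
    },
    exp = exp(sx_eval(x$a, env)),
    stop("unknown node kind: ", x$k)
  )
}

# free symbols of an AST
sx_syms <- function(x) {
  switch(x$k,
    num = character(0),
    sym = x$name,
    neg = sx_syms(x$a),
    sqrt = sx_syms(x$a),
    exp = sx_syms(x$a),
    pow = sx_syms(x$a),
    div = union(sx_syms(x$a), sx_syms(x$b)),
    add = unique(unlist(lapply(x$args, sx_syms))),
    mul = unique(unlist(lapply(x$args, sx_syms)))
  )
}

# number of additive terms (used to pick the entry replaced by the
# row-sum complement)
sx_nterms <- function(x) {
  if (x$k == "add") length(x$args) else 1L
}
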