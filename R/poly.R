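# Exact sparse Laurent multivariate polynomial arithmetic over the rationals.
#
# Terms are rows of an integer exponent matrix (columns = symbols, exponents
# may be negative) with exact rational coefficients stored as numerator /
# denominator pairs of doubles (all integers involved stay far below 2^53).
# A "differential ring" is completed by an optional table of derivative rules
# for extension symbols (exp/tan/tanh/sqrt images and jet coordinates), so
# that differentiation stays exact and closed within the ring.

## ---- vectorised exact rational helpers ----

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  if (length(a) && max(a, b) > 2^53)
    stop("exact rational arithmetic overflow: integer exceeds 2^53")
  while (any(b != 0)) {
    r <- ifelse(b != 0, a %% b, 0)
    a <- ifelse(b != 0, b, a)
    b <- r
  }
  ifelse(a == 0, 1, a)
}

rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- rat_gcd(num, den)
  list(num = num / g, den = den / g)
}

rat_add2 <- function(n1, d1, n2, d2) rat_reduce(n1 * d2 + n2 * d1, d1 * d2)
rat_mul2 <- function(n1, d1, n2, d2) rat_reduce(n1 * n2, d1 * d2)

## ---- construction / normalisation ----

mp_zero <- function() {
  structure(list(exp = matrix(integer(0), 0, 0), num = numeric(0), den = numeric(0)),
            class = "mp")
}

mp_is_zero <- function(p) nrow(p$exp) == 0L

# canonicalise: sorted symbol columns, merged duplicate monomials, no zero
# terms, no all-zero columns
mp_make <- function(exp, num, den) {
  if (length(num) == 0L) return(mp_zero())
  if (is.null(dim(exp))) exp <- matrix(exp, nrow = length(num))
  storage.mode(exp) <- "integer"
  vars <- colnames(exp)
  if (ncol(exp) > 0L) {
    o <- order(vars)
    exp <- exp[, o, drop = FALSE]
  }
  r <- rat_reduce(num, den)
  num <- r$num; den <- r$den
  keep <- num != 0
  exp <- exp[keep, , drop = FALSE]; num <- num[keep]; den <- den[keep]
  if (length(num) == 0L) return(mp_zero())
  key <- if (ncol(exp) == 0L) rep("", nrow(exp)) else
    do.call(paste, c(as.data.frame(exp), sep = ","))
  if (anyDuplicated(key)) {
    o <- order(key)
    exp <- exp[o, , drop = FALSE]; num <- num[o]; den <- den[o]; key <- key[o]
    grp <- cumsum(!duplicated(key))
    n_out <- num[!duplicated(key)] * 0
    d_out <- n_out + 1
    first <- which(!duplicated(key))
    for (i in seq_along(num)) {
      g <- grp[i]
      s <- rat_add2(n_out[g], d_out[g], num[i], den[i])
      n_out[g] <- s$num; d_out[g] <- s$den
    }
    exp <- exp[first, , drop = FALSE]; num <- n_out; den <- d_out
    keep <- num != 0
    exp <- exp[keep, , drop = FALSE]; num <- num[keep]; den <- den[keep]
    if (length(num) == 0L) return(mp_zero())
  }
  if (ncol(exp) > 0L) {
    nz <- colSums(exp != 0L) > 0L
    exp <- exp[, nz, drop = FALSE]
  }
  key <- if (ncol(exp) == 0L) rep("", nrow(exp)) else
    do.call(paste, c(as.data.frame(exp), sep = ","))
  o <- order(key)
  structure(list(exp = exp[o, , drop = FALSE], num = num[o], den = den[o]),
            class = "mp")
}

mp_const <- function(num, den = 1) {
  if (num == 0) return(mp_zero())
  mp_make(matrix(integer(0), 1, 0), num, den)
}

mp_one <- function() mp_const(1)

mp_var <- function(name, pow = 1L, num = 1, den = 1) {
  e <- matrix(as.integer(pow), 1, 1, dimnames = list(NULL, name))
  mp_make(e, num, den)
}

mp_vars <- function(p) colnames(p$exp)

# pad exponent matrices of p, q onto the union of their symbol sets
mp_align <- function(p, q) {
  vp <- colnames(p$exp); vq <- colnames(q$exp)
  vars <- sort(union(vp, vq))
  pad <- function(m, from, nr) {
    out <- matrix(0L, nr, length(vars), dimnames = list(NULL, vars))
    if (length(from)) out[, from] <- m
    out
  }
  list(pe = pad(p$exp, vp, nrow(p$exp)), qe = pad(q$exp, vq, nrow(q$exp)),
       vars = vars)
}

## ---- arithmetic ----

mp_add <- function(p, q) {
  if (mp_is_zero(p)) return(q)
  if (mp_is_zero(q)) return(p)
  al <- mp_align(p, q)
  mp_make(rbind(al$pe, al$qe), c(p$num, q$num), c(p$den, q$den))
}

mp_neg <- function(p) { p$num <- -p$num; p }
mp_sub <- function(p, q) mp_add(p, mp_neg(q))

mp_scale <- function(p, num, den = 1) {
  if (num == 0) return(mp_zero())
  r <- rat_mul2(p$num, p$den, num, den)
  mp_make(p$exp, r$num, r$den)
}

mp_mul <- function(p, q) {
  if (mp_is_zero(p) || mp_is_zero(q)) return(mp_zero())
  al <- mp_align(p, q)
  n1 <- nrow(al$pe); n2 <- nrow(al$qe)
  i <- rep(seq_len(n1), each = n2); j <- rep(seq_len(n2), times = n1)
  r <- rat_mul2(p$num[i], p$den[i], q$num[j], q$den[j])
  mp_make(al$pe[i, , drop = FALSE] + al$qe[j, , drop = FALSE], r$num, r$den)
}

mp_pow <- function(p, k) {
  k <- as.integer(k)
  if (k == 0L) return(mp_one())
  if (k < 0L) return(mp_pow(mp_inv_monomial(p), -k))
  out <- mp_one()
  base <- p
  while (k > 0L) {
    if (k %% 2L == 1L) out <- mp_mul(out, base)
    base <- if (k > 1L) mp_mul(base, base) else base
    k <- k %/% 2L
  }
  out
}

# monomial inverse (single-term polynomial)
mp_inv_monomial <- function(p) {
  if (nrow(p$exp) != 1L) stop("cannot invert a non-monomial polynomial exactly")
  mp_make(-p$exp, p$den, p$num)
}

mp_sum <- function(lst) Reduce(mp_add, lst, mp_zero())
mp_prod <- function(lst) Reduce(mp_mul, lst, mp_one())

## ---- calculus ----

# derivative rules: named list, rules[[sym]] is a named list mapping a base
# variable to an mp giving d(sym)/d(var).  Symbols without an entry are
# treated as independent coordinates (d sym / d var = [sym == var]).
mp_deriv <- function(p, var, rules = NULL) {
  if (mp_is_zero(p)) return(p)
  out <- mp_zero()
  vars <- colnames(p$exp)
  for (s in vars) {
    es <- p$exp[, s]
    act <- es != 0L
    if (!any(act)) next
    if (!is.null(rules) && !is.null(rules[[s]])) {
      ds <- rules[[s]][[var]]
      if (is.null(ds) || mp_is_zero(ds)) next
    } else if (s == var) {
      ds <- mp_one()
    } else next
    e2 <- p$exp[act, , drop = FALSE]
    r <- rat_mul2(p$num[act], p$den[act], e2[, s], 1)
    e2[, s] <- e2[, s] - 1L
    term <- mp_make(e2, r$num, r$den)
    out <- mp_add(out, mp_mul(term, ds))
  }
  out
}

## ---- substitution, evaluation, splitting ----

# substitute polynomial q for symbol var in p; negative powers of var require
# q to be a monomial
mp_subst <- function(p, var, q) {
  if (mp_is_zero(p) || !(var %in% colnames(p$exp))) return(p)
  ev <- p$exp[, var]
  out <- mp_zero()
  for (k in sort(unique(ev))) {
    sel <- ev == k
    part <- mp_make(p$exp[sel, setdiff(colnames(p$exp), var), drop = FALSE],
                    p$num[sel], p$den[sel])
    fac <- if (k == 0L) mp_one()
           else if (k > 0L) mp_pow(q, k)
           else mp_pow(mp_inv_monomial(q), -k)
    out <- mp_add(out, mp_mul(part, fac))
  }
  out
}

mp_subst_all <- function(p, subs) {
  for (v in names(subs)) p <- mp_subst(p, v, subs[[v]])
  p
}

# numeric / complex evaluation; vals is a named vector or list
mp_eval <- function(p, vals) {
  if (mp_is_zero(p)) return(0)
  vals <- unlist(vals)
  vars <- colnames(p$exp)
  miss <- setdiff(vars, names(vals))
  if (length(miss))
    stop("no value supplied for symbol(s): ", paste(miss, collapse = ", "))
  acc <- p$num / p$den
  for (v in vars) acc <- acc * vals[[v]]^p$exp[, v]
  sum(acc)
}

# split p into coefficients of monomials in `vars`: returns a list with one
# element per distinct monomial, each holding the exponent vector and the
# coefficient polynomial in the remaining symbols
mp_split <- function(p, vars) {
  if (mp_is_zero(p)) return(list())
  present <- intersect(vars, colnames(p$exp))
  sub <- matrix(0L, nrow(p$exp), length(vars), dimnames = list(NULL, vars))
  if (length(present)) sub[, present] <- p$exp[, present]
  key <- do.call(paste, c(as.data.frame(sub), sep = ","))
  rest <- setdiff(colnames(p$exp), vars)
  lapply(split(seq_len(nrow(p$exp)), key), function(idx) {
    list(mono = sub[idx[1L], ],
         coef = mp_make(p$exp[idx, rest, drop = FALSE], p$num[idx], p$den[idx]))
  })
}

# antiderivative in one variable (fails on exponent -1, which cannot stay in
# the Laurent ring)
mp_integrate <- function(p, var) {
  if (mp_is_zero(p)) return(p)
  al <- mp_align(p, mp_var(var))  # ensure the column exists
  e <- al$pe
  if (any(e[, var] == -1L))
    stop("mp_integrate: logarithmic term (exponent -1) in ", var)
  r <- rat_mul2(p$num, p$den, 1, e[, var] + 1L)
  e[, var] <- e[, var] + 1L
  mp_make(e, r$num, r$den)
}

# total degree restricted to a symbol set (Laurent: uses signed exponent sum)
mp_degree <- function(p, vars = NULL) {
  if (mp_is_zero(p)) return(-Inf)
  e <- p$exp
  if (!is.null(vars)) {
    keep <- intersect(vars, colnames(e))
    if (!length(keep)) return(0L)
    e <- e[, keep, drop = FALSE]
  }
  max(rowSums(e))
}

mp_equal <- function(p, q) mp_is_zero(mp_sub(p, q))

# extract scalar rational value of a constant polynomial
mp_as_rational <- function(p) {
  if (mp_is_zero(p)) return(c(num = 0, den = 1))
  if (nrow(p$exp) != 1L || (ncol(p$exp) > 0L && any(p$exp != 0L)))
    stop("polynomial is not constant")
  c(num = p$num, den = p$den)
}

## ---- parsing R expressions into polynomials ----

# Parse an R expression (language object or string) into an mp.  Handles
# + - * / ^ with integer (possibly negative) exponents; division requires a
# monomial divisor.  Anything else must enter through explicit constructors.
mp_parse <- function(e) {
  if (is.character(e)) e <- str2lang(e)
  rec <- function(x) {
    if (is.numeric(x)) {
      if (x != round(x)) {
        # decimal literal: exact via denominator power of 10
        d <- 10^max(0, nchar(sub("^[^.]*\\.?", "", format(x, digits = 15))))
        return(mp_const(round(x * d), d))
      }
      return(mp_const(x))
    }
    if (is.symbol(x)) return(mp_var(as.character(x)))
    if (is.call(x)) {
      op <- as.character(x[[1L]])
      if (op == "(") return(rec(x[[2L]]))
      if (op == "+" && length(x) == 2L) return(rec(x[[2L]]))
      if (op == "-" && length(x) == 2L) return(mp_neg(rec(x[[2L]])))
      if (op == "+") return(mp_add(rec(x[[2L]]), rec(x[[3L]])))
      if (op == "-") return(mp_sub(rec(x[[2L]]), rec(x[[3L]])))
      if (op == "*") return(mp_mul(rec(x[[2L]]), rec(x[[3L]])))
      if (op == "/") {
        den <- rec(x[[3L]])
        if (nrow(den$exp) == 1L) return(mp_mul(rec(x[[2L]]), mp_inv_monomial(den)))
        stop("mp_parse: division by a non-monomial: ", deparse(x))
      }
      if (op == "^") {
        k <- x[[3L]]
        if (length(all.vars(k)))
          stop("mp_parse: symbolic exponent in ", deparse(x))
        k <- eval(k, baseenv())
        if (!is.numeric(k) || k != round(k))
          stop("mp_parse: non-integer exponent in ", deparse(x))
        base <- rec(x[[2L]])
        if (k < 0 && nrow(base$exp) != 1L)
          stop("mp_parse: negative power of non-monomial in ", deparse(x))
        return(if (k >= 0) mp_pow(base, k) else mp_pow(mp_inv_monomial(base), -k))
      }
    }
    stop("mp_parse: cannot interpret ", deparse(x))
  }
  rec(e)
}

## ---- pretty printing / export ----

mp_format <- function(p) {
  if (mp_is_zero(p)) return("0")
  terms <- vapply(seq_len(nrow(p$exp)), function(i) {
    co <- if (p$den[i] == 1) format(p$num[i]) else
      paste0(format(p$num[i]), "/", format(p$den[i]))
    facs <- character(0)
    for (v in colnames(p$exp)) {
      k <- p$exp[i, v]
      if (k == 1L) facs <- c(facs, v)
      else if (k != 0L) facs <- c(facs, paste0(v, "^", k))
    }
    if (!length(facs)) return(co)
    if (co == "1") paste(facs, collapse = "*")
    else if (co == "-1") paste0("-", paste(facs, collapse = "*"))
    else paste(c(co, facs), collapse = "*")
  }, character(1))
  out <- paste(terms, collapse = " + ")
  gsub("\\+ -", "- ", out)
}

#' @export
print.mp <- function(x, ...) { cat(mp_format(x), "\n"); invisible(x) }

# convert to an R expression (for numeric evaluation outside the ring)
mp_to_expr <- function(p) str2lang(if (mp_is_zero(p)) "0" else mp_format(p))
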