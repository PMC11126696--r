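# Symbolic layer on plain R expressions: exact recursive differentiation,
# substitution, numeric/complex evaluation, a randomized polynomial-identity
# zero test, and the bridge that lifts closed-form candidates (containing
# exp/tan/tanh/coth/sqrt and half-integer powers) into the exact Laurent
# differential ring of poly.R, where zero testing is exact.

#' Differentiate a mathematical expression
#'
#' Exact recursive symbolic differentiation of an R expression with respect to
#' one variable.  Supports the arithmetic operators and the elementary
#' functions appearing in travelling-wave analysis (`exp`, `log`, `sqrt`,
#' `sin`, `cos`, `tan`, `cot`, `sinh`, `cosh`, `tanh`, `coth`).  Piecewise or
#' non-smooth constructs (`abs`, `sign`, `ifelse`) raise an error naming the
#' offending term, since candidate PDE solutions must be smooth.
#'
#' @param expr an R expression (quoted language object) or a string.
#' @param var name of the differentiation variable.
#' @param n order of the derivative (default 1).
#' @return a language object for the derivative.
#' @examples
#' sym_d(quote(tanh(2 * z)), "z")
#' @export
sym_d <- function(expr, var, n = 1L) {
  if (is.character(expr)) expr <- str2lang(expr)
  for (i in seq_len(n)) expr <- sym_d1(expr, var)
  expr
}

sym_d1 <- function(e, var) {
  num0 <- quote(0)
  if (is.numeric(e)) return(num0)
  if (is.symbol(e)) return(if (identical(as.character(e), var)) quote(1) else num0)
  if (!is.call(e)) stop("sym_d: cannot differentiate ", deparse(e))
  op <- as.character(e[[1L]])
  simp <- function(op, a, b) {
    # light structural simplification to keep derivatives readable
    za <- identical(a, quote(0)) || identical(a, 0)
    zb <- identical(b, quote(0)) || identical(b, 0)
    oa <- identical(a, quote(1)) || identical(a, 1)
    ob <- identical(b, quote(1)) || identical(b, 1)
    switch(op,
      "+" = if (za) b else if (zb) a else call("+", a, b),
      "-" = if (zb) a else if (za) call("-", b) else call("-", a, b),
      "*" = if (za || zb) quote(0) else if (oa) b else if (ob) a else call("*", a, b),
      "/" = if (za) quote(0) else if (ob) a else call("/", a, b),
      call(op, a, b))
  }
  if (op == "(") return(sym_d1(e[[2L]], var))
  if (op == "+" && length(e) == 2L) return(sym_d1(e[[2L]], var))
  if (op == "-" && length(e) == 2L) {
    d <- sym_d1(e[[2L]], var)
    return(if (identical(d, quote(0))) d else call("-", d))
  }
  if (op %in% c("+", "-"))
    return(simp(op, sym_d1(e[[2L]], var), sym_d1(e[[3L]], var)))
  if (op == "*") {
    a <- e[[2L]]; b <- e[[3L]]
    return(simp("+", simp("*", sym_d1(a, var), b), simp("*", a, sym_d1(b, var))))
  }
  if (op == "/") {
    a <- e[[2L]]; b <- e[[3L]]
    return(simp("-", simp("/", sym_d1(a, var), b),
                simp("/", simp("*", a, sym_d1(b, var)), call("^", b, 2))))
  }
  if (op == "^") {
    a <- e[[2L]]; b <- e[[3L]]
    da <- sym_d1(a, var)
    if (is.numeric(b) || (is.call(b) && !any(all.vars(b) == var)) ||
        (is.symbol(b) && as.character(b) != var)) {
      bm1 <- if (is.numeric(b)) b - 1 else call("-", b, 1)
      return(simp("*", simp("*", b, call("^", a, bm1)), da))
    }
    # general power: a^b * (db*log(a) + b*da/a)
    db <- sym_d1(b, var)
    return(call("*", e, call("+", call("*", db, call("log", a)),
                             call("/", call("*", b, da), a))))
  }
  if (grepl("^\\.h[0-9]+$", op)) {
    # derivative placeholders for a reduced profile: .hk(s) is the k-th
    # derivative of h evaluated at s, so d/dvar .hk(s) = .h(k+1)(s) * ds/dvar
    a <- e[[2L]]
    da <- sym_d1(a, var)
    if (identical(da, quote(0))) return(quote(0))
    k <- as.integer(sub("^\\.h", "", op))
    nxt <- as.call(list(as.symbol(paste0(".h", k + 1L)), a))
    return(if (identical(da, quote(1))) nxt else call("*", nxt, da))
  }
  if (length(e) >= 2L) {
    a <- e[[2L]]
    da <- sym_d1(a, var)
    outer <- switch(op,
      exp  = e,
      log  = call("/", quote(1), a),
      sqrt = call("/", quote(1), call("*", 2, call("sqrt", a))),
      sin  = call("cos", a),
      cos  = call("-", call("sin", a)),
      tan  = call("+", 1, call("^", call("tan", a), 2)),
      cot  = call("-", call("+", 1, call("^", call("cot", a), 2))),
      sinh = call("cosh", a),
      cosh = call("sinh", a),
      tanh = call("-", 1, call("^", call("tanh", a), 2)),
      coth = call("-", 1, call("^", call("coth", a), 2)),
      abs  = ,
      sign = ,
      ifelse = stop("sym_d: candidate is not differentiable: derivative of `",
                    op, "` at a kink is undefined in ", deparse(e)),
      stop("sym_d: unsupported function `", op, "` in ", deparse(e)))
    if (identical(da, quote(0))) return(quote(0))
    return(simp("*", outer, da))
  }
  stop("sym_d: cannot differentiate ", deparse(e))
}

#' Substitute expressions for symbols
#'
#' @param expr expression or string.
#' @param subs named list; each element (expression, string, or number) replaces
#'   the symbol of that name.
#' @return a language object.
#' @export
sym_subst <- function(expr, subs) {
  if (is.character(expr)) expr <- str2lang(expr)
  subs <- lapply(subs, function(s) if (is.character(s)) str2lang(s) else s)
  rec <- function(x) {
    if (is.symbol(x)) {
      nm <- as.character(x)
      if (nm %in% names(subs)) return(subs[[nm]])
      return(x)
    }
    if (is.call(x)) {
      for (i in seq_along(x)[-1L]) x[[i]] <- rec(x[[i]])
      return(x)
    }
    x
  }
  rec(expr)
}

# evaluation environment with the hyperbolic/trig reciprocals R lacks
sym_eval_env <- function(parent = baseenv()) {
  env <- new.env(parent = parent)
  env$coth <- function(x) cosh(x) / sinh(x)
  env$cot <- function(x) cos(x) / sin(x)
  env$sech <- function(x) 1 / cosh(x)
  env$csch <- function(x) 1 / sinh(x)
  env
}

#' Evaluate an expression numerically
#'
#' @param expr expression or string.
#' @param vals named list/vector of numeric (or complex) values.
#' @return numeric or complex scalar/vector.
#' @export
sym_eval <- function(expr, vals) {
  if (is.character(expr)) expr <- str2lang(expr)
  env <- sym_eval_env()
  eval(expr, envir = as.list(vals), enclos = env)
}

#' Randomized zero test for an expression
#'
#' Evaluates `expr` at `n` random points drawn away from the origin and poles.
#' An identically-zero expression evaluates to roundoff at every point; a
#' nonzero analytic expression fails with overwhelming probability
#' (Schwartz-Zippel in the polynomial case).  Used as the fallback zero test
#' when an expression cannot be lifted into the exact ring.
#'
#' @param expr expression or string.
#' @param vars character vector of free symbols (defaults to `all.vars`).
#' @param n number of random points.
#' @param tol absolute tolerance on the relative residual.
#' @param seed optional seed for reproducibility.
#' @return logical.
#' @export
sym_is_zero_num <- function(expr, vars = NULL, n = 16L, tol = 1e-8, seed = NULL) {
  if (is.character(expr)) expr <- str2lang(expr)
  if (is.null(vars)) vars <- all.vars(expr)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  got <- 0L; tries <- 0L
  while (got < n && tries < 40L * n) {
    tries <- tries + 1L
    vals <- stats::runif(length(vars), 0.35, 1.45) * sample(c(-1, 1), length(vars), TRUE)
    names(vals) <- vars
    v <- tryCatch(sym_eval(expr, as.list(vals)), error = function(e) NaN)
    if (!is.finite(abs(v))) next
    # scale by the magnitude of the largest additive contribution
    sc <- tryCatch(sym_eval_magnitude(expr, as.list(vals)), error = function(e) 1)
    if (!is.finite(sc) || sc < 1) sc <- 1
    if (abs(v) > tol * sc) return(FALSE)
    got <- got + 1L
  }
  if (got == 0L) stop("sym_is_zero_num: expression undefined at all sampled points")
  TRUE
}

# magnitude of the largest top-level additive term, for relative scaling
sym_eval_magnitude <- function(expr, vals) {
  terms <- list()
  walk <- function(x) {
    if (is.call(x) && as.character(x[[1L]]) %in% c("+", "-") && length(x) == 3L) {
      walk(x[[2L]]); walk(x[[3L]])
    } else terms[[length(terms) + 1L]] <<- x
  }
  walk(if (is.character(expr)) str2lang(expr) else expr)
  m <- vapply(terms, function(t)
    abs(tryCatch(sym_eval(t, vals), error = function(e) NA_complex_)), numeric(1))
  max(c(1, m[is.finite(m)]))
}

## ---- lifting expressions into the exact differential ring ----

# Lift an expression into an mp over a differential ring, creating extension
# symbols for transcendental subexpressions with polynomial closure of their
# derivatives:
#   exp(a)   -> E,   dE/dv  = a' E
#   tan(a)   -> T,   dT/dv  = a' (1 + T^2)          cot(a)  -> -a'(1 + C^2)
#   tanh(a)  -> H,   dH/dv  = a' (1 - H^2)          coth(a) -> a'(1 - K^2)
#   sqrt(a)  -> W,   dW/dv  = a' / (2 W)   (Laurent), with a polynomial
#   sin(a)/cos(a) -> paired symbols S, C with dS = a'C, dC = -a'S
#   a^(m/2)  -> W^m via W = sqrt(a)
# Arguments of transcendental calls must themselves be polynomial.
# Returns list(poly, rules, ext) where rules feed mp_deriv.
expr_to_ring <- function(expr, env = NULL) {
  if (is.character(expr)) expr <- str2lang(expr)
  if (is.null(env)) {
    env <- new.env()
    env$rules <- list()
    env$ext <- list()      # key = deparsed call -> symbol name
    env$counter <- 0L
  }
  new_sym <- function(prefix) {
    env$counter <- env$counter + 1L
    paste0(".", prefix, env$counter)
  }
  poly_arg <- function(a) {
    # argument of a transcendental call: must lift to a plain polynomial
    p <- rec(a)
    if (any(grepl("^\\.", mp_vars(p))))
      stop("expr_to_ring: nested transcendental argument in ", deparse(a))
    p
  }
  arg_derivs <- function(ap) {
    vars <- mp_vars(ap)
    setNames(lapply(vars, function(v) mp_deriv(ap, v)), vars)
  }
  make_ext <- function(key, prefix, drule_fun, a) {
    # deduplicate by the canonical polynomial form of the argument, so
    # algebraically equal radicands share one extension symbol
    ap <- poly_arg(a)
    key <- paste0(sub(":.*$", "", key), ":", mp_format(ap))
    if (!is.null(env$ext[[key]])) return(env$ext[[key]])
    s <- new_sym(prefix)
    dv <- arg_derivs(ap)
    env$rules[[s]] <- lapply(dv, function(da) drule_fun(s, da))
    env$ext[[key]] <- s
    s
  }
  rec <- function(x) {
    if (is.numeric(x)) {
      if (x == round(x)) return(mp_const(x))
      d <- 10^max(0, nchar(sub("^[^.]*\\.?", "", format(x, digits = 15))))
      return(mp_const(round(x * d), d))
    }
    if (is.symbol(x)) return(mp_var(as.character(x)))
    if (!is.call(x)) stop("expr_to_ring: cannot interpret ", deparse(x))
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
      stop("expr_to_ring: non-monomial denominator in ", deparse(x),
           " (rewrite the candidate or use the numeric residual)")
    }
    if (op == "^") {
      k <- x[[3L]]
      if (length(all.vars(k)))
        stop("expr_to_ring: symbolic exponent in ", deparse(x))
      kv <- eval(k, baseenv())
      if (kv == round(kv)) {
        base <- rec(x[[2L]])
        if (kv < 0 && nrow(base$exp) != 1L)
          stop("expr_to_ring: negative power of non-monomial in ", deparse(x))
        return(if (kv >= 0) mp_pow(base, kv) else mp_pow(mp_inv_monomial(base), -kv))
      }
      if (abs(2 * kv - round(2 * kv)) < 1e-12) {
        # half-integer power: route through a sqrt extension symbol
        m <- round(2 * kv)
        s <- make_ext(paste0("sqrt:", deparse(x[[2L]])), "W",
                      function(sym, da) mp_mul(mp_scale(da, 1, 2), mp_var(sym, -1L)),
                      x[[2L]])
        return(mp_var(s, as.integer(m)))
      }
      stop("expr_to_ring: non half-integer exponent in ", deparse(x))
    }
    a <- x[[2L]]
    key <- paste0(op, ":", deparse(a))
    s <- switch(op,
      exp = make_ext(key, "E", function(sym, da) mp_mul(da, mp_var(sym)), a),
      sqrt = make_ext(key, "W", function(sym, da)
        mp_mul(mp_scale(da, 1, 2), mp_var(sym, -1L)), a),
      tan = make_ext(key, "T", function(sym, da)
        mp_mul(da, mp_add(mp_one(), mp_var(sym, 2L))), a),
      cot = make_ext(key, "Ct", function(sym, da)
        mp_neg(mp_mul(da, mp_add(mp_one(), mp_var(sym, 2L)))), a),
      tanh = make_ext(key, "H", function(sym, da)
        mp_mul(da, mp_sub(mp_one(), mp_var(sym, 2L))), a),
      coth = make_ext(key, "K", function(sym, da)
        mp_mul(da, mp_sub(mp_one(), mp_var(sym, 2L))), a),
      sin = ,
      cos = {
        ks <- paste0("sin:", deparse(a)); kc <- paste0("cos:", deparse(a))
        if (is.null(env$ext[[ks]])) {
          ss <- new_sym("S"); sc <- new_sym("C")
          ap <- poly_arg(a); dv <- arg_derivs(ap)
          env$rules[[ss]] <- lapply(dv, function(da) mp_mul(da, mp_var(sc)))
          env$rules[[sc]] <- lapply(dv, function(da) mp_neg(mp_mul(da, mp_var(ss))))
          env$ext[[ks]] <- ss; env$ext[[kc]] <- sc
        }
        env$ext[[if (op == "sin") ks else kc]]
      },
      stop("expr_to_ring: unsupported function `", op, "` in ", deparse(x)))
    return(mp_var(s))
  }
  poly <- rec(expr)
  list(poly = poly, rules = env$rules, ext = env$ext, env = env)
}
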