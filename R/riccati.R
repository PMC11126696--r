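# Exact verification machinery for the auxiliary (Riccati) equation:
# lifting closed-form expressions with quotients into rational functions
# over the differential ring, derivatives of such quotients, and Riccati
# residuals.  Also: polynomials in the auxiliary function F with
# rational-function coefficients (used to substitute travelling-wave
# ansatz into the reduced ODE exactly).

# Lift an expression into an rf over a differential ring.  Like
# expr_to_ring() but with unrestricted division; extension symbols and their
# derivative rules can be pre-seeded through `rules`.
expr_to_rf <- function(expr, rules = list()) {
  if (is.character(expr)) expr <- str2lang(expr)
  env <- new.env()
  env$rules <- rules
  env$ext <- list()
  env$counter <- 0L
  new_sym <- function(prefix) {
    env$counter <- env$counter + 1L
    paste0(".", prefix, env$counter, "r")
  }
  poly_part <- function(x) {
    r <- rec(x)
    if (!mp_equal(r$den, mp_one()))
      stop("expr_to_rf: transcendental argument is not polynomial: ", deparse(x))
    r$num
  }
  make_ext <- function(key, prefix, drule_fun, a) {
    ap <- poly_part(a)
    key <- paste0(sub(":.*$", "", key), ":", mp_format(ap))
    if (!is.null(env$ext[[key]])) return(env$ext[[key]])
    s <- new_sym(prefix)
    dv <- lapply(setNames(nm = mp_vars(ap)), function(v) mp_deriv(ap, v))
    env$rules[[s]] <- lapply(dv, function(da) drule_fun(s, da))
    env$ext[[key]] <- s
    s
  }
  rec <- function(x) {
    if (is.numeric(x)) {
      if (x == round(x)) return(rf(mp_const(x)))
      d <- 10^max(0, nchar(sub("^[^.]*\\.?", "", format(x, digits = 15))))
      return(rf(mp_const(round(x * d), d)))
    }
    if (is.symbol(x)) return(rf(mp_var(as.character(x))))
    if (!is.call(x)) stop("expr_to_rf: cannot interpret ", deparse(x))
    op <- as.character(x[[1L]])
    if (op == "(") return(rec(x[[2L]]))
    if (op == "+" && length(x) == 2L) return(rec(x[[2L]]))
    if (op == "-" && length(x) == 2L) return(rf_neg(rec(x[[2L]])))
    if (op == "+") return(rf_add(rec(x[[2L]]), rec(x[[3L]])))
    if (op == "-") return(rf_sub(rec(x[[2L]]), rec(x[[3L]])))
    if (op == "*") return(rf_mul(rec(x[[2L]]), rec(x[[3L]])))
    if (op == "/") return(rf_div(rec(x[[2L]]), rec(x[[3L]])))
    if (op == "^") {
      k <- x[[3L]]
      if (length(all.vars(k))) stop("expr_to_rf: symbolic exponent")
      kv <- eval(k, baseenv())
      base <- rec(x[[2L]])
      if (kv == round(kv)) {
        kv <- as.integer(kv)
        if (kv >= 0L) return(rf(mp_pow(base$num, kv), mp_pow(base$den, kv)))
        return(rf(mp_pow(base$den, -kv), mp_pow(base$num, -kv)))
      }
      if (abs(2 * kv - round(2 * kv)) < 1e-12) {
        m <- as.integer(round(2 * kv))
        s <- make_ext(paste0("sqrt:", deparse(x[[2L]])), "W",
                      function(sym, da) mp_mul(mp_scale(da, 1, 2), mp_var(sym, -1L)),
                      x[[2L]])
        return(rf(mp_var(s, m)))
      }
      stop("expr_to_rf: unsupported exponent in ", deparse(x))
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
      stop("expr_to_rf: unsupported function `", op, "`"))
    rf(mp_var(s))
  }
  val <- rec(expr)
  list(rf = val, rules = env$rules, ext = env$ext)
}

# derivative of an rf with respect to `var` under derivative rules
rf_deriv <- function(x, var, rules = NULL) {
  n <- x$num; d <- x$den
  dn <- mp_deriv(n, var, rules); dd <- mp_deriv(d, var, rules)
  rf(mp_sub(mp_mul(dn, d), mp_mul(n, dd)), mp_mul(d, d))
}

#' Exact residual of a candidate against a Riccati equation
#'
#' Computes `F' - (quad F^2 + lin F + const)` exactly, with `F` an arbitrary
#' closed-form expression in `sigma` (quotients, exp/tan/tanh/coth/sqrt all
#' allowed), and returns the rational-function residual.
#'
#' @param F_expr expression/string for `F(sigma)`.
#' @param quad,lin,const expressions/strings for the Riccati coefficients.
#' @param pre_rules optional pre-seeded derivative rules (named list of named
#'   lists of `mp`), for manually introduced algebraic extension symbols.
#' @return list with `residual` (rf), `zero` (logical, exact).
#' @export
riccati_residual <- function(F_expr, quad, lin, const, pre_rules = list()) {
  lift <- expr_to_rf(F_expr, rules = pre_rules)
  Fv <- lift$rf
  Fp <- rf_deriv(Fv, "sigma", lift$rules)
  as_rf <- function(e) expr_to_rf(e, rules = lift$rules)$rf
  rhs <- rf_add(rf_add(rf_mul(as_rf(quad), rf_mul(Fv, Fv)),
                       rf_mul(as_rf(lin), Fv)), as_rf(const))
  res <- rf_sub(Fp, rhs)
  list(residual = res, zero = rf_is_zero(res))
}

## ---- polynomials in F with rf coefficients ----

# represented as list of rf, element i+1 = coefficient of F^i
rfp <- function(coefs) structure(coefs, class = "rfp")
rfp_zero <- function() rfp(list())
rfp_const <- function(x) rfp(list(x))
rfp_trim <- function(p) {
  n <- length(p)
  while (n > 0L && rf_is_zero(p[[n]])) n <- n - 1L
  rfp(p[seq_len(n)])
}
rfp_add <- function(p, q) {
  n <- max(length(p), length(q))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- if (i <= length(p)) p[[i]] else rf_zero()
    b <- if (i <= length(q)) q[[i]] else rf_zero()
    out[[i]] <- rf_add(a, b)
  }
  rfp_trim(rfp(out))
}
rfp_mul <- function(p, q) {
  if (!length(p) || !length(q)) return(rfp_zero())
  out <- rep(list(rf_zero()), length(p) + length(q) - 1L)
  for (i in seq_along(p)) for (j in seq_along(q))
    out[[i + j - 1L]] <- rf_add(out[[i + j - 1L]], rf_mul(p[[i]], q[[j]]))
  rfp_trim(rfp(out))
}
rfp_scale <- function(p, s) rfp_trim(rfp(lapply(p, function(x) rf_mul(x, s))))
# sigma-derivative with F' = quad F^2 + lin F + const (rf scalars)
rfp_deriv <- function(p, quad, lin, const) {
  if (length(p) <= 1L) return(rfp_zero())
  dP <- rep(list(rf_zero()), max(0L, length(p) - 1L))
  for (i in 2:length(p))
    dP[[i - 1L]] <- rf_mul(p[[i]], rf_const(i - 1L))
  rfp_mul(rfp_trim(rfp(dP)), rfp(list(const, lin, quad)))
}
rfp_is_zero <- function(p) !length(rfp_trim(p))

# evaluate a coefficient polynomial at a specific rf value of F
rfp_eval_rf <- function(p, Frf) {
  acc <- rf_zero(); pw <- rf_one()
  for (i in seq_along(p)) {
    acc <- rf_add(acc, rf_mul(p[[i]], pw))
    pw <- rf_mul(pw, Frf)
  }
  acc
}
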