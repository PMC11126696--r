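# Similarity reductions: from a symmetry generator to an invariant variable
# sigma, a solution form u = P(z,t) + A(z,t) h(sigma), and the reduced ODE
# for the profile h.
#
# The characteristic system dz/phi1 = dt/phi2 = du/eta is solved by a
# rule-based integrator covering the generator structures arising in the
# optimal system: constant (phi1, phi2) with u-independent eta, and the
# scaling family phi2 = c*t with eta affine in u.  Integration constants
# follow the conventions that reproduce the printed similarity variables of
# the reduced classes (sigma = t - z for the travelling frame, sigma = z
# with 1/t^2 decay for the scaling class, and so on).
#
# In the reduced ODE the profile and its derivatives are the ring symbols
# H0 = h, H1 = h', H2 = h'', H3 = h''', H4 = h'''' and the invariant
# variable is the symbol `sigma`.

#' Similarity variable and solution form of a generator
#'
#' @param field a [vector_field()].
#' @param c_value numeric value for the free parameter when the field
#'   contains the scaling generator with a translation (class L1); not
#'   needed otherwise.
#' @return an object of class `similarity_reduction` with fields
#'   `generator`, `sigma` (expression in `z`, `t`), `u_form` (expression in
#'   `z`, `t` and `h(sigma)` shown as `.h0(...)`), internal bookkeeping for
#'   [reduce_pde()], and `verified_convention` (FALSE for generator
#'   structures whose printed reduction has no source to compare against).
#' @export
characteristic_invariants <- function(field, c_value = NULL) {
  phi1 <- field$phi1; phi2 <- field$phi2; eta <- field$eta
  if (mp_is_zero(phi1) && mp_is_zero(phi2))
    stop("no invariant solution form: the generator acts only on u ",
         "(phi1 = phi2 = 0), so (z, t) carries no invariant")
  is_const <- function(p) mp_is_zero(p) ||
    (nrow(p$exp) == 1L && !any(c("z", "t", "u") %in% mp_vars(p)))
  const_val <- function(p) if (mp_is_zero(p)) 0 else p$num / p$den
  eta_u <- mp_deriv(eta, "u")
  verified <- TRUE

  if (is_const(phi1) && is_const(phi2) && mp_is_zero(eta_u) &&
      all(is.finite(suppressWarnings(c(const_val(phi1), const_val(phi2)))))) {
    a1 <- const_val(phi1); a2 <- const_val(phi2)
    if (a1 == 0) {
      # sigma = z; integrate du/dt = eta/phi2 at fixed z
      P <- mp_integrate(mp_scale(eta, 1, a2), "t")
      sigma <- quote(z)
      elim <- list(var = "z", by = quote(sigma))
      leftover <- "t"
    } else {
      # sigma = t - (a2/a1) z; integrate along z with t = sigma + (a2/a1) z
      r <- a2 / a1
      eta_sub <- mp_subst(eta, "t",
                          mp_add(mp_var("sigma"),
                                 mp_scale(mp_var("z"), r)))
      P <- mp_integrate(mp_scale(eta_sub, 1, a1), "z")
      # express back in (z, t): sigma -> t - r z
      P <- mp_subst(P, "sigma", mp_sub(mp_var("t"), mp_scale(mp_var("z"), r)))
      sigma <- if (r == 0) quote(t) else
        str2lang(paste0("t - ", deparse_rational(r), "*z"))
      if (r == 0) { elim <- list(var = "t", by = quote(sigma)); leftover <- "z" }
      else {
        elim <- list(var = "z",
                     by = str2lang(paste0("(t - sigma)*", deparse_rational(1 / r))))
        leftover <- "t"
      }
    }
    u_form <- finish_form(P_expr = mp_to_expr(P), A_expr = quote(1), sigma = sigma)
    return(new_reduction(field, sigma, u_form, mp_to_expr(P), quote(1),
                         elim, leftover, verified))
  }

  # scaling family: phi2 = c*t, eta = eta_u * u + B(z, t)
  dphi2 <- mp_deriv(phi2, "t")
  if (is_const(dphi2) && mp_is_zero(mp_deriv(phi2, "z")) &&
      mp_is_zero(mp_deriv(phi2, "u")) &&
      mp_is_zero(mp_subst(phi2, "t", mp_zero())) && is_const(eta_u) &&
      is_const(phi1)) {
    cc <- const_val(dphi2)
    au <- const_val(eta_u)
    B <- mp_sub(eta, mp_mul(eta_u, mp_var("u")))
    if (!mp_is_zero(mp_deriv(B, "u")))
      stop("unsupported generator: eta is not affine in u")
    a1 <- const_val(phi1)
    if (a1 == 0) {
      # sigma = z, u = u_p(z) + t^(au/cc) h(sigma)
      if (!mp_is_zero(mp_deriv(B, "t")))
        stop("unsupported generator: inhomogeneity depends on t in the scaling class")
      if (au == 0) stop("unsupported generator: pure scaling with no u weight")
      m <- au / cc
      if (m != round(m)) stop("non-integer scaling weight ", m)
      u_p <- mp_scale(B, -1, au)
      A_expr <- str2lang(paste0("t^(", format(round(m)), ")"))
      sigma <- quote(z)
      u_form <- finish_form(mp_to_expr(u_p), A_expr, sigma)
      return(new_reduction(field, sigma, u_form, mp_to_expr(u_p), A_expr,
                           list(var = "z", by = quote(sigma)), "t", verified))
    }
    # translation + scaling (class L1): sigma = t*exp(-(cc/a1) z),
    # u = u_p(z) + exp((au/a1) z) h(sigma); u_p affine from
    # a1 u_p' = au u_p + B  (B affine in z)
    if (is.null(c_value)) {
      if (cc == 0) stop("degenerate scaling")
    }
    B1 <- mp_deriv(B, "z"); B0 <- mp_subst(B, "z", mp_zero())
    if (!mp_is_zero(mp_deriv(B1, "z")) || au == 0)
      stop("unsupported generator: cannot build a particular solution")
    # affine particular solution a1 u_p' = au u_p + B: coefficients are
    # parameter monomials, kept exact in the ring
    a_c <- mp_scale(B1, -1, au)
    b_c <- mp_scale(mp_sub(mp_scale(a_c, a1), B0), 1, au)
    u_p <- mp_to_expr(mp_add(mp_mul(a_c, mp_var("z")), b_c))
    A_expr <- str2lang(paste0("exp(", deparse_rational(au / a1), "*z)"))
    sigma <- str2lang(paste0("t*exp(", deparse_rational(-cc / a1), "*z)"))
    u_form <- finish_form(u_p, A_expr, sigma)
    red <- new_reduction(field, sigma, u_form, u_p, A_expr,
                         list(var = "t",
                              by = str2lang(paste0("sigma*exp(",
                                                   deparse_rational(cc / a1), "*z)"))),
                         "z", FALSE)
    return(red)
  }
  stop("unsupported generator structure for the characteristic integrator")
}

deparse_rational <- function(x) {
  if (x == round(x)) return(format(round(x)))
  # small rationals only (components of printed generators)
  for (d in 2:48) if (abs(x * d - round(x * d)) < 1e-12)
    return(paste0("(", format(round(x * d)), "/", d, ")"))
  format(x, digits = 15)
}

finish_form <- function(P_expr, A_expr, sigma) {
  h <- as.call(list(as.symbol(".h0"), sigma))
  Ah <- if (identical(A_expr, quote(1))) h else call("*", A_expr, h)
  if (identical(P_expr, quote(0)) || identical(P_expr, 0)) Ah
  else call("+", P_expr, Ah)
}

new_reduction <- function(field, sigma, u_form, P_expr, A_expr, elim,
                          leftover, verified) {
  structure(list(generator = field, sigma = sigma, u_form = u_form,
                 P_expr = P_expr, A_expr = A_expr, eliminate = elim,
                 leftover = leftover, verified_convention = verified,
                 reduced_ode = NULL),
            class = "similarity_reduction")
}

#' @export
print.similarity_reduction <- function(x, ...) {
  cat("Similarity reduction\n")
  cat("  sigma  =", deparse(x$sigma), "\n")
  cat("  u      =", gsub("\\.h0", "h", paste(deparse(x$u_form), collapse = "")), "\n")
  if (!is.null(x$reduced_ode))
    cat("  ODE    :", reduced_ode_format(x$reduced_ode), "= 0\n")
  if (!x$verified_convention)
    cat("  (integration-constant convention unverified against a printed reduction)\n")
  invisible(x)
}

#' Check that the generator annihilates the solution form
#'
#' Applies `phi1 d/dz + phi2 d/dt + eta d/du` to `u - u_form` and tests the
#' result for zero on the solution manifold (the `.h1` term generated by the
#' sigma-dependence must cancel exactly).
#'
#' @param red a [characteristic_invariants()] result.
#' @param params named numeric values substituted for symbolic parameters in
#'   the randomized fallback.
#' @return logical.
#' @export
invariance_holds <- function(red, params = list(alpha = 1.3, gamma = 0.7)) {
  f <- red$generator
  u_expr <- red$u_form
  # X(u_form) - eta, with u substituted by u_form inside eta
  act <- call("+",
    call("*", mp_to_expr(f$phi1), sym_d(u_expr, "z")),
    call("*", mp_to_expr(f$phi2), sym_d(u_expr, "t")))
  eta_expr <- sym_subst(mp_to_expr(f$eta), list(u = u_expr))
  resid <- call("-", act, eta_expr)
  # replace profile placeholders by generic smooth stand-ins for the
  # randomized test: .hk(s) -> exp(ck * s) with distinct constants
  stand <- resid
  for (k in 0:1) {
    stand <- subst_calls(stand, paste0(".h", k),
                         function(arg) call("*", 0.7 + 0.31 * k,
                                            call("exp", call("*", 0.9 - 0.13 * k, arg))))
  }
  stand <- sym_subst(stand, params)
  sym_is_zero_num(stand, seed = 5L)
}

# replace every call  fname(arg)  by builder(arg)
subst_calls <- function(e, fname, builder) {
  rec <- function(x) {
    if (is.call(x)) {
      if (identical(as.character(x[[1L]]), fname)) return(builder(rec(x[[2L]])))
      for (i in seq_along(x)[-1L]) x[[i]] <- rec(x[[i]])
    }
    x
  }
  rec(e)
}

#' Reduce the PDE along a similarity reduction
#'
#' Substitutes the solution form into the PDE, eliminates the redundant
#' independent variable through the definition of `sigma`, verifies that the
#' residual collapses onto a single power of the leftover variable, and
#' returns the reduced ODE as an exact polynomial in
#' `sigma, H0 (=h), H1 (=h'), ..., H4 (=h'''')`, sign-normalised so the
#' highest derivative's leading coefficient is positive.
#'
#' @param model a [dna_model()].
#' @param red a [characteristic_invariants()] result (updated in place-style:
#'   the returned copy carries `reduced_ode`).
#' @return `red` with `reduced_ode` (class `mp`) and `ode_prefactor` set.
#' @export
reduce_pde <- function(model = dna_model(), red) {
  u_expr <- red$u_form
  d <- list(
    uz = sym_d(u_expr, "z"), uzz = sym_d(u_expr, "z", 2),
    utt = sym_d(u_expr, "t", 2),
    uzztt = sym_d(sym_d(u_expr, "z", 2), "t", 2))
  res <- sym_subst(model$residual_expr, c(d, model_params(model)))
  # profile calls -> plain symbols H0..H4
  for (k in 0:4)
    res <- subst_calls(res, paste0(".h", k), local({
      kk <- k; function(arg) as.symbol(paste0("H", kk))
    }))
  # eliminate the redundant coordinate via sigma
  res <- sym_subst(res, setNames(list(red$eliminate$by), red$eliminate$var))
  lifted <- expr_to_ring(res)
  p <- lifted$poly
  # any exp-extension symbols of the elimination also count as leftover
  leftover <- c(red$leftover, grep("^\\.", mp_vars(p), value = TRUE))
  groups <- mp_split(p, leftover)
  nz <- Filter(function(g) !mp_is_zero(g$coef), groups)
  if (length(nz) != 1L)
    stop("not an invariant reduction: residual spreads over ",
         length(nz), " distinct powers of (", paste(leftover, collapse = ", "),
         ") after eliminating ", red$eliminate$var)
  ode <- nz[[1L]]$coef
  pref <- nz[[1L]]$mono
  # canonical sign: highest H-derivative's leading coefficient positive
  ode <- ode_canonical(ode)
  red$reduced_ode <- ode
  red$ode_prefactor <- pref
  red
}

# sign/content canonicalisation of a reduced ODE polynomial
ode_canonical <- function(ode) {
  hs <- intersect(paste0("H", 4:0), mp_vars(ode))
  if (length(hs)) {
    top <- hs[[1L]]
    sel <- ode$exp[, top] > 0L
    lead <- ode$num[sel][which.max(rowSums(ode$exp[sel, , drop = FALSE]))]
    if (length(lead) && lead < 0) ode <- mp_neg(ode)
  }
  # divide by the scalar content
  l <- Reduce(function(a, b) a / rat_gcd(a, b) * b, ode$den, 1)
  ints <- ode$num * (l / ode$den)
  g <- Reduce(rat_gcd, abs(ints))
  mp_make(ode$exp, ints / g, rep(1, length(ints)))
}

reduced_ode_format <- function(ode) {
  txt <- mp_format(ode)
  subs <- c(H0 = "h", H1 = "h'", H2 = "h''", H3 = "h'''", H4 = "h''''")
  for (nm in names(subs)) txt <- gsub(nm, subs[[nm]], txt, fixed = TRUE)
  txt
}

#' Compare a computed reduced ODE with a printed one
#'
#' Equality is accepted up to multiplication by a nonzero constant (possibly
#' a parameter monomial); otherwise the symbolic difference after the best
#' attempted scaling is reported.
#'
#' @param computed `mp` polynomial in `sigma`, `H0..H4` (from [reduce_pde()]).
#' @param printed expression/string in the same symbols (and parameters).
#' @return list with `match` (logical), `factor` (rf scalar such that
#'   `computed = factor * printed` when `match`), and `difference` (mp,
#'   nonzero only on mismatch).
#' @export
match_printed <- function(computed, printed) {
  q <- if (inherits(printed, "mp")) printed else mp_parse(printed)
  hvars <- c("sigma", paste0("H", 0:4))
  sp_c <- mp_split(computed, hvars)
  sp_q <- mp_split(q, hvars)
  key <- intersect(names(sp_q), names(sp_c))
  if (!length(key))
    return(list(match = FALSE, factor = NULL, difference = mp_sub(computed, q)))
  fac <- rf_div(rf(sp_c[[key[1L]]]$coef), rf(sp_q[[key[1L]]]$coef))
  scaled <- if (nrow(fac$den$exp) == 1L)
    mp_mul(q, rf_to_mp(fac)) else NULL
  if (!is.null(scaled) && mp_equal(computed, scaled))
    return(list(match = TRUE, factor = fac, difference = mp_zero()))
  list(match = FALSE, factor = fac, difference = mp_sub(computed, q))
}

#' Reductions for the optimal-system classes
#'
#' Convenience map from class labels to completed reductions (invariants +
#' reduced ODE).  Classes `L8` and `L10` act only on `u` and admit no
#' similarity variable; requesting them raises the explanatory error from
#' [characteristic_invariants()].
#'
#' @param label `"L1"`..`"L9"` except `"L8"`.
#' @param sign,sign2 sign variants, see [optimal_representative()].
#' @param c_value free parameter for `L1`.
#' @param model a [dna_model()].
#' @return a `similarity_reduction` with `reduced_ode` filled in (for `L1`
#'   the reduction stops at the invariants: the scaling-translation mix is
#'   left to the numeric route).
#' @export
class_reduction <- function(label, sign = "+", sign2 = "+", c_value = NULL,
                            model = dna_model()) {
  default_model <- is.character(model$alpha) && is.character(model$gamma) &&
    is.character(model$beta)
  key <- paste0("red:", label, sign, sign2, "c", c_value %||% "")
  if (default_model) {
    cached <- .dnalie_cache[[key]]
    if (!is.null(cached)) return(cached)
  }
  field <- optimal_representative(label, sign, sign2, c_value)
  red <- characteristic_invariants(field, c_value)
  if (label != "L1") red <- reduce_pde(model, red)
  if (default_model) .dnalie_cache[[key]] <- red
  red
}
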