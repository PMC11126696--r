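# Prolongation of point-symmetry fields to fourth-order jet space.
#
# Jet coordinates are named u, uz, ut, uzz, uzt, utt, ... (z-index first).
# The prolonged coefficient for multi-index J is obtained by the standard
# total-derivative recursion
#   eta^{J,i} = D_i eta^J - (D_i phi1) u_{J,z} - (D_i phi2) u_{J,t}
# with D_i the total derivative treating u and its jets as functions of (z,t).

jet_orders <- function(order) {
  out <- list()
  for (o in 0:order) for (nz in o:0) out[[length(out) + 1L]] <- c(nz = nz, nt = o - nz)
  out
}

# total derivative of a jet-ring polynomial with respect to x in {z, t}
total_derivative <- function(p, x, max_order = 5L) {
  out <- mp_deriv(p, x)   # explicit dependence
  vars <- mp_vars(p)
  for (o in 0:max_order) for (nz in o:0) {
    nt <- o - nz
    j <- jet_sym(nz, nt)
    if (!(j %in% vars)) next
    succ <- if (x == "z") jet_sym(nz + 1L, nt) else jet_sym(nz, nt + 1L)
    dj <- mp_deriv(p, j)
    if (!mp_is_zero(dj)) out <- mp_add(out, mp_mul(dj, mp_var(succ)))
  }
  out
}

#' Prolong a vector field to jet space
#'
#' Computes the coefficients `eta^J` of the prolonged field `Y^[order]` for
#' all derivative multi-indices up to the requested total order, via the
#' total-derivative recursion.
#'
#' @param field a [vector_field()].
#' @param order prolongation order, between 1 and 4 (the PDE is fourth
#'   order).
#' @return an object of class `prolonged_field`: the base field plus a named
#'   list `eta` of jet-ring polynomials keyed by jet coordinate name
#'   (`"u"`, `"uz"`, `"ut"`, `"uzz"`, ...).
#' @examples
#' pf <- prolong(vector_field(0, 0, "t"), 2)
#' pf$eta$ut   # = 1
#' @export
prolong <- function(field, order = 4L) {
  order <- as.integer(order)
  if (order < 1L || order > 4L)
    stop("prolongation order must be between 1 and 4")
  eta <- list()
  eta[["u"]] <- field$eta
  for (o in 1:order) for (nz in o:0) {
    nt <- o - nz
    if (nz > 0L) { prev <- jet_sym(nz - 1L, nt); x <- "z" }
    else         { prev <- jet_sym(nz, nt - 1L); x <- "t" }
    # u_{J',z} and u_{J',t} where J' is the predecessor index
    if (x == "z") { jz <- jet_sym(nz, nt); jt <- jet_sym(nz - 1L, nt + 1L) }
    else          { jz <- jet_sym(nz + 1L, nt - 1L); jt <- jet_sym(nz, nt) }
    eta[[jet_sym(nz, nt)]] <- mp_sub(
      total_derivative(eta[[prev]], x),
      mp_add(mp_mul(total_derivative(field$phi1, x), mp_var(jz)),
             mp_mul(total_derivative(field$phi2, x), mp_var(jt))))
  }
  structure(list(base = field, order = order, eta = eta),
            class = "prolonged_field")
}

#' @export
print.prolonged_field <- function(x, ...) {
  cat("Prolonged field (order", x$order, ")\n")
  for (j in names(x$eta)) cat("  eta_", j, " = ", mp_format(x$eta[[j]]), "\n", sep = "")
  invisible(x)
}

# independent brute-force prolongation via the characteristic
#   Q = eta - phi1 uz - phi2 ut;  eta^J = D_J Q + phi1 u_{J,z} + phi2 u_{J,t}
# (used as the oracle in tests; shares only the total-derivative primitive)
prolong_characteristic <- function(field, order = 4L) {
  Q <- mp_sub(field$eta, mp_add(mp_mul(field$phi1, mp_var("uz")),
                                mp_mul(field$phi2, mp_var("ut"))))
  eta <- list(u = field$eta)
  for (o in 1:order) for (nz in o:0) {
    nt <- o - nz
    DQ <- Q
    for (i in seq_len(nz)) DQ <- total_derivative(DQ, "z")
    for (i in seq_len(nt)) DQ <- total_derivative(DQ, "t")
    eta[[jet_sym(nz, nt)]] <- mp_sum(list(
      DQ,
      mp_mul(field$phi1, mp_var(jet_sym(nz + 1L, nt))),
      mp_mul(field$phi2, mp_var(jet_sym(nz, nt + 1L)))))
  }
  structure(list(base = field, order = order, eta = eta),
            class = "prolonged_field")
}

# apply the prolonged field to a jet-ring polynomial Delta
apply_prolonged <- function(pf, delta) {
  out <- mp_add(mp_mul(pf$base$phi1, mp_deriv(delta, "z")),
                mp_mul(pf$base$phi2, mp_deriv(delta, "t")))
  for (j in names(pf$eta)) {
    dd <- mp_deriv(delta, j)
    if (!mp_is_zero(dd)) out <- mp_add(out, mp_mul(pf$eta[[j]], dd))
  }
  out
}

# substitute Delta = 0, solved for the highest mixed derivative uzztt (which
# enters Delta linearly with constant coefficient beta/alpha^2)
on_shell <- function(p) {
  mp_subst(p, "uzztt",
           mp_parse("alpha^2*beta^-1*(-utt + alpha^2*uzz + 2*gamma*uz*uzz)"))
}

all_jet_names <- function(order = 5L, min_order = 1L) {
  out <- character(0)
  for (o in min_order:order) for (nz in o:0) out <- c(out, jet_sym(nz, o - nz))
  out
}

#' Verify the Lie symmetry condition for a field
#'
#' Applies the fourth prolongation of `field` to the PDE's left-hand side,
#' eliminates `uzztt` using the equation itself, and returns the on-shell
#' residual as an exact jet-ring polynomial; the field is a point symmetry
#' exactly when the residual is zero.
#'
#' @param field a [vector_field()].
#' @param model a [dna_model()]; numeric parameter values are substituted
#'   into the residual.
#' @return a polynomial (class `mp`); test with [mp_is_zero] via
#'   [is_symmetry()].
#' @export
verify_symmetry <- function(field, model = dna_model()) {
  E <- on_shell(apply_prolonged(prolong(field, 4L), delta_jet()))
  for (nm in c("alpha", "gamma", "beta")) {
    v <- model[[nm]]
    if (is.numeric(v)) E <- mp_subst(E, nm, mp_const(v))
  }
  E
}

#' @rdname verify_symmetry
#' @export
is_symmetry <- function(field, model = dna_model())
  mp_is_zero(verify_symmetry(field, model))
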