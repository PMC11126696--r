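# Point-symmetry vector fields on (z, t, u)-space:
#   Y = phi1(z,t,u) d/dz + phi2(z,t,u) d/dt + eta(z,t,u) d/du
# Coefficient functions are exact Laurent polynomials, so rational-monomial
# parameter dependence such as alpha^2/gamma is carried exactly.

#' Create a point-symmetry vector field
#'
#' @param phi1,phi2,eta coefficient functions of `z`, `t`, `u` (and the model
#'   parameters `alpha`, `gamma`, `beta`): expressions, strings, or numbers.
#' @return an object of class `vector_field`.
#' @examples
#' vector_field(0, "t", "-2*u - alpha^2/gamma * z")  # the scaling symmetry
#' @export
vector_field <- function(phi1 = 0, phi2 = 0, eta = 0) {
  as_mp <- function(x) {
    if (inherits(x, "mp")) return(x)
    if (is.numeric(x)) return(mp_const(x))
    mp_parse(x)
  }
  structure(list(phi1 = as_mp(phi1), phi2 = as_mp(phi2), eta = as_mp(eta)),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  parts <- character(0)
  if (!mp_is_zero(x$phi1)) parts <- c(parts, paste0("(", mp_format(x$phi1), ") d/dz"))
  if (!mp_is_zero(x$phi2)) parts <- c(parts, paste0("(", mp_format(x$phi2), ") d/dt"))
  if (!mp_is_zero(x$eta))  parts <- c(parts, paste0("(", mp_format(x$eta), ") d/du"))
  cat(if (length(parts)) paste(parts, collapse = " + ") else "0", "\n")
  invisible(x)
}

vf_is_zero <- function(X)
  mp_is_zero(X$phi1) && mp_is_zero(X$phi2) && mp_is_zero(X$eta)

#' @export
`+.vector_field` <- function(e1, e2) {
  structure(list(phi1 = mp_add(e1$phi1, e2$phi1),
                 phi2 = mp_add(e1$phi2, e2$phi2),
                 eta  = mp_add(e1$eta, e2$eta)), class = "vector_field")
}

#' @export
`-.vector_field` <- function(e1, e2) {
  if (missing(e2))
    return(structure(list(phi1 = mp_neg(e1$phi1), phi2 = mp_neg(e1$phi2),
                          eta = mp_neg(e1$eta)), class = "vector_field"))
  e1 + (-e2)
}

#' Scale a vector field
#' @param X a `vector_field`; @param num,den exact rational scale.
#' @export
vf_scale <- function(X, num, den = 1) {
  structure(list(phi1 = mp_scale(X$phi1, num, den),
                 phi2 = mp_scale(X$phi2, num, den),
                 eta  = mp_scale(X$eta, num, den)), class = "vector_field")
}

# scale by an mp (e.g. a Laurent parameter monomial)
vf_scale_mp <- function(X, m) {
  structure(list(phi1 = mp_mul(X$phi1, m), phi2 = mp_mul(X$phi2, m),
                 eta = mp_mul(X$eta, m)), class = "vector_field")
}

vf_equal <- function(X, Y)
  mp_equal(X$phi1, Y$phi1) && mp_equal(X$phi2, Y$phi2) && mp_equal(X$eta, Y$eta)

# apply the first-order operator to a scalar polynomial f(z,t,u)
vf_apply <- function(X, f) {
  mp_sum(list(mp_mul(X$phi1, mp_deriv(f, "z")),
              mp_mul(X$phi2, mp_deriv(f, "t")),
              mp_mul(X$eta,  mp_deriv(f, "u"))))
}

#' Commutator of two vector fields
#'
#' `[X, Y] = X(Y) - Y(X)` acting on coefficient functions; with this sign
#' convention `[Y1, Y4] = Y2` for the time translation and `t d/du`.
#'
#' @param X,Y `vector_field` objects.
#' @return a `vector_field`.
#' @export
commutator <- function(X, Y) {
  structure(list(
    phi1 = mp_sub(vf_apply(X, Y$phi1), vf_apply(Y, X$phi1)),
    phi2 = mp_sub(vf_apply(X, Y$phi2), vf_apply(Y, X$phi2)),
    eta  = mp_sub(vf_apply(X, Y$eta),  vf_apply(Y, X$eta))
  ), class = "vector_field")
}

#' The five printed symmetry generators
#'
#' `Y1 = d/dt`, `Y2 = d/du`, `Y3 = d/dz`, `Y4 = t d/du`,
#' `Y5 = t d/dt + (-2u - alpha^2/gamma z) d/du`.
#'
#' @return list of five `vector_field`s in this order.
#' @export
symmetry_basis <- function() {
  list(
    vector_field(0, 1, 0),
    vector_field(0, 0, 1),
    vector_field(1, 0, 0),
    vector_field(0, 0, "t"),
    vector_field(0, "t", "-2*u - alpha^2*gamma^-1*z")
  )
}

# rf -> mp when the denominator is a monomial (true for this algebra)
rf_to_mp <- function(x) {
  if (rf_is_zero(x)) return(mp_zero())
  if (nrow(x$den$exp) != 1L)
    stop("rational function with non-monomial denominator cannot enter a ",
         "vector-field coefficient exactly")
  mp_mul(x$num, mp_inv_monomial(x$den))
}

# linear combination sum_i coefs[[i]] * basis[[i]], coefs rf or numeric
vf_lincomb <- function(coefs, basis) {
  out <- vector_field(0, 0, 0)
  for (i in seq_along(basis)) {
    ci <- coefs[[i]]
    if (is.numeric(ci)) {
      if (ci == 0) next
      out <- out + vf_scale(basis[[i]], ci)
    } else {
      if (rf_is_zero(ci)) next
      out <- out + vf_scale_mp(basis[[i]], rf_to_mp(ci))
    }
  }
  out
}

# Decompose `field` in `basis`: returns list of rf coefficients or NULL when
# the field is outside the span.  Works by matching coefficients of all
# (z,t,u)-monomials across the three components.
vf_in_basis <- function(field, basis) {
  comp <- c("phi1", "phi2", "eta")
  keys <- character(0)
  getcoefs <- function(X) {
    out <- list()
    for (cp in comp) {
      sp <- mp_split(X[[cp]], c("z", "t", "u"))
      for (s in sp) {
        key <- paste0(cp, ":", paste(s$mono, collapse = ","),
                      ":", paste(names(s$mono), collapse = ","))
        out[[key]] <- s$coef
      }
    }
    out
  }
  bc <- lapply(basis, getcoefs)
  fc <- getcoefs(field)
  keys <- unique(c(unlist(lapply(bc, names)), names(fc)))
  M <- lapply(keys, function(k)
    lapply(bc, function(b) if (is.null(b[[k]])) rf_zero() else rf(b[[k]])))
  b <- lapply(keys, function(k) if (is.null(fc[[k]])) rf_zero() else rf(fc[[k]]))
  sol <- rf_solve(M, b)
  if (is.null(sol)) return(NULL)
  # confirm exactly (guards against rank deficiency leaving residue)
  if (!vf_equal(vf_lincomb(sol, basis), field)) return(NULL)
  sol
}
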