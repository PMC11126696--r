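# Determining equations for Lie point symmetries of the DNA equation.
#
# The coefficient functions (phi1, phi2, eta) are taken polynomial in
# (z, t, u) up to a chosen total degree with undetermined constants; applying
# the fourth prolongation to Delta, eliminating uzztt on-shell, and splitting
# on monomials in the jet coordinates and in (z, t, u) yields a homogeneous
# linear system over the field of rational functions of (alpha, gamma, beta).
# Its nullspace is the symmetry algebra within the ansatz.

poly_monomials <- function(degree) {
  out <- list()
  for (d in 0:degree) for (ez in d:0) for (et in (d - ez):0) {
    eu <- d - ez - et
    out[[length(out) + 1L]] <- c(z = ez, t = et, u = eu)
  }
  out
}

mono_mp <- function(mono) {
  p <- mp_one()
  for (v in names(mono)) if (mono[[v]] > 0L) p <- mp_mul(p, mp_var(v, mono[[v]]))
  p
}

#' Build the determining system for point symmetries
#'
#' @param model a [dna_model()] (parameters are kept symbolic in the system;
#'   numeric values can be substituted when solving).
#' @param degree total polynomial degree of the coefficient-function ansatz
#'   in `(z, t, u)` (default 2; the general infinitesimal of this equation is
#'   affine, so degree 2 already contains it strictly).
#' @return an object of class `determining_system`: `unknowns` (constant
#'   names), `rows` (list of equations; each a list of `rf` coefficients),
#'   `template` (function mapping a coefficient vector to a
#'   [vector_field()]), `n_equations`, `degree`.
#' @export
determining_system <- function(model = dna_model(), degree = 2L) {
  degree <- as.integer(degree)
  if (degree < 1L) stop("ansatz degree must be >= 1")
  monos <- poly_monomials(degree)
  nm <- length(monos)
  cname <- function(comp, i) paste0("cc", comp, "_", i)
  comp_poly <- function(comp) {
    mp_sum(lapply(seq_len(nm), function(i)
      mp_mul(mp_var(cname(comp, i)), mono_mp(monos[[i]]))))
  }
  field <- structure(list(phi1 = comp_poly(1L), phi2 = comp_poly(2L),
                          eta = comp_poly(3L)), class = "vector_field")
  unknowns <- c(vapply(seq_len(nm), function(i) cname(1L, i), ""),
                vapply(seq_len(nm), function(i) cname(2L, i), ""),
                vapply(seq_len(nm), function(i) cname(3L, i), ""))
  E <- on_shell(apply_prolonged(prolong(field, 4L), delta_jet()))
  split_vars <- c(all_jet_names(5L), "z", "t", "u")
  groups <- mp_split(E, split_vars)
  rows <- lapply(groups, function(g) {
    co <- g$coef   # linear homogeneous in the unknowns
    lapply(unknowns, function(ck) {
      d <- mp_deriv(co, ck)
      if (mp_degree(d, unknowns) > 0)
        stop("internal error: determining equation not linear in ansatz constants")
      rf(d)
    })
  })
  template <- function(coefs) {
    # coefs: list of rf/numeric of length 3*nm
    take <- function(offset) {
      out <- mp_zero()
      for (i in seq_len(nm)) {
        ci <- coefs[[offset + i]]
        cm <- if (is.numeric(ci)) mp_const(ci) else rf_to_mp(ci)
        if (!mp_is_zero(cm)) out <- mp_add(out, mp_mul(cm, mono_mp(monos[[i]])))
      }
      out
    }
    structure(list(phi1 = take(0L), phi2 = take(nm), eta = take(2L * nm)),
              class = "vector_field")
  }
  structure(list(unknowns = unknowns, rows = rows, template = template,
                 n_equations = length(rows), degree = degree, model = model),
            class = "determining_system")
}

#' @export
print.determining_system <- function(x, ...) {
  cat("Determining system: degree-", x$degree, " ansatz, ",
      length(x$unknowns), " unknown constants, ", x$n_equations,
      " linear equations\n", sep = "")
  invisible(x)
}

# substitute exact rational parameter values into every row (for fast exact
# dimension counts at generic parameters)
ds_instantiate <- function(sys, alpha = c(5, 3), gamma = c(7, 4), beta = c(11, 6)) {
  subs <- list(alpha = mp_const(alpha[1], alpha[2]),
               gamma = mp_const(gamma[1], gamma[2]),
               beta  = mp_const(beta[1], beta[2]))
  lapply(sys$rows, function(row) lapply(row, function(x) {
    rf(mp_subst_all(x$num, subs), mp_subst_all(x$den, subs))
  }))
}

#' Solve the determining system
#'
#' Exact Gauss-Jordan nullspace computation over the field of rational
#' functions of `(alpha, gamma, beta)`.  Rank deficiency is expected (the
#' nullspace *is* the symmetry algebra); an inconsistency cannot arise in a
#' homogeneous system.
#'
#' @param sys a [determining_system()].
#' @return list of [vector_field()] basis elements of the symmetry algebra.
#' @export
solve_determining <- function(sys) {
  ns <- rf_nullspace(sys$rows, length(sys$unknowns))
  lapply(ns, sys$template)
}

#' Dimension of the solution space at generic parameter values
#'
#' Substitutes random exact rational values for `(alpha, gamma, beta)` and
#' counts the nullspace dimension; the minimum over draws is the generic
#' dimension (specialisation can only lower the rank).
#'
#' @param sys a [determining_system()].
#' @param n_draws number of random rational parameter draws.
#' @param seed RNG seed for the draws.
#' @return integer dimension.
#' @export
determining_dimension <- function(sys, n_draws = 2L, seed = 7L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dims <- integer(0)
  for (k in seq_len(n_draws)) {
    draw <- function() c(sample(2:13, 1), sample(2:13, 1))
    rows <- ds_instantiate(sys, draw(), draw(), draw())
    ns <- rf_nullspace(rows, length(sys$unknowns))
    dims <- c(dims, length(ns))
  }
  min(dims)
}

## ---- span comparison of bases ----

# coefficient matrix of a list of fields over the union of
# (component, monomial) slots; entries rf
basis_matrix <- function(fields) {
  comp <- c("phi1", "phi2", "eta")
  slots <- character(0)
  coefs <- lapply(fields, function(X) {
    out <- list()
    for (cp in comp) {
      for (s in mp_split(X[[cp]], c("z", "t", "u"))) {
        key <- paste0(cp, ":", paste(names(s$mono), s$mono, sep = "^", collapse = " "))
        out[[key]] <- s$coef
      }
    }
    out
  })
  slots <- sort(unique(unlist(lapply(coefs, names))))
  M <- lapply(coefs, function(co)
    lapply(slots, function(k) if (is.null(co[[k]])) rf_zero() else rf(co[[k]])))
  list(M = M, slots = slots)
}

#' Test whether two sets of vector fields span the same space
#'
#' Both bases are reduced to row-echelon form over an ordered monomial list;
#' spans are equal when each field of one basis decomposes exactly in the
#' other and vice versa.
#'
#' @param basis1,basis2 lists of [vector_field()]s.
#' @return logical.
#' @export
span_equal <- function(basis1, basis2) {
  all(vapply(basis1, function(X) !is.null(vf_in_basis(X, basis2)), logical(1))) &&
    all(vapply(basis2, function(X) !is.null(vf_in_basis(X, basis1)), logical(1)))
}

#' Reduce a basis of vector fields to a canonical echelon form
#'
#' @param fields list of [vector_field()]s.
#' @return list of [vector_field()]s spanning the same space, in row-echelon
#'   normal form over the ordered `(component, monomial)` slots.
#' @export
basis_echelon <- function(fields) {
  bm <- basis_matrix(fields)
  rr <- rf_rref(bm$M)
  keep <- rr$rref[seq_along(rr$pivots)]
  lapply(keep, function(row) {
    X <- vector_field(0, 0, 0)
    for (j in seq_along(bm$slots)) {
      if (rf_is_zero(row[[j]])) next
      slot <- bm$slots[j]
      cp <- sub(":.*$", "", slot)
      mono_txt <- sub("^[^:]*:", "", slot)
      mono <- mp_one()
      if (nzchar(mono_txt)) {
        for (f in strsplit(mono_txt, " ")[[1]]) {
          ve <- strsplit(f, "^", fixed = TRUE)[[1]]
          if (as.integer(ve[2]) != 0L)
            mono <- mp_mul(mono, mp_var(ve[1], as.integer(ve[2])))
        }
      }
      X[[cp]] <- mp_add(X[[cp]], mp_mul(rf_to_mp(row[[j]]), mono))
    }
    X
  })
}

#' Find the symmetry algebra of the model
#'
#' Convenience wrapper: builds the determining system at the given ansatz
#' degree, solves it, and returns the echelon-normalised basis.
#'
#' @inheritParams determining_system
#' @return list of [vector_field()]s.
#' @export
find_symmetries <- function(model = dna_model(), degree = 2L) {
  basis_echelon(solve_determining(determining_system(model, degree)))
}
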