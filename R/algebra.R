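# Lie-algebra structure of the symmetry algebra: structure constants,
# commutator and adjoint tables, and the one-dimensional optimal system.
#
# The adjoint action Ad(exp(eps Y_m)) Y_n is summed from the series
#   Y_n - eps [Y_m,Y_n] + eps^2/2 [Y_m,[Y_m,Y_n]] - ...
# Every entry for this algebra closes to the form  A + B*eps + C*exp(r*eps)
# with rational-in-(alpha, gamma) coefficients; the series recogniser checks
# this shape against 12 computed terms and fails loudly otherwise.

# package-level cache: the DNA symmetry algebra and its adjoint maps are
# fixed objects, recomputing them in every orbit step would be wasteful
.dnalie_cache <- new.env(parent = emptyenv())

#' The symmetry algebra of the DNA equation (cached)
#'
#' @return the [lie_algebra()] built on [symmetry_basis()], computed once per
#'   session.
#' @export
dna_algebra <- function() {
  if (is.null(.dnalie_cache$alg)) .dnalie_cache$alg <- lie_algebra()
  .dnalie_cache$alg
}

adjoint_maps_cached <- function(alg) {
  key <- "maps"
  if (!identical(alg, .dnalie_cache$alg)) return(NULL)
  if (is.null(.dnalie_cache[[key]])) {
    n <- alg$dim
    .dnalie_cache[[key]] <- lapply(seq_len(n), function(m)
      lapply(seq_len(n), function(k) adjoint(m, k, alg)))
  }
  .dnalie_cache[[key]]
}

#' Lie algebra of the symmetry generators
#'
#' Computes the structure-constant tensor `c[m, n, p]` with
#' `[Y_m, Y_n] = sum_p c[m,n,p] Y_p` over the rational functions of
#' `(alpha, gamma)` and verifies antisymmetry.
#'
#' @param basis list of [vector_field()]s (defaults to the five generators of
#'   the DNA equation, [symmetry_basis()]).
#' @return object of class `lie_algebra`: `basis`, `sc` (nested list
#'   `sc[[m]][[n]][[p]]` of `rf` scalars), `dim`.
#' @export
lie_algebra <- function(basis = symmetry_basis()) {
  n <- length(basis)
  sc <- vector("list", n)
  for (m in seq_len(n)) {
    sc[[m]] <- vector("list", n)
    for (k in seq_len(n)) {
      co <- vf_in_basis(commutator(basis[[m]], basis[[k]]), basis)
      if (is.null(co))
        stop("basis is not closed under the commutator: [Y", m, ", Y", k, "]")
      sc[[m]][[k]] <- co
    }
  }
  # antisymmetry check
  for (m in seq_len(n)) for (k in seq_len(n)) for (p in seq_len(n))
    if (!rf_equal(sc[[m]][[k]][[p]], rf_neg(sc[[k]][[m]][[p]])))
      stop("structure constants violate antisymmetry")
  structure(list(basis = basis, sc = sc, dim = n), class = "lie_algebra")
}

#' @export
print.lie_algebra <- function(x, ...) {
  cat(x$dim, "-dimensional Lie algebra\n", sep = "")
  invisible(x)
}

#' Structure constant c[m,n,p]
#' @param alg a [lie_algebra()]; @param m,n,p basis indices.
#' @return an `rf` scalar.
#' @export
structure_constant <- function(alg, m, n, p) alg$sc[[m]][[n]][[p]]

#' Verify the Jacobi identity symbolically
#'
#' Checks `[[Ym,Yn],Yp] + [[Yn,Yp],Ym] + [[Yp,Ym],Yn] = 0` identically in
#' `(alpha, gamma)` for every index triple.
#'
#' @param alg a [lie_algebra()].
#' @return logical.
#' @export
jacobi_holds <- function(alg) {
  b <- alg$basis
  n <- alg$dim
  for (m in seq_len(n)) for (k in seq_len(n)) for (p in seq_len(n)) {
    s <- commutator(commutator(b[[m]], b[[k]]), b[[p]]) +
         commutator(commutator(b[[k]], b[[p]]), b[[m]]) +
         commutator(commutator(b[[p]], b[[m]]), b[[k]])
    if (!vf_is_zero(s)) return(FALSE)
  }
  TRUE
}

#' Commutator table
#'
#' @param alg a [lie_algebra()].
#' @param format `"rf"` (raw scalars), `"character"` (formatted), or
#'   `"markdown"`.
#' @return a matrix (list or character) of table cells; cell `(m, n)` holds
#'   the expansion of `[Y_m, Y_n]` in the basis.
#' @export
commutator_table <- function(alg = dna_algebra(), format = c("character", "rf", "markdown")) {
  format <- match.arg(format)
  n <- alg$dim
  fmt_cell <- function(co) {
    parts <- character(0)
    for (p in seq_len(n)) {
      if (rf_is_zero(co[[p]])) next
      cs <- rf_format(co[[p]])
      parts <- c(parts, if (cs == "1") paste0("Y", p)
                 else if (cs == "-1") paste0("-Y", p)
                 else paste0("(", cs, ")*Y", p))
    }
    if (!length(parts)) "0" else paste(parts, collapse = " + ")
  }
  if (format == "rf")
    return(lapply(seq_len(n), function(m) alg$sc[[m]]))
  M <- matrix("", n, n, dimnames = list(paste0("Y", 1:n), paste0("Y", 1:n)))
  for (m in seq_len(n)) for (k in seq_len(n)) M[m, k] <- fmt_cell(alg$sc[[m]][[k]])
  if (format == "markdown") {
    hdr <- paste0("| [.,.] | ", paste(colnames(M), collapse = " | "), " |")
    sep <- paste(rep("|---", n + 1), collapse = "")
    rows <- vapply(seq_len(n), function(m)
      paste0("| ", rownames(M)[m], " | ", paste(M[m, ], collapse = " | "), " |"), "")
    return(paste(c(hdr, paste0(sep, "|"), rows), collapse = "\n"))
  }
  M
}

## ---- adjoint representation ----

# ad-matrix of Y_m acting on coordinates: (ad_m v)_p = sum_n v_n c[m,n,p]
ad_matrix <- function(alg, m) {
  n <- alg$dim
  lapply(seq_len(n), function(p) lapply(seq_len(n), function(q) alg$sc[[m]][[q]][[p]]))
}

# apply an rf matrix (rows p, cols q) to an rf vector
rf_matvec <- function(A, v) {
  lapply(A, function(row) {
    acc <- rf_zero()
    for (q in seq_along(v)) if (!rf_is_zero(v[[q]]) && !rf_is_zero(row[[q]]))
      acc <- rf_add(acc, rf_mul(row[[q]], v[[q]]))
    acc
  })
}

#' Adjoint action of a one-parameter subgroup on a generator
#'
#' Sums the adjoint series in closed form.  Every component is recognised as
#' `A + B*eps + C*exp(r*eps)` from 12 series terms (the recognition is then
#' verified against all computed terms); failure to close signals wrong
#' structure constants and raises an error.
#'
#' @param m,n basis indices: the action of `exp(eps Y_m)` on `Y_n`.
#' @param alg a [lie_algebra()].
#' @param n_terms series terms used for recognition (default 12).
#' @return object of class `adjoint_map` with `components`: per basis index a
#'   list `const`, `lin`, `exp_coef` (rf scalars) and rational `rate`, so the
#'   coefficient of `Y_p` is `const + lin*eps + exp_coef*exp(rate*eps)`.
#' @export
adjoint <- function(m, n, alg = dna_algebra(), n_terms = 12L) {
  A <- ad_matrix(alg, m)
  dimn <- alg$dim
  v <- rep(list(rf_zero()), dimn); v[[n]] <- rf_one()
  terms <- list(v)                     # ad^k applied to e_n
  for (k in seq_len(n_terms)) terms[[k + 1L]] <- rf_matvec(A, terms[[k]])
  comps <- vector("list", dimn)
  for (p in seq_len(dimn)) {
    # series coefficient of eps^k: s_k = (-1)^k/k! * (ad^k e_n)_p
    s <- lapply(0:n_terms, function(k)
      rf_mul(terms[[k + 1L]][[p]], rf_const((-1)^k, factorial(k))))
    nz <- which(!vapply(s[-1L], rf_is_zero, logical(1)))
    if (!length(nz)) {
      comps[[p]] <- list(const = s[[1L]], lin = rf_zero(),
                         exp_coef = rf_zero(), rate = 0)
      next
    }
    if (identical(nz, 1L)) {           # affine entry
      comps[[p]] <- list(const = s[[1L]], lin = s[[2L]],
                         exp_coef = rf_zero(), rate = 0)
      next
    }
    # exponential entry: s_k = B r^k / k!, k >= 1
    k1 <- nz[1L]
    if (k1 != 1L) stop("adjoint series has unexpected leading gap")
    r_rf <- rf_div(rf_mul(s[[3L]], rf_const(2)), s[[2L]])
    if (nrow(r_rf$num$exp) != 1L || any(r_rf$num$exp != 0L) ||
        !mp_equal(r_rf$den, mp_one()))
      stop("adjoint series rate is not a rational constant")
    rate <- unname(r_rf$num$num / r_rf$num$den)
    B <- rf_div(s[[2L]], r_rf)
    # ratio form of s_k = B r^k / k! keeps the integers small:
    # (k+1) s_{k+1} = r s_k for all k
    ok <- TRUE
    for (k in seq_len(n_terms - 1L)) {
      lhs <- rf_mul(s[[k + 2L]], rf_const(k + 1))
      if (!rf_equal(lhs, rf_mul(s[[k + 1L]], r_rf))) { ok <- FALSE; break }
    }
    if (!ok)
      stop("adjoint series for (m=", m, ", n=", n, ") does not close to ",
           "A + B*exp(r*eps) within ", n_terms, " terms")
    comps[[p]] <- list(const = rf_sub(s[[1L]], B), lin = rf_zero(),
                       exp_coef = B, rate = rate)
  }
  structure(list(m = m, n = n, components = comps), class = "adjoint_map")
}

# format one closed-form scalar component
adjoint_comp_format <- function(cp) {
  parts <- character(0)
  if (!rf_is_zero(cp$const)) parts <- c(parts, rf_format(cp$const))
  if (!rf_is_zero(cp$lin)) parts <- c(parts, paste0("(", rf_format(cp$lin), ")*epsilon"))
  if (!rf_is_zero(cp$exp_coef)) {
    rs <- if (cp$rate == 1) "epsilon" else paste0(format(cp$rate), "*epsilon")
    parts <- c(parts, paste0("(", rf_format(cp$exp_coef), ")*exp(", rs, ")"))
  }
  if (!length(parts)) "0" else paste(parts, collapse = " + ")
}

#' @export
print.adjoint_map <- function(x, ...) {
  cat("Ad(exp(epsilon*Y", x$m, ")) Y", x$n, " =\n", sep = "")
  for (p in seq_along(x$components)) {
    f <- adjoint_comp_format(x$components[[p]])
    if (f != "0") cat("  + [", f, "] Y", p, "\n", sep = "")
  }
  invisible(x)
}

# numeric evaluation of one component at given eps and parameter values
adjoint_comp_eval <- function(cp, eps, params) {
  ev <- function(x) if (rf_is_zero(x)) 0 else rf_eval(x, params)
  ev(cp$const) + ev(cp$lin) * eps + ev(cp$exp_coef) * exp(cp$rate * eps)
}

#' Numeric adjoint matrix
#'
#' Matrix `M` with `Ad(exp(eps Y_m)) Y_n = sum_p M[n, p] Y_p` at numeric
#' `eps` and parameter values.
#'
#' @param m basis index of the acting generator.
#' @param eps numeric group parameter.
#' @param params named values for `alpha`, `gamma`.
#' @param alg a [lie_algebra()].
#' @export
adjoint_matrix_num <- function(m, eps, params = c(alpha = 1, gamma = 1),
                               alg = dna_algebra()) {
  n <- alg$dim
  maps <- adjoint_maps_cached(alg)
  M <- matrix(0, n, n)
  for (k in seq_len(n)) {
    am <- if (is.null(maps)) adjoint(m, k, alg) else maps[[m]][[k]]
    for (p in seq_len(n))
      M[k, p] <- adjoint_comp_eval(am$components[[p]], eps, params)
  }
  M
}

#' Adjoint table
#'
#' Full table of closed-form adjoint actions; cell `(m, n)` is
#' `Ad(exp(eps Y_m)) Y_n`.
#'
#' @param alg a [lie_algebra()].
#' @param format `"character"`, `"adjoint_map"` or `"markdown"`.
#' @export
adjoint_table <- function(alg = dna_algebra(), format = c("character", "adjoint_map", "markdown")) {
  format <- match.arg(format)
  n <- alg$dim
  maps <- lapply(seq_len(n), function(m) lapply(seq_len(n), function(k) adjoint(m, k, alg)))
  if (format == "adjoint_map") return(maps)
  M <- matrix("", n, n, dimnames = list(paste0("Y", 1:n), paste0("Y", 1:n)))
  for (m in seq_len(n)) for (k in seq_len(n)) {
    cell <- character(0)
    for (p in seq_len(n)) {
      f <- adjoint_comp_format(maps[[m]][[k]]$components[[p]])
      if (f == "0") next
      cell <- c(cell, if (f == "1") paste0("Y", p) else paste0("(", f, ")*Y", p))
    }
    M[m, k] <- if (length(cell)) paste(cell, collapse = " + ") else "0"
  }
  if (format == "markdown") {
    hdr <- paste0("| Ad | ", paste(colnames(M), collapse = " | "), " |")
    sep <- paste(rep("|---", n + 1), collapse = "")
    rows <- vapply(seq_len(n), function(m)
      paste0("| Y", m, " | ", paste(M[m, ], collapse = " | "), " |"), "")
    return(paste(c(hdr, paste0(sep, "|"), rows), collapse = "\n"))
  }
  M
}

#' Adjoint ODE oracle
#'
#' Independent check: `W(eps) = Ad(exp(eps Y_m)) Y_n` solves the linear
#' matrix ODE `dW/deps = -[Y_m, W]`, `W(0) = Y_n`, in basis coordinates.
#' Integrates the coordinate ODE numerically with `deSolve` and returns the
#' maximum absolute deviation from the closed form at `eps_end`.
#'
#' @param m,n basis indices; @param eps_end endpoint.
#' @param params named numeric values for `alpha`, `gamma`.
#' @param alg a [lie_algebra()].
#' @return numeric deviation (should be below ~1e-8).
#' @export
adjoint_ode_deviation <- function(m, n, eps_end = 1, params = c(alpha = 1.3, gamma = 0.7),
                                  alg = dna_algebra()) {
  A <- ad_matrix(alg, m)
  An <- matrix(0, alg$dim, alg$dim)
  for (p in seq_len(alg$dim)) for (q in seq_len(alg$dim))
    An[p, q] <- if (rf_is_zero(A[[p]][[q]])) 0 else rf_eval(A[[p]][[q]], params)
  y0 <- rep(0, alg$dim); y0[n] <- 1
  sol <- deSolve::ode(y = y0, times = c(0, eps_end),
                      func = function(t, y, parms) list(-An %*% y),
                      method = "lsoda", rtol = 1e-11, atol = 1e-12)
  num <- sol[nrow(sol), -1]
  am <- adjoint(m, n, alg)
  closed <- vapply(seq_len(alg$dim), function(p)
    adjoint_comp_eval(am$components[[p]], eps_end, params), numeric(1))
  max(abs(num - closed))
}
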