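# Closed-form invariant solutions: integrate the quadrature-solvable reduced
# ODEs and assemble u(z,t) through the solution form, verifying each result
# against the PDE.
#
# Three quadrature patterns cover all reduced classes:
#   (i)   c * H2 = 0                    -> h = c1 sigma + c2
#   (ii)  H2 * (A H1 + B) = 0           -> branch h'' = 0 and branch
#                                          h' = -B/A (both integrated)
#   (iii) A H1 H2 + B H2 + C = 0        -> first integral
#         (A/2) h'^2 + B h' + C (sigma + c1) = 0, solved for h' and
#         integrated:  h = -(B/A) sigma -/+ rad^(3/2) / (3 A^2 C) + c2,
#         rad = B^2 - 2 A C (sigma + c1)
# Reduced ODEs containing the profile itself (H0) have no elementary
# quadrature; they signal `numeric_only` and route to the numeric
# integrator.

#' Integrate a reduced ODE by quadrature
#'
#' @param ode an `mp` polynomial in `sigma`, `H0..H4` (from [reduce_pde()]).
#' @return list of solution branches; each branch is a list with `h`
#'   (expression in `sigma`, free constants `c1`, `c2`), `branch` label and
#'   `domain` (validity condition as a string, `""` if none).  If the ODE is
#'   not quadrature-solvable the list carries attribute
#'   `numeric_only = TRUE` and is empty.
#' @export
integrate_reduced <- function(ode) {
  vars <- mp_vars(ode)
  if ("H0" %in% vars || "H3" %in% vars || "H4" %in% vars) {
    out <- list()
    attr(out, "numeric_only") <- TRUE
    return(out)
  }
  lin <- function() list(h = quote(c1 * sigma + c2), branch = "linear", domain = "")
  # split off the H2 factor: ode = H2 * Q(H1) + C
  Q <- mp_deriv(ode, "H2")           # works because ode is linear in H2
  C <- mp_subst(ode, "H2", mp_zero())
  if (!mp_is_zero(mp_deriv(Q, "H2")))
    stop("reduced ODE is nonlinear in h'': no implemented quadrature")
  A <- mp_deriv(Q, "H1")             # coefficient of H1 H2
  B <- mp_subst(Q, "H1", mp_zero())  # coefficient of H2
  if (!all(vapply(list(A, B, C), function(p)
    !any(c("sigma", "H1", "H2") %in% mp_vars(p)), logical(1))))
    stop("reduced ODE coefficients depend on sigma or h': no implemented quadrature")
  if (mp_is_zero(C)) {
    if (mp_is_zero(A)) return(list(lin()))          # pattern (i)
    # pattern (ii): factored; both branches
    slope <- mp_neg(mp_mul(B, mp_inv_monomial(A)))  # h' = -B/A (A monomial here)
    root_branch <- list(
      h = call("+", quote(c1),
               call("*", mp_to_expr(slope), quote(sigma))),
      branch = "h' = const root", domain = "")
    return(list(lin(), root_branch))
  }
  if (mp_is_zero(A))
    stop("reduced ODE with B h'' + C = 0 and constant C integrates to a ",
         "polynomial; pattern not needed for this equation family")
  # pattern (iii)
  Ae <- mp_to_expr(A); Be <- mp_to_expr(B); Ce <- mp_to_expr(C)
  rad <- bquote(.(Be)^2 - 2 * .(Ae) * .(Ce) * (sigma + c1))
  mk <- function(s) {
    sign_str <- if (s > 0) "+" else "-"
    h <- bquote(-(.(Be) / .(Ae)) * sigma +
                  .(if (s > 0) quote(-1) else quote(1)) *
                  (.(rad))^(3 / 2) / (3 * .(Ae)^2 * .(Ce)) + c2)
    list(h = h, branch = paste0("sqrt branch ", sign_str),
         domain = paste0(deparse(rad), " >= 0"))
  }
  list(mk(1), mk(-1))
}

#' Assemble an invariant solution of the PDE
#'
#' Substitutes a profile solution `h(sigma)` back through the similarity
#' form `u = P(z,t) + A(z,t) h(sigma(z,t))` and verifies the result against
#' the PDE.  A failed verification does not discard the solution: it is
#' returned flagged, with the residual attached.
#'
#' @param red a [characteristic_invariants()] result.
#' @param h_solution one branch from [integrate_reduced()] (or a list with
#'   an `h` expression in `sigma`).
#' @param model a [dna_model()].
#' @param source optional provenance label.
#' @return object of class `closed_form_solution`: `expression` (in `z`,
#'   `t`, `c1`, `c2` and parameters), `constraints`, `branch`,
#'   `residual_zero`, `residual` (language, `0` when verified).
#' @export
assemble <- function(red, h_solution, model = dna_model(), source = "") {
  h_of_sigma <- sym_subst(h_solution$h, list(sigma = red$sigma))
  u <- sym_subst(red$u_form, list())
  u <- subst_calls(u, ".h0", function(arg) h_of_sigma)
  res <- pde_residual(u, model)
  ok <- symbolic_zero(res)
  constraints <- c("gamma != 0", "alpha != 0",
                   if (nzchar(h_solution$domain)) h_solution$domain)
  structure(list(expression = u, branch = h_solution$branch,
                 constraints = constraints, source = source,
                 residual_zero = ok, residual = if (ok) quote(0) else res),
            class = "closed_form_solution")
}

#' @export
print.closed_form_solution <- function(x, ...) {
  cat("u(z,t) =", paste(deparse(x$expression), collapse = "\n          "), "\n")
  cat("  branch     :", x$branch, "\n")
  cat("  constraints:", paste(x$constraints, collapse = "; "), "\n")
  cat("  PDE residual zero:", x$residual_zero, "\n")
  invisible(x)
}

#' All closed-form invariant solutions of the quadrature classes
#'
#' Runs the full chain reduction -> quadrature -> assembly for every
#' optimal-system class whose reduced ODE integrates in closed form, and
#' returns the seven distinct solution families (the linear branches of the
#' two `h'' = 0` sub-cases of the space-translation class coincide).
#'
#' @param model a [dna_model()].
#' @return named list of `closed_form_solution` objects; names encode class
#'   and branch.
#' @export
invariant_solutions <- function(model = dna_model()) {
  out <- list()
  add <- function(label, sign, branch_idx, key) {
    red <- class_reduction(label, sign = sign, model = model)
    sols <- integrate_reduced(red$reduced_ode)
    out[[key]] <<- assemble(red, sols[[branch_idx]], model, source = key)
  }
  add("L9", "+", 1L, "L9.linear")       # u = c1 z + c2
  add("L9", "+", 2L, "L9.root")         # u = c1 - alpha^2/(2 gamma) z
  add("L6", "+", 1L, "L6.linear")       # u = c1 t + c2
  add("L7", "+", 1L, "L7.plus")         # polynomial/sqrt profile, + class
  add("L7", "-", 2L, "L7.minus")        # the branch carrying +rad^(3/2)
  add("L4", "+", 1L, "L4.plus")         # u = (c1 + z) t + c2
  add("L4", "-", 1L, "L4.minus")        # u = (c1 - z) t + c2
  out
}
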