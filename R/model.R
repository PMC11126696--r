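# The DNA strand-displacement model
#
#   u_tt - alpha^2 u_zz + (beta/alpha^2) u_zztt - gamma (u_z^2)_z = 0
#
# u(z,t) is the longitudinal displacement difference between the two strands,
# alpha the wave-speed parameter, gamma the nonlinearity coefficient and beta
# the fourth-order dispersion coefficient (all dimensionless).  The dispersion
# coefficient is named beta throughout this package because the catalogue of
# auxiliary-equation branches uses an unrelated three-symbol family of
# coefficients; keeping distinct names avoids any clash.

#' Create the DNA strand-displacement PDE model
#'
#' @param alpha wave-speed parameter; a nonzero number, or the string
#'   `"alpha"` to keep it symbolic (default).
#' @param gamma nonlinearity coefficient; nonzero number or `"gamma"`.
#' @param beta dispersion coefficient; number or `"beta"`.
#' @return an object of class `pde_model` with fields `alpha`, `gamma`,
#'   `beta`, and the left-hand side `residual_expr` written in derivative
#'   placeholders `utt`, `uzz`, `uzztt`, `uz` (so `gamma*(uz^2)_z` appears
#'   expanded as `2*gamma*uz*uzz`).
#' @examples
#' m <- dna_model()
#' m$residual_expr
#' @export
dna_model <- function(alpha = "alpha", gamma = "gamma", beta = "beta") {
  chk <- function(x, nm, nonzero) {
    if (is.character(x)) return(x)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("`", nm, "` must be a finite number or a symbol name")
    if (nonzero && x == 0) stop("`", nm, "` must be nonzero: it appears in ",
                                "denominators of the symmetry algebra")
    x
  }
  m <- structure(list(
    alpha = chk(alpha, "alpha", TRUE),
    gamma = chk(gamma, "gamma", TRUE),
    beta  = chk(beta,  "beta",  FALSE)
  ), class = "pde_model")
  m$residual_expr <- str2lang(
    "utt - alpha^2*uzz + (beta/alpha^2)*uzztt - 2*gamma*uz*uzz")
  m
}

#' @export
print.pde_model <- function(x, ...) {
  cat("DNA strand-displacement PDE: u_tt - alpha^2 u_zz + (beta/alpha^2) u_zztt - gamma (u_z^2)_z = 0\n")
  cat(sprintf("  alpha = %s, gamma = %s, beta = %s\n",
              format(x$alpha), format(x$gamma), format(x$beta)))
  invisible(x)
}

# named list of parameter substitutions (numbers stay numbers, symbols become
# language symbols)
model_params <- function(model) {
  lapply(list(alpha = model$alpha, gamma = model$gamma, beta = model$beta),
         function(v) if (is.character(v)) as.symbol(v) else v)
}

# jet coordinate name u_{z^nz t^nt}
jet_sym <- function(nz, nt) paste0("u", strrep("z", nz), strrep("t", nt))

# Delta as an exact polynomial in the jet ring (params always symbolic here;
# substitute numbers afterwards if needed)
delta_jet <- function() {
  mp_parse("utt - alpha^2*uzz + beta*alpha^-2*uzztt - 2*gamma*uz*uzz")
}

#' Symbolic PDE residual of a candidate solution
#'
#' Substitutes `u = candidate(z, t)` into the model's left-hand side using
#' exact symbolic differentiation and returns the residual expression.  The
#' residual is identically zero exactly when the candidate solves the PDE.
#'
#' @param candidate an expression (or string) in `z` and `t`; free constants
#'   such as `c1`, `c2` may appear and are carried symbolically.
#' @param model a [dna_model()].
#' @return a language object (`0` for an exact solution after simplification
#'   through the exact ring when the candidate lifts into it).
#' @examples
#' pde_residual(quote(c1 * z + c2), dna_model())
#' @export
pde_residual <- function(candidate, model = dna_model()) {
  if (is.character(candidate)) candidate <- str2lang(candidate)
  d <- list(
    uz    = sym_d(candidate, "z"),
    uzz   = sym_d(candidate, "z", 2),
    utt   = sym_d(candidate, "t", 2),
    uzztt = sym_d(sym_d(candidate, "z", 2), "t", 2)
  )
  res <- sym_subst(model$residual_expr, c(d, model_params(model)))
  # exact simplification when the candidate lifts into the differential ring
  z <- tryCatch(expr_to_ring(res), error = function(e) NULL)
  if (!is.null(z)) {
    if (mp_is_zero(z$poly)) return(quote(0))
    # return the ring-normalised form with extension symbols expanded back
    return(ring_to_expr(z))
  }
  res
}

# rebuild an expression from a lifted ring element (extension symbols are
# replaced by their defining calls)
ring_to_expr <- function(lifted) {
  e <- mp_to_expr(lifted$poly)
  if (!length(lifted$ext)) return(e)
  subs <- list()
  for (key in names(lifted$ext)) {
    sym <- lifted$ext[[key]]
    op <- sub(":.*$", "", key)
    arg <- str2lang(sub("^[^:]*:", "", key))
    subs[[sym]] <- if (op == "sqrt") call("sqrt", arg) else call(op, arg)
  }
  sym_subst(e, subs)
}

#' Exactness test for a residual expression
#'
#' Tries to lift the expression into the exact Laurent differential ring
#' (exact zero test); if the expression does not lift, falls back to a
#' randomized evaluation identity test.
#'
#' @param expr expression or string.
#' @param seed seed for the randomized fallback.
#' @return logical.
#' @export
symbolic_zero <- function(expr, seed = 1L) {
  if (is.character(expr)) expr <- str2lang(expr)
  if (is.numeric(expr)) return(expr == 0)
  lifted <- tryCatch(expr_to_ring(expr), error = function(e) NULL)
  if (!is.null(lifted)) return(mp_is_zero(lifted$poly))
  sym_is_zero_num(expr, seed = seed)
}

#' Gridded numeric residual of a candidate solution
#'
#' Samples the PDE residual on a rectangular grid.  Symbolic candidates are
#' differentiated analytically; black-box functions `u(z, t)` use fourth-order
#' central finite differences with a step tied to the grid spacing.  Points
#' where the candidate or residual is non-finite (poles) are masked and
#' counted.
#'
#' @param candidate expression/string in `z`, `t`, or a function `f(z, t)`.
#' @param model a [dna_model()]; numeric parameters are required unless
#'   supplied through `constraints`.
#' @param grid list with components `z = c(min, max)`, `t = c(min, max)`,
#'   `n = c(nz, nt)`.
#' @param constraints named list of numeric values for free constants
#'   (e.g. `c1`, `c2`) and/or symbolic model parameters.
#' @param tol absolute tolerance defining "numerically zero".
#' @return a `residual_report`: fields `symbolic_zero` (NA for black-box
#'   candidates), `max_abs_residual`, `grid_spec`, `constraint_set`,
#'   `n_masked`, `n_evaluated`.
#' @export
numeric_residual <- function(candidate, model = dna_model(),
                             grid = list(z = c(0, 1), t = c(0, 1), n = c(50, 50)),
                             constraints = list(), tol = 1e-8) {
  zs <- seq(grid$z[1], grid$z[2], length.out = grid$n[1])
  ts <- seq(grid$t[1], grid$t[2], length.out = grid$n[2])
  pars <- model_params(model)
  for (nm in names(constraints)) pars[[nm]] <- constraints[[nm]]
  sym_pars <- names(Filter(function(v) !is.numeric(v), pars))
  if (length(sym_pars))
    stop("numeric residual needs numeric values for: ",
         paste(sym_pars, collapse = ", "))
  symzero <- NA
  if (!is.function(candidate)) {
    res_expr <- pde_residual(candidate, model)
    res_expr_num <- sym_subst(res_expr, pars)
    symzero <- symbolic_zero(sym_subst(res_expr, Filter(is.numeric, pars)))
    g <- expand.grid(z = zs, t = ts)
    vals <- tryCatch(
      sym_eval(res_expr_num, list(z = g$z, t = g$t)),
      error = function(e) stop("residual evaluation failed: ", conditionMessage(e)))
    if (length(vals) == 1L) vals <- rep(vals, nrow(g))
  } else {
    hz <- diff(zs[1:2]); ht <- diff(ts[1:2])
    f <- function(z, t) candidate(z, t)
    d2 <- function(g, x, h) (-g(x + 2*h) + 16*g(x + h) - 30*g(x) + 16*g(x - h) - g(x - 2*h)) / (12*h^2)
    g <- expand.grid(z = zs, t = ts)
    utt <- mapply(function(z, t) d2(function(tt) f(z, tt), t, ht), g$z, g$t)
    uzz <- mapply(function(z, t) d2(function(zz) f(zz, t), z, hz), g$z, g$t)
    uz <- mapply(function(z, t) {
      h <- hz; (f(z - 2*h, t) - 8*f(z - h, t) + 8*f(z + h, t) - f(z + 2*h, t)) / (12*h)
    }, g$z, g$t)
    uzztt <- mapply(function(z, t)
      d2(function(tt) d2(function(zz) f(zz, tt), z, hz), t, ht), g$z, g$t)
    vals <- utt - pars$alpha^2 * uzz + (pars$beta / pars$alpha^2) * uzztt -
      2 * pars$gamma * uz * uzz
  }
  av <- abs(vals)
  masked <- !is.finite(av)
  if (all(masked)) stop("all grid points masked: candidate singular on the grid")
  structure(list(
    symbolic_zero = symzero,
    max_abs_residual = max(av[!masked]),
    grid_spec = grid,
    constraint_set = Filter(is.numeric, pars),
    n_masked = sum(masked),
    n_evaluated = sum(!masked),
    tol = tol,
    numerically_zero = max(av[!masked]) <= tol
  ), class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat("PDE residual report\n")
  cat("  symbolic zero   :", x$symbolic_zero, "\n")
  cat("  max |residual|  :", format(x$max_abs_residual), "on",
      x$n_evaluated, "points (", x$n_masked, "masked )\n")
  cat("  numerically zero:", x$numerically_zero, "(tol", x$tol, ")\n")
  invisible(x)
}

#' Serialize a residual report to JSON
#' @param x a `residual_report`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
residual_report_json <- function(x, path = NULL) {
  obj <- unclass(x)
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
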