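# One-dimensional optimal system of subalgebras.
#
# A general element k1 Y1 + ... + k5 Y5 is normalised by adjoint actions
# following a ten-case branch structure on which coefficients vanish.  The
# package reproduces the ten labelled representative classes and, separately,
# validates every case's stated intermediate adjoint steps with orbit_reduce,
# recording (rather than reproducing) any step whose printed coefficient
# pattern disagrees with the adjoint table actually computed from the
# structure constants.

#' The ten-class one-dimensional optimal system
#'
#' @param alg a [lie_algebra()] (five-dimensional DNA symmetry algebra).
#' @return list of `optimal_class` objects with fields `label`
#'   (`"L1"`..`"L10"`), `conditions` (named integer pattern on `k1..k5`:
#'   1 = nonzero, 0 = zero, NA = unconstrained), `representative` (a
#'   [vector_field()]; the free nonzero parameter of L1 enters as symbol
#'   `c`), `sign_variants` (number of printed +/- sign choices, each kept as
#'   one labelled class), and `description`.
#' @export
optimal_system <- function(alg = dna_algebra()) {
  Y <- alg$basis
  cls <- function(label, conditions, rep_field, sign_variants, description) {
    structure(list(label = label, conditions = conditions,
                   representative = rep_field, sign_variants = sign_variants,
                   description = description), class = "optimal_class")
  }
  cvar <- mp_var("c")
  list(
    cls("L1",  c(k1 = NA, k2 = NA, k3 = 1, k4 = NA, k5 = 1),
        Y[[3]] + vf_scale_mp(Y[[5]], cvar), 1,
        "Y3 + c*Y5, c != 0"),
    cls("L2",  c(k1 = NA, k2 = NA, k3 = 0, k4 = NA, k5 = 1), Y[[5]], 1, "Y5"),
    cls("L3",  c(k1 = 1, k2 = NA, k3 = 1, k4 = 1, k5 = 0),
        Y[[1]] + Y[[3]] + Y[[4]], 4, "Y1 +/- Y3 +/- Y4"),
    cls("L4",  c(k1 = 0, k2 = NA, k3 = 1, k4 = 1, k5 = 0),
        Y[[3]] + Y[[4]], 2, "Y3 +/- Y4"),
    cls("L5",  c(k1 = 1, k2 = NA, k3 = 1, k4 = 0, k5 = 0),
        Y[[1]] + Y[[3]], 2, "Y1 +/- Y3"),
    cls("L6",  c(k1 = 0, k2 = NA, k3 = 1, k4 = 0, k5 = 0), Y[[3]], 1, "Y3"),
    cls("L7",  c(k1 = 1, k2 = NA, k3 = 0, k4 = 1, k5 = 0),
        Y[[1]] + Y[[4]], 2, "Y1 +/- Y4"),
    cls("L8",  c(k1 = 0, k2 = NA, k3 = 0, k4 = 1, k5 = 0), Y[[4]], 1, "Y4"),
    cls("L9",  c(k1 = 1, k2 = NA, k3 = 0, k4 = 0, k5 = 0), Y[[1]], 1, "Y1"),
    cls("L10", c(k1 = 0, k2 = 1, k3 = 0, k4 = 0, k5 = 0), Y[[2]], 1, "Y2")
  )
}

#' @export
print.optimal_class <- function(x, ...) {
  cat(x$label, ": ", x$description, "\n", sep = "")
  invisible(x)
}

#' Resolve an optimal-system class to a concrete generator
#'
#' @param label one of `"L1"`..`"L10"`.
#' @param sign `"+"` or `"-"`: sign of the second printed generator where the
#'   class has sign variants (L3 uses `sign` for Y3 and `sign2` for Y4).
#' @param sign2 sign of the third generator (L3 only).
#' @param c_value numeric value for the free parameter of L1 (nonzero).
#' @param alg a [lie_algebra()].
#' @return a [vector_field()].
#' @export
optimal_representative <- function(label, sign = "+", sign2 = "+", c_value = NULL,
                                   alg = dna_algebra()) {
  Y <- alg$basis
  s1 <- if (sign == "+") 1 else -1
  s2 <- if (sign2 == "+") 1 else -1
  switch(label,
    L1 = {
      if (is.null(c_value) || c_value == 0)
        stop("L1 needs a nonzero `c_value` for Y3 + c*Y5")
      Y[[3]] + vf_scale(Y[[5]], c_value)
    },
    L2 = Y[[5]],
    L3 = Y[[1]] + vf_scale(Y[[3]], s1) + vf_scale(Y[[4]], s2),
    L4 = Y[[3]] + vf_scale(Y[[4]], s1),
    L5 = Y[[1]] + vf_scale(Y[[3]], s1),
    L6 = Y[[3]],
    L7 = Y[[1]] + vf_scale(Y[[4]], s1),
    L8 = Y[[4]],
    L9 = Y[[1]],
    L10 = Y[[2]],
    stop("unknown optimal-system label: ", label))
}

#' Apply a sequence of adjoint actions to a general element
#'
#' Coordinates transform as `v'_p = sum_n v_n M[n, p](eps)` under
#' `Ad(exp(eps Y_m))`.  An action's `eps` may be a number, or
#' `list(solve = p)` to request the value of `eps` that annihilates
#' component `p`; when no `eps` achieves the cancellation the component is
#' left untouched and a discrepancy is recorded (never silently fixed).
#'
#' @param k numeric coordinate vector of length 5 (the `k1..k5`).
#' @param actions list of actions `list(m = index, eps = value | list(solve = p))`.
#' @param params named numeric `alpha`, `gamma`.
#' @param alg a [lie_algebra()].
#' @return list with `v` (final coordinates), `eps_used`, and `discrepancies`
#'   (character vector).
#' @export
orbit_reduce <- function(k, actions, params = c(alpha = 1, gamma = 1),
                         alg = dna_algebra()) {
  v <- as.numeric(k)
  eps_used <- numeric(0)
  disc <- character(0)
  for (a in actions) {
    m <- a$m
    apply_eps <- function(eps) {
      M <- adjoint_matrix_num(m, eps, params, alg)
      as.numeric(v %*% M)
    }
    eps <- a$eps
    if (is.list(eps) && !is.null(eps$solve)) {
      p <- eps$solve
      f <- function(e) apply_eps(e)[p]
      f0 <- f(0)
      # affine in eps (shift actions): exact linear solve
      slope <- f(1) - f0
      eps_num <- NA_real_
      if (abs((f(2) - f(1)) - slope) < 1e-10 * max(1, abs(slope))) {
        if (abs(slope) > 1e-12) eps_num <- -f0 / slope
      } else {
        # exponential in eps (Y5-based): root-find on expanding brackets
        for (b in c(2, 8, 30)) {
          r <- tryCatch(stats::uniroot(f, c(-b, b), tol = 1e-13)$root,
                        error = function(e) NA_real_)
          if (is.finite(r)) { eps_num <- r; break }
        }
      }
      if (!is.finite(eps_num) || abs(f(eps_num)) > 1e-8) {
        disc <- c(disc, sprintf(
          "action Ad(exp(eps*Y%d)) cannot annihilate component %d (value %.6g)",
          m, p, v[p]))
        eps_num <- 0
      }
      eps <- eps_num
    }
    v <- apply_eps(eps)
    eps_used <- c(eps_used, eps)
  }
  list(v = v, eps_used = eps_used, discrepancies = disc)
}

# ---- validation of the printed ten-case construction ----

# Printed intermediate steps: for each case, the acting generator of each
# step and the coefficient pattern claimed after it (functions of the
# incoming k and the step's eps; exponential factors written explicitly).
optimal_case_steps <- function() {
  list(
    list(case = 1L,  pick = c(k5 = 1, k3 = 1),
         steps = list(list(m = 1L, claimed_zero = c(1L, 2L)),
                      list(m = 4L, claimed_zero = 4L)),
         absorb = list(list(m = 3L, target = 2L)), final_nonzero = c(3L, 5L)),
    list(case = 2L,  pick = c(k5 = 1, k3 = 0),
         steps = list(list(m = 1L, claimed_zero = c(1L, 2L)),
                      list(m = 4L, claimed_zero = 4L)),
         absorb = list(list(m = 3L, target = 2L)), final_nonzero = 5L),
    list(case = 3L,  pick = c(k5 = 0, k4 = 1, k3 = 1, k1 = 1),
         steps = list(list(m = 5L, claimed_zero = integer(0),
                           claimed_factors = c("1", "exp(-eps)", "exp(-4*eps)", "0", "0"))),
         absorb = list(list(m = 4L, target = 2L)), final_nonzero = c(1L, 3L, 4L)),
    list(case = 4L,  pick = c(k5 = 0, k4 = 1, k3 = 1, k1 = 0),
         steps = list(list(m = 1L, claimed_zero = 2L),
                      list(m = 5L, claimed_zero = integer(0),
                           claimed_factors = c("0", "0", "1", "exp(-3*eps)", "0"))),
         absorb = list(), final_nonzero = c(3L, 4L)),
    list(case = 5L,  pick = c(k5 = 0, k4 = 0, k3 = 1, k1 = 1),
         steps = list(list(m = 4L, claimed_zero = 2L),
                      list(m = 5L, claimed_zero = integer(0),
                           claimed_factors = c("1", "0", "exp(-eps)", "0", "0"))),
         absorb = list(), final_nonzero = c(1L, 3L)),
    list(case = 6L,  pick = c(k5 = 0, k4 = 0, k3 = 1, k1 = 0),
         steps = list(list(m = 5L, claimed_zero = 2L)),
         absorb = list(), final_nonzero = 3L),
    list(case = 7L,  pick = c(k5 = 0, k4 = 1, k3 = 0, k1 = 1),
         steps = list(list(m = 1L, claimed_zero = 2L),
                      list(m = 5L, claimed_zero = integer(0),
                           claimed_factors = c("1", "0", "0", "exp(-4*eps)", "0"))),
         absorb = list(), final_nonzero = c(1L, 4L)),
    list(case = 8L,  pick = c(k5 = 0, k4 = 1, k3 = 0, k1 = 0),
         steps = list(list(m = 1L, claimed_zero = 2L)),
         absorb = list(), final_nonzero = 4L),
    list(case = 9L,  pick = c(k5 = 0, k4 = 0, k3 = 0, k1 = 1),
         steps = list(list(m = 4L, claimed_zero = 2L)),
         absorb = list(), final_nonzero = 1L),
    list(case = 10L, pick = c(k5 = 0, k4 = 0, k3 = 0, k1 = 0),
         steps = list(), absorb = list(), final_nonzero = 2L)
  )
}

#' Validate the ten-case optimal-system construction
#'
#' For each case, draws random coefficient vectors satisfying the case
#' conditions and follows the stated sequence of adjoint actions, solving for
#' each step's group parameter.  Three kinds of finding are recorded, never
#' silently fixed:
#' * a stated single action that cannot achieve all of its claimed
#'   cancellations (one one-parameter family has one parameter);
#' * a printed exponential factor that disagrees with the adjoint table
#'   computed from the structure constants (notably the `exp(-4*eps)` factor
#'   claimed in two scaling steps, where the table gives `exp(-3*eps)` on Y4
#'   and leaves Y3 unscaled);
#' * a residual `Y2` component whose absorption by a scaling action exists
#'   only under a sign condition on the drawn coefficients.
#' Documented absorption actions (`Y3`- or `Y4`-based shifts removing a
#' residual `Y2` component when `k5` resp. `k1` is available) are applied
#' after the stated steps.  A draw "reaches" its class when the final
#' coordinates have exactly the representative's nonzero pattern.
#'
#' @param params named numeric `alpha`, `gamma`.
#' @param n_draws random draws per case.
#' @param seed RNG seed.
#' @param alg a [lie_algebra()].
#' @return list with `per_case` (per case: `n_reached`, `n_draws`,
#'   `discrepancies`), `shift_cases_reached` (cases whose cancellations use
#'   only shift actions all reached on every draw), and `n_classes`.
#' @export
validate_optimal_system <- function(params = c(alpha = 1.2, gamma = 0.8),
                                    n_draws = 3L, seed = 11L,
                                    alg = dna_algebra()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cases <- optimal_case_steps()
  per_case <- list()
  for (cs in cases) {
    logs <- character(0)
    n_reached <- 0L
    for (d in seq_len(n_draws)) {
      k <- stats::runif(5, 0.5, 2) * sample(c(-1, 1), 5, TRUE)
      for (nm in names(cs$pick)) {
        i <- as.integer(sub("k", "", nm))
        if (cs$pick[[nm]] == 0) k[i] <- 0
      }
      v <- k
      for (st in cs$steps) {
        if (length(st$claimed_zero)) {
          # one action has one parameter: solve for the first achievable
          # claimed component, then audit the rest
          solved <- FALSE
          for (p in st$claimed_zero) {
            if (solved || abs(v[p]) < 1e-12) next
            r <- orbit_reduce(v, list(list(m = st$m, eps = list(solve = p))),
                              params, alg)
            if (!length(r$discrepancies)) { v <- r$v; solved <- TRUE }
            else logs <- c(logs, sprintf("case %d: %s", cs$case, r$discrepancies))
          }
          left <- st$claimed_zero[abs(v[st$claimed_zero]) > 1e-8]
          if (length(left))
            logs <- c(logs, sprintf(
              "case %d: stated single Ad(exp(eps*Y%d)) action leaves claimed-zero component(s) %s nonzero",
              cs$case, st$m, paste(left, collapse = ",")))
        }
        if (!is.null(st$claimed_factors)) {
          eps0 <- 0.37
          act <- orbit_reduce(v, list(list(m = st$m, eps = eps0)), params, alg)$v
          for (p in 1:5) {
            fac <- st$claimed_factors[p]
            claimed <- if (fac == "0") 0 else
              v[p] * eval(str2lang(fac), list(eps = eps0))
            if (abs(act[p] - claimed) > 1e-9 * max(1, abs(claimed)))
              logs <- c(logs, sprintf(
                "case %d: printed factor %s for component %d disagrees with the adjoint table (actual %.6g vs printed %.6g)",
                cs$case, fac, p, act[p], claimed))
          }
          v <- act
        }
      }
      for (ab in cs$absorb) {
        if (abs(v[ab$target]) < 1e-8) next
        r <- orbit_reduce(v, list(list(m = ab$m, eps = list(solve = ab$target))),
                          params, alg)
        if (length(r$discrepancies))
          logs <- c(logs, sprintf("case %d absorb: %s", cs$case, r$discrepancies))
        else v <- r$v
      }
      # residual Y2 with no shift available: only the Y5 scaling can touch it,
      # and an exact zero needs a sign condition
      if (abs(v[2]) > 1e-8 && !length(cs$absorb) && cs$case != 10L) {
        r <- orbit_reduce(v, list(list(m = 5L, eps = list(solve = 2L))), params, alg)
        if (!length(r$discrepancies)) v <- r$v
        else logs <- c(logs, sprintf(
          "case %d: Y2 absorption by the Y5 scaling needs a sign condition; this draw violates it",
          cs$case))
      }
      pattern <- which(abs(v) > 1e-8)
      if (setequal(pattern, cs$final_nonzero)) n_reached <- n_reached + 1L
      else logs <- c(logs, sprintf(
        "case %d: final pattern {%s} != representative pattern {%s}",
        cs$case, paste(pattern, collapse = ","),
        paste(cs$final_nonzero, collapse = ",")))
    }
    per_case[[paste0("case", cs$case)]] <-
      list(n_reached = n_reached, n_draws = n_draws,
           discrepancies = unique(logs))
  }
  # cases whose cancellations involve only shift actions (exactly solvable)
  shift_cases <- paste0("case", c(1, 2, 3, 4, 5, 7, 8, 9, 10))
  list(per_case = per_case,
       shift_cases_reached = all(vapply(per_case[shift_cases], function(x)
         x$n_reached == x$n_draws, logical(1))),
       n_classes = length(optimal_system(alg)))
}
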