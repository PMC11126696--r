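# the PDE container and residual operations

test_that("exact solutions give an exactly zero symbolic residual", {
  m <- dna_model()
  expect_identical(pde_residual(quote(c1 * z + c2), m), quote(0))
  expect_identical(pde_residual(quote(0), m), quote(0))
  expect_identical(pde_residual(quote(c1 * t + c2), m), quote(0))
})

test_that("a non-solution leaves the residual computed by direct differentiation", {
  m <- dna_model(alpha = 1, gamma = 1, beta = 1)
  res <- pde_residual(quote(sin(z)), m)
  expect_false(symbolic_zero(res))
  # oracle: direct substitution gives sin(z) - 2*cos(z)*sin(z) at these params
  # (u_tt = 0, -u_zz = sin z, u_zztt = 0, -2 u_z u_zz = -2 cos z (-sin z))
  oracle <- quote(sin(z) + 2 * cos(z) * sin(z))
  diff <- call("-", res, oracle)
  expect_true(sym_is_zero_num(diff, seed = 2))
})

test_that("residual is quasilinear: deviation from additivity is the nonlinear cross flux", {
  m <- dna_model()
  set.seed(7)
  for (i in 1:4) {
    u1 <- str2lang(paste0(sample(1:3, 1), "*z^2*t + ", sample(1:3, 1), "*t^3"))
    u2 <- str2lang(paste0(sample(1:3, 1), "*z^3 + ", sample(1:3, 1), "*z*t^2"))
    lhs <- call("-", call("-", pde_residual(call("+", u1, u2), m),
                          pde_residual(u1, m)), pde_residual(u2, m))
    # cross term of -gamma (u_z^2)_z: -2 gamma (u1_z u2_z)_z
    cross <- call("*", quote(-2 * gamma),
                  sym_d(call("*", sym_d(u1, "z"), sym_d(u2, "z")), "z"))
    expect_true(symbolic_zero(call("-", lhs, cross)))
  }
})

test_that("numeric residual: exact solutions vanish on the grid, non-solutions do not", {
  m <- dna_model(alpha = 1, gamma = 1, beta = 1)
  grid <- list(z = c(0, 1), t = c(0, 1), n = c(20, 20))
  r1 <- numeric_residual(quote(c1 * t + c2), m, grid, constraints = list(c1 = 1, c2 = 2))
  expect_true(r1$symbolic_zero)
  expect_identical(r1$max_abs_residual, 0)
  r2 <- numeric_residual(quote(z * t^2), m, grid)
  expect_gt(r2$max_abs_residual, 0.1)
  # the sqrt-profile invariant solution: symbolic zero implies tiny grid residual
  sols <- invariant_solutions(m)
  u51 <- sym_subst(sols$L7.plus$expression, list(c1 = 1, c2 = 1))
  r3 <- numeric_residual(u51, m, list(z = c(0, 1), t = c(0, 1), n = c(50, 50)))
  expect_true(r3$symbolic_zero)
  expect_lt(r3$max_abs_residual, 1e-8)
})

test_that("black-box candidates are handled by finite differences, poles masked", {
  m <- dna_model(alpha = 1, gamma = 1, beta = 1)
  f <- function(z, t) 3 * t + 2          # exact solution as a function
  r <- numeric_residual(f, m, list(z = c(0, 1), t = c(0, 1), n = c(10, 10)))
  expect_lt(r$max_abs_residual, 1e-6)
  g <- function(z, t) 1 / (z - 0.5)      # pole inside the window
  rg <- numeric_residual(g, m, list(z = c(0, 1), t = c(0, 1), n = c(11, 5)))
  expect_gt(rg$n_masked, 0)
})

test_that("model invariants are enforced and the report serializes", {
  expect_error(dna_model(gamma = 0), "nonzero")
  expect_error(dna_model(alpha = 0), "nonzero")
  r <- numeric_residual(quote(c1 * z + c2), dna_model(1.2, 0.7, 0.4),
                        list(z = c(0, 1), t = c(0, 1), n = c(5, 5)),
                        constraints = list(c1 = 1, c2 = 0))
  js <- residual_report_json(r)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$max_abs_residual, r$max_abs_residual)
})
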