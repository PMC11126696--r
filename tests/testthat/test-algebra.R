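# structure constants, commutator/adjoint tables, Jacobi identity

# expected structure constants: the only nonzero brackets are
# [Y1,Y4] = Y2, [Y1,Y5] = Y1, [Y2,Y5] = -2 Y2, [Y3,Y5] = -(alpha^2/gamma) Y2,
# [Y4,Y5] = -3 Y4 (and antisymmetric partners)
expected_sc <- function(m, n, p) {
  key <- paste(m, n, p)
  tab <- list("1 4 2" = "1", "1 5 1" = "1", "2 5 2" = "-2",
              "3 5 2" = "-alpha^2/gamma", "4 5 4" = "-3")
  if (!is.null(tab[[key]])) return(rf_of(tab[[key]]))
  key2 <- paste(n, m, p)
  if (!is.null(tab[[key2]])) return(rf_neg(rf_of(tab[[key2]])))
  rf_zero()
}

test_that("every commutator-table cell reproduces symbolically", {
  alg <- dna_algebra()
  for (m in 1:5) for (n in 1:5) for (p in 1:5)
    expect_true(rf_equal(structure_constant(alg, m, n, p), expected_sc(m, n, p)),
                info = sprintf("c[%d,%d,%d]", m, n, p))
})

test_that("commutator examples: [Y1,Y4], antisymmetry, [Y5,Y3]", {
  Ys <- symmetry_basis()
  expect_true(vf_equal(commutator(Ys[[1]], Ys[[4]]), Ys[[2]]))
  expect_true(dnalie:::vf_is_zero(commutator(Ys[[2]], Ys[[2]])))
  c53 <- commutator(Ys[[5]], Ys[[3]])
  expect_true(mp_equal(c53$eta, mp_parse("alpha^2*gamma^-1")))
})

test_that("the Jacobi identity holds identically in alpha and gamma", {
  expect_true(jacobi_holds(dna_algebra()))
})

# expected adjoint table as coefficient functions of (eps, alpha, gamma):
# row m, column n |-> coefficients of Y1..Y5
expected_adjoint <- function(m, n, eps, alpha, gamma) {
  v <- numeric(5); v[n] <- 1
  if (m == 1 && n == 4) v[2] <- -eps
  if (m == 1 && n == 5) v[1] <- -eps
  if (m == 2 && n == 5) v[2] <- 2 * eps
  if (m == 3 && n == 5) v[2] <- alpha^2 / gamma * eps
  if (m == 4 && n == 1) v[2] <- eps
  if (m == 4 && n == 5) v[4] <- 3 * eps
  if (m == 5) {
    if (n == 1) v[1] <- exp(eps)
    if (n == 2) v[2] <- exp(-2 * eps)
    if (n == 3) v[2] <- alpha^2 / (2 * gamma) * (-1 + exp(-2 * eps))
    if (n == 4) v[4] <- exp(-3 * eps)
  }
  v
}

test_that("every adjoint-table cell reproduces (numeric check of the closed forms)", {
  alg <- dna_algebra()
  for (pars in list(c(alpha = 1.3, gamma = 0.7), c(alpha = 0.8, gamma = 1.9))) {
    for (eps in c(-0.7, 0.4)) {
      for (m in 1:5) {
        M <- adjoint_matrix_num(m, eps, pars, alg)
        for (n in 1:5)
          expect_equal(M[n, ], expected_adjoint(m, n, eps, pars["alpha"], pars["gamma"]),
                       tolerance = 1e-12, ignore_attr = TRUE,
                       info = sprintf("Ad(exp(eps Y%d)) Y%d", m, n))
      }
    }
  }
})

test_that("spot adjoint closed forms: exponential rates and couplings", {
  alg <- dna_algebra()
  a54 <- adjoint(5, 4, alg)
  expect_equal(a54$components[[4]]$rate, -3)
  expect_true(rf_equal(a54$components[[4]]$exp_coef, rf_of("1")))
  a51 <- adjoint(5, 1, alg)
  expect_equal(a51$components[[1]]$rate, 1)
  a53 <- adjoint(5, 3, alg)
  expect_true(rf_equal(a53$components[[2]]$exp_coef, rf_of("alpha^2/(2*gamma)")))
  expect_true(rf_equal(a53$components[[2]]$const, rf_of("-alpha^2/(2*gamma)")))
  # Ad(e^{eps Y2}) Y3 = Y3 (commuting pair)
  a23 <- adjoint(2, 3, alg)
  expect_true(rf_equal(a23$components[[3]]$const, rf_of("1")))
  expect_true(rf_is_zero(a23$components[[2]]$lin))
})

test_that("adjoint maps agree with the linear matrix ODE oracle to 1e-8", {
  for (m in 1:5) for (n in 1:5)
    expect_lt(adjoint_ode_deviation(m, n, eps_end = 0.9,
                                    params = c(alpha = 1.4, gamma = 0.6)),
              1e-8)
})

test_that("adjoint actions form one-parameter groups", {
  pars <- c(alpha = 1.2, gamma = 0.9)
  for (m in 1:5) {
    M1 <- adjoint_matrix_num(m, 0.3, pars)
    M2 <- adjoint_matrix_num(m, 0.5, pars)
    M12 <- adjoint_matrix_num(m, 0.8, pars)
    expect_equal(M1 %*% M2, M12, tolerance = 1e-10)
    expect_equal(adjoint_matrix_num(m, 0, pars), diag(5), tolerance = 1e-12)
  }
})
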