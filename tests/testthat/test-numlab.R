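# numeric integration of the unsolved reductions and figure profiles

test_that("the equilibrium of the scaling reduction stays at zero", {
  s <- solve_reduced_ode(ivp_spec("scaling", ic = c(h = 0, h1 = 0)), n_out = 201L)
  expect_identical(max(abs(s$trajectory$h)), 0)
})

test_that("a small perturbation oscillates with tiny a posteriori residual", {
  s <- solve_reduced_ode(ivp_spec("scaling", ic = c(h = 0.1, h1 = 0)), n_out = 2001L)
  expect_false(s$stopped_early)
  expect_lt(s$max_residual, 1e-6)
  expect_lt(min(s$trajectory$h), 0)   # crosses zero: oscillatory
  expect_gt(max(s$trajectory$h), 0)
})

test_that("the singularity guard stops integration before the effective mass vanishes", {
  s <- solve_reduced_ode(ivp_spec("scaling", ic = c(h = 2, h1 = 0), sigma_end = 50),
                         n_out = 2001L)
  expect_true(s$stopped_early)
  expect_match(s$stop_reason, "guard")
  p <- as.list(s$spec$params)
  m_end <- 6 * p$beta - 2 * p$alpha^2 * p$gamma * tail(s$trajectory$h1, 1)
  expect_lt(abs(m_end), 1e-2)
})

test_that("the fourth-order shifted-frame reduction integrates with small residual on its window", {
  s <- solve_reduced_ode(ivp_spec("shifted_wave"), n_out = 1001L)
  expect_lt(s$max_residual, 1e-5)
})

test_that("halving tolerances leaves the trajectory unchanged to 1e-6", {
  s1 <- solve_reduced_ode(ivp_spec("scaling", rtol = 1e-8, atol = 1e-10), n_out = 501L)
  s2 <- solve_reduced_ode(ivp_spec("scaling", rtol = 5e-9, atol = 5e-11), n_out = 501L)
  expect_lt(max(abs(s1$trajectory$h - s2$trajectory$h)), 1e-6)
})

test_that("figure profiles are deterministic and reproduce spot values", {
  p1 <- sample_profiles(1, z_range = c(0, 1), n = 2L)
  # the polynomial-nature profile at z = 0, t = 1 equals (18 + 5^(3/2))/12
  expect_equal(p1$data$u[p1$data$z == 0 & p1$data$t == 1],
               (18 + 5^1.5) / 12, tolerance = 1e-12)
  # exponential wave at sigma = 0 (z = t) reduces to the background b0 = 1
  p5 <- sample_profiles(5, z_range = c(0, 0), n = 1L)
  expect_equal(p5$data$u[p5$data$t == 0], 1, tolerance = 1e-12)
  # determinism: repeated sampling is identical
  a <- sample_profiles(3, z_range = c(-2, 2), n = 41L)
  b <- sample_profiles(3, z_range = c(-2, 2), n = 41L)
  expect_identical(a$data, b$data)
  expect_identical(a$n_masked, b$n_masked)
})

test_that("the singular wave's profile masks its pole", {
  p4 <- sample_profiles(4, z_range = c(-1, 1), n = 401L)
  expect_gt(p4$n_masked, 0)
})
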