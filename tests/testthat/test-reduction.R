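# similarity reductions and reduced-ODE matching

printed_odes <- list(
  L9 = "-H2*(2*gamma*H1 + alpha^2)",
  L6 = "H2",
  L7 = "-2*gamma*H1*H2 - alpha^2*H2 + 1",
  L4 = "H2",
  L5 = "-alpha^2*(alpha^2 - 2*gamma*H1 - 1)*H2 + beta*H4",
  L2 = "(-2*alpha^2*gamma*H1 + 6*beta)*H2 + 6*alpha^2*H0",
  L3 = paste0("beta*H4 - 2*alpha^2*((gamma*sigma + alpha^2/2 - gamma*H1",
              " - 1/2)*H2 - gamma*sigma - alpha^2/2 + gamma*H1)"))

test_that("similarity variables and solution forms match the printed conventions", {
  r9 <- class_reduction("L9")
  expect_identical(r9$sigma, quote(z))
  r7 <- class_reduction("L7")
  r7_p <- dnalie:::subst_calls(r7$u_form, ".h0", function(a) quote(0))
  expect_true(symbolic_zero(call("-", r7_p, quote(t^2 / 2))))
  expect_identical(r7$sigma, quote(z))
  r3 <- characteristic_invariants(optimal_representative("L3"))
  # u = -z^2/2 + z t + h(t - z)
  expect_true(symbolic_zero(call("-",
    dnalie:::subst_calls(r3$u_form, ".h0", function(a) quote(0)),
    quote(-z^2 / 2 + z * t))))
})

test_that("every reduced ODE matches its printed form up to a nonzero factor", {
  for (lab in names(printed_odes)) {
    red <- class_reduction(lab)
    m <- match_printed(red$reduced_ode, printed_odes[[lab]])
    expect_true(m$match, info = lab)
    expect_false(rf_is_zero(m$factor), info = lab)
  }
})

test_that("the sign-variant classes reduce to the printed variant equations", {
  m_minus <- match_printed(class_reduction("L7", sign = "-")$reduced_ode,
                           "2*gamma*H1*H2 + alpha^2*H2 + 1")
  expect_true(m_minus$match)
  expect_true(match_printed(class_reduction("L4", sign = "-")$reduced_ode, "H2")$match)
})

test_that("the scaling-class reduction reproduces its printed ODE exactly (factor -1/(2 alpha^2))", {
  m <- match_printed(class_reduction("L2")$reduced_ode, printed_odes$L2)
  expect_true(m$match)
  expect_true(rf_equal(m$factor, rf_of("-1/(2*alpha^2)")))
})

test_that("match_printed reports honest mismatches with a difference", {
  red <- class_reduction("L6")
  m <- match_printed(red$reduced_ode, "H2 + H1")
  expect_false(m$match)
  expect_false(mp_is_zero(m$difference))
})

test_that("generators acting only on u admit no similarity variable", {
  expect_error(characteristic_invariants(optimal_representative("L8")),
               "no invariant solution form")
  expect_error(characteristic_invariants(optimal_representative("L10")),
               "no invariant solution form")
})

test_that("each reduction's solution form is annihilated by its generator", {
  for (lab in c("L9", "L6", "L7", "L4", "L5", "L3", "L2"))
    expect_true(invariance_holds(class_reduction(lab)), info = lab)
})

test_that("the scaling-translation class yields an exp-weighted form flagged unverified", {
  red <- characteristic_invariants(optimal_representative("L1", c_value = 1), c_value = 1)
  expect_false(red$verified_convention)
  expect_true(invariance_holds(red))
})
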