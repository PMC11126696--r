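# quadrature integration and closed-form invariant solutions

test_that("the factored first-order case yields both printed branches", {
  sols <- integrate_reduced(class_reduction("L9")$reduced_ode)
  expect_length(sols, 2)
  expect_identical(sols[[1]]$h, quote(c1 * sigma + c2))
  # second branch: h = c1 - alpha^2/(2 gamma) sigma
  diff <- call("-", sols[[2]]$h, quote(c1 - alpha^2 / (2 * gamma) * sigma))
  expect_true(symbolic_zero(diff))
})

test_that("double integration of h''=0 gives the linear profile", {
  sols <- integrate_reduced(class_reduction("L4")$reduced_ode)
  expect_length(sols, 1)
  expect_identical(sols[[1]]$h, quote(c1 * sigma + c2))
})

test_that("the quadratic-in-h' case integrates to the printed 3/2-power profile", {
  sols <- integrate_reduced(class_reduction("L7")$reduced_ode)
  expect_length(sols, 2)
  printed <- quote((-6 * alpha^2 * gamma * sigma +
                      ((4 * c1 + 4 * sigma) * gamma + alpha^4)^(3 / 2)) /
                     (12 * gamma^2) + c2)
  expect_true(symbolic_zero(call("-", sols[[1]]$h, printed)))
  expect_match(sols[[1]]$domain, ">= 0")
  # the other square-root branch also solves the reduced ODE (checked
  # downstream through assembly)
})

test_that("ODEs containing the profile itself signal the numeric route", {
  s61 <- integrate_reduced(class_reduction("L2")$reduced_ode)
  expect_length(s61, 0)
  expect_true(attr(s61, "numeric_only"))
  s63 <- integrate_reduced(class_reduction("L3")$reduced_ode)
  expect_true(attr(s63, "numeric_only"))
})

printed_solutions <- list(
  L9.linear = quote(c1 * z + c2),
  L9.root = quote(c1 - alpha^2 / (2 * gamma) * z),
  L6.linear = quote(c1 * t + c2),
  L7.plus = quote(((6 * t^2 + 12 * c2) * gamma^2 - 6 * alpha^2 * gamma * z +
                     ((4 * c1 + 4 * z) * gamma + alpha^4)^(3 / 2)) / (12 * gamma^2)),
  L7.minus = quote(((-6 * t^2 + 12 * c2) * gamma^2 - 6 * alpha^2 * gamma * z +
                      ((-4 * c1 - 4 * z) * gamma + alpha^4)^(3 / 2)) / (12 * gamma^2)),
  L4.plus = quote((c1 + z) * t + c2),
  L4.minus = quote((c1 - z) * t + c2))

test_that("all seven printed invariant solutions are reproduced and verify to zero residual", {
  sols <- invariant_solutions()
  expect_length(sols, 7)
  for (nm in names(printed_solutions)) {
    s <- sols[[nm]]
    expect_true(s$residual_zero, info = nm)
    expect_true(symbolic_zero(call("-", s$expression, printed_solutions[[nm]])),
                info = nm)
  }
})

test_that("both square-root branches of the quadratic case verify against the PDE", {
  red <- class_reduction("L7")
  sols <- integrate_reduced(red$reduced_ode)
  for (s in sols) {
    a <- assemble(red, s)
    expect_true(a$residual_zero, info = s$branch)
  }
})

test_that("a wrong profile is returned flagged, with its residual attached", {
  red <- class_reduction("L6")
  bad <- list(h = quote(sigma^2), branch = "bogus", domain = "")
  a <- assemble(red, bad)
  expect_false(a$residual_zero)
  expect_false(identical(a$residual, quote(0)))
})
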