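# exact Laurent polynomial / rational-function engine

test_that("arithmetic is exact on rational coefficients and Laurent powers", {
  p <- mp_parse("(z + 2*t)^3 - z^3 - 6*t*z^2 - 12*t^2*z - 8*t^3")
  expect_true(mp_is_zero(p))
  q <- mp_parse("alpha^2/gamma * z - u/t^2")
  expect_equal(mp_eval(q, c(alpha = 2, gamma = 1, z = 3, u = 4, t = 2)), 11)
  # thirds stay exact: (x/3)*3 - x == 0
  r <- mp_sub(dnalie:::mp_scale(mp_var("x"), 1, 3), mp_parse("x/3"))
  expect_true(mp_is_zero(r))
  expect_true(mp_is_zero(mp_sub(mp_pow(mp_parse("1 - x"), 4),
                                mp_parse("1 - 4*x + 6*x^2 - 4*x^3 + x^4"))))
})

test_that("differentiation follows the product/power rules, including negative powers", {
  q <- mp_parse("alpha^2*gamma^-1*z - u*t^-2")
  expect_equal(mp_format(mp_deriv(q, "t")), "2*t^-3*u")
  set.seed(3)
  for (i in 1:5) {
    a <- mp_parse(paste0(sample(1:5, 1), "*x^", sample(1:4, 1), "*y^", sample(1:3, 1)))
    b <- mp_parse(paste0(sample(1:5, 1), "*x^", sample(0:3, 1)))
    lhs <- mp_deriv(mp_mul(a, b), "x")
    rhs <- mp_add(mp_mul(mp_deriv(a, "x"), b), mp_mul(a, mp_deriv(b, "x")))
    expect_true(mp_equal(lhs, rhs))
  }
})

test_that("differential-ring extension rules close exactly", {
  # tanh: F' = 1 - F^2
  lr <- expr_to_ring(quote(tanh(s)))
  dF <- mp_deriv(lr$poly, "s", lr$rules)
  expect_true(mp_is_zero(mp_sub(dF, mp_sub(mp_one(), mp_pow(lr$poly, 2)))))
  # d/dz of a 3/2-power: ((4*c1 + 4*z)*gamma + alpha^4)^(3/2) -> 6*gamma*sqrt(.)
  lr2 <- expr_to_ring(quote(((4 * c1 + 4 * z) * gamma + alpha^4)^(3 / 2)))
  d2 <- mp_deriv(lr2$poly, "z", lr2$rules)
  w <- names(lr2$rules)[1]
  expect_true(mp_equal(d2, mp_mul(mp_parse("6*gamma"), mp_var(w))))
  # exp: E' = a E under d/dx exp(a*x)
  lr3 <- expr_to_ring(quote(exp(a * x)))
  expect_true(mp_equal(mp_deriv(lr3$poly, "x", lr3$rules),
                       mp_mul(mp_var("a"), lr3$poly)))
})

test_that("rational-function elimination finds exact nullspaces", {
  M <- list(list(rf_of("alpha"), rf_of("gamma")),
            list(rf_of("alpha^2"), rf_of("alpha*gamma")))
  ns <- rf_nullspace(M, 2)
  expect_length(ns, 1)
  # nullspace vector is (-gamma/alpha, 1) up to scale
  v <- ns[[1]]
  expect_true(rf_equal(dnalie:::rf_mul(v[[1]], rf_of("alpha")),
                       rf_neg(dnalie:::rf_mul(v[[2]], rf_of("gamma")))))
  # full-rank system has empty nullspace
  M2 <- list(list(rf_of("1"), rf_of("0")), list(rf_of("0"), rf_of("gamma")))
  expect_length(rf_nullspace(M2, 2), 0)
})

test_that("symbolic differentiation of expressions handles the analysis toolkit", {
  d <- sym_d(quote(tanh(2 * z)^2), "z")
  vals <- c(z = 0.37)
  num <- (function(h) (tanh(2 * (0.37 + h))^2 - tanh(2 * (0.37 - h))^2) / (2 * h))(1e-6)
  expect_equal(sym_eval(d, as.list(vals)), num, tolerance = 1e-8)
  expect_error(sym_d(quote(abs(z)), "z"), "not differentiable")
  # randomized identity testing distinguishes identities from near-misses
  expect_true(sym_is_zero_num(quote(sin(x)^2 + cos(x)^2 - 1), seed = 1))
  expect_false(sym_is_zero_num(quote(sin(x)^2 - cos(x)^2), seed = 1))
})
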