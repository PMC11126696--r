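# prolongation, determining equations, symmetry verification

test_that("prolongation of translations and t d/du matches hand computation", {
  pf_u <- prolong(vector_field(0, 0, 1), 4)
  for (j in setdiff(names(pf_u$eta), "u"))
    expect_true(mp_is_zero(pf_u$eta[[j]]))
  pf4 <- prolong(vector_field(0, 0, "t"), 2)
  expect_true(mp_equal(pf4$eta$ut, mp_one()))
  expect_true(mp_is_zero(pf4$eta$uz))
  expect_true(mp_is_zero(pf4$eta$uzz))
  expect_error(prolong(vector_field(0, 0, 1), 5), "between 1 and 4")
})

test_that("prolongation agrees with the characteristic-formula oracle on random fields", {
  set.seed(11)
  for (i in 1:4) {
    rnd <- function() paste(sample(-2:2, 4, replace = TRUE),
                            c("1", "z*u", "t^2", "u^2"), sep = "*", collapse = " + ")
    X <- vector_field(rnd(), rnd(), rnd())
    a <- prolong(X, 3)
    b <- prolong_characteristic(X, 3)
    for (j in names(a$eta))
      expect_true(mp_equal(a$eta[[j]], b$eta[[j]]))
  }
})

test_that("prolongation is linear in the field", {
  X <- vector_field("z", "t^2", "u*t")
  Y <- vector_field("u", "1", "z^2")
  aXbY <- dnalie:::vf_scale(X, 3) + dnalie:::vf_scale(Y, -2)
  pa <- prolong(aXbY, 3)
  px <- prolong(X, 3); py <- prolong(Y, 3)
  for (j in names(pa$eta))
    expect_true(mp_equal(pa$eta[[j]],
                         mp_add(dnalie:::mp_scale(px$eta[[j]], 3),
                                dnalie:::mp_scale(py$eta[[j]], -2))))
})

test_that("the five printed generators and their combinations are symmetries", {
  Ys <- symmetry_basis()
  for (Y in Ys) expect_true(is_symmetry(Y))
  set.seed(13)
  for (i in 1:3) {
    co <- sample(-3:3, 5, replace = TRUE)
    comb <- Reduce(`+`, Map(vf_scale, Ys, co))
    expect_true(is_symmetry(comb))
  }
  # space scaling is not a symmetry
  expect_false(is_symmetry(vector_field("z", 0, 0)))
})

test_that("seeded negative-control fields all fail the symmetry condition", {
  fx <- generate_fixtures(seed = 0L, n = 5L)
  for (X in fx$neg_fields) expect_false(is_symmetry(X))
})

test_that("degree-2 determining system has a five-dimensional solution spanning the printed algebra", {
  sys <- determining_system(degree = 2L)
  basis <- solve_determining(sys)
  expect_length(basis, 5)
  expect_true(span_equal(basis, symmetry_basis()))
  # the general infinitesimal: phi1 constant, phi2 affine in t, eta affine
  for (X in basis) {
    expect_true(mp_is_zero(mp_deriv(X$phi1, "z")) &&
                  mp_is_zero(mp_deriv(X$phi1, "t")) &&
                  mp_is_zero(mp_deriv(X$phi1, "u")))
    expect_true(mp_is_zero(mp_deriv(mp_deriv(X$phi2, "t"), "t")))
    for (v in c("z", "t", "u"))
      for (w in c("z", "t", "u"))
        expect_true(mp_is_zero(mp_deriv(mp_deriv(X$eta, v), w)))
  }
})

test_that("degree-1 ansatz stays inside the printed span", {
  basis1 <- solve_determining(determining_system(degree = 1L))
  expect_lte(length(basis1), 5)
  for (X in basis1) expect_false(is.null(vf_in_basis(X, symmetry_basis())))
})

test_that("no further symmetries appear within a cubic ansatz", {
  sys3 <- determining_system(degree = 3L)
  expect_identical(determining_dimension(sys3, n_draws = 1L), 5L)
})

test_that("solved basis elements pass verify_symmetry exactly", {
  for (X in find_symmetries(degree = 2L))
    expect_true(mp_is_zero(verify_symmetry(X)))
})
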