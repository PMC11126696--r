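# auxiliary-equation method: Riccati transform, balancing, coefficient
# solve, 17-case catalogue, 24 waves

test_that("the Riccati image of the auxiliary equation is Theta-free", {
  aux <- aux_equation(1, -1, 1)
  ric <- to_riccati(aux)
  expect_identical(ric$quad, -1)   # coefficient of F^2 is g2
  expect_identical(ric$lin, 1)
  # tanh solves F' = 1 - F^2 (g1 = 0, g2 = -1, g3 = 1)
  r <- dnalie:::riccati_residual("tanh(sigma)", "-1", "0", "1")
  expect_true(r$zero)
  expect_error(aux_equation(theta = 1), "different from 1")
})

test_that("balancing gives k = 1 for the travelling ODE and k = 2 once integrated", {
  ode <- class_reduction("L5")$reduced_ode
  bal <- aux_balance(ode)
  expect_identical(bal$k, 1L)
  expect_identical(bal$k_integrated, 2L)
  expect_error(aux_balance(class_reduction("L6")$reduced_ode), "inapplicable")
})

test_that("the assembled coefficient system solves to the printed family modulo the recorded conflicts", {
  sys <- assemble_system(2L)
  expect_true(all(paste0("F", c(0, 3, 5, 7)) %in% names(sys$equations)))
  sol <- solve_aux_system(sys)
  expect_true(sol$verified)
  expect_true(rf_is_zero(sol$b$b2))      # quadratic coefficient drops out
  rep <- coefficient_report()
  expect_true(rep$b1_matches)            # numerator 6 G1 (alpha^2-1), denominator gamma (4 G1 G3 - G2^2)
  expect_true(rep$b2_matches)
  expect_false(rep$beta_matches)         # printed beta has the opposite sign
  expect_true(rep$beta_matches_up_to_sign)
})

test_that("degenerate ansatz degrees behave: k = 0 leaves no conditions", {
  sys0 <- assemble_system(0L)
  expect_length(sys0$equations, 0)
})

test_that("canonical Riccati solutions verify exactly in every discriminant class", {
  # D > 0: parametrise c = (b^2 - w^2)/(4 a)
  r <- dnalie:::riccati_residual(
    "-b/(2*a) - w/(2*a) * tanh(w/2 * (sigma - s0))",
    "a", "b", "(b^2 - w^2)/(4*a)")
  expect_true(r$zero)
  # D < 0: c = (b^2 + w^2)/(4 a)
  r2 <- dnalie:::riccati_residual(
    "-b/(2*a) + w/(2*a) * tan(w/2 * (sigma - s0))",
    "a", "b", "(b^2 + w^2)/(4*a)")
  expect_true(r2$zero)
  # D = 0: c = b^2/(4 a)
  r3 <- dnalie:::riccati_residual(
    "-b/(2*a) - 1/(a*(sigma - s0))", "a", "b", "b^2/(4*a)")
  expect_true(r3$zero)
  # a = 0: linear equation
  r4 <- dnalie:::riccati_residual("-c/b + exp(b*(sigma - s0))", "0", "b", "c")
  expect_true(r4$zero)
})

expected_classification <- c(
  "1.1" = "exact", "1.2" = "exact_after_reflection",
  "2.1" = "exact_after_reflection", "2.2" = "exact",
  "3.1" = "fails_printed", "3.2" = "fails_printed",
  "4.1" = "no_real_parameters",
  "5.1" = "fails_printed", "5.2" = "fails_printed",
  "6.1" = "fails_printed", "6.2" = "fails_printed",
  "7.1" = "exact", "7.2" = "exact",
  "8.1" = "fails_printed", "8.2" = "fails_printed",
  "9.1" = "exact", "10.1" = "exact_at_k1", "11.1" = "exact_at_k1",
  "12.1" = "exact_under_sign_twin", "13.1" = "exact",
  "14.1" = "exact_under_sign_twin", "15.1" = "exact",
  "16.1" = "exact", "17.1" = "exact")

test_that("all seventeen catalogue cases are classified, failures carrying a canonical repair", {
  rep <- catalogue_report()
  expect_identical(sort(unique(rep$case)), 1:17)
  got <- setNames(rep$classification, paste(rep$case, rep$branch, sep = "."))
  for (nm in names(expected_classification))
    expect_identical(got[[nm]], expected_classification[[nm]], info = nm)
  # every failing branch has a repaired canonical expression
  fails <- rep[rep$classification == "fails_printed", ]
  expect_true(all(nzchar(fails$repaired)))
  # none of the printed branches satisfies the auxiliary ODE read literally
  expect_false(any(rep$eq_aux_exact))
})

test_that("catalogue spot checks match the printed formulas", {
  cat9 <- printed_catalogue()[[9]]
  expect_match(cat9$F[[1]], "th1\\*sigma \\+ 2")
  cat16 <- printed_catalogue()[[16]]
  expect_match(cat16$F[[1]], "tan")
  cat10 <- printed_catalogue()[[10]]
  expect_identical(cat10$F[[1]], "exp(sigma) - 1")
  # case 10's exponential form verifies only when its k-dependence cancels
  expect_identical(verify_entry(10, 1, "derived")$classification, "fails_printed")
  expect_identical(verify_entry(10, 1, "derived", k_value = 1)$classification, "exact")
})

test_that("exact catalogue branches agree with numeric Riccati integration to 1e-6", {
  for (case_id in c(1, 2, 9, 13, 15, 16, 17)) {
    idn <- "derived"
    cls <- classify_entry(case_id, 1)
    if (!grepl("^exact", cls$classification)) next
    dev <- riccati_numeric_check(case_id, 1, cls$identification,
                                 reflected = grepl("reflection", cls$classification))
    expect_lt(dev, 1e-6, label = paste("case", case_id))
  }
})

test_that("twenty-four travelling waves are emitted with conditions and the sigma convention", {
  tw <- traveling_waves()
  expect_length(tw, 24)
  expect_true(all(vapply(tw, function(w) w$sigma_convention == "t - z", logical(1))))
  expect_identical(tw[[13]]$case_id, 7L)   # the dark-soliton tanh^2 wave
  expect_identical(tw[[24]]$case_id, 17L)
  expect_match(tw[[17]]$u_sigma, "exp\\(sigma\\) - 1")
})

test_that("the re-derived first-power waves verify end-to-end for every exact branch", {
  for (w in wave_index_table()) {
    d <- derived_wave(w$case_id, w$branch)
    if (grepl("^exact", d$classification)) {
      expect_true(d$symbolic_zero,
                  label = sprintf("derived wave case %d branch %d", w$case_id, w$branch))
      expect_true(d$b0_free)
    }
  }
})

test_that("printed squared waves verify only for the pure tanh/tan cases; residuals are never silent", {
  v13 <- verify_wave(13, "consistent", "derived")
  expect_true(v13$symbolic_zero)
  expect_true(v13$b0_free)
  v23 <- verify_wave(23, "consistent", "derived")
  expect_true(v23$symbolic_zero)
  v1 <- verify_wave(1, "consistent", "derived")
  expect_false(v1$symbolic_zero)
  expect_gt(v1$max_abs_residual, 1)
})

test_that("as-printed figure parameters make the dark-soliton radicals imaginary", {
  v <- verify_wave(13, "as_printed")
  # sqrt(-th2 th3) with th2 = th3 = 1 is imaginary under the caption values
  # (the squared bracket happens to come back real, which the report shows
  # through max_im ~ 0 alongside the radical flag)
  expect_true(v$imaginary_radicals)
  expect_lt(v$max_im, 1e-10)
  v17 <- verify_wave(17, "as_printed")
  expect_false(v17$imaginary_radicals)
  expect_lt(v17$max_im, 1e-12)
})
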