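# Deterministic covariate algebra: FFM, BSA, DMSA and the final
# individual-parameter equations.

test_that("fat-free mass reproduces the six-patient fixture to 1 d.p.", {
  tab <- table1_fixture()
  ffm <- fat_free_mass(tab$bw[1:5], tab$ht[1:5], tab$sex[1:5])
  expect_equal(round(ffm, 1), c(22.8, 23.8, 43.0, 10.3, 11.4))
  # patient 6 is a documented rounding/averaging artifact in the source
  # table (formula gives 35.3 from the baseline covariates)
  expect_equal(fat_free_mass(tab$bw[6], tab$ht[6], tab$sex[6]), 35.26,
               tolerance = 1e-3)
})

test_that("fat-free mass is monotone in body weight and sex-specific", {
  bw <- seq(5, 80, by = 5)
  ffm <- fat_free_mass(bw, 1.4, "male")
  expect_true(all(diff(ffm) > 0))
  expect_gt(fat_free_mass(30, 1.4, "male"),
            fat_free_mass(30, 1.4, "female"))
  expect_error(fat_free_mass(30, 1.4, "unknown"), "sex")
})

test_that("BSA formula, bounds and shape", {
  expect_equal(bsa(10), 47 / 100)
  expect_equal(bsa(90), 367 / 180)
  bw <- seq(1, 200, by = 1)
  expect_true(all(diff(bsa(bw)) > 0))
  expect_true(all(bsa(bw) < 4))
})

test_that("DMSA defaults to 85% of BSA", {
  expect_equal(dmsa_from_bw(11.4), 0.85 * 52.6 / 101.4)
  expect_equal(dmsa_from_bw(11.4), 0.441, tolerance = 1e-3)
  expect_equal(dmsa_from_bw(51), 0.85 * 211 / 141)
  expect_equal(dmsa_from_bw(51), 1.272, tolerance = 1e-3)
  expect_equal(dmsa_from_bw(10, coefficient = 1), bsa(10))
  expect_error(dmsa_from_bw(10, coefficient = 2), "coefficient")
})

test_that("individual equations return the typical values at reference", {
  typ <- c(cl = 0.186, v = 14.6, cldial = 1.98)
  ref <- individual_structural(typ, subject_covariates(bw = 70, dmsa = 1))
  expect_identical(ref$cl_residual, 0.186)
  expect_identical(ref$v_central, 14.6)
  expect_identical(ref$cl_dialysis, 1.98)

  half <- individual_structural(typ, subject_covariates(bw = 35, dmsa = 1))
  expect_equal(half$cl_residual, 0.186 * 0.5^0.75, tolerance = 1e-12)
  expect_equal(half$cl_residual, 0.1106, tolerance = 1e-3)
  expect_equal(half$v_central, 14.6 * 0.5)

  dbl <- individual_structural(typ, subject_covariates(bw = 70, dmsa = 1),
                               eta = c(cl = log(2)))
  expect_equal(dbl$cl_residual, 2 * 0.186, tolerance = 1e-12)
})

test_that("generic covariate-effect engine handles power and categorical", {
  typ <- c(cl = 0.2, v = 10, cldial = 1)
  covs <- subject_covariates(bw = 25, dmsa = 0.6, sex_num = 1)
  # exponent 0 is the identity
  e0 <- list(covariate_effect("cl", "bw", "power", 0, reference = 70))
  expect_equal(individual_structural(typ, covs, effects = e0)$cl_residual,
               0.2)
  # categorical fold-change 1 is the identity
  c1 <- list(covariate_effect("cl", "sex_num", "categorical", 1))
  expect_equal(individual_structural(typ, covs, effects = c1)$cl_residual,
               0.2)
  # categorical fold-change applies only to category 1
  c2 <- list(covariate_effect("v", "sex_num", "categorical", 1.5))
  expect_equal(individual_structural(typ, covs, effects = c2)$v_central,
               15)
  covs0 <- subject_covariates(bw = 25, dmsa = 0.6, sex_num = 0)
  expect_equal(individual_structural(typ, covs0, effects = c2)$v_central,
               10)
})

test_that("per-session membrane changes rescale dialysis clearance", {
  ses <- dialysis_sessions(c(0, 48), c(4, 52), dmsa = c(1.4, 1.7))
  scaled <- session_scales(ses, subject_dmsa = 1.55, beta = 1.26)
  expect_equal(scaled$clearance_scale, c((1.4 / 1.55)^1.26,
                                         (1.7 / 1.55)^1.26))
})
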