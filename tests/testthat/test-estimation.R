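# MAP-Bayes estimation, importance-sampling marginal likelihood, SAEM
# recovery and the covariate retention rule.

make_subject <- function(eta, bw = 20, b_err = 0.01,
                         model = population_model(
                           error = error_model("proportional", b = b_err))) {
  covs <- subject_covariates(bw = bw)
  inf <- infusion_events(seq(0, 144, by = 24), rep(0.5, 7),
                         rep(20 * bw, 7))
  ses <- dialysis_sessions(c(33, 81, 129), c(37, 85, 133))
  sch <- event_schedule(inf, ses, horizon = 168)
  tt <- c(0.5, 2, 6, 23.5, 33, 35, 37, 40, 71.5, 81, 85, 143.5)
  pars <- individual_structural(model$typicals, covs, eta, model$effects)
  obs <- data.frame(time = tt,
                    conc = simulate_profile(pars, sch, tt)$conc,
                    blq = FALSE)
  list(id = 1, schedule = sch, covariates = covs, obs = obs)
}

test_that("MAP recovers the generating etas from noise-free rich data", {
  eta0 <- c(cl = 0.6, v = -0.15, cldial = 0)
  model <- population_model(error = error_model("proportional", b = 0.01))
  subj <- make_subject(eta0, model = model)
  fitind <- map_individual(model, subj)
  expect_equal(fitind$eta[["cl"]], 0.6, tolerance = 1e-3)
  expect_equal(fitind$eta[["v"]], -0.15, tolerance = 1e-3)
  expect_equal(fitind$convergence, 0L)
  expect_equal(fitind$pred, subj$obs$conc, tolerance = 1e-3)
})

test_that("MAP limits: tight prior pins etas, flat prior gives the MLE", {
  eta0 <- c(cl = 0.6, v = -0.15, cldial = 0)
  subj <- make_subject(eta0)
  tight <- population_model(omega = c(cl = 1e-4, v = 1e-4, cldial = 0),
                            error = error_model("proportional", b = 0.3))
  expect_lt(max(abs(map_individual(tight, subj)$eta)), 1e-3)

  flat <- population_model(omega = c(cl = 10, v = 10, cldial = 0),
                           error = error_model("proportional", b = 0.01))
  expect_equal(map_individual(flat, subj)$eta[["cl"]], 0.6,
               tolerance = 1e-3)
})

test_that("a single trough at the typical prediction gives eta = 0", {
  # additive error: the observation sd does not depend on the prediction,
  # so the posterior mode coincides with the prior mode when the data sit
  # exactly on the typical curve (with prediction-dependent error the
  # -log sd term shifts the mode slightly)
  model <- population_model(error = error_model("additive", a = 2))
  covs <- subject_covariates(bw = 20)
  sch <- event_schedule(infusion_events(0, 0.5, 400), horizon = 24)
  pars <- individual_structural(model$typicals, covs,
                                effects = model$effects)
  trough <- simulate_profile(pars, sch, 23.5)$conc
  subj <- list(id = 1, schedule = sch, covariates = covs,
               obs = data.frame(time = 23.5, conc = trough, blq = FALSE))
  expect_lt(max(abs(map_individual(model, subj)$eta)), 1e-4)
  expect_error(map_individual(model, list(id = 1, schedule = sch,
                                          covariates = covs,
                                          obs = subj$obs[0, ])),
               "observation")
})

test_that("marginal likelihood: point prior is exact, IS matches quadrature", {
  model0 <- population_model(omega = c(cl = 0, v = 0, cldial = 0))
  subj <- make_subject(c(cl = 0, v = 0, cldial = 0), model = model0)
  ds <- pk_dataset(list(subj))
  cp <- compile_dataset(ds, model0)[[1]]
  exact <- loglik_subject(predict_compiled(cp, cp$mu), cp$y, model0$error)
  ml0 <- marginal_loglik(ds, model0, n_is = 50, seed = 1)
  expect_equal(ml0$loglik, exact, tolerance = 1e-12)

  # one free random effect: 1-D quadrature oracle
  model1 <- population_model(omega = c(cl = 0.5, v = 0, cldial = 0),
                             error = error_model("proportional", b = 0.2))
  subj1 <- make_subject(c(cl = 0.3, v = 0, cldial = 0), model = model1)
  set.seed(2)
  subj1$obs$conc <- subj1$obs$conc * (1 + 0.2 * rnorm(nrow(subj1$obs)))
  ds1 <- pk_dataset(list(subj1))
  cp1 <- compile_dataset(ds1, model1)[[1]]
  integrand <- function(e) {
    vapply(e, function(ei) {
      psi <- cp1$mu + c(ei, 0, 0)
      exp(loglik_subject(predict_compiled(cp1, psi), cp1$y,
                         model1$error)) * dnorm(ei, 0, 0.5)
    }, 0)
  }
  quad <- log(integrate(integrand, -3, 3, rel.tol = 1e-10)$value)
  is_est <- marginal_loglik(ds1, model1, n_is = 4000, seed = 3)$loglik
  expect_equal(is_est, quad, tolerance = 5e-4)

  # replicate runs with different seeds are stable
  reps <- vapply(11:16, function(s) {
    marginal_loglik(ds1, model1, n_is = 1000, seed = s)$loglik
  }, 0)
  expect_lt(sd(reps), 0.5)
})

test_that("SAEM is deterministic given seed and settings", {
  ds <- rich_design_dataset(n = 8, seed = 5)
  init <- population_model(typicals = c(cl = 0.4, v = 10, cldial = 1),
                           omega = c(cl = 0.4, v = 0.4, cldial = 0.2),
                           error = error_model("proportional", b = 0.3))
  st <- saem_settings(n_explore = 25, n_smooth = 15,
                      compute_loglik = FALSE)
  f1 <- fit_saem(ds, init, st, seed = 99)
  f2 <- fit_saem(ds, init, st, seed = 99)
  expect_identical(f1$model$typicals, f2$model$typicals)
  expect_identical(f1$model$omega, f2$model$omega)
  expect_identical(f1$ebe, f2$ebe)
})

test_that("SAEM recovers a low-noise generating model", {
  gen <- population_model(omega = c(cl = 0.2, v = 0.2, cldial = 0),
                          error = error_model("proportional", b = 0.05))
  ds <- rich_design_dataset(n = 40, model = gen, seed = 17)
  init <- population_model(typicals = c(cl = 0.4, v = 10, cldial = 1),
                           omega = c(cl = 0.5, v = 0.5, cldial = 0.3),
                           error = error_model("proportional", b = 0.3))
  fit <- fit_saem(ds, init,
                  saem_settings(n_explore = 150, n_smooth = 100,
                                compute_loglik = FALSE), seed = 4)
  expect_equal(fit$model$typicals[["cl"]], 0.186, tolerance = 0.05)
  expect_equal(fit$model$typicals[["v"]], 14.6, tolerance = 0.05)
  expect_equal(fit$model$typicals[["cldial"]], 1.98, tolerance = 0.05)
  expect_equal(fit$model$error$b, 0.05, tolerance = 0.3)
  # degenerate BSV on CLdial is recognized as (near) zero
  expect_lt(fit$model$omega[["cldial"]], 0.05)
})

test_that("shrinkage reflects the information content of the design", {
  gen <- population_model(omega = c(cl = 0.3, v = 0.2, cldial = 0),
                          error = error_model("proportional", b = 0.1))
  ds <- rich_design_dataset(n = 30, model = gen, seed = 23)
  init <- population_model(typicals = c(cl = 0.3, v = 12, cldial = 1.5),
                           omega = c(cl = 0.4, v = 0.4, cldial = 0.1),
                           error = error_model("proportional", b = 0.2))
  fit <- fit_saem(ds, init,
                  saem_settings(n_explore = 100, n_smooth = 80,
                                compute_loglik = FALSE), seed = 6)
  expect_lt(shrinkage(fit)[["cl"]], 15)

  # the same model on single-observation subjects: a lone end-of-infusion
  # peak says almost nothing about clearance, so its eta collapses to the
  # prior and shrinkage is large
  sparse <- ds
  sparse$subjects <- lapply(sparse$subjects, function(s) {
    s$obs <- s$obs[1, , drop = FALSE]   # one peak each
    s
  })
  fit_sp <- fit_saem(sparse, init,
                     saem_settings(n_explore = 60, n_smooth = 40,
                                   compute_loglik = FALSE), seed = 7)
  expect_gt(shrinkage(fit_sp)[["cl"]], 50)
})

test_that("covariate retention rule: real effects kept, absent ones not", {
  # generator WITH the membrane-area effect on dialysis clearance
  gen <- population_model(omega = c(cl = 0.3, v = 0.2, cldial = 0.3),
                          error = error_model("proportional", b = 0.1))
  ds <- rich_design_dataset(n = 30, model = gen, seed = 31)
  # base model ignores DMSA entirely
  base_eff <- list(covariate_effect("cl", "bw", "power", 0.75,
                                    reference = 70),
                   covariate_effect("v", "bw", "power", 1, reference = 70))
  init <- population_model(typicals = c(cl = 0.3, v = 12, cldial = 1.5),
                           effects = base_eff,
                           omega = c(cl = 0.4, v = 0.4, cldial = 0.4),
                           error = error_model("proportional", b = 0.2))
  st <- saem_settings(n_explore = 100, n_smooth = 80, n_is = 300)
  base_fit <- fit_saem(ds, init, st, seed = 8)
  cand <- covariate_effect("cldial", "dmsa", "power", 1, reference = 1,
                           estimate = TRUE)
  step <- covariate_step(ds, base_fit, cand, seed = 9)
  expect_true(step$retained)
  expect_lt(step$delta_BIC, 0)
  expect_lt(step$delta_BSV, 0)

  # re-proposing an effect that is already in the model cannot pay its
  # BIC penalty
  dup <- covariate_step(ds, step$fit, cand, seed = 10)
  expect_false(dup$retained)
})
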