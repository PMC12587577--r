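# Simulation-based diagnostics: NPDE calibration and direction, pc-VPC
# coverage and correction, goodness-of-fit tables.

test_that("NPDE of a correctly specified model is calibrated", {
  m <- cefazolin_hd_model()
  ds <- generate_study(study_design(seed = 301), m)
  res <- npde(ds, m, k_sim = 500, seed = 302)
  n <- nrow(res$table)
  expect_true(all(is.finite(res$table$npde)))
  expect_lt(abs(res$mean), 3 / sqrt(n))
  expect_gt(res$variance, 0.7)
  expect_lt(res$variance, 1.3)
  # clamping bounds the extremes at the simulation resolution
  expect_lte(max(abs(res$table$npde)), qnorm(1 - 1 / 1000) + 1e-12)
})

test_that("NPDE detects a misspecified clearance directionally", {
  m <- cefazolin_hd_model()
  ds <- generate_study(study_design(seed = 311), m)
  wrong <- m
  wrong$typicals[["cl"]] <- m$typicals[["cl"]] / 2
  wrong$typicals[["cldial"]] <- m$typicals[["cldial"]] / 2
  res <- npde(ds, wrong, k_sim = 300, seed = 312)
  # halved clearances inflate the simulated concentrations, so the
  # observations rank low among them: the NPDE mean is significantly
  # negative (and symmetric for the opposite misspecification)
  expect_lt(res$mean, 0)
  expect_lt(res$tests[["mean"]], 0.05)
  fast <- m
  fast$typicals[["cl"]] <- m$typicals[["cl"]] * 2
  fast$typicals[["cldial"]] <- m$typicals[["cldial"]] * 2
  res2 <- npde(ds, fast, k_sim = 300, seed = 313)
  expect_gt(res2$mean, 0)
})

test_that("npde input guards", {
  m <- cefazolin_hd_model()
  ds <- generate_study(study_design(seed = 321), m)
  expect_error(npde(ds, m, k_sim = 50, seed = 1), "k_sim")
  expect_error(npde(ds, m, k_sim = 500), "seed")
})

test_that("pc-VPC of a self-simulated dataset covers the observed percentiles", {
  m <- cefazolin_hd_model()
  ds <- generate_study(study_design(seed = 331), m)
  vpc <- pc_vpc(ds, m, n_sim = 300, bins = 6, seed = 332)
  expect_gte(vpc$coverage, 0.9)
  # percentiles are ordered in every bin, observed and simulated
  with(vpc$bins, {
    expect_true(all(obs_p5 <= obs_p50 & obs_p50 <= obs_p95))
    expect_true(all(pred_p5 <= pred_p50 & pred_p50 <= pred_p95))
    expect_true(all(lo_p50 <= hi_p50))
  })
  expect_error(pc_vpc(ds, m, n_sim = 1, seed = 1), "n_sim")
})

test_that("prediction correction is the identity for homogeneous subjects", {
  m <- population_model(omega = c(cl = 0.3, v = 0.2, cldial = 0),
                        error = error_model("proportional", b = 0.2))
  covs <- subject_covariates(bw = 20)
  sch <- event_schedule(infusion_events(0, 0.5, 400), horizon = 24)
  tt <- c(1, 6, 23)
  pars <- individual_structural(m$typicals, covs, effects = m$effects)
  pred <- simulate_profile(pars, sch, tt)$conc
  subjects <- lapply(1:4, function(i) {
    list(id = i, schedule = sch, covariates = covs,
         obs = data.frame(time = tt, conc = pred * (0.8 + 0.1 * i),
                          blq = FALSE))
  })
  ds <- pk_dataset(subjects)
  vpc <- pc_vpc(ds, m, n_sim = 50, bins = 3, seed = 3)
  # identical schedules and covariates -> every population prediction in
  # a bin equals the bin median -> corrected == raw observations
  expect_equal(vpc$table$pc_observed, vpc$table$observed,
               tolerance = 1e-12)
})

test_that("GOF tables: exact self-fit, residual spread, row count", {
  m <- cefazolin_hd_model()
  ds <- generate_study(study_design(seed = 341, noise = FALSE), m)
  truth <- attr(ds, "truth")
  ebe0 <- matrix(0, length(ds$subjects), 3,
                 dimnames = list(NULL, c("cl", "v", "cldial")))
  g0 <- gof_tables(ds, model = m, ebe = ebe0)
  expect_equal(nrow(g0), n_observations(ds))
  # noise-free data generated at eta = 0: individual predictions are the
  # observations exactly
  expect_equal(g0$ipred, g0$observed, tolerance = 1e-10)

  dsn <- generate_study(study_design(seed = 342), m)
  gn <- gof_tables(dsn, model = m, ebe = attr(dsn, "truth")$eta)
  # proportional error: absolute residuals grow with the prediction
  fitline <- lm(abs(gn$observed - gn$ipred) ~ gn$ipred)
  expect_gt(coef(fitline)[2], 0)
  # outlier screen flags nothing on clean data at the default threshold
  expect_equal(nrow(flag_outliers(gn)), 0)
})
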