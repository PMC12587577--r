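# The piecewise-analytic solver against closed forms and an independent
# adaptive-step ODE oracle.

test_that("breakpoints are the deduplicated union of event boundaries", {
  empty <- event_schedule(horizon = 24)
  expect_equal(breakpoints(empty), c(0, 24))

  one <- event_schedule(infusion_events(2, 1, 500),
                        dialysis_sessions(10, 14), horizon = 24)
  expect_equal(breakpoints(one), c(0, 2, 3, 10, 14, 24))

  # infusion end coinciding with session start collapses to one point
  touch <- event_schedule(infusion_events(9, 1, 500),
                          dialysis_sessions(10, 14), horizon = 24)
  expect_equal(breakpoints(touch), c(0, 9, 10, 14, 24))
})

test_that("schedule validation rejects malformed input", {
  expect_error(dialysis_sessions(c(0, 2), c(3, 6)), "overlap")
  expect_error(event_schedule(infusion_events(20, 1, 100), horizon = 10),
               "horizon")
  expect_error(structural_params(0, 14.6), "cl_residual")
  expect_error(structural_params(0.2, -1), "v_central")
  expect_error(structural_params(0.2, 14.6, q_inter = 1), "together")
})

test_that("infusion profile matches closed form and the ODE oracle", {
  p <- structural_params(0.186, 14.6)
  sch <- event_schedule(infusion_events(0, 1, 1000), horizon = 24)
  prof <- simulate_profile(p, sch, c(0.5, 1, 2, 12))
  # during the infusion: C(t) = R/CL (1 - exp(-CL t / V))
  expect_equal(prof$conc[2], 1000 / 0.186 * (1 - exp(-0.186 / 14.6)),
               tolerance = 1e-12)
  expect_equal(prof$conc[2], 68.0587, tolerance = 1e-5)
  ora <- ode_profile_oracle(p, sch, c(0.5, 1, 2, 12))
  expect_equal(prof$conc, ora, tolerance = 1e-7)
})

test_that("no input means zero concentration everywhere", {
  p <- structural_params(0.5, 10, 1)
  sch <- event_schedule(sessions = dialysis_sessions(4, 8), horizon = 24)
  expect_true(all(simulate_profile(p, sch, 0:24)$conc == 0))
})

test_that("a dialysis session removes the closed-form fraction", {
  # bolus-loaded compartment, one 4-h session covering the whole window
  p <- structural_params(0.0125, 4.171, 1.2)   # CLtot = 1.2125 L/h
  sch <- event_schedule(sessions = dialysis_sessions(0, 4), horizon = 4)
  prof <- simulate_profile(p, sch, c(0, 4), c0 = 100)
  removed <- 1 - prof$conc[2] / 100
  expect_equal(removed, 1 - exp(-1.2125 * 4 / 4.171), tolerance = 1e-12)
  expect_equal(removed, 0.6874, tolerance = 1e-4)
})

test_that("analytic engine agrees with the ODE oracle on random schedules", {
  set.seed(101)
  for (rep in 1:8) {
    sch <- random_schedule()
    p <- random_params()
    tt <- sort(runif(12, 0, sch$horizon))
    conc <- simulate_profile(p, sch, tt)$conc
    ora <- ode_profile_oracle(p, sch, tt)
    expect_lt(max(abs(conc - ora)) / max(ora, 1e-6), 1e-6)
  }
})

test_that("concentration is linear in dose and continuous at breakpoints", {
  set.seed(7)
  sch <- random_schedule()
  p <- random_params()
  tt <- sort(runif(20, 0, sch$horizon))
  base <- simulate_profile(p, sch, tt)$conc
  scaled_sch <- event_schedule(
    infusion_events(sch$infusions$start, sch$infusions$duration,
                    sch$infusions$amount * 3.7),
    sch$sessions, sch$horizon)
  expect_equal(simulate_profile(p, scaled_sch, tt)$conc, 3.7 * base,
               tolerance = 1e-12)
  # continuity across every breakpoint
  bp <- breakpoints(sch)
  inner <- bp[bp > 0 & bp < sch$horizon]
  eps <- 1e-7
  for (b in inner) {
    pair <- simulate_profile(p, sch, c(b - eps, b + eps))$conc
    expect_lt(abs(diff(pair)), 1e-4 * max(pair, 1))
  }
})

test_that("concentration decreases strictly when no infusion runs", {
  p <- structural_params(0.3, 8, 1.5)
  sch <- event_schedule(infusion_events(0, 1, 800),
                        dialysis_sessions(6, 10), horizon = 48)
  tt <- seq(1.01, 48, by = 0.25)
  conc <- simulate_profile(p, sch, tt)$conc
  expect_true(all(diff(conc) < 0))
})

test_that("mass balance closes: dose in = eliminated + remaining", {
  set.seed(21)
  for (rep in 1:5) {
    sch <- random_schedule()
    p <- random_params()
    dose_in <- sum(sch$infusions$amount)
    auc_tot <- exposure_metrics(p, sch, c(0, sch$horizon))$auc
    auc_ses <- 0
    if (nrow(sch$sessions)) {
      for (i in seq_len(nrow(sch$sessions))) {
        auc_ses <- auc_ses + exposure_metrics(
          p, sch, c(sch$sessions$start[i], sch$sessions$end[i]))$auc
      }
    }
    c_end <- simulate_profile(p, sch, sch$horizon)$conc
    eliminated <- p$cl_residual * auc_tot + p$cl_dialysis * auc_ses
    expect_equal(eliminated + c_end * p$v_central, dose_in,
                 tolerance = 1e-8)
  }
})

test_that("two-compartment solution decouples and matches the ODE oracle", {
  sch <- event_schedule(infusion_events(c(0, 12), c(1, 0.5), c(900, 600)),
                        dialysis_sessions(20, 24), horizon = 48)
  tt <- c(0.5, 1, 4, 12.25, 15, 21, 23, 30, 48)
  p1 <- structural_params(0.4, 9, 1.8)
  p2 <- structural_params(0.4, 9, 1.8, q_inter = 0, v_peripheral = 5)
  expect_equal(simulate_profile_2cmt(p2, sch, tt)$conc,
               simulate_profile(p1, sch, tt)$conc, tolerance = 1e-9)

  p3 <- structural_params(0.4, 9, 1.8, q_inter = 0.7, v_peripheral = 6)
  ora <- ode_profile_oracle_2cmt(p3, sch, tt)
  conc <- simulate_profile_2cmt(p3, sch, tt)$conc
  expect_lt(max(abs(conc - ora)) / max(ora), 1e-6)

  # enormous peripheral volume acts as an extra clearance early on
  p4 <- structural_params(0.4, 9, 0, q_inter = 0.7, v_peripheral = 1e7)
  p5 <- structural_params(0.4 + 0.7, 9, 0)
  short <- event_schedule(infusion_events(0, 1, 900), horizon = 6)
  expect_equal(simulate_profile_2cmt(p4, short, c(1, 3, 6))$conc,
               simulate_profile(p5, short, c(1, 3, 6))$conc,
               tolerance = 1e-3)
  expect_error(simulate_profile_2cmt(p1, sch, tt), "q_inter")
})

test_that("exposure metrics are exact (extrema, AUC, time in band)", {
  p <- structural_params(0.186, 14.6)
  sch <- event_schedule(infusion_events(0, 1, 1000), horizon = 240)
  em <- exposure_metrics(p, sch, c(0, Inf))
  expect_equal(em$auc, 1000 / 0.186, tolerance = 1e-10)  # dose / CL
  expect_equal(em$cmin, 0)

  fin <- exposure_metrics(p, sch, c(0, 240), band = c(0, Inf))
  expect_equal(fin$time_in_band, 1)
  expect_equal(fin$cmax, simulate_profile(p, sch, 1)$conc,
               tolerance = 1e-10)   # peak at end of infusion

  # band crossing on a pure decay: time above level L from peak C0 is
  # ln(C0/L)/k
  k <- 0.186 / 14.6
  c_peak <- fin$cmax
  lvl <- 30
  tib <- exposure_metrics(p, sch, c(1, 240), band = c(lvl, Inf))
  expect_equal(tib$time_in_band * 239, log(c_peak / lvl) / k,
               tolerance = 1e-6)
  expect_error(exposure_metrics(p, sch, c(10, 10)), "window")
})

test_that("half-life by phase follows ln2 V / CL", {
  p <- structural_params(0.186, 14.6, 1.98)
  expect_equal(half_life(p, "interdialytic"), log(2) * 14.6 / 0.186)
  expect_equal(half_life(p, "interdialytic"), 54.41, tolerance = 1e-3)
  expect_equal(half_life(p, "intradialytic"), log(2) * 14.6 / 2.166)
  expect_equal(half_life(p, "intradialytic"), 4.672, tolerance = 1e-3)
  p0 <- structural_params(0.186, 14.6, 0)
  expect_equal(half_life(p0, "interdialytic"),
               half_life(p0, "intradialytic"))
})
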