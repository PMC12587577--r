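# Study-like synthetic data.  The raw concentration data of the pediatric
# hemodialysis cohort are not publicly deposited, so this module generates
# stand-in datasets that reproduce the published design facts: six
# subjects with the reported covariates, 30-60 min infusions every 6-48 h,
# three dialysis sessions per week, sparse TDM-style sampling, and
# concentrations drawn from the population model with log-normal BSV and
# proportional residual error.  Every generator records the ground truth
# so estimation code can be tested by parameter recovery.

#' The six-patient covariate fixture
#'
#' Baseline characteristics of the six study-like patients: body weight,
#' height, sex, mean serum albumin, dialysis membrane surface area,
#' dialysis-session counts and involvement duration.  Patient 6 used two
#' membranes (1.4 and 1.7 m^2); the subject-level DMSA is their mean and
#' the per-session values are carried separately.
#'
#' @return A data.frame with one row per patient.
#' @export
table1_fixture <- function() {
  data.frame(
    id = 1:6,
    age = c(11.0, 11.2, 14.6, 1.3, 4.5, 14.3),
    sex = c("male", "male", "male", "male", "male", "female"),
    bw = c(23.2, 24.5, 47.5, 11.4, 12.3, 51.0),
    ht = c(1.35, 1.36, 1.70, 0.83, 0.89, 1.64),
    albumin = c(26.1, 29.2, 47.0, 37.2, 26.3, 34.6),
    dmsa = c(1, 1, 1.5, 0.2, 0.3, 1.55),
    n_sessions = c(1L, 10L, 3L, 13L, 6L, 13L),
    involvement_days = c(4L, 17L, 7L, 15L, 10L, 31L)
  )
}

#' Study design configuration for the synthetic generator
#'
#' Defaults emulate the observed study: six subjects with the fixture
#' covariates, doses of 5-26 mg/kg infused over 30-60 min at intervals
#' drawn from 6/8/12/24/48 h, three 4-h dialysis sessions per week (days
#' 3, 5, 8 of a weekly cycle, i.e. session starts at cycle hours 9, 57 and
#' 105), and sparse TDM sampling (troughs, end-of-infusion peaks, pre- and
#' post-dialysis samples).
#'
#' @param n_subjects Number of subjects (ignored when
#'   `covariate_source = "table1"`).
#' @param covariate_source `"table1"` (the six-patient fixture) or
#'   `"sampled"` (body weight uniform on `bw_range`, DMSA = 0.85 BSA).
#' @param bw_range Body-weight range, kg, for sampled covariates.
#' @param sessions_per_week,session_starts,session_duration Weekly
#'   dialysis pattern: session start hours within the 168-h cycle and
#'   duration (h).
#' @param dose_interval_set Allowed dosing intervals, h (one drawn per
#'   subject).
#' @param dose_mgkg_range Per-infusion dose range, mg/kg.
#' @param infusion_duration_range Infusion duration range, h.
#' @param horizon_days Study length per subject, days; `NA` with the
#'   table1 source uses each patient's involvement duration.
#' @param sampling `"tdm"` (sparse routine-care times) or `"rich"` (a
#'   12-point schedule with intra- and post-dialysis samples).
#' @param noise Apply BSV and residual error? `FALSE` yields noise-free
#'   typical-prediction data (for oracle tests).
#' @param seed Integer seed (mandatory).
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_subjects = 6,
                         covariate_source = c("table1", "sampled"),
                         bw_range = c(10, 70),
                         sessions_per_week = 3,
                         session_starts = c(9, 57, 105),
                         session_duration = 4,
                         dose_interval_set = c(6, 8, 12, 24, 48),
                         dose_mgkg_range = c(5, 26),
                         infusion_duration_range = c(0.5, 1),
                         horizon_days = NA,
                         sampling = c("tdm", "rich"),
                         noise = TRUE,
                         seed) {
  if (missing(seed)) stop("'seed' is required")
  covariate_source <- match.arg(covariate_source)
  sampling <- match.arg(sampling)
  stopifnot(n_subjects >= 1, all(bw_range > 0), session_duration > 0,
            all(dose_interval_set > 0), all(dose_mgkg_range > 0),
            all(infusion_duration_range > 0))
  structure(list(n_subjects = n_subjects,
                 covariate_source = covariate_source, bw_range = bw_range,
                 sessions_per_week = sessions_per_week,
                 session_starts = session_starts,
                 session_duration = session_duration,
                 dose_interval_set = dose_interval_set,
                 dose_mgkg_range = dose_mgkg_range,
                 infusion_duration_range = infusion_duration_range,
                 horizon_days = horizon_days, sampling = sampling,
                 noise = noise, seed = as.integer(seed)),
            class = "study_design")
}

# weekly session pattern unrolled over a horizon
unroll_sessions <- function(session_starts, session_duration, horizon) {
  starts <- numeric()
  week <- 0
  repeat {
    s <- session_starts + 168 * week
    s <- s[s + session_duration <= horizon]
    if (!length(s)) break
    starts <- c(starts, s)
    week <- week + 1
    if (168 * week > horizon) break
  }
  dialysis_sessions(starts, starts + session_duration)
}

# sparse TDM-style sampling times for one subject's schedule: an
# end-of-infusion peak on the first dose of every few days, a pre-dose
# trough on the first dose of every other day, and paired pre-/post-
# dialysis samples for every other session -- routine-care density
# (~10-20 samples per subject depending on involvement)
tdm_sampling_times <- function(infusions, sessions, horizon) {
  tt <- numeric()
  ends <- infusions$start + infusions$duration
  day <- floor(infusions$start / 24)
  first_of_day <- !duplicated(day)
  peak_days <- unique(day)[seq_along(unique(day)) %% 7L == 1L]
  tt <- c(tt, (ends[first_of_day])[unique(day) %in% peak_days] + 0.1)
  trough_days <- unique(day)[seq_along(unique(day)) %% 2L == 0L]
  tt <- c(tt, (infusions$start[first_of_day])[unique(day) %in%
                                                trough_days] - 0.1)
  if (nrow(sessions)) {
    pick <- seq_len(nrow(sessions)) %% 2L == 1L
    tt <- c(tt, sessions$start[pick] - 0.1, sessions$end[pick] + 0.1)
  }
  tt <- tt[tt > 0 & tt <= horizon]
  sort(unique(round(tt, 6)))
}

# the 12-point rich schedule used for recovery experiments (q24 dosing,
# sessions on days 2/4/6 starting at 33/81/129 h): an end-of-infusion
# peak, three well-spaced interdialytic troughs, and dense sampling
# through two dialysis sessions (start, intra, end, post) -- the
# intradialytic decay is what identifies the dialysis clearance, so most
# of the sampling budget sits there
rich_sampling_times <- function() {
  c(0.5, 23.5, 33, 34.5, 36, 37, 38, 71.5, 81, 83, 85, 143.5)
}

#' Generate a study-like synthetic dataset
#'
#' Builds per-subject event schedules according to the design, samples
#' random effects from the population model, simulates concentrations
#' with the exact PK engine and applies residual error.  The returned
#' dataset carries a `truth` attribute (generating model, per-subject
#' etas and noise-free predictions) for parameter-recovery tests.
#'
#' @param config A [study_design()].
#' @param model A [population_model()] (default: the reference cefazolin
#'   hemodialysis model).
#' @return A [pk_dataset()] with attribute `truth`.
#' @export
generate_study <- function(config, model = cefazolin_hd_model()) {
  stopifnot(inherits(config, "study_design"),
            inherits(model, "population_model"))
  set.seed(config$seed)
  if (config$covariate_source == "table1") {
    tab <- table1_fixture()
    covs <- lapply(seq_len(nrow(tab)), function(i) {
      subject_covariates(bw = tab$bw[i], ht = tab$ht[i], sex = tab$sex[i],
                         albumin = tab$albumin[i], dmsa = tab$dmsa[i])
    })
    horizons <- if (is.na(config$horizon_days)) {
      tab$involvement_days * 24
    } else rep(config$horizon_days * 24, nrow(tab))
  } else {
    n <- config$n_subjects
    bw <- stats::runif(n, config$bw_range[1], config$bw_range[2])
    covs <- lapply(bw, function(w) subject_covariates(bw = w))
    horizons <- rep(if (is.na(config$horizon_days)) 7 * 24 else
      config$horizon_days * 24, n)
  }
  n <- length(covs)
  subjects <- vector("list", n)
  truth_eta <- matrix(0, n, 3L, dimnames = list(NULL, c("cl", "v", "cldial")))
  truth_pred <- vector("list", n)
  for (i in seq_len(n)) {
    horizon <- horizons[i]
    tau <- sample(config$dose_interval_set, 1L)
    mgkg <- stats::runif(1L, config$dose_mgkg_range[1],
                         config$dose_mgkg_range[2])
    dur <- stats::runif(1L, config$infusion_duration_range[1],
                        config$infusion_duration_range[2])
    starts <- seq(0, horizon - dur - 1e-9, by = tau)
    inf <- infusion_events(starts, rep(dur, length(starts)),
                           rep(mgkg * covs[[i]]$bw, length(starts)))
    ses <- unroll_sessions(config$session_starts, config$session_duration,
                           horizon)
    sched <- event_schedule(inf, ses, horizon)
    tt <- if (config$sampling == "rich") {
      tm <- rich_sampling_times()
      tm[tm <= horizon]
    } else {
      tdm_sampling_times(inf, ses, horizon)
    }
    eta <- if (config$noise) stats::rnorm(3L, 0, model$omega) else c(0, 0, 0)
    names(eta) <- c("cl", "v", "cldial")
    truth_eta[i, ] <- eta
    pars <- individual_structural(model$typicals, covs[[i]], eta,
                                  model$effects)
    pred <- simulate_profile(pars, sched, tt)$conc
    truth_pred[[i]] <- pred
    conc <- if (config$noise) apply_residual_error(pred, model$error) else
      pred
    keep <- conc > 0          # proportional error can undershoot zero
    obs <- data.frame(time = tt[keep], conc = conc[keep],
                      blq = conc[keep] < 0.5)
    subjects[[i]] <- list(id = i, schedule = sched,
                          covariates = covs[[i]], obs = obs)
  }
  ds <- pk_dataset(subjects)
  attr(ds, "truth") <- list(model = model, eta = truth_eta,
                            pred = truth_pred, seed = config$seed)
  ds
}

#' The rich-design recovery experiment dataset
#'
#' Convenience wrapper for the standard parameter-recovery setting: `n`
#' virtual subjects with body weight uniform on 10-70 kg and
#' DMSA = 0.85 BSA, dosed 20 mg/kg over 30 min every 24 h for 7 days with
#' three 4-h dialysis sessions (days 2, 4, 6), and 12 samples per subject
#' including intra- and post-dialysis times.
#'
#' @param n Number of subjects (default 100).
#' @param model Generating [population_model()].
#' @param seed Integer seed.
#' @return A [pk_dataset()] with attribute `truth`.
#' @export
rich_design_dataset <- function(n = 100, model = cefazolin_hd_model(),
                                seed) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  bw <- stats::runif(n, 10, 70)
  subjects <- vector("list", n)
  truth_eta <- matrix(0, n, 3L, dimnames = list(NULL, c("cl", "v", "cldial")))
  horizon <- 168
  starts <- seq(0, 144, by = 24)
  ses <- dialysis_sessions(c(33, 81, 129), c(37, 85, 133))
  tt <- rich_sampling_times()
  for (i in seq_len(n)) {
    covs <- subject_covariates(bw = bw[i])
    inf <- infusion_events(starts, rep(0.5, length(starts)),
                           rep(20 * bw[i], length(starts)))
    sched <- event_schedule(inf, ses, horizon)
    eta <- stats::rnorm(3L, 0, model$omega)
    names(eta) <- c("cl", "v", "cldial")
    truth_eta[i, ] <- eta
    pars <- individual_structural(model$typicals, covs, eta, model$effects)
    pred <- simulate_profile(pars, sched, tt)$conc
    conc <- apply_residual_error(pred, model$error)
    keep <- conc > 0
    subjects[[i]] <- list(id = i, schedule = sched, covariates = covs,
                          obs = data.frame(time = tt[keep],
                                           conc = conc[keep],
                                           blq = FALSE))
  }
  ds <- pk_dataset(subjects)
  attr(ds, "truth") <- list(model = model, eta = truth_eta, seed = seed)
  ds
}

#' Multiply selected observations to emulate assay outliers
#'
#' `k` randomly chosen observations are multiplied (odd picks) or divided
#' (even picks) by `magnitude`; the affected rows are recorded in the
#' dataset's `outliers` attribute so residual-based flagging can be
#' validated against ground truth.
#'
#' @param dataset A [pk_dataset()].
#' @param k Number of outliers (`k <=` total observations).
#' @param magnitude Fold-change applied (> 1).
#' @param seed Integer seed.
#' @return The modified dataset.
#' @export
inject_outliers <- function(dataset, k, magnitude = 5, seed) {
  stopifnot(inherits(dataset, "pk_dataset"), magnitude > 1)
  if (missing(seed)) stop("'seed' is required")
  nper <- vapply(dataset$subjects, function(s) nrow(s$obs), 0L)
  total <- sum(nper)
  if (k > total) stop("'k' exceeds the number of observations")
  if (k == 0) {
    attr(dataset, "outliers") <- data.frame(subject = integer(),
                                            row = integer(),
                                            factor = numeric())
    return(dataset)
  }
  set.seed(seed)
  picks <- sort(sample.int(total, k))
  cum <- cumsum(nper)
  rec <- data.frame(subject = integer(k), row = integer(k),
                    factor = numeric(k))
  for (j in seq_len(k)) {
    subj <- which(picks[j] <= cum)[1L]
    row <- picks[j] - if (subj > 1L) cum[subj - 1L] else 0L
    fac <- if (j %% 2L == 1L) magnitude else 1 / magnitude
    dataset$subjects[[subj]]$obs$conc[row] <-
      dataset$subjects[[subj]]$obs$conc[row] * fac
    rec[j, ] <- list(subj, row, fac)
  }
  attr(dataset, "outliers") <- rec
  dataset
}
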