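# Multi-subject observation dataset: per subject an event schedule, the
# covariates, and the measured concentrations.

#' Assemble a multi-subject PK dataset
#'
#' @param subjects A list; each element is a list with fields `id`,
#'   `schedule` ([event_schedule()]), `covariates`
#'   ([subject_covariates()]), and `obs` (data.frame with columns `time`
#'   (h), `conc` (mg/L) and optionally `blq` (logical, below limit of
#'   quantification)).
#' @param loq Lower limit of quantification of the assay, mg/L (default
#'   0.5, the bottom of the validated calibration range). Observations
#'   flagged BLQ are excluded from fitting with a logged count.
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(subjects, loq = 0.5) {
  for (s in subjects) {
    if (is.null(s$schedule) || !inherits(s$schedule, "event_schedule")) {
      stop("each subject needs an 'event_schedule'")
    }
    if (is.null(s$obs) || !all(c("time", "conc") %in% names(s$obs))) {
      stop("each subject needs 'obs' with columns time, conc")
    }
    if (any(s$obs$time < 0 | s$obs$time > s$schedule$horizon + 1e-9)) {
      stop("observation times must lie within the schedule horizon")
    }
    blq <- if (!is.null(s$obs$blq)) s$obs$blq else rep(FALSE, nrow(s$obs))
    if (any(s$obs$conc[!blq] <= 0)) {
      stop("non-BLQ concentrations must be > 0")
    }
  }
  structure(list(subjects = subjects, loq = loq), class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) nrow(s$obs), 0L))
  cat(sprintf("PK dataset: %d subject(s), %d observation(s), LOQ %.3g mg/L\n",
              length(x$subjects), nobs, x$loq))
  invisible(x)
}

#' Number of (quantifiable) observations
#' @param dataset A [pk_dataset()].
#' @param include_blq Count BLQ rows too?
#' @return Integer count.
#' @export
n_observations <- function(dataset, include_blq = FALSE) {
  sum(vapply(dataset$subjects, function(s) {
    blq <- if (!is.null(s$obs$blq)) s$obs$blq else rep(FALSE, nrow(s$obs))
    if (include_blq) nrow(s$obs) else sum(!blq)
  }, 0L))
}

# Pre-compile every subject for repeated likelihood evaluation: segment
# tables at the observation times, the quantifiable observation vector,
# and the design information of the covariate model.
compile_dataset <- function(dataset, model) {
  lapply(dataset$subjects, function(s) {
    blq <- if (!is.null(s$obs$blq)) s$obs$blq else rep(FALSE, nrow(s$obs))
    obs <- s$obs[!blq, , drop = FALSE]
    ord <- order(obs$time)
    obs <- obs[ord, , drop = FALSE]
    cs <- compile_schedule(s$schedule, obs$time)
    list(id = s$id, cs = cs, y = obs$conc, times = obs$time,
         covariates = s$covariates, n_blq = sum(blq),
         mu = log_typical_individual(model, s$covariates))
  })
}

# predicted concentrations at the observation times for one compiled
# subject given individual log-parameters psi = (log CL, log V, log CLdial)
predict_compiled <- function(cp, psi) {
  conc <- eval_conc_grid(cp$cs, exp(psi[1L]), exp(psi[2L]), exp(psi[3L]))
  conc[cp$cs$obs_idx]
}
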