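# File formats and configuration.  Datasets travel as three CSV files in
# the conventional pharmacometric event layout (comma-separated, '.'
# decimal, header row mandatory):
#   events:     ID, TIME (h), EVID (0 obs / 1 dose), AMT (mg), RATE (mg/h)
#               or DURATION (h), DV (mg/L), MDV
#   sessions:   ID, START, END, DMSA (optional), SCALE (optional)
#   covariates: ID, BW (kg), HT (cm), SEX, ALB (g/L), DMSA (optional),
#               HORIZON (h, optional)
# Run configuration is a YAML (or JSON) file with blocks `model`,
# `estimation`, `simulation`, `dosing` plus `seed` and `output_dir`.

require_columns <- function(df, cols, file) {
  miss <- setdiff(cols, toupper(names(df)))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s) %s", file,
                 paste(miss, collapse = ", ")))
  }
}

#' Read a PK dataset from event, session and covariate CSV files
#'
#' @param event_csv Path to the event file. Dose rows (`EVID = 1`) need
#'   `AMT` plus either `RATE` (mg/h) or `DURATION` (h); observation rows
#'   (`EVID = 0`) need `DV` (mg/L). Times are hours from each subject's
#'   first event.
#' @param sessions_csv Path to the dialysis-session file (may describe no
#'   sessions for some subjects).
#' @param covariates_csv Path to the covariate file (`HT` in cm,
#'   converted to m internally).
#' @param loq Assay limit of quantification, mg/L.
#' @return A [pk_dataset()].
#' @export
read_pk_dataset <- function(event_csv, sessions_csv, covariates_csv,
                            loq = 0.5) {
  for (f in c(event_csv, sessions_csv, covariates_csv)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  ev <- utils::read.csv(event_csv)
  names(ev) <- toupper(names(ev))
  require_columns(ev, c("ID", "TIME", "EVID"), event_csv)
  ses <- utils::read.csv(sessions_csv)
  names(ses) <- toupper(names(ses))
  if (nrow(ses)) require_columns(ses, c("ID", "START", "END"), sessions_csv)
  cov <- utils::read.csv(covariates_csv)
  names(cov) <- toupper(names(cov))
  require_columns(cov, c("ID", "BW"), covariates_csv)
  has_rate <- "RATE" %in% names(ev)
  has_dur <- "DURATION" %in% names(ev)
  subjects <- lapply(seq_len(nrow(cov)), function(i) {
    id <- cov$ID[i]
    e <- ev[ev$ID == id, , drop = FALSE]
    if (!nrow(e)) stop("no event rows for subject ", id)
    if (any(diff(e$TIME) < 0)) {
      bad <- which(diff(e$TIME) < 0)[1L] + 1L
      stop(sprintf("%s: times not sorted for subject %s (row %d)",
                   event_csv, id, which(ev$ID == id)[bad]))
    }
    doses <- e[e$EVID == 1, , drop = FALSE]
    if (nrow(doses)) {
      if (!"AMT" %in% names(e) || any(is.na(doses$AMT)) ||
          any(doses$AMT <= 0)) {
        stop(sprintf("%s: dose rows need AMT > 0 (subject %s)", event_csv,
                     id))
      }
      dur <- if (has_rate && !all(is.na(doses$RATE))) {
        if (any(is.na(doses$RATE) | doses$RATE <= 0)) {
          stop(sprintf("%s: dose without a positive RATE (subject %s, row %d)",
                       event_csv, id,
                       which(ev$ID == id)[e$EVID == 1][which(is.na(doses$RATE) |
                                                             doses$RATE <= 0)[1L]]))
        }
        doses$AMT / doses$RATE
      } else if (has_dur) {
        if (any(is.na(doses$DURATION) | doses$DURATION <= 0)) {
          stop(sprintf("%s: dose without RATE or DURATION (subject %s)",
                       event_csv, id))
        }
        doses$DURATION
      } else {
        stop(sprintf("%s: dose rows need a RATE or DURATION column",
                     event_csv))
      }
      inf <- infusion_events(doses$TIME, dur, doses$AMT)
    } else {
      inf <- infusion_events()
    }
    oo <- e[e$EVID == 0, , drop = FALSE]
    if (nrow(oo) && (!"DV" %in% names(e) || any(is.na(oo$DV)))) {
      stop(sprintf("%s: observation rows need DV (subject %s)", event_csv,
                   id))
    }
    si <- ses[ses$ID == id, , drop = FALSE]
    sd_tab <- if (nrow(si)) {
      dialysis_sessions(si$START, si$END,
                        if ("DMSA" %in% names(si)) si$DMSA else NA_real_,
                        if ("SCALE" %in% names(si)) si$SCALE else 1)
    } else dialysis_sessions()
    horizon <- if ("HORIZON" %in% names(cov) && !is.na(cov$HORIZON[i])) {
      cov$HORIZON[i]
    } else {
      max(e$TIME, if (nrow(si)) si$END else 0,
          if (nrow(doses)) max(inf$start + inf$duration) else 0)
    }
    covs <- subject_covariates(
      bw = cov$BW[i],
      ht = if ("HT" %in% names(cov) && !is.na(cov$HT[i]))
        cov$HT[i] / 100 else NA_real_,
      sex = if ("SEX" %in% names(cov)) tolower(as.character(cov$SEX[i]))
        else NA_character_,
      albumin = if ("ALB" %in% names(cov)) cov$ALB[i] else NA_real_,
      dmsa = if ("DMSA" %in% names(cov) && !is.na(cov$DMSA[i]))
        cov$DMSA[i] else NULL)
    obs <- data.frame(time = oo$TIME, conc = oo$DV,
                      blq = oo$DV < loq)
    list(id = id, schedule = event_schedule(inf, sd_tab, horizon),
         covariates = covs, obs = obs)
  })
  pk_dataset(subjects, loq = loq)
}

#' Write a PK dataset to the three-file CSV layout
#'
#' Inverse of [read_pk_dataset()]; `read_pk_dataset()` on the written
#' files reproduces the dataset.
#'
#' @param dataset A [pk_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"study"`).
#' @return Invisibly, the three file paths.
#' @export
write_pk_dataset <- function(dataset, dir, prefix = "study") {
  stopifnot(inherits(dataset, "pk_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- list(); ses <- list(); cov <- list()
  for (s in dataset$subjects) {
    inf <- s$schedule$infusions
    if (nrow(inf)) {
      ev[[length(ev) + 1L]] <- data.frame(
        ID = s$id, TIME = inf$start, EVID = 1L, AMT = inf$amount,
        RATE = inf$amount / inf$duration, DV = NA_real_, MDV = 1L)
    }
    if (nrow(s$obs)) {
      ev[[length(ev) + 1L]] <- data.frame(
        ID = s$id, TIME = s$obs$time, EVID = 0L, AMT = NA_real_,
        RATE = NA_real_, DV = s$obs$conc, MDV = 0L)
    }
    st <- s$schedule$sessions
    if (nrow(st)) {
      ses[[length(ses) + 1L]] <- data.frame(
        ID = s$id, START = st$start, END = st$end, DMSA = st$dmsa,
        SCALE = st$clearance_scale)
    }
    cv <- s$covariates
    cov[[length(cov) + 1L]] <- data.frame(
      ID = s$id, BW = cv$bw,
      HT = if (is.na(cv$ht)) NA_real_ else cv$ht * 100,
      SEX = cv$sex, ALB = cv$albumin, DMSA = cv$dmsa,
      HORIZON = s$schedule$horizon)
  }
  evd <- do.call(rbind, ev)
  evd <- evd[order(evd$ID, evd$TIME, -evd$EVID), , drop = FALSE]
  paths <- file.path(dir, paste0(prefix, c("_events.csv", "_sessions.csv",
                                           "_covariates.csv")))
  utils::write.csv(evd, paths[1L], row.names = FALSE)
  utils::write.csv(if (length(ses)) do.call(rbind, ses) else
    data.frame(ID = integer(), START = numeric(), END = numeric(),
               DMSA = numeric(), SCALE = numeric()),
    paths[2L], row.names = FALSE)
  utils::write.csv(do.call(rbind, cov), paths[3L], row.names = FALSE)
  invisible(paths)
}

#' Read a run configuration (YAML or JSON)
#'
#' Recognized top-level keys: `model`, `estimation`, `simulation`,
#' `dosing`, `seed`, `output_dir`, `verbosity`; unknown keys are
#' rejected.  The `model` block accepts `typicals`, `omega`, `error`
#' (`kind`, `a`, `b`), `structure` and an `effects` list (each with
#' `parameter`, `covariate`, `kind`, `value`, `reference`, `estimate`).
#'
#' @param path Path to the configuration file.
#' @return A list with a constructed `model` ([population_model()]) where
#'   a model block is present, plus the remaining blocks as lists.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("model", "estimation", "simulation", "dosing", "seed",
             "output_dir", "verbosity")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$model)) {
    mb <- cfg$model
    effects <- if (!is.null(mb$effects)) {
      lapply(mb$effects, function(e) {
        covariate_effect(e$parameter, e$covariate, e$kind, e$value,
                         if (is.null(e$reference)) 1 else e$reference,
                         isTRUE(e$estimate))
      })
    } else reference_effects()
    err <- if (!is.null(mb$error)) {
      error_model(mb$error$kind,
                  if (is.null(mb$error$a)) 0 else mb$error$a,
                  if (is.null(mb$error$b)) 0 else mb$error$b)
    } else error_model("proportional", b = 0.398)
    cfg$model <- population_model(
      typicals = if (!is.null(mb$typicals)) unlist(mb$typicals) else
        c(cl = 0.186, v = 14.6, cldial = 1.98),
      effects = effects,
      omega = if (!is.null(mb$omega)) unlist(mb$omega) else
        c(cl = 1.07, v = 0.197, cldial = 0),
      error = err,
      structure = if (!is.null(mb$structure)) mb$structure else "1cmt")
  }
  cfg
}

#' Write a fit report as JSON (+ EBE table as TSV)
#'
#' Emits the final estimates, BIC/log-likelihood, shrinkage and run
#' provenance (seed, settings, package version) as machine-readable JSON,
#' and the per-subject empirical Bayes etas as TSV.
#'
#' @param fit An [fit_saem()] result.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_fit_report <- function(fit, dir) {
  stopifnot(inherits(fit, "saem_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- fit$model
  report <- list(
    estimates = list(
      typicals = as.list(m$typicals),
      effects = lapply(m$effects, function(e) {
        e[c("parameter", "covariate", "kind", "value", "reference",
            "estimate")]
      }),
      omega = as.list(m$omega),
      error = list(kind = m$error$kind, a = m$error$a, b = m$error$b)),
    loglik = fit$loglik, BIC = fit$BIC,
    shrinkage_pct = as.list(fit$shrinkage),
    se = if (!is.null(fit$se)) as.list(fit$se),
    n_subjects = fit$n_subjects, n_obs = fit$n_obs, n_blq = fit$n_blq,
    provenance = list(seed = fit$seed,
                      settings = unclass(fit$settings),
                      package_version =
                        as.character(utils::packageVersion("cefadial")),
                      timestamp = format(Sys.time(), tz = "UTC")))
  jpath <- file.path(dir, "fit.json")
  jsonlite::write_json(report, jpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  ebes <- data.frame(subject = vapply(fit$dataset$subjects,
                                      function(s) s$id, numeric(1)),
                     fit$ebe)
  tpath <- file.path(dir, "ebes.tsv")
  utils::write.table(ebes, tpath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(jpath, tpath))
}
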