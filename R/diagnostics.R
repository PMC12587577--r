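# Simulation-based model diagnostics: normalized prediction distribution
# errors (NPDE) with the three calibration tests (mean 0, variance 1,
# normality), the prediction-corrected visual predictive check (pc-VPC),
# and goodness-of-fit tables.

# simulate k replicate observation vectors for one compiled subject
# (BSV + residual error), rows = replicates
simulate_replicates <- function(model, cp, k) {
  n_i <- length(cp$y)
  eta <- matrix(stats::rnorm(3L * k, 0, model$omega), k, 3L, byrow = TRUE)
  sims <- matrix(0, k, n_i)
  for (r in seq_len(k)) {
    f <- predict_compiled(cp, cp$mu + eta[r, ])
    sims[r, ] <- apply_residual_error(f, model$error)
  }
  sims
}

#' Normalized prediction distribution errors
#'
#' For each subject, `k_sim` replicate observation vectors are simulated
#' under the model (BSV and residual error); the observed and simulated
#' vectors are decorrelated with the inverse Cholesky factor of the
#' empirical simulation covariance; each observation's prediction
#' discrepancy is its rank among the simulations, clamped to
#' `[1/(2k), 1 - 1/(2k)]` and mapped through the standard-normal
#' quantile.  Under a correct model the NPDE are iid standard normal,
#' which is checked by a one-sample t test (mean 0), a chi-square test on
#' the variance (1) and a Shapiro-Wilk normality test.
#'
#' @param dataset A [pk_dataset()].
#' @param model A [population_model()].
#' @param k_sim Simulated replicates per subject (>= 100).
#' @param seed Integer seed.
#' @return An object of class `npde_result`: `table` (subject, time,
#'   observed, npde), `tests` (p-values `mean`, `variance`,
#'   `normality`), `mean`, `variance`.
#' @export
npde <- function(dataset, model, k_sim = 500, seed) {
  stopifnot(inherits(dataset, "pk_dataset"),
            inherits(model, "population_model"))
  if (k_sim < 100) stop("'k_sim' must be >= 100")
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  compiled <- compile_dataset(dataset, model)
  out <- list()
  for (i in seq_along(compiled)) {
    cp <- compiled[[i]]
    n_i <- length(cp$y)
    if (n_i == 0L) next
    sims <- simulate_replicates(model, cp, k_sim)
    Ey <- colMeans(sims)
    V <- stats::cov(sims)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) {
      warning("singular simulation covariance for subject ", cp$id,
              "; ridge-regularized")
      V <- V + diag(1e-6 * mean(diag(V)) + 1e-12, n_i)
      U <- chol(V)
    }
    Linv <- function(x) backsolve(U, x, transpose = TRUE)
    ystar <- Linv(cp$y - Ey)
    sstar <- Linv(t(sims) - Ey)          # n_i x k matrix
    pde <- vapply(seq_len(n_i), function(j) {
      mean(sstar[j, ] < ystar[j])
    }, 0)
    pde <- pmin(pmax(pde, 1 / (2 * k_sim)), 1 - 1 / (2 * k_sim))
    out[[length(out) + 1L]] <- data.frame(subject = cp$id,
                                          time = cp$times,
                                          observed = cp$y,
                                          npde = stats::qnorm(pde))
  }
  tab <- do.call(rbind, out)
  x <- tab$npde
  nn <- length(x)
  v <- stats::var(x)
  chisq <- (nn - 1) * v            # ~ chi^2(nn-1) under variance 1
  p_var <- 2 * min(stats::pchisq(chisq, nn - 1),
                   stats::pchisq(chisq, nn - 1, lower.tail = FALSE))
  tests <- c(mean = stats::t.test(x)$p.value,
             variance = min(p_var, 1),
             normality = stats::shapiro.test(x)$p.value)
  structure(list(table = tab, tests = tests, mean = mean(x), variance = v),
            class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  cat(sprintf("NPDE over %d observations: mean %.3f, variance %.3f\n",
              nrow(x$table), x$mean, x$variance))
  cat(sprintf("  p-values: mean %.3f, variance %.3f, normality %.3f\n",
              x$tests["mean"], x$tests["variance"], x$tests["normality"]))
  invisible(x)
}

# time after last dose for a vector of times given a schedule
time_after_last_dose <- function(schedule, times) {
  starts <- schedule$infusions$start
  vapply(times, function(t) {
    prior <- starts[starts <= t + 1e-9]
    if (!length(prior)) t else t - max(prior)
  }, 0)
}

#' Prediction-corrected visual predictive check
#'
#' Observed and simulated concentrations are normalized by the ratio of
#' the bin-median population prediction to each point's own population
#' prediction, removing dose and covariate heterogeneity; per bin of time
#' after last dose the 5th/50th/95th observed percentiles are compared to
#' the 90% confidence bands of the same percentiles across `n_sim`
#' simulated replicates of the study.
#'
#' @param dataset A [pk_dataset()].
#' @param model A [population_model()].
#' @param n_sim Simulated study replicates (>= 2; 500 is the default used
#'   for reporting).
#' @param bins Number of equal-count bins on the time-after-last-dose
#'   axis, or a numeric vector of bin edges.
#' @param seed Integer seed.
#' @return An object of class `pc_vpc`: `bins` data.frame with observed
#'   percentiles and simulated 90% bands, plus the per-observation table.
#' @export
pc_vpc <- function(dataset, model, n_sim = 500, bins = 6, seed) {
  stopifnot(inherits(dataset, "pk_dataset"),
            inherits(model, "population_model"))
  if (n_sim < 2) stop("'n_sim' must be >= 2 (bands are degenerate)")
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  compiled <- compile_dataset(dataset, model)
  # per-observation: time after last dose and population prediction
  tal <- list(); pred <- list(); yobs <- list(); subj <- list()
  for (i in seq_along(compiled)) {
    cp <- compiled[[i]]
    if (!length(cp$y)) next
    tal[[i]] <- time_after_last_dose(dataset$subjects[[i]]$schedule,
                                     cp$times)
    pred[[i]] <- pmax(predict_compiled(cp, cp$mu), 1e-10)
    yobs[[i]] <- cp$y
    subj[[i]] <- rep(cp$id, length(cp$y))
  }
  tal <- unlist(tal); pred <- unlist(pred); yobs <- unlist(yobs)
  n_tot <- length(yobs)
  if (length(bins) == 1L) {
    edges <- unique(stats::quantile(tal, probs = seq(0, 1,
                                                     length.out = bins + 1)))
    if (length(edges) < 2L) edges <- range(tal) + c(-1e-9, 1e-9)
  } else {
    edges <- sort(unique(bins))
  }
  edges[1L] <- edges[1L] - 1e-9
  edges[length(edges)] <- edges[length(edges)] + 1e-9
  bin <- cut(tal, edges, labels = FALSE, include.lowest = TRUE)
  # merge any empty bin with its lower neighbour
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  if (any(counts == 0L)) {
    message("empty VPC bin(s) merged with neighbours")
    keep <- which(counts > 0L)
    edges <- edges[c(keep, length(edges))]
    bin <- cut(tal, edges, labels = FALSE, include.lowest = TRUE)
  }
  binf <- factor(bin, levels = sort(unique(bin)))
  n_bins <- nlevels(binf)
  binmed <- as.numeric(tapply(pred, binf, stats::median))
  med_of <- binmed[as.integer(binf)]
  pc_obs <- yobs * med_of / pred
  probs <- c(0.05, 0.5, 0.95)
  perc <- function(x) stats::quantile(x, probs, names = FALSE, type = 7)
  obs_p <- t(vapply(split(pc_obs, binf), perc, numeric(3L)))
  # simulate replicate studies and collect corrected percentiles
  sim_p <- array(NA_real_, c(n_sim, n_bins, 3L))
  for (r in seq_len(n_sim)) {
    ysim <- numeric(n_tot)
    pos <- 1L
    for (i in seq_along(compiled)) {
      cp <- compiled[[i]]
      if (!length(cp$y)) next
      eta <- stats::rnorm(3L, 0, model$omega)
      f <- predict_compiled(cp, cp$mu + eta)
      ysim[pos:(pos + length(f) - 1L)] <- apply_residual_error(f,
                                                               model$error)
      pos <- pos + length(f)
    }
    pc_sim <- ysim * med_of / pred
    sim_p[r, , ] <- t(vapply(split(pc_sim, binf), perc, numeric(3L)))
  }
  band <- function(q) apply(sim_p, c(2L, 3L), stats::quantile, probs = q,
                            names = FALSE)
  lo <- band(0.05); mid <- band(0.5); hi <- band(0.95)
  bt <- data.frame(
    bin = seq_len(n_bins),
    tal_lo = as.numeric(tapply(tal, binf, min)),
    tal_hi = as.numeric(tapply(tal, binf, max)),
    n = as.integer(table(binf)),
    obs_p5 = obs_p[, 1L], obs_p50 = obs_p[, 2L], obs_p95 = obs_p[, 3L],
    pred_p5 = mid[, 1L], pred_p50 = mid[, 2L], pred_p95 = mid[, 3L],
    lo_p5 = lo[, 1L], hi_p5 = hi[, 1L],
    lo_p50 = lo[, 2L], hi_p50 = hi[, 2L],
    lo_p95 = lo[, 3L], hi_p95 = hi[, 3L])
  rownames(bt) <- NULL
  covered <- with(bt, (obs_p5 >= lo_p5 & obs_p5 <= hi_p5) +
                    (obs_p50 >= lo_p50 & obs_p50 <= hi_p50) +
                    (obs_p95 >= lo_p95 & obs_p95 <= hi_p95))
  structure(list(bins = bt,
                 coverage = sum(covered) / (3 * n_bins),
                 table = data.frame(subject = unlist(subj), tal = tal,
                                    observed = yobs, pred = pred,
                                    pc_observed = pc_obs,
                                    bin = as.integer(bin))),
            class = "pc_vpc")
}

#' @export
print.pc_vpc <- function(x, ...) {
  cat(sprintf("pc-VPC: %d bins, %d observations, band coverage %.0f%%\n",
              nrow(x$bins), nrow(x$table), 100 * x$coverage))
  invisible(x)
}

#' Goodness-of-fit tables
#'
#' Observed concentrations against population (eta = 0) and individual
#' (empirical Bayes) predictions, with individual weighted residuals --
#' the tidy input for the standard popPK diagnostic panels.  No plotting
#' dependency is required.
#'
#' @param fit An [fit_saem()] result, or a [pk_dataset()] when `model`
#'   and `ebe` are supplied explicitly.
#' @param model A [population_model()] (only when `fit` is a dataset).
#' @param ebe Matrix of empirical Bayes etas (only when `fit` is a
#'   dataset).
#' @return A data.frame with one row per observation: `subject`, `time`,
#'   `tal`, `observed`, `pred`, `ipred`, `iwres`.
#' @export
gof_tables <- function(fit, model = NULL, ebe = NULL) {
  if (inherits(fit, "saem_fit")) {
    dataset <- fit$dataset
    model <- fit$model
    ebe <- fit$ebe
  } else {
    dataset <- fit
    stopifnot(inherits(dataset, "pk_dataset"), !is.null(model),
              !is.null(ebe))
  }
  compiled <- compile_dataset(dataset, model)
  rows <- lapply(seq_along(compiled), function(i) {
    cp <- compiled[[i]]
    if (!length(cp$y)) return(NULL)
    pr <- predict_compiled(cp, cp$mu)
    ip <- predict_compiled(cp, cp$mu + ebe[i, ])
    data.frame(subject = cp$id, time = cp$times,
               tal = time_after_last_dose(dataset$subjects[[i]]$schedule,
                                          cp$times),
               observed = cp$y, pred = pr, ipred = ip,
               iwres = (cp$y - ip) / error_sd(model$error, pmax(ip, 1e-10)))
  })
  do.call(rbind, rows)
}

#' Flag observations with extreme individual weighted residuals
#'
#' Optional outlier screen: rows whose `|iwres|` exceeds the threshold are
#' flagged for review.  Nothing is removed automatically.
#'
#' @param gof A [gof_tables()] data.frame.
#' @param threshold Absolute IWRES cut-off (default 5).
#' @return The flagged subset of the table.
#' @export
flag_outliers <- function(gof, threshold = 5) {
  gof[abs(gof$iwres) > threshold, , drop = FALSE]
}
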