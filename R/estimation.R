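# Parameter inference for the nonlinear mixed-effects model.
#
# fit_saem(): stochastic approximation EM.  The individual log-parameters
# psi_i = (log CL_i, log Vd_i, log CLdial_i) are the latent variables;
# the E-step runs a few Metropolis kernels per subject (one independence
# draw from the prior plus adaptive component-wise random walks), the
# SA-step smooths the complete-data sufficient statistics with step size
# 1 during exploration and 1/(k - k0) during smoothing, and the M-step is
# closed form because every covariate effect is log-linear: each
# parameter's typical value and estimable effect coefficients solve a
# small least-squares system, omega^2 is the mean squared residual of
# that regression, and the proportional error coefficient is the RMS
# relative residual.
#
# map_individual(): MAP-Bayes empirical Bayes estimates, the TDM
# individualization core.  marginal_loglik(): importance sampling with a
# t proposal centred at the MAP, for BIC-based model comparison.

#' SAEM algorithm settings
#'
#' @param n_explore Exploration iterations (step size 1, variance
#'   annealing active).
#' @param n_smooth Smoothing iterations (step size `1/(k - n_explore)`).
#' @param n_sweeps Component-wise Metropolis sweeps per iteration (on top
#'   of one independence kernel).
#' @param omega_floor Lower bound on the BSV standard deviation used for
#'   conditional sampling only; keeps the Markov chains mobile when a
#'   variance estimate collapses towards zero.  Reported estimates are the
#'   unconstrained updates.
#' @param estimate_omega Named logical: which BSV terms to estimate
#'   (others stay at their initial value).
#' @param compute_loglik Estimate the marginal log-likelihood (and BIC) by
#'   importance sampling after the fit?
#' @param n_is Importance-sampling draws per subject for the
#'   log-likelihood.
#' @param se_method `"none"` or `"bootstrap"` (nonparametric, resampling
#'   subjects).
#' @param n_boot Bootstrap replicates when `se_method = "bootstrap"`.
#' @return A list of class `saem_settings`.
#' @export
saem_settings <- function(n_explore = 300, n_smooth = 200, n_sweeps = 2,
                          omega_floor = 0.05,
                          estimate_omega = c(cl = TRUE, v = TRUE,
                                             cldial = TRUE),
                          compute_loglik = TRUE, n_is = 300,
                          se_method = c("none", "bootstrap"),
                          n_boot = 100) {
  se_method <- match.arg(se_method)
  eo <- c(cl = TRUE, v = TRUE, cldial = TRUE)
  eo[names(estimate_omega)] <- estimate_omega
  structure(list(n_explore = n_explore, n_smooth = n_smooth,
                 n_sweeps = n_sweeps, omega_floor = omega_floor,
                 estimate_omega = eo, compute_loglik = compute_loglik,
                 n_is = n_is, se_method = se_method, n_boot = n_boot),
            class = "saem_settings")
}

# design information of the log-linear covariate model, per parameter:
# psi_p,i = X_p[i,] %*% beta_p + offset_p[i] + eta_p,i
# (column 1 of X is the intercept = log typical value; estimable power
# effects contribute log(cov/ref) columns, categorical effects 0/1
# indicator columns whose coefficient is the log fold-change)
build_design <- function(model, compiled) {
  n <- length(compiled)
  lapply(c(cl = "cl", v = "v", cldial = "cldial"), function(p) {
    efs <- Filter(function(e) e$parameter == p, model$effects)
    fixed <- Filter(function(e) !e$estimate, efs)
    est <- Filter(function(e) e$estimate, efs)
    offset <- vapply(compiled, function(cp) {
      sum(vapply(fixed, function(e) effect_log_term(e, cp$covariates), 0))
    }, 0)
    X <- matrix(1, n, 1L + length(est))
    if (length(est)) {
      for (j in seq_along(est)) {
        X[, j + 1L] <- vapply(compiled, function(cp) {
          effect_design_term(est[[j]], cp$covariates)
        }, 0)
      }
    }
    list(X = X, XtX = crossprod(X), offset = offset, est = est)
  })
}

# beta vector of the current model for one parameter design
current_beta <- function(model, p, des) {
  b <- log(model$typicals[[p]])
  if (length(des$est)) {
    more <- vapply(des$est, function(e) {
      cur <- Filter(function(m) m$parameter == e$parameter &&
                      m$covariate == e$covariate && m$kind == e$kind,
                    model$effects)[[1L]]
      if (e$kind == "power") cur$value else log(cur$value)
    }, 0)
    b <- c(b, more)
  }
  b
}

# write beta back into the model (typical value + estimable effects)
apply_beta <- function(model, p, des, beta) {
  model$typicals[[p]] <- exp(beta[1L])
  if (length(des$est)) {
    for (j in seq_along(des$est)) {
      e <- des$est[[j]]
      for (m in seq_along(model$effects)) {
        me <- model$effects[[m]]
        if (me$parameter == e$parameter && me$covariate == e$covariate &&
            me$kind == e$kind) {
          model$effects[[m]]$value <-
            if (e$kind == "power") beta[j + 1L] else exp(beta[j + 1L])
        }
      }
    }
  }
  model
}

# per-subject prior means mu_i given the current model
prior_means <- function(model, designs, compiled) {
  n <- length(compiled)
  mu <- matrix(0, n, 3L, dimnames = list(NULL, c("cl", "v", "cldial")))
  for (p in c("cl", "v", "cldial")) {
    des <- designs[[p]]
    beta <- current_beta(model, p, des)
    mu[, p] <- as.numeric(des$X %*% beta) + des$offset
  }
  mu
}

#' Fit the population model by SAEM
#'
#' Maximum-likelihood estimation of the typical values, estimable
#' covariate coefficients, BSV standard deviations and residual-error
#' parameters.  Deterministic given `seed` and settings.
#'
#' @param dataset A [pk_dataset()].
#' @param init Initial [population_model()] (structure, error kind and
#'   which effects are estimable are taken from it).
#' @param settings An [saem_settings()] list.
#' @param seed Integer seed (mandatory).
#' @return An object of class `saem_fit` with elements `model` (final
#'   estimates), `trace` (parameter path per iteration), `ebe` (empirical
#'   Bayes etas), `shrinkage`, `loglik`, `BIC`, `se`, `rse` and
#'   bookkeeping fields.
#' @export
fit_saem <- function(dataset, init = population_model(),
                     settings = saem_settings(), seed) {
  stopifnot(inherits(dataset, "pk_dataset"),
            inherits(init, "population_model"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  compiled <- compile_dataset(dataset, init)
  n <- length(compiled)
  n_obs <- sum(vapply(compiled, function(cp) length(cp$y), 0L))
  if (n_obs == 0L) stop("no quantifiable observations to fit")
  n_blq <- sum(vapply(compiled, function(cp) cp$n_blq, 0L))
  if (n_blq > 0L) {
    message(n_blq, " BLQ observation(s) excluded from fitting")
  }
  designs <- build_design(init, compiled)
  # identifiability warning: dialysis clearance needs sessions
  if (!any(vapply(dataset$subjects, function(s) nrow(s$schedule$sessions),
                  0L) > 0L)) {
    warning("no dialysis sessions in the dataset: CLdial is not ",
            "informed by these data")
  }
  model <- init
  params <- c("cl", "v", "cldial")
  omega2 <- pmax(model$omega, 1e-3)^2
  names(omega2) <- params
  est_om <- settings$estimate_omega
  err <- model$error
  b2 <- err$b^2
  a2 <- err$a^2

  mu <- prior_means(model, designs, compiled)
  psi <- mu + matrix(stats::rnorm(n * 3L, 0, 0.1), n, 3L)
  ll_y <- vapply(seq_len(n), function(i) {
    loglik_subject(predict_compiled(compiled[[i]], psi[i, ]),
                   compiled[[i]]$y, err)
  }, 0)
  scales <- matrix(0.4, n, 3L)
  # SA accumulators
  s1 <- lapply(designs, function(d) numeric(ncol(d$X)))
  s2 <- c(cl = 0, v = 0, cldial = 0)
  s_err <- 0
  n_iter <- settings$n_explore + settings$n_smooth
  trace <- matrix(NA_real_, n_iter,
                  3L + sum(vapply(designs, function(d) length(d$est), 0L)) +
                    3L + 2L)
  for (k in seq_len(n_iter)) {
    gam <- if (k <= settings$n_explore) 1 else 1 / (k - settings$n_explore)
    # annealed sampling floor: conditional chains start wide so that
    # parameters whose BSV collapses (or is fixed near zero) still feel
    # the likelihood through their eta, then tighten to omega_floor over
    # the exploration phase
    anneal <- 0.5 * exp(-3 * (k - 1) / max(settings$n_explore, 1))
    om_samp <- sqrt(pmax(omega2, settings$omega_floor^2, anneal^2))
    # ---- E-step: Metropolis kernels ------------------------------------
    for (i in seq_len(n)) {
      cp <- compiled[[i]]
      # kernel 1: independence proposal from the prior
      cand <- mu[i, ] + stats::rnorm(3L, 0, om_samp)
      llc <- loglik_subject(predict_compiled(cp, cand), cp$y, err)
      if (log(stats::runif(1L)) < llc - ll_y[i]) {
        psi[i, ] <- cand
        ll_y[i] <- llc
      }
      # kernels 2..: adaptive component-wise random walks
      for (sw in seq_len(settings$n_sweeps)) {
        for (cc in 1:3) {
          cand <- psi[i, ]
          cand[cc] <- cand[cc] + scales[i, cc] * stats::rnorm(1L)
          llc <- loglik_subject(predict_compiled(cp, cand), cp$y, err)
          lr <- (llc - ll_y[i]) +
            (stats::dnorm(cand[cc], mu[i, cc], om_samp[cc], log = TRUE) -
             stats::dnorm(psi[i, cc], mu[i, cc], om_samp[cc], log = TRUE))
          acc <- log(stats::runif(1L)) < lr
          if (acc) {
            psi[i, ] <- cand
            ll_y[i] <- llc
          }
          scales[i, cc] <- scales[i, cc] *
            exp(0.4 * ((if (acc) 1 else 0) - 0.35) / sqrt(k))
        }
      }
    }
    # ---- SA-step: smooth sufficient statistics -------------------------
    for (p in params) {
      des <- designs[[p]]
      r <- psi[, p] - des$offset
      s1[[p]] <- s1[[p]] + gam * (as.numeric(crossprod(des$X, r)) - s1[[p]])
      s2[p] <- s2[p] + gam * (sum(r^2) - s2[p])
    }
    res2 <- 0
    for (i in seq_len(n)) {
      f <- pmax(predict_compiled(compiled[[i]], psi[i, ]), 1e-10)
      res2 <- res2 + switch(err$kind,
        proportional = sum(((compiled[[i]]$y - f) / f)^2),
        additive = sum((compiled[[i]]$y - f)^2),
        combined = sum((compiled[[i]]$y - f)^2 / (1 + (err$b / err$a)^2 *
                                                    f^2)))
    }
    s_err <- s_err + gam * (res2 - s_err)
    # ---- M-step: closed-form updates -----------------------------------
    for (p in params) {
      des <- designs[[p]]
      beta <- as.numeric(solve(des$XtX, s1[[p]]))
      model <- apply_beta(model, p, des, beta)
      if (est_om[[p]]) {
        o2 <- max((s2[[p]] - sum(s1[[p]] * beta)) / n, 1e-8)
        omega2[p] <- if (k <= settings$n_explore) {
          max(o2, 0.95 * omega2[p])
        } else o2
      }
    }
    if (err$kind == "proportional") {
      b2_new <- s_err / n_obs
      b2 <- if (k <= settings$n_explore) max(b2_new, 0.95 * b2) else b2_new
      err$b <- sqrt(b2)
    } else if (err$kind == "additive") {
      a2_new <- s_err / n_obs
      a2 <- if (k <= settings$n_explore) max(a2_new, 0.95 * a2) else a2_new
      err$a <- sqrt(a2)
    } else {
      # combined: scale a keeping the a/b ratio, then refine b by a 1-D
      # search on the complete-data likelihood every 10 iterations
      a2_new <- s_err / n_obs
      a2 <- if (k <= settings$n_explore) max(a2_new, 0.95 * a2) else a2_new
      err$a <- sqrt(a2)
      if (k %% 10L == 0L || k == n_iter) {
        obj <- function(lb) {
          bb <- exp(lb)
          tot <- 0
          for (i in seq_len(n)) {
            f <- pmax(predict_compiled(compiled[[i]], psi[i, ]), 1e-10)
            sd <- sqrt(err$a^2 + (bb * f)^2)
            tot <- tot - sum(stats::dnorm(compiled[[i]]$y, f, sd,
                                          log = TRUE))
          }
          tot
        }
        opt <- stats::optimize(obj, c(log(1e-4), log(2)))
        err$b <- exp(opt$minimum)
      }
    }
    model$error <- err
    mu <- prior_means(model, designs, compiled)
    # prior changed; observation likelihood ll_y is unaffected
    trace[k, ] <- c(unlist(model$typicals),
                    unlist(lapply(params, function(p) {
                      b <- current_beta(model, p, designs[[p]])
                      if (length(b) > 1L) b[-1L] else numeric()
                    })),
                    sqrt(omega2), err$a, err$b)
  }
  model$omega <- sqrt(omega2)
  names(model$omega) <- params
  model$error <- err

  # empirical Bayes estimates and shrinkage
  ebe <- t(vapply(seq_len(n), function(i) {
    map_eta_compiled(model, compiled[[i]], mu[i, ])$eta
  }, numeric(3L)))
  colnames(ebe) <- params
  shr <- vapply(params, function(p) {
    if (model$omega[[p]] > 1e-6) {
      100 * (1 - stats::sd(ebe[, p]) / model$omega[[p]])
    } else NA_real_
  }, 0)

  fit <- structure(list(model = model, init = init, trace = trace,
                        psi = psi, ebe = ebe, shrinkage = shr,
                        loglik = NA_real_, BIC = NA_real_,
                        se = NULL, rse = NULL,
                        n_subjects = n, n_obs = n_obs, n_blq = n_blq,
                        settings = settings, seed = seed,
                        dataset = dataset),
                   class = "saem_fit")
  if (settings$compute_loglik) {
    ml <- marginal_loglik(dataset, model, n_is = settings$n_is,
                          seed = seed + 1L)
    fit$loglik <- ml$loglik
    fit$BIC <- bic_from_loglik(ml$loglik, model, designs, n, n_obs)
  }
  if (settings$se_method == "bootstrap") {
    fit <- add_bootstrap_se(fit, seed + 2L)
  }
  fit
}

# BIC with mixed-level penalty: subject-level parameters (typical values,
# covariate coefficients, omegas) use log(N_subjects); residual-error
# parameters use log(N_observations)
bic_from_loglik <- function(loglik, model, designs, n, n_obs) {
  k_subj <- sum(vapply(designs, function(d) ncol(d$X), 0L)) +
    sum(model$omega > 1e-6)
  k_err <- switch(model$error$kind, proportional = 1L, additive = 1L,
                  combined = 2L)
  -2 * loglik + k_subj * log(n) + k_err * log(n_obs)
}

#' @export
print.saem_fit <- function(x, ...) {
  cat("SAEM fit:", x$n_subjects, "subjects,", x$n_obs, "observations\n")
  print(x$model)
  if (is.finite(x$loglik)) {
    cat(sprintf("  loglik %.2f   BIC %.2f\n", x$loglik, x$BIC))
  }
  shr <- x$shrinkage[!is.na(x$shrinkage)]
  if (length(shr)) {
    cat("  shrinkage (%):",
        paste(sprintf("%s %.1f", names(shr), shr), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parameter table of a fit
#'
#' Tidy summary of the final estimates in the conventional popPK report
#' layout (typical values, covariate exponents, BSV, residual error), with
#' relative standard errors and shrinkage where available.
#'
#' @param fit An [fit_saem()] result.
#' @return A data.frame.
#' @export
parameter_table <- function(fit) {
  stopifnot(inherits(fit, "saem_fit"))
  m <- fit$model
  rows <- data.frame(parameter = c("CL_pop (L/h)", "Vd_pop (L)",
                                   "CLdial_pop (L/h)"),
                     estimate = unname(unlist(m$typicals[c("cl", "v",
                                                           "cldial")])))
  for (ef in m$effects) {
    rows <- rbind(rows, data.frame(
      parameter = sprintf("beta_%s/%s%s", ef$covariate, ef$parameter,
                          if (ef$estimate) "" else " (fixed)"),
      estimate = ef$value))
  }
  rows <- rbind(rows,
                data.frame(parameter = c("omega_CL", "omega_Vd",
                                         "omega_CLdial"),
                           estimate = unname(m$omega[c("cl", "v",
                                                       "cldial")])),
                data.frame(parameter = c("a (additive, mg/L)",
                                         "b (proportional)"),
                           estimate = c(m$error$a, m$error$b)))
  rows$rse_pct <- NA_real_
  if (!is.null(fit$rse)) {
    idx <- match(rows$parameter, names(fit$rse))
    rows$rse_pct <- unname(fit$rse[idx])
  }
  shr <- rep(NA_real_, nrow(rows))
  shr[rows$parameter == "omega_CL"] <- fit$shrinkage[["cl"]]
  shr[rows$parameter == "omega_Vd"] <- fit$shrinkage[["v"]]
  shr[rows$parameter == "omega_CLdial"] <- fit$shrinkage[["cldial"]]
  rows$shrinkage_pct <- shr
  rows
}

# MAP eta for one compiled subject (free dimensions: omega > 0; the rest
# are pinned at 0 by the degenerate prior)
map_eta_compiled <- function(model, cp, mu, omega = model$omega) {
  free <- which(omega > 1e-8)
  eta <- c(cl = 0, v = 0, cldial = 0)
  if (!length(free)) {
    return(list(eta = eta, convergence = 0L))
  }
  obj <- function(ef) {
    e <- eta
    e[free] <- ef
    ll <- loglik_subject(predict_compiled(cp, mu + e), cp$y, model$error)
    -ll + 0.5 * sum((ef / omega[free])^2)
  }
  best <- NULL
  for (start in list(rep(0, length(free)),
                     0.5 * omega[free] * rep(1, length(free)))) {
    o <- tryCatch(stats::optim(start, obj, method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) {
    return(list(eta = eta, convergence = 1L))
  }
  eta[free] <- best$par
  list(eta = eta, convergence = best$convergence)
}

#' MAP-Bayes individual estimation
#'
#' Posterior-mode random effects given a subject's sparse observations and
#' the population priors -- the computational core of therapeutic drug
#' monitoring: the returned individual clearances feed directly into
#' dose-regimen selection for that patient.
#'
#' Minimizes `-loglik(eta) + 0.5 * sum((eta/omega)^2)` by quasi-Newton
#' search with restarts; random effects whose omega is 0 are pinned at 0.
#'
#' @param model A [population_model()].
#' @param subject A list with `schedule`, `covariates` and `obs` (one
#'   element of a [pk_dataset()]'s `subjects`).
#' @return A list with `eta`, `params` ([structural_params()]), `pred`
#'   (individual predictions at the observation times) and `convergence`
#'   (0 = converged).
#' @export
map_individual <- function(model, subject) {
  stopifnot(inherits(model, "population_model"))
  if (is.null(subject$obs) || nrow(subject$obs) == 0L) {
    stop("MAP estimation needs at least one observation")
  }
  cp <- compile_dataset(pk_dataset(list(subject)), model)[[1L]]
  res <- map_eta_compiled(model, cp, cp$mu)
  psi <- cp$mu + res$eta
  params <- structural_params(exp(psi[["cl"]]), exp(psi[["v"]]),
                              exp(psi[["cldial"]]))
  list(eta = res$eta, params = params,
       pred = predict_compiled(cp, psi), times = cp$times,
       convergence = res$convergence)
}

#' Marginal log-likelihood by importance sampling
#'
#' Estimates `sum_i log integral p(y_i | eta) p(eta) d eta` with a
#' multivariate t (4 df) proposal centred at each subject's MAP with the
#' curvature of the posterior mode.  Random effects with omega = 0
#' contribute as point priors.
#'
#' @param dataset A [pk_dataset()].
#' @param model A [population_model()].
#' @param n_is Importance samples per subject.
#' @param seed Integer seed.
#' @return A list with `loglik`, per-subject `by_subject`, and the
#'   minimum effective sample size `min_ess` (a warning is raised when it
#'   falls below 5% of `n_is`).
#' @export
marginal_loglik <- function(dataset, model, n_is = 1000, seed) {
  stopifnot(inherits(dataset, "pk_dataset"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  compiled <- compile_dataset(dataset, model)
  omega <- model$omega
  free <- which(omega > 1e-8)
  d <- length(free)
  by_subject <- numeric(length(compiled))
  min_ess <- Inf
  for (i in seq_along(compiled)) {
    cp <- compiled[[i]]
    if (d == 0L) {
      by_subject[i] <- loglik_subject(predict_compiled(cp, cp$mu), cp$y,
                                      model$error)
      next
    }
    map <- map_eta_compiled(model, cp, cp$mu)
    center <- map$eta[free]
    negpost <- function(ef) {
      e <- c(cl = 0, v = 0, cldial = 0)
      e[free] <- ef
      -loglik_subject(predict_compiled(cp, cp$mu + e), cp$y, model$error) +
        0.5 * sum((ef / omega[free])^2)
    }
    H <- tryCatch(stats::optimHess(center, negpost),
                  error = function(e) NULL)
    Sigma <- NULL
    if (!is.null(H)) {
      eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
      vals <- pmax(eg$values, 1e-4)
      Sigma <- eg$vectors %*% diag(1 / vals, d) %*% t(eg$vectors)
    }
    if (is.null(Sigma)) Sigma <- diag(omega[free]^2, d)
    L <- chol(Sigma)
    df <- 4
    z <- matrix(stats::rnorm(n_is * d), n_is, d)
    u <- stats::rchisq(n_is, df)
    draws <- sweep((z %*% L) * sqrt(df / u), 2L, center, "+")
    # log density of the multivariate t proposal
    quad <- rowSums((sweep(draws, 2L, center) %*% solve(L))^2)
    logdet <- 2 * sum(log(diag(L)))
    logq <- lgamma((df + d) / 2) - lgamma(df / 2) -
      0.5 * (d * log(df * pi) + logdet) -
      (df + d) / 2 * log1p(quad / df)
    logw <- vapply(seq_len(n_is), function(s) {
      e <- c(cl = 0, v = 0, cldial = 0)
      e[free] <- draws[s, ]
      loglik_subject(predict_compiled(cp, cp$mu + e), cp$y, model$error) +
        sum(stats::dnorm(draws[s, ], 0, omega[free], log = TRUE))
    }, 0) - logq
    mx <- max(logw)
    by_subject[i] <- mx + log(mean(exp(logw - mx)))
    w <- exp(logw - mx)
    min_ess <- min(min_ess, sum(w)^2 / sum(w^2))
  }
  if (is.finite(min_ess) && min_ess < 0.05 * n_is) {
    warning(sprintf("low importance-sampling effective sample size (%.1f)",
                    min_ess))
  }
  list(loglik = sum(by_subject), by_subject = by_subject,
       min_ess = min_ess)
}

#' Test one candidate covariate effect
#'
#' Refits the model with the candidate effect added (marked estimable) and
#' applies the retention rule used for covariate selection: the effect is
#' kept only if it decreases the BIC **and** reduces the BSV of the
#' parameter it acts on.
#'
#' @param dataset A [pk_dataset()].
#' @param base_fit The [fit_saem()] result of the model without the
#'   candidate (must have been run with `compute_loglik = TRUE`).
#' @param candidate A [covariate_effect()].
#' @param seed Integer seed for the refit.
#' @return A list with `delta_BIC`, `delta_BSV`, `retained`, and the
#'   candidate `fit`.
#' @export
covariate_step <- function(dataset, base_fit, candidate, seed) {
  stopifnot(inherits(base_fit, "saem_fit"),
            inherits(candidate, "covariate_effect"))
  if (!is.finite(base_fit$BIC)) {
    stop("base fit has no BIC; rerun with compute_loglik = TRUE")
  }
  dup <- any(vapply(base_fit$model$effects, function(e) {
    e$parameter == candidate$parameter &&
      e$covariate == candidate$covariate && e$kind == candidate$kind
  }, TRUE))
  if (dup) {
    # a redundant copy of an existing effect adds a parameter without
    # adding information: only the BIC penalty changes
    message("candidate duplicates an effect already in the model")
    return(list(delta_BIC = log(base_fit$n_subjects), delta_BSV = 0,
                retained = FALSE, fit = base_fit))
  }
  candidate$estimate <- TRUE
  init <- base_fit$model
  init$effects <- c(init$effects, list(candidate))
  fit <- fit_saem(dataset, init, base_fit$settings, seed = seed)
  p <- candidate$parameter
  delta_bic <- fit$BIC - base_fit$BIC
  delta_bsv <- fit$model$omega[[p]] - base_fit$model$omega[[p]]
  list(delta_BIC = delta_bic, delta_BSV = delta_bsv,
       retained = delta_bic < 0 && delta_bsv < 0, fit = fit)
}

#' Eta-shrinkage of a fit
#'
#' `100 * (1 - sd(EBE) / omega)` per random effect; near 0 when the data
#' are rich, large when individual etas are poorly identified and collapse
#' to the population prior.  Undefined (NA) when omega is 0.
#'
#' @param fit An [fit_saem()] result.
#' @return Named numeric vector of percentages.
#' @export
shrinkage <- function(fit) {
  stopifnot(inherits(fit, "saem_fit"))
  fit$shrinkage
}

# nonparametric bootstrap SEs: resample subjects, refit (loglik skipped),
# SD across replicates
add_bootstrap_se <- function(fit, seed) {
  set.seed(seed)
  sub <- fit$dataset$subjects
  n <- length(sub)
  setts <- fit$settings
  setts$compute_loglik <- FALSE
  setts$se_method <- "none"
  grab <- function(f) {
    c(unlist(f$model$typicals),
      vapply(Filter(function(e) e$estimate, f$model$effects),
             function(e) e$value, 0),
      f$model$omega, b = f$model$error$b, a = f$model$error$a)
  }
  reps <- matrix(NA_real_, setts$n_boot, length(grab(fit)))
  for (r in seq_len(setts$n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bds <- pk_dataset(lapply(seq_along(idx), function(j) {
      s <- sub[[idx[j]]]
      s$id <- j
      s
    }), loq = fit$dataset$loq)
    bf <- tryCatch(fit_saem(bds, fit$init, setts, seed = seed + r),
                   error = function(e) NULL)
    if (!is.null(bf)) reps[r, ] <- grab(bf)
  }
  est <- grab(fit)
  se <- apply(reps, 2L, stats::sd, na.rm = TRUE)
  names(se) <- names(est)
  fit$se <- se
  fit$rse <- 100 * se / abs(est)
  fit
}
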