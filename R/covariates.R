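# Deterministic covariate algebra: fat-free mass, body surface area,
# dialysis membrane surface area, allometric scaling and the final
# individual-parameter equations of the pediatric hemodialysis model.

# Sex-specific constants of the fat-free mass model: WHS_max is the maximal
# FFM per height squared, WHS_50 the total body weight at which FFM is half
# of that maximum.
.ffm_constants <- list(
  male   = c(whs_max = 42.92, whs_50 = 30.93),
  female = c(whs_max = 37.99, whs_50 = 35.98)
)

#' Fat-free mass
#'
#' Semi-mechanistic fat-free mass from total body weight, height and sex:
#' `FFM = WHSmax * HT^2 * BW / (WHS50 * HT^2 + BW)` with sex-specific
#' constants (`WHSmax` 42.92/37.99 kg/m^2, `WHS50` 30.93/35.98 kg/m^2 for
#' males/females).
#'
#' @param bw Body weight, kg.
#' @param ht Height, m (note: metres, not cm).
#' @param sex `"male"` or `"female"` (recycled).
#' @return Fat-free mass, kg. Vectorized over all arguments.
#' @export
fat_free_mass <- function(bw, ht, sex) {
  if (any(bw <= 0) || any(ht <= 0)) stop("'bw' and 'ht' must be > 0")
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    stop("'sex' must be \"male\" or \"female\"")
  }
  n <- max(length(bw), length(ht), length(sex))
  bw <- rep_len(bw, n); ht <- rep_len(ht, n); sex <- rep_len(sex, n)
  kmax <- vapply(sex, function(s) .ffm_constants[[s]]["whs_max"], 0)
  k50 <- vapply(sex, function(s) .ffm_constants[[s]]["whs_50"], 0)
  unname(kmax * ht^2 * bw / (k50 * ht^2 + bw))
}

#' Body surface area from body weight
#'
#' Weight-only BSA approximation used in pediatric dialysis practice:
#' `BSA = (4 BW + 7) / (BW + 90)`.
#'
#' @param bw Body weight, kg (> 0).
#' @return Body surface area, m^2.
#' @export
bsa <- function(bw) {
  if (any(bw <= 0)) stop("'bw' must be > 0")
  (4 * bw + 7) / (bw + 90)
}

#' Default dialysis membrane surface area from body weight
#'
#' Pediatric dialysis membranes are prescribed at roughly 75-100% of the
#' patient's body surface area; the default coefficient 0.85 sits in the
#' middle of that range and is the value used to initiate dialysis in many
#' centers: `DMSA = coefficient * BSA(BW)`.
#'
#' @param bw Body weight, kg.
#' @param coefficient Fraction of BSA, in `(0, 1.5]` (default 0.85).
#' @return Membrane surface area, m^2.
#' @export
dmsa_from_bw <- function(bw, coefficient = 0.85) {
  if (any(coefficient <= 0) || any(coefficient > 1.5)) {
    stop("'coefficient' must be in (0, 1.5]")
  }
  coefficient * bsa(bw)
}

#' Subject covariates
#'
#' @param bw Body weight, kg.
#' @param ht Height, m (optional; needed only for fat-free mass).
#' @param sex `"male"` or `"female"` (optional).
#' @param albumin Serum albumin, g/L (optional).
#' @param dmsa Dialysis membrane surface area, m^2. When missing it is
#'   derived as `0.85 * BSA(bw)`; a per-session value on the schedule takes
#'   precedence over this subject-level value.
#' @param ... Further named covariates (e.g. `rrt_technique`,
#'   `vascular_access`) carried through for covariate-effect testing.
#' @return A list of class `subject_covariates`.
#' @export
subject_covariates <- function(bw, ht = NA_real_, sex = NA_character_,
                               albumin = NA_real_, dmsa = NULL, ...) {
  if (!is.numeric(bw) || length(bw) != 1L || bw <= 0) {
    stop("'bw' must be a single positive number (kg)")
  }
  if (!is.na(ht) && ht <= 0) stop("'ht' must be > 0 (m)")
  if (is.null(dmsa) || is.na(dmsa)) dmsa <- dmsa_from_bw(bw)
  if (dmsa <= 0) stop("'dmsa' must be > 0 (m^2)")
  structure(c(list(bw = bw, ht = ht, sex = sex, albumin = albumin,
                   dmsa = dmsa), list(...)),
            class = "subject_covariates")
}

#' Describe a covariate effect on a structural parameter
#'
#' Power effects multiply the typical value by `(cov / reference)^value`;
#' categorical effects multiply it by `value` when the covariate equals 1
#' (reference category 0 leaves the parameter unchanged).  Both are
#' log-linear, which is what makes the closed-form SAEM M-step possible.
#'
#' @param parameter `"cl"`, `"v"` or `"cldial"`.
#' @param covariate Name of the covariate field (e.g. `"bw"`, `"dmsa"`,
#'   `"albumin"`).
#' @param kind `"power"` or `"categorical"`.
#' @param value Exponent (power) or fold-change for category 1
#'   (categorical).
#' @param reference Reference covariate value for power effects (must be
#'   > 0); ignored for categorical effects.
#' @param estimate Should the effect coefficient be estimated during a fit
#'   (`TRUE`) or held fixed (`FALSE`, e.g. allometric exponents)?
#' @return A list of class `covariate_effect`.
#' @export
covariate_effect <- function(parameter, covariate,
                             kind = c("power", "categorical"),
                             value, reference = 1, estimate = FALSE) {
  kind <- match.arg(kind)
  parameter <- match.arg(parameter, c("cl", "v", "cldial"))
  if (kind == "power" && reference <= 0) {
    stop("'reference' must be > 0 for power effects")
  }
  if (kind == "categorical" && !estimate && value <= 0) {
    stop("categorical fold-change must be > 0")
  }
  structure(list(parameter = parameter, covariate = covariate, kind = kind,
                 value = value, reference = reference, estimate = estimate),
            class = "covariate_effect")
}

# multiplier contributed by one effect for one subject, on the log scale
effect_log_term <- function(effect, covs) {
  x <- covs[[effect$covariate]]
  if (is.null(x) || is.na(x)) {
    stop("covariate '", effect$covariate, "' missing for a subject")
  }
  if (effect$kind == "power") {
    effect$value * log(x / effect$reference)
  } else {
    if (!x %in% c(0, 1)) stop("categorical covariates must be coded 0/1")
    x * log(effect$value)
  }
}

# the design row for the estimable part: power -> log(cov/ref),
# categorical -> 0/1 indicator (coefficient is log fold-change)
effect_design_term <- function(effect, covs) {
  x <- covs[[effect$covariate]]
  if (effect$kind == "power") log(x / effect$reference) else as.numeric(x)
}

#' The published covariate model of this package
#'
#' The final pediatric hemodialysis equations: allometric body-weight
#' scaling of residual clearance (exponent 0.75, reference 70 kg) and
#' volume (exponent 1), and a power effect of dialysis membrane surface
#' area on dialysis clearance (exponent 1.26, reference 1 m^2).
#'
#' @param beta_dmsa DMSA exponent on dialysis clearance (default 1.26).
#' @param estimate_beta_dmsa Mark the DMSA exponent as estimable.
#' @return List of [covariate_effect()] objects.
#' @export
reference_effects <- function(beta_dmsa = 1.26, estimate_beta_dmsa = FALSE) {
  list(
    covariate_effect("cl", "bw", "power", 0.75, reference = 70),
    covariate_effect("v", "bw", "power", 1, reference = 70),
    covariate_effect("cldial", "dmsa", "power", beta_dmsa, reference = 1,
                     estimate = estimate_beta_dmsa)
  )
}

#' Individual structural parameters from typical values, covariates and etas
#'
#' Applies the covariate model and log-normal between-subject random
#' effects:
#' `CL_i = CLpop (BW_i/70)^0.75 e^eta_CL`,
#' `Vd_i = Vdpop (BW_i/70) e^eta_V`,
#' `CLdial_i = CLdialpop (DMSA_i/1)^1.26 e^eta_dial`
#' under the default effect list; arbitrary [covariate_effect()] lists are
#' applied the same way.
#'
#' @param typicals Named numeric vector/list with `cl`, `v`, `cldial`
#'   typical values (L/h, L, L/h), or a `population_model`.
#' @param covs A [subject_covariates()] object (or bare list with the
#'   needed fields).
#' @param eta Named numeric: random effects on the log scale (default all
#'   zero).
#' @param effects List of [covariate_effect()]; default the reference
#'   pediatric hemodialysis model.
#' @return A [structural_params()] object.
#' @export
individual_structural <- function(typicals, covs,
                                  eta = c(cl = 0, v = 0, cldial = 0),
                                  effects = reference_effects()) {
  if (inherits(typicals, "population_model")) {
    effects <- typicals$effects
    typicals <- typicals$typicals
  }
  typicals <- unlist(typicals)[c("cl", "v", "cldial")]
  if (any(is.na(typicals)) || any(typicals <= 0)) {
    stop("'typicals' must contain positive 'cl', 'v' and 'cldial'")
  }
  eta_full <- c(cl = 0, v = 0, cldial = 0)
  eta_full[names(eta)] <- unlist(eta)
  # multiplicative form: at reference covariates and eta = 0 every factor
  # is exactly 1 and the typical values are returned bit-for-bit
  par <- typicals * exp(eta_full)
  for (ef in effects) {
    par[ef$parameter] <- par[ef$parameter] * exp(effect_log_term(ef, covs))
  }
  structural_params(cl_residual = unname(par["cl"]),
                    v_central = unname(par["v"]),
                    cl_dialysis = unname(par["cldial"]))
}

#' Per-session dialysis clearance scale factors
#'
#' When a subject switches membranes between sessions, the session's
#' effective dialysis clearance scales as
#' `(dmsa_session / dmsa_subject)^beta`.  Returns the session table with
#' its `clearance_scale` column filled in accordingly (sessions without a
#' per-session DMSA keep scale 1).
#'
#' @param sessions A [dialysis_sessions()] data.frame.
#' @param subject_dmsa The subject-level DMSA used in the covariate model,
#'   m^2.
#' @param beta DMSA exponent (default 1.26).
#' @return The sessions data.frame with updated `clearance_scale`.
#' @export
session_scales <- function(sessions, subject_dmsa, beta = 1.26) {
  has <- !is.na(sessions$dmsa)
  sessions$clearance_scale[has] <-
    (sessions$dmsa[has] / subject_dmsa)^beta
  sessions
}
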