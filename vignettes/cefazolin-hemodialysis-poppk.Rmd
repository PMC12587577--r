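---
title: "Cefazolin population pharmacokinetics under intermittent hemodialysis: models, methods and design choices"
author: "cefadial package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cefazolin population pharmacokinetics under intermittent hemodialysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cefazolin is the first-line antibiotic for methicillin-susceptible
*Staphylococcus aureus* (MSSA) bacteremia, a leading severe infection in
children on maintenance hemodialysis. It is cleared renally, so in kidney
failure only a small residual clearance remains — until a dialysis session
starts, at which point the machine adds an extracorporeal clearance an
order of magnitude larger than the residual one, for a few hours, three
times a week. Exposure therefore alternates between very slow interdialytic
decay and rapid intradialytic washout, and the between-subject variability
of the residual clearance is large. Dosing by habit risks both
subtherapeutic troughs (treatment failure, resistance) and accumulation
above the neurotoxicity range.

`cefadial` implements the full quantitative workflow for this setting:

* an exact event-driven PK engine for infusions plus session-gated
  dialysis clearance,
* the pediatric covariate model and its population parameter estimates,
* SAEM estimation of the nonlinear mixed-effects model from sparse
  therapeutic-drug-monitoring (TDM) data,
* MAP-Bayes individualization (the computational core of TDM dosing),
* simulation-based diagnostics (NPDE, prediction-corrected VPC),
* Monte Carlo probability of target attainment and dosing-regimen
  optimization over a weekly dialysis cycle.

Units everywhere: hours, mg, L, mg/L, L/h. Time 0 is the first event of a
subject record.

# Structural and statistical model

## One compartment with switching clearance

The base model is a one-compartment linear model with zero-order infusion
input and first-order elimination. Outside dialysis sessions the
elimination clearance is the residual clearance CL; during a session the
machine clearance CLdial adds to it:

$$ V \frac{dC}{dt} = R(t) - \big(\mathrm{CL} + \mathrm{CLdial}\cdot
\mathbb{1}_{\text{session}}(t)\big)\, C $$

Both the infusion rate $R(t)$ and the total clearance are piecewise
constant, so between any two event boundaries the solution is a single
exponential segment,

$$ C(t_0+\Delta) = C_\infty + (C(t_0) - C_\infty)e^{-k\Delta},
\qquad C_\infty = \frac{R}{kV},\; k = \frac{\mathrm{CL_{tot}}}{V}, $$

which `simulate_profile()` evaluates exactly (an `expm1` form keeps small
$k\Delta$ accurate). Because each segment is monotone, extrema, AUCs and
band-crossing times are closed-form per segment: `exposure_metrics()`
returns exact minima, maxima, AUC and time-in-band, with no grid error. A
two-compartment variant (`simulate_profile_2cmt()`, per-segment
eigen-decomposition of the 2x2 system) is provided because both structures
are candidates during model development; the one-compartment model is the
retained structure.

## Covariates

Individual parameters follow fixed allometric scaling of body weight
(exponent 0.75 on clearances, 1 on volume, reference 70 kg) and a power
effect of the dialysis membrane surface area (DMSA) on the dialysis
clearance:

$$ \mathrm{CL}_i = 0.186\,(BW_i/70)^{0.75} e^{\eta_{CL,i}}, \quad
\mathrm{Vd}_i = 14.6\,(BW_i/70)\, e^{\eta_{V,i}}, \quad
\mathrm{CLdial}_i = 1.98\,(\mathrm{DMSA}_i/1)^{1.26} $$

These reference estimates ship as `cefazolin_hd_model()`. DMSA resolution
follows clinical precedence: a per-session membrane area (patients can
switch membranes) overrides the subject-level value, which defaults to
$0.85 \times \mathrm{BSA}$ with $\mathrm{BSA} = (4BW+7)/(BW+90)$ — 0.85
sits mid-way in the 75–100% of body surface area range used to prescribe
pediatric membranes. Fat-free mass (`fat_free_mass()`) uses the
sex-specific maximal-FFM form (WHSmax 42.92/37.99, WHS50 30.93/35.98
kg/m², heights in metres); it is a candidate covariate, not part of the
final model.

The covariate engine is generic: any list of `covariate_effect()` objects
(power or categorical) can be attached to any parameter, and every effect
is log-linear — which is precisely what makes the SAEM M-step closed form.

## Variability

Between-subject variability (BSV) is log-normal with diagonal
$\Omega$: $\omega_{CL} = 1.07$, $\omega_{Vd} = 0.197$, and no random
effect on CLdial (the membrane-area effect absorbs essentially all of its
interindividual variability). Residual error is proportional with
$b = 0.398$; additive and combined forms are supported for model
development. Inter-occasion variability and random-effect correlations are
deliberately out of scope. Negative simulated concentrations (possible
under proportional error at low levels) are kept in likelihoods and
dropped only from generated datasets and reports.

# Estimation

## SAEM

`fit_saem()` maximizes the marginal likelihood by stochastic approximation
EM with the individual log-parameters
$\psi_i = (\log CL_i, \log Vd_i, \log CLdial_i)$ as latent variables.

* **E-step.** Per subject and iteration: one independence Metropolis draw
  from the current prior, then `n_sweeps` (default 2; 3 for the heavier
  recovery protocol) component-wise random-walk sweeps with per-subject,
  per-component step sizes adapted towards ~35% acceptance.
* **SA-step.** Complete-data sufficient statistics — per parameter the
  design cross-products $X_p^\top(\psi_p - \text{offset}_p)$ and sums of
  squares, plus the residual sum for the error model — are smoothed with
  step size $\gamma_k = 1$ for `n_explore` iterations (default 300) and
  $1/(k - k_0)$ for `n_smooth` more (default 200).
* **M-step.** Because all covariate effects are log-linear, each
  parameter's typical value and estimable effect coefficients solve a
  small least-squares system; $\omega_p^2$ is the mean squared residual of
  that regression and the proportional error coefficient is the RMS
  relative residual. Typical values are intrinsically positive (the
  intercept lives on the log scale). During exploration, variances are
  annealed (they may shrink by at most 5% per iteration) so the chains do
  not collapse into early local modes.

**Degenerate random effects.** When a BSV term collapses towards zero —
as the dialysis-clearance BSV does in the final model — the conditional
chain for that $\psi$ component would freeze at its prior mean and its
typical value and covariate coefficient would stop updating. Two
safeguards keep such parameters identifiable: the sampling prior uses a
floor on $\omega$ (`omega_floor`, default 0.05), and the floor is annealed
from 0.5 down over the exploration phase, so early iterations let the
likelihood position $\psi$ freely while late iterations tighten the
hierarchy. Reported $\omega$ estimates are the unconstrained M-step
updates; values at or below the floor are not distinguishable from zero.

Defaults are sized for sparse pediatric datasets (a handful of subjects to
a few hundred): 300 + 200 iterations, 2 sweeps. The parameter-recovery
protocol used in the acceptance script runs 400 + 300 with 3 sweeps, which
brings the estimator's replication spread close to the design's intrinsic
information floor ($\omega_{CL}/\sqrt{n} \approx 11\%$ for the typical
residual clearance at $n = 100$ subjects).

## Likelihood, BIC, covariate selection

`marginal_loglik()` estimates the observed-data log-likelihood by
importance sampling with a multivariate t (4 df) proposal centred at each
subject's MAP with the posterior-mode curvature; random effects with
$\omega = 0$ contribute as point priors, and a low effective sample size
raises a warning. The BIC uses the mixed-level convention: subject-level
parameters (typical values, covariate coefficients, BSV terms) are
penalized with $\log N_{\text{subjects}}$, residual-error parameters with
$\log N_{\text{observations}}$. This convention is a documented choice
(`bic_from_loglik()`), configurable in the sense that the pieces are small
and explicit.

`covariate_step()` applies the retention rule used throughout this model's
development: a candidate effect is kept only if it decreases the BIC *and*
reduces the BSV of the parameter it acts on. A candidate duplicating an
existing effect short-circuits to "not retained" with the penalty-only BIC
change (the design matrix would otherwise be singular).

`shrinkage()` reports $100(1 - \mathrm{sd}(\hat\eta)/\hat\omega)$; it is
near zero for rich designs and grows as individual etas collapse to the
population prior.

Standard errors are available by nonparametric bootstrap (resampling
subjects; `se_method = "bootstrap"`), which is honest but expensive; the
default fit reports estimates without SEs.

## MAP-Bayes individualization

`map_individual()` minimizes
$-\log p(y_i \mid \eta) + \tfrac12 \eta^\top \Omega^{-1} \eta$ by BFGS
with two starts; random effects with $\omega = 0$ are pinned at zero. Note
a subtlety used in the tests: with prediction-dependent (proportional)
error the posterior mode does not sit exactly at $\eta = 0$ even when the
data fall on the typical curve, because of the $-\log(b f)$ term; the
identity holds exactly for additive error.

# Diagnostics

`npde()` simulates `k_sim` (default 500) replicate observation vectors per
subject under the full model, decorrelates observed and simulated vectors
with the inverse Cholesky factor of the empirical simulation covariance
(ridge-regularized if singular), ranks the observation among simulations,
clamps to $[1/2k,\, 1 - 1/2k]$ and maps through the standard-normal
quantile. Under a correct model the NPDE are iid N(0,1); the three
calibration tests are a one-sample t (mean), a chi-square on the variance
and Shapiro–Wilk (normality) — the targets are standard, the specific
tests are this package's choice. Direction matters when reading the mean:
a model whose clearances are too *low* simulates concentrations that are
too *high*, so observations rank low and the NPDE mean goes negative.

`pc_vpc()` bins on time after last dose (default 6 equal-count bins,
empty bins merged), normalizes each observed and simulated value by the
bin-median population prediction over its own population prediction, and
compares observed 5th/50th/95th percentiles to 90% confidence bands of
the same percentiles across `n_sim` (default 500) simulated replicates.
Percentiles use linear interpolation of order statistics (R type 7);
binning is on time-after-last-dose without stratification by dialysis
phase — with sparse pediatric data, phase-stratified bins would be too
empty to be useful. `gof_tables()` produces the tidy
observed/population/individual prediction table with individual weighted
residuals; `flag_outliers()` screens at $|IWRES| > 5$ and never removes
anything automatically.

# Dosing

## Targets

For a time-dependent antibiotic with ~20% unbound fraction, free trough
(or steady-state) concentrations of at least 4x MIC translate to total
concentrations of at least 20x MIC, with 80 mg/L as the accepted upper
(toxicity) limit. `band_from_mic()` encodes this: MIC 1 mg/L gives the
20–80 mg/L band, MIC 2 mg/L (the *S. aureus* epidemiological cut-off)
gives 40–80 mg/L, and MIC 4 has no feasible band.

## The weekly cycle

Regimens live on a 168-h cycle with dialysis on days 3, 5 and 8 — the
day-8 session wraps onto day 1 of the next week, giving the clinical
2/2/3-day pattern. Session clock times and durations are never published
for this cohort; the defaults are 09:00 starts and 4-h sessions, both
configurable. Candidate administrations never overlap a session (a
maintenance slot falling inside one is deferred to session end, as in
practice — the extracorporeal circuit would clear much of an intradialytic
infusion), and post-dialysis supplements are first-class members of the
candidate family.

## Optimization objective

The optimizer scores the fraction of time the steady-state concentration
spends inside the band over the last of `n_weeks` (default 4) simulated
cycles, with a lexicographic rule: maximize the fraction; among candidates
within 1% of the best, minimize the weekly dose; break ties with fewer
administrations.

Which time counts is the scientifically loaded choice. Holding the band
*through* a dialysis session is only physically possible when the
concentration retained over a session, $e^{-\mathrm{CL_{tot}}\,d/V}$,
is large enough that a session-start level within the band maps to a
session-end level still above the floor. For a near-anuric child that is
the case; for a child with high residual clearance it is not — any
pre-session level at or below 80 mg/L decays below 20 mg/L before the
session ends, and chasing in-session coverage only drives doses (and
peaks) up against the toxicity cap. The default `"adaptive"` objective
therefore scores the full week when in-session coverage is feasible
without the session-start level exceeding 90% of the upper bound (the 10%
headroom avoids designing regimens that ride the toxicity cap), and
scores interdialytic time only — treating sessions as unavoidable
sub-target excursions repaired by post-dialysis redosing — when it is
not. The pure `"full_week"` and `"interdialytic"` objectives remain
available. `pta()` always reports the full-week fraction: attainment
probabilities should not hide the intradialytic dip.

Concentration is linear in dose, so each candidate pattern is simulated
once at unit dose and the whole mg/kg grid (default 0.5–40 by 0.1) is
scanned through closed-form band crossings — the scan is exact and fast.

## The stratified table

Residual clearance is unobservable a priori, so dosing is stratified over
six CL ranges (`cl_strata()`), represented by the arithmetic midpoint for
the lowest (near-anuric) stratum and geometric midpoints elsewhere.
`stratified_dosing_table()` crosses strata with a pediatric weight grid
(default 10, 20, 30, 40, 51 kg). Physically, the per-weight optimal mg/kg
dose cannot be weight-invariant (the weekly cleared volume does not scale
proportionally with weight), so two summaries are offered:

* `shared = TRUE`: one mg/kg regimen per stratum, selected by maximizing
  the *mean* fraction across the weight grid — the constraint under which
  a table can print a single weight-invariant dose per stratum;
* `shared = FALSE`: per-weight optimization, with the stratum summarized
  by the conditional-probability-weighted mean of the per-weight daily
  doses, weights $P(\mathrm{CL} \in \text{stratum} \mid BW)$ under the
  population model. This mirrors how a Monte Carlo study that bins
  simulated subjects by realized clearance composes its strata: small
  children are over-represented in the near-anuric stratum and heavy
  children in the high-clearance one.

For high-clearance strata at low body weight the band may be unattainable
at any candidate dose (the interdialytic half-life is shorter than the
shortest candidate interval allows); those cells carry `attained = FALSE`
and the lexicographic rule still returns the best-coverage minimal-dose
regimen.

`pta()` quantifies what the typical-subject optimization cannot: with BSV
on CL and Vd and (optionally) residual variability, the probability that
a virtual subject spends the entire assessment week in band. Residual
error is assessed on an hourly grid (time-in-band under continuous noise
is otherwise ill-defined); without it the fraction is exact. Clearances
can be drawn uniformly from a stratum instead of from the full BSV
distribution.

# Synthetic data

The raw concentrations behind the reference model are not publicly
deposited, so `generate_study()` produces study-like stand-ins and every
generator records its ground truth (generating model, per-subject etas,
noise-free predictions) for recovery testing. The default design emulates
the cohort: the six-patient covariate fixture (`table1_fixture()`,
including the patient who used two membrane sizes), 30–60 min infusions
every 6–48 h at 5–26 mg/kg, three 4-h sessions per week, horizons equal to
each patient's involvement (4–31 days), and routine-care sampling
(end-of-infusion peaks, pre-dose troughs, pre-/post-dialysis pairs,
~10–20 samples per subject). Actual sampling clock times of the cohort
are unknown; this scheme is a documented assumption.

`rich_design_dataset()` is the standard recovery experiment: `n` subjects
with weight uniform on 10–70 kg, DMSA = 0.85 BSA, 20 mg/kg 30-min
infusions every 24 h for 7 days, sessions on days 2/4/6, and 12 samples
per subject — one peak, three spread troughs, and dense sampling through
two sessions, because the intradialytic decay is what identifies the
dialysis clearance and its membrane-area exponent.

What the generator does *not* emulate: assay drift, dialysis-circuit
adsorption, intra-dialytic hemodynamic instability, dose-timing
irregularities of real wards, or informative sampling (samples taken
*because* a level looked wrong). Passing recovery tests therefore show
the estimator is correct under the stated model, not that the model is
complete for real data. `inject_outliers()` exists to exercise the
residual-based outlier screen against known perturbations.

# Numerical choices and problem sizes

* Breakpoint times are deduplicated after rounding to 1e-9 h; window
  endpoints are matched against the grid at half that resolution.
* $k = 0$ is impossible by construction (CL > 0 enforced), and small
  $k\Delta$ uses `expm1`.
* BLQ observations (below 0.5 mg/L, the assay's lower calibration bound)
  are excluded from fitting with a logged count — the reference dataset
  had none, so no censored-likelihood machinery is carried.
* Test-suite problem sizes are the package's own choices, sized to give
  decisive checks at interactive cost: engine properties on randomized
  72-h schedules against a 1e-11-tolerance ODE oracle; SAEM recovery at
  40–100 subjects; diagnostics on 6–15 subject studies with 200–500
  simulation replicates.
* All stochastic entry points require an explicit integer seed and are
  bit-reproducible given it.

# Limitations

* The hierarchy is diagonal-Ω, one- or two-compartment, linear
  elimination; no inter-occasion variability, no saturable binding. The
  albumin-binding covariate relationship can be expressed as a power
  effect, but mechanistic nonlinear protein-binding models are not
  implemented.
* SAEM standard errors come from an optional bootstrap; no
  Fisher-information approximation is reported by default.
* The dosing optimizer treats dialysis session times as fixed and
  identical across weeks, and its candidate family, while covering the
  clinically sensible patterns (maintenance q6–48 h, post-dialysis
  supplements and anchored patterns), is a grid, not a continuous search.
* Total plasma concentration is modelled throughout, as in the underlying
  clinical dataset; free-fraction conversion enters only through the
  target-band algebra.
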