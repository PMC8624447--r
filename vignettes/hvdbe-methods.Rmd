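---
title: "Simulation methods for bioequivalence power of highly variable drugs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation methods for bioequivalence power of highly variable drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A bioequivalence (BE) study declares a test formulation equivalent to a
reference when the 90% confidence intervals of the geometric mean ratios
(GMR) of Cmax and AUC fall within 80–125%. For highly variable drugs (HVDs)
— within-subject SD of log Cmax or log AUC at or above 0.294, i.e.
within-subject CV ≥ 30% — that band is hard to hit at reasonable sample
sizes even when the products are truly equivalent, so both the EMA and the
FDA allow *reference scaling*: the acceptance region widens with the
measured within-subject variability of the reference product, which in turn
requires a design that administers the reference at least twice (a 3×3
partial replicate or a 2×4 full replicate rather than the conventional 2×2
crossover).

Whether a large 2×2 trial or a smaller replicate trial is the more efficient
way to demonstrate BE for a given drug is a genuine design question: the
decision rules are rule-laden enough (scaling thresholds, caps, point-estimate
constraints, per-endpoint routing) that closed-form power is
impractical. `hvdbe` answers it by Monte-Carlo simulation from a population
pharmacokinetic (PK) model: simulate whole trials, push each one through the
exact regulatory decision procedure, and report the pass rate as power
against the total number of observations N = subjects × periods (a proxy for
study cost measured in hospitalisations).

# The pharmacokinetic model

Concentrations follow a two-compartment model with first-order absorption,
evaluated in closed form as a sum of three exponentials in the micro rate
constants k10 = CL/Vc, k12 = Q/Vc, k21 = Q/Vp and the disposition
eigenvalues λ1 ≤ λ2 (see `?conc_2cpt`). The default typical values are a
clopidogrel-like parameter set — CL 29400 L/h, Vc 14600 L, Q 1040 L/h,
Vp 57300 L, Ka 1.34 (test) / 1.31 (reference) 1/h — with a 75 mg dose held
in pg so concentrations come out in pg/mL, the scale on which the additive
assay error (20 pg/mL) is expressed. The dose itself only matters through
that additive term; it is configurable.

Random effects are lognormal with mean-zero log effects:

* **Between-subject (BSV)**, one draw per subject shared across all periods:
  SDs 0.91 (CL), 1.17 (Vc), 1.33 (Q), 1.20 (Vp), 0.42 (Ka), 0.7 (F). The
  disposition block is correlated: corr(CL, Vc) = corr(Q, Vp) = 0.5, other
  cross-correlations 0. The printed parameter table spans each "0.5" across
  a CL/Vc and a Q/Vp row pair; pairing them within those pairs is the
  natural reading, but the full 4×4 matrix is an argument
  (`corr_disposition`) for anyone who reads it otherwise.
* **Treatment-specific subject effects** for Ka and F: a bivariate
  (test, reference) draw with correlations 0.8 (Ka) and 0.9 (F). Correlation
  1.0 means a subject's test and reference effects coincide.
* **Within-subject / occasion (WSV)**, an independent draw per
  administration, for Ka (SD 0.1) and F (SD 0.20–0.55, the main variability
  dial): because the model is linear in F, the occasion SD of log F *is* the
  within-subject SD of log Cmax and log AUC when no other within-subject
  source is active. Disposition parameters have no occasion effects.
* **Residual error** per concentration sample: C·(1+εp) + εa with
  εp ~ N(0, 0.15²), εa ~ N(0, 20²). The error-exclusion sensitivity arm
  (`include_error = FALSE`) switches both off.

The ratio of typical bioavailabilities tv_f_test/tv_f_ref is the true GMR;
the power grids sweep it over 0.9–1.1.

Each simulated administration is sampled on a schedule dense around the
expected Tmax (0, 0.25, …, 3, 4, 6, 8, 12, 24 h — Ka ≈ 1.3/h puts Tmax near
1 h), then reduced by noncompartmental analysis: Cmax is the observed
maximum, AUC the linear trapezoid to the last sample (AUC0–t, the regulatory
default for single-dose studies; no extrapolation to infinity, no λz fit).

# Decision procedures

**EMA (average BE with expanded limits).** All designs are analysed with a
fixed-effects linear model of the log endpoint on treatment, sequence,
period and subject-within-sequence. In replicate designs the within-reference
SD (SWR) of Cmax comes from the same model restricted to the reference
administrations. If SWR ≥ 0.294 the Cmax limits widen to
100·exp(±0.760·SWR), capped at 69.84–143.19% (the range at CV 50%), with the
additional constraint that the GMR point estimate stay within 80–125%. AUC
is never scaled, and in a 2×2 design nothing is (SWR is not estimable).
Subjects contribute only if they provide at least one test and one reference
value.

**FDA (mixed scaling / RSABE).** Two per-subject log contrasts drive the
scaled analysis: ilat (mean test minus mean reference) and dlat (first minus
second reference administration). s²WR = var(dlat | sequence)/2, per
endpoint. If SWR ≥ 0.294 the criterion is a Howe-type 95% upper confidence
bound on (μT−μR)² − (ln 1.25/0.25)²·σWR² being ≤ 0, plus the 80–125% GMR
constraint; otherwise the unscaled TOST applies — through the
five-variance-term mixed model for the 2×4 full replicate (between-subject
variance per product, their covariance, and within-subject variance per
product; REML via `nlme::lme` with treatment-specific residual weights) and
through the fixed-effects model for 3×3 and 2×2. Subjects missing a record
needed for a contrast simply drop out of that contrast.

Sequence adjustment of the contrast summaries uses the unweighted mean of
per-sequence means with the sequence-stratified residual variance — the
estimator implied by "sequence as an explanatory variable" for (near-)
balanced data; degrees of freedom follow the fitted model
(n − number of sequences).

Overall BE under either guideline is the intersection of the two endpoint
decisions; no multiplicity adjustment is applied (the regulatory
convention).

# Monte-Carlo engine

`estimate_power()` runs `n_replicates` independent trials per grid cell
(design × n × GMR × WSV), each replicate being simulate → residual error →
NCA → dropout → both decisions. Power is the pass fraction with an exact
binomial 95% interval. Replicate seeds are drawn once from the master seed
(`sample.int(2^31−2, cells × replicates)`), so any replicate is reproducible
in isolation and a parallel execution would match the sequential one. A
replicate whose analysis fails (insufficient degrees of freedom after
dropout, inestimable contrasts, non-convergent mixed fit with no usable
fallback) counts as a BE failure with a reason code — a trial that cannot be
analysed is a failed trial — and the per-cell count of such failures is
reported.

Dropout is completely at random and monotone: each subject independently
receives a dropout period from cumulative probabilities 3% / 4% / 6% by
periods 2 / 3 / 4 (truncated to the design), and all records from that
period on are removed. The printed rates are read as cumulative ("increased
proportionally" with duration); an incremental reading is available via
`dropout_schedule(cumulative = FALSE)`.

The 3×3 partial replicate uses sequences RRT/RTR/TRR — the layout that
administers the reference twice per subject, without which SWR would not be
estimable; the source material never prints its sequence set, so this
standard partial-replicate choice is the default and explicit sequences can
be supplied.

# The validation preset

`validation_preset()` reproduces the conditions under which simulation-based
power can be compared against published LMM-based sample-size results:
test–reference correlations of 1, occasion variability confined to F
(SD 0.294, so the within-reference CV is exactly 30%), Ka occasion SD 0, and
no residual error. Because those conditions require a subject's PK to be
*identical* across products, the preset also equates the Ka typical values
(both 1.31); leaving the 1.34/1.31 split in place would shift the true Cmax
GMR off the bioavailability ratio and contradict the stated premise. Under
this preset the true GMR of both endpoints is exactly `tv_f_test`, which is
what the parameter-recovery checks in the test suite exploit.

# Post-hoc subsampling

Given an observed three-period replicate dataset (one test, two reference
records per subject), `posthoc_power()` repeatedly draws virtual trials:

* **2×2**: keep the test record and one uniformly chosen reference record
  per subject; the synthesized sequence label follows the retained
  chronological order and periods are re-indexed 1..2 so the fixed-effects
  design matrix stays coherent. An optional subject subsample first matches
  a smaller N.
* **3×3**: keep `round(N/3)` randomly chosen subjects intact.

The pass fraction over iterations is the post-hoc power. Reported
within-subject CVs follow the design's estimable quantity: within-*total*
CV (residual SD of the fixed-effects model) for 2×2 subsamples,
within-*reference* CV for 3×3.

One behavioural subtlety is worth knowing: if bioavailability is the *only*
within-subject source, log AUC and log Cmax are identical up to a per-record
constant, so under the EMA rule the never-scaled AUC test binds equally for
every design and the replicate designs lose their apparent advantage at
matched N. The replicate advantage reappears whenever Cmax carries extra
within-subject variability (absorption-rate occasion effects, residual
error) — which is both the realistic situation and the one the main
parameter set produces.

# Numerical choices

* Eigenvalue degeneracy: if Ka falls within 1e-9 relative of λ1 or λ2 (a
  removable singularity of the closed form) it is perturbed by 1e-6 relative
  and a message is emitted.
* Negative observed concentrations from the additive error are floored at 0
  and retained; no LLOQ rule is applied, keeping the NCA defined.
* C(0) is forced to exactly 0 (the three exponential terms cancel
  analytically; floating point leaves a ~1e-12 residue).
* All logs are natural; limits are carried on the log scale and converted to
  percent for reporting (two decimals, matching the printed precision of
  69.84–143.19%).
* Mixed-model fits use `opt = "optim"` with raised iteration caps; on any
  failure the fixed-effects CI is used and flagged (`fallback = TRUE`).

# What the tests do and do not show

The suite checks the closed form against independent ODE integration
(deviations below 1e-6 where the curve is above ~1e-9 of its peak; far
below that the comparison hits the solver's absolute-tolerance floor), the
decision statistics against hand-built QR/normal-equations and brute-force
Howe-bound oracles, parameter recovery (SWR and GMR) at the validation
conditions, the TOST type-I error at the 80% boundary, and the qualitative
power trends (power grows with N; GMR 1.0 beats 0.9; the 2×2 is the weakest
design at CV 0.6 and matched N; dropout lowers and error-exclusion raises
power). Trend checks run at 200 replicates per cell with paired
common-random-number comparisons where possible, and recovery runs use
n = 200 subjects × 200 replicates — sizes chosen to keep Monte-Carlo error
well inside the asserted margins. Simulated trials are synthetic throughout:
they emulate the stated variability structure, not assay artefacts (LLOQ
censoring, sampling-time deviations, carryover), so passing tests speak to
the statistical machinery, not to any particular real dataset.

# Limitations

* Zero-plus-first-order absorption (the richer model a real clopidogrel fit
  suggests) is out of scope; the simulator uses pure first-order absorption.
* Fitting the PK model to raw concentration data is out of scope; typical
  values and variabilities are inputs.
* Dropout is completely at random; informative withdrawal is not modelled.
* Only `T`/`R` two-formulation crossovers are supported — no two-stage or
  adaptive designs.

# A minimal session

```{r}
library(hvdbe)

# power of a 2x4 full replicate for a borderline HVD, true GMR 1.05
sc <- be_scenario(model = pk_model(tv_f_test = 1.05,
                                   wsv = c(ka = 0.1, f = cv2sigma(0.35))),
                  design = "2x4", n_grid = c(24, 36, 48),
                  gmr_grid = 1.05, n_replicates = 1000, seed = 1)
curve <- estimate_power(sc)
plot_power_curve(curve)

# one fully reproducible trial and its decisions
ds <- simulate_trial_dataset(sc$model, "2x4", 36, seed = 42)
ema_decision(ds, be_design("2x4"))
fda_decision(ds, be_design("2x4"))
```
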