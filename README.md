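# hvdbe

Model-based design and power simulation for bioequivalence trials of highly
variable drugs (HVDs).

A drug is highly variable when the within-subject SD of log Cmax or log AUC
is ≥ 0.294 (within-subject CV ≥ 30%). For such drugs the conventional 2×2
crossover with the 80–125% acceptance range needs prohibitive sample sizes,
so regulators allow *reference-scaled average bioequivalence*: the EMA
expands the Cmax limits to 100·exp(±0.760·S_WR) (capped at 69.84–143.19%),
the FDA tests a 95% upper confidence bound on

    (μT − μR)² − (ln 1.25 / 0.25)² · σ²WR  ≤  0

— both only in designs that give the reference twice (3×3 partial
replicate, 2×4 full replicate), both with a GMR point-estimate constraint,
and both falling back to the unscaled TOST when S_WR < 0.294. Which design
reaches a target power with the fewest total observations N = subjects ×
periods is the planning question this package answers, for trial
statisticians and clinical pharmacologists sizing HVD bioequivalence
studies.

Instead of assuming a variance model directly on the endpoints, `hvdbe`
simulates whole trials from a two-compartment oral population PK model
(clopidogrel-like defaults; lognormal between-subject, occasion-level and
test–reference-correlated random effects; additive + proportional assay
error), reduces every administration to Cmax and AUC0–t by noncompartmental
analysis, applies the exact EMA and FDA decision algorithms, and reports
power as the Monte-Carlo pass rate — including dropout and error-exclusion
sensitivity arms and a post-hoc subsampling power analysis for observed
replicate datasets.

## Worked example

Power of a 2×4 full replicate for a drug with within-subject CV 45% and a
true GMR of 105%:

```r
library(hvdbe)

m <- pk_model(tv_f_test = 1.05, wsv = c(ka = 0.1, f = cv2sigma(0.45)))

# one fully reproducible trial and its regulatory decisions
ds <- simulate_trial_dataset(m, "2x4", 36, seed = 42)
ema_decision(ds, be_design("2x4"))
#> EMA bioequivalence decision: FAIL
#>   cmax (scaled) GMR 115.83%  90% CI [101.05, 132.77]  limits [ 69.84, 143.19]  SWR 0.485  pass
#>   auc  (unscaled) GMR 111.25%  90% CI [ 98.57, 125.56]  limits [ 80.00, 125.00]  fail
fda_decision(ds, be_design("2x4"))
#> FDA bioequivalence decision: PASS
#>   cmax (scaled) GMR 115.83%  SWR 0.485  pass
#>   auc  (scaled) GMR 111.25%  SWR 0.439  pass
```

The same trial passes under the FDA rule but fails under the EMA rule: the
FDA scales both endpoints while the EMA never scales AUC, whose 90% CI here
(98.57–125.56%) just misses 125%. That asymmetry is exactly what the power
curves quantify:

```r
sc <- be_scenario(model = m, design = "2x4", n_grid = c(24, 36, 48),
                  gmr_grid = 1.05, n_replicates = 200, seed = 1)
estimate_power(sc)
#>   design guideline  gmr cv_wr n_subjects   N power mc_lower mc_upper
#> 1    2x4       EMA 1.05  0.45         24  96 0.405    0.336    0.477
#> 2    2x4       FDA 1.05  0.45         24  96 0.740    0.673    0.799
#> 3    2x4       EMA 1.05  0.45         36 144 0.740    0.673    0.799
#> 4    2x4       FDA 1.05  0.45         36 144 0.925    0.879    0.957
#> 5    2x4       EMA 1.05  0.45         48 192 0.830    0.771    0.879
#> 6    2x4       FDA 1.05  0.45         48 192 0.960    0.923    0.983
```

Each row is one grid cell: `power` is the fraction of 200 simulated trials
passing overall bioequivalence (both endpoints), with an exact binomial 95%
Monte-Carlo interval; `N` is the total-observation cost axis used to compare
designs. `plot_power_curve()` draws power vs N, one line per design,
faceted by guideline and GMR. Set `n_replicates = 1000` for
production-grade curves.

A thin command-line front end lives in `inst/cli/hvdbe.R`
(`simulate`, `power-curve`, `validate`, `posthoc`), driven by YAML configs
(`load_scenario()` / `save_scenario()`).

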