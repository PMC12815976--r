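# atezosim

Population pharmacokinetic (popPK) Monte-Carlo simulation of intravenous
atezolizumab dosing regimens, built for pharmacometricians evaluating
extended-interval schedules: can a lower, less frequent maintenance dose keep
serum concentrations above the 6 µg/mL minimum effective concentration (MEC)
while reducing overall exposure?

The package simulates four regimens over 7 cycles — the standard
**1200 mg q3w** and three extended-interval schedules (two loading doses of
840 mg q2w, 1200 mg q3w, or 1680 mg q4w, followed by five maintenance doses
of **840 mg q6w**) — for a 1000-subject virtual population, and summarizes
per-cycle exposure as geometric means with 90% prediction intervals.

## The model

**Virtual population.** Age ~ U(20, 80) yr; even-odds sex;
weight (kg) = 65 (F) or 85 (M) + 0.75·(age − 40) + N(0, 3.5² F / 10² M);
albumin ~ exp(N(ln 42, 0.10²)) g/L; baseline tumor size ~ exp(N(4.2, 0.70²)) mm;
anti-drug antibodies (ADA) ~ Bernoulli(0.40). All draws are seeded with
per-quantity substreams.

**PK model.** A linear two-compartment IV model, CL/V1/Q/V2, with
covariates as power models for continuous covariates,
`θ·(x/x_ref)^γ`, and proportional shifts for binary ones, and log-normal
inter-individual variability `θ_i = θ·e^η`, `η ~ N(0, Ω)`. The biexponential
macro constants α ≥ β solve `s² − (k10+k12+k21)s + k10·k21 = 0` with
`k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`. Profiles are evaluated in closed
form — exact infusion integrals superposed over dose events — and
cross-validated against a `deSolve` ODE integration to ≤1e−6 relative. The
shipped default configuration transcribes the published atezolizumab popPK
parameterization (Stroh et al. 2017 / FDA CDER clinical pharmacology review);
see `inst/extdata/default_config.yaml`.

**Exposure metrics.** Per cycle: Cmax (maximum on the grid, attained at end
of infusion), Cmin (trough at the end of the dosing interval), and weekly AUC
(trapezoidal AUC over the interval × 7/interval-days, the only AUC scale
comparable across 14/21/28/42-day intervals). Population summaries report
geometric means and the 5th/50th/95th percentiles (90% PI).

## Worked example

```r
library(atezosim)
cfg  <- read_run_config()                       # shipped default config
spec <- cfg$population
spec$seed <- derive_seed(cfg$seed, "population")
pop  <- generate_population(spec)               # 1000 virtual patients
sim  <- simulate_population(pop, cfg$model, cfg$regimens[["1200 mg q3w"]],
                            seed = cfg$seed)
summarize_exposure(exposure_metrics(sim))
```

```
      regimen cycle     metric geo_mean     p5    p50  p95   mean    sd
1 1200 mg q3w     1       cmax    381.6  260.0  374.3  581  393.7 100.6
2 1200 mg q3w     1       cmin     76.1   44.8   78.2  117   79.4  22.1
3 1200 mg q3w     1 weekly_auc    949.0  697.4  955.6 1263  964.3 170.9
4 1200 mg q3w     7       cmax    564.8  382.0  559.9  871  582.9 148.7
5 1200 mg q3w     7       cmin    172.9   73.9  177.3  368  193.9  92.0
6 1200 mg q3w     7 weekly_auc   1886.8 1060.5 1893.2 3327 2003.7 700.3
```

Reading the cycle-7 rows: at approximate steady state the standard regimen's
geometric-mean trough is ~173 µg/mL with a 90% PI of 74–368 µg/mL — every
simulated subject stays far above the 6 µg/mL MEC — and the geometric-mean
weekly AUC is ~1887 µg·day/mL, consistent with the steady-state identity
weekly AUC ≈ dose/(3·CL) for a 3-week interval.

`run_pipeline(cfg, "out/")` executes everything (population table, one
exposure summary per regimen, and median/90%-PI ribbon figures for cycles 1
and 7 of each regimen, with the MEC reference line). A thin command-line
wrapper with subcommands (`generate-pop`, `simulate`, `summarize`, `plot`,
`export-nonmem`, `benchmark`, `run-all`) lives at `inst/cli/atezosim.R`.
`export_nonmem_dataset()` writes a NONMEM-style event/observation dataset
(ID/TIME/AMT/RATE/EVID/CMT/DV plus covariates) for cross-tool validation.

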