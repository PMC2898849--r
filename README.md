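# plumetrace

Historical drinking-water exposure reconstruction and case-control
analysis for groundwater contamination settings.

When a wastewater facility discharges effluent to a sand aquifer
upgradient of drinking-water wells, the epidemiological question is
*when* each study participant's tap water first carried effluent — a
joint function of groundwater flow, well pumping history, and where each
person lived over decades. plumetrace implements the whole chain:

* **Flow** — steady-state groundwater flow on a block-centered
  finite-difference grid, solved independently for each calendar-bounded
  pumping period (`build_stress_periods()`, `assemble_system()`,
  `solve_steady_state()`). Inter-cell conductances are harmonic-mean
  conductivity times face area over center distance; the sparse SPD
  system is solved by a direct Cholesky factorisation with an explicit
  mass-balance check.
* **Tracking** — semi-analytical advective particle tracking
  (per-axis linear velocity, closed-form cell transit times) from the
  effluent source to the wells under alternative pumping scenarios,
  yielding a first-impact calendar year per well
  (`track_particle()`, `detect_arrivals()`), plus a 100-ft depth rule
  for private wells (`private_well_impact()`).
* **Exposure** — residential histories + impact schedule give each
  subject ever-exposure, first exposed year and cumulative duration
  under latency assumptions of 0/10/15/20 years
  (`compute_exposure()`).
* **Analysis** — 2x2 tables against a never-exposed referent, crude
  odds ratios with Woolf 95% CIs
  (`crude_or()`: point $(ad)/(bc)$, interval
  $\exp(\ln OR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$), and covariate-adjusted
  ORs by logistic regression (`fit_logistic()`,
  `run_analysis_grid()`, `stratified_analysis()`).
* **Synthetic ground truth** — a generator for a small solvable
  aquifer fixture and a case-control cohort with a known true exposure
  OR and a real confounder, so every stage is testable without any
  confidential data (`generate_aquifer()`, `generate_cohort()`).

Units are feet and days throughout; 365.25 days per calendar year.

## Worked example

```r
library(plumetrace)

model <- generate_aquifer()                       # synthetic aquifer fixture
high  <- simulate_scenario(model, "high", seed = 1)  # 75%-capacity scenario
high$schedule
#>   scenario_id          well_id first_impact_year
#> 1        high      hyannisport              1969
#> 2        high      straightway              1967
#> 3        high     simmons_pond              1971
#> 4        high straightway_repl              1990
```

Effluent released at the source in 1937 first reaches a supply-well cell
in 1967 under the high pumping scenario (1969 under the low one — higher
pumping pulls the plume in sooner). Now a cohort with a known true
exposure odds ratio of 1.5, exposure reconstructed through the same
machinery, and the latency-by-contrast analysis grid:

```r
cohort  <- generate_cohort(cohort_config(true_or = 1.5, seed = 11),
                           model, high)
records <- do.call(rbind, lapply(c(0, 10, 15, 20), function(L)
  compute_exposure(cohort$subjects, cohort$residences, high$schedule,
                   cohort$systems, latency = L,
                   private_arrivals = high$private_arrivals,
                   grid = model$grid)))
grid <- run_analysis_grid(cohort$subjects, records,
                          covariates = "family_history")
grid[grid$contrast == "ever",
     c("latency", "cases_exposed", "controls_exposed",
       "cor_text", "aor_text")]
#>  latency cases_exposed controls_exposed      cor_text      aor_text
#>        0           109              111 1.3 (1.0-1.8) 1.3 (0.9-1.7)
#>       10            98              100 1.3 (0.9-1.8) 1.3 (0.9-1.8)
#>       15            92               89 1.4 (1.0-2.0) 1.3 (0.9-1.9)
#>       20            55               56 1.3 (0.9-2.0) 1.3 (0.9-2.0)
```

The exposed count shrinks as the latency requirement grows, and the
adjusted OR estimates hover around the generating value of 1.5. The OR
machinery itself reproduces published sparse-table arithmetic exactly:

```r
crude_or(contingency_table(7, 2, 535, 704))
#> <or_result> 4.6 (1.0-22.3) [crude_woolf]
```

`run_pipeline(pipeline_config(out_dir = "out", seed = 1))` chains all
stages for the low and high scenarios and writes schedules, tracks,
exposure records, head fields, the analysis grid and a hash manifest;
reruns with the same seed are bit-identical.

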