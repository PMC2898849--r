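---
title: "Reconstructing historical drinking-water exposure from groundwater modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing historical drinking-water exposure from groundwater modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumetrace)
```

## The problem

Wastewater treatment plants that discharge effluent to a permeable sand
aquifer create a slowly moving contaminant plume. Where public and
private drinking-water wells sit downgradient of such a facility, the
question for an epidemiologist is not only *who lived where*, but *when
the water at each address first carried effluent*. plumetrace
reconstructs that history in four stages and then estimates the
exposure-disease association in a case-control design:

1. **Flow** (`assemble_system()`, `solve_steady_state()`,
   `cell_velocities()`): steady-state groundwater flow on a
   block-centered finite-difference grid, one independent solution per
   historical pumping period.
2. **Tracking** (`seed_particles()`, `track_particle()`,
   `detect_arrivals()`): advective particle tracking from the effluent
   source through the per-period velocity fields, recording the first
   calendar year each supply well's grid cell captures a particle.
3. **Exposure** (`assign_water_source()`, `compute_exposure()`):
   residential histories plus the well impact schedule give each subject
   an ever-exposed flag, a first exposed year and a cumulative duration,
   per latency assumption.
4. **Analysis** (`crude_or()`, `fit_logistic()`,
   `run_analysis_grid()`): 2x2 tables against a never-exposed referent,
   crude odds ratios with Woolf intervals, and covariate-adjusted odds
   ratios by logistic regression.

All lengths are in feet, rates in feet^3/day, and time in days, with
365.25 days per calendar year. Cells are addressed `(layer, row, col)`,
1-based, layer 1 shallowest.

## The flow model and its assumptions

The aquifer is discretised into rectangular cells with per-cell
hydraulic conductivity $K$ and effective porosity $n$. Steady-state
conservation in cell $i$ reads

$$\sum_{j \in \mathrm{nbr}(i)} C_{ij}\,(h_j - h_i) + Q_i = 0,$$

where $h$ is hydraulic head (ft), $Q_i$ collects well rates and areal
recharge (ft^3/day), and the interblock conductance between adjacent
cells is the harmonic-mean conductivity times face area over center
distance:

$$C_{ij} = \frac{A_{ij}}{L_i/(2K_i) + L_j/(2K_j)}.$$

Fixing the head in at least one cell (constant-head boundaries) makes
the system symmetric positive definite; it is solved by a direct sparse
Cholesky factorisation (via the Matrix package), and the per-cell mass
balance residual is checked against a tolerance of $10^{-8}$ times the
largest stress (with a floor of $10^{-8}$ ft^3/day). A direct solve was
chosen over an iterative one because the package's grids stay below a
few tens of thousands of unknowns, where factorisation is both faster
and free of convergence tuning; the residual check is the same contract
an iterative solver would satisfy.

Key simplifying assumptions, made deliberately and visible in the API:

* **Piecewise-steady flow.** Each stress period — a calendar interval
  with fixed pumping, delimited by supply-well start and replacement
  years (`build_stress_periods()`) — is solved as an independent steady
  state. Transients at period boundaries are ignored.
* **Confined-equivalent transmissivity.** Layer thickness is fixed;
  the water-table (saturated-thickness) nonlinearity is not iterated.
* **Advection only.** Effluent is assumed to move with the groundwater;
  dispersion, retardation and decay are out of scope, so the package
  reports arrival years, never concentrations.

## Particle tracking

Within a cell, each seepage-velocity component is interpolated linearly
along its own axis from the two face values,
$v(x) = v_1 + A\,(x - x_1)$ with $A = (v_2 - v_1)/\Delta x$, which gives
a closed-form transit time to each candidate exit face,

$$t_e = \frac{1}{A}\,\ln\!\frac{v(x_\mathrm{exit})}{v(x_p)}
\qquad\left(\to \frac{x_\mathrm{exit} - x_p}{v}\ \text{as}\ A \to 0\right),$$

the exit face being the axis with the smallest positive $t_e$
(`pollock_step()`). Seepage velocity is the face Darcy flux divided by
the porosity of the cell being crossed. The numerical switch between
the logarithmic and uniform forms triggers when
$|v_2 - v_1| \le 10^{-10}\max(|v_1|,|v_2|)$; exit coordinates are
snapped exactly onto the crossed face, and candidate times $\le 0$ are
treated as unavailable, so a particle sitting on a face never steps
backwards. A particle whose candidate exits are all unavailable (an
internal stagnation point) terminates as `stagnant`.

Tracks are advanced under the velocity field of the stress period
containing the particle's current calendar time; at a period boundary
the particle keeps its position and continues under the next field, with
no interpolation between fields. A track ends by:

* **capture** — the particle enters a grid cell whose wells are a net
  sink in the current period (this is the "track ends in the cell
  containing the well" rule; a cell whose wells inject on balance lets
  particles pass);
* **domain exit** — the particle leaves the grid or enters a
  constant-head cell, which stands for far-field boundary water;
* **stagnation** or **horizon exhaustion**.

Arrival years are `floor(release_year + clock/365.25)`, credited only
within a well's operating years; the earliest captured particle defines
the well's first impact year. Particle density defaults to 25 per
source cell on a stratified lattice whose strata are fixed by the count
and whose within-stratum jitter is the only seeded randomness — the
published-style analyses this mirrors do not state a density, so the
default was chosen so that doubling it moves fixture arrival years by
at most one year (a property the test suite checks).

Private wells are screened with a depth criterion: a residence on a
private well is impacted from the first year any track passes through
its planar grid cell within 100 ft of land surface (the top of layer 1),
reflecting how shallow domestic wells in this kind of aquifer typically
are. Segment midpoints are tested along with vertices so a fast
crossing of a cell still registers.

## Exposure metrics

A residence's impact years are the inclusive intersection of its
occupancy years with the years its water was impacted: for a public
residence, from the serving system's first impact year onward (all
addresses on a system share one status per year, because systems mix
their wells' water in a common standpipe); for a private residence,
from the depth-criterion first year onward. Years after the subject's
index year (diagnosis year for cases, assigned year for controls) never
count.

Two conventions required a decision because "adding the number of
ever-exposed residence years" is ambiguous:

* **Duration.** The default (`duration_mode = "occupancy"`) counts all
  occupancy years at ever-exposed residences, truncated at the index
  year — pre-impact years at an impacted address count. The alternative
  (`"impacted-only"`) counts only calendar years with impact. Both are
  implemented; the default matches the larger duration maxima a
  zero-latency analysis can produce when occupancy predates impact.
* **Latency.** A latency of $L$ years is an induction criterion on the
  first exposed year (`first_exposed_year <= index_year - L`), not a
  truncation of duration at $index - L$. A subject failing the
  criterion is treated as unexposed at that latency and is excluded
  from both cells of the latency's tables (the referent is always the
  set of subjects never exposed over the whole study period).

Subjects whose every residence has an unknown water source are flagged
non-analyzable and excluded from table denominators, with counts
available via the records. A concentration-weighted sensitivity score
(`nitrate_weighted_exposure()`) sums available nitrate-N concentrations
at the supply wells over each subject's exposed residence-years and
assigns quartiles among the exposed.

## Effect estimation

`crude_or()` computes $(ad)/(bc)$ with the Woolf interval
$\exp(\ln\widehat{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$; any zero
cell renders the estimate undefined and displayed as a dash — no
continuity correction, matching the published-table convention the
package reproduces. Display rounding is one decimal, half-up.
`fit_logistic()` fits case/control status on the binary exposure plus
dummy-encoded categorical covariates by maximum likelihood (`stats::glm`)
and reports the adjusted OR as the antilog of the exposure coefficient
with a Wald interval; non-convergence or separation (detected as
non-finite or extreme coefficients or standard errors) suppresses the
estimate rather than reporting an unstable number. Duration contrasts
`>0-5`, `>5` and `>10` years are each compared with the never-exposed
referent; the latter two overlap by construction. No multiplicity
adjustment is applied — each contrast carries its own interval.

## What the synthetic generator emulates

Because the residential histories and regional model behind the original
analyses are confidential or available only on request, the package
ships a synthetic stand-in with the same *structure*, not a
reconstruction of the real geography:

* `generate_aquifer()` builds a single-layer, 24 x 46-cell, 250-ft
  sand aquifer (K = 200 ft/day, porosity 0.39, thickness 140 ft,
  regional gradient about 0.001 maintained by constant-head columns,
  recharge 0.001 ft/day) with a persistent effluent source
  (130,000 ft^3/day, roughly 1 MGD) about 1.5 miles upgradient of four
  supply wells. Well start years 1953, 1961 (replaced 1984) and 1970
  split 1937-1993 into five stress periods. The well with unknown
  pumping history is scenario-scaled to 30%, 50% or 75% of its rated
  96,250 ft^3/day (28,875 / 48,125 / 72,188 ft^3/day); its neighbours
  hold 30% and 50% as ordinary operating points. These values are
  typical of glacial outwash water-supply settings and were fixed once;
  with them, effluent released in 1937 reaches the well cluster in the
  late 1960s, earlier under higher pumping — the qualitative behaviour
  the sensitivity analysis needs.
* `generate_cohort()` draws a source-population pool, reconstructs each
  member's exposure through the package's own exposure machinery, and
  assigns disease from a logistic model with a configurable true
  exposure OR plus one binary confounder that raises both the chance of
  living in the impacted service area and the outcome odds — so crude
  estimates are confounded and adjusted ones should not be. Sampling
  exactly 638 cases and 842 controls preserves the exposure OR
  (case-control sampling moves only the intercept). Defaults mirror the
  emulated study's shape: index years 1983-1993 shared by cases and
  controls, about 79%/18%/3% of subjects with 1 / 2-3 / 4-6 addresses,
  roughly 23% bottled-water users, and service-area membership
  probabilities (0.17 with the confounder, 0.10 without, with
  probability 0.65 of staying on a move) chosen so that about one in
  six subjects is ever exposed, as in that study. Residences outside
  the service area are drawn from a study region four times the model
  footprint, so most lie beyond the plume neighbourhood — without this
  the small synthetic domain would wildly over-represent private-well
  impact.

What the generator does **not** emulate: real geography and pipe
networks, proxy-response and other reporting error, migration in and
out of the study area, missing residential spells, secular trends in
index years, or any dose-response structure (exposure is binary at the
year-address level). Passing tests therefore demonstrate that the
machinery recovers known effects under clean conditions, not that any
particular real-world estimate is unbiased.

## Numerical and design choices

* 1-based `(layer, row, col)` indexing, the R idiom, rather than
  0-based.
* Direct sparse Cholesky solve; residual tolerance
  $10^{-8} \times$ max stress; isolated cells and missing constant-head
  boundaries are errors, as are wells in constant-head cells.
* Transit-time uniform/logarithmic switch at relative $10^{-10}$; exit
  positions clamped into the cell and snapped onto faces.
* Arrival year by `floor()`; 365.25 days/year.
* Earliest-particle arrival (not a plume-fraction threshold) defines a
  well's first impact; the alternative would need a particle-mass
  bookkeeping the advection-only design does not carry.
* Half-up display rounding to one decimal; ASCII `-` for undefined
  estimates.
* Test problem sizes: Thiem verification on an 81 x 81 grid, coverage
  studies on 200 replicate cohorts per true OR — sizes at which the
  checked tolerances (2% drawdown error, 0.1% transit error, ~95%
  coverage) are comfortably resolved.

## Known limitations

* Single-phase, confined-equivalent, advection-only: no concentrations,
  no unconfined rewetting, no transient storage.
* The weak-sink rule (terminate only in net-sink cells) is a
  simplification of flux-weighted capture; it can make first arrivals
  at weak sinks slightly early.
* The private-well depth rule tests track geometry only; it knows
  nothing about actual well screens.
* Exposure is annual and binary per address; partial years and personal
  water use are not modeled.
* The published-table fixture carries three printed values that are
  inconsistent with their own printed counts under any single rounding
  rule; the reproduction test reports them as mismatches rather than
  silently accepting either side.
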