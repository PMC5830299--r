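---
title: "Methods: Monte Carlo resource selection functions for ice seals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo resource selection functions for ice seals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealrsf)
```

# The model and its assumptions

`sealrsf` estimates a resource selection function (RSF) in a matched
use-availability design. Observed telemetry locations are the *cases*;
*controls* are locations simulated from a null movement model fitted to
the same animals, matched one-to-one in time and count. The logistic
regression of case against control,

$$\mathrm{logit}\,P(\text{case}) = \beta_0 + \beta^\top x,$$

is then a log-ratio of use to availability: positive coefficients mark
selected habitat, negative coefficients avoided habitat, and
$\exp(\beta^\top x)$ is the *odds of selection* (> 1 chosen, < 1
rejected).

Two deliberate modelling positions are inherited by the whole package:

* **Equal observation weights, no random effects.** Every location
  counts equally, so animals with longer records carry proportionally
  more weight. A mixed model would weight animals more equally; we use
  the simple logistic regression throughout.
* **Monte Carlo variance correction.** Locations are strongly
  autocorrelated in space and time, so the model-based standard errors
  of any single logistic fit are biased downward. Instead, one
  regression is fitted per control replicate (default 20), the per-term
  estimate is the mean across replicates, and the standard error is the
  *standard deviation* (not the standard error of the mean) of the
  coefficients across replicates; $z = \bar\beta / \mathrm{SD}$ with
  two-sided normal p-values. The across-replicate spread captures the
  control-sampling noise that a single fit pretends away. Twenty
  replicates is the long-standing minimal count for Monte Carlo tests of
  this kind.

A consequence worth knowing: because the cases are shared across
replicates while each replicate has its own controls, the z statistic is
mildly anti-conservative (the shared-case variance appears in the mean
but not in the SD). The calibration test in the suite measures the
realized retention rate of an inert term under the null and accepts it
within a binomial band around α.

# The null movement model

Tracks are decomposed into steps: elapsed time, initial great-circle
bearing, great-circle length, speed = length/elapsed. The null model is
a correlated random walk with

* a first-order Markov transition table over binned absolute bearings
  (default 36 bins × 10°), additively smoothed (α = 0.5 per cell) so no
  row is degenerate. Any directional drift in the data — here, the
  southerly push of animals following advancing ice — is inherited by
  the simulations rather than hard-coded, which is what keeps controls a
  sensible availability sample as the season progresses;
* a speed distribution on a variance-stabilized scale: speeds are capped
  (default 8 km/h) and fourth-root transformed before binning (default
  20 bins). Argos positional error inflates apparent speeds over short
  intervals and skews the raw distribution badly; the cap and the
  fourth root are the auditable knobs standing in for that skew control.
  A previous-bin-conditioned (Markov) speed table is available
  (`condition_speed = TRUE`) but the marginal is the default;
* exclusion of steps longer than `max_gap_h` (default 72 h) from
  *fitting* — they say nothing about swimming speed — while the matched
  timestamps are still *simulated* as a single draw, because temporal
  matching is non-negotiable.

Simulated tracks start at the template's first observed position of the
analysis segment and reproduce its timestamps bit-for-bit. Draws landing
on land are redrawn (fresh bearing and speed, up to 50 times, then an
error with context); silent clamping would bias coastal habitat.

Geodesy is spherical (R = 6371 km, haversine distances, forward
azimuths). At subpolar latitudes the ellipsoidal error is below 0.5%,
far inside Argos noise, and no projection dialect is introduced.

# Habitat covariates

Per location (case and control alike): distance to coast `d2coast`,
seafloor depth `depth_m`, distance to the 1000 m isobath `d21kiso`
(shelf break), distance to the same-day ice edge `d2ice`, cell ice
concentration `ice_conc` and its square, and the binary `sea_ice`.
Conventions, with the reasoning where the choice was genuinely open:

* **Ice edge** = the 10% concentration isoline of that day's grid; 10%
  rather than 0% buys robustness to low-concentration measurement
  noise. Isolines shorter than 50 km are discarded as speckle — the
  minimum applies to the ice edge only; isobaths and coastlines keep all
  segments.
* **Raster values** are read from the containing cell, no interpolation;
  ice layers are resolved by the UTC calendar date of the fix with no
  temporal interpolation. Case and control rows for the same animal and
  timestamp therefore share layers, preserving the matching.
* **Distances** are haversine minima to polylines densified to ≤ 1 km
  vertex spacing, bounding the error by the densification without
  committing to a projection.
* **`sea_ice`** is `ice_conc > 0` at the cell (threshold configurable).
  Zero is the natural boundary for microwave concentration products,
  which report 0 in open water.
* **Transforms**: `d2coast`, `d2ice`, `d21kiso` and `depth_m` enter as
  square roots (linearizing heavily right-skewed positive covariates);
  `ice_conc` also enters squared to allow an interior optimum. The
  reference final model names its depth term `depth_m`, but we model
  `sqrt(depth_m)` uniformly with the other skewed covariates and note
  the naming inconsistency here rather than silently resolving it.
* **Coastline** is derived from the grid's own land mask (the 0.5
  isoline of the 0/1 land indicator), the same grid that defines the
  study area and the land filter.
* Rows with any unresolvable covariate (e.g. a day with no ice edge
  anywhere in the grid) are flagged and excluded from fitting, with the
  count logged in the table's `n_incomplete` attribute and the run
  manifest.

# Stepwise elimination and its hierarchy

The initial model holds all eight single effects, `sea_ice:sqrt(d2ice)`,
sex crossed with every other single effect, and the three-way
`sex:sea_ice:sqrt(d2ice)` (17 terms; the intercept never leaves). Each
pass refits all replicates, runs the Monte Carlo inference, and removes
the least significant *removable* term with p > α (default 0.05);
elimination stops when every removable term is significant.

* **Removable** means: contained in no other remaining term, where
  containment is factor-subset (and `ice_conc` is treated as contained
  in `ice_conc^2`, so the linear term cannot outlive the quadratic).
  This protects main effects under their interactions and, by the same
  rule, two-way interactions under the three-way. Published analyses of
  this design have sometimes applied the hierarchy to main effects only;
  we apply the stricter containment rule uniformly.
* **Ties** (equal p) remove the higher-order term first, then
  alphabetically.
* **Non-identifiable terms** (a constant design column — e.g. `sea_ice`
  in a world with no open water) are fixed at coefficient 0 in every
  replicate, yielding a degenerate SD of 0. They carry no information
  and are removed first, recorded at p = 1. Degenerate-SD terms with
  *nonzero* estimates signal replicate under-dispersion instead; they
  are retained and flagged (`degenerate = TRUE`, p reported as NA, never
  as 0).
* **Refitting**: replicates are refitted after every removal (default).
  `refit = FALSE` decides all removals from the initial model's frozen
  p-values and refits only the final model — cheaper, and available for
  comparison.

Separation in a replicate fit (fitted probabilities at the boundary or
runaway slopes) is flagged on the fit; non-converged replicates are
excluded from the Monte Carlo aggregation, which requires at least two
converged fits.

# The synthetic world

The generator exists so that every stage of the pipeline can be tested
against known truth with no downloads. It emulates:

* **Ice**: a north-high logistic concentration ramp whose 10% level
  advances south at a configured rate (default 12 km/day — a typical
  freeze-up progression across a subarctic shelf), ramp width 120 km (a
  realistic marginal ice zone), cell-level Gaussian noise (SD 5%,
  mimicking the patchiness of passive-microwave products), and
  truncation of concentrations below 1% to 0 so open water exists.
  Without the noise, concentration would be a deterministic monotone
  function of distance to the edge and multi-covariate selection models
  would be structurally unidentifiable.
* **Bathymetry**: a shelf deepening from ~0.7× to ~1.5× the nominal
  shelf depth (default 60 m) toward a slope that crosses 1000 m, with a
  gentle longitudinal ripple so depth is not a pure function of
  latitude.
* **Land**: a northern coast and an eastern coast (an "L"), giving the
  coastline distance both latitude and longitude structure.
* **Movement**: a drifting correlated walk (south by default) with
  lognormal capped speeds and gamma-distributed irregular fix intervals.
* **Selection**: at each step, `m = 20` candidate endpoints are drawn
  from the kernel and one is chosen with probability
  $\propto \exp(\text{truth}^\top x)$. `m` is *the* knob coupling the
  nominal truth to realized selection: the weighting acts per step over
  what is locally reachable, so realized RSF coefficients against CRW
  availability match the truth in sign and roughly in magnitude, not
  exactly.
* **Argos error**: isotropic Gaussian noise per quality class with
  conventional magnitudes (km: 3→0.25, 2→0.5, 1→1.5, 0→5, A→8, B→15).
  The positioning system does not publish per-class magnitudes; these
  are order-of-magnitude conventions, and the truth coordinates are
  retained alongside for diagnostics.
* **Independent rows** (`simulate_rsf_rows`): a row-level case-control
  generator in which controls are i.i.d. draws from an availability
  distribution and cases are importance-resampled with weight
  $\exp(\text{truth}^\top x)$. By the exponential-tilt construction the
  case/control logistic slope *equals* the truth exactly, which is what
  makes sharp parameter-recovery and calibration tests possible. Cases
  are drawn once and shared across replicates, mirroring the matched
  design.

What the generator does **not** emulate: currents and tides, floe-scale
ice geometry, haul-out behaviour, diurnal sampling structure, or the
anisotropic error ellipses of real Doppler positioning. A green test
therefore establishes the correctness of the *statistical machinery* on
a world with the right gross structure — not oceanographic realism, and
not that any particular field dataset satisfies the model's assumptions.

# Numerical choices

* Logistic fits: IRLS (`glm.fit`), tolerance 1e-8, ≤ 100 iterations,
  verified against an independent Newton optimizer to 1e-6 in the suite.
* Constant design columns are dropped from the fit and reported as
  coefficient 0 (no information), keeping coefficient vectors conformable
  across replicates.
* Bearing bins half-open `[lo, hi)` with 360 wrapping to 0; a degenerate
  step (coincident positions) has bearing 0 by convention.
* Contours come from marching-squares isolines on the cell-centre
  lattice; land cells are missing values and are skipped. A level absent
  from the data yields an empty contour set (not an error), which
  propagates as a missing `d2ice` covariate.
* Seeds: one master seed fans out deterministically to per-stage,
  per-animal, per-replicate streams (all below 2³¹); reruns with the
  same configuration are identical, and the configuration hash is
  recorded in every output artifact.
* Boundary latitude 65°45′N is encoded as decimal 65.75; entry is
  detected on consecutive retained locations straddling the parallel
  (the *last* southward crossing), and inclusion additionally requires
  southern residence from that crossing to the end of record. Duplicate
  timestamps keep the first fix and log the rest. Durations are
  date-based (last minus first transmission date) to match the fixture
  metadata path.

# Known limitations

* The Monte Carlo z-test is mildly anti-conservative by construction
  (shared cases), as measured by the suite's calibration check.
* Conditional (stratum-matched) logistic regression, mixed-effects RSFs,
  AIC-based selection, state-space position smoothing and continuous-time
  movement models are deliberately out of scope.
* The track-level generator's truth is local; quantitative
  coefficient-recovery guarantees are made (and tested) only for the
  independent-row generator.
* Distances are exact only to the 1 km densification; contour geometry
  is exact only to the grid's linear interpolation.
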