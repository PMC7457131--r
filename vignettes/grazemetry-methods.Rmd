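---
title: "Models and methods behind grazemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grazemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazemetry)
library(dplyr)
```

grazemetry analyses comparative grazing experiments in which several
cattle breeds simultaneously graze heterogeneous (typically alpine)
pastures. Three families of quantities are computed per animal — anatomy,
movement, and diet selection — and their pairwise scaling relationships
are fitted as standardized major axes with multi-group tests. A seeded
synthetic-herd generator produces complete studies with a known
breed-structured signal, so every stage of the pipeline can be tested
end to end without field data. This vignette records the models, their
assumptions, and the numerical and design choices a maintainer would want
to know.

## Anatomy

The claw base of each cow is measured from traced outlines of the medial
and lateral claws of the left fore- and hindfoot, in calibrated cm
coordinates. `polygon_area()` evaluates the shoelace formula on the
vertex ring; the result is orientation-invariant and self-intersecting
rings are rejected rather than silently "fixed". Left claws proxy the
right side, so `total_claw_base()` doubles the summed outline area.
Derived quantities:

* static pressure `weight / claw base` in kg/cm² — a mass loading, not a
  force; multiply by 98.0665 for kPa. The end-of-season weight is used by
  default because the claw base is measured at the end of the grazing
  season (configurable).
* daily weight change `(w_end − w_start) / days`, sign preserved.
* metabolic livestock units `(W / 600 kg)^0.75`, the standard
  metabolic-mass normalization; `stocking_density()` sums LU over
  hectares.

## Movement

GPS fixes (15 s nominal interval, projected metric coordinates) are
reduced per cow and paddock:

* **Speed**: summed Euclidean inter-fix distances over elapsed hours.
  Segments longer than `max_step_m` or implying more than 10 km/h
  (configurable; the cutoff scales with the time gap) are treated as
  receiver error and dropped from the distance while the elapsed time is
  kept, so filtering can only lower the estimate.
* **Occupancy**: fixes are counted in half-open 5 × 5 m cells anchored at
  the paddock bounding-box lower-left corner. Cells whose centre falls
  inside the boundary form the mask; fixes outside it are counted and
  reported, never dropped silently.
* **Camargo evenness** of space use, `E = 1 − Σ_{i<j} |p_i − p_j| / S`,
  is computed over *all* masked cells, zeros included: evenness is judged
  against the available area, and excluding unvisited cells would make
  clustered use look deceptively even. The pairwise sum uses the sorted
  prefix identity `Σ_{i<j} |p_i − p_j| = Σ_k (2k − 1 − S) p_(k)`
  (O(S log S)); tests pin it against brute-force enumeration at 1e-12.
* **Covariates**: percent slope by Horn's eight-neighbour kernel
  (replicated-edge padding keeps all masked cells finite) and Euclidean
  distance to the nearest water point, both sampled at cell centres.
* **Covariate effects**: cell counts are regressed on one z-scored
  covariate at a time with a log-linear quasi-Poisson model. This is a
  deliberate simplification of a latent-Gaussian spatial model: the
  spatially structured error is absorbed into a single overdispersion
  factor that inflates the standard errors, while the z-scoring keeps
  coefficients comparable across paddocks and individuals. The point
  estimates are the Poisson IRLS solution (`glm`, convergence 1e-12);
  tests compare them to an independent Newton solver at 1e-8. The cost of
  the simplification is that residual spatial autocorrelation is summarized,
  not modelled; per-cell standard errors should not be over-interpreted.

Pedometer intervals aggregate by duration weighting into steps/h and the
lying ratio.

## Foraging

Bite records (taxon of every second bite during an observation bout)
reduce to relative consumption `p_s = count_s / n_bites`. Forage value
uses Briemle-style indicator values `q ∈ [1, 9]`; field-recording groups
(e.g. broad-leaved Poaceae) get a per-pasture effective
`q = Σ a_m q_m` over their member species' relevée abundances. Then

* diet quality `Q = Σ p_s q_s` (convex, so bounded by the consumed
  qualities),
* Pielou selection evenness `J = (−Σ p ln p) / ln S` over the taxa
  actually consumed (`p > 0`) — the quantity describes how strictly the
  animal selected among what it ate, not coverage of the species pool. A
  single-taxon diet has no defined evenness and is returned as a flagged
  `NA`, never as 0 or 1.
* plant-group shares partition the diet over broad grasses, fine grasses,
  legumes, thistles, shrubs and a rest class.

Observation bouts of different lengths enter as-is (proportions are
per-bout); no duration weighting is applied. `estimate_selectivity()`
inverts the generator's softmax diet model (below) by profile maximum
likelihood, which is used in parameter-recovery checks.

## Standardized major axis allometry

For trait pairs measured with error on both axes, ordinary regression
attenuates slopes; the SMA slope `b = sign(r) · s_y / s_x` treats both
variables symmetrically. `sma_fit()` reports slope, intercept, r², and
the F-based slope interval `b(\sqrt{B+1} ± \sqrt{B})`,
`B = F_{1−α}(1, n−2)(1−r²)/(n−2)`.

For `g` groups, `sma_group_test()` works on the residual axis
`r = y − b x` and fitted axis `f = y + b x`, which are uncorrelated at a
group's own SMA slope:

* **Common slope**: the statistic `LR(b) = Σ_i (n_i − 2.5) ·
  (−log(1 − ρ_i(b)²))`, with `ρ_i` the residual–fitted correlation in
  group i, is minimized over `b`; the minimum is referred to χ²(g−1).
  The `n − 2.5` weights are a Bartlett-type small-sample correction;
  with plain `n` the empirical size at n = 30, g = 3 runs to ≈ 0.055–0.06,
  with the correction it sits at ≈ 0.045–0.05 (4000-simulation check).
  The minimization runs on log |b| with the sign fixed by the group
  fits, because the profile has twin minima at ±|b| and an unconstrained
  search can cross zero after axis rescaling — which would silently
  exchange the meaning of the next two tests.
* **Shift along the line**: Wald comparison of group means of `f` —
  displacement of the point clouds *along* the common axis (larger
  animals further up the same line).
* **Elevation**: Wald comparison of group means of `r` — parallel offset
  *between* lines (same x, different y).

Both Wald statistics use per-group score variances on `n_i − 2` df plus
the common-slope sampling variance (from the curvature of the LR
profile), with covariance `x̄_i x̄_j Var(b_c)` between group means. They
are referred to `F(g−1, Σ(n_i − 2))`: with the χ² reference the n = 30
empirical size was ≈ 0.055–0.066, with the F reference 0.047–0.051.
When the common-slope test rejects (α = 0.05, configurable), shift and
elevation are still reported but flagged `slope_forced` — comparisons at
a forced common slope, mirroring how allometric lines of genuinely
different slope are still summarized in comparative work.

Log-transforming the axes before fitting, common in allometry, is *off*
by default: the trait pairs here mix signs (daily weight change) and
bounded indices, and the comparative results of interest are on original
scales. Callers can transform columns before fitting if desired.

Breed differences in single variables use Tukey range tests
(`aov`/`TukeyHSD`, studentized-range CDF via `ptukey`); with two groups
this reduces exactly to the pooled t-test. Effects of breed, paddock
size and their interaction use a sequential (type I) ANOVA of
`response ~ breed * size`. Across the nine standard allometry pairs no
multiplicity adjustment is applied (per-pair p-values are reported);
apply `p.adjust` downstream if a family-wise claim is needed.

## The synthetic herd

The generator is first-class, tested code. It emulates:

* **Cows**: lognormal body weight; total claw base
  `A = k_a W^{k_b} e^ε`, rendered as four regular octagons of area `A/8`
  so `total_claw_base()` recovers `A` exactly.
* **Pastures**: square paddocks; DEM as a Gaussian random field
  (separable kernel smoothing, sd 3 cells) rescaled so the Horn mean
  slope hits the target; random water points; a smooth forage-quality
  surface centred on the availability-weighted mean Briemle value.
* **Tracks**: a discrete-time walk on the 5 m grid alternating resting
  bouts (two-state Markov chain, long-run lying fraction `rest_prob`,
  mean bout 30 min) and active steps. An active step proposes one of the
  8 neighbours (heading-persistent for `persistence > 0`) and accepts
  with the Metropolis ratio of habitat weights
  `w ∝ exp(−β_s z(slope) − β_w z(water) + τ z(quality))`. The Metropolis
  form is essential: it makes the stationary occupancy exactly
  proportional to `w`, so the log-linear covariate regression has an
  identifiable target (sampling destinations proportionally to `w`
  instead would concentrate occupancy like `w²` and bias recovered
  coefficients by about a factor two). The per-step move probability is
  calibrated so the realized speed matches the breed's step rate through
  `steps_per_m`.
* **GPS error**: AR(1)-autocorrelated bivariate noise with stationary
  median radial error 3.1 m (σ = 3.1/√(2 ln 2), lag-1 coefficient 0.98
  per 15 s fix). Receiver error is strongly autocorrelated in practice;
  independent jitter of this magnitude would add a spurious ~1 km/h to
  every track and is not a useful error model at 15 s fixes. Even so,
  simulated speeds carry a noise floor of roughly 100 m/h, so absolute
  speeds run above their noise-free values while orderings are
  preserved.
* **Pedometer**: steps per interval ~ Poisson(`steps_per_m` × true
  distance); lying time = resting-state seconds.
* **Bites**: i.i.d. multinomial with weights ∝ availability ·
  exp(τ · q); τ = 0 is availability sampling.
* **Weights**: daily change = `intake_efficiency · (Q − maintenance_quality)`
  plus noise, so a low-maintenance breed gains where a demanding breed
  loses on the same pasture.

The default three breeds (`HC`, `OB`, `AH`) span a productivity
gradient. Their means are anchored at published comparative values
(358/582/679 kg; ≈78/111/105 steps per hour; +0.08/−0.3/−0.6 kg/day) and
the preference parameters are *calibrated* so the generated herd
reproduces the qualitative orderings such a gradient produces — the
light breed rests most, moves least, spreads most evenly, selects least
strictly, eats the poorest diet and still gains weight. Within-breed
variances are order-of-magnitude choices; no field study reports them.
The maintenance-quality thresholds (2.5/7.2/8.1 on the 1–9 scale) are
calibration constants tied to the *realized* selected diet quality of
each breed under the default pastures, not physiological measurements.
What passing tests show is therefore that the pipeline detects a signal
of this structure when present; they do not validate the generator
against real herds, and real data bring features the generator omits
(social behaviour, diurnal rhythm, weather, non-square paddocks,
heterogeneous taxa within cells).

## Numerical choices and degenerate inputs

* Half-open grid cells `[x0, x0+5)`; a fix exactly on an edge belongs to
  the higher-index cell, once.
* Camargo and Pielou reject all-zero inputs explicitly; Pielou flags the
  single-category case as undefined rather than guessing.
* `sma_fit` requires n ≥ 3 and positive variance on both axes; r = 0
  leaves the slope magnitude defined but its sign flagged.
* Validation is total: unknown ids, non-monotone timestamps and
  non-normalized abundances raise errors naming the offending row; no
  reader drops records silently.
* All generator stages derive child seeds deterministically from the
  master seed, so a bundle is byte-identical for a given (seed, config)
  and report regeneration is exact.

## Problem sizes used by the shipped checks

The package's own test suite and the acceptance script run a 3-breed ×
9-cow × 3-pasture study with 6 tracked hours per cow and paddock
(≈ 116k fixes), 300 bites per observation bout, 1000-simulation null
calibrations of the common-slope and elevation tests at n = 30 per
group, 50 replicate walks on a ≈ 2000-cell paddock for slope-aversion
recovery, and 3000 bites for selectivity recovery. These sizes were
chosen to keep full runs in the order of minutes on a single core while
leaving the Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The spatial error structure of occupancy counts is summarized by one
  overdispersion factor; no spatial random field is fitted.
* Pielou's S counts recorded taxa (species or field groups) as units; a
  different grouping convention changes J.
* The GPS-error model is stationary and isotropic; multipath or canopy
  effects are not emulated.
* Shift/elevation tests assume the common slope; when it is rejected
  they are reported only as forced-slope summaries.
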