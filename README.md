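# grazemetry

Comparative grazing studies ask how cattle breeds of different
productivity differ in what their bodies do to a pasture and in what
they take from it: how much weight rests on each square centimetre of
claw, how far and how evenly the animals move across heterogeneous
terrain, and how strictly they select their forage. grazemetry is an R
package for analysing such experiments end to end — per-animal anatomy,
GPS/pedometer movement, and bite-record diet metrics, tied together by
standardized major axis (SMA) allometry with multi-group tests — plus a
seeded synthetic-herd generator so the whole pipeline is testable
without field data.

It is written for ecologists and animal scientists running
multi-breed grazing trials (and for anyone who needs honest SMA
shift/elevation tests in R without further dependencies).

## What it computes

**Anatomy** — claw-base area from traced outlines (shoelace formula,
left claws doubled), static pressure `P = W / A` (kg/cm²), daily weight
change, metabolic livestock units `LU = (W/600)^0.75` and stocking
densities.

**Movement** — per cow × paddock: speed from 15 s GPS fixes with an
error filter, steps/h and lying ratio from pedometers, occupancy of
5 × 5 m grid cells, Camargo's evenness of space use over *all* cells
inside the paddock

> E = 1 − Σ_{i<j} |p_i − p_j| / S,

and standardized slope / water-distance effects from a quasi-Poisson
log-linear regression of cell counts on z-scored covariates.

**Foraging** — relative consumption per taxon, diet quality
`Q = Σ p_s q_s` on the 1–9 Briemle indicator scale (species groups
resolved per pasture via relevée abundances), Pielou's selection
evenness `J = (−Σ p ln p)/ln S`, and plant-group shares.

**Allometry** — SMA fits `b = sign(r)·s_y/s_x` per group, a
Bartlett-corrected likelihood-ratio test for a common slope, and Wald
tests for **shift** (displacement along the common line, on scores
`y + b_c x`) and **elevation** (parallel offset between lines, on
`y − b_c x`); plus Tukey range tests among breeds and a breed ×
paddock-size ANOVA.

## Worked example

```r
library(grazemetry)
library(dplyr)

bundle <- simulate_study(sim_config(seed = 1, n_cows_per_breed = 9,
                                    track_hours = 6))
report <- run_study(bundle)

report$cow_means |>
  group_by(breed) |>
  summarise(weight = mean(weight_end), claw = mean(claw_base_total),
            pressure = mean(static_pressure),
            steps = mean(steps_per_h, na.rm = TRUE),
            camargo = mean(camargo_evenness),
            quality = mean(quality_score))
#> # A tibble: 3 × 7
#>   breed weight  claw pressure steps camargo quality
#>   <chr>  <dbl> <dbl>    <dbl> <dbl>   <dbl>   <dbl>
#> 1 AH      644.  284.     2.27  84.8   0.111    6.54
#> 2 HC      357.  183.     1.95  64.2   0.169    4.85
#> 3 OB      560.  243.     2.31  94.8   0.149    6.16
```

The light, low-productivity breed (HC) weighs and moves least, exerts
the lowest claw pressure, spreads most evenly over the paddock (highest
Camargo evenness) and selects the poorest diet; the heavy breed (AH) is
the opposite. The weight–claw allometry with breed structure:

```r
report$sma$A
#> Grouped SMA: claw_base_total ~ weight_end, 3 groups (AH, HC, OB)
#>   common slope b_c = 0.4128
#>   slope      LR(2)   =    1.323, p = 0.516
#>   shift      Wald(2) =   84.309, p = 4.441e-08
#>   elevation  Wald(2) =    5.273, p = 0.09516
```

All breeds share one slope (claw base scales the same way with weight),
but the breeds sit at very different positions *along* that line — the
highly significant shift. `autoplot(report$sma$A)` draws the grouped
fit; `tidy()` / `glance()` give the tables.

A thin command-line wrapper ships in `inst/cli/grazemetry.R` with
subcommands `simulate`, `metrics`, `compare`, `allometry`, `report`.

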