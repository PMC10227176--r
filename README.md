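# hydrodisp

Simulators of seed-dispersal evolution for shoreline plants whose seeds
travel downstream on river flow (hydrochory), aimed at a question from
restoration ecology: when riparian habitat is fragmented and later
reconnected, does the evolved dispersal strategy recover — or is there
evolutionary hysteresis, so that much higher connectivity is needed to win
back long-distance dispersal than was needed to lose it?

## The models

Both models live on a 1-D river lattice (one cell = 1 m) of habitat patches
of `x_h` cells separated by `x_ipd` matrix cells. Seed size `S` (0.5–30 mm)
is the evolving trait; it controls both the dispersal kernel and the seed
budget.

**Kernel.** A floating seed stays in the water column with per-cell
probability λ, so landing distances are geometric, P(k) = λᵏ(1 − λ), and λ
is a sigmoid in seed size, λ(S) = 1 − 1/(1 + e^{α + β(S − 0.5)}). The
kernel is calibrated from the median dispersal distances of the smallest
and largest seeds via α = logit(0.5^{1/d05}),
β = [logit(0.5^{1/d30}) − α]/29.5.

**Deterministic model.** A lone parent at the upstream edge of a patch
releases N_tot seeds over a 5000-cell downstream window. Producing size-S
seeds costs the fraction c = c₁πS³/6 of the budget, the cell at distance d
receives N_d = N_tot(1 − c)(λᵈ − λ^{d+1})/(1 − λ^{d_max}) expected seeds,
and it is colonized with probability P⁺_d = 1 − (1 − g)^{N_d}. Fitness is
Σ P⁺_d over habitable cells; seed size evolves by a ±0.01-mm hill climb to
the locally optimal size.

**Stochastic model.** An individual-based population on a periodic
landscape: non-overlapping generations, parents disperse
N_j = round(N_tot(1 − c)) seeds each in random order, seeds establish on
empty habitable cells with probability g, and established seedlings mutate
their seed size by ±1 mm at rate μ.

**Sweep protocol.** Inter-patch distance is swept up and then back down,
carrying the evolved state across levels. `detect_hysteresis()` quantifies
the collapse and recovery transitions (50%-of-running-maximum crossings of
the evolved median dispersal distance) and the hysteresis-zone size in
cells. `sensitivity_grid()` crosses any configuration axes and returns one
hysteresis summary per combination.

## Worked example

A full-range deterministic sweep (inter-patch distance 0 → 5000 → 0 cells,
10-cell steps) with kernel medians 60 and 700 cells and the default
demography:

```r
library(hydrodisp)
cfg <- run_config("deterministic", d05 = 60, d30 = 700,
                  ipd_step = 10L, x_max = 5000L)
sw  <- sweep_deterministic(cfg)   # ~2 s
detect_hysteresis(sw)
#> # A tibble: 1 × 5
#>   up_transition down_transition zone_size max_gap   tol
#>           <dbl>           <dbl>     <dbl>   <dbl> <dbl>
#> 1          3370            2560       810    206.    10
```

Reading: as fragmentation grows, the evolved median dispersal distance
first *rises* (from ~295 to ~313 cells — larger gaps select for farther
dispersal while patches are still reachable), then declines gradually, and
at an inter-patch distance of 3370 cells collapses in a single 10-cell step
to ~60 cells (within-patch dispersal). On the way back down, dispersal does
not recover until the inter-patch distance shrinks to 2560 cells: an 810-cell
hysteresis zone in which the evolved strategy depends on the landscape's
history. `autoplot(sw)` draws the two curves.

A configuration can be saved, shared, and rerun exactly
(`write_run_config()` / `read_run_config()` / `write_results()`), and
`inst/scripts/run_sweep.R` wraps the same calls for shell use.

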