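# stempatterns

Stochastic individual-based simulation of stem-cell differentiation in a
confluent planar monolayer, with the spatial statistics needed to
characterise the two-type patterns that emerge.

Cultured stem-cell populations differentiate into patches of distinct cell
types rather than a well-mixed salt-and-pepper field.  This package is for
modellers and quantitative biologists who want to ask *which intercellular
signalling mechanism could produce an observed pattern, and at what
scale*: it simulates a minimal mechanistic model of fate choice biased by
either diffusible morphogens or juxtacrine (contact) signalling, and it
measures patterns — simulated or segmented from images — with marked
point-process statistics.

## The model

Cells sit statically on a doubly periodic square `[0, L)²` (lengths in cell
radii) after a brief mechanical relaxation of random seeding.  Each cell
carries a stemness `s` and a fate variable `f`, evolving by the
Euler–Maruyama discretisation of

    ds = -s dt
    df = (B + χ(1/2 - s) f - ν f³) dt + √(2δ) dW

a supercritical pitchfork in `f` with bifurcation parameter `s`: as `s`
decays through 1/2 each cell falls into the `f > 0` (type R) or `f < 0`
(type G) well.  The signalling bias `B` tilts the choice toward the fate of
the neighbourhood, via either

* diffusive signalling — type-specific morphogens secreted by
  differentiated cells, advanced by a Douglas ADI finite-volume solver on a
  periodic grid, `B = S_diff (a − b)`; or
* juxtacrine signalling — inverse-distance-weighted contact signals from
  neighbours within `3 r_c`, `B = S_juxt Σ 2 r_c (β_a − β_b)/d`.

Patterns are quantified by the pair correlation function `g(r)`, the
same-type PCF `g_S(r)` (squared-density-weighted combination of `g_RR` and
`g_GG`), the pattern scale `r_p` (interpolated crossing of `g_S` and `g`),
quadrat histograms of type proportions with a truncated-normal null, and a
conservative pattern-presence criterion (more than 10% of quadrats almost
purely one type).

## Worked example

One full-scale juxtacrine realisation at high sensitivity:

```r
library(stempatterns)
cfg <- run_config("juxtacrine", master_seed = 1, S_juxt = 1e-2)
r <- run_realisation(cfg, 1)
print(r)
#> Realisation 1 (seed 1000004): N_R = 1917, N_G = 1583
#>   max(g_S - g) = 0.5683, r_p = 13.60
qh <- quadrat_histogram(r$pattern, cfg$M_q)
print(qh)
#> Quadrat histogram: 12 x 12 quadrats, 144 non-empty (pooled), N_q = 24.3
#>   extreme-bin fraction = 0.007
pattern_criterion(qh)
#> [1] FALSE
```

The two types split near 50:50, and the same-type PCF exceeds the all-pairs
PCF by up to 0.57 at short range — nearby cells are far more likely to
share a type than chance — with the excess vanishing at `r_p ≈ 14` cell
radii: the patch scale.  The quadrat histogram still shows few *purely*
single-type quadrats (extreme-bin fraction 0.7%), because juxtacrine
patches are comparable in size to the quadrats; the conservative presence
criterion therefore stays FALSE even though the PCFs show clear structure.
Diffusive signalling at high sensitivity produces much larger patches
(`r_p ≈ 38` at `S_diff = 40`, `λ = 10`) that do trip the criterion.

`plot(r$pattern)` draws the marked pattern; `plot(r$g)` the PCF.  External
centroid tables (`id,x,y,type` CSV) enter the same statistics through
`read_pattern()`, and `inst/cli/stempatterns-cli.R` exposes
`simulate`/`sweep`/`stats`/`fixtures` subcommands for shell use.

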