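# fencescr

Spatial capture-recapture (SCR) density estimation for camera-trap surveys
in **fenced reserves**, built to answer one question rigorously: *how much
does the assumption that a fence is impermeable inflate density
estimates?*

For carnivores such as the brown hyaena, which dig under and exploit holes
in fences, that assumption is a modelling choice, not a fact. In SCR the
choice lives in the *state space* (habitat mask) over which each animal's
latent activity centre is integrated: clipped to the fence polygon
(impermeable) or buffered far beyond the detectors (permeable). The same
capture histories can yield order-of-magnitude different densities under
the two masks, with small reserves the most sensitive.

## What the package implements

- **Capture histories** from raw detection records: noon-to-noon
  occasions (no "midnight problem" for nocturnal species), majority-flank
  selection, binarised individual × occasion × detector arrays with
  station-usage matrices, 30-min-chained relative abundance indices (RAI,
  captures per 100 trap-days), z-scored session covariates, MCP camera
  areas.
- **Habitat masks**: lattice masks (default 0.5 km spacing) clipped to a
  fence or buffered around detectors, exclusion polygons, and a
  closed-form buffer suggestion from a pilot RPSV estimate of σ.
- **Multi-session maximum-likelihood SCR**: half-normal, hazard-rate and
  negative-exponential detection functions; density and g0 constant,
  session-structured, covariate-structured, or (g0 only) with a learned
  response; full and conditional likelihoods

  ℓ = Σ_r [ Σ_i log( a Σ_x D_r(x) Pr(ω_i|x) ) − a Σ_x D_r(x) p·(x) − log n_r! ]

  maximised on link scales with a finite-difference Hessian for variances.
- **Selection and derived quantities**: AICc tables with Akaike weights
  and ΔAICc < 2 retention, Horvitz–Thompson density with lognormal CIs,
  expected/realized region-N, and combined activity-centre surfaces
  (observed-animal posteriors plus undetected intensity).
- **The permeability experiment**: paired clipped/buffered fits on
  identical histories, per-site density ratios, and inverse-Gaussian /
  gamma / gaussian GLMs of ratio vs reserve size with AIC comparison.
- **A simulator** of fenced-reserve surveys with known truth, including a
  fence-permeability parameter ρ ∈ [0, 1] scaling the detectability of
  animals centred outside the fence.

## Worked example

Simulate a fully permeable 150 km² fenced reserve (true density 8 animals
per 100 km², σ = 3 km), then fit the same model under both mask
assumptions:

```r
library(fencescr)

geom <- make_reserve(square_fence(150, c(-6.1, -6.1)),
                     n_stations = 25, spacing = 2, seed = 2)
cfg  <- sim_config(true_density = 8, g0_true = 0.15, sigma_true = 3,
                   n_occasions = 30, permeability = 1, seed = 7)
sv <- simulate_survey(geom, cfg)
sv$history
#> Capture history [sim1]: 49 individuals, 30 occasions, 25 detectors, 580 detections

dual <- run_dual_mask(sv$history, geom,
                      scr_model("~1", "~1", "HN", "full"),
                      buffer = 12, spacing = 1)
dual$estimates
#>   session reserve_size_km2 D_impermeable D_permeable
#> 1    sim1              150      34.05816    9.925055

attr(density_ratio(dual), "mean_ratio")
#> [1] 3.431534

derived_density(dual$buffered)
#>   session  n  esa_km2        D       SE      lcl      ucl mask_mode
#> 1    sim1 49 493.7001 9.925055 1.541185 7.333994 13.43152  buffered
```

Reading the output: the buffered ("permeable") fit recovers the truth —
9.9 animals per 100 km² with a 95% CI of 7.3–13.4 around the true 8 —
while clipping the state space to the fence concentrates the same 49
animals into 150 km² and reports 34.1 per 100 km², a 3.4× inflation. In
simulations across reserves of 100–800 km² the inflation shrinks
monotonically toward 1 as reserves grow, because large reserves hold their
camera array far from the fence.

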