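# trophicniche

Quantifying trophic niche overlap between two sympatric marine predators —
developed for harbour seals (*Phoca vitulina*) and grey seals (*Halichoerus
grypus*) sharing a haulout site — from three complementary data streams:

1. **Scat hard parts** → diet reconstruction (counting rules, allometric
   length/mass regressions), a scats × 6 functional-group composition
   matrix, Ward.D2 clustering with bootstrap confidence intervals, and the
   Pianka dietary overlap index
   `O = Σ P_iA P_iB / sqrt(Σ P_iA² · Σ P_iB²)` with a resampling CI
   (segregation is substantial when O < 0.4).
2. **Whisker stable isotopes** (δ¹³C/δ¹⁵N along the whisker) → a
   hierarchical Bayesian bivariate model separating within-individual from
   between-individual variability,

   ```
   Y_ik ~ N₂(α_ik, Σ_k)          α_ik ~ t₂(df = n_ik; μ_k, Ω_k)
   Ω_k, Σ_k ~ InvWishart(3, diag(a, b)),  a, b ~ InvGamma(0.5, 1)   (Huang–Wand)
   μ_k ~ N(0, 20²) per tracer
   ```

   fitted by a data-augmented Gibbs sampler (exact conjugate conditionals;
   split-R̂ convergence gate at 1.05), then 95% standard ellipses per
   posterior draw, niche areas (π·q₀.₉₅·√det), overlap and nestedness
   proportions with credible intervals, probability-of-membership grids,
   and prey comparisons shifted by a trophic enrichment factor
   (+2.4 ‰ δ¹³C, +2.6 ‰ δ¹⁵N).
3. **Dive telemetry** → selection of faster U-shaped (foraging) dives by
   the time-allocation-at-depth index and descent speed, and per-individual
   kernel-density foraging areas at the 50/75/95% contours on an equal-area
   projection.

A seeded synthetic-data module generates all three streams with known
ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(trophicniche)

## Diet: simulate scats, reconstruct, cluster, overlap
scats <- simulate_scats(diet_sim_config(seed = 1))
cm    <- diet_composition(scats$parts, sim_allometry())
dietary_overlap(cm, seed = 1)
#> Pianka dietary overlap O = 0.77 [0.61-0.87]
select_k(scale_matrix(cm), 2:8)$k
#> [1] 6

## Isotopes: simulate whiskers, fit the hierarchical model, niche overlap
whisk <- simulate_whiskers(isotope_sim_config(seed = 1))
fit   <- fit_isotope_model(whisk$series, config = fit_config(seed = 1))
fit
#> Hierarchical bivariate isotope model fit
#>   harbour: 8 individuals, posterior mean mu = (-15.38, 17.73) permil
#>   grey: 10 individuals, posterior mean mu = (-15.04, 16.68) permil
#>   max split-Rhat = 1.002 (converged)
sets <- lapply(c("harbour", "grey"), function(sp)
  ellipse_set(posterior_predict_individuals(fit, sp, seed = 1), sp))
summarize_overlap(sets[[1]], sets[[2]])
#> Niche areas: harbour = 5.9 [2.5-16.4] permil^2, grey = 4.8 [2.3-11.9] permil^2
#> Overlap: 19.9% [5.6-39.6] of the total niche area
#> Nestedness: harbour-in-grey 31.3% [8.4-70.6]; grey-in-harbour 37.6% [12.5-79.5]
#> P(area grey > area harbour) = 0.38; P(harbour more nested) = 0.38
```

The Pianka index is computed from the two species' pooled mass-weighted
compositions; its CI comes from 10,000 random pairings of two sets of 1,000
bootstrap compositions. The niche summaries are posterior medians with 95%
credible intervals over 1,000 paired posterior-draw ellipses; with the
default generator both species are planted near the same isotopic centroid,
so a moderate overlap and near-symmetric nestedness is the expected answer.
See `vignette source in vignettes/methods.Rmd` for the model, priors,
sampler and all design decisions.

## Command line

```sh
inst/cli/trophicniche simulate --kind scats --seed 1 --out data/
inst/cli/trophicniche diet build-matrix --scats data/scats.csv --allometry data/allometry.csv --out data/composition.csv
inst/cli/trophicniche diet cluster --matrix data/composition.csv --fixed-k 6 --out out/
inst/cli/trophicniche niche run --whiskers data/whiskers.csv --out out/
inst/cli/trophicniche forage --dives data/dives.csv --out out/
```

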