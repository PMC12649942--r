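# isodiet

Integrative diet reconstruction from bulk carbon and nitrogen stable
isotopes for consumers with **limited prior dietary information** — sessile
or soft-bodied marine invertebrates, for instance, whose stomach contents
cannot be read. The package was built around the diet of the plumose sea
anemone in a demersal shelf ecosystem, but every stage is generic: it takes
tidy per-individual tracer tables (δ¹³C, δ¹⁵N in ‰) and per-source summary
tables (mean, SD, n per tracer) and chains four analyses:

1. **Dual-baseline trophic position** — consumer reliance on a pelagic vs a
   benthic baseline from δ¹³C,
   α₁ = (δ¹³C_cons − δ¹³C_base2)/(δ¹³C_base1 − δ¹³C_base2), then
   TP = 2 + [δ¹⁵N_cons − (α₁ δ¹⁵N_base1 + α₂ δ¹⁵N_base2)]/3.4, with
   half-open trophic-level bins.
2. **Bayesian isotopic niche** — bivariate-normal niches in (δ¹⁵N, δ¹³C)
   sampled from the conjugate Jeffreys/inverse-Wishart posterior; α-level
   probability ellipses and pairwise *directional* overlap
   (P[individual of A inside B's 95% region]).
3. **Mixing-polygon diagnostics** — Monte-Carlo resampling (default 1500
   iterations) of TEF-corrected source means; per-consumer inclusion
   proportions in the convex hull, a feasibility raster, and a hull-area
   running-variance stability check.
4. **Dirichlet–Gaussian mixing model** — the summary-based likelihood
   y_ij ~ N(Σ_k p_k(μ_kj + μ_TEF,j), √(Σ_k p_k²(σ_kj² + σ_TEF,j²) + σ_j²))
   with a flat Dirichlet prior on the diet simplex and half-Normal(0, 5 ‰)
   priors on residual SDs, sampled by adaptive multi-chain
   Metropolis (log-ratio parameterisation, Laplace-seeded proposals,
   heavy-tailed independence component), with split-chain R-hat, posterior
   correlations, combined-pool contributions, posterior-predictive checks,
   deviance, and a source-set sensitivity mode.

A seeded synthetic-data generator reconstructs per-individual data from
published group moments by exact moment matching; because the mixing
likelihood depends on the data only through per-tracer means and SDs, fits
on moment-matched individuals reproduce the posterior the unpublished
originals would give. See `vignettes/diet-reconstruction.Rmd` for the full
methods account.

## Worked example

Reconstruct the packaged anemone case end to end: 10 consumers
moment-matched to the published group (δ¹³C −20.16 ± 0.50 ‰,
δ¹⁵N 12.45 ± 0.74 ‰), five candidate sources, TEFs 1.0 ± 0.2 / 3.4 ± 0.2 ‰.

```r
library(isodiet)

sources   <- nys_sources()
consumers <- gen_source_samples(nys_anemone_summary(), n = 10, seed = 101)

fit <- fit_mixing(consumers, sources, default_tef(), seed = 1)
print(fit)
#> Bayesian mixing model: 5 sources, 10 consumers
#>   4 chains x 10000 iterations (1000 burn-in); converged (all R-hat <= 1.1)
#>            parameter   unit   mean     sd ci_2.5 ci_97.5 rhat
#> 1 Small-Sized Fishes      % 41.009 15.842 7.2183  66.418 1.01
#> 2            Shrimps      % 21.230 11.742 2.5583  45.797 1.02
#> 3        Zooplankton      % 18.610 11.012 0.9718  40.063 1.02
#> 4                POM      % 11.652  7.999 0.6717  29.900 1.03
#> 5                SOM      %  7.499  5.473 0.1694  20.557 1.01
#> 6         sigma_d13C permil  0.396  0.213 0.0427   0.879 1.00
#> 7         sigma_d15N permil  0.585  0.328 0.0557   1.337 1.02

combined_contribution(fit, c("Small-Sized Fishes", "Shrimps"))$mean
#> [1] 0.6223981
posterior_correlation(fit)["Small-Sized Fishes", "Shrimps"]
#> [1] -0.962428
```

Read: the two fishery-organism sources jointly supply about 62% of
assimilated diet, but their posterior draws are almost perfectly
anticorrelated (−0.96) — the tracers cannot separate them, so the *pool* is
the reliable quantity, not the split. The mixing-polygon diagnostic
confirms the source set is geometrically adequate:

```r
ms <- run_mixspace(consumers, sources, default_tef(), seed = 5)
median(ms$per_consumer_inclusion)
#> [1] 1
convergence_check(ms)$iteration
#> [1] 110
```

The numbered scripts under `analysis/` run the full workflow (simulation →
trophic position → niche overlap → mixing space → mixing model →
six-source sensitivity), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_trophic_position.R
# ... through analysis/06_sensitivity_six_source.R
```

Stage 2, for example, places the anemones at TP 3.10 ± 0.24 (trophic
level 3) on the benthic baseline — alongside the predatory groups, not the
suspension feeders.

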