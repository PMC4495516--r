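# nichemax

Presence-only maximum-entropy niche modelling for small occurrence
samples, with the validation battery and niche-comparison statistics used
in multi-species habitat studies.

Ecologists mapping elusive species — camera-trap records of forest
mammals, confirmed sightings along transects — typically hold a few dozen
presence points per species, a stack of environmental rasters, and no
absence data. `nichemax` fits the maximum-entropy (maxent) model to that
setting: the probability distribution over background grid cells that is
closest to uniform subject to softly matching the environmental
conditions at the presences,

```
raw(x) = exp(λ·f(x)) / Z(λ)
J(λ)   = −(1/m) Σᵢ λ·f(xᵢ) + log Z(λ) + Σⱼ βⱼ|λⱼ|   →  min
```

with the classic default feature expansion (linear/quadratic/hinge by
sample size, indicators for categorical layers) and default
regularisation (βⱼ = class default(m) · sd of fⱼ at the presences / √m).
Fitted surfaces are reported on the entropy-calibrated logistic scale
`e^H·raw/(1 + e^H·raw)` in (0,1).

Because no single presence-only statistic is trustworthy alone, models
are validated four ways:

* **AUC** — presence-vs-background discrimination, exact midrank
  computation, cross-validated over 10 folds;
* **random-occurrence null model** — is the AUC better than models fitted
  to randomly placed points (999 replicates, empirical 95th-percentile
  rule)?
* **continuous Boyce index** — Spearman correlation of
  predicted-to-expected occurrence ratios over 100 equal suitability
  classes, one-tailed;
* **small-sample jackknife** (n < 25) — leave-one-out prediction successes
  weighted by predicted-area size, `D = Σ Xᵢ(1−Pᵢ)`, with an exact
  enumeration p-value.

Suitability maps are binarised at the minimum-training-presence threshold
(zero training omission) and species are compared pairwise with
Schoener's D, the Hellinger-based I statistic, a range-overlap index
`N_xy / min(N_x, N_y)`, shared occurrence localities, and environmental
summaries within predicted ranges.

A synthetic-landscape generator (spatially autocorrelated gradient
layers, categorical cover, derived slope/distance layers, presence
samples drawn from known response curves) makes the whole pipeline
testable end-to-end and supports parameter-recovery experiments; see the
methods vignette (`vignettes/niche-modelling-methods.Rmd`).

## Worked example

```r
library(nichemax)

pk <- gradient_study_scenario(seed = 1, n_rows = 60, n_cols = 60,
                              n = c(30L, 25L, 20L, 12L))
m <- maxent(pk$stack, pk$occurrences$species_a)
print(m)
#> maxent niche model for 'species_a'
#>   30 presences, 3600 background cells, 618 features (26 active)
#>   beta multiplier 1, entropy H = 7.0724, converged: TRUE (5 sweeps)

crossvalidate(m$features, pk$occurrences$species_a, k = 10, seed = 1)
#> 10-fold cross-validation of 'species_a': mean test AUC 0.7957
#>   (replicates 0.850, 0.889, 0.710, 0.579, 0.773, 0.849, 0.857,
#>    0.789, 0.779, 0.881)

mtp_threshold(m)
#> [1] 0.157

s <- predict(m, type = "logistic")          # suitability surface in (0,1)
boyce_index(s, pk$occurrences$species_a)
#> Boyce index: rho = 0.4369 over 80/100 usable classes,
#>   one-tailed p = 2.538e-05

cor(as.vector(pk$truth$species_a$surface), as.vector(s),
    method = "spearman", use = "complete.obs")
#> [1] 0.916
```

The fit uses 26 of 618 candidate features, discriminates held-out
presences from background with mean test AUC 0.80, shows suitability
tracking occurrence density (Boyce rho 0.44, p < 0.001), and — because
this is a synthetic landscape with known truth — recovers the generating
suitability surface to rank correlation 0.92. `run_study()` wraps the
whole design (all species, all four validations, comparison matrices)
into one seeded, reproducible report; a command-line wrapper lives at
`inst/cli/nichemax.R` with subcommands `synth`, `fit`, `evaluate`,
`compare`, `run-all`.

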