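# energyscape

Energy landscape analysis of oscillatory brain network states with pairwise
maximum entropy models.

## What it is for

Resting-state electrophysiology (MEG/EEG source space, or any multichannel
band-limited signal) can be reduced to a sequence of discrete network
states: at each time point, each region of interest (ROI) is either high
(+1) or low (−1) in band-limited oscillatory power. `energyscape` models the
occurrence probabilities of these states with the **pairwise maximum entropy
model** (pMEM) — the Ising model's Boltzmann distribution

    P(s | h, J) = exp(−E(s)) / Σ exp(−E(s')),
    E(s) = − Σᵢ hᵢ rᵢ − ½ Σ_{i≠j} J_ij rᵢ rⱼ,

fitted so the model's per-region means ⟨rᵢ⟩ and pairwise co-occurrences
⟨rᵢrⱼ⟩ match the data. The energy E(s) turns state statistics into a
landscape over all 2^N states: **local minima** (states below all N
single-flip neighbours) are attractor-like network patterns, **basins** are
their steepest-descent catchment areas, **disconnectivity graphs** show the
minimax barriers between minima, and Metropolis–Hastings simulation of the
fitted model measures how long the dynamics dwell in each basin. Group
analyses test minima against a parameter-shuffling permutation null and
classify individual participants (e.g. patients vs controls) with
leave-one-out SVMs on relative-energy features, with feature selection done
inside each fold.

The package is aimed at researchers applying energy-landscape methods to
clinical or cognitive cohorts, and ships a synthetic-cohort generator with
known ground truth (including planted group effects at chosen minima) so the
whole pipeline is testable without access to any recordings.

## Worked example

A synthetic two-group cohort (N = 6 regions, 10 + 10 participants,
20,000 samples each) with a 0.6 energy elevation planted at one non-global
minimum in the "patient" group:

```r
library(energyscape)

spec <- synthetic_spec(N = 6, J_scale = 0.3, T = 20000, n_per_group = 10,
                       effect = list(delta = 0.6), seed = 35)
cohort <- make_cohort(spec, tol = 1e-5)   # samples series and fits each participant

# fit quality for one participant
b   <- sample_state_series(cohort$truth$participants$params[[1]], 20000, seed = 1)
fit <- fit_pmem(empirical_stats(b))
fit
#> <pmem_fit> N = 6; converged after 236 iterations (max moment gap 7.85e-07)
#>   accuracy index d = 0.9977 (D1 = 0.7409, D2 = 0.001729 bits)
```

`d` near 1 says the pairwise model captures almost all of the improvement
over an independent-region model (D1, D2 are KL divergences to the data, in
bits). The landscape of this fit has two minima:

```r
find_local_minima(energy_landscape(fit))
#> # A tibble: 2 × 4
#>   state pattern energy relative_energy
#> 1    16 ----+-   -3.49            0
#> 2    47 ++++-+   -2.36            1.13
```

Group-level minima of the cohort's aggregated landscape, tested against the
shuffled-parameter null (reversed direction: "deeper than chance"):

```r
permutation_test_minima(cohort$cohort, n_perm = 1000, seed = 2,
                        alternative = "less")
#> # A tibble: 2 × 7
#>   state pattern energy relative_energy p_value p_bonf significant
#> 1    16 ----+-   -3.81            0          0      0 TRUE
#> 2    47 ++++-+   -2.13            1.67       0      0 TRUE
```

Leave-one-out classification on relative-energy features (features selected
in-fold), and its label-permutation significance:

```r
cl <- loo_svm_classify(cohort$cohort, seed = 3)
cl
#> <loo_classification> accuracy 75.0% (sensitivity 80.0%, specificity 70.0%) over 20 folds
classification_permutation(cl, n_perm = 1000, seed = 4)$p_value
#> [1] 0.038
```

So the planted 0.6-energy elevation is recoverable from individual fits:
three quarters of participants are classified correctly, unlikely under
label exchange (p = 0.038). Basin occupancy under simulated dynamics
(20,000 Metropolis–Hastings steps, 1,000 burn-in):

```r
basin_durations(simulate_mh(fit, seed = 5),
                assign_basins(aggregate_cohort(cohort$cohort)))
#> # A tibble: 2 × 3
#>   state pattern proportion
#> 1    16 ----+-       0.810
#> 2    47 ++++-+       0.190
```

Plots: `autoplot(fit)` (model vs empirical state probabilities),
`autoplot(energy_landscape(fit))`, `autoplot(disconnectivity_graph(...))`,
`plot_basin_durations(...)`. Tidy accessors: `tidy()` / `glance()` on fits
and classification results.

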