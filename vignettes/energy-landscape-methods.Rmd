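---
title: "Energy landscape analysis of oscillatory network states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy landscape analysis of oscillatory network states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(energyscape)
library(dplyr)
```

## The model

`energyscape` analyses the collective dynamics of a brain network as a
sequence of discrete activity states. Each region of interest (ROI) is
reduced, at every time point, to one bit: high (+1) or low (−1) band-limited
oscillatory power. An $N$-ROI network therefore visits states
$s \in \{-1,+1\}^N$, and the package models their occurrence probabilities
with the pairwise maximum entropy model (pMEM) — the maximum-entropy
distribution constrained to match each region's mean activation
$\langle r_i \rangle$ and each pair's co-occurrence
$\langle r_i r_j \rangle$. That distribution is the Ising model's Boltzmann
law

$$P(s \mid h, J) = \frac{e^{-E(s)}}{\sum_{s'} e^{-E(s')}}, \qquad
E(s) = -\sum_i h_i r_i - \tfrac{1}{2}\sum_{i \ne j} J_{ij} r_i r_j,$$

where $h_i$ biases region $i$ towards high or low power and $J_{ij}$ couples
region pairs. Low-energy states are frequent states; a state with strictly
lower energy than its $N$ single-flip (Hamming-1) neighbours is a *local
minimum*, interpreted as an attractor-like network pattern. The collection of
all $2^N$ energies plus this adjacency is the *energy landscape*.

The model is exact and enumerative: everything (probabilities, moments,
minima, basins, barriers) is computed over all $2^N$ states, which confines
the method to $N \le 15$. The networks this package ships definitions for
(`network_rois()`) have 6–10 ROIs.

## Binarization front end

Continuous per-ROI signals are reduced to ±1 series in three steps:
`bandpass_filter()` (zero-phase Butterworth, default order 4, band presets in
`band_presets()`), `hilbert_envelope()` (magnitude of the FFT-based analytic
signal), and `binarize_median()` (per-column median split; strictly above the
median is +1). Conventions worth knowing:

* Ties at the median map to −1 — "above threshold" is read strictly, which
  makes the rule deterministic; constant columns binarize to all −1 with a
  warning.
* The median is taken over the full series per column, so for even $T$ with
  distinct values each column is exactly balanced.
* Edge distortion from the zero-phase filter and the Hilbert transform can
  be clipped with `binarize_median(edge_trim = 0.05)`; the default is no
  trimming.
* Two band presets ship: `"methods"` (theta 4–8, alpha 8–12, beta 13–30,
  low-gamma 35–60 Hz — the default) and `"abstract"` (4–7, 8–13, 15–25,
  30–60 Hz), reflecting the two conventions in circulation.
* The pipeline equally accepts pre-binarized ±1 matrices via
  `binary_states()`; source reconstruction is out of scope and resampling is
  left to the caller.

## Fitting

`fit_pmem()` runs gradient ascent on the log-likelihood, whose gradient is
the moment gap: $h_i \mathrel{+}= \epsilon(\langle r_i\rangle_{emp} -
\langle r_i\rangle_{mod})$ and likewise for $J_{ij}$, from $h = 0, J = 0$.
The problem is convex, so the moment-matching solution is unique. Two
schedules are available:

* **Default (adaptive):** start at $\epsilon = 0.05$; reject any step that
  decreases the log-likelihood and halve $\epsilon$ (backtracking on the
  likelihood, which gradient ascent increases monotonically — the max
  moment gap itself is not monotone along the path), grow by 10% (capped at
  1) on accepted steps; stop when the gap falls below `tol = 1e-6`. Typical
  fits at $N = 10$ converge in a few hundred iterations.
* **`legacy_mode = TRUE`:** the fixed schedule used in the original energy-landscape literature,
  $\epsilon = 10^{-8}$ for up to $5 \times 10^6$ iterations. At that rate
  parameters move by at most $\sim 0.05$ in total; the preset exists for
  protocol fidelity, not as a practical convergence criterion.

Empirical means of exactly ±1 (a region always high or always low) would
need infinite parameters; they are clamped to $\pm(1 - 1/(2T))$ before
`artanh` and before fitting.

Goodness of fit is the accuracy index $d = (D_1 - D_2)/D_1$, where $D_2$ is
the Kullback–Leibler divergence (base 2, summed over observed states,
$0\log 0 := 0$) from the empirical distribution to the pairwise model and
$D_1$ the same for the independent model ($J = 0$, fitted analytically as
$h_i = \operatorname{artanh}\langle r_i\rangle$). $d = 1$ means the pairwise
model reproduces the empirical distribution exactly; $d = 0$ means pairwise
couplings add nothing. When $D_1$ is numerically zero (a factorized
empirical law) $d$ is defined as 0 — otherwise the ratio would divide the
pairwise fit's convergence error by machine noise. A subtlety the test suite
documents: distributions with purely higher-order structure (e.g. the
three-spin parity law) have *zero* pairwise structure, so $d = 0$ for them
even though they are far from independent — $d$ measures second-order
improvement only.

## Landscape measures

* `find_local_minima()` scans all states exhaustively; minima require
  *strictly* lower energy than all neighbours (exact ties are measure-zero
  for fitted parameters, and the strict rule keeps results deterministic).
* `global_minimum()` breaks exact ties by lowest state index, with a
  warning.
* `relative_energies()` reports each minimum's energy above the global
  minimum — the landscape-shape quantity used for group comparison and
  classification, since the global minimum's depth varies per participant.
* `assign_basins()` performs steepest descent (lowest-energy neighbour,
  ties by lowest index; plateau states follow tie-break descent with a
  warning) to partition all $2^N$ states into basins of attraction.
* `disconnectivity_graph()` computes, for every pair of minima, the minimax
  barrier — the lowest possible highest energy along any Hamming-1 path —
  by sorting states by energy and merging connected components
  incrementally (union-find threshold sweep). This is the standard exact
  equivalent of shortest-widest-path formulations and is cross-checked in
  the tests against a brute-force connectivity oracle; the merge tree is
  ultrametric by construction and exports to Newick via
  `write_disconnectivity_newick()`.
* `aggregate_landscapes()` / `aggregate_cohort()` average energies
  state-by-state across participants (no refitting of pooled data), giving
  the group landscape on which common minima are identified.

## Generative simulation

`simulate_mh()` runs the single-flip Metropolis–Hastings chain: propose one
of the $N$ neighbours uniformly; accept downhill or equal moves always,
uphill moves with probability $e^{-\Delta E}$. Rejected proposals re-count
the current state — the standard dwell-time convention, which makes the
chain's stationary law exactly the model's Boltzmann distribution (detailed
balance is asserted numerically in the tests). Defaults follow the standard
protocol: 20,000 steps, the first 1,000 discarded, 19,000 retained.
`basin_durations()` then reports the fraction of retained time per basin.
Raising a minimum's energy (see planting, below) strictly shortens its
simulated basin duration. Steps are model time, not physiological time.

## Permutation test of minima

`permutation_test_minima()` asks whether each minimum of the aggregated
landscape reflects the observed activation/co-activation structure: per
permutation, each participant's $h$ entries are shuffled across regions and
the upper-triangle $J$ entries across pairs (independently per participant,
symmetry preserved), landscapes re-averaged, and the minimum's null energies
collected over 1,000 permutations by default; Bonferroni correction is
applied across the minima tested. Because energies are linear in the
parameters, all null landscapes for one permutation reduce to a single
matrix product, so the test is exact and fast.

Two conventions deserve care:

* **Ties.** The p-value counts ties as exceeding
  ($p = \#\{null \ge obs\}/n_{perm}$, no $+1$), because the all-off and
  all-on states are *exactly* invariant under the shuffle (their energies
  depend only on $\sum h$ and $\sum J$) and must come out $p = 1$ — they are
  structurally non-significant, matching the reported $p > 0.88$ behaviour.
  `plus_one = TRUE` gives the conservative variant.
* **Direction.** The default follows the stated convention literally:
  $p$ is the fraction of null samples *greater than or equal to* the
  observed energy. Under this reading an unusually *deep* minimum has
  $p \approx 1$: on synthetic cohorts with genuine coupling structure every
  structured minimum gets $p = 1$ under the default and $p \approx 0$ under
  the reversed direction (`alternative = "less"`). Since a test in which
  depth can never be significant cannot select features, analyses that need
  to *detect* characteristic minima — including the classifier's in-fold
  feature selection — use `alternative = "less"`; the classifier defaults
  to it, while `permutation_test_minima()` itself keeps the literal default.
* p-values at a *pre-specified* state are exactly calibrated (uniform) when
  participants' parameters are exchangeable across regions/pairs; p-values
  at data-selected minima inherit a selection effect and are not expected
  to be uniform. The calibration test therefore probes a fixed state.

## Classification

`loo_svm_classify()` implements leave-one-out classification of patients vs
controls with an RBF-kernel SVM at $C = 1$. Each fold re-derives its feature
space from the training participants only: aggregate training landscapes,
find minima, select significant ones by the in-fold permutation test
(`n_perm_select = 200` by default; 1,000 for the full-fidelity protocol),
and use each participant's *relative energies* at those minima as features.
Folds with no significant minima fall back to the training majority class.
Unstated details resolved here, all logged in the result: features are
z-scored with training-fold statistics; the kernel width follows the median
heuristic on training features ($\gamma = 1/(2\,\mathrm{median}\,\|x_i -
x_j\|^2)$), configurable. `classification_permutation()` assesses
significance by recomputing the accuracy of the *fixed* fold predictions
against 1,000 shuffled labelings; sensitivity/specificity treat "patient" as
the positive class.

## Synthetic cohorts

Because the motivating recordings are not public, `synthetic_spec()` /
`make_cohort()` generate everything the pipeline needs with known ground
truth:

* Ground-truth models draw $h_i \sim N(0, 0.3^2)$ and
  $J_{ij} \sim N(0, J_{scale}^2)$; participants are jittered copies
  (s.d. 0.05) of one base model; patients receive a planted effect.
* **Planting is exact on the measured scale.** The patient perturbation is
  the minimum-norm parameter change that raises the targeted states'
  energies by exactly $\Delta$ (energies are linear in the parameters, so
  this is a small exactly-solvable linear system); spillover onto other
  states is reported. This makes the planted effect the very quantity the
  pipeline estimates, rather than an indirect parameter nudge. Targets are
  chosen as the non-global minima with the largest local depth, and
  `make_cohort()` refuses a $\Delta$ that would destroy the targeted
  minimum (the elevated state must remain a strict minimum).
* State series are sampled i.i.d. from the enumerated Boltzmann law, or as
  a thinned Metropolis–Hastings chain when temporal autocorrelation is
  wanted; `synth_envelope_signals()` additionally renders binary series as
  continuous narrowband signals whose envelopes encode the states, for
  testing the binarization front end. Its recovery guarantee (≥ 90% of
  labels at SNR ≥ 10) holds for per-column *balanced* targets — a median
  split cannot reproduce an imbalanced high/low ratio — and requires state
  hold times long against the inverse analysis bandwidth (default 125
  samples = 0.5 s at 250 Hz; faster switching pushes the modulation
  sidebands outside a 4-Hz-wide band).
* Default sizes: $N = 6$ (sensorimotor-sized) for fast tests; the
  end-to-end validation uses $N = 10$ (fronto-parietal-sized), 26 + 26
  participants, $T = 20{,}000$ samples each, $\Delta = 0.8$, and
  $J_{scale} = 0.25$ — strong enough that the base landscape is multistable
  (4–8 minima), which the planted-minimum design presupposes. $\Delta =
  0.8$ is comparable to the spread of relative energies across minima, i.e.
  a large but not degenerate group effect.

What passing synthetic tests do *not* show: real MEG envelopes are not
narrowband log-normal two-level processes, real between-participant
variability is not isotropic parameter jitter, and real group effects are
not exact energy increments at single states. The synthetic cohort
validates the *machinery* — fitting, landscape characterization, null
calibration, leakage-free classification — not the neurophysiological
claims.

## Numerical choices and limitations

* Boltzmann probabilities use max-shift stabilization; arbitrarily large
  $|E|$ cannot overflow.
* All tie-breaks (argmin, descent, minima) resolve to the lowest state
  index, for bit-reproducibility.
* Every stochastic function takes a `seed` and records it in its output.
* Enumeration bounds everything at $N \le 15$; no pseudo-likelihood or
  mean-field approximations are provided for larger networks.
* The fitted pMEM is a stationary model: it captures state occupancy, not
  transition asymmetries; Metropolis–Hastings dynamics are a model *of the
  fitted distribution*, not of physiological time courses.

## A worked end-to-end example

```{r example, eval = FALSE}
spec <- synthetic_spec(N = 6, J_scale = 0.3, T = 20000, n_per_group = 10,
                       effect = list(delta = 0.6), seed = 35)
cohort <- make_cohort(spec, tol = 1e-5)

glance(fit_pmem(empirical_stats(
  sample_state_series(cohort$truth$participants$params[[1]], 20000,
                      seed = 1))))

minima <- permutation_test_minima(cohort$cohort, n_perm = 1000, seed = 2,
                                  alternative = "less")
classification <- loo_svm_classify(cohort$cohort, seed = 3)
classification_permutation(classification, n_perm = 1000, seed = 4)$p_value
```
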