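---
title: "Semi-orthogonal value subspaces: theory, estimation, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-orthogonal value subspaces: theory, estimation, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindgeom)
```

## The problem

When a neural population represents two offers at once -- each with a value
and a context (its side of the screen, or its position in a presentation
sequence) -- a perfectly factorized code is ambiguous: the summed population
response to "high on the left, low on the right" is identical to the summed
response to the swapped assignment. A downstream reader can recover both
values and both contexts but not which value goes with which context. This is
the binding problem, and its failure mode is the *misbinding* (swap) error.
Fully orthogonal, context-specific value codes solve binding but destroy
*generalization*: a value decoder learned in one context tells you nothing
about the other.

`bindgeom` implements an analytic theory of codes that sit between these
extremes, a set of simulators that realize such codes explicitly, and the
estimation pipeline that recovers a code's geometry from trial-by-neuron
firing-rate tables: per-neuron regression, subspace correlations with a noise
ceiling, cross-validated (crossnobis) distance decomposition, predicted error
rates, and population decoding with cross-condition generalization. Because
no recordings ship with the package, a first-class synthetic-data module
generates complete experiments -- risky-choice trials, a subjective-value
agent, and neural sessions with controlled geometry -- so every claim the
package makes is exercised end to end against known ground truth.

## The linear-nonlinear code

A stimulus is a point on a lattice of `K` features with `n` levels each
(`stimulus_spec()`). Its population response is

    r(x) = L x_z + M f_N(x) + noise,

where `L` (N x K) carries the *linear* part -- a shared value axis of length
`dLV` and a context axis of length `dLA` -- and `M` (N x n^K) carries the
*conjunctive* part: one column of length `m = dN / sqrt(2)` per lattice
point, switched on by the conjunctive identity `f_N`. Two stimuli whose
conjunctive columns differ sit `dN` apart in the nonlinear part. Isotropic
Gaussian noise with standard deviation `sigma` per dimension completes the
model (`code_params()`).

Stimulus features enter `x_z` as centered, unit-spacing levels
(`x - (n+1)/2`): with this coding the linear geometry is controlled entirely
by the column lengths of `L`, which is what the theory assumes. `build_code()`
realizes codes with *exactly* orthogonal columns (QR of a random Gaussian
basis) rather than relying on high-dimensional near-orthogonality, so the
analytic identities below hold to machine precision in every test, not just
in expectation.

Key closed forms (all verified against enumeration or simulation in the test
suite):

* linear power of a uniformly sampled lattice:
  `PL = K dL^2 (n^2 - 1) / 12` (`linear_distance_from_power()` inverts it);
* neighbor counts `NLA`, `NLD` (adjacent and diagonal lattice neighbors) and
  `NNL = n^K - 1`, by exhaustive enumeration (`neighbor_counts()`);
* combined distances `dC = sqrt(dL^2 + dN^2)`,
  `dCplus1 = sqrt(2 dL^2 + dN^2)`, and the chimera distance
  `dS = |M1 + M2 - M3 - M4| = sqrt(2) dN` (`code_distances()`);
* union-bound error rates, with `Q` the standard normal CDF:
  overall `NC Q(-dC/2s) + NCplus1 Q(-dCplus1/2s)` (`overall_error_rate()`),
  misbinding `NS Q(-dS/2s)` (`binding_error_rate()`), and generalization
  `Q(-(dLV^2 / (2 sqrt(dLV^2 + dN^2 + eps^2))) / s)`
  (`generalization_error_rate()`);
* the subspace correlation identity `rho = dLV^2 / (dLV^2 + dN^2)`
  (`subspace_correlation_from_distances()`);
* for two continuous offer values encoded at angle `theta`, the decoding
  variance `2 sigma^2 / sin(theta)^2` (`continuous_estimator_variance()`).

The structure of the tradeoff is immediate: the misbinding rate depends only
on `dN` and `sigma`; the generalization rate worsens as `dN` grows and
improves with `dLV`; at fixed total power, moving power between the two parts
trades one error against the other (`power_tradeoff_curve()`).

### Enumeration over closed forms

The average chimera count `NS` and the neighbor counts are *defined* by
exhaustive lattice enumeration (`chimeric_set_count()`), cached per
`(K, n, S)`. The averaging convention for `NS` treats stimulus sets as
ordered draws with replacement, which yields the value `1/4` for two
two-valued features and two stimuli; unordered-distinct averaging would give
`1/3` instead, and we fix the convention once. Printed summation formulas for
these counts are brittle to transcription; enumeration is exact for every
lattice the package supports, and the tests compare it against an
independently written brute-force counter.

Two constants are similarly fixed by explicit construction rather than by a
printed coefficient: the conjunctive column length is `m = dN / sqrt(2)` (so
that two orthogonal columns sit `dN` apart) and consequently
`dS = 2m = sqrt(2) dN`; and the nonlinear power convention in the tradeoff
sweep is `PN = dN^2 / 4`.

### Where the union bound is tight

The union bound counts each confusable neighbor as if errors were disjoint,
so it is an upper bound that is tight only when total error rates are small.
The theory-versus-simulation battery therefore runs on a grid
(`dL` in {1, 1.25}, `dN` in {0.5, 1}, `sigma` in {0.2, 0.25, 0.3}; 1e5
Monte-Carlo trials per point) where rates stay below roughly 10%, and the
agreement criterion is `max(0.02, 3 MC standard errors)`. At noise levels
that push error rates past ~15% the bound visibly over-predicts -- that is a
property of the approximation, not a bug, and both rates are still clipped to
their chance levels.

## Estimation pipeline

**Per-neuron regression** (`fit_neuron_models()`): ordinary least squares for
the noise (intercept), linear (value + side), and interaction
(+ value x side) models, fit to identical trials for all neurons at once.
Value is min-max normalized to [0, 1]; side is effects-coded -1/+1. A spline
value basis is deliberately not implemented: knot placement is a free choice
we cannot pin down, and every downstream quantity uses the linear-value
design.

**Stacking** (`stack_models()`): each neuron receives a simplex weight over
the three models maximizing the leave-one-out log predictive density of the
weight-mixed Gaussian predictive. LOO densities are exact via hat-matrix
deletion identities -- no sampling, deterministic, and fast enough to run per
neuron.

**Permutation ANOVA** (`permutation_anova()`): value is discretized into 7
quantile levels (re-binned downward if a cell empties), and the F statistics
for value, side, and their interaction are recomputed under row permutations
of the rates; `p = (#(F_perm > F_obs) + 1) / (n_perm + 1)`, which can never
be zero. The implementation projects permuted responses onto precomputed
orthonormal model bases, so 500 neurons x 1000 permutations run in seconds,
and its type-I rate on null neurons is verified to sit in [0.03, 0.07] at the
5% level.

**Subspace vectors and correlations** (`value_subspace_vector()`,
`subspace_correlation()`): the value direction at side `s` is
`betaValue + s * betaInteraction` -- the predicted high-value response minus
the value/side intercept response, from which intercept and pure-side terms
cancel exactly.

**Noise ceiling** (`noise_ceiling_test()`): raw cross-context correlations
are attenuated by estimation noise, so "less than perfectly correlated" is
not evidence of distinct subspaces. Each draw splits trials into two disjoint
stratified halves and fits both contexts on both halves; the observed value
is the mean cross-context, cross-half correlation and the ceiling is the mean
same-context, cross-half correlation. Because both statistics compare
disjoint-data fits, their error structures are identical, and under a truly
shared subspace the two distributions coincide -- the paired one-sided
p-value is calibrated. (The naive alternative, correlating overlapping
bootstrap resamples of the same data for the ceiling only, shares the
full-sample estimation error between ceiling partners and rejects shared
subspaces essentially always; we verified this and rebuilt the test on
disjoint splits.)

**Disattenuated subspace correlation** (`estimate_subspace_rho()`): for
recovering the generative `rho` as a number, the package uses the standard
errors-in-variables moment correction -- subtracting the OLS error
(co)variances implied by the design from the across-neuron weight
(co)variances -- with a stratified delete-block jackknife (40 blocks) for its
confidence interval. A with-replacement trial bootstrap is avoided here:
duplicated rows shrink the apparent residual variance and bias the
correction. Jackknife coverage was verified at ~95% on synthetic populations
at two signal-to-noise levels.

**Crossnobis decomposition** (`crossnobis_rdm()`, `decompose_rdm()`,
`decompose_session()`): squared condition distances are estimated as averages
of inner products of fold-wise mean differences across independent folds
(5 stratified folds by default, no noise whitening), which is unbiased and
admits negative draws. The six pairwise distances among the four
value x context conditions are decomposed by non-negative least squares
(`pracma::lsqnonneg`) against the design whose rows are `[1 0 2]` (value-only
pairs), `[0 1 2]` (context-only), `[1 1 2]` (both), with unknowns
`(dLV^2, dLA^2, m^2)` and reported `dN = sqrt(2) m`. Bootstrap uncertainty
resamples trials within condition x fold cells, so duplicated trials never
cross folds -- crossing would break the estimator's independence structure
and we measured the resulting positive bias before adopting this scheme.

**Noise and standard-error distance** (`estimate_noise_and_sem()`):
`sigma_hat` is the standard deviation of single-trial residuals projected on
the training-pair decoding direction. `epsilon_hat` is the *standard-error
distance*: the expected length of the centroid-estimation error vector, i.e.
per-condition total residual variance over trials, summed across the two
training centroids (approximately `2 N sigma^2 / n`). This full-vector
convention -- rather than the 1-D projected SEM, which would be numerically
negligible next to `dN^2` -- is what reproduces the empirical generalization
deficit of decoders trained on finite data.

**Decoding** (`build_pseudopopulation()`, `preprocess_features()`,
`decode_value()`): neurons enter a pseudopopulation only if every
value x context condition has at least 160 trials (broad splits) or 80
(narrow); per-condition trials are subsampled without replacement to a common
count (replacement only when a session is short, since duplicates merely add
decoder noise). Preprocessing is z-scoring then PCA retaining 99% variance,
both fit on the training split only. The decoder is a soft-margin linear SVM
(`e1071::svm`), cost fixed at 1 by default; because a fixed cost can overfit
when features are numerous relative to training trials, `cost = "cv"` selects
it from {1e-3, ..., 1} by held-out accuracy *within the training context* --
the generalization set is never touched. Held-out accuracy is the mean over
ten 90/10 splits with classes balanced by subsampling; generalization
accuracy is measured on all trials of the other context.

**Error-trial projections** (`error_trial_projection()`,
`error_projection_battery()`): two readouts of the simultaneous-offer window
-- which *side* carried the higher offer, and which *presentation* did -- are
trained on optimal-choice trials only; the signed, toward-correct,
norm-normalized distance to the boundary is averaged over held-out optimal
trials and over suboptimal trials, as equal-weighted means over
class x other-readout cells (so finite-sample cell imbalance cannot
masquerade as an effect), averaged over five repeated holdout splits. Session
means feed a one-sided paired t-test across sessions.

## The synthetic experiment

`generate_task_trials()` draws offers with the task's statistics: types
medium/large/safe with probabilities 0.4375/0.4375/0.125, stakes
0.165/0.240/0.125 mL, gamble win probabilities uniform on (0, 1), safe offers
guaranteed, sides randomized; safe trials are flagged and excluded from
neural analyses. `simulate_agent()` realizes the subjective-value model
`SV = exp(-beta (-ln p)^alpha) * s^gamma` with a softmax choice rule; the
default agent (`gamma = 1.3`, `alpha = 0.7`, `beta = 1`, temperature 60) is
risk-seeking with an inverse-S probability warp, and its temperature was
calibrated once so that the higher-SV choice rate is approximately 0.82, the
realism anchor for this task. `fit_choice_model()` fits the four-variant
model space (objective/subjective stakes x objective/warped probability) by
multi-start maximum likelihood and compares variants by BIC -- a deliberate
substitution for variational-Bayes free-energy comparison, which ranks models
equivalently at this scale without a bespoke inference engine. The
two-parameter Prelec form is likewise a fixed convention. At 5000 trials per
agent, the softmax temperature's maximum-likelihood uncertainty is ~14%
relative (it trades against the utility exponent with only three stakes
levels), so recovery is scored as the mean signed relative error across
replicate agents, which isolates estimator bias from sampling noise.

`generate_population_session()` composes everything: per-offer epoch
responses carry the space-value code (shared value axis `dLV`, side axis
`dLA`, side x value conjunctions `dN_space`) plus an egocentric-time code
(`dLA_time`, epoch x value conjunctions `dN_time`); a simultaneous window
encodes both offers at once, yielding the eight order x value conditions used
by the misbinding-distance contrasts; an optional planted shift moves
suboptimal-choice trials toward the spatially swapped condition. Continuous
(normalized subjective) value drives the linear part while the conjunctive
part switches on binarized levels, mirroring how the analyses move between
the continuous task variable and the discrete theory. Per-neuron
multiplicative gain jitter (default sd 0.1) is the one concession to
biological heterogeneity.

What the generator does *not* emulate -- and hence what passing tests do not
establish about real recordings: Poisson or correlated spiking noise,
temporal dynamics within trials, session-to-session drift, neurons whose
tuning violates the equal-length conjunctive assumption, and eye-movement or
attentional confounds. Passing the battery shows the pipeline recovers the
geometry it is designed to recover when its model family is correct.

## Problem sizes and numerical choices

The packaged battery (`recovery_suite()`) uses: a 2 x 2 x 3 theory-validation
grid at 1e5 Monte-Carlo trials per point; one geometry-recovery session of
200 neurons x 500 trials per condition with `dLV = 2`, `dLA = 1.6`,
`dN = 1.2`, `sigma = 1` -- per-neuron coefficients of 0.1-0.2 z-units, chosen
by power analysis so that the crossnobis estimator's own sampling error
supports a 10% recovery check at this session size (the decomposition pools
the two offer epochs, as the space-value analysis averages over first and
second offers); twenty 30-neuron, 800-trial sessions per projection battery;
eight replicate 5000-trial agents; and 500 null neurons x 1000 permutations
for ANOVA calibration. On one CPU the battery runs in about 40 seconds and
the full test suite in under two minutes.

Degenerate inputs are handled explicitly: `dLV = 0` returns chance
generalization; `dLV = dN = 0` makes the subspace correlation an error rather
than a silent `NaN`; `sin(theta) = 0` is a singular-encoding error; all-equal
values binarize to all-excluded; error rates are clipped to their chance
levels because union bounds exceed them at high noise; ML decoding ties are
broken uniformly at random under the module seed (exactly the `dN = 0`
boundary, where the chimera ties the truth); NNLS receives negative
crossnobis entries un-clipped and only the solution is constrained
non-negative.

## Known limitations

* The union-bound rates are upper bounds; quantitative agreement with
  simulation is limited to the low-to-moderate error regime.
* `overall_error_rate()` supports unequal `dLV`/`dLA` only for `K = 2`
  (per-axis union bound); the symmetric formula covers all `K`.
* The decomposition assumes equal conjunctive lengths across conditions; with
  strongly heterogeneous nonlinearity `dN` becomes an effective average.
* The "no temporal effect" and null false-positive checks in the projection
  battery are significance statements at the 5% level and retain the
  corresponding irreducible failure probability under reruns with other
  seeds.
* The behavior model space is the four-variant family; no hierarchical
  pooling across sessions is attempted.
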