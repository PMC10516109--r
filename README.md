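# bindgeom

Tools for studying how neural populations *bind* feature values to contexts
— which offer value belongs to which side of the screen, or to which moment
in a sequence — using semi-orthogonal coding subspaces, and what that
geometry costs in *generalization*.

A perfectly factorized population code (value and position encoded on
independent axes) cannot tell "high-left, low-right" from its swap: the
summed response is identical, so even an ideal decoder misbinds at chance.
Fully separate value codes per context solve binding but a value decoder
learned in one context then transfers nothing to the other. `bindgeom`
implements the analytic theory of linear–nonlinear codes that interpolate
between these extremes, together with the full estimation pipeline for
trial-by-neuron firing-rate data and a synthetic-experiment generator that
validates every stage end to end.

The core model writes the response to stimulus `x` (a point on a `K`-feature,
`n`-level lattice) as

    r(x) = L x_z + M f_N(x) + ε,   ε ~ N(0, σ² I)

with a linear part `L` (value axis of length `d_LV`, context axis `d_LA`) and
a conjunctive part `M` (one orthogonal column of length `m = d_N/√2` per
lattice point). Its headline quantities, all closed-form:

- misbinding rate `N_S · Q(−√2·d_N / 2σ)` — depends only on the conjunctive
  distance and noise;
- cross-condition generalization error
  `Q(−d_LV² / (2σ·√(d_LV² + d_N² + ε²)))` — worsens as `d_N` grows;
- subspace correlation `ρ = d_LV² / (d_LV² + d_N²)` — the single number that
  mediates the tradeoff;
- overall union-bound error rate, and `Var(v̂) = 2σ²/sin²θ` for the
  continuous two-offer case.

## What's in the package

| Module | Functions |
| --- | --- |
| Closed-form theory | `stimulus_spec`, `code_params`, `neighbor_counts`, `chimeric_set_count`, `overall_error_rate`, `binding_error_rate`, `generalization_error_rate`, `subspace_correlation_from_distances`, `continuous_estimator_variance`, `power_tradeoff_curve` |
| Explicit code simulators | `build_code`, `encode_trials`, `ml_decode_sets`, `simulate_error_curves`, `prototype_ccgp`, `simulate_continuous_mse` |
| Behavior | `sv_model`, `subjective_value`, `choice_probability`, `fit_choice_model`, `compare_choice_models`, `binarize_value` |
| Per-neuron models | `fit_neuron_models`, `stack_models`, `permutation_anova`, `subspace_contribution` |
| Subspace geometry | `value_subspace_vector`, `subspace_correlation`, `noise_ceiling_test`, `estimate_subspace_rho` |
| Geometry decomposition | `crossnobis_rdm`, `decompose_rdm`, `decompose_session`, `estimate_noise_and_sem`, `predicted_error_rates`, `misbinding_distance_contrasts` |
| Decoding | `build_pseudopopulation`, `preprocess_features`, `decode_value`, `error_trial_projection`, `error_projection_battery` |
| Synthetic experiments | `task_config`, `generate_task_trials`, `simulate_agent`, `generate_population_session`, `recovery_suite` |

The numbered scripts under `analysis/` run the workflow as a narrative —
theory validation, behavior, single neurons, subspaces, geometry
decomposition, decoding — and write their tables under `results/`. The
methods vignette (`vignettes/binding-geometry.Rmd`) documents the model,
estimators, and design choices.

## Worked example

Estimate a synthetic session's geometry and predict its error rates:

```r
library(bindgeom)

ses <- generate_population_session(n_neurons = 200, n_trials = 2000,
                                   dLV = 2, dLA = 1.6, dN_space = 1.2,
                                   dN_time = 0, dLA_time = 0,
                                   heterogeneity = 0, value_coding = "binary",
                                   seed = 61)
dec <- decompose_session(ses$rates, ses$trials$level,
                         ifelse(ses$trials$side == 1, "left", "right"),
                         n_boot = 500, seed = 62)
dec$decomp
#> RDM decomposition: dLV = 2.016, dLA = 1.548, dN = 1.253 (residual 0.295)

predicted_error_rates(dec$decomp, dec$sigma_hat, dec$epsilon_hat)[
  c("binding", "generalization", "rho", "chance_binding")]
#> $binding        [1] 0.0463186
#> $generalization [1] 0.2016248
#> $rho            [1] 0.7212944
#> $chance_binding [1] 0.125
```

The generative truth was `dLV = 2, dLA = 1.6, dN = 1.2` (so ρ = 0.735): the
crossnobis + non-negative-least-squares decomposition recovers all three
distances within a few percent (the 4%-low dLA reflects this session's
sampling noise; the bootstrap CI covers the truth). The predicted misbinding rate (4.6%, vs 12.5%
chance) says this code's conjunctive component makes value–side swaps rare;
the predicted generalization error (20%) is the price paid, and
`analysis/06_decoding_and_errors.R` shows a linear SVM trained on left-offer
trials and tested on right-offer trials empirically reproduces it (empirical
cross-condition error 0.228 vs 0.202 predicted on this session).

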