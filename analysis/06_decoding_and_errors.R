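#!/usr/bin/env Rscript
# Decoding analyses: cross-condition generalization of a linear SVM against
# the predicted rate, the eight-condition misbinding distance contrasts, and
# the error-trial projection battery with a planted spatial misbinding shift.
#
# Writes: results/ccgp.csv, results/misbinding_contrasts.csv,
#         results/error_projection.csv

library(bindgeom)
dir.create("results", showWarnings = FALSE)

## CCGP: predicted vs empirical on the decomposition session
ses <- generate_population_session(n_neurons = 200, n_trials = 2000,
                                   dLV = 2, dLA = 1.6, dN_space = 1.2,
                                   dN_time = 0, dLA_time = 0,
                                   heterogeneity = 0, value_coding = "binary",
                                   seed = 61)
dec <- decompose_session(ses$rates, ses$trials$level,
                         ifelse(ses$trials$side == 1, "left", "right"),
                         n_boot = 0, seed = 62)
pred <- predicted_error_rates(dec$decomp, dec$sigma_hat, dec$epsilon_hat)
e1 <- ses$trials$epoch == 1
pseudo <- build_pseudopopulation(
  list(list(rates = ses$rates[e1, ], value = ses$trials$level[e1],
            context = ifelse(ses$trials$side[e1] == 1, "left", "right"))),
  "broad", seed = 63)
dr <- decode_value(pseudo, "left", "right", cost = "cv", seed = 64)
ccgp <- data.frame(standard_accuracy = dr$standard,
                   generalization_accuracy = dr$generalization,
                   empirical_gen_error = 1 - dr$generalization,
                   predicted_gen_error = pred$generalization)
write.csv(ccgp, "results/ccgp.csv", row.names = FALSE)
cat(sprintf("CCGP: standard %.3f, generalization %.3f (empirical error %.3f vs predicted %.3f)\n",
            dr$standard, dr$generalization, 1 - dr$generalization,
            pred$generalization))

## eight-condition misbinding contrasts
ses8 <- generate_population_session(n_neurons = 60, n_trials = 1200,
                                    dN_space = 1, dN_time = 1,
                                    heterogeneity = 0, value_coding = "binary",
                                    seed = 65)
mc <- misbinding_distance_contrasts(ses8$rates_sim, ses8$sim_labels,
                                    n_boot = 500, seed = 66)
write.csv(mc, "results/misbinding_contrasts.csv", row.names = FALSE)
print(mc, digits = 3, row.names = FALSE)
cat("reading: temporal, spatial and spatio-temporal misbinding pairs are\n",
    "separated (codes with both conjunctions can disambiguate all swaps);\n",
    "the same-value low-low/high-high pairs sit at zero by construction.\n")

## error-trial projection battery with a planted spatial shift
mk <- function(sd, shift) generate_population_session(
  n_neurons = 30, n_trials = 800, planted_misbinding = shift, seed = sd)
planted <- error_projection_battery(lapply(1:20, function(i) mk(100 + i, 0.8)),
                                    seed = 1)
null <- error_projection_battery(lapply(1:20, function(i) mk(200 + i, 0)),
                                 seed = 1)
proj <- data.frame(battery = rep(c("planted", "null"), each = 2),
                   readout = rep(c("spatial", "temporal"), 2),
                   mean_diff = c(mean(planted$spatial$diffs),
                                 mean(planted$temporal$diffs),
                                 mean(null$spatial$diffs),
                                 mean(null$temporal$diffs)),
                   t = c(planted$spatial$t, planted$temporal$t,
                         null$spatial$t, null$temporal$t),
                   p = c(planted$spatial$p, planted$temporal$p,
                         null$spatial$p, null$temporal$p))
write.csv(proj, "results/error_projection.csv", row.names = FALSE)
print(proj, digits = 3, row.names = FALSE)
cat("reading: with a spatial misbinding shift planted on suboptimal-choice\n",
    "trials, the left-vs-right-higher decoder loses a large projection margin\n",
    "on those trials, while any drop for the first-vs-second-higher decoder is\n",
    "an order of magnitude smaller; without the shift both sit at the null.\n")
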