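#!/usr/bin/env Rscript
# Subspace geometry: the left/right value-subspace correlation with its
# bootstrap noise ceiling across populations of known generative rho, and the
# disattenuated correlation estimate.
#
# Writes: results/subspace_ceiling.csv

library(bindgeom)
dir.create("results", showWarnings = FALSE)

# dN chosen to realize rho = 1, 0.75, 0.5, 0.25, 0 at dLV = 1 (dLV = 0 for 0)
grid <- data.frame(rho = c(1, 0.75, 0.5, 0.25, 0),
                   dLV = c(1, 1, 1, 1, 1e-3),
                   dN = c(0, sqrt(1 / 3), 1, sqrt(3), 1))
rows <- lapply(seq_len(nrow(grid)), function(i) {
  ses <- generate_population_session(n_neurons = 50, n_trials = 800,
                                     dLV = grid$dLV[i], dN_space = grid$dN[i],
                                     dN_time = 0, heterogeneity = 0,
                                     value_coding = "binary", seed = 30 + i)
  e1 <- ses$trials$epoch == 1
  nc <- noise_ceiling_test(ses$rates[e1, ], ses$trials$value[e1],
                           ses$trials$side[e1], n_boot = 500, seed = 40 + i)
  est <- estimate_subspace_rho(ses$rates, ses$trials$value, ses$trials$side,
                               seed = 50 + i)
  data.frame(rho_true = grid$rho[i], raw_corr = est$raw,
             rho_disattenuated = est$rho, ci_lo = est$ci[1], ci_hi = est$ci[2],
             observed_median = median(nc$observed),
             ceiling_median = median(nc$ceiling),
             p_vs_ceiling = nc$p_vs_ceiling, p_vs_zero = nc$p_vs_zero)
})
out <- do.call(rbind, rows)
write.csv(out, "results/subspace_ceiling.csv", row.names = FALSE)
print(out, digits = 3, row.names = FALSE)
cat("reading: parallel subspaces (rho = 1) sit inside the ceiling; semi-orthogonal\n",
    "populations fall below it while staying above zero; orthogonal populations\n",
    "are indistinguishable from zero.\n")
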