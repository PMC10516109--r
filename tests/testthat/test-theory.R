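# Closed-form theory: distances, neighbor counts, error rates, subspace
# correlation and the continuous-case estimator variance.

test_that("linear distance <-> power relation matches the uniform lattice", {
  sp22 <- stimulus_spec(2, 2)
  expect_equal(linear_distance_from_power(0.5, sp22), 1.0)
  expect_equal(linear_distance_from_power(0.25, stimulus_spec(1, 2)), 1.0)
  # round trip to machine precision
  for (PL in c(0.1, 0.7, 3)) {
    dL <- linear_distance_from_power(PL, stimulus_spec(2, 3))
    expect_equal(power_from_linear_distance(dL, stimulus_spec(2, 3)), PL)
  }
  # Monte-Carlo oracle: variance of a uniformly sampled K=2, n=3 lattice with
  # spacing dL = 1 equals the inverse-relation power
  set.seed(42)
  n_mc <- 1e6
  pts <- cbind(sample(0:2, n_mc, replace = TRUE), sample(0:2, n_mc, replace = TRUE))
  mc_var <- mean(rowSums(sweep(pts, 2, colMeans(pts))^2))
  expect_equal(mc_var, power_from_linear_distance(1, stimulus_spec(2, 3)),
               tolerance = 0.005)
})

test_that("invalid stimulus specs are rejected", {
  expect_error(stimulus_spec(0, 2), "K")
  expect_error(stimulus_spec(2, 1), "n")
})

# independent brute-force neighbor counter (direct pairwise distances)
brute_neighbors <- function(K, n) {
  pts <- as.matrix(expand.grid(rep(list(seq_len(n)), K)))
  d2 <- as.matrix(stats::dist(pts))^2
  nla <- mean(rowSums(abs(d2 - 1) < 1e-9))
  nld <- mean(rowSums(abs(d2 - 2) < 1e-9))
  c(NLA = nla, NLD = nld)
}

test_that("neighbor counts equal exact lattice enumeration", {
  nb <- neighbor_counts(stimulus_spec(2, 2))
  expect_equal(nb$NLA, 2); expect_equal(nb$NLD, 1); expect_equal(nb$NNL, 3)
  expect_equal(nb$NC, nb$NLA); expect_equal(nb$NCplus1, nb$NLD)
  nb1 <- neighbor_counts(stimulus_spec(1, 2))
  expect_equal(nb1$NLA, 1); expect_equal(nb1$NLD, 0); expect_equal(nb1$NNL, 1)
  for (kn in list(c(3, 4), c(2, 3), c(4, 2), c(2, 9))) {
    nb <- neighbor_counts(stimulus_spec(kn[1], kn[2]))
    bf <- brute_neighbors(kn[1], kn[2])
    expect_equal(nb$NLA, unname(bf["NLA"]))
    expect_equal(nb$NLD, unname(bf["NLD"]))
    expect_equal(nb$NNL, kn[2]^kn[1] - 1)
  }
})

# independent brute-force chimera counter over ordered tuples
brute_chimeras <- function(K, n, S) {
  pts <- as.matrix(expand.grid(rep(list(seq_len(n)), K)))
  npt <- nrow(pts)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(npt)), S)))
  counts <- numeric(nrow(tuples))
  key <- function(ix) paste(sort(ix), collapse = "-")
  sums <- apply(tuples, 1, function(ix) paste(colSums(pts[ix, , drop = FALSE]),
                                              collapse = "-"))
  keys <- apply(tuples, 1, key)
  for (i in seq_len(nrow(tuples))) {
    same_sum <- keys[sums == sums[i]]
    counts[i] <- length(unique(same_sum)) - 1
  }
  mean(counts)
}

test_that("chimeric set counts match brute-force enumeration", {
  expect_equal(chimeric_set_count(stimulus_spec(2, 2, 2)), 0.25)
  expect_equal(chimeric_set_count(stimulus_spec(1, 2, 2)), 0)
  expect_equal(chimeric_set_count(stimulus_spec(2, 3, 2)),
               brute_chimeras(2, 3, 2))
  expect_equal(chimeric_set_count(stimulus_spec(3, 2, 2)),
               brute_chimeras(3, 2, 2))
  expect_error(chimeric_set_count(stimulus_spec(2, 2, 1)), "S >= 2")
  expect_error(chimeric_set_count(stimulus_spec(3, 9, 2)), "cap")
})

test_that("combined code distances follow the orthogonal geometry", {
  p <- code_params(dLV = 3, dLA = 3, dN = 4, sigma = 1)
  dd <- code_distances(p)
  expect_equal(dd$dC, 5)                       # 3-4-5 triangle
  expect_equal(dd$dCplus1, sqrt(2 * 9 + 16))
  expect_equal(dd$dS, sqrt(2) * 4)             # |M1+M2-M3-M4| with |Mi| = dN/sqrt(2)
  p0 <- code_params(dLV = 0, dLA = 0, dN = 2, sigma = 1)
  dd0 <- code_distances(p0, dL = 0)
  expect_equal(dd0$dC, 2); expect_equal(dd0$dCplus1, 2)
  # non-orthogonal case returns the cross-term scales
  dn <- code_distances(p, orthogonal = FALSE, N = 100)
  expect_equal(dn$cross_sd_dC2, 2 * 4 * 3 / 10)
  expect_equal(dn$cross_sd_dCplus12, sqrt(8) * 4 * 3 / 10)
  expect_error(code_distances(p, orthogonal = FALSE), "N")
})

test_that("overall error rate behaves at its limits and is clipped", {
  sp <- stimulus_spec(2, 2)
  expect_lt(overall_error_rate(code_params(1, 1, 1, sigma = 1e-3), sp), 1e-10)
  # zero distances: union bound exceeds chance and is clipped to 1 - 1/n^K
  expect_equal(overall_error_rate(code_params(0, 0, 0, sigma = 1), sp), 0.75)
  expect_error(overall_error_rate(code_params(1, 1, 1, sigma = 0), sp), "sigma")
  # monotone decreasing in dN
  rates <- sapply(seq(0, 2, by = 0.25), function(dn)
    overall_error_rate(code_params(1, 1, dn, sigma = 0.4), sp))
  expect_true(all(diff(rates) <= 1e-12))
  # asymmetric dLV != dLA reduces to the printed form when equal
  expect_equal(overall_error_rate(code_params(1, 1, 0.5, sigma = 0.3), sp),
               overall_error_rate(code_params(1, 1 + 1e-12, 0.5, sigma = 0.3), sp),
               tolerance = 1e-6)
})

test_that("binding error rate depends only on dN and sigma", {
  sp <- stimulus_spec(2, 2, 2)
  expect_equal(binding_error_rate(code_params(1, 1, 0, sigma = 0.5), sp), 0.125)
  expect_lt(binding_error_rate(code_params(1, 1, 50, sigma = 0.5), sp), 1e-12)
  # exact invariance to the linear distances
  base <- binding_error_rate(code_params(1, 1, 0.8, sigma = 0.4), sp)
  for (dlv in c(0, 0.5, 1, 2)) for (dla in c(0, 1, 3))
    expect_identical(binding_error_rate(code_params(dlv, dla, 0.8, sigma = 0.4), sp),
                     base)
  # strictly decreasing in dN
  rates <- sapply(seq(0, 2, by = 0.25), function(dn)
    binding_error_rate(code_params(1, 1, dn, sigma = 0.4), sp))
  expect_true(all(diff(rates) < 0))
})

test_that("generalization error rate follows the closed form", {
  expect_equal(generalization_error_rate(code_params(0, 1, 1, sigma = 0.3)), 0.5)
  expect_equal(generalization_error_rate(code_params(0, 0, 0, sigma = 0.3)), 0.5)
  # dN = epsilon = 0 reduces to Q(-dLV / (2 sigma))
  expect_equal(generalization_error_rate(code_params(1, 1, 0, sigma = 0.3)),
               pnorm(-1 / 0.6))
  # invariant to dLA; increasing in dN and epsilon; decreasing in dLV
  base <- generalization_error_rate(code_params(1, 0.3, 0.7, sigma = 0.3))
  for (dla in c(0, 1, 5))
    expect_identical(generalization_error_rate(code_params(1, dla, 0.7, sigma = 0.3)),
                     base)
  g_dn <- sapply(seq(0, 2, by = 0.5), function(dn)
    generalization_error_rate(code_params(1, 1, dn, sigma = 0.3)))
  expect_true(all(diff(g_dn) > 0))
  g_eps <- sapply(c(0, 0.5, 1), function(e)
    generalization_error_rate(code_params(1, 1, 0.5, sigma = 0.3, epsilon = e)))
  expect_true(all(diff(g_eps) > 0))
  g_dlv <- sapply(c(0.5, 1, 2), function(d)
    generalization_error_rate(code_params(d, 1, 0.5, sigma = 0.3)))
  expect_true(all(diff(g_dlv) < 0))
})

test_that("subspace correlation identity and explicit vector construction agree", {
  expect_equal(subspace_correlation_from_distances(1, 0), 1)
  expect_equal(subspace_correlation_from_distances(0, 1), 0)
  expect_equal(subspace_correlation_from_distances(1, 1), 0.5)
  expect_error(subspace_correlation_from_distances(0, 0), "undefined")
  # explicit v1 = L1 + M1 - M2, v2 = L1 + M3 - M4 with orthonormal columns
  m <- 1 / sqrt(2)  # dN = 1
  L1 <- c(1, rep(0, 4)); M <- rbind(0, diag(4) * m)
  v1 <- L1 + M[, 1] - M[, 2]; v2 <- L1 + M[, 3] - M[, 4]
  expect_equal(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)),
               subspace_correlation_from_distances(1, 1))
})

test_that("continuous estimator variance is 2 sigma^2 / sin^2(theta)", {
  expect_equal(continuous_estimator_variance(pi / 2, 1), 2)
  expect_equal(continuous_estimator_variance(pi / 6, 1), 8)
  expect_error(continuous_estimator_variance(0, 1), "singular")
  expect_error(continuous_estimator_variance(pi, 1), "singular")
})

test_that("power tradeoff curve moves the two error rates in opposite directions", {
  tc <- power_tradeoff_curve(1, sigma = 0.4)
  expect_true(all(diff(tc$binding) >= -1e-12))          # more linear -> more misbinding
  expect_true(all(diff(tc$generalization) <= 1e-12))    # more linear -> better generalization
  expect_equal(tc$PL + tc$PNL, rep(1, nrow(tc)))
})
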