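# Explicit population codes: construction geometry, trial encoding,
# maximum-likelihood set decoding, and theory-versus-simulation agreement.

test_that("build_code realizes the requested geometry exactly", {
  sp <- stimulus_spec(2, 2, 2)
  par <- code_params(dLV = 1.2, dLA = 0.7, dN = 0.9, sigma = 0.5)
  code <- build_code(16, sp, par, seed = 3)
  # orthogonality and column norms are exact (QR construction)
  B <- cbind(code$L, code$M)
  G <- crossprod(B)
  expect_equal(G[upper.tri(G)], rep(0, sum(upper.tri(G))), tolerance = 1e-12)
  expect_equal(sqrt(diag(crossprod(code$L))), c(1.2, 0.7))
  expect_equal(unname(sqrt(diag(crossprod(code$M)))), rep(0.9 / sqrt(2), 4))
  # realized pairwise distances: single-feature difference = sqrt(dL^2 + dN^2)
  i11 <- 1
  d <- as.matrix(dist(code$means))
  expect_equal(d[1, 2], sqrt(1.2^2 + 0.9^2))  # value step
  expect_equal(d[1, 3], sqrt(0.7^2 + 0.9^2))  # side step
  expect_equal(d[1, 4], sqrt(1.2^2 + 0.7^2 + 0.9^2))
  expect_error(build_code(5, sp, par), "N must be")
})

test_that("subspace correlation of a built code matches the rho identity", {
  sp <- stimulus_spec(2, 2, 2)
  code0 <- build_code(12, sp, code_params(1, 1, 0, sigma = 1), seed = 1)
  expect_equal(measured_subspace_correlation(code0), 1)  # factorized code
  code1 <- build_code(12, sp, code_params(1, 1, 1, sigma = 1), seed = 2)
  expect_equal(measured_subspace_correlation(code1), 0.5, tolerance = 1e-9)
  code2 <- build_code(12, sp, code_params(1.5, 1, 0.8, sigma = 1), seed = 3)
  expect_equal(measured_subspace_correlation(code2),
               subspace_correlation_from_distances(1.5, 0.8), tolerance = 1e-9)
})

test_that("mean responses of a set and its chimera coincide iff dN = 0", {
  sp <- stimulus_spec(2, 2, 2)
  for (dn in c(0, 0.8)) {
    code <- build_code(12, sp, code_params(1, 0.6, dn, sigma = 1), seed = 4)
    X <- rbind(c(1, 1), c(2, 2)); S <- rbind(c(1, 2), c(2, 1))
    delta <- encode_trials(code, X, sigma = 0, trials = 1) -
      encode_trials(code, S, sigma = 0, trials = 1)
    if (dn == 0) expect_equal(sum(delta^2), 0, tolerance = 1e-20)
    else expect_equal(sqrt(sum(delta^2)), code_distances(code$params)$dS,
                      tolerance = 1e-9)
  }
})

test_that("encode_trials produces the stated noise model", {
  sp <- stimulus_spec(2, 2, 1)
  code <- build_code(12, sp, code_params(1, 1, 0.5, sigma = 1), seed = 5)
  x <- rbind(c(1, 2))
  r0 <- encode_trials(code, x, sigma = 0, trials = 3, seed = 6)
  expect_equal(r0[1, ], r0[2, ])  # noiseless encoding is exact
  # lattice rows are (1,1), (2,1), (1,2), (2,2): x = (1,2) is row 3
  expect_equal(r0[1, ], code$means[3, ], ignore_attr = TRUE, tolerance = 1e-12)
  rn <- encode_trials(code, x, sigma = 0.7, trials = 4000, seed = 7)
  expect_equal(mean(apply(rn, 2, var)), 0.49, tolerance = 0.05)
})

test_that("ML set decoding is correct without noise and ties break at dN = 0", {
  sp <- stimulus_spec(2, 2, 2)
  code <- build_code(12, sp, code_params(1, 1, 0.8, sigma = 1), seed = 8)
  X <- rbind(c(1, 1), c(2, 2))
  r <- encode_trials(code, X, sigma = 1e-9, trials = 50, seed = 9)
  dec <- ml_decode_sets(code, r, S = 2, true_sets = X, seed = 10)
  expect_true(all(dec$outcome == "correct"))
  # purely linear code: exact tie between the set and its chimera
  code0 <- build_code(12, sp, code_params(1, 1, 0, sigma = 1), seed = 11)
  r0 <- encode_trials(code0, X, sigma = 1e-6, trials = 400, seed = 12)
  dec0 <- ml_decode_sets(code0, r0, S = 2, true_sets = X, seed = 13)
  expect_true(all(dec0$outcome %in% c("correct", "misbinding")))
  expect_equal(mean(dec0$outcome == "misbinding"), 0.5, tolerance = 0.1)
})

test_that("empirical misbinding rate matches the union-bound theory", {
  sp <- stimulus_spec(2, 2, 2)
  par <- code_params(1, 1, 1, sigma = 0.4)
  code <- build_code(12, sp, par, seed = 14)
  mb <- simulate_misbinding(code, 0.4, trials = 4e4, seed = 15)
  expect_lt(abs(mb$rate - binding_error_rate(par, sp)),
            max(0.02, 3 * mb$se) + 1e-12)
})

test_that("prototype CCGP margins and error match the analytic derivation", {
  sp <- stimulus_spec(2, 2, 2)
  par <- code_params(1, 1, 1, sigma = 0.3)
  code <- build_code(12, sp, par, seed = 16)
  cg <- prototype_ccgp(code, 0.3, trials = 4e4, seed = 17)
  # d12 and d22 reproduce +/- dLV^2 / (2 sqrt(dLV^2 + dN^2))
  margin <- 0.5 * 1 / sqrt(1 + 1)
  expect_equal(cg$d12, -margin, tolerance = 1e-9)
  expect_equal(cg$d22, margin, tolerance = 1e-9)
  expect_lt(abs(cg$rate - generalization_error_rate(par)), 3 * cg$se + 0.005)
  # dLV = 0: chance
  code0 <- build_code(12, sp, code_params(1e-9, 1, 1, sigma = 0.3), seed = 18)
  cg0 <- prototype_ccgp(code0, 0.3, trials = 2e4, seed = 19)
  expect_equal(cg0$rate, 0.5, tolerance = 0.02)
})

test_that("code power splits into linear and conjunctive parts as constructed", {
  sp <- stimulus_spec(2, 2, 1)
  par <- code_params(dLV = 1, dLA = 1, dN = 0.9, sigma = 1)
  code <- build_code(14, sp, par, seed = 20)
  # variance of noiseless encodings over the uniform lattice: the linear part
  # contributes exactly PL, the conjunctive part m^2 (1 - 1/n^K)
  mu <- code$means
  tot <- mean(rowSums(sweep(mu, 2, colMeans(mu))^2))
  PL <- power_from_linear_distance(1, sp)
  m2 <- (0.9 / sqrt(2))^2
  expect_equal(tot, PL + m2 * (1 - 1 / 4), tolerance = 1e-9)
})

test_that("simulated error curves are seeded-deterministic and chance-saturating", {
  sp <- stimulus_spec(2, 2, 2)
  t1 <- simulate_error_curves(sp, 1, 1, 0.3, trials = 2000, seed = 5)
  t2 <- simulate_error_curves(sp, 1, 1, 0.3, trials = 2000, seed = 5)
  expect_identical(t1, t2)
  # sigma -> infinity: overall error approaches chance 1 - 1/n^K
  code <- build_code(12, sp, code_params(1, 1, 1, sigma = 50), seed = 21)
  ov <- simulate_overall_error(code, 50, trials = 2e4, seed = 22)
  expect_equal(ov$rate, 0.75, tolerance = 0.02)
})

test_that("continuous decoder MSE matches 2 sigma^2 / sin^2(theta)", {
  for (ts in list(c(pi / 4, 0.5), c(pi / 3, 1), c(1.2, 0.3))) {
    mc <- simulate_continuous_mse(ts[1], ts[2], nsim = 2e5, seed = 23)
    expect_lt(abs(mc$mse - continuous_estimator_variance(ts[1], ts[2])),
              3 * mc$se)
  }
  expect_error(simulate_continuous_mse(0, 1), "singular")
})
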