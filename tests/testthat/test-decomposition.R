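# Crossnobis distances, linear/nonlinear decomposition, noise and SEM
# estimation, predicted error rates, and misbinding contrasts.

test_that("crossnobis is unbiased, including at zero distance", {
  set.seed(1)
  # identical distributions: mean estimate ~ 0, individual draws can be < 0
  zero_draws <- replicate(60, {
    X <- matrix(rnorm(200 * 30), 200, 30)
    crossnobis_rdm(X, rep(c("a", "b"), each = 100), n_folds = 4,
                   seed = sample.int(1e6, 1))$dist2[1, 2]
  })
  expect_lt(abs(mean(zero_draws)), 3 * sd(zero_draws) / sqrt(60))
  expect_gt(sum(zero_draws < 0), 0)
  # known offset delta: estimate -> delta^2
  delta <- 1.1
  off_draws <- replicate(60, {
    X <- matrix(rnorm(200 * 30), 200, 30)
    X[101:200, 1] <- X[101:200, 1] + delta
    crossnobis_rdm(X, rep(c("a", "b"), each = 100), n_folds = 4,
                   seed = sample.int(1e6, 1))$dist2[1, 2]
  })
  expect_lt(abs(mean(off_draws) - delta^2), 3 * sd(off_draws) / sqrt(60))
})

test_that("plain squared Euclidean distance is upward-biased where crossnobis is not", {
  set.seed(2)
  n <- 50; p <- 40
  bias_draws <- replicate(80, {
    X <- matrix(rnorm(2 * n * p), 2 * n, p)
    cond <- rep(c("a", "b"), each = n)
    naive <- sum((colMeans(X[1:n, ]) - colMeans(X[n + 1:n, ]))^2)
    cv <- crossnobis_rdm(X, cond, n_folds = 5, seed = sample.int(1e6, 1))$dist2[1, 2]
    c(naive, cv)
  })
  # expected naive bias at zero distance: 2 * trace(I_p) / n = 2p/n
  expect_equal(mean(bias_draws[1, ]), 2 * p / n, tolerance = 0.15)
  expect_lt(abs(mean(bias_draws[2, ])), 0.2)
})

test_that("crossnobis validates its inputs", {
  X <- matrix(rnorm(40 * 5), 40, 5)
  expect_error(crossnobis_rdm(X, rep(c("a", "b"), c(36, 4)), n_folds = 5),
               "'b'")
  expect_error(crossnobis_rdm(X, rep(c("a", "b"), each = 20), n_folds = 1),
               "folds")
})

test_that("decomposition solves the design system exactly when consistent", {
  # six distances exactly A [1, 1, 0.25]: residual 0 and exact recovery
  truth <- c(dLV2 = 1, dLA2 = 1, m2 = 0.25)
  conds <- c("high:L", "high:R", "low:L", "low:R")
  value_of <- setNames(sub(":.*", "", conds), conds)
  context_of <- setNames(sub(".*:", "", conds), conds)
  D <- matrix(0, 4, 4, dimnames = list(conds, conds))
  for (i in 1:3) for (j in (i + 1):4) {
    row <- c(value_of[i] != value_of[j], context_of[i] != context_of[j], 2)
    D[i, j] <- D[j, i] <- sum(row * truth)
  }
  rdm <- structure(list(dist2 = D, conditions = conds, n_folds = 5),
                   class = "crossnobis_rdm")
  dec <- decompose_rdm(rdm, value_of, context_of)
  expect_equal(unname(dec$est2), unname(truth), tolerance = 1e-9)
  expect_equal(dec$dN, sqrt(2 * 0.25), tolerance = 1e-9)
  expect_lt(dec$residual, 1e-12)
  expect_equal(dim(dec$A), c(6, 3))
})

test_that("a purely linear code yields a zero nonlinear estimate at the boundary", {
  ses <- generate_population_session(n_neurons = 60, n_trials = 600,
                                     dLV = 1.5, dLA = 1, dN_space = 0,
                                     dN_time = 0, heterogeneity = 0,
                                     value_coding = "binary", seed = 3)
  dec <- decompose_session(ses$rates, ses$trials$level,
                           ifelse(ses$trials$side == 1, "L", "R"),
                           n_boot = 0, seed = 4)
  expect_lt(dec$decomp$dN, 0.35)  # clipped at or near the boundary
  expect_equal(dec$decomp$dLV, 1.5, tolerance = 0.2)
})

test_that("generate -> crossnobis -> decompose recovers the code parameters", {
  ses <- generate_population_session(n_neurons = 100, n_trials = 2000,
                                     dLV = 2, dLA = 1.6, dN_space = 1.2,
                                     dN_time = 0, dLA_time = 0,
                                     heterogeneity = 0,
                                     value_coding = "binary", seed = 5)
  dec <- decompose_session(ses$rates, ses$trials$level,
                           ifelse(ses$trials$side == 1, "L", "R"),
                           n_boot = 100, seed = 6)
  expect_equal(dec$decomp$dLV, 2, tolerance = 0.2)
  expect_equal(dec$decomp$dLA, 1.6, tolerance = 0.16)
  expect_equal(dec$decomp$dN, 1.2, tolerance = 0.12)
  expect_equal(dec$sigma_hat, 1, tolerance = 0.05)
  # bootstrap CIs cover the squared components being positive
  expect_true(all(dec$p_positive < 0.05))
})

test_that("noise and SEM estimates behave with trial count", {
  mk <- function(n_per, seed) {
    set.seed(seed)
    mu <- rbind(c(rep(0, 30)), c(2, rep(0, 29)), c(0, 2, rep(0, 28)),
                c(2, 2, rep(0, 28)))
    cond <- rep(c("a", "b", "c", "d"), each = n_per)
    X <- mu[rep(1:4, each = n_per), ] + matrix(rnorm(4 * n_per * 30, sd = 0.8),
                                               4 * n_per, 30)
    estimate_noise_and_sem(X, cond, c("a", "b"))
  }
  e1 <- mk(100, 7); e2 <- mk(400, 8)
  expect_equal(e1$sigma_hat, 0.8, tolerance = 0.08)
  # quadrupling trials halves epsilon (1/sqrt(n) scaling)
  expect_equal(e1$epsilon_hat / e2$epsilon_hat, 2, tolerance = 0.2)
  expect_error(mk(1, 9), "at least 2")
})

test_that("predicted error rates plug into the closed-form theory", {
  conds <- c("high:L", "high:R", "low:L", "low:R")
  value_of <- setNames(sub(":.*", "", conds), conds)
  context_of <- setNames(sub(".*:", "", conds), conds)
  mkdec <- function(dLV2, dLA2, m2) {
    D <- matrix(0, 4, 4, dimnames = list(conds, conds))
    tr <- c(dLV2, dLA2, m2)
    for (i in 1:3) for (j in (i + 1):4) {
      row <- c(value_of[i] != value_of[j], context_of[i] != context_of[j], 2)
      D[i, j] <- D[j, i] <- sum(row * tr)
    }
    decompose_rdm(structure(list(dist2 = D, conditions = conds, n_folds = 5),
                            class = "crossnobis_rdm"), value_of, context_of)
  }
  # dN = 0: binding prediction is exactly chance NS/2 = 0.125
  p0 <- predicted_error_rates(mkdec(1, 1, 0), sigma = 0.5)
  expect_equal(p0$binding, p0$chance_binding)
  expect_equal(p0$binding, 0.125)
  # matches direct theory calls
  dec <- mkdec(1, 0.8, 0.3)
  pr <- predicted_error_rates(dec, sigma = 0.4, epsilon = 0.2)
  par <- code_params(dLV = dec$dLV, dLA = dec$dLA, dN = dec$dN,
                     sigma = 0.4, epsilon = 0.2)
  expect_equal(pr$binding, binding_error_rate(par, stimulus_spec(2, 2, 2)))
  expect_equal(pr$generalization, generalization_error_rate(par))
  expect_equal(pr$rho, subspace_correlation_from_distances(dec$dLV, dec$dN))
  # epsilon strictly increases predicted generalization error
  pr2 <- predicted_error_rates(dec, sigma = 0.4, epsilon = 0.5)
  expect_gt(pr2$generalization, pr$generalization)
  expect_error(predicted_error_rates(dec, sigma = 0), "sigma")
})

test_that("misbinding contrasts reflect which conjunctions the code carries", {
  # both space- and time-conjunctive terms: all three contrasts positive
  ses <- generate_population_session(n_neurons = 50, n_trials = 900,
                                     dN_space = 1, dN_time = 1,
                                     heterogeneity = 0,
                                     value_coding = "binary", seed = 10)
  mc <- misbinding_distance_contrasts(ses$rates_sim, ses$sim_labels,
                                      n_boot = 300, seed = 11)
  expect_equal(mc$contrast,
               c("temporal", "spatial", "spatio-temporal", "low-low", "high-high"))
  expect_true(all(mc$p_vs_zero[1:3] < 0.05))
  # low-low conditions are generated identically across orders: centered on 0
  expect_gt(mc$p_vs_zero[4], 0.05)
  expect_true(mc$ci_lo[4] < 0)
  # spatial-only conjunction: spatial contrast positive, temporal near zero
  ses_sp <- generate_population_session(n_neurons = 50, n_trials = 900,
                                        dN_space = 1, dN_time = 0,
                                        heterogeneity = 0,
                                        value_coding = "binary", seed = 12)
  mc_sp <- misbinding_distance_contrasts(ses_sp$rates_sim, ses_sp$sim_labels,
                                         n_boot = 300, seed = 13)
  expect_lt(mc_sp$p_vs_zero[mc_sp$contrast == "spatial"], 0.05)
  expect_gt(mc_sp$p_vs_zero[mc_sp$contrast == "temporal"], 0.05)
  expect_lt(abs(mc_sp$dist2[mc_sp$contrast == "temporal"]), 0.5)
})
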