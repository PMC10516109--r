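# Pseudopopulations, preprocessing, SVM decoding with cross-condition
# generalization, and the error-trial projection analysis.

# minimal session for pseudopopulation tests: known per-condition counts
fixed_count_session <- function(counts, n_neurons = 6, seed = 1L) {
  set.seed(seed)
  conds <- names(counts)
  value <- context <- character(0)
  for (cl in conds) {
    vv <- strsplit(cl, ":")[[1]]
    value <- c(value, rep(vv[1], counts[[cl]]))
    context <- c(context, rep(vv[2], counts[[cl]]))
  }
  list(rates = matrix(rnorm(length(value) * n_neurons), ncol = n_neurons),
       value = value, context = context)
}

test_that("pseudopopulation inclusion applies the trial thresholds exactly", {
  base <- c("high:left" = 90, "low:left" = 90, "high:right" = 90,
            "low:right" = 90)
  s_ok <- fixed_count_session(base, seed = 1)
  s_edge <- fixed_count_session(replace(base, 2, 80), seed = 2)   # exactly 80
  s_out <- fixed_count_session(replace(base, 2, 79), seed = 3)    # below
  ps <- build_pseudopopulation(list(s_ok, s_edge, s_out), "narrow", seed = 4)
  expect_equal(ps$included, c(TRUE, TRUE, FALSE))
  expect_equal(ncol(ps$X[[1]]), 12)   # 2 sessions x 6 neurons
  expect_equal(ps$n_per_condition, 80)
  # broad split requires 160: nothing qualifies
  expect_error(build_pseudopopulation(list(s_ok), "broad"), "zero qualifying")
  # seeded rerun gives an identical assembly
  ps2 <- build_pseudopopulation(list(s_ok, s_edge, s_out), "narrow", seed = 4)
  expect_identical(ps$X, ps2$X)
})

test_that("preprocessing fits on train only and retains 99% variance", {
  set.seed(5)
  # rank-2 training data -> 2 components
  basis <- matrix(rnorm(10 * 2), 2, 10)
  train <- matrix(rnorm(60 * 2), 60, 2) %*% basis
  pp <- preprocess_features(train, train[1:5, , drop = FALSE])
  expect_equal(pp$k, 2)
  # a test point equal to a train point maps identically
  expect_equal(pp$test[1, ], pp$train[1, ], tolerance = 1e-9)
  # isotropic 50-dim data: nearly all dimensions are needed for 99%
  iso <- matrix(rnorm(400 * 50), 400, 50)
  expect_gte(preprocess_features(iso)$k, 45)
  # zero-variance features are dropped with a warning
  bad <- cbind(train, 7)
  expect_warning(preprocess_features(bad), "zero-variance")
})

# single-session pseudopopulation over left/right with a given geometry
geometry_pseudo <- function(dLV, dN, seed, n_trials = 1200, sigma = 0.6) {
  ses <- generate_population_session(n_neurons = 40, n_trials = n_trials,
                                     dLV = dLV, dLA = 0.8, dN_space = dN,
                                     dN_time = 0, dLA_time = 0, sigma = sigma,
                                     heterogeneity = 0,
                                     value_coding = "binary", seed = seed)
  e1 <- ses$trials$epoch == 1
  build_pseudopopulation(
    list(list(rates = ses$rates[e1, ], value = ses$trials$level[e1],
              context = ifelse(ses$trials$side[e1] == 1, "left", "right"))),
    "broad", seed = seed + 1)
}

test_that("cross-condition generalization tracks the code geometry", {
  # factorized code (rho = 1), low noise: generalization ~ standard
  ps1 <- decode_value(geometry_pseudo(1.5, 0, seed = 6, sigma = 0.4),
                      "left", "right", seed = 7)
  expect_gt(ps1$standard, 0.9)
  expect_lt(abs(ps1$standard - ps1$generalization), 0.05)
  # orthogonal code (no shared value axis): chance generalization despite
  # high standard accuracy
  ps0 <- decode_value(geometry_pseudo(0.001, 1.5, seed = 8), "left", "right",
                      seed = 9)
  expect_gt(ps0$standard, 0.85)
  expect_lt(abs(ps0$generalization - 0.5), 0.07)
  expect_error(decode_value(geometry_pseudo(1, 0.5, seed = 10), "left", "left"),
               "must differ")
})

test_that("label-shuffled decoding is at chance", {
  ps <- geometry_pseudo(1.5, 0.5, seed = 11)
  # shuffle by reassigning condition matrices to scrambled labels
  shuf <- ps
  set.seed(12)
  for (cl in ps$conditions) {
    M <- do.call(rbind, ps$X)
    shuf$X[[cl]] <- M[sample(nrow(M), nrow(ps$X[[cl]])), , drop = FALSE]
  }
  dr <- decode_value(shuf, "left", "right", seed = 13)
  expect_lt(abs(dr$standard - 0.5), 0.08)
  expect_lt(abs(dr$generalization - 0.5), 0.08)
})

test_that("CCGP is non-decreasing in the subspace correlation", {
  accs <- sapply(list(c(0.3, 1.4), c(1, 1), c(1.5, 0.3)), function(g) {
    decode_value(geometry_pseudo(g[1], g[2], seed = 14), "left", "right",
                 cost = "cv", seed = 15)$generalization
  })
  expect_true(all(diff(accs) > -0.05))
  expect_gt(accs[3] - accs[1], 0.15)
})

test_that("error-trial projection is deterministic and handles missing cases", {
  ses <- small_session(seed = 16, planted_misbinding = 0.8)
  p1 <- error_trial_projection(ses, seed = 17)
  p2 <- error_trial_projection(ses, seed = 17)
  expect_identical(p1, p2)
  expect_true(p1$spatial$applicable)
  # all-optimal session: not applicable
  ses_opt <- ses
  ses_opt$sim_labels$optimal <- TRUE
  p3 <- error_trial_projection(ses_opt, seed = 18)
  expect_false(p3$spatial$applicable)
  expect_error(error_trial_projection(list(rates_sim = ses$rates_sim[, 1:5],
                                           sim_labels = ses$sim_labels)),
               "fewer than")
})

test_that("projection battery detects a planted spatial misbinding shift only", {
  mk <- function(sd, shift) generate_population_session(
    n_neurons = 30, n_trials = 800, planted_misbinding = shift, seed = sd)
  bat <- error_projection_battery(lapply(1:12, function(i) mk(300 + i, 0.8)),
                                  seed = 19)
  expect_lt(bat$spatial$p, 0.01)
  expect_gt(bat$temporal$p, 0.05)
  expect_gt(mean(bat$spatial$diffs), 0)
})
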