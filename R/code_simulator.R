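# Explicit linear-nonlinear population codes: construction, trial encoding,
# maximum-likelihood set decoding and empirical error-rate measurement. These
# simulators are the package's independent check on the closed-form theory.

#' Build an explicit linear-nonlinear population code
#'
#' Realizes a code in an `N`-dimensional response space. A random Gaussian
#' basis is orthonormalized exactly (QR), so the `K` columns of the linear
#' transform `L` and the `n^K` columns of the conjunctive transform `M` are
#' mutually orthogonal by construction (not merely in the large-`N` limit).
#' The first column of `L` is scaled to `dLV` (value), the remaining columns
#' to `dLA` (the bound variable); every column of `M` has length
#' `m = dN/sqrt(2)`. Stimulus features are coded with centered unit-spacing
#' levels (`x - (n+1)/2`) so that the linear geometry is controlled entirely
#' by `L`.
#'
#' @param N Number of response dimensions (neurons); must be at least
#'   `K + n^K` to leave room for orthogonalization.
#' @param spec A [stimulus_spec()].
#' @param params A [code_params()].
#' @param seed Integer seed for the random basis.
#' @return An object of class `population_code` with elements `L`, `M`,
#'   `spec`, `params`, `stimuli` (lattice points), `means` (noiseless encoding
#'   of each lattice point, `n^K x N`), and `seed`.
#' @export
build_code <- function(N, spec, params, seed = 1L) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(params, "code_params"))
  ncols <- spec$K + spec$n^spec$K
  if (N < ncols) stop(sprintf("N must be >= K + n^K = %d", ncols))
  set.seed(seed)
  B <- qr.Q(qr(matrix(stats::rnorm(N * ncols), N, ncols)))
  scales_L <- c(params$dLV, rep(params$dLA, spec$K - 1))
  L <- B[, seq_len(spec$K), drop = FALSE] %*% diag(scales_L, nrow = spec$K)
  M <- B[, spec$K + seq_len(spec$n^spec$K), drop = FALSE] * params$m
  pts <- lattice_points(spec)
  xz <- pts - (spec$n + 1) / 2
  means <- xz %*% t(L) + diag(nrow(pts)) %*% t(M)  # one conjunctive column per point
  structure(list(L = L, M = M, spec = spec, params = params,
                 stimuli = pts, means = means, seed = seed),
            class = "population_code")
}

#' @export
print.population_code <- function(x, ...) {
  cat(sprintf("Linear-nonlinear population code: N = %d, K = %d, n = %d\n",
              nrow(x$L), x$spec$K, x$spec$n))
  print(x$params)
  invisible(x)
}

# index of a lattice point (row vector of features) in code$stimuli
stim_index <- function(code, x) {
  hit <- which(colSums(abs(t(code$stimuli) - as.numeric(x))) == 0)
  if (length(hit) != 1L) stop("stimulus not on the lattice")
  hit
}

# noiseless mean response to a stimulus set (matrix: one stimulus per row)
set_mean <- function(code, set) {
  idx <- apply(set, 1, function(x) stim_index(code, x))
  colSums(code$means[idx, , drop = FALSE])
}

#' Encode noisy trials for stimulus sets
#'
#' Each trial's response is the sum of the set members' noiseless encodings
#' plus isotropic Gaussian noise of standard deviation `sigma` per dimension.
#'
#' @param code A [build_code()] result.
#' @param sets Either a single set (matrix with one stimulus per row, features
#'   in columns) or a list of such sets, one per trial (recycled if length 1).
#' @param sigma Noise standard deviation (>= 0).
#' @param trials Number of trials (used when `sets` is a single set).
#' @param seed Integer seed.
#' @return A `trials x N` response matrix.
#' @export
encode_trials <- function(code, sets, sigma, trials = NULL, seed = 1L) {
  stopifnot(inherits(code, "population_code"), sigma >= 0)
  if (is.matrix(sets)) {
    mu <- matrix(set_mean(code, sets), nrow = trials %||% 1,
                 ncol = nrow(code$L), byrow = TRUE)
  } else {
    mu <- t(vapply(sets, function(s) set_mean(code, s), numeric(nrow(code$L))))
  }
  set.seed(seed)
  mu + matrix(stats::rnorm(length(mu), sd = sigma), nrow(mu), ncol(mu))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All candidate multisets of size S over the lattice: list of index vectors
candidate_multisets <- function(spec) {
  npt <- spec$n^spec$K
  combs <- utils::combn(npt + spec$S - 1, spec$S)
  # combinations with repetition via stars-and-bars shift
  lapply(seq_len(ncol(combs)), function(j) combs[, j] - seq_len(spec$S) + 1L)
}

# per-feature value multiset signature for chimera classification
feature_multiset_sig <- function(code, idx) {
  vals <- code$stimuli[idx, , drop = FALSE]
  paste(apply(vals, 2, function(col) paste(sort(col), collapse = "-")),
        collapse = "|")
}

#' Maximum-likelihood decoding of stimulus sets
#'
#' Decodes each response row to the candidate multiset of `S` stimuli whose
#' summed noiseless encoding is nearest in Euclidean distance (the ML rule for
#' isotropic Gaussian noise). Ties are broken uniformly at random under
#' `seed`. Outcomes are classified against the true set: `correct` (same
#' multiset), `misbinding` (same per-feature value multisets but different
#' pairing -- a chimera), or `other` error.
#'
#' @param code A [build_code()] result.
#' @param responses Response matrix from [encode_trials()].
#' @param S Set size.
#' @param true_sets List (or single matrix) of true stimulus sets per trial.
#' @param seed Integer seed for tie breaking.
#' @return A data.frame with columns `decoded` (candidate index), `outcome`,
#'   and `margin` (log-likelihood margin between best and runner-up, in
#'   squared-distance units).
#' @export
ml_decode_sets <- function(code, responses, S, true_sets, seed = 1L) {
  stopifnot(inherits(code, "population_code"))
  spec <- code$spec
  spec_s <- stimulus_spec(spec$K, spec$n, S)
  cands <- candidate_multisets(spec_s)
  if (length(cands) > 1e6) stop("candidate space exceeds 1e6 multisets")
  Cmu <- t(vapply(cands, function(ix) colSums(code$means[ix, , drop = FALSE]),
                  numeric(ncol(code$means))))
  # squared distances trials x candidates
  d2 <- outer(rowSums(responses^2), rowSums(Cmu^2), "+") - 2 * responses %*% t(Cmu)
  set.seed(seed)
  tie_eps <- 1e-9
  decoded <- integer(nrow(d2)); margin <- numeric(nrow(d2))
  for (i in seq_len(nrow(d2))) {
    di <- d2[i, ]
    best <- which(di <= min(di) + tie_eps)
    decoded[i] <- if (length(best) > 1L) sample(best, 1L) else best
    srt <- sort(di, partial = 2)[1:2]
    margin[i] <- srt[2] - srt[1]
  }
  if (is.matrix(true_sets)) true_sets <- rep(list(true_sets), nrow(responses))
  cand_sig <- vapply(cands, function(ix) paste(sort(ix), collapse = ","),
                     character(1))
  cand_fsig <- vapply(cands, function(ix) feature_multiset_sig(code, ix),
                      character(1))
  outcome <- character(nrow(d2))
  for (i in seq_len(nrow(d2))) {
    true_idx <- sort(apply(true_sets[[i]], 1, function(x) stim_index(code, x)))
    tsig <- paste(true_idx, collapse = ",")
    if (cand_sig[decoded[i]] == tsig) outcome[i] <- "correct"
    else if (cand_fsig[decoded[i]] ==
             feature_multiset_sig(code, true_idx)) outcome[i] <- "misbinding"
    else outcome[i] <- "other"
  }
  data.frame(decoded = decoded, outcome = outcome, margin = margin)
}

#' Empirical single-stimulus overall error rate
#'
#' Draws stimuli uniformly from the lattice, encodes noisy single-stimulus
#' trials, decodes by nearest noiseless mean, and returns the error frequency
#' with its Monte-Carlo standard error.
#'
#' @param code A [build_code()] result.
#' @param sigma Noise standard deviation.
#' @param trials Number of Monte-Carlo trials.
#' @param seed Integer seed.
#' @return List with `rate`, `se`, `trials`.
#' @export
simulate_overall_error <- function(code, sigma, trials = 1e5, seed = 1L) {
  set.seed(seed)
  npt <- nrow(code$stimuli)
  truth <- sample.int(npt, trials, replace = TRUE)
  R <- code$means[truth, , drop = FALSE] +
    matrix(stats::rnorm(trials * ncol(code$means), sd = sigma), trials)
  d2 <- outer(rowSums(R^2), rowSums(code$means^2), "+") - 2 * R %*% t(code$means)
  dec <- max.col(-d2, ties.method = "random")
  rate <- mean(dec != truth)
  list(rate = rate, se = sqrt(rate * (1 - rate) / trials), trials = trials)
}

#' Empirical misbinding error rate for stimulus sets
#'
#' Draws ordered stimulus sets of size `S` uniformly with replacement, encodes
#' noisy trials, ML-decodes among all candidate multisets, and returns the
#' frequency of misbinding outcomes (chimeric decodes) with its Monte-Carlo
#' standard error.
#'
#' @inheritParams simulate_overall_error
#' @param S Set size (default from `code$spec$S`).
#' @return List with `rate`, `se`, `trials`, and `other_rate` (non-chimeric
#'   errors).
#' @export
simulate_misbinding <- function(code, sigma, trials = 1e5, S = code$spec$S,
                                seed = 1L) {
  set.seed(seed)
  npt <- nrow(code$stimuli)
  spec_s <- stimulus_spec(code$spec$K, code$spec$n, S)
  cands <- candidate_multisets(spec_s)
  Cmu <- t(vapply(cands, function(ix) colSums(code$means[ix, , drop = FALSE]),
                  numeric(ncol(code$means))))
  cand_sig <- vapply(cands, function(ix) paste(sort(ix), collapse = ","),
                     character(1))
  cand_fsig <- vapply(cands, function(ix) feature_multiset_sig(code, ix),
                      character(1))
  truth <- matrix(sample.int(npt, trials * S, replace = TRUE), trials, S)
  if (S == 2L) {
    true_sorted <- cbind(pmin(truth[, 1], truth[, 2]), pmax(truth[, 1], truth[, 2]))
  } else {
    true_sorted <- t(apply(truth, 1, sort))
  }
  tsig <- do.call(paste, c(as.data.frame(true_sorted), sep = ","))
  # look the true multiset up among candidates so its signatures come cached
  t_cand <- match(tsig, cand_sig)
  tfsig <- cand_fsig[t_cand]
  mu <- Reduce(`+`, lapply(seq_len(S), function(s)
    code$means[truth[, s], , drop = FALSE]))
  R <- mu + matrix(stats::rnorm(trials * ncol(mu), sd = sigma), trials)
  d2 <- outer(rowSums(R^2), rowSums(Cmu^2), "+") - 2 * R %*% t(Cmu)
  dec <- max.col(-d2, ties.method = "random")
  correct <- cand_sig[dec] == tsig
  misbind <- !correct & cand_fsig[dec] == tfsig
  rate <- mean(misbind)
  list(rate = rate, se = sqrt(rate * (1 - rate) / trials),
       other_rate = mean(!correct & !misbind), trials = trials)
}

#' Empirical cross-condition generalization of the prototype decoder
#'
#' Trains the centroid-difference (prototype) decoder on the noiseless
#' centroids of the training conditions `x11` vs `x21` (value decoded at the
#' first level of the bound variable) and evaluates it on noisy trials of the
#' held-out conditions `x12` and `x22`. The decoder direction is
#' `vD = (r(x21) - r(x11))/c` with `c` the centroid separation, and the
#' decision threshold sits at `c/2` along `vD`.
#'
#' @param code A [build_code()] result (requires `K >= 2`).
#' @param sigma Noise standard deviation.
#' @param trials Number of test trials per held-out condition.
#' @param seed Integer seed.
#' @return List with `rate`, `se`, `trials`, and the signed threshold margins
#'   `d12`, `d22` of the two held-out centroids.
#' @export
prototype_ccgp <- function(code, sigma, trials = 1e5, seed = 1L) {
  spec <- code$spec
  if (spec$K < 2) stop("prototype CCGP requires K >= 2")
  i11 <- stim_index(code, c(1, 1, rep(1, spec$K - 2)))
  i21 <- stim_index(code, c(2, 1, rep(1, spec$K - 2)))
  i12 <- stim_index(code, c(1, 2, rep(1, spec$K - 2)))
  i22 <- stim_index(code, c(2, 2, rep(1, spec$K - 2)))
  diff <- code$means[i21, ] - code$means[i11, ]
  cc <- sqrt(sum(diff^2))
  vD <- diff / cc
  base <- sum(vD * code$means[i11, ])
  # signed margins of held-out centroids relative to the threshold
  d12 <- sum(vD * code$means[i12, ]) - base - cc / 2
  d22 <- sum(vD * code$means[i22, ]) - base - cc / 2
  set.seed(seed)
  z12 <- sum(vD * code$means[i12, ]) + stats::rnorm(trials, sd = sigma)
  z22 <- sum(vD * code$means[i22, ]) + stats::rnorm(trials, sd = sigma)
  thr <- base + cc / 2
  err <- c(z12 >= thr, z22 < thr)  # x12 is low-value, x22 high-value
  rate <- mean(err)
  list(rate = rate, se = sqrt(rate * (1 - rate) / (2 * trials)),
       trials = 2 * trials, d12 = d12, d22 = d22)
}

#' Theory-versus-simulation error curves
#'
#' For each grid point (`dLV = dLA = dL`, `dN`, `sigma`) builds an explicit
#' code, measures the empirical overall, misbinding and generalization error
#' rates, and tabulates them against the analytic predictions with Monte-Carlo
#' standard errors.
#'
#' @param spec A [stimulus_spec()] (with `S` for the misbinding rows).
#' @param dL_grid,dN_grid,sigma_grid Numeric grids.
#' @param trials Monte-Carlo trials per point.
#' @param N Response dimensionality for the explicit codes.
#' @param seed Integer seed.
#' @return A data.frame with columns `error_type`, `dL`, `dN`, `sigma`,
#'   `empirical`, `analytic`, `se`, `trials`, `seed`.
#' @export
simulate_error_curves <- function(spec, dL_grid, dN_grid, sigma_grid,
                                  trials = 1e5, N = 24, seed = 1L) {
  stopifnot(inherits(spec, "stimulus_spec"))
  grid <- expand.grid(dL = dL_grid, dN = dN_grid, sigma = sigma_grid)
  rows <- vector("list", nrow(grid) * 3)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    dL <- grid$dL[g]; dN <- grid$dN[g]; sg <- grid$sigma[g]
    par <- code_params(dLV = dL, dLA = dL, dN = dN, sigma = sg)
    code <- build_code(N, spec, par, seed = seed + g)
    ov <- simulate_overall_error(code, sg, trials, seed = seed + 1000L + g)
    mb <- simulate_misbinding(code, sg, trials, S = max(spec$S, 2L),
                              seed = seed + 2000L + g)
    cg <- prototype_ccgp(code, sg, trials, seed = seed + 3000L + g)
    spec_s <- stimulus_spec(spec$K, spec$n, max(spec$S, 2L))
    ana <- c(overall = overall_error_rate(par, spec),
             misbinding = binding_error_rate(par, spec_s),
             generalization = generalization_error_rate(par))
    emp <- list(overall = ov, misbinding = mb, generalization = cg)
    for (ty in names(emp)) {
      k <- k + 1L
      rows[[k]] <- data.frame(error_type = ty, dL = dL, dN = dN, sigma = sg,
                              empirical = emp[[ty]]$rate, analytic = ana[[ty]],
                              se = emp[[ty]]$se, trials = emp[[ty]]$trials,
                              seed = seed)
    }
  }
  do.call(rbind, rows)
}

#' Monte-Carlo mean squared error of the continuous two-offer decoder
#'
#' Simulates `r = A v + eta` with `A = [[1, cos(theta)], [0, sin(theta)]]` and
#' isotropic noise, decodes by `v_hat = A^{-1} r`, and returns the empirical
#' total mean squared error of `v_hat - v`, the Monte-Carlo counterpart of
#' [continuous_estimator_variance()].
#'
#' @param theta Encoding angle in radians.
#' @param sigma Noise standard deviation.
#' @param nsim Number of simulated decodes.
#' @param seed Integer seed.
#' @return List with `mse`, `se` (standard error of the MSE), `nsim`.
#' @export
simulate_continuous_mse <- function(theta, sigma, nsim = 1e5, seed = 1L) {
  if (abs(sin(theta)) < 1e-12) stop("singular encoding: sin(theta) = 0")
  A <- matrix(c(1, 0, cos(theta), sin(theta)), 2, 2)
  Ainv <- solve(A)
  set.seed(seed)
  eta <- matrix(stats::rnorm(2 * nsim, sd = sigma), 2, nsim)
  err <- Ainv %*% eta  # v_hat - v = A^{-1} eta, independent of v
  sq <- colSums(err^2)
  list(mse = mean(sq), se = stats::sd(sq) / sqrt(nsim), nsim = nsim)
}

#' Measured subspace correlation of an explicit code
#'
#' Computes the cosine similarity between the value-coding vectors at the two
#' levels of the bound variable, built directly from the code's noiseless
#' means (`v_ctx = r(x2,ctx) - r(x1,ctx)`).
#'
#' @param code A [build_code()] result with `K >= 2`, `n = 2`.
#' @return Cosine similarity (the code's realized subspace correlation).
#' @export
measured_subspace_correlation <- function(code) {
  spec <- code$spec
  if (spec$K < 2 || spec$n != 2) stop("requires K >= 2 and n = 2")
  rest <- rep(1, spec$K - 2)
  v1 <- code$means[stim_index(code, c(2, 1, rest)), ] -
    code$means[stim_index(code, c(1, 1, rest)), ]
  v2 <- code$means[stim_index(code, c(2, 2, rest)), ] -
    code$means[stim_index(code, c(1, 2, rest)), ]
  sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
}
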