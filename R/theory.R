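# Closed-form theory of linear-nonlinear population codes: distances, neighbor
# counts, union-bound error rates, subspace correlation and the continuous-case
# estimator variance. All error rates use Q(.), the standard normal CDF,
# evaluated at negative arguments; chance-level clipping is applied because the
# union bound can exceed chance at high noise.

#' Stimulus lattice specification
#'
#' Describes the discrete stimulus space of a linear-nonlinear code: `K`
#' features that each take `n` values, with `S` stimuli presented
#' simultaneously. The stimulus lattice has `n^K` points.
#'
#' @param K Number of features (positive integer).
#' @param n Number of values per feature (integer >= 2).
#' @param S Number of simultaneously presented stimuli (positive integer).
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec(K = 2, n = 2, S = 2)
#' @export
stimulus_spec <- function(K = 2L, n = 2L, S = 1L) {
  K <- as.integer(K); n <- as.integer(n); S <- as.integer(S)
  if (length(K) != 1L || is.na(K) || K < 1L) stop("K must be a positive integer")
  if (length(n) != 1L || is.na(n) || n < 2L) stop("n must be an integer >= 2")
  if (length(S) != 1L || is.na(S) || S < 1L) stop("S must be a positive integer")
  structure(list(K = K, n = n, S = S), class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("Stimulus lattice: K = %d features x n = %d values (%d points), S = %d stimuli\n",
              x$K, x$n, x$n^x$K, x$S))
  invisible(x)
}

#' Linear-nonlinear code parameters
#'
#' Bundles the geometric parameters of a linear-nonlinear code: the linear
#' distance for the value feature (`dLV`), the linear distance for the bound
#' variable -- side or presentation time -- (`dLA`), the nonlinear
#' (conjunctive) distance `dN`, the per-dimension noise standard deviation
#' `sigma`, and the standard-error distance `epsilon` contributed by
#' finite-trial centroid estimation. Each conjunctive column has length
#' `m = dN / sqrt(2)`, so that two stimuli whose conjunctive perturbations are
#' orthogonal sit at nonlinear distance `dN`.
#'
#' @param dLV,dLA,dN Non-negative distances in (z-scored) response units.
#' @param sigma Noise standard deviation per response dimension (>= 0).
#' @param epsilon Standard-error distance (>= 0), default 0.
#' @return An object of class `code_params`.
#' @examples
#' code_params(dLV = 1, dLA = 1, dN = 0.5, sigma = 0.3)
#' @export
code_params <- function(dLV = 1, dLA = dLV, dN = 0, sigma = 0.5, epsilon = 0) {
  vals <- c(dLV = dLV, dLA = dLA, dN = dN, sigma = sigma, epsilon = epsilon)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all code parameters must be finite and >= 0")
  structure(list(dLV = dLV, dLA = dLA, dN = dN, sigma = sigma,
                 epsilon = epsilon, m = dN / sqrt(2)),
            class = "code_params")
}

#' @export
print.code_params <- function(x, ...) {
  cat(sprintf("Code parameters: dLV = %.4g, dLA = %.4g, dN = %.4g, sigma = %.4g, epsilon = %.4g\n",
              x$dLV, x$dLA, x$dN, x$sigma, x$epsilon))
  invisible(x)
}

# Standard normal CDF, written as Q(.) in the error-rate formulas.
qfun <- function(z) stats::pnorm(z)

#' Linear distance from linear power
#'
#' For a uniformly sampled K-dimensional lattice with `n` points per dimension
#' spaced `dL` apart, the variance (linear power) is
#' `PL = K * dL^2 * (n^2 - 1) / 12`. This function inverts that relation:
#' `dL = sqrt(12 * PL / (K * (n^2 - 1)))`.
#'
#' @param PL Linear power (variance units), >= 0.
#' @param spec A [stimulus_spec()].
#' @return The adjacent-stimulus linear distance `dL`.
#' @seealso [power_from_linear_distance()]
#' @export
linear_distance_from_power <- function(PL, spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (any(PL < 0)) stop("PL must be >= 0")
  if (spec$n < 2) stop("invalid spec: n must be >= 2")
  sqrt(12 * PL / (spec$K * (spec$n^2 - 1)))
}

#' Linear power from linear distance
#'
#' Inverse of [linear_distance_from_power()]:
#' `PL = K * dL^2 * (n^2 - 1) / 12`.
#'
#' @param dL Adjacent-stimulus linear distance, >= 0.
#' @param spec A [stimulus_spec()].
#' @return The linear power `PL`.
#' @export
power_from_linear_distance <- function(dL, spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (any(dL < 0)) stop("dL must be >= 0")
  spec$K * dL^2 * (spec$n^2 - 1) / 12
}

#' Nonlinear power from nonlinear distance
#'
#' The nonlinear distance relates to nonlinear power as `dN = 2 * sqrt(PN)`,
#' i.e. `PN = dN^2 / 4`.
#'
#' @param dN Nonlinear distance (>= 0).
#' @return Nonlinear power `PN`.
#' @export
power_from_nonlinear_distance <- function(dN) {
  if (any(dN < 0)) stop("dN must be >= 0")
  dN^2 / 4
}

#' @rdname power_from_nonlinear_distance
#' @param PN Nonlinear power (>= 0).
#' @export
nonlinear_distance_from_power <- function(PN) {
  if (any(PN < 0)) stop("PN must be >= 0")
  2 * sqrt(PN)
}

# All lattice points as an (n^K x K) integer matrix with levels 1..n.
lattice_points <- function(spec) {
  as.matrix(expand.grid(rep(list(seq_len(spec$n)), spec$K)))
}

# memoised cache for enumeration results
.theory_cache <- new.env(parent = emptyenv())

#' Exact lattice neighbor counts
#'
#' Average numbers of nearest lattice neighbors (`NLA`, one feature differs by
#' one step), nearest diagonal neighbors (`NLD`, two features each differ by
#' one step), and nonlinear-part neighbors (`NNL = n^K - 1`; every other
#' stimulus sits at the minimum nonlinear distance because the conjunctive
#' perturbations are mutually orthogonal). The combined-code neighbor counts
#' are `NC = NLA` and `NCplus1 = NLD`. Computed by exhaustive enumeration of
#' the lattice (results cached per `(K, n)`).
#'
#' @param spec A [stimulus_spec()].
#' @return A list with `NLA`, `NLD`, `NNL`, `NC`, `NCplus1`.
#' @examples
#' neighbor_counts(stimulus_spec(K = 2, n = 2))  # NLA = 2, NLD = 1, NNL = 3
#' @export
neighbor_counts <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  key <- sprintf("nb_%d_%d", spec$K, spec$n)
  if (!is.null(.theory_cache[[key]])) return(.theory_cache[[key]])
  pts <- lattice_points(spec)
  npt <- nrow(pts)
  nla <- 0; nld <- 0
  for (i in seq_len(npt)) {
    diffs <- abs(sweep(pts, 2, pts[i, ], "-"))
    one_step <- diffs == 1L
    changed <- diffs > 0L
    n_changed <- rowSums(changed)
    all_one <- rowSums(one_step) == n_changed
    nla <- nla + sum(n_changed == 1L & all_one)
    nld <- nld + sum(n_changed == 2L & all_one)
  }
  out <- list(NLA = nla / npt, NLD = nld / npt, NNL = npt - 1,
              NC = nla / npt, NCplus1 = nld / npt)
  .theory_cache[[key]] <- out
  out
}

#' Combined code distances
#'
#' Distances between stimulus representations in a code with linear adjacent
#' distance `dL` and nonlinear distance `dN`. With orthogonal linear and
#' nonlinear parts the nearest combined distance is `dC = sqrt(dL^2 + dN^2)`
#' and the next-nearest (diagonal) distance is `dCplus1 = sqrt(2*dL^2 + dN^2)`.
#' Without the orthogonality constraint the distances acquire a random cross
#' term `2*dN*dL*eta` (resp. `sqrt(8)*dN*dL*eta`) under the square root, with
#' `eta ~ N(0, 1/N)`; in that case the returned `dC`/`dCplus1` are the central
#' values and the cross-term standard deviations are reported alongside.
#'
#' The chimeric-set distance `dS` is computed from explicitly constructed
#' conjunctive columns: four orthogonal columns of length `m = dN/sqrt(2)`
#' give `dS = |M1 + M2 - M3 - M4| = 2*m = sqrt(2)*dN`.
#'
#' @param params A [code_params()]; `dL` is taken from `dLV` unless given.
#' @param orthogonal If `TRUE` (default) the linear and nonlinear parts are
#'   exactly orthogonal.
#' @param dL Adjacent linear distance; defaults to `params$dLV`.
#' @param N Population size used for the non-orthogonal cross-term variance.
#' @return A list with `dC`, `dCplus1`, `dS`, and (if `orthogonal = FALSE`)
#'   `cross_sd_dC2`, `cross_sd_dCplus12`, the standard deviations of the random
#'   cross terms added to the squared distances.
#' @export
code_distances <- function(params, orthogonal = TRUE, dL = params$dLV, N = NULL) {
  stopifnot(inherits(params, "code_params"))
  dN <- params$dN
  m <- dN / sqrt(2)
  # explicit construction: four orthonormal directions scaled to length m
  M <- diag(4) * m
  dS <- sqrt(sum((M[, 1] + M[, 2] - M[, 3] - M[, 4])^2))
  out <- list(dC = sqrt(dL^2 + dN^2), dCplus1 = sqrt(2 * dL^2 + dN^2), dS = dS)
  if (!orthogonal) {
    if (is.null(N) || N < 1) stop("N must be supplied for the non-orthogonal case")
    out$cross_sd_dC2 <- 2 * dN * dL / sqrt(N)
    out$cross_sd_dCplus12 <- sqrt(8) * dN * dL / sqrt(N)
  }
  out
}

#' Overall error rate of a linear-nonlinear code
#'
#' Nearest-neighbor union bound on the probability that a maximum-likelihood
#' decoder reports the wrong stimulus:
#' `P(error) = NC * Q(-dC/(2*sigma)) + NCplus1 * Q(-dCplus1/(2*sigma))`,
#' clipped to `[0, 1 - 1/n^K]` (the union bound can exceed chance at high
#' noise). When `dLV != dLA` (supported for `K = 2`) the bound is evaluated
#' per axis: one neighbor at `sqrt(dLV^2 + dN^2)`, one at
#' `sqrt(dLA^2 + dN^2)`, and the diagonal neighbor at
#' `sqrt(dLV^2 + dLA^2 + dN^2)`; this reduces exactly to the printed
#' single-`dL` form when the two linear distances agree.
#'
#' @param params A [code_params()] with `sigma > 0`.
#' @param spec A [stimulus_spec()].
#' @return Error probability in `[0, 1 - 1/n^K]`.
#' @export
overall_error_rate <- function(params, spec) {
  stopifnot(inherits(params, "code_params"), inherits(spec, "stimulus_spec"))
  if (params$sigma <= 0) stop("sigma must be > 0")
  nb <- neighbor_counts(spec)
  s <- params$sigma
  dN <- params$dN
  chance <- 1 - 1 / spec$n^spec$K
  if (isTRUE(all.equal(params$dLV, params$dLA))) {
    dd <- code_distances(params, dL = params$dLV)
    p <- nb$NC * qfun(-dd$dC / (2 * s)) + nb$NCplus1 * qfun(-dd$dCplus1 / (2 * s))
  } else if (spec$K == 2L) {
    dV <- sqrt(params$dLV^2 + dN^2)
    dA <- sqrt(params$dLA^2 + dN^2)
    dDiag <- sqrt(params$dLV^2 + params$dLA^2 + dN^2)
    # NC splits evenly across the two axes on the symmetric lattice
    p <- (nb$NC / 2) * (qfun(-dV / (2 * s)) + qfun(-dA / (2 * s))) +
      nb$NCplus1 * qfun(-dDiag / (2 * s))
  } else {
    stop("dLV != dLA is only supported for K = 2")
  }
  min(max(p, 0), chance)
}

#' Average number of chimeric stimulus sets
#'
#' For a stimulus set of `S` ordered draws (with replacement) from the lattice,
#' a chimeric set is a *different* multiset of stimuli whose purely-linear mean
#' response is identical (same coordinate-wise feature sums) -- the sets a
#' purely factorized code cannot tell apart. `NS` is the average number of
#' such chimeras over all ordered stimulus sets, computed by exhaustive
#' enumeration.
#'
#' @param spec A [stimulus_spec()] with `S >= 2`.
#' @return The mean chimera count `NS` (e.g. 0.25 for `K = n = S = 2`).
#' @export
chimeric_set_count <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$S < 2) stop("chimeric sets require S >= 2")
  key <- sprintf("ns_%d_%d_%d", spec$K, spec$n, spec$S)
  if (!is.null(.theory_cache[[key]])) return(.theory_cache[[key]])
  npt <- spec$n^spec$K
  n_tuples <- npt^spec$S
  if (n_tuples > 250000) stop("enumeration size cap exceeded: (n^K)^S > 250000")
  pts <- lattice_points(spec)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(npt)), spec$S)))
  # multiset id: sorted point indices; linear signature: summed coordinates
  ms_id <- apply(tuples, 1, function(ix) paste(sort(ix), collapse = ","))
  sums <- matrix(0, nrow(tuples), spec$K)
  for (s in seq_len(spec$S)) sums <- sums + pts[tuples[, s], , drop = FALSE]
  sig <- apply(sums, 1, paste, collapse = ",")
  # distinct multisets per signature
  ms_sig <- tapply(sig, ms_id, `[`, 1)
  sig_counts <- table(ms_sig)
  chim_per_ms <- as.numeric(sig_counts[ms_sig]) - 1
  names(chim_per_ms) <- names(ms_sig)
  ns <- mean(chim_per_ms[ms_id])
  .theory_cache[[key]] <- ns
  ns
}

#' Misbinding (chimeric) error rate
#'
#' Union-bound rate at which a maximum-likelihood decoder reports a chimeric
#' stimulus set -- correct feature values bound to the wrong partners:
#' `P(binding error) = NS * Q(-dS/(2*sigma))` with `dS = sqrt(2)*dN` from
#' [code_distances()]. The rate depends only on the nonlinear distance and the
#' noise, not on `dLV` or `dLA`; at `dN = 0` it equals the chance level
#' `NS/2`.
#'
#' @param params A [code_params()] with `sigma > 0`.
#' @param spec A [stimulus_spec()] with `S >= 2`.
#' @return Misbinding probability.
#' @export
binding_error_rate <- function(params, spec) {
  stopifnot(inherits(params, "code_params"), inherits(spec, "stimulus_spec"))
  if (params$sigma <= 0) stop("sigma must be > 0")
  if (spec$S < 2) stop("binding errors require S >= 2")
  ns <- chimeric_set_count(spec)
  ds <- code_distances(params)$dS
  p <- ns * qfun(-ds / (2 * params$sigma))
  min(max(p, 0), 1)
}

#' Cross-condition generalization (CCGP) error rate
#'
#' Error rate of a prototype decoder trained on one context's value conditions
#' and tested on the other context's:
#' `P(CCGP error) = Q(-(1/sigma) * dLV^2 / (2 * sqrt(dLV^2 + dNeps^2)))`
#' where `dNeps = sqrt(dN^2 + epsilon^2)` combines the reliable conjunctive
#' distance with the unreliable standard-error distance. The rate is
#' independent of `dLA`, decreasing in `dLV`, and increasing in `dN` and
#' `epsilon`. Degenerate `dLV = 0` (including `dLV = dN = epsilon = 0`)
#' returns chance, 0.5.
#'
#' @param params A [code_params()] with `sigma > 0`.
#' @return Generalization error probability in `[0, 0.5]`.
#' @export
generalization_error_rate <- function(params) {
  stopifnot(inherits(params, "code_params"))
  if (params$sigma <= 0) stop("sigma must be > 0")
  dLV <- params$dLV
  if (dLV == 0) return(0.5)
  dNe <- sqrt(params$dN^2 + params$epsilon^2)
  qfun(-(1 / params$sigma) * 0.5 * dLV^2 / sqrt(dLV^2 + dNe^2))
}

#' Subspace correlation from linear and nonlinear distances
#'
#' The cosine similarity between the value-coding vectors of two contexts
#' (e.g. left and right offers) in a linear-nonlinear code:
#' `rho = dLV^2 / (dLV^2 + dN^2)`. `rho = 1` means fully shared (parallel)
#' value coding; `rho = 0` means orthogonal coding.
#'
#' @param dLV Linear value distance (>= 0).
#' @param dN Nonlinear distance (>= 0).
#' @return Correlation in `[0, 1]`.
#' @export
subspace_correlation_from_distances <- function(dLV, dN) {
  if (dLV < 0 || dN < 0) stop("distances must be >= 0")
  if (dLV == 0 && dN == 0) stop("subspace correlation undefined when dLV = dN = 0")
  dLV^2 / (dLV^2 + dN^2)
}

#' Estimator variance for a continuous two-offer code
#'
#' For two offer values encoded linearly as `r = A v + eta` with encoding
#' matrix `A = [[1, cos(theta)], [0, sin(theta)]]` (columns at angle `theta`,
#' subspace correlation `cos(theta)`) and isotropic noise `eta ~ N(0, sigma^2)`,
#' the total variance of the least-squares estimate `v_hat = A^{-1} r` is
#' `Var(v_hat - v) = 2 * sigma^2 / sin(theta)^2`: recovery degrades without
#' bound as the two value subspaces become parallel.
#'
#' @param theta Angle between encoding vectors in radians; `sin(theta)` must be
#'   nonzero.
#' @param sigma Noise standard deviation.
#' @return Total mean squared error of the decoded value pair.
#' @export
continuous_estimator_variance <- function(theta, sigma) {
  s2 <- sin(theta)^2
  if (s2 < .Machine$double.eps) stop("singular encoding: sin(theta) = 0, A has no inverse")
  2 * sigma^2 / s2
}

#' Power-tradeoff curves at fixed total power
#'
#' Sweeps the split of a fixed total power `P = PL + PNL` between the linear
#' and nonlinear parts of a code and reports, for each split, the implied
#' distances, the subspace correlation, and the predicted misbinding and
#' generalization error rates. Linear power is allocated to the value feature
#' (the bound variable's linear distance does not enter either rate).
#'
#' @param P Total power (> 0).
#' @param sigma Noise standard deviation (> 0).
#' @param spec A [stimulus_spec()]; `S >= 2` is required for the binding rate.
#' @param epsilon Standard-error distance, default 0.
#' @param fractions Linear-power fractions to sweep (default 0 to 1 in 0.02
#'   steps; endpoints handled by the degenerate-case conventions).
#' @return A data.frame with columns `frac_linear`, `PL`, `PNL`, `dLV`, `dN`,
#'   `rho`, `binding`, `generalization`.
#' @export
power_tradeoff_curve <- function(P, sigma, spec = stimulus_spec(2, 2, 2),
                                 epsilon = 0, fractions = seq(0, 1, by = 0.02)) {
  stopifnot(P > 0, sigma > 0)
  rows <- lapply(fractions, function(f) {
    PL <- f * P; PNL <- (1 - f) * P
    dLV <- linear_distance_from_power(PL, spec)
    dN <- nonlinear_distance_from_power(PNL)
    par <- code_params(dLV = dLV, dLA = dLV, dN = dN, sigma = sigma,
                       epsilon = epsilon)
    rho <- if (dLV == 0 && dN == 0) NA_real_ else
      subspace_correlation_from_distances(dLV, dN)
    data.frame(frac_linear = f, PL = PL, PNL = PNL, dLV = dLV, dN = dN,
               rho = rho,
               binding = binding_error_rate(par, spec),
               generalization = generalization_error_rate(par))
  })
  do.call(rbind, rows)
}
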