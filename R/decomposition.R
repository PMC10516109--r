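# Unbiased pairwise condition distances (crossnobis), decomposition of the
# distance matrix into linear and nonlinear components by non-negative least
# squares, noise and standard-error estimation, predicted error rates, and
# the eight-condition misbinding distance contrasts.

#' Cross-validated (crossnobis) squared distances between conditions
#'
#' For every unordered pair of conditions, the squared distance is estimated
#' as the average over fold pairs of the inner product of fold-wise mean
#' differences. Because the two factors come from independent data folds the
#' estimator is unbiased: its expectation is the true squared distance
#' between condition means, and single estimates can legitimately be
#' negative. No noise-whitening is applied.
#'
#' @param rates Trials x neurons rate matrix.
#' @param conditions Condition label per trial.
#' @param n_folds Number of folds (>= 2), assigned stratified within
#'   condition.
#' @param seed Integer seed for fold assignment.
#' @param fold Optional explicit fold assignment per trial (overrides the
#'   seeded stratified assignment); used by bootstrap wrappers so resampled
#'   duplicates never cross folds, which would break the estimator's
#'   cross-fold independence.
#' @return An object of class `crossnobis_rdm`: list with `dist2` (symmetric
#'   condition x condition matrix of squared distances, zero diagonal),
#'   `conditions`, `n_folds`.
#' @export
crossnobis_rdm <- function(rates, conditions, n_folds = 5, seed = 1L,
                           fold = NULL) {
  rates <- as.matrix(rates)
  conditions <- as.character(conditions)
  if (n_folds < 2) stop("need at least 2 folds")
  levs <- sort(unique(conditions))
  counts <- table(conditions)
  if (any(counts < 2 * n_folds)) {
    short <- names(counts)[which.min(counts)]
    stop(sprintf("condition '%s' has too few trials for %d folds (need >= 2 per fold)",
                 short, n_folds))
  }
  if (is.null(fold)) {
    set.seed(seed)
    fold <- integer(nrow(rates))
    for (cl in levs) {
      ix <- which(conditions == cl)
      fold[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
    }
  } else if (length(fold) != nrow(rates)) stop("fold length mismatch")
  # fold x condition mean responses
  means <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    sel <- fold == f
    means[[f]] <- rowsum(rates[sel, , drop = FALSE], conditions[sel]) /
      as.vector(table(conditions[sel])[levs])
  }
  nc <- length(levs)
  D <- matrix(0, nc, nc, dimnames = list(levs, levs))
  fp <- utils::combn(n_folds, 2)
  for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
    vals <- vapply(seq_len(ncol(fp)), function(k) {
      d1 <- means[[fp[1, k]]][a, ] - means[[fp[1, k]]][b, ]
      d2 <- means[[fp[2, k]]][a, ] - means[[fp[2, k]]][b, ]
      sum(d1 * d2)
    }, numeric(1))
    D[a, b] <- D[b, a] <- mean(vals)
  }
  structure(list(dist2 = D, conditions = levs, n_folds = n_folds),
            class = "crossnobis_rdm")
}

#' Decompose a 4-condition RDM into linear and nonlinear distances
#'
#' Solves `d_empirical = A d_est` by non-negative least squares, where
#' `d_empirical` is the 6-vector of squared crossnobis distances among the
#' four value x context conditions and the unknowns are
#' `(dLV^2, dLA^2, m^2)` with `m` the per-condition conjunctive perturbation
#' length. Each row of the 6 x 3 design gives the integer multiples for a
#' condition pair: value-only pairs are `[1 0 2]`, context-only pairs
#' `[0 1 2]`, and both-differ (diagonal) pairs `[1 1 2]` -- any two
#' conditions' conjunctive parts differ by two orthogonal length-`m` vectors.
#' The reported nonlinear distance is `dN = sqrt(2) * m`, matching the
#' theory's definition.
#'
#' @param rdm A [crossnobis_rdm()] over exactly 4 conditions.
#' @param value_of Named vector mapping condition label to its value level.
#' @param context_of Named vector mapping condition label to its context
#'   (side or time) level.
#' @return An object of class `rdm_decomposition`: list with `dLV`, `dLA`,
#'   `dN`, the squared estimates `est2 = c(dLV2, dLA2, m2)`, `residual`
#'   (sum of squared residuals), `A`, `d_empirical`.
#' @export
decompose_rdm <- function(rdm, value_of, context_of) {
  stopifnot(inherits(rdm, "crossnobis_rdm"))
  levs <- rdm$conditions
  if (length(levs) != 4) stop("decomposition requires exactly 4 conditions")
  if (!all(levs %in% names(value_of)) || !all(levs %in% names(context_of)))
    stop("value_of / context_of must name every condition")
  pairs <- utils::combn(4, 2)
  A <- t(apply(pairs, 2, function(pq) {
    dv <- value_of[levs[pq[1]]] != value_of[levs[pq[2]]]
    dc <- context_of[levs[pq[1]]] != context_of[levs[pq[2]]]
    c(as.numeric(dv), as.numeric(dc), 2)
  }))
  colnames(A) <- c("dLV2", "dLA2", "m2")
  d_emp <- apply(pairs, 2, function(pq) rdm$dist2[pq[1], pq[2]])
  sol <- pracma::lsqnonneg(A, d_emp)
  est2 <- sol$x
  names(est2) <- colnames(A)
  structure(list(dLV = sqrt(est2[["dLV2"]]), dLA = sqrt(est2[["dLA2"]]),
                 dN = sqrt(2 * est2[["m2"]]), est2 = est2,
                 residual = sol$resid.norm, A = A, d_empirical = d_emp),
            class = "rdm_decomposition")
}

#' @export
print.rdm_decomposition <- function(x, ...) {
  cat(sprintf("RDM decomposition: dLV = %.4g, dLA = %.4g, dN = %.4g (residual %.3g)\n",
              x$dLV, x$dLA, x$dN, x$residual))
  invisible(x)
}

#' Estimate noise and standard-error distance along the decoding direction
#'
#' The decoding direction is the difference of the two training-condition
#' centroids. `sigma_hat` is the standard deviation of single-trial residual
#' projections onto that unit direction, pooled across all conditions.
#' `epsilon_hat` is the standard-error distance: the expected *length* of the
#' centroid-estimation error vector, which perturbs the code geometry the
#' same way the conjunctive distances do (it enters the generalization rate
#' through `dNeps^2 = dN^2 + epsilon^2`). Per training centroid the expected
#' squared error length is the total residual variance (trace of the
#' residual covariance) divided by the per-condition trial count;
#' `epsilon_hat^2` sums this over the two training centroids, so for
#' isotropic noise `epsilon_hat^2 ~ 2 N sigma^2 / n` and doubling the trial
#' count halves it.
#'
#' @param rates Trials x neurons rate matrix.
#' @param conditions Condition label per trial.
#' @param train_pair Length-2 character vector naming the two training
#'   conditions that define the decoding direction.
#' @return List with `sigma_hat`, `epsilon_hat`, `direction` (unit vector).
#' @export
estimate_noise_and_sem <- function(rates, conditions, train_pair) {
  rates <- as.matrix(rates)
  conditions <- as.character(conditions)
  if (length(train_pair) != 2 || !all(train_pair %in% conditions))
    stop("train_pair must name two present conditions")
  counts <- table(conditions)
  if (any(counts < 2)) stop("every condition needs at least 2 trials")
  levs <- names(counts)
  cents <- rowsum(rates, conditions) / as.vector(counts[sort(unique(conditions))])
  v <- cents[train_pair[2], ] - cents[train_pair[1], ]
  v <- v / sqrt(sum(v^2))
  proj <- as.vector(rates %*% v)
  cent_proj <- as.vector(cents %*% v)
  names(cent_proj) <- rownames(cents)
  resid <- proj - cent_proj[conditions]
  # pooled residual variance along the direction
  sigma2 <- sum(resid^2) / (length(resid) - length(levs))
  # total residual variance (all dimensions) per training condition
  full_resid <- rates - cents[conditions, , drop = FALSE]
  tr_var <- vapply(train_pair, function(cl) {
    sel <- conditions == cl
    sum(full_resid[sel, ]^2) / (sum(sel) - 1)
  }, numeric(1))
  eps2 <- sum(tr_var / counts[train_pair])
  list(sigma_hat = sqrt(sigma2), epsilon_hat = sqrt(eps2), direction = v)
}

#' Full session decomposition with bootstrap uncertainty
#'
#' Runs [crossnobis_rdm()] + [decompose_rdm()] + [estimate_noise_and_sem()]
#' on a trials x neurons table with value-level and context labels, and
#' attaches a trial-resampling bootstrap distribution (stratified within
#' condition) of all estimates.
#'
#' @param rates Trials x neurons rate matrix.
#' @param value Value level per trial (two levels).
#' @param context Context (side or time) level per trial (two levels).
#' @param n_folds Crossnobis folds (default 5).
#' @param n_boot Bootstrap resamples (default 1000; 0 disables).
#' @param seed Integer seed.
#' @return List with `decomp` ([decompose_rdm()] result), `sigma_hat`,
#'   `epsilon_hat`, `rdm`, `boot` (n_boot x 3 matrix of `dLV`, `dLA`, `dN`),
#'   `ci` (2.5/97.5% quantiles), `p_positive` (one-sided bootstrap p that
#'   each squared component is > 0).
#' @export
decompose_session <- function(rates, value, context, n_folds = 5,
                              n_boot = 1000, seed = 1L) {
  rates <- as.matrix(rates)
  cond <- paste(value, context, sep = ":")
  levs <- sort(unique(cond))
  if (length(levs) != 4) stop("need exactly 4 value x context conditions")
  value_of <- stats::setNames(sub(":.*", "", levs), levs)
  context_of <- stats::setNames(sub(".*:", "", levs), levs)
  vlev <- sort(unique(as.character(value)))
  clev <- sort(unique(as.character(context)))
  train_pair <- paste(vlev, clev[1], sep = ":")

  # fixed fold assignment; bootstrap resamples within condition x fold cells
  set.seed(seed)
  fold <- integer(nrow(rates))
  for (cl in levs) {
    ix <- which(cond == cl)
    fold[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
  }
  run <- function(ix) {
    rdm <- crossnobis_rdm(rates[ix, , drop = FALSE], cond[ix], n_folds,
                          fold = fold[ix])
    dec <- decompose_rdm(rdm, value_of, context_of)
    ns <- estimate_noise_and_sem(rates[ix, , drop = FALSE], cond[ix], train_pair)
    list(dec = dec, ns = ns, rdm = rdm)
  }
  full <- run(seq_len(nrow(rates)))
  boot <- NULL; ci <- NULL; p_positive <- NULL
  if (n_boot > 0) {
    set.seed(seed + 1L)
    strata <- paste(cond, fold)
    boot2 <- matrix(NA_real_, n_boot, 3,
                    dimnames = list(NULL, c("dLV2", "dLA2", "m2")))
    for (b in seq_len(n_boot)) {
      ix <- stratified_boot(strata)
      boot2[b, ] <- run(ix)$dec$est2
    }
    boot <- cbind(dLV = sqrt(boot2[, "dLV2"]), dLA = sqrt(boot2[, "dLA2"]),
                  dN = sqrt(2 * boot2[, "m2"]))
    ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
    p_positive <- (colSums(boot2 <= 0) + 1) / (n_boot + 1)
    names(p_positive) <- c("dLV2", "dLA2", "m2")
  }
  list(decomp = full$dec, sigma_hat = full$ns$sigma_hat,
       epsilon_hat = full$ns$epsilon_hat, rdm = full$rdm,
       boot = boot, ci = ci, p_positive = p_positive)
}

#' Predicted error rates from an estimated decomposition
#'
#' Plugs the estimated distances, noise and standard-error distance into the
#' closed-form theory: the misbinding rate depends on `dN` and `sigma`
#' (chance when `m^2 = 0`), the generalization rate on `dLV`, `dN`,
#' `epsilon` and `sigma`, and the subspace correlation is
#' `dLV^2/(dLV^2 + dN^2)`. A fixed-total-power tradeoff curve
#' ([power_tradeoff_curve()], with total power `PL(dLV) + PN(dN)` on the
#' symmetric 2 x 2 code) is attached.
#'
#' @param decomp An [decompose_rdm()] result (or the `decomp` element of
#'   [decompose_session()]).
#' @param sigma Estimated noise standard deviation (> 0).
#' @param epsilon Estimated standard-error distance (default 0).
#' @param spec A [stimulus_spec()] (default 2 features x 2 values, 2 stimuli).
#' @return List with `binding`, `generalization`, `rho`, `chance_binding`,
#'   and `tradeoff` (data.frame).
#' @export
predicted_error_rates <- function(decomp, sigma, epsilon = 0,
                                  spec = stimulus_spec(2, 2, 2)) {
  stopifnot(inherits(decomp, "rdm_decomposition"))
  if (sigma <= 0) stop("sigma must be > 0")
  par <- code_params(dLV = decomp$dLV, dLA = decomp$dLA, dN = decomp$dN,
                     sigma = sigma, epsilon = epsilon)
  binding <- binding_error_rate(par, spec)
  chance_binding <- chimeric_set_count(spec) / 2
  P <- power_from_linear_distance(decomp$dLV, spec) +
    power_from_nonlinear_distance(decomp$dN)
  tradeoff <- if (P > 0)
    power_tradeoff_curve(P, sigma, spec, epsilon = epsilon) else NULL
  list(binding = binding,
       generalization = generalization_error_rate(par),
       rho = if (decomp$dLV == 0 && decomp$dN == 0) NA_real_ else
         subspace_correlation_from_distances(decomp$dLV, decomp$dN),
       chance_binding = chance_binding, tradeoff = tradeoff)
}

# map the mixed (one-high-one-low) conditions of a simultaneous-window
# session to (side of high offer, time of high offer)
high_offer_cells <- function(sim_labels) {
  mixed <- sim_labels$v_left != sim_labels$v_right
  side_high <- ifelse(sim_labels$v_left == 1, "L", "R")
  first_side <- ifelse(sim_labels$order == "left-first", "L", "R")
  time_high <- ifelse(side_high == first_side, 1L, 2L)
  data.frame(mixed = mixed, side_high = side_high, time_high = time_high)
}

#' Misbinding distance contrasts over the eight order x value conditions
#'
#' From a simultaneous-window response matrix labeled with the eight
#' order x value conditions, computes the crossnobis distances between
#' condition pairs whose confusion would constitute a temporal misbinding
#' (high offer on the same side, different presentation time), a spatial
#' misbinding (same time, different side), or a spatio-temporal misbinding
#' (both differ), plus the low-low and high-high ambiguity distances (the
#' same-values conditions across the two orders). Each contrast is the mean
#' squared crossnobis distance over its pairs, with a stratified
#' trial-resampling bootstrap CI and a one-sided bootstrap p-value against
#' zero.
#'
#' @param rates_sim Trials x neurons matrix for the simultaneous window.
#' @param sim_labels Data.frame with columns `v_left`, `v_right` (0/1) and
#'   `order` (`"left-first"`/`"right-first"`), as produced by
#'   [generate_population_session()].
#' @param n_folds Crossnobis folds (default 5).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Data.frame with one row per contrast (`temporal`, `spatial`,
#'   `spatio-temporal`, `low-low`, `high-high`): `dist2`, `ci_lo`, `ci_hi`,
#'   `p_vs_zero`.
#' @export
misbinding_distance_contrasts <- function(rates_sim, sim_labels, n_folds = 5,
                                          n_boot = 1000, seed = 1L) {
  rates_sim <- as.matrix(rates_sim)
  cond <- sim_labels$cond8 %||% paste0(sim_labels$v_left, sim_labels$v_right,
                                       ":", sim_labels$order)
  if (length(unique(cond)) != 8)
    stop(sprintf("expected 8 conditions, found %d", length(unique(cond))))
  cells <- high_offer_cells(sim_labels)

  # representative condition label for each (side_high, time_high) cell and
  # for the same-value cells
  cell_label <- function(sel) unique(cond[sel])[1]
  mixed_lab <- matrix(NA_character_, 2, 2, dimnames = list(c("L", "R"), 1:2))
  for (s in c("L", "R")) for (tm in 1:2) {
    sel <- cells$mixed & cells$side_high == s & cells$time_high == tm
    if (!any(sel)) stop(sprintf("missing condition: high %s at time %d", s, tm))
    mixed_lab[s, as.character(tm)] <- cell_label(sel)
  }
  low_lab <- sapply(c("left-first", "right-first"), function(o)
    cell_label(sim_labels$v_left == 0 & sim_labels$v_right == 0 &
                 sim_labels$order == o))
  high_lab <- sapply(c("left-first", "right-first"), function(o)
    cell_label(sim_labels$v_left == 1 & sim_labels$v_right == 1 &
                 sim_labels$order == o))

  contrast_pairs <- list(
    temporal = list(c(mixed_lab["L", 1], mixed_lab["L", 2]),
                    c(mixed_lab["R", 1], mixed_lab["R", 2])),
    spatial = list(c(mixed_lab["L", 1], mixed_lab["R", 1]),
                   c(mixed_lab["L", 2], mixed_lab["R", 2])),
    `spatio-temporal` = list(c(mixed_lab["L", 1], mixed_lab["R", 2]),
                             c(mixed_lab["L", 2], mixed_lab["R", 1])),
    `low-low` = list(unname(low_lab)),
    `high-high` = list(unname(high_lab)))

  set.seed(seed)
  fold <- integer(length(cond))
  for (cl in unique(cond)) {
    ix <- which(cond == cl)
    fold[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
  }
  eval_contrasts <- function(ix) {
    rdm <- crossnobis_rdm(rates_sim[ix, , drop = FALSE], cond[ix],
                          n_folds, fold = fold[ix])
    vapply(contrast_pairs, function(prs)
      mean(vapply(prs, function(pq) rdm$dist2[pq[1], pq[2]], numeric(1))),
      numeric(1))
  }
  obs <- eval_contrasts(seq_along(cond))
  set.seed(seed + 1L)
  strata <- paste(cond, fold)
  boot <- matrix(NA_real_, n_boot, length(obs),
                 dimnames = list(NULL, names(obs)))
  for (b in seq_len(n_boot))
    boot[b, ] <- eval_contrasts(stratified_boot(strata))
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  p0 <- (colSums(boot <= 0) + 1) / (n_boot + 1)
  data.frame(contrast = names(obs), dist2 = unname(obs),
             ci_lo = ci[1, ], ci_hi = ci[2, ], p_vs_zero = unname(p0),
             row.names = NULL)
}
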