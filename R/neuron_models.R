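# Per-neuron encoding models on trial x neuron rate tables: noise / linear /
# interaction OLS fits on identical trials, stacking-based model comparison
# via exact leave-one-out predictive densities, permutation-ANOVA selectivity,
# and per-neuron subspace contribution scores.

# design matrices for the three nested models; value is min-max normalized,
# side is effects-coded -1/+1
neuron_designs <- function(value, side) {
  n <- length(value)
  list(noise = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
       linear = cbind("(Intercept)" = 1, value = value, side = side),
       interaction = cbind("(Intercept)" = 1, value = value, side = side,
                           "value:side" = value * side))
}

#' Fit the three per-neuron encoding models
#'
#' Ordinary least squares fits of the noise (intercept only), linear
#' (value + side) and interaction (value + side + value x side) models on
#' identical trials, for every neuron at once. Value is min-max normalized to
#' `[0, 1]`; side is effects-coded -1/+1 (+1 = left).
#'
#' @param rates Trials x neurons firing-rate matrix (z-scored per neuron for
#'   task-faithful input; any numeric matrix is accepted).
#' @param value Numeric vector of trial values.
#' @param side Numeric vector of -1/+1 trial sides.
#' @return An object of class `neuron_fits`: list with per-model `coef`
#'   (coefficients x neurons), `rss`, `df_residual`, `hat` (leverages),
#'   `resid`, plus `n_trials`, `n_neurons`.
#' @export
fit_neuron_models <- function(rates, value, side) {
  rates <- as.matrix(rates)
  n <- nrow(rates)
  if (n < 50) stop("need at least 50 trials")
  if (length(value) != n || length(side) != n) stop("label length mismatch")
  if (stats::sd(value) == 0) stop("rank-deficient design: value is constant")
  vr <- range(value)
  value <- (value - vr[1]) / max(diff(vr), .Machine$double.eps)
  designs <- neuron_designs(value, side)
  fits <- lapply(designs, function(X) {
    if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
    qrX <- qr(X)
    coef <- qr.coef(qrX, rates)
    res <- rates - X %*% coef
    hat <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)
    list(coef = coef, resid = res, rss = colSums(res^2),
         df_residual = n - ncol(X), hat = hat)
  })
  structure(c(fits, list(n_trials = n, n_neurons = ncol(rates),
                         value = value, side = side)),
            class = "neuron_fits")
}

#' Extract a coefficient across neurons
#'
#' @param fits A [fit_neuron_models()] result.
#' @param model Model name (`"noise"`, `"linear"`, `"interaction"`).
#' @param term Coefficient name, e.g. `"value"`, `"side"`, `"value:side"`.
#' @return Numeric vector over neurons.
#' @export
neuron_coef <- function(fits, model = "interaction", term = "value") {
  stopifnot(inherits(fits, "neuron_fits"))
  fits[[model]]$coef[term, ]
}

# exact LOO log predictive densities for a Gaussian linear model:
# deleted residual e_i/(1-h_i), deleted variance from RSS without point i
loo_log_density <- function(fit_entry, n) {
  h <- fit_entry$hat
  p <- n - fit_entry$df_residual
  e <- fit_entry$resid                       # trials x neurons
  d <- e / (1 - h)                           # deleted residuals
  rss_i <- sweep(-e^2 / (1 - h), 2, fit_entry$rss, "+")  # RSS without i
  s2_i <- pmax(sweep(rss_i, 2, rep(n - 1 - p, ncol(e)), "/"), 1e-12)
  pred_var <- s2_i * (1 + h)                 # predictive variance at x_i
  stats::dnorm(d, mean = 0, sd = sqrt(pred_var), log = TRUE)
}

#' Bayesian stacking of the per-neuron encoding models
#'
#' Assigns each neuron a weight simplex over the noise, linear and interaction
#' models by maximizing the leave-one-out log predictive density of the
#' weight-mixed Gaussian predictive distribution. LOO densities are exact,
#' via hat-matrix deletion identities. Optimization is over softmax-
#' parameterized weights; on failure the neuron falls back to uniform weights
#' with a warning.
#'
#' @param fits A [fit_neuron_models()] result.
#' @return Neurons x 3 matrix of stacking weights (columns `noise`, `linear`,
#'   `interaction`), rows on the simplex.
#' @export
stack_models <- function(fits) {
  stopifnot(inherits(fits, "neuron_fits"))
  n <- fits$n_trials
  ld <- lapply(c("noise", "linear", "interaction"),
               function(m) loo_log_density(fits[[m]], n))
  W <- matrix(NA_real_, fits$n_neurons, 3,
              dimnames = list(NULL, c("noise", "linear", "interaction")))
  fallback <- 0L
  for (j in seq_len(fits$n_neurons)) {
    D <- cbind(ld[[1]][, j], ld[[2]][, j], ld[[3]][, j])
    obj <- function(z) {
      w <- exp(c(z, 0)); w <- w / sum(w)
      mx <- apply(D, 1, max)
      -sum(mx + log(exp(D - mx) %*% w))
    }
    opt <- try(stats::optim(c(0, 0), obj, method = "BFGS"), silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$value)) {
      W[j, ] <- rep(1 / 3, 3); fallback <- fallback + 1L
    } else {
      w <- exp(c(opt$par, 0)); W[j, ] <- w / sum(w)
    }
  }
  if (fallback > 0L)
    warning(sprintf("stacking fell back to uniform weights for %d neuron(s)", fallback))
  W
}

# sequential sums of squares for value (7-level categorical), side, and
# their interaction; returns F statistics for the three effects given a
# response matrix (trials x responses), vectorized over columns
anova_F <- function(proj, Y) {
  tot <- colSums(Y^2)
  fitted_ss <- function(Q) colSums(crossprod(Q, Y)^2)
  r0 <- tot - fitted_ss(proj$Q0); r1 <- tot - fitted_ss(proj$Q1)
  r2 <- tot - fitted_ss(proj$Q2); r3 <- tot - fitted_ss(proj$Q3)
  mse <- r3 / proj$df_res
  rbind(value = ((r0 - r1) / proj$df_value) / mse,
        side = ((r1 - r2) / proj$df_side) / mse,
        interaction = ((r2 - r3) / proj$df_int) / mse)
}

anova_projections <- function(value_f, side_f) {
  X0 <- stats::model.matrix(~1, data.frame(value_f))
  X1 <- stats::model.matrix(~value_f)
  X2 <- stats::model.matrix(~value_f + side_f)
  X3 <- stats::model.matrix(~value_f * side_f)
  Qmat <- function(X) qr.Q(qr(X))[, seq_len(qr(X)$rank), drop = FALSE]
  rk <- function(X) qr(X)$rank
  list(Q0 = Qmat(X0), Q1 = Qmat(X1), Q2 = Qmat(X2), Q3 = Qmat(X3),
       df_value = rk(X1) - rk(X0), df_side = rk(X2) - rk(X1),
       df_int = rk(X3) - rk(X2), df_res = nrow(X3) - rk(X3))
}

#' Permutation-ANOVA neuron selectivity
#'
#' For each neuron, fits a two-way ANOVA with value treated as categorical
#' over 7 equally spaced levels, side, and their interaction; a null
#' distribution of F-scores is built by refitting on `n_perm` permutations of
#' the firing rates. The p-value for each effect is
#' `(#(F_perm > F_main) + 1) / (n_perm + 1)`, so it can never be 0. Neurons
#' are classified as `linear-selective` (exactly one main effect),
#' `linear-mixed` (both main effects), `nonlinear` (significant interaction,
#' regardless of main effects), or `none`. Empty value levels trigger
#' re-binning into fewer levels with a warning.
#'
#' @param rates Trials x neurons rate matrix.
#' @param value Numeric trial values (binned into 7 levels).
#' @param side -1/+1 trial sides.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Significance level for classification (default 0.05).
#' @param seed Integer seed.
#' @return List with `p` (3 x neurons matrix of p-values), `F` (observed
#'   F-scores), `class` (per-neuron selectivity class), `n_levels`.
#' @export
permutation_anova <- function(rates, value, side, n_perm = 1000, alpha = 0.05,
                              seed = 1L) {
  rates <- as.matrix(rates)
  n <- nrow(rates)
  n_levels <- 7L
  repeat {
    breaks <- stats::quantile(value, seq(0, 1, length.out = n_levels + 1),
                              names = FALSE)
    value_f <- cut(value, unique(breaks), include.lowest = TRUE)
    tab <- table(value_f, side)
    if (all(tab > 0) || n_levels <= 2L) break
    n_levels <- n_levels - 1L
    warning(sprintf("empty value level; re-binning to %d levels", n_levels))
  }
  side_f <- factor(side)
  proj <- anova_projections(value_f, side_f)
  F_main <- anova_F(proj, rates)
  set.seed(seed)
  exceed <- matrix(0L, 3, ncol(rates))
  # permute rates (rows) jointly across neurons, block-wise to bound memory
  for (b in seq_len(n_perm)) {
    Yp <- rates[sample.int(n), , drop = FALSE]
    exceed <- exceed + (anova_F(proj, Yp) > F_main)
  }
  p <- (exceed + 1) / (n_perm + 1)
  rownames(p) <- rownames(F_main)
  sig <- p < alpha
  cls <- apply(sig, 2, function(s) {
    if (s["interaction"]) "nonlinear"
    else if (s["value"] && s["side"]) "linear-mixed"
    else if (xor(s["value"], s["side"])) "linear-selective"
    else "none"
  })
  list(p = p, F = F_main, class = cls, n_levels = n_levels)
}

#' Per-neuron subspace contribution
#'
#' Percent variance each neuron contributes to a coding subspace, using the
#' participation-ratio convention `contribution_i = w_i^4 / sum_j w_j^4`
#' (contributions sum to 1), and the smallest set of neurons covering 95%
#' cumulative contribution.
#'
#' @param weights Per-neuron subspace coefficients (non-zero vector).
#' @param top Cumulative contribution covered by the top set (default 0.95).
#' @return List with `contribution` (per neuron, sums to 1) and `top_set`
#'   (indices, largest contribution first).
#' @export
subspace_contribution <- function(weights, top = 0.95) {
  if (all(weights == 0)) stop("weight vector is all zero")
  contrib <- weights^4 / sum(weights^4)
  ord <- order(contrib, decreasing = TRUE)
  k <- which(cumsum(contrib[ord]) >= top)[1]
  list(contribution = contrib, top_set = ord[seq_len(k)])
}
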