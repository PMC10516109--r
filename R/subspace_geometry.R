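# Value-encoding subspace vectors from regression coefficients, correlations
# across task-functional contrasts, and the bootstrap noise-ceiling test that
# decides whether two value subspaces are genuinely distinct or merely
# noise-corrupted copies of one shared subspace.

#' Value subspace vector for a context
#'
#' Per-neuron value-direction weights for a given side, built from the
#' interaction-model coefficients as the difference between the predicted
#' high-value response and the value/side intercept response at that side:
#' intercept and pure-side terms cancel exactly, leaving
#' `w = betaValue + side * betaInteraction` (side +1 = left, -1 = right).
#'
#' @param fits A [fit_neuron_models()] result.
#' @param side +1 (left) or -1 (right).
#' @return Numeric vector of per-neuron weights.
#' @export
value_subspace_vector <- function(fits, side) {
  stopifnot(inherits(fits, "neuron_fits"))
  if (!side %in% c(-1, 1)) stop("side must be +1 (left) or -1 (right)")
  co <- fits$interaction$coef
  if (!all(c("value", "value:side") %in% rownames(co)))
    stop("interaction-model coefficients missing")
  co["value", ] + side * co["value:side", ]
}

#' Subspace correlation between two weight vectors
#'
#' Pearson correlation of the per-neuron value weights of two contexts.
#'
#' @param v1,v2 Numeric weight vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
subspace_correlation <- function(v1, v2) {
  if (length(v1) != length(v2) || length(v1) < 3)
    stop("vectors must have equal length >= 3")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("undefined correlation: zero-variance vector")
  stats::cor(v1, v2)
}

#' Disattenuated subspace correlation with bootstrap CI
#'
#' The raw correlation between two contexts' estimated value vectors is
#' attenuated by per-neuron regression noise (each estimated weight is true
#' weight plus estimation error), so it underestimates the generative
#' subspace correlation. This estimator removes the attenuation with the
#' standard errors-in-variables moment correction: the across-neuron
#' (co)variances of the estimated left/right weights are corrected by the
#' OLS error moments,
#' `rho_hat = (cov(vL, vR) - eLR) / sqrt((var(vL) - eLL)(var(vR) - eRR))`,
#' where `eLL`, `eRR`, `eLR` are the mean per-neuron error (co)variances of
#' the weights `w = betaValue +/- side * betaInteraction` implied by the
#' design and the per-neuron residual variances. The CI uses a delete-block
#' jackknife over trials: the trials are partitioned into `n_blocks`
#' stratified (side x value level) blocks, the estimator is recomputed with
#' each block deleted, and the jackknife variance gives a normal-
#' approximation CI. A with-replacement trial bootstrap is avoided
#' deliberately: duplicated rows shrink the apparent residual variance and
#' bias the error-moment correction.
#'
#' @param rates Trials x neurons rate matrix.
#' @param value Numeric trial values.
#' @param side -1/+1 trial sides.
#' @param n_blocks Jackknife blocks (default 40).
#' @param seed Integer seed (block assignment).
#' @return List with `rho` (disattenuated point estimate, clamped to
#'   `[-1, 1]`), `raw` (attenuated full-data correlation), `ci`
#'   (normal-approximation 95% CI), `se`, `jack` (the leave-block-out
#'   values).
#' @export
estimate_subspace_rho <- function(rates, value, side, n_blocks = 40,
                                  seed = 1L) {
  rates <- as.matrix(rates)
  lev <- ifelse(value > stats::median(value), "high", "low")
  strata <- paste(side, lev)
  corrected <- function(ix) {
    R <- rates[ix, , drop = FALSE]
    v <- value[ix]; s <- side[ix]
    vr <- range(v)
    vn <- (v - vr[1]) / max(diff(vr), .Machine$double.eps)
    X <- cbind(1, vn, s, vn * s)
    qrX <- qr(X)
    co <- qr.coef(qrX, R)
    res <- R - X %*% co
    s2 <- colSums(res^2) / (nrow(X) - ncol(X))   # per-neuron residual var
    XtXinv <- chol2inv(qr.R(qrX))
    cvv <- XtXinv[2, 2]; cii <- XtXinv[4, 4]; cvi <- XtXinv[2, 4]
    vL <- co[2, ] + co[4, ]; vR <- co[2, ] - co[4, ]
    eLL <- mean(s2) * (cvv + cii + 2 * cvi)
    eRR <- mean(s2) * (cvv + cii - 2 * cvi)
    eLR <- mean(s2) * (cvv - cii)
    num <- stats::cov(vL, vR) - eLR
    den2 <- (stats::var(vL) - eLL) * (stats::var(vR) - eRR)
    if (den2 <= 0) return(NA_real_)
    max(min(num / sqrt(den2), 1), -1)
  }
  rho <- corrected(seq_len(nrow(rates)))
  f_all <- fit_neuron_models(rates, value, side)
  raw <- subspace_correlation(value_subspace_vector(f_all, 1),
                              value_subspace_vector(f_all, -1))
  set.seed(seed)
  block <- integer(nrow(rates))
  for (st in unique(strata)) {
    ix <- which(strata == st)
    block[ix] <- sample(rep_len(seq_len(n_blocks), length(ix)))
  }
  jack <- vapply(seq_len(n_blocks), function(g)
    corrected(which(block != g)), numeric(1))
  ok <- is.finite(jack)
  G <- sum(ok)
  se <- sqrt((G - 1) / G * sum((jack[ok] - mean(jack[ok]))^2))
  ci <- rho + c(-1, 1) * stats::qnorm(0.975) * se
  names(ci) <- c("2.5%", "97.5%")
  list(rho = rho, raw = raw, ci = ci, se = se, jack = jack)
}

# fast interaction-model value vectors: returns cbind(v_left, v_right) from
# a single OLS fit (used by bootstrap-heavy estimators where the full
# three-model machinery of fit_neuron_models is not needed)
value_vectors_fast <- function(rates, value, side) {
  vr <- range(value)
  v <- (value - vr[1]) / max(diff(vr), .Machine$double.eps)
  X <- cbind(1, v, side, v * side)
  co <- qr.coef(qr(X), rates)
  cbind(left = co[2, ] + co[4, ], right = co[2, ] - co[4, ])
}

# stratified bootstrap indices: resample trials with replacement within
# condition strata so condition balance is preserved
stratified_boot <- function(strata) {
  idx <- seq_along(strata)
  unlist(lapply(split(idx, strata), function(ix)
    ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
}

#' Bootstrap noise-ceiling test for subspace separability
#'
#' Decides whether two contexts' value subspaces are genuinely distinct or
#' merely noise-corrupted estimates of one shared subspace. Each of the
#' `n_boot` draws splits the trials into two disjoint stratified halves
#' (side x value-level cells) and fits the interaction regression on each
#' half. The *observed* value for that draw is the mean cross-context,
#' cross-half correlation (context A from one half against context B from
#' the other, both pairings averaged); the *ceiling* value is the mean
#' same-context cross-half correlation. Because both quantities compare
#' vectors estimated from disjoint data, their estimation errors are
#' independent in exactly the same way, and under truly shared subspaces
#' (generative `rho = 1`) the observed and ceiling distributions coincide --
#' the test is calibrated. An observed distribution below the ceiling
#' indicates genuinely distinct subspaces.
#'
#' Contexts are defined by a `contrast`: `"left-right"` compares the left and
#' right value vectors fit on the same trials; `"left-right-across"` fits the
#' two epochs separately and compares left (epoch 1) with right (epoch 2);
#' `"same-side-across"` compares the same side's vector across the two
#' epochs.
#'
#' One-sided p-values use the paired draws with the +1 small-sample
#' correction: `p_vs_ceiling = (#(observed >= ceiling) + 1) / (n_boot + 1)`
#' (small when the observed correlation falls below the ceiling) and
#' `p_vs_zero = (#(observed <= 0) + 1) / (n_boot + 1)`.
#'
#' @param rates Trials x neurons rate matrix.
#' @param value Numeric trial values.
#' @param side -1/+1 trial sides.
#' @param epoch Optional trial epoch labels (1/2), required for the
#'   across-epoch contrasts.
#' @param contrast One of `"left-right"`, `"left-right-across"`,
#'   `"same-side-across"`.
#' @param which_side Side used by `"same-side-across"` (+1 or -1).
#' @param n_boot Number of bootstrap resamples (even; default 1000).
#' @param seed Integer seed.
#' @return List with `observed` (length `n_boot`), `ceiling` (length
#'   `n_boot`), `point` (full-data correlation), `p_vs_ceiling`, `p_vs_zero`.
#' @export
noise_ceiling_test <- function(rates, value, side, epoch = NULL,
                               contrast = c("left-right", "left-right-across",
                                            "same-side-across"),
                               which_side = 1, n_boot = 1000, seed = 1L) {
  contrast <- match.arg(contrast)
  rates <- as.matrix(rates)
  if (n_boot %% 2L != 0L) stop("n_boot must be even")
  if (contrast != "left-right" && is.null(epoch))
    stop("epoch labels required for across-epoch contrasts")
  lev <- ifelse(value > stats::median(value), "high", "low")
  strata <- paste(side, lev, if (!is.null(epoch)) epoch)
  per_cell <- table(strata)
  if (any(per_cell < 4)) stop("insufficient trials in a condition stratum")

  side_col <- function(s) if (s == 1) "left" else "right"
  # value vectors for both contexts, fit on the given trials
  vectors_at <- function(ix) {
    if (contrast == "left-right") {
      V <- value_vectors_fast(rates[ix, , drop = FALSE], value[ix], side[ix])
      list(V[, "left"], V[, "right"])
    } else {
      i1 <- ix[epoch[ix] == 1L]; i2 <- ix[epoch[ix] == 2L]
      V1 <- value_vectors_fast(rates[i1, , drop = FALSE], value[i1], side[i1])
      V2 <- value_vectors_fast(rates[i2, , drop = FALSE], value[i2], side[i2])
      if (contrast == "left-right-across")
        list(V1[, "left"], V2[, "right"])
      else
        list(V1[, side_col(which_side)], V2[, side_col(which_side)])
    }
  }
  pt <- vectors_at(seq_len(nrow(rates)))
  point <- subspace_correlation(pt[[1]], pt[[2]])

  set.seed(seed)
  observed <- ceiling_vals <- numeric(n_boot)
  idx_all <- seq_len(nrow(rates))
  for (b in seq_len(n_boot)) {
    half <- unlist(lapply(split(idx_all, strata), function(jj)
      sample(jj, length(jj) %/% 2)), use.names = FALSE)
    vs1 <- vectors_at(half)
    vs2 <- vectors_at(setdiff(idx_all, half))
    observed[b] <- mean(c(subspace_correlation(vs1[[1]], vs2[[2]]),
                          subspace_correlation(vs2[[1]], vs1[[2]])))
    ceiling_vals[b] <- mean(c(subspace_correlation(vs1[[1]], vs2[[1]]),
                              subspace_correlation(vs1[[2]], vs2[[2]])))
  }
  p_vs_ceiling <- (sum(observed >= ceiling_vals) + 1) / (n_boot + 1)
  p_vs_zero <- (sum(observed <= 0) + 1) / (n_boot + 1)
  list(observed = observed, ceiling = ceiling_vals, point = point,
       p_vs_ceiling = p_vs_ceiling, p_vs_zero = p_vs_zero)
}
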