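# Subjective-value choice model for the sequential risky-choice task:
# power-law utility x Prelec probability weighting x softmax, with ML fitting,
# BIC model comparison over the 4-model space, and session-wise value
# binarization.

#' Subjective-value model
#'
#' A risky-choice model in which the subjective value of an offer is
#' `SV = w(p) * u(s)` with power-law utility `u(s) = s^gamma` and
#' two-parameter Prelec probability weighting
#' `w(p) = exp(-beta * (-log p)^alpha)`; choices follow a softmax on the
#' subjective-value difference with inverse temperature `temperature`.
#'
#' Four variants span the model space: `"ev"` (objective stakes and
#' probability), `"utility"` (free `gamma`, objective probability), `"prob"`
#' (objective stakes, free Prelec), and `"full"` (all free). Pinned
#' parameters are held at identity (`gamma = 1`, `alpha = beta = 1`).
#'
#' @param gamma Utility exponent (> 0).
#' @param alpha,beta Prelec warp parameters (> 0).
#' @param temperature Softmax inverse temperature (> 0).
#' @param variant One of `"ev"`, `"utility"`, `"prob"`, `"full"`.
#' @return An object of class `sv_model`.
#' @export
sv_model <- function(gamma = 1, alpha = 1, beta = 1, temperature = 1,
                     variant = c("full", "ev", "utility", "prob")) {
  variant <- match.arg(variant)
  if (temperature <= 0) stop("temperature must be > 0")
  if (gamma <= 0 || alpha <= 0 || beta <= 0)
    stop("gamma, alpha, beta must be > 0")
  if (variant %in% c("ev", "prob") && gamma != 1)
    stop("variant pins gamma = 1")
  if (variant %in% c("ev", "utility") && (alpha != 1 || beta != 1))
    stop("variant pins alpha = beta = 1")
  structure(list(gamma = gamma, alpha = alpha, beta = beta,
                 temperature = temperature, variant = variant),
            class = "sv_model")
}

#' @export
print.sv_model <- function(x, ...) {
  cat(sprintf("Subjective-value model (%s): gamma = %.3f, alpha = %.3f, beta = %.3f, T = %.3f\n",
              x$variant, x$gamma, x$alpha, x$beta, x$temperature))
  invisible(x)
}

#' Prelec probability weighting
#'
#' `w(p) = exp(-beta * (-log p)^alpha)`, with `w(0) = 0` and `w(1) = 1`. At
#' `alpha = beta = 1` this reduces exactly to the identity `w(p) = p`.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param alpha,beta Warp parameters (> 0).
#' @return Weighted probabilities.
#' @export
prelec_weight <- function(p, alpha = 1, beta = 1) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- exp(-beta * (-log(p[pos]))^alpha)
  out
}

#' Subjective value of an offer
#'
#' `SV = w(p) * u(s)` under a [sv_model()].
#'
#' @param p Win probability in `[0, 1]`.
#' @param s Stakes (reward volume, mL), > 0.
#' @param model A [sv_model()].
#' @return Subjective value(s).
#' @export
subjective_value <- function(p, s, model) {
  stopifnot(inherits(model, "sv_model"))
  if (any(s <= 0)) stop("stakes must be > 0")
  prelec_weight(p, model$alpha, model$beta) * s^model$gamma
}

#' Softmax choice probability
#'
#' Probability of choosing offer 1 given subjective values and the inverse
#' temperature: `P(1) = 1 / (1 + exp(-temperature * (SV1 - SV2)))`. The rule
#' is symmetric, `P(1) + P(2) = 1`.
#'
#' @param SV1,SV2 Subjective values of the two offers.
#' @param temperature Inverse temperature (> 0).
#' @return Probability of choosing offer 1.
#' @export
choice_probability <- function(SV1, SV2, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  stats::plogis(temperature * (SV1 - SV2))
}

# negative log likelihood of choices (1 = offer1 chosen) for a parameter
# vector on the variant's free-parameter scale (log-transformed)
sv_nll <- function(logpar, trials, variant) {
  par <- sv_unpack(logpar, variant)
  sv1 <- prelec_weight(trials$probability1, par$alpha, par$beta) *
    trials$stakes1^par$gamma
  sv2 <- prelec_weight(trials$probability2, par$alpha, par$beta) *
    trials$stakes2^par$gamma
  p1 <- stats::plogis(par$temperature * (sv1 - sv2))
  p1 <- pmin(pmax(p1, 1e-12), 1 - 1e-12)
  -sum(log(ifelse(trials$choice == 1L, p1, 1 - p1)))
}

sv_free_names <- function(variant) {
  switch(variant,
         ev = "temperature",
         utility = c("gamma", "temperature"),
         prob = c("alpha", "beta", "temperature"),
         full = c("gamma", "alpha", "beta", "temperature"))
}

sv_unpack <- function(logpar, variant) {
  par <- list(gamma = 1, alpha = 1, beta = 1, temperature = 1)
  par[sv_free_names(variant)] <- as.list(exp(logpar))
  par
}

#' Fit the subjective-value choice model by maximum likelihood
#'
#' Fits one of the four model variants to a trial table by multi-start
#' maximum likelihood (L-BFGS-B on log-parameters), keeping the best
#' optimum. Model comparison across variants uses BIC, and predictive
#' accuracy is estimated by k-fold cross-validation (fraction of held-out
#' choices on the predicted side).
#'
#' @param trials Data.frame with columns `probability1`, `probability2`,
#'   `stakes1`, `stakes2`, `choice` (1 = offer 1 chosen, 2 = offer 2).
#' @param variant Model variant, see [sv_model()].
#' @param n_starts Number of optimizer restarts (default 8).
#' @param cv_folds Folds for the accuracy estimate (default 5).
#' @param seed Integer seed for start jitter and fold assignment.
#' @return A list with `model` (fitted [sv_model()]), `logLik`, `BIC`,
#'   `accuracy` (cross-validated), `n`, `status` (`"ok"` or
#'   `"non-identifiable"`).
#' @export
fit_choice_model <- function(trials, variant = c("full", "ev", "utility", "prob"),
                             n_starts = 8, cv_folds = 5, seed = 1L) {
  variant <- match.arg(variant)
  if (nrow(trials) < 100) stop("need at least 100 trials")
  status <- "ok"
  if (length(unique(trials$choice)) < 2L) status <- "non-identifiable"
  free <- sv_free_names(variant)
  np <- length(free)
  set.seed(seed)
  base <- log(c(gamma = 1, alpha = 1, beta = 1, temperature = 10))[free]
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- base + if (s == 1) 0 else stats::rnorm(np, sd = 0.7)
    opt <- try(stats::optim(start, sv_nll, trials = trials, variant = variant,
                            method = "L-BFGS-B", lower = rep(-7, np),
                            upper = rep(7, np)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed for all starts")
  par <- sv_unpack(best$par, variant)
  model <- sv_model(gamma = par$gamma, alpha = par$alpha, beta = par$beta,
                    temperature = par$temperature, variant = variant)
  ll <- -best$value
  bic <- np * log(nrow(trials)) - 2 * ll
  # k-fold predictive accuracy: refit without the fold, predict the argmax side
  fold <- sample(rep_len(seq_len(cv_folds), nrow(trials)))
  hits <- 0L
  for (f in seq_len(cv_folds)) {
    tr <- trials[fold != f, , drop = FALSE]
    te <- trials[fold == f, , drop = FALSE]
    opt_f <- stats::optim(best$par, sv_nll, trials = tr, variant = variant,
                          method = "L-BFGS-B", lower = rep(-7, np),
                          upper = rep(7, np))
    pf <- sv_unpack(opt_f$par, variant)
    sv1 <- prelec_weight(te$probability1, pf$alpha, pf$beta) * te$stakes1^pf$gamma
    sv2 <- prelec_weight(te$probability2, pf$alpha, pf$beta) * te$stakes2^pf$gamma
    pred <- ifelse(sv1 >= sv2, 1L, 2L)
    hits <- hits + sum(pred == te$choice)
  }
  list(model = model, logLik = ll, BIC = bic,
       accuracy = hits / nrow(trials), n = nrow(trials), status = status)
}

#' Compare the four choice-model variants
#'
#' Fits all four variants and ranks them by BIC.
#'
#' @inheritParams fit_choice_model
#' @return A data.frame (one row per variant, sorted by BIC) and the list of
#'   fits in `attr(, "fits")`.
#' @export
compare_choice_models <- function(trials, n_starts = 8, seed = 1L) {
  variants <- c("ev", "utility", "prob", "full")
  fits <- lapply(variants, function(v)
    fit_choice_model(trials, v, n_starts = n_starts, seed = seed))
  names(fits) <- variants
  tab <- data.frame(variant = variants,
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    BIC = vapply(fits, `[[`, numeric(1), "BIC"),
                    accuracy = vapply(fits, `[[`, numeric(1), "accuracy"))
  tab <- tab[order(tab$BIC), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Binarize subjective values session-wise
#'
#' Labels each value `"low"` (below the 35th percentile), `"high"` (above the
#' 65th), or `"excluded"` (middle 30 percent, including ties with the
#' percentile bounds). Percentiles use linear interpolation
#' (`quantile(type = 7)`). With degenerate (all-equal) values everything is
#' excluded.
#'
#' @param sv Numeric vector of session subjective values (length >= 10).
#' @return Factor with levels `low`, `high`, `excluded`.
#' @export
binarize_value <- function(sv) {
  if (length(sv) < 10) stop("need at least 10 values")
  qs <- stats::quantile(sv, c(0.35, 0.65), type = 7, names = FALSE)
  out <- rep("excluded", length(sv))
  out[sv < qs[1]] <- "low"
  out[sv > qs[2]] <- "high"
  factor(out, levels = c("low", "high", "excluded"))
}
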