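# Pseudopopulation construction, train-only preprocessing (z-score + PCA),
# linear SVM decoding with cross-condition generalization, and the
# trial-by-trial error-projection analysis on optimal vs suboptimal choices.

#' Assemble a pseudopopulation across sessions
#'
#' Combines neurons from several sessions into condition-aligned response
#' tensors. A neuron (session) is included only if every one of the four
#' value x context conditions has at least `min_trials` trials (160 for the
#' broad splits, 80 for the narrow splits). Within each condition, every
#' session's trials are resampled with replacement to a common per-condition
#' count, so non-simultaneously recorded neurons can be decoded jointly.
#'
#' @param sessions List of sessions; each a list with `rates` (trials x
#'   neurons), `value` (two-level labels) and `context` (two-level labels).
#' @param split `"broad"` (min 160 trials/condition) or `"narrow"` (min 80).
#' @param n_per_condition Trials drawn per condition (default: the smallest
#'   qualifying condition count across included sessions).
#' @param seed Integer seed for the resampling.
#' @return An object of class `pseudopopulation`: list with `X` (per
#'   condition: trials x total-neurons matrix), `conditions` (the four
#'   labels), `value_of`, `context_of`, `included` (logical per session),
#'   `n_per_condition`.
#' @export
build_pseudopopulation <- function(sessions, split = c("broad", "narrow"),
                                   n_per_condition = NULL, seed = 1L) {
  split <- match.arg(split)
  min_trials <- if (split == "broad") 160L else 80L
  conds <- function(s) paste(s$value, s$context, sep = ":")
  counts <- lapply(sessions, function(s) table(conds(s)))
  cond_levels <- sort(Reduce(union, lapply(counts, names)))
  if (length(cond_levels) != 4) stop("sessions must carry 4 value x context conditions")
  included <- vapply(counts, function(ct)
    all(cond_levels %in% names(ct)) && all(ct[cond_levels] >= min_trials),
    logical(1))
  if (!any(included)) stop("zero qualifying sessions/neurons for this split")
  keep <- which(included)
  if (is.null(n_per_condition))
    n_per_condition <- min(vapply(counts[keep], function(ct)
      min(ct[cond_levels]), numeric(1)))
  set.seed(seed)
  X <- stats::setNames(vector("list", 4), cond_levels)
  for (cl in cond_levels) {
    blocks <- lapply(keep, function(i) {
      s <- sessions[[i]]
      ix <- which(conds(s) == cl)
      # subsample without replacement where possible; duplicated trials
      # would only add decoder noise
      take <- if (length(ix) >= n_per_condition)
        sample(ix, n_per_condition) else
          ix[sample.int(length(ix), n_per_condition, replace = TRUE)]
      s$rates[take, , drop = FALSE]
    })
    X[[cl]] <- do.call(cbind, blocks)
  }
  structure(list(X = X, conditions = cond_levels,
                 value_of = sub(":.*", "", cond_levels),
                 context_of = sub(".*:", "", cond_levels),
                 included = included, n_per_condition = n_per_condition),
            class = "pseudopopulation")
}

#' Train-only preprocessing: z-score then PCA at 99% variance
#'
#' Fits the per-feature z-score and the PCA on the training set only, retains
#' the smallest number of components whose cumulative variance reaches
#' `var_retained`, and maps the test set through the training transforms.
#' Zero-variance training features are dropped with a warning.
#'
#' @param train,test Feature matrices (rows = trials).
#' @param var_retained Fraction of variance to retain (default 0.99).
#' @return List with `train`, `test` (transformed), `k` (retained
#'   dimensions), `kept` (feature indices kept after the variance screen).
#' @export
preprocess_features <- function(train, test = NULL, var_retained = 0.99) {
  train <- as.matrix(train)
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  kept <- which(sdv > 0)
  if (length(kept) < ncol(train))
    warning(sprintf("dropped %d zero-variance feature(s)", ncol(train) - length(kept)))
  zs <- function(M) sweep(sweep(M[, kept, drop = FALSE], 2, mu[kept]), 2,
                          sdv[kept], "/")
  ztr <- zs(train)
  pca <- stats::prcomp(ztr, center = FALSE, scale. = FALSE)
  cumvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- which(cumvar >= var_retained)[1]
  out <- list(train = pca$x[, seq_len(k), drop = FALSE], k = k, kept = kept)
  if (!is.null(test))
    out$test <- zs(as.matrix(test)) %*% pca$rotation[, seq_len(k), drop = FALSE]
  out
}

# balanced index sets: subsample the larger class to the smaller's size
balance_classes <- function(y) {
  tab <- table(y)
  n <- min(tab)
  unlist(lapply(split(seq_along(y), y), function(ix)
    if (length(ix) > n) sort(sample(ix, n)) else ix), use.names = FALSE)
}

# class balancing stratified over a nuisance factor: every class x nuisance
# cell is subsampled to the smallest cell, so the trained decoder cannot
# acquire systematic weights on the nuisance dimension from imbalance
balance_classes_stratified <- function(y, nuisance) {
  cell <- interaction(y, nuisance, drop = TRUE)
  n <- min(table(cell))
  unlist(lapply(split(seq_along(y), cell), function(ix)
    if (length(ix) > n) sort(sample(ix, n)) else ix), use.names = FALSE)
}

#' Linear SVM value decoding with cross-condition generalization
#'
#' Trains a soft-margin linear SVM (fixed cost 1) to discriminate high from
#' low value within the training context, reports held-out accuracy on 10%
#' of the training-context trials (repeated over `n_rep` disjoint folds and
#' averaged), and the cross-condition generalization accuracy on *all* trials
#' of the test context. Classes are balanced by subsampling before training;
#' z-score + PCA preprocessing is fit on each training split only.
#'
#' @param pseudo A [build_pseudopopulation()] result, or any list of four
#'   condition matrices with parallel `value_of` / `context_of` labels.
#' @param train_context,test_context Context labels; must differ.
#' @param n_rep Number of holdout repetitions (default 10, i.e. 10-fold).
#' @param cost SVM regularization constant (default 1), or `"cv"` to select
#'   it from `{1e-3, 1e-2, 1e-1, 1}` by held-out accuracy *within the
#'   training context* (the generalization set is never touched); with many
#'   features per training trial the fixed default can overfit.
#' @param seed Integer seed.
#' @return An object of class `decoder_report`: list with `standard`
#'   (mean held-out accuracy), `standard_sd`, `generalization`, `n_train`,
#'   `k` (mean retained PCA dimensions), `config`.
#' @export
decode_value <- function(pseudo, train_context, test_context, n_rep = 10,
                         cost = 1, seed = 1L) {
  if (train_context == test_context)
    stop("train and generalization contexts must differ")
  tr_conds <- pseudo$conditions[pseudo$context_of == train_context]
  te_conds <- pseudo$conditions[pseudo$context_of == test_context]
  if (length(tr_conds) != 2 || length(te_conds) != 2)
    stop("each context needs exactly 2 value conditions")
  lab_of <- function(conds) rep(pseudo$value_of[match(conds, pseudo$conditions)],
                                vapply(pseudo$X[conds], nrow, integer(1)))
  Xtr_all <- do.call(rbind, pseudo$X[tr_conds])
  ytr_all <- factor(lab_of(tr_conds))
  Xte <- do.call(rbind, pseudo$X[te_conds])
  yte <- factor(lab_of(te_conds), levels = levels(ytr_all))
  set.seed(seed)
  bal <- balance_classes(ytr_all)
  Xtr_all <- Xtr_all[bal, , drop = FALSE]; ytr_all <- ytr_all[bal]
  if (identical(cost, "cv")) {
    grid <- c(1e-3, 1e-2, 1e-1, 1)
    inner <- sample(rep_len(1:5, length(ytr_all)))
    acc_c <- vapply(grid, function(cc) {
      tr <- inner != 1L
      pp <- preprocess_features(Xtr_all[tr, , drop = FALSE],
                                Xtr_all[!tr, , drop = FALSE])
      fit <- e1071::svm(pp$train, ytr_all[tr], kernel = "linear", cost = cc,
                        scale = FALSE)
      mean(stats::predict(fit, pp$test) == ytr_all[!tr])
    }, numeric(1))
    cost <- grid[which.max(acc_c)]
  }
  fold <- sample(rep_len(seq_len(n_rep), length(ytr_all)))
  acc <- gen <- ks <- numeric(n_rep)
  for (f in seq_len(n_rep)) {
    tr <- fold != f
    pp <- preprocess_features(Xtr_all[tr, , drop = FALSE],
                              rbind(Xtr_all[!tr, , drop = FALSE], Xte))
    n_ho <- sum(!tr)
    fit <- e1071::svm(pp$train, ytr_all[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- stats::predict(fit, pp$test)
    acc[f] <- mean(pred[seq_len(n_ho)] == ytr_all[!tr])
    gen[f] <- mean(pred[-seq_len(n_ho)] == yte)
    ks[f] <- pp$k
  }
  structure(list(standard = mean(acc), standard_sd = stats::sd(acc),
                 generalization = mean(gen), generalization_sd = stats::sd(gen),
                 n_train = length(ytr_all), k = mean(ks),
                 config = list(n_rep = n_rep, cost = cost, seed = seed)),
            class = "decoder_report")
}

#' @export
print.decoder_report <- function(x, ...) {
  cat(sprintf("Decoder: standard %.3f (sd %.3f), generalization %.3f (n = %d, k = %.1f)\n",
              x$standard, x$standard_sd, x$generalization, x$n_train, x$k))
  invisible(x)
}

# signed distance to an SVM boundary, normalized by the weight norm and
# sign-flipped so positive = toward the correct class
svm_projection <- function(fit, X, y_true) {
  w_norm <- sqrt(sum((t(fit$coefs) %*% fit$SV)^2))
  dec <- attr(stats::predict(fit, X, decision.values = TRUE), "decision.values")
  # decision value sign corresponds to the first level in fit$levels
  sgn <- ifelse(y_true == fit$levels[1], 1, -1)
  as.vector(dec) * sgn / w_norm
}

#' Error-trial projection analysis for one session
#'
#' Trains a linear SVM on optimal-choice trials only, for two readouts of the
#' simultaneous window: which *side* carried the higher offer (left vs
#' right), and which *presentation* carried it (first vs second). For each
#' readout, the signed, toward-correct distance from the decision boundary
#' (normalized by the weight norm) is averaged over held-out optimal trials
#' and over all suboptimal trials. Lower projections on suboptimal trials
#' indicate that the corresponding binding of value (to side or to time) was
#' degraded when the animal chose poorly.
#'
#' @param session A [generate_population_session()] result, or a list with
#'   `rates_sim` and `sim_labels` (needs `v_left`, `v_right`, `order`,
#'   `optimal`).
#' @param holdout Fraction of optimal trials held out per split (default
#'   0.2).
#' @param n_rep Number of repeated holdout splits averaged (default 5).
#' @param cost SVM cost (default 1).
#' @param min_neurons Minimum neurons required (default 10).
#' @param seed Integer seed.
#' @return List with one element per readout (`spatial`, `temporal`), each
#'   holding `proj_optimal`, `proj_suboptimal` (means over splits),
#'   `n_optimal`, `n_suboptimal`, and `applicable` (FALSE when no suboptimal
#'   trials exist).
#' @export
error_trial_projection <- function(session, holdout = 0.2, n_rep = 5,
                                   cost = 1, min_neurons = 10, seed = 1L) {
  X <- as.matrix(session$rates_sim)
  lb <- session$sim_labels
  if (ncol(X) < min_neurons)
    stop(sprintf("session has fewer than %d neurons", min_neurons))
  mixed <- lb$v_left != lb$v_right
  readouts <- list(
    spatial = factor(ifelse(lb$v_left == 1, "left", "right")),
    temporal = factor(ifelse((lb$order == "left-first") == (lb$v_left == 1),
                             "first", "second")))
  set.seed(seed)
  out <- list()
  for (nm in names(readouts)) {
    y <- readouts[[nm]]
    use <- mixed
    opt <- use & lb$optimal
    sub <- use & !lb$optimal
    if (!any(sub)) {
      out[[nm]] <- list(applicable = FALSE)
      next
    }
    other <- setdiff(names(readouts), nm)
    opt_ix <- which(opt)
    po <- ps <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      ho <- sample(opt_ix, max(1, round(holdout * length(opt_ix))))
      tr <- setdiff(opt_ix, ho)
      # balance classes within the other readout's cells so the decoder
      # cannot inherit systematic weights on the other binding dimension
      tr <- tr[balance_classes_stratified(y[tr], readouts[[other]][tr])]
      pp <- preprocess_features(X[tr, , drop = FALSE],
                                rbind(X[ho, , drop = FALSE],
                                      X[which(sub), , drop = FALSE]))
      fit <- e1071::svm(pp$train, droplevels(y[tr]), kernel = "linear",
                        cost = cost, scale = FALSE)
      proj <- svm_projection(fit, pp$test,
                             as.character(y[c(ho, which(sub))]))
      n_ho <- length(ho)
      # equal-weighted cell means over class x other-readout cells, so a
      # finite-sample cell imbalance cannot masquerade as an effect
      cell_mean <- function(p, ix) {
        cells <- interaction(y[ix], readouts[[other]][ix], drop = TRUE)
        mean(tapply(p, cells, mean))
      }
      po[r] <- cell_mean(proj[seq_len(n_ho)], ho)
      ps[r] <- cell_mean(proj[-seq_len(n_ho)], which(sub))
    }
    out[[nm]] <- list(applicable = TRUE,
                      proj_optimal = mean(po), proj_suboptimal = mean(ps),
                      n_optimal = length(opt_ix), n_suboptimal = sum(sub))
  }
  out
}

#' Cross-session error-projection battery
#'
#' Runs [error_trial_projection()] on each session and, per readout, tests
#' whether projections on suboptimal trials are lower than on held-out
#' optimal trials by a paired one-sided t-test on the per-session mean
#' differences.
#'
#' @param sessions List of sessions (see [error_trial_projection()]).
#' @param seed Integer seed (incremented per session).
#' @return List per readout with `diffs` (optimal - suboptimal per session),
#'   `t`, `p` (one-sided, alternative: optimal > suboptimal), `n_sessions`.
#' @export
error_projection_battery <- function(sessions, seed = 1L) {
  res <- lapply(seq_along(sessions), function(i)
    error_trial_projection(sessions[[i]], seed = seed + i))
  out <- list()
  for (nm in c("spatial", "temporal")) {
    diffs <- vapply(res, function(r)
      if (isTRUE(r[[nm]]$applicable))
        r[[nm]]$proj_optimal - r[[nm]]$proj_suboptimal else NA_real_,
      numeric(1))
    diffs <- diffs[!is.na(diffs)]
    tt <- stats::t.test(diffs, alternative = "greater")
    out[[nm]] <- list(diffs = diffs, t = unname(tt$statistic),
                      p = tt$p.value, n_sessions = length(diffs))
  }
  out
}
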