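# Generators for fully synthetic experiments: task trials with the
# risky-choice offer statistics, a softmax subjective-value agent, and neural
# sessions with controlled representational geometry (shared value axis plus
# side- and order-conjunctive perturbations). Ground truth is recorded so
# every pipeline stage can be scored for recovery.

#' Task configuration for the sequential risky-choice task
#'
#' Offer types are drawn with probabilities 43.75% medium gamble (165 uL),
#' 43.75% large gamble (240 uL), and 12.5% safe (125 uL, guaranteed). Gamble
#' win probabilities are uniform on (0, 1); safe offers have probability 1.
#' Sides of the first and second offer are randomized.
#'
#' @param n_trials Number of trials.
#' @param type_probs Offer-type probabilities (medium, large, safe); must sum
#'   to 1.
#' @param stakes Reward volumes in mL for (medium, large, safe).
#' @param seed Integer seed.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_trials = 1000,
                        type_probs = c(medium = 0.4375, large = 0.4375, safe = 0.125),
                        stakes = c(medium = 0.165, large = 0.240, safe = 0.125),
                        seed = 1L) {
  if (abs(sum(type_probs) - 1) > 1e-9) stop("type_probs must sum to 1")
  structure(list(n_trials = n_trials, type_probs = type_probs,
                 stakes = stakes, seed = seed),
            class = "task_config")
}

#' Generate task trials
#'
#' Draws the two offers of each trial independently (type, then stakes and win
#' probability), randomizes which side carries the first offer, and flags
#' trials containing a safe offer (excluded from the neural analyses, as in
#' the task design).
#'
#' @param cfg A [task_config()].
#' @return A data.frame with columns `trial`, `probability1`, `probability2`,
#'   `stakes1`, `stakes2`, `type1`, `type2`, `side1` (`"left"`/`"right"`,
#'   side of the first offer), `safe` (logical).
#' @export
generate_task_trials <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  set.seed(cfg$seed)
  n <- cfg$n_trials
  draw_offer <- function() {
    ty <- sample(names(cfg$type_probs), n, replace = TRUE, prob = cfg$type_probs)
    p <- ifelse(ty == "safe", 1, stats::runif(n))
    list(type = ty, p = p, s = unname(cfg$stakes[ty]))
  }
  o1 <- draw_offer(); o2 <- draw_offer()
  data.frame(trial = seq_len(n),
             probability1 = o1$p, probability2 = o2$p,
             stakes1 = o1$s, stakes2 = o2$s,
             type1 = o1$type, type2 = o2$type,
             side1 = sample(c("left", "right"), n, replace = TRUE),
             safe = o1$type == "safe" | o2$type == "safe")
}

#' Simulate a softmax subjective-value agent
#'
#' Computes each offer's subjective value under `model` and samples the choice
#' from the softmax choice rule.
#'
#' @param trials Trial table from [generate_task_trials()].
#' @param model A [sv_model()].
#' @param seed Integer seed.
#' @return The trial table with added columns `sv1`, `sv2`, `choice`
#'   (1 or 2), and `optimal` (chose the higher-SV offer).
#' @export
simulate_agent <- function(trials, model, seed = 1L) {
  stopifnot(inherits(model, "sv_model"))
  sv1 <- subjective_value(trials$probability1, trials$stakes1, model)
  sv2 <- subjective_value(trials$probability2, trials$stakes2, model)
  p1 <- choice_probability(sv1, sv2, model$temperature)
  set.seed(seed)
  choice <- ifelse(stats::runif(nrow(trials)) < p1, 1L, 2L)
  trials$sv1 <- sv1; trials$sv2 <- sv2; trials$choice <- choice
  trials$optimal <- (choice == 1L) == (sv1 >= sv2)
  trials
}

# orthonormal direction bank for a session: value, side, 4 space-conjunctive
# (side x value-level), time, 4 time-conjunctive (epoch x value-level)
session_directions <- function(n_neurons) {
  if (n_neurons < 12) stop("need at least 12 neurons for the direction bank")
  Q <- qr.Q(qr(matrix(stats::rnorm(n_neurons * 11), n_neurons, 11)))
  list(val = Q[, 1], side = Q[, 2],
       conj_space = Q[, 3:6],   # columns: (left,low) (left,high) (right,low) (right,high)
       time = Q[, 7],
       conj_time = Q[, 8:11])   # columns: (e1,low) (e1,high) (e2,low) (e2,high)
}

conj_space_col <- function(side, high) 2 * (side < 0) + high + 1L  # side +1 left
conj_time_col <- function(epoch, high) 2 * (epoch - 1L) + high + 1L

#' Generate a synthetic neural session with controlled geometry
#'
#' Composes the task generator, the softmax agent and an explicit
#' linear-nonlinear encoding into a full session. Two kinds of response
#' windows are produced:
#'
#' * Per-offer epochs (`rates`, one row per trial x epoch): the presented
#'   offer is encoded as
#'   `dLV * u_val * (v - 1/2) + dLA * u_side * s/2 + m_s * u_conj(side, level)`
#'   plus an egocentric-time term
#'   `dLA_time * u_time * (e - 3/2) + m_t * u_conj(epoch, level)`,
#'   heterogeneous per-neuron gain, and isotropic Gaussian noise. Continuous
#'   (min-max normalized subjective) value `v` drives the linear part; the
#'   conjunctive part uses the binarized level, mirroring how the analyses
#'   move between the continuous task variable and the discrete theory.
#' * A simultaneous window (`rates_sim`, one row per trial) in which both
#'   offers are encoded at once, yielding the eight order x value conditions
#'   used by the misbinding-distance analyses. An optional planted misbinding
#'   shift moves suboptimal-choice trials toward the spatially swapped
#'   condition.
#'
#' The realized spatial subspace correlation is
#' `rho = dLV^2 / (dLV^2 + dN_space^2)`.
#'
#' @param n_neurons Number of neurons (>= 12).
#' @param n_trials Number of task trials.
#' @param dLV Linear value distance.
#' @param dLA Linear side distance.
#' @param dN_space Spatial conjunctive (nonlinear) distance.
#' @param dN_time Temporal conjunctive distance.
#' @param dLA_time Linear time distance.
#' @param sigma Trial noise standard deviation per neuron.
#' @param heterogeneity Per-neuron multiplicative gain jitter sd (0 = exact
#'   geometry).
#' @param value_coding `"binary"` draws offer values from the two binarized
#'   levels only (condition-based sampling, used by geometry-recovery
#'   analyses); `"task"` runs the full task + agent pipeline with continuous
#'   values.
#' @param agent A [sv_model()] generating choices (used for `"task"` coding
#'   and for choice labels in both modes).
#' @param planted_misbinding Fraction (0-1) of the spatial-swap displacement
#'   added to `rates_sim` on suboptimal-choice trials.
#' @param seed Integer seed.
#' @return An object of class `bg_session`: list with `rates`, `trials`
#'   (labels for `rates`: `trial`, `epoch`, `side` (+1 left / -1 right),
#'   `value`, `level`, `order`), `rates_sim`, `sim_labels` (`v_left`,
#'   `v_right`, `order`, `optimal`, condition label `cond8`), `behavior`,
#'   `truth`, `n_neurons`, `seed`.
#' @export
generate_population_session <- function(n_neurons = 60, n_trials = 800,
                                        dLV = 1, dLA = 0.8, dN_space = 0.6,
                                        dN_time = 0.6, dLA_time = 0.5,
                                        sigma = 1, heterogeneity = 0.1,
                                        value_coding = c("binary", "task"),
                                        agent = sv_model(gamma = 1.3, alpha = 0.7,
                                                         beta = 1, temperature = 60,
                                                         variant = "full"),
                                        planted_misbinding = 0, seed = 1L) {
  value_coding <- match.arg(value_coding)
  set.seed(seed)
  dirs <- session_directions(n_neurons)
  m_s <- dN_space / sqrt(2); m_t <- dN_time / sqrt(2)
  gain <- 1 + heterogeneity * stats::rnorm(n_neurons)

  if (value_coding == "task") {
    beh <- simulate_agent(generate_task_trials(task_config(n_trials, seed = seed + 1L)),
                          agent, seed = seed + 2L)
    beh <- beh[!beh$safe, , drop = FALSE]
    sv_all <- c(beh$sv1, beh$sv2)
    rng <- range(sv_all)
    v1 <- (beh$sv1 - rng[1]) / diff(rng)
    v2 <- (beh$sv2 - rng[1]) / diff(rng)
    lab <- binarize_value(c(v1, v2))
    nt <- nrow(beh)
    lev1 <- lab[seq_len(nt)]; lev2 <- lab[nt + seq_len(nt)]
    # encoding level: median split (the code binds actual value; the
    # excluded-middle binarization is an analysis-side choice)
    med <- stats::median(c(v1, v2))
    enc1 <- as.integer(v1 > med); enc2 <- as.integer(v2 > med)
  } else {
    nt <- n_trials
    enc1 <- sample(0:1, nt, replace = TRUE)
    enc2 <- sample(0:1, nt, replace = TRUE)
    v1 <- enc1; v2 <- enc2
    lev1 <- factor(ifelse(enc1 == 1L, "high", "low"),
                   levels = c("low", "high", "excluded"))
    lev2 <- factor(ifelse(enc2 == 1L, "high", "low"),
                   levels = c("low", "high", "excluded"))
    beh <- data.frame(trial = seq_len(nt),
                      side1 = sample(c("left", "right"), nt, replace = TRUE),
                      sv1 = v1, sv2 = v2)
    # binary levels differ by 1 SV unit; anchor higher-SV choice rate ~0.82
    p1 <- choice_probability(v1, v2, stats::qlogis(0.82))
    beh$choice <- ifelse(stats::runif(nt) < p1, 1L, 2L)
    beh$optimal <- (beh$choice == 1L) == (v1 >= v2)
  }

  side1 <- ifelse(beh$side1 == "left", 1L, -1L)
  side2 <- -side1
  # per-offer epoch responses: rows = trial x epoch
  epoch <- rep(1:2, each = nt)
  trial <- rep(seq_len(nt), 2)
  side <- c(side1, side2)
  value <- c(v1, v2)
  level <- c(as.character(lev1), as.character(lev2))
  enc <- c(enc1, enc2)
  mu <- outer((value - 0.5) * dLV, dirs$val) +
    outer(side / 2 * dLA, dirs$side) +
    m_s * t(dirs$conj_space[, conj_space_col(side, enc)]) +
    outer((epoch - 1.5) * dLA_time, dirs$time) +
    m_t * t(dirs$conj_time[, conj_time_col(epoch, enc)])
  mu <- sweep(mu, 2, gain, "*")
  rates <- mu + matrix(stats::rnorm(length(mu), sd = sigma), nrow(mu))

  trials_df <- data.frame(trial = trial, epoch = epoch, side = side,
                          value = value, level = level,
                          order = rep(ifelse(side1 == 1L, "left-first",
                                             "right-first"), 2))

  # simultaneous window: both offers encoded at once
  v_left <- ifelse(side1 == 1L, enc1, enc2)
  v_right <- ifelse(side1 == 1L, enc2, enc1)
  vv_left <- ifelse(side1 == 1L, v1, v2)
  vv_right <- ifelse(side1 == 1L, v2, v1)
  order <- ifelse(side1 == 1L, "left-first", "right-first")
  mu_sim <- outer((vv_left - 0.5) * dLV + (vv_right - 0.5) * dLV, dirs$val) +
    m_s * (t(dirs$conj_space[, conj_space_col(rep(1L, nt), v_left)]) +
             t(dirs$conj_space[, conj_space_col(rep(-1L, nt), v_right)])) +
    m_t * (t(dirs$conj_time[, conj_time_col(rep(1L, nt), enc1)]) +
             t(dirs$conj_time[, conj_time_col(rep(2L, nt), enc2)]))
  if (planted_misbinding > 0) {
    swap <- which(!beh$optimal & v_left != v_right)
    if (length(swap)) {
      shift <- m_s * (t(dirs$conj_space[, conj_space_col(rep(1L, length(swap)), v_right[swap])]) +
                        t(dirs$conj_space[, conj_space_col(rep(-1L, length(swap)), v_left[swap])]) -
                        t(dirs$conj_space[, conj_space_col(rep(1L, length(swap)), v_left[swap])]) -
                        t(dirs$conj_space[, conj_space_col(rep(-1L, length(swap)), v_right[swap])]))
      mu_sim[swap, ] <- mu_sim[swap, ] + planted_misbinding * shift
    }
  }
  mu_sim <- sweep(mu_sim, 2, gain, "*")
  rates_sim <- mu_sim + matrix(stats::rnorm(length(mu_sim), sd = sigma), nt)

  sim_labels <- data.frame(trial = seq_len(nt), v_left = v_left,
                           v_right = v_right, value_left = vv_left,
                           value_right = vv_right, order = order,
                           optimal = beh$optimal,
                           cond8 = paste0(ifelse(v_left == 1, "+L", "-L"),
                                          ifelse(v_right == 1, "+R", "-R"),
                                          ":", order))

  truth <- list(dLV = dLV, dLA = dLA, dN_space = dN_space, dN_time = dN_time,
                dLA_time = dLA_time, sigma = sigma,
                rho_space = subspace_correlation_from_distances(dLV, dN_space),
                heterogeneity = heterogeneity,
                planted_misbinding = planted_misbinding,
                agent = agent, value_coding = value_coding)
  structure(list(rates = rates, trials = trials_df, rates_sim = rates_sim,
                 sim_labels = sim_labels, behavior = beh, truth = truth,
                 n_neurons = n_neurons, seed = seed),
            class = "bg_session")
}

#' @export
print.bg_session <- function(x, ...) {
  cat(sprintf("Synthetic session: %d neurons, %d trials (%s value coding)\n",
              x$n_neurons, nrow(x$rates_sim), x$truth$value_coding))
  cat(sprintf("  truth: dLV = %.3g, dLA = %.3g, dN_space = %.3g, dN_time = %.3g, sigma = %.3g, rho = %.3g\n",
              x$truth$dLV, x$truth$dLA, x$truth$dN_space, x$truth$dN_time,
              x$truth$sigma, x$truth$rho_space))
  invisible(x)
}
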