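#' PPO configuration
#'
#' Hyperparameters of the reinforcement-learning agent.  The reward
#' compares each batch's classification accuracy to a benchmark of 0.9:
#' above it the agent receives +1, at or below it -1.  Episodes are
#' single-step (one batch = one episode), so the advantage is simply
#' reward minus the critic's value estimate.
#'
#' @param epsilon PPO-Clip radius; the importance ratio is clipped to
#'   `[1 - epsilon, 1 + epsilon]`.
#' @param benchmark_accuracy accuracy benchmark of the reward step
#'   function.
#' @param epochs_per_update gradient passes over the collected transitions
#'   per policy snapshot.
#' @param learning_rate initial Adam learning rate of the generator (and
#'   critic).
#' @param action_mode `"spatial"` (default): the action vector is reshaped
#'   to a square grid and bilinearly upsampled over the feature map;
#'   `"channel"`: one weight per channel (ablation).
#' @param hidden hidden-layer widths of the policy network.
#' @param critic_hidden hidden width of the critic.
#' @param critic_lr Adam learning rate of the critic's value regression
#'   (held fixed; a conservative rate keeps the baseline stable while the
#'   state distribution moves under the alternating schedule).
#' @param init_log_std initial log standard deviation of the Gaussian
#'   exploration noise (learned thereafter).
#' @param normalize_advantage standardize advantages (mean 0, sd 1) within
#'   each update batch (skipped when they are all equal); bounds the
#'   surrogate's gradient scale.
#' @param entropy_coef optional entropy bonus coefficient (default off).
#' @return object of class `ppo_config`.
#' @export
ppo_config <- function(epsilon = 0.2,
                       benchmark_accuracy = 0.9,
                       epochs_per_update = 4L,
                       learning_rate = 0.01,
                       action_mode = c("spatial", "channel"),
                       hidden = c(512L, 512L),
                       critic_hidden = 64L,
                       critic_lr = 0.001,
                       init_log_std = log(0.1),
                       normalize_advantage = TRUE,
                       entropy_coef = 0) {
  cfg <- list(epsilon = epsilon,
              benchmark_accuracy = benchmark_accuracy,
              epochs_per_update = as.integer(epochs_per_update),
              learning_rate = learning_rate,
              action_mode = match.arg(action_mode),
              hidden = as.integer(hidden),
              critic_hidden = as.integer(critic_hidden),
              critic_lr = critic_lr,
              init_log_std = init_log_std,
              normalize_advantage = isTRUE(normalize_advantage),
              entropy_coef = entropy_coef)
  if (cfg$epsilon <= 0 || cfg$epsilon >= 1) {
    stop("epsilon must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$benchmark_accuracy <= 0 || cfg$benchmark_accuracy >= 1) {
    stop("benchmark_accuracy must lie in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "ppo_config")
}

#' Initialize the generator (policy) network
#'
#' A multilayer perceptron from the pooled state to a Tanh action mean
#' (default 256 -> 512 -> 512 -> 256), with a learned per-dimension
#' Gaussian log standard deviation.  The output layer starts at zero so
#' the initial deterministic action is the zero vector -- identity gating.
#'
#' @param state_dim,action_dim input / output dimensionality (both equal
#'   the backbone's final channel count).
#' @param hidden hidden-layer widths.
#' @param init_log_std initial log exploration scale.
#' @param seed integer seed.
#' @return object of class `drl_policy`.
#' @export
policy_init <- function(state_dim = 256L, action_dim = 256L,
                        hidden = c(512L, 512L), init_log_std = log(0.1),
                        seed = 1L) {
  withr::with_seed(derive_seed(seed, "policy"), {
    params <- list(l1 = linear_init(state_dim, hidden[1]),
                   l2 = linear_init(hidden[1], hidden[2]),
                   l3 = linear_init(hidden[2], action_dim, zero = TRUE),
                   log_std = rep(init_log_std, action_dim))
    structure(list(params = params, state_dim = as.integer(state_dim),
                   action_dim = as.integer(action_dim)),
              class = "drl_policy")
  })
}

#' Initialize the critic network
#'
#' A small value MLP (default 256 -> 64 -> 1 with LeakyReLU) estimating the
#' expected reward of a state; used as the advantage baseline.
#'
#' @param state_dim input dimensionality.
#' @param hidden hidden width.
#' @param seed integer seed.
#' @return object of class `drl_critic`.
#' @export
critic_init <- function(state_dim = 256L, hidden = 64L, seed = 1L) {
  withr::with_seed(derive_seed(seed, "critic"), {
    params <- list(l1 = linear_init(state_dim, hidden),
                   l2 = linear_init(hidden, 1L))
    structure(list(params = params, state_dim = as.integer(state_dim)),
              class = "drl_critic")
  })
}

leaky_fwd <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
leaky_bwd <- function(dy, x, slope = 0.01) dy * ifelse(x > 0, 1, slope)

# Policy MLP forward: returns pre-Tanh action mean and the cache needed
# for backpropagation.
policy_mlp <- function(policy, states) {
  p <- policy$params
  a1 <- linear_fwd(states, p$l1); h1 <- relu_fwd(a1)
  a2 <- linear_fwd(h1, p$l2); h2 <- relu_fwd(a2)
  m <- linear_fwd(h2, p$l3)
  list(m = m, cache = list(states = states, h1 = h1, h2 = h2))
}

# Log density of a Tanh-squashed diagonal Gaussian at pre-squash value u.
gauss_tanh_logp <- function(u, m, log_std) {
  sd_e <- exp(log_std)
  lp <- colSums(stats::dnorm(u, m, sd_e, log = TRUE))
  lp - colSums(log(1 - tanh(u)^2 + 1e-7))
}

#' Query the policy for an action
#'
#' In deterministic mode the action is the Tanh of the policy-network
#' output.  In sample mode a diagonal Gaussian around the pre-Tanh mean is
#' drawn and squashed through Tanh; the returned log density includes the
#' Tanh change-of-variables correction and matches the returned action.
#'
#' @param policy a `drl_policy`.
#' @param state state vector, or a states matrix (state-dim x batch).
#' @param mode `"sample"` or `"deterministic"`.
#' @return list with `action` (action-dim x batch), `log_density` (length
#'   batch) and `pre_tanh` (the unsquashed draw, kept for PPO updates).
#' @export
policy_act <- function(policy, state, mode = c("sample", "deterministic")) {
  mode <- match.arg(mode)
  if (!is.matrix(state)) state <- matrix(state, ncol = 1)
  if (any(!is.finite(state))) {
    stop("non-finite state passed to the policy", call. = FALSE)
  }
  fw <- policy_mlp(policy, state)
  u <- if (mode == "deterministic") {
    fw$m
  } else {
    fw$m + exp(policy$params$log_std) *
      matrix(stats::rnorm(length(fw$m)), nrow(fw$m), ncol(fw$m))
  }
  list(action = tanh(u),
       log_density = gauss_tanh_logp(u, fw$m, policy$params$log_std),
       pre_tanh = u)
}

#' Build a gate from an action vector
#'
#' Weights are `1 + action`, lying in (0, 2) with the identity at action
#' zero.  In spatial mode the action length must be a perfect square; the
#' weights are reshaped to a square grid and bilinearly upsampled to the
#' feature-map resolution, so one weight governs one image region.  In
#' channel mode each weight scales one channel.
#'
#' @param action action vector, or action-dim x batch matrix.
#' @param mode `"spatial"` or `"channel"`.
#' @param H,W,C feature-map dimensions.
#' @return gate object: list with `mode` and a `values` multiplier matrix
#'   ((H*W) x batch in spatial mode, C x batch in channel mode).
#' @export
action_gate <- function(action, mode = c("spatial", "channel"), H, W, C) {
  mode <- match.arg(mode)
  if (!is.matrix(action)) action <- matrix(action, ncol = 1)
  w <- 1 + action
  if (mode == "channel") {
    if (nrow(action) != C) {
      stop("channel-mode action length must equal the channel count",
           call. = FALSE)
    }
    return(list(mode = "channel", values = w))
  }
  g <- sqrt(nrow(action))
  if (g != floor(g)) {
    stop("spatial-mode action length must be a perfect square", call. = FALSE)
  }
  g <- as.integer(g)
  vals <- apply(w, 2, function(col) {
    as.numeric(resize_bilinear(matrix(col, g, g), H, W))
  })
  list(mode = "spatial", values = matrix(vals, H * W, ncol(action)))
}

#' Multiplicatively re-weight a feature map with an action
#'
#' @param feature_map 3-D array (H x W x C).
#' @param action action vector (length C in channel mode; a perfect square
#'   in spatial mode).
#' @param mode `"spatial"` or `"channel"`.
#' @return gated feature map, same shape.  The all-zero action is the
#'   identity.
#' @export
apply_action <- function(feature_map, action, mode = c("spatial", "channel")) {
  mode <- match.arg(mode)
  d <- dim(feature_map)
  stopifnot(length(d) == 3L)
  gate <- action_gate(action, mode, d[1], d[2], d[3])
  if (gate$mode == "spatial") {
    G <- matrix(gate$values[, 1], d[1], d[2])
    out <- feature_map
    for (cc in seq_len(d[3])) out[, , cc] <- feature_map[, , cc] * G
    out
  } else {
    sweep(feature_map, 3, gate$values[, 1], `*`)
  }
}

#' Reward of a batch accuracy
#'
#' A step function with its single breakpoint at the benchmark: +1 when
#' the accuracy exceeds it, -1 otherwise (the boundary counts as not
#' exceeding).
#'
#' @param batch_accuracy fraction in [0,1].
#' @param config a [ppo_config()].
#' @return +1 or -1.
#' @export
compute_reward <- function(batch_accuracy, config = ppo_config()) {
  stopifnot(batch_accuracy >= 0, batch_accuracy <= 1)
  if (batch_accuracy > config$benchmark_accuracy) 1 else -1
}

#' One-step advantage
#'
#' Episodes are single-step, so the advantage of a transition is its
#' reward minus the critic's value estimate, with no discounting.
#'
#' @param transition list with `reward` and `value`.
#' @return scalar advantage.
#' @export
advantage <- function(transition) transition$reward - transition$value

# Collate a list of transitions (or pass through an already-batched set).
transitions_batch <- function(transitions) {
  if (!is.null(transitions$states)) return(transitions)
  list(states = do.call(cbind, lapply(transitions, `[[`, "state")),
       pre_tanh = do.call(cbind, lapply(transitions, `[[`, "pre_tanh")),
       log_density = vapply(transitions, `[[`, 0, "log_density"),
       reward = vapply(transitions, `[[`, 0, "reward"),
       value = vapply(transitions, `[[`, 0, "value"))
}

batch_advantages <- function(tb, config) {
  adv <- tb$reward - tb$value
  if (!config$normalize_advantage) return(adv)
  if (stats::sd(tb$reward) > 0 && stats::sd(adv) > 0) {
    # informative batch (both reward signs): standardize to unit scale
    (adv - mean(adv)) / stats::sd(adv)
  } else {
    # uniform rewards carry no preference between the sampled actions: an
    # ideal baseline cancels them exactly.  Center the advantages so the
    # residual critic error cannot push the policy mean off in one
    # direction (the all-negative-reward saturation pathology).
    adv - mean(adv)
  }
}

#' PPO-Clip surrogate objective
#'
#' The mean over transitions of `min(rho * A, clip(rho, 1 - eps, 1 + eps)
#' * A)`, where `rho` is the importance ratio of the current policy to the
#' snapshot policy that sampled the actions.  At `policy == snapshot` the
#' ratio is 1 and the objective equals the mean advantage.
#'
#' @param transitions list of transition records (each with `state`,
#'   `pre_tanh`, `log_density`, `reward`, `value`), or a collated batch.
#' @param policy current `drl_policy`.
#' @param config a [ppo_config()].
#' @return scalar objective (to be maximized).
#' @export
ppo_clip_objective <- function(transitions, policy, config = ppo_config()) {
  tb <- transitions_batch(transitions)
  fw <- policy_mlp(policy, tb$states)
  logp <- gauss_tanh_logp(tb$pre_tanh, fw$m, policy$params$log_std)
  rho <- exp(logp - tb$log_density)
  if (any(!is.finite(rho))) {
    stop("non-finite importance ratio in the PPO objective", call. = FALSE)
  }
  adv <- batch_advantages(tb, config)
  mean(pmin(rho * adv,
            pmin(pmax(rho, 1 - config$epsilon), 1 + config$epsilon) * adv))
}

# Gradient of the clipped surrogate (plus optional entropy bonus) with
# respect to the policy parameters; returns a tree shaped like
# policy$params.  d obj / d logp_i is rho_i * A_i / N wherever the clip is
# inactive, 0 where it binds.
ppo_policy_grads <- function(policy, tb, config) {
  fw <- policy_mlp(policy, tb$states)
  sd2 <- exp(2 * policy$params$log_std)
  logp <- gauss_tanh_logp(tb$pre_tanh, fw$m, policy$params$log_std)
  rho <- exp(logp - tb$log_density)
  adv <- batch_advantages(tb, config)
  n <- length(adv)
  clipped <- (rho > 1 + config$epsilon & adv > 0) |
    (rho < 1 - config$epsilon & adv < 0)
  wts <- ifelse(clipped, 0, rho * adv) / n

  diff <- tb$pre_tanh - fw$m                     # action-dim x n
  dm <- sweep(diff / sd2, 2, wts, `*`)
  dlog_std <- as.numeric((sweep(diff, 1, sqrt(sd2), `/`)^2 - 1) %*% wts) +
    config$entropy_coef
  p <- policy$params
  l3b <- linear_bwd(fw$cache$h2, p$l3, dm)
  dh2 <- relu_bwd(l3b$dx, fw$cache$h2)
  l2b <- linear_bwd(fw$cache$h1, p$l2, dh2)
  dh1 <- relu_bwd(l2b$dx, fw$cache$h1)
  l1b <- linear_bwd(fw$cache$states, p$l1, dh1)
  list(l1 = list(W = l1b$dW, b = l1b$db),
       l2 = list(W = l2b$dW, b = l2b$db),
       l3 = list(W = l3b$dW, b = l3b$db),
       log_std = dlog_std)
}

# Critic forward: value estimates for a states matrix.
critic_values <- function(critic, states) {
  if (!is.matrix(states)) states <- matrix(states, ncol = 1)
  p <- critic$params
  a1 <- linear_fwd(states, p$l1)
  as.numeric(linear_fwd(leaky_fwd(a1), p$l2))
}

#' Critic loss
#'
#' Mean squared error between the critic's value estimates and the
#' observed rewards.
#'
#' @param transitions list of transitions or a collated batch.
#' @param critic a `drl_critic`.
#' @return scalar loss.
#' @export
critic_loss <- function(transitions, critic) {
  tb <- transitions_batch(transitions)
  v <- critic_values(critic, tb$states)
  mean((v - tb$reward)^2)
}

critic_grads <- function(critic, tb) {
  p <- critic$params
  a1 <- linear_fwd(tb$states, p$l1)
  h1 <- leaky_fwd(a1)
  v <- as.numeric(linear_fwd(h1, p$l2))
  dv <- matrix(2 * (v - tb$reward) / length(v), 1)
  l2b <- linear_bwd(h1, p$l2, dv)
  dh1 <- leaky_bwd(l2b$dx, a1)
  l1b <- linear_bwd(tb$states, p$l1, dh1)
  list(l1 = list(W = l1b$dW, b = l1b$db),
       l2 = list(W = l2b$dW, b = l2b$db))
}

# One PPO update phase: several Adam ascent steps on the clipped surrogate
# from a fixed snapshot, plus critic regression to the rewards.
ppo_update <- function(policy, critic, transitions, config, lr,
                       policy_opt, critic_opt) {
  tb <- transitions_batch(transitions)
  obj0 <- ppo_clip_objective(tb, policy, config)
  for (k in seq_len(config$epochs_per_update)) {
    pg <- ppo_policy_grads(policy, tb, config)
    neg <- tree_map(pg, function(g) if (is_weight(g)) -g else g)
    st <- adam_step(policy$params, neg, policy_opt, lr)
    policy$params <- st$params
    policy_opt <- st$state
    cg <- critic_grads(critic, tb)
    stc <- adam_step(critic$params, cg, critic_opt, config$critic_lr)
    critic$params <- stc$params
    critic_opt <- stc$state
  }
  list(policy = policy, critic = critic, policy_opt = policy_opt,
       critic_opt = critic_opt, objective = obj0,
       critic_loss = critic_loss(tb, critic))
}
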