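test_that("the policy's deterministic action is zero at initialization", {
  pol <- policy_init(8L, 4L, hidden = c(6L, 6L), seed = 1)
  st <- withr::with_seed(2, matrix(rnorm(8), 8, 1))
  act <- policy_act(pol, st, mode = "deterministic")
  expect_equal(act$action, matrix(0, 4, 1))
  expect_error(policy_act(pol, c(NA, 1:7)), "non-finite")
})

test_that("sampled actions shrink to the deterministic action as the noise vanishes", {
  pol <- policy_init(3L, 4L, hidden = c(5L, 5L), seed = 2)
  pol$params$l3 <- withr::with_seed(3, drlroi:::linear_init(5L, 4L))
  pol$params$log_std <- rep(-20, 4)   # sd -> 0 limit
  st <- withr::with_seed(4, matrix(rnorm(3), 3, 1))
  det <- policy_act(pol, st, "deterministic")
  sam <- withr::with_seed(5, policy_act(pol, st, "sample"))
  expect_equal(sam$action, det$action, tolerance = 1e-7)
})

test_that("the log density matches the Gaussian + Tanh change of variables", {
  pol <- policy_init(3L, 2L, hidden = c(5L, 5L), seed = 2)
  pol$params$l3 <- withr::with_seed(3, drlroi:::linear_init(5L, 2L))
  st <- withr::with_seed(4, matrix(rnorm(6), 3, 2))
  act <- withr::with_seed(9, policy_act(pol, st, "sample"))
  m <- drlroi:::policy_mlp(pol, st)$m
  sd_ <- exp(pol$params$log_std)
  for (n in 1:2) {
    lp <- sum(stats::dnorm(act$pre_tanh[, n], m[, n], sd_, log = TRUE)) -
      sum(log(1 - tanh(act$pre_tanh[, n])^2 + 1e-7))
    expect_equal(act$log_density[n], lp, tolerance = 1e-12)
  }
  # log densities are finite and match the returned action
  expect_true(all(is.finite(act$log_density)))
  expect_equal(act$action, tanh(act$pre_tanh))
})

test_that("action gating follows the 1 + a weight map", {
  fm <- withr::with_seed(1, array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  # zero action is the identity
  expect_identical(apply_action(fm, rep(0, 4), "channel"), fm)
  expect_identical(apply_action(fm, rep(0, 4), "spatial"), fm)
  # action -> -1 suppresses the map toward zero
  sup <- apply_action(fm, rep(-1 + 1e-9, 4), "channel")
  expect_lt(max(abs(sup)), 1e-8)
  # spatial mode: weights upsampled with the documented bilinear kernel
  a <- c(0.5, -0.2, 0.1, 0.3)
  G <- resize_bilinear(matrix(1 + a, 2, 2), 8, 8)
  out <- apply_action(fm, a, "spatial")
  for (ch in 1:4) expect_equal(out[, , ch], fm[, , ch] * G, tolerance = 1e-12)
  # channel mode scales each channel by its weight
  outc <- apply_action(fm, a, "channel")
  expect_equal(outc[, , 2], fm[, , 2] * 0.8, tolerance = 1e-12)
  expect_error(apply_action(fm, rep(0, 3), "spatial"), "perfect square")
})

test_that("the reward is a step function with its breakpoint at the benchmark", {
  cfg <- ppo_config()
  expect_identical(compute_reward(0.95, cfg), 1)
  expect_identical(compute_reward(0.85, cfg), -1)
  expect_identical(compute_reward(0.90, cfg), -1)   # boundary not exceeded
  accs <- seq(0, 1, by = 0.01)
  r <- vapply(accs, compute_reward, 0, config = cfg)
  expect_setequal(unique(r), c(-1, 1))
  expect_equal(sum(diff(r) != 0), 1L)               # single breakpoint
  expect_identical(accs[which(diff(r) != 0) + 1L], 0.91)
})

test_that("advantages are reward minus value, with optional standardization", {
  expect_equal(advantage(list(reward = 1, value = 0.3)), 0.7)
  expect_equal(advantage(list(reward = -1, value = -1)), 0)
  tb <- list(states = matrix(0, 2, 6), reward = c(1, 1, -1, -1, 1, -1),
             value = rnorm(6, 0, 0.2))
  adv <- drlroi:::batch_advantages(tb, ppo_config(normalize_advantage = TRUE))
  expect_equal(mean(adv), 0, tolerance = 1e-12)
  expect_equal(stats::sd(adv), 1, tolerance = 1e-12)
  raw <- drlroi:::batch_advantages(tb, ppo_config(normalize_advantage = FALSE))
  expect_equal(raw, tb$reward - tb$value)
})

test_that("the clipped surrogate matches hand-evaluated values", {
  # craft transitions with controlled importance ratios by shifting the
  # stored snapshot log densities
  pol <- policy_init(2L, 2L, hidden = c(4L, 4L), seed = 5)
  st <- withr::with_seed(6, matrix(rnorm(2), 2, 1))
  act <- withr::with_seed(7, policy_act(pol, st, "sample"))
  base <- list(states = st, pre_tanh = act$pre_tanh,
               log_density = act$log_density, reward = 1, value = 0)
  cfg <- ppo_config(epsilon = 0.2, normalize_advantage = FALSE)

  # rho = 1: objective equals the advantage
  expect_equal(ppo_clip_objective(base, pol, cfg), 1, tolerance = 1e-12)
  # rho = 1 with A = 2
  b2 <- base; b2$reward <- 2
  expect_equal(ppo_clip_objective(b2, pol, cfg), 2, tolerance = 1e-12)
  # rho = 1.5, A = 1 -> clipped to 1.2
  b3 <- base; b3$log_density <- act$log_density - log(1.5)
  expect_equal(ppo_clip_objective(b3, pol, cfg), 1.2, tolerance = 1e-9)
  # rho = 0.5, A = -1 -> min(-0.5, -0.8) = -0.8
  b4 <- base; b4$log_density <- act$log_density - log(0.5)
  b4$reward <- -1
  expect_equal(ppo_clip_objective(b4, pol, cfg), -0.8, tolerance = 1e-9)
})

test_that("the surrogate never exceeds the unclipped objective", {
  pol <- policy_init(3L, 2L, hidden = c(4L, 4L), seed = 8)
  cfg <- ppo_config(normalize_advantage = FALSE)
  for (rep in 1:20) {
    st <- withr::with_seed(100 + rep, matrix(rnorm(3 * 5), 3, 5))
    act <- withr::with_seed(200 + rep, policy_act(pol, st, "sample"))
    tb <- withr::with_seed(300 + rep, list(
      states = st, pre_tanh = act$pre_tanh,
      log_density = act$log_density + rnorm(5, 0, 0.5),
      reward = sample(c(-1, 1), 5, TRUE), value = rnorm(5, 0, 0.5)))
    fw <- drlroi:::policy_mlp(pol, tb$states)
    logp <- drlroi:::gauss_tanh_logp(tb$pre_tanh, fw$m, pol$params$log_std)
    rho <- exp(logp - tb$log_density)
    unclipped <- mean(rho * (tb$reward - tb$value))
    expect_lte(ppo_clip_objective(tb, pol, cfg), unclipped + 1e-12)
  }
})

test_that("policy and critic gradients agree with finite differences", {
  pol <- policy_init(3L, 4L, hidden = c(5L, 5L), seed = 2)
  pol$params$l3 <- withr::with_seed(3, drlroi:::linear_init(5L, 4L))
  cr <- critic_init(3L, hidden = 4L, seed = 3)
  st <- withr::with_seed(5, matrix(rnorm(3 * 6), 3, 6))
  act <- withr::with_seed(6, policy_act(pol, st, "sample"))
  tb <- withr::with_seed(7, list(
    states = st, pre_tanh = act$pre_tanh,
    log_density = act$log_density + rnorm(6, 0, 0.3),
    reward = sample(c(-1, 1), 6, TRUE), value = rnorm(6, 0, 0.3)))
  cfg <- ppo_config(normalize_advantage = FALSE)

  pg <- drlroi:::ppo_policy_grads(pol, tb, cfg)
  # spot-check representative leaves of each parameter group
  eps <- 1e-6
  for (spec in list(list("l1", "W", 7L), list("l2", "b", 2L),
                    list("l3", "W", 11L), list("log_std", NULL, 2L))) {
    pp <- pol; pm <- pol
    if (is.null(spec[[2]])) {
      pp$params[[spec[[1]]]][spec[[3]]] <-
        pp$params[[spec[[1]]]][spec[[3]]] + eps
      pm$params[[spec[[1]]]][spec[[3]]] <-
        pm$params[[spec[[1]]]][spec[[3]]] - eps
      g_an <- pg[[spec[[1]]]][spec[[3]]]
    } else {
      pp$params[[spec[[1]]]][[spec[[2]]]][spec[[3]]] <-
        pp$params[[spec[[1]]]][[spec[[2]]]][spec[[3]]] + eps
      pm$params[[spec[[1]]]][[spec[[2]]]][spec[[3]]] <-
        pm$params[[spec[[1]]]][[spec[[2]]]][spec[[3]]] - eps
      g_an <- pg[[spec[[1]]]][[spec[[2]]]][spec[[3]]]
    }
    g_num <- (ppo_clip_objective(tb, pp, cfg) -
                ppo_clip_objective(tb, pm, cfg)) / (2 * eps)
    expect_equal(g_an, g_num, tolerance = 1e-5)
  }

  # critic: analytic gradient matches finite differences, and a descent
  # step reduces the loss on a fixed batch
  cg <- drlroi:::critic_grads(cr, tb)
  cp <- cr; cp$params$l1$W[3] <- cp$params$l1$W[3] + eps
  cm <- cr; cm$params$l1$W[3] <- cm$params$l1$W[3] - eps
  expect_equal(cg$l1$W[3],
               (critic_loss(tb, cp) - critic_loss(tb, cm)) / (2 * eps),
               tolerance = 1e-5)
  stepped <- cr
  stepped$params <- drlroi:::tree_map2(cr$params, cg, function(p, g) {
    if (is.double(p)) p - 0.01 * g else p
  })
  expect_lt(critic_loss(tb, stepped), critic_loss(tb, cr))

  # oracles: a critic that outputs 0 has loss 0 on zero rewards and loss 1
  # on +/-1 rewards
  zero_cr <- cr
  zero_cr$params <- drlroi:::tree_map(cr$params, function(p) {
    if (is.double(p)) p * 0 else p
  })
  zb <- list(states = matrix(0, 3, 2), reward = c(0, 0), value = c(0, 0))
  expect_equal(critic_loss(zb, zero_cr), 0)
  zb$reward <- c(1, -1)
  expect_equal(critic_loss(zb, zero_cr), 1)
})
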