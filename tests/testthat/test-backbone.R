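test_that("attention rows sum to one and degenerate inputs give uniform weights", {
  set.seed(4)
  X <- matrix(rnorm(6 * 3), 6, 3)
  layer <- list(WQ = matrix(rnorm(9), 3), WK = matrix(rnorm(9), 3),
                WV = matrix(rnorm(9), 3))
  at <- self_attention(X, layer)
  expect_equal(rowSums(at$A), rep(1, 6), tolerance = 1e-12)

  # identical tokens: every attention row is uniform
  Xc <- matrix(rep(c(1, -2, 0.5), each = 5), 5, 3)
  expect_equal(self_attention(Xc, layer)$A, matrix(1 / 5, 5, 5),
               tolerance = 1e-12)

  # WQ = 0 gives QK' = 0, hence uniform attention regardless of X
  layer0 <- layer
  layer0$WQ <- layer0$WQ * 0
  expect_equal(self_attention(X, layer0)$A, matrix(1 / 6, 6, 6),
               tolerance = 1e-12)

  expect_error(self_attention(X, list(WQ = diag(2), WK = diag(2),
                                      WV = diag(2))),
               "dimension")
})

test_that("attention matches a hand evaluation on two tokens", {
  X <- matrix(c(1, -1, 2, 0.5), 2, 2)
  layer <- list(WQ = matrix(c(0.3, -0.2, 0.1, 0.4), 2),
                WK = matrix(c(-0.5, 0.2, 0.7, 0.1), 2),
                WV = matrix(c(1, 0, 0, 1), 2))
  at <- self_attention(X, layer)
  # independent evaluation of softmax(Q K' / sqrt(d_k)) V + X
  Q <- X %*% layer$WQ
  K <- X %*% layer$WK
  S <- Q %*% t(K) / sqrt(2)
  A <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(at$A, A, tolerance = 1e-12)
  expect_equal(at$Y, X + A %*% (X %*% layer$WV), tolerance = 1e-12)
})

test_that("cross-entropy loss matches closed-form oracles", {
  expect_equal(cross_entropy_loss(c(0, 0), 0L)$loss, log(2),
               tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(10, -10), 0L)$loss, log(1 + exp(-20)),
               tolerance = 1e-15)
  expect_equal(cross_entropy_loss(c(1, 3), 1L)$loss, log(1 + exp(-2)),
               tolerance = 1e-12)
  # one-hot-favoring logits score strictly below uniform logits
  expect_lt(cross_entropy_loss(c(3, 1), 0L)$loss,
            cross_entropy_loss(c(0, 0), 0L)$loss)
  expect_error(cross_entropy_loss(c(0, 0), 2L), "out of range")
})

test_that("forward pass produces the documented shapes and pooled state", {
  cfg <- tiny_backbone()
  net <- backbone_init(cfg, seed = 1)
  imgs <- withr::with_seed(2, lapply(1:3, function(i) {
    matrix(stats::runif(32 * 32), 32, 32)
  }))
  fw <- backbone_forward(net, imgs)
  expect_identical(dim(fw$logits), c(2L, 3L))
  d <- attr(fw$feature_map, "dims")
  # two stride-2 stages: 32 -> 8 spatial, final channel count 16
  expect_equal(unname(d), c(8L, 8L, 16L))
  expect_identical(dim(fw$pooled_state), c(16L, 3L))
  # pooled state is the per-channel spatial mean of the feature map
  arr <- array(fw$feature_map[, 2], c(8, 8, 16))
  expect_equal(fw$pooled_state[, 2], apply(arr, 3, mean), tolerance = 1e-12)
  expect_error(backbone_forward(net, list(matrix(0, 16, 16))),
               "input_size")
})

test_that("all-ones gating is a bit-exact no-op on the logits", {
  cfg <- tiny_backbone()
  net <- backbone_init(cfg, seed = 3)
  imgs <- withr::with_seed(5, lapply(1:2, function(i) {
    matrix(stats::runif(32 * 32), 32, 32)
  }))
  plain <- backbone_forward(net, imgs)
  gated <- backbone_forward(net, imgs,
                            weights = matrix(0, 16, 2), action_mode = "spatial")
  expect_identical(plain$logits, gated$logits)
  ch <- backbone_forward(net, imgs,
                         weights = matrix(0, 16, 2), action_mode = "channel")
  expect_identical(plain$logits, ch$logits)
})

test_that("disabling attention reduces the net to a plain residual network", {
  cfg_on <- tiny_backbone()
  cfg_off <- tiny_backbone(attention_enabled = FALSE)
  net_off <- backbone_init(cfg_off, seed = 1)
  expect_null(net_off$params$attn)
  img <- withr::with_seed(1, list(matrix(stats::runif(32 * 32), 32, 32)))
  fw <- backbone_forward(net_off, img)
  expect_identical(dim(fw$logits), c(2L, 1L))
})

test_that("class activation maps are linear in the feature map and scale-free", {
  set.seed(8)
  fm <- array(stats::runif(8 * 8 * 4), c(8, 8, 4))
  W <- rbind(c(0, 0, 1, 0), c(0.2, -0.3, 0.4, 0.1))
  # one-hot head weights: CAM proportional to that channel's activation
  cam <- class_activation_map(fm, W, target_class = 0L, out_size = 8L)
  ch <- fm[, , 3]
  expect_equal(cam, (ch - min(ch)) / (max(ch) - min(ch)), tolerance = 1e-12)
  # doubling the head weights leaves the normalized CAM unchanged
  cam1 <- class_activation_map(fm, W, 1L, out_size = 16L)
  cam2 <- class_activation_map(fm, 2 * W, 1L, out_size = 16L)
  expect_equal(cam1, cam2, tolerance = 1e-12)
  expect_true(all(cam1 >= 0 & cam1 <= 1))
})

test_that("backbone gradients agree with finite differences end to end", {
  cfg <- backbone_config(in_channels = 1, stem_channels = 2,
                         stage_channels = c(2, 3, 4), blocks_per_stage = 1,
                         input_size = 8)
  net <- backbone_init(cfg, seed = 7)
  imgs <- withr::with_seed(42, lapply(1:3, function(i) {
    matrix(stats::runif(64), 8, 8)
  }))
  X <- drlroi:::images_to_batch(imgs, cfg)
  lbl <- c(0L, 1L, 1L)
  lossf <- function(net) {
    fw <- backbone_forward(net, X, train = TRUE, keep_cache = TRUE)
    ce <- cross_entropy_loss(fw$logits, lbl)
    list(loss = ce$loss, fw = fw, ce = ce)
  }
  r <- lossf(net)
  grads <- drlroi:::backbone_backward(net, r$fw$cache, r$ce$dlogits)
  flat_paths <- function(tree, prefix = integer()) {
    if (is.list(tree)) {
      unlist(lapply(seq_along(tree), function(i) {
        flat_paths(tree[[i]], c(prefix, i))
      }), recursive = FALSE)
    } else list(prefix)
  }
  get_leaf <- function(tree, path) { for (i in path) tree <- tree[[i]]; tree }
  set_leaf <- function(tree, path, v) {
    if (length(path) == 1) { tree[[path]] <- v; return(tree) }
    tree[[path[1]]] <- set_leaf(tree[[path[1]]], path[-1], v)
    tree
  }
  paths <- flat_paths(net$params)
  checked <- 0L
  set.seed(1)
  while (checked < 12L) {
    pi_ <- sample(length(paths), 1)
    leaf <- get_leaf(net$params, paths[[pi_]])
    if (!is.double(leaf)) next
    li <- sample(length(leaf), 1)
    g_an <- get_leaf(grads, paths[[pi_]])[li]
    lp <- leaf; lp[li] <- lp[li] + 1e-5
    lm <- leaf; lm[li] <- lm[li] - 1e-5
    np <- net; np$params <- set_leaf(net$params, paths[[pi_]], lp)
    nm <- net; nm$params <- set_leaf(net$params, paths[[pi_]], lm)
    g_num <- (lossf(np)$loss - lossf(nm)$loss) / 2e-5
    expect_equal(g_an, g_num, tolerance = 1e-4)
    checked <- checked + 1L
  }
})
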