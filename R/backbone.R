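#' Configuration of the attention-augmented residual backbone
#'
#' A CIFAR-style residual network: a 3x3 convolution stem, three residual
#' stages (the second and third halve the spatial resolution), one
#' self-attention layer over the final-stage spatial tokens, global average
#' pooling and a linear two-class head.  Total convolutional depth is
#' `2 + 6 * blocks_per_stage`; the default `blocks_per_stage = 9` gives the
#' depth-56 network, and the default channel plan (16; 64, 128, 256 on a
#' 128-pixel input) is the full-scale architecture, ending in a
#' 256-channel 32 x 32 feature map.  Smaller settings are used for desk
#' experiments.
#'
#' @param in_channels input image channels (1 for grayscale).
#' @param stem_channels channels of the stem convolution.
#' @param stage_channels length-3 channel plan of the residual stages.  The
#'   final value is also the dimensionality of the pooled state vector and
#'   of the agent's action.
#' @param blocks_per_stage residual blocks (two 3x3 convolutions each) per
#'   stage.
#' @param n_classes number of output classes.
#' @param attention_enabled if `FALSE` the attention layer is skipped and
#'   the model reduces to a plain residual network (ablation hook).
#' @param input_size input side length in pixels.
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(in_channels = 1L,
                            stem_channels = 16L,
                            stage_channels = c(64L, 128L, 256L),
                            blocks_per_stage = 9L,
                            n_classes = 2L,
                            attention_enabled = TRUE,
                            input_size = 128L) {
  cfg <- list(in_channels = as.integer(in_channels),
              stem_channels = as.integer(stem_channels),
              stage_channels = as.integer(stage_channels),
              blocks_per_stage = as.integer(blocks_per_stage),
              n_classes = as.integer(n_classes),
              attention_enabled = isTRUE(attention_enabled),
              input_size = as.integer(input_size))
  stopifnot(length(cfg$stage_channels) == 3L,
            all(cfg$stage_channels > 0L), cfg$stem_channels > 0L,
            cfg$blocks_per_stage >= 1L, cfg$input_size >= 8L)
  cfg$depth <- 2L + 6L * cfg$blocks_per_stage
  structure(cfg, class = "backbone_config")
}

#' Initialize backbone parameters
#'
#' He-normal initialization for convolutions, unit batch-norm scales, and a
#' small-variance linear head; deterministic given `seed`.
#'
#' @param config a [backbone_config()].
#' @param seed integer seed for the parameter draw.
#' @return object of class `drl_backbone` holding `params`, batch-norm
#'   `buffers` and the `config`.
#' @export
backbone_init <- function(config = backbone_config(), seed = 1L) {
  withr::with_seed(derive_seed(seed, "backbone"), {
    sc <- config$stage_channels
    params <- list(
      stem = conv_init(config$in_channels, config$stem_channels, 3L),
      stem_bn = bn_init(config$stem_channels),
      stages = vector("list", 3L),
      head = linear_init(sc[3], config$n_classes, sd = 0.01)
    )
    buffers <- list(stem_bn = bn_buffers_init(config$stem_channels),
                    stages = vector("list", 3L))
    in_ch <- config$stem_channels
    for (s in 1:3) {
      blocks <- vector("list", config$blocks_per_stage)
      bbuf <- vector("list", config$blocks_per_stage)
      for (b in seq_len(config$blocks_per_stage)) {
        stride <- if (s > 1L && b == 1L) 2L else 1L
        blk <- list(conv1 = conv_init(in_ch, sc[s], 3L, stride = stride),
                    bn1 = bn_init(sc[s]),
                    conv2 = conv_init(sc[s], sc[s], 3L),
                    bn2 = bn_init(sc[s]))
        bf <- list(bn1 = bn_buffers_init(sc[s]), bn2 = bn_buffers_init(sc[s]))
        if (stride != 1L || in_ch != sc[s]) {
          blk$proj <- conv_init(in_ch, sc[s], 1L, stride = stride, pad = 0L)
          blk$proj_bn <- bn_init(sc[s])
          bf$proj_bn <- bn_buffers_init(sc[s])
        }
        blocks[[b]] <- blk
        bbuf[[b]] <- bf
        in_ch <- sc[s]
      }
      params$stages[[s]] <- blocks
      buffers$stages[[s]] <- bbuf
    }
    if (config$attention_enabled) params$attn <- attn_init(sc[3])
    structure(list(params = params, buffers = buffers, config = config),
              class = "drl_backbone")
  })
}

# Stack a list of samples / image matrices into the (C*H*W) x N batch
# layout, replicating channels if the backbone expects more than one.
images_to_batch <- function(images, config) {
  if (!is.null(images$samples)) images <- images$samples
  if (is.matrix(images)) images <- list(images)
  cols <- lapply(images, function(im) {
    if (is.list(im)) im <- im$image
    if (nrow(im) != config$input_size || ncol(im) != config$input_size) {
      stop("image size ", nrow(im), "x", ncol(im),
           " does not match backbone input_size ", config$input_size,
           call. = FALSE)
    }
    rep(as.numeric(im), config$in_channels)
  })
  do.call(cbind, cols)
}

# Residual block forward; returns output, new dims, updated buffers, cache.
# The backward pass rebuilds im2col patches in C++ (cheaper than shipping
# them across the C++/R boundary).
block_fwd <- function(x, bp, bb, H, W, train, update = TRUE, keep = FALSE) {
  Ho <- (H + 2L * bp$conv1$pad - bp$conv1$k) %/% bp$conv1$stride + 1L
  Wo <- (W + 2L * bp$conv1$pad - bp$conv1$k) %/% bp$conv1$stride + 1L
  HWo <- Ho * Wo
  c1 <- conv_fwd(x, bp$conv1, H, W)
  b1 <- bn_fwd(c1, bp$bn1, bb$bn1, HWo, train, update = update)
  r1 <- relu_fwd(b1$y)
  c2 <- conv_fwd(r1, bp$conv2, Ho, Wo)
  b2 <- bn_fwd(c2, bp$bn2, bb$bn2, HWo, train, update = update)
  if (!is.null(bp$proj)) {
    sc <- conv_fwd(x, bp$proj, H, W)
    sb <- bn_fwd(sc, bp$proj_bn, bb$proj_bn, HWo, train, update = update)
    shortcut <- sb$y
    bb$proj_bn <- sb$buf
    proj_cache <- sb$cache
  } else {
    shortcut <- x
    proj_cache <- NULL
  }
  y <- relu_fwd(b2$y + shortcut)
  bb$bn1 <- b1$buf
  bb$bn2 <- b2$buf
  list(y = y, H = Ho, W = Wo, buf = bb,
       cache = if (keep) {
         list(x = x, r1 = r1, y = y, bn1 = b1$cache, bn2 = b2$cache,
              proj_bn = proj_cache, H = H, W = W, Ho = Ho, Wo = Wo)
       })
}

block_bwd <- function(dy, bp, cache) {
  dsum <- relu_bwd(dy, cache$y)
  bn2b <- bn_bwd(dsum, bp$bn2, cache$bn2)
  c2b <- conv_bwd(cache$r1, bp$conv2, bn2b$dx, cache$Ho, cache$Wo)
  dr1 <- relu_bwd(c2b$dX, cache$r1)
  bn1b <- bn_bwd(dr1, bp$bn1, cache$bn1)
  c1b <- conv_bwd(cache$x, bp$conv1, bn1b$dx, cache$H, cache$W)
  grads <- list(conv1 = list(W = c1b$dW, b = c1b$db,
                             k = bp$conv1$k * 0L, stride = bp$conv1$stride * 0L,
                             pad = bp$conv1$pad * 0L, Cin = 0L, Cout = 0L),
                bn1 = list(gamma = bn1b$dgamma, beta = bn1b$dbeta),
                conv2 = list(W = c2b$dW, b = c2b$db,
                             k = 0L, stride = 0L, pad = 0L, Cin = 0L, Cout = 0L),
                bn2 = list(gamma = bn2b$dgamma, beta = bn2b$dbeta))
  if (!is.null(bp$proj)) {
    pbn <- bn_bwd(dsum, bp$proj_bn, cache$proj_bn)
    pc <- conv_bwd(cache$x, bp$proj, pbn$dx, cache$H, cache$W)
    grads$proj <- list(W = pc$dW, b = pc$db, k = 0L, stride = 0L, pad = 0L,
                       Cin = 0L, Cout = 0L)
    grads$proj_bn <- list(gamma = pbn$dgamma, beta = pbn$dbeta)
    dx <- c1b$dX + pc$dX
  } else {
    dx <- c1b$dX + dsum
  }
  list(dx = dx, grads = grads)
}

# Expand a per-sample gate into the full (C*HW) x N multiplier matrix.
expand_gate <- function(gate, HW, C) {
  if (is.null(gate)) return(NULL)
  if (gate$mode == "spatial") {
    gate$values[rep(seq_len(HW), C), , drop = FALSE]
  } else {
    gate$values[rep(seq_len(C), each = HW), , drop = FALSE]
  }
}

#' Forward pass of the backbone
#'
#' Runs stem, residual stages, the attention layer (if enabled), optional
#' multiplicative gating of the final feature map, global average pooling
#' and the linear head.  `pooled_state` is the per-channel spatial mean of
#' the (pre-gating) final feature map -- the state vector handed to the RL
#' agent.  When neither `weights` nor `policy` is given the gate is the
#' identity (all ones).
#'
#' @param net a `drl_backbone`.
#' @param images a `drlroi_cohort`, list of samples, list of matrices, or a
#'   prebuilt batch matrix.
#' @param weights optional gate: either a per-sample action matrix
#'   (action-dim x batch) interpreted through `action_mode`, or a gate
#'   object from [action_gate()].
#' @param policy optional policy network; its deterministic action is
#'   computed from the pooled state and applied as the gate.
#' @param action_mode `"spatial"` or `"channel"`; how actions map onto the
#'   feature map.
#' @param train logical; use batch statistics (and, unless `bn_update =
#'   FALSE`, update the running ones) in batch norm.
#' @param bn_update update the batch-norm running statistics (train mode
#'   only).  Set to `FALSE` for forward passes during the agent phase,
#'   when the classifier must stay bit-identical.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return list with `logits` (classes x batch), `feature_map`
#'   ((C*H*W) x batch matrix with a `dims` attribute), `pooled_state`
#'   (channels x batch), `action` (if a policy was applied), `gate`,
#'   `cache` (if requested) and `net` with updated batch-norm buffers.
#' @export
backbone_forward <- function(net, images, weights = NULL, policy = NULL,
                             action_mode = c("spatial", "channel"),
                             train = FALSE, keep_cache = FALSE,
                             bn_update = TRUE) {
  action_mode <- match.arg(action_mode)
  cfg <- net$config
  x <- if (is.matrix(images) &&
           nrow(images) == cfg$in_channels * cfg$input_size^2) {
    images
  } else {
    images_to_batch(images, cfg)
  }
  H <- cfg$input_size; W <- cfg$input_size
  cache <- list()

  c0 <- conv_fwd(x, net$params$stem, H, W)
  b0 <- bn_fwd(c0, net$params$stem_bn, net$buffers$stem_bn, H * W, train,
               update = bn_update)
  net$buffers$stem_bn <- b0$buf
  r0 <- relu_fwd(b0$y)
  if (keep_cache) {
    cache$stem <- list(x = x, bn = b0$cache, r = r0, H = H, W = W)
  }

  out <- r0
  block_caches <- list()
  for (s in 1:3) {
    for (b in seq_along(net$params$stages[[s]])) {
      bf <- block_fwd(out, net$params$stages[[s]][[b]],
                      net$buffers$stages[[s]][[b]], H, W, train,
                      update = bn_update, keep = keep_cache)
      out <- bf$y; H <- bf$H; W <- bf$W
      net$buffers$stages[[s]][[b]] <- bf$buf
      if (keep_cache) block_caches[[paste0(s, "_", b)]] <- bf$cache
    }
  }
  C <- cfg$stage_channels[3]
  HW <- H * W

  if (cfg$attention_enabled) {
    at <- attn_fwd(out, net$params$attn, HW, C)
    fmap <- at$y
    if (keep_cache) cache$attn <- at$cache
  } else {
    fmap <- out
  }
  pooled_state <- gap_fwd(fmap, HW, C)

  action <- NULL
  gate <- NULL
  if (!is.null(policy)) {
    action <- policy_act(policy, pooled_state, mode = "deterministic")$action
    gate <- action_gate(action, action_mode, H, W, C)
  } else if (!is.null(weights)) {
    gate <- if (is.list(weights)) weights else {
      action_gate(weights, action_mode, H, W, C)
    }
  }
  gfull <- expand_gate(gate, HW, C)
  gated <- if (is.null(gfull)) fmap else fmap * gfull
  pooled <- gap_fwd(gated, HW, C)
  logits <- linear_fwd(pooled, net$params$head)

  if (keep_cache) {
    cache$blocks <- block_caches
    cache$fmap <- fmap
    cache$gfull <- gfull
    cache$pooled <- pooled
    cache$H <- H; cache$W <- W; cache$C <- C
  }
  res <- list(logits = logits, feature_map = fmap,
              pooled_state = pooled_state, action = action, gate = gate,
              net = net)
  attr(res$feature_map, "dims") <- c(H = H, W = W, C = C)
  if (keep_cache) res$cache <- cache
  res
}

# Backward pass through the cached forward; returns a gradient tree shaped
# like net$params.  The gate is treated as a constant (no gradient flows
# into the agent from the classification loss).
backbone_backward <- function(net, cache, dlogits) {
  cfg <- net$config
  HW <- cache$H * cache$W; C <- cache$C
  hb <- linear_bwd(cache$pooled, net$params$head, dlogits)
  dgated <- gap_bwd(hb$dx, HW)
  dfmap <- if (is.null(cache$gfull)) dgated else dgated * cache$gfull
  grads <- list(head = list(W = hb$dW, b = hb$db))

  if (cfg$attention_enabled) {
    ab <- attn_bwd(dfmap, net$params$attn, cache$attn)
    dout <- ab$dx
    grads$attn <- list(WQ = ab$dWQ, WK = ab$dWK, WV = ab$dWV)
  } else {
    dout <- dfmap
  }

  grads$stages <- vector("list", 3L)
  for (s in 3:1) {
    nb <- length(net$params$stages[[s]])
    grads$stages[[s]] <- vector("list", nb)
    for (b in nb:1) {
      bw <- block_bwd(dout, net$params$stages[[s]][[b]],
                      cache$blocks[[paste0(s, "_", b)]])
      dout <- bw$dx
      grads$stages[[s]][[b]] <- bw$grads
    }
  }

  dr0 <- relu_bwd(dout, cache$stem$r)
  bnb <- bn_bwd(dr0, net$params$stem_bn, cache$stem$bn)
  cb <- conv_bwd(cache$stem$x, net$params$stem, bnb$dx,
                 cache$stem$H, cache$stem$W)
  grads$stem <- list(W = cb$dW, b = cb$db, k = 0L, stride = 0L, pad = 0L,
                     Cin = 0L, Cout = 0L)
  grads$stem_bn <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
  grads[names(net$params)]
}

#' Class activation map
#'
#' Projects the weights of the linear output layer back onto the final
#' convolutional feature map: `CAM = sum_c w[class, c] * F[,, c]`,
#' bilinearly upsampled to the requested size and min-max normalized to
#' [0,1].
#'
#' @param feature_map 3-D array (H x W x C), or the matrix-with-`dims`
#'   feature map returned by [backbone_forward()] (single sample).
#' @param head_weights classes x channels weight matrix of the output
#'   layer.
#' @param target_class class index in `0:(K-1)`.
#' @param out_size side length of the upsampled map.
#' @return `out_size` x `out_size` matrix in [0,1].
#' @export
class_activation_map <- function(feature_map, head_weights, target_class,
                                 out_size = 128L) {
  if (is.matrix(feature_map) && !is.null(attr(feature_map, "dims"))) {
    d <- attr(feature_map, "dims")
    feature_map <- array(feature_map[, 1], c(d["H"], d["W"], d["C"]))
  }
  stopifnot(length(dim(feature_map)) == 3L)
  C <- dim(feature_map)[3]
  w <- head_weights[target_class + 1L, ]
  cam <- matrix(0, dim(feature_map)[1], dim(feature_map)[2])
  for (cc in seq_len(C)) cam <- cam + w[cc] * feature_map[, , cc]
  cam <- resize_bilinear(cam, out_size, out_size)
  rng <- range(cam)
  if (rng[2] > rng[1]) (cam - rng[1]) / (rng[2] - rng[1]) else cam * 0
}
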