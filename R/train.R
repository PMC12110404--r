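#' Training configuration
#'
#' Optimizer protocol of the alternating training: momentum SGD for the
#' classifier (initial learning rate 0.1), Adam for the generator and
#' critic (initial learning rate 0.01), both rates decaying by a factor of
#' 0.1 every 100 epochs, batch size 32, weight decay 5e-4.  The defaults
#' are the full-scale protocol (600 epochs); desk experiments shrink
#' `epochs` and `batch_size`.
#'
#' @param epochs training epochs.
#' @param batch_size slices per batch.
#' @param classifier_lr initial classifier learning rate (momentum SGD).
#' @param generator_lr initial generator/critic learning rate (Adam).
#' @param lr_decay_factor multiplicative decay factor.
#' @param lr_decay_every decay period in epochs.
#' @param weight_decay L2 weight decay of the classifier optimizer.
#' @param momentum SGD momentum.
#' @param seed integer; seeds data order, augmentation, initialization and
#'   action sampling.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 600L, batch_size = 32L,
                         classifier_lr = 0.1, generator_lr = 0.01,
                         lr_decay_factor = 0.1, lr_decay_every = 100L,
                         weight_decay = 5e-4, momentum = 0.9, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              classifier_lr = classifier_lr, generator_lr = generator_lr,
              lr_decay_factor = lr_decay_factor,
              lr_decay_every = as.integer(lr_decay_every),
              weight_decay = weight_decay, momentum = momentum,
              seed = as.integer(seed))
  stopifnot(cfg$epochs >= 1L, cfg$batch_size >= 2L, cfg$classifier_lr > 0,
            cfg$generator_lr > 0, cfg$lr_decay_factor > 0,
            cfg$lr_decay_every >= 1L, cfg$weight_decay >= 0)
  if (cfg$lr_decay_every > cfg$epochs) {
    # legal: the rate simply never decays within the run
    cfg$lr_decay_every <- cfg$lr_decay_every
  }
  structure(cfg, class = "train_config")
}

#' Stepwise learning-rate schedule
#'
#' `base_lr * decay_factor ^ floor(epoch / decay_every)`; with the default
#' configuration the rate drops by a factor of 10 every 100 epochs.
#'
#' @param epoch 0-based epoch index.
#' @param base_lr initial rate.
#' @param config a [train_config()].
#' @return learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, base_lr, config = train_config()) {
  stopifnot(epoch >= 0)
  base_lr * config$lr_decay_factor ^ (epoch %/% config$lr_decay_every)
}

# Shuffle indices and cut them into batches; drops a trailing singleton
# (batch norm needs at least two samples).
make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  starts <- seq(1L, n, by = batch_size)
  batches <- lapply(starts, function(s) idx[s:min(s + batch_size - 1L, n)])
  batches[lengths(batches) >= 2L]
}

# Logits after multiplicative gating of an already-computed feature map.
gated_logits <- function(net, fmap, gate, HW, C) {
  gfull <- expand_gate(gate, HW, C)
  pooled <- gap_fwd(if (is.null(gfull)) fmap else fmap * gfull, HW, C)
  linear_fwd(pooled, net$params$head)
}

#' Fit the RL-weighted classifier
#'
#' Alternating training: in phase 1 of each epoch the generator is frozen
#' and the classifier is trained with softmax cross-entropy on batches
#' whose final feature map is gated by the generator's deterministic
#' action; in phase 2 the classifier is frozen, actions are sampled, each
#' batch's classification accuracy is turned into a +/-1 reward against
#' the 0.9 benchmark, and the generator and critic are updated by
#' PPO-Clip.  With `rl_enabled = FALSE` the loop reduces exactly to plain
#' classifier training (the no-RL baseline).
#'
#' @param cohort a `drlroi_cohort` of training slices already cropped to
#'   the backbone input size (see [preprocess_cohort()]).
#' @param backbone a [backbone_config()].
#' @param rl a [ppo_config()].
#' @param train a [train_config()].
#' @param augment optional [augment_config()] applied to phase-1 batches.
#' @param rl_enabled train the generator/critic and gate the classifier;
#'   otherwise plain residual-network training.
#' @param balance equalize per-class slice counts by minority upsampling
#'   before training.
#' @param warmup_epochs epochs of classifier-only training before the
#'   alternation begins.  The zero-initialized generator gates as the
#'   identity until its first update, so the warm start lets the
#'   classifier approach its working accuracy range -- where the 0.9
#'   reward benchmark is informative -- before the agent starts learning
#'   (the standard remedy for RL-rate instability at small sample sizes,
#'   alongside lowering the rate itself).
#' @param verbose print a line per epoch.
#' @param trace_freeze record checksums of the classifier and generator
#'   parameters at every phase boundary (attribute `freeze_trace` of the
#'   returned fit); used to audit the freeze contract of the alternating
#'   schedule.
#' @return object of class `drlroi_fit` with elements `net`, `policy`,
#'   `critic`, `history` (per-epoch data frame), the configurations and
#'   optimizer states.
#' @export
drlroi_fit <- function(cohort,
                       backbone = backbone_config(),
                       rl = ppo_config(),
                       train = train_config(),
                       augment = NULL,
                       rl_enabled = TRUE,
                       balance = TRUE,
                       warmup_epochs = 0L,
                       verbose = FALSE,
                       trace_freeze = FALSE) {
  stopifnot(inherits(cohort, "drlroi_cohort"))
  if (balance) {
    cohort <- withr::with_seed(derive_seed(train$seed, "balance"),
                               balance_upsample(cohort))
  }
  samples <- cohort$samples
  labels <- vapply(samples, `[[`, 0L, "label")
  n <- length(samples)
  C <- backbone$stage_channels[3]

  net <- backbone_init(backbone, seed = train$seed)
  policy <- NULL
  critic <- NULL
  policy_opt <- NULL
  critic_opt <- NULL
  if (rl_enabled) {
    policy <- policy_init(C, C, hidden = rl$hidden,
                          init_log_std = rl$init_log_std, seed = train$seed)
    critic <- critic_init(C, hidden = rl$critic_hidden, seed = train$seed)
    policy_opt <- adam_init(policy$params)
    critic_opt <- adam_init(critic$params)
  }
  cls_opt <- sgd_init(net$params)

  history <- vector("list", train$epochs)
  freeze_trace <- if (trace_freeze) vector("list", train$epochs) else NULL
  snapshot <- function() {
    list(net = config_hash(list(net$params, net$buffers)),
         agent = if (rl_enabled) {
           config_hash(list(policy$params, critic$params))
         } else NA_character_)
  }
  for (epoch in seq_len(train$epochs) - 1L) {
    if (trace_freeze) before_p1 <- snapshot()
    lr_c <- lr_schedule(epoch, train$classifier_lr, train)
    lr_g <- lr_schedule(epoch, train$generator_lr, train)

    # ---- phase 1: train the classifier, generator frozen -------------------
    p1 <- withr::with_seed(derive_seed(train$seed, paste0("e", epoch, "p1")), {
      losses <- c(); accs <- c()
      for (batch in make_batches(n, train$batch_size)) {
        bs <- samples[batch]
        if (!is.null(augment)) {
          bs <- lapply(bs, function(s) {
            s$image <- augment_image(s$image, augment)
            s
          })
        }
        X <- images_to_batch(bs, backbone)
        fw <- backbone_forward(net, X, policy = policy,
                               action_mode = rl$action_mode,
                               train = TRUE, keep_cache = TRUE)
        net <- fw$net
        ce <- cross_entropy_loss(fw$logits, labels[batch])
        if (!is.finite(ce$loss)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (classifier lr ", lr_c, ", generator lr ", lr_g, ")",
               call. = FALSE)
        }
        grads <- backbone_backward(net, fw$cache, ce$dlogits)
        st <- sgd_step(net$params, grads, cls_opt, lr_c,
                       momentum = train$momentum,
                       weight_decay = train$weight_decay)
        net$params <- st$params
        cls_opt <- st$state
        losses <- c(losses, ce$loss)
        pred <- max.col(t(ce$probs)) - 1L
        accs <- c(accs, mean(pred == labels[batch]))
      }
      list(loss = mean(losses), acc = mean(accs), net = net, opt = cls_opt)
    })
    net <- p1$net
    cls_opt <- p1$opt
    if (trace_freeze) after_p1 <- snapshot()

    # ---- phase 2: train the agent, classifier frozen -----------------------
    reward_rate <- NA_real_
    ppo_obj <- NA_real_
    cl <- NA_real_
    if (rl_enabled && epoch >= warmup_epochs) {
      p2 <- withr::with_seed(derive_seed(train$seed, paste0("e", epoch, "p2")), {
        trans <- list(states = NULL, pre_tanh = NULL, log_density = NULL,
                      reward = NULL, value = NULL)
        rewards <- c()
        for (batch in make_batches(n, train$batch_size)) {
          bs <- samples[batch]
          if (!is.null(augment)) {
            bs <- lapply(bs, function(s) {
              s$image <- augment_image(s$image, augment)
              s
            })
          }
          X <- images_to_batch(bs, backbone)
          # batch statistics, as in phase 1, but without touching the
          # frozen classifier's running buffers
          fw <- backbone_forward(net, X, train = TRUE, bn_update = FALSE)
          d <- attr(fw$feature_map, "dims")
          # one episode per batch: one sampled action, evaluated through
          # the batch's classification accuracy
          state <- matrix(rowMeans(fw$pooled_state), ncol = 1)
          act <- policy_act(policy, state, mode = "sample")
          gate <- action_gate(matrix(act$action[, 1], ncol = length(batch),
                                     nrow = nrow(act$action)),
                              rl$action_mode, d["H"], d["W"], d["C"])
          logits <- gated_logits(net, fw$feature_map, gate,
                                 d["H"] * d["W"], d["C"])
          pred <- max.col(t(logits)) - 1L
          acc <- mean(pred == labels[batch])
          r <- compute_reward(acc, rl)
          rewards <- c(rewards, r)
          v <- critic_values(critic, state)
          trans$states <- cbind(trans$states, state)
          trans$pre_tanh <- cbind(trans$pre_tanh, act$pre_tanh)
          trans$log_density <- c(trans$log_density, act$log_density)
          trans$reward <- c(trans$reward, r)
          trans$value <- c(trans$value, v)
        }
        up <- ppo_update(policy, critic, trans, rl, lr_g,
                         policy_opt, critic_opt)
        list(up = up, reward_rate = mean(rewards > 0))
      })
      policy <- p2$up$policy
      critic <- p2$up$critic
      policy_opt <- p2$up$policy_opt
      critic_opt <- p2$up$critic_opt
      ppo_obj <- p2$up$objective
      cl <- p2$up$critic_loss
      reward_rate <- p2$reward_rate
    }

    if (trace_freeze) {
      after_p2 <- snapshot()
      freeze_trace[[epoch + 1L]] <- data.frame(
        epoch = epoch,
        agent_frozen_in_phase1 = identical(before_p1$agent, after_p1$agent),
        net_frozen_in_phase2 = identical(after_p1$net, after_p2$net),
        net_hash_after_p1 = after_p1$net,
        net_hash_after_p2 = after_p2$net,
        agent_hash_before_p1 = before_p1$agent,
        agent_hash_after_p1 = after_p1$agent)
    }
    history[[epoch + 1L]] <- data.frame(
      epoch = epoch, loss = p1$loss, train_acc = p1$acc,
      reward_rate = reward_rate, ppo_objective = ppo_obj, critic_loss = cl,
      lr_classifier = lr_c, lr_generator = lr_g)
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  acc %.3f  reward_rate %s  lr %.4g/%.4g",
        epoch, p1$loss, p1$acc,
        ifelse(is.na(reward_rate), "-", sprintf("%.2f", reward_rate)),
        lr_c, lr_g))
    }
  }

  out <- structure(list(net = net, policy = policy, critic = critic,
                 rl_enabled = rl_enabled,
                 backbone_config = backbone, rl_config = rl,
                 train_config = train, augment_config = augment,
                 history = do.call(rbind, history),
                 classifier_opt = cls_opt, policy_opt = policy_opt,
                 critic_opt = critic_opt,
                 epochs_trained = train$epochs),
            class = "drlroi_fit")
  if (trace_freeze) attr(out, "freeze_trace") <- do.call(rbind, freeze_trace)
  out
}

#' @export
print.drlroi_fit <- function(x, ...) {
  cfg <- x$backbone_config
  cat("RL-weighted residual classifier\n")
  cat(sprintf("  backbone: depth %d, channels %s, input %dx%d, attention %s\n",
              cfg$depth, paste(cfg$stage_channels, collapse = "/"),
              cfg$input_size, cfg$input_size,
              ifelse(cfg$attention_enabled, "on", "off")))
  cat(sprintf("  RL gating: %s\n",
              if (x$rl_enabled) paste0("on (", x$rl_config$action_mode,
                                       " mode)") else "off (baseline)"))
  h <- utils::tail(x$history, 1)
  cat(sprintf("  trained %d epochs; final loss %.4f, train accuracy %.3f\n",
              x$epochs_trained, h$loss, h$train_acc))
  invisible(x)
}

#' @export
summary.drlroi_fit <- function(object, ...) {
  print(object)
  cat("\ntraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' Predict slice or patient probabilities
#'
#' Runs the backbone in evaluation mode (frozen batch-norm statistics,
#' deterministic gating when the agent is enabled) and returns positive-
#' class probabilities.  Patient probabilities are the arithmetic mean of
#' the patient's slice probabilities.
#'
#' @param object a `drlroi_fit`.
#' @param newdata a `drlroi_cohort` (or list of samples).
#' @param type `"patient"` (default) or `"slice"`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return data.frame with ids, `label` and `prob` (positive-class
#'   probability).
#' @export
predict.drlroi_fit <- function(object, newdata, type = c("patient", "slice"),
                               batch_size = 64L, ...) {
  type <- match.arg(type)
  samples <- if (inherits(newdata, "drlroi_cohort")) newdata$samples else newdata
  n <- length(samples)
  probs <- numeric(n)
  net <- object$net
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    X <- images_to_batch(samples[idx], object$backbone_config)
    fw <- backbone_forward(net, X, policy = object$policy,
                           action_mode = object$rl_config$action_mode,
                           train = FALSE)
    sm <- cross_entropy_loss(fw$logits, 0L)$probs
    probs[idx] <- sm[2L, ]
  }
  out <- data.frame(
    patient_id = vapply(samples, `[[`, "", "patient_id"),
    slice_id = vapply(samples, `[[`, "", "slice_id"),
    label = vapply(samples, `[[`, 0L, "label"),
    prob = probs, stringsAsFactors = FALSE)
  if (type == "slice") return(out)
  agg <- aggregate_patients(out)
  agg
}

# Patient-level aggregation of slice probabilities.
aggregate_patients <- function(slice_df) {
  sp <- split(slice_df, slice_df$patient_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(patient_id = d$patient_id[1], label = d$label[1],
               prob = patient_probability(d$prob),
               n_slices = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Plot training history
#'
#' @param x a `drlroi_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.drlroi_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", main = "classifier", ...)
  if (x$rl_enabled && any(!is.na(h$reward_rate))) {
    graphics::plot(h$epoch, h$reward_rate, type = "l", ylim = c(0, 1),
                   xlab = "epoch", ylab = "fraction of +1 rewards",
                   main = "agent", ...)
  } else {
    graphics::plot(h$epoch, h$train_acc, type = "l", ylim = c(0, 1),
                   xlab = "epoch", ylab = "training accuracy",
                   main = "accuracy", ...)
  }
  invisible(h)
}

#' Save / restore a fitted model
#'
#' The checkpoint carries all learned parameters, batch-norm buffers,
#' optimizer states and configurations, so `drlroi_restore()` reproduces
#' forward outputs bit-exactly and training can resume at the recorded
#' epoch of the learning-rate schedule.
#'
#' @param fit a `drlroi_fit`.
#' @param path file path of the checkpoint.
#' @return `drlroi_checkpoint()` returns `path` invisibly;
#'   `drlroi_restore()` returns the restored `drlroi_fit`.
#' @export
drlroi_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "drlroi_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname drlroi_checkpoint
#' @export
drlroi_restore <- function(path) {
  if (!file.exists(path)) {
    stop("checkpoint file not found: ", path, call. = FALSE)
  }
  fit <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt checkpoint archive: ", conditionMessage(e), call. = FALSE)
  })
  if (!inherits(fit, "drlroi_fit")) {
    stop("corrupt checkpoint archive: not a drlroi_fit object", call. = FALSE)
  }
  fit
}

#' Class activation map for one slice
#'
#' Computes the CAM of the (gated) final feature map for the predicted or
#' a requested class, upsampled to the input resolution.
#'
#' @param fit a `drlroi_fit`.
#' @param sample one cohort sample (list with `image`).
#' @param target_class class in {0,1}; default is the predicted class.
#' @return list with `cam` (input-size matrix in [0,1]), `predicted`
#'   class, and `prob` (positive-class probability).
#' @export
drlroi_cam <- function(fit, sample, target_class = NULL) {
  cfg <- fit$backbone_config
  X <- images_to_batch(list(sample), cfg)
  fw <- backbone_forward(fit$net, X, policy = fit$policy,
                         action_mode = fit$rl_config$action_mode,
                         train = FALSE)
  d <- attr(fw$feature_map, "dims")
  fmap <- fw$feature_map
  if (!is.null(fw$gate)) {
    fmap <- fmap * expand_gate(fw$gate, d["H"] * d["W"], d["C"])
  }
  probs <- cross_entropy_loss(fw$logits, 0L)$probs
  pred <- which.max(probs[, 1]) - 1L
  if (is.null(target_class)) target_class <- pred
  fm_arr <- array(fmap[, 1], c(d["H"], d["W"], d["C"]))
  cam <- class_activation_map(fm_arr, fit$net$params$head$W, target_class,
                              out_size = cfg$input_size)
  list(cam = cam, predicted = pred, prob = probs[2L, 1])
}
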