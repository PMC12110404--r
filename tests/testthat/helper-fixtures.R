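# Shared fixtures: small configurations used across the test files.

tiny_phantom <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_patients_per_class = 4L, slices_per_patient = 2L,
         image_size = 32L, roi_radius_range = c(5, 8),
         background_distractor_count = 4L, noise_sigma = 0.05,
         roi_center_jitter = 0.08, seed = seed),
    list(...))
  do.call(phantom_config, args)
}

tiny_backbone <- function(...) {
  args <- utils::modifyList(
    list(in_channels = 1L, stem_channels = 4L, stage_channels = c(4L, 8L, 16L),
         blocks_per_stage = 1L, input_size = 32L),
    list(...))
  do.call(backbone_config, args)
}

tiny_rl <- function(...) {
  do.call(ppo_config, utils::modifyList(list(hidden = c(16L, 16L)), list(...)))
}

# A quick patient-grouped score simulator: latent signal plus noise.
simulate_scores <- function(n_per_class, sep = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- rep(c(0L, 1L), each = n_per_class)
  scores <- stats::rnorm(2 * n_per_class) + sep * labels
  list(scores = scores, labels = labels)
}

# Held-out AUC of a pixel-level ridge read-out (closed-form linear probe,
# well-posed for any feature count); the cheap reference classifier used
# for the phantom identifiability properties.
pixel_readout_auc <- function(cohort, seed = 1L, downsample = 8L,
                              lambda = 1) {
  samples <- cohort$samples
  feats <- t(vapply(samples, function(s) {
    as.numeric(resize_bilinear(s$image, downsample, downsample))
  }, numeric(downsample^2)))
  labels <- vapply(samples, `[[`, 0L, "label")
  pids <- vapply(samples, `[[`, "", "patient_id")
  pat <- unique(data.frame(pid = pids, label = labels))
  set.seed(seed)
  val_pids <- unlist(lapply(split(pat$pid, pat$label), function(p) {
    sample(p, max(1L, length(p) %/% 3L))
  }))
  tr <- !(pids %in% val_pids)
  X <- scale(feats[tr, ], scale = FALSE)
  y <- labels[tr] - mean(labels[tr])
  beta <- solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, y))
  eta <- scale(feats[!tr, ], center = attr(X, "scaled:center"),
               scale = FALSE) %*% beta
  roc_auc(as.numeric(eta), labels[!tr])$auc
}
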