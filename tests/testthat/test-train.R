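# A very small trained fit reused across several tests in this file.
small_fit_cache <- new.env()
small_fit <- function(rl_enabled = TRUE) {
  key <- if (rl_enabled) "rl" else "plain"
  if (is.null(small_fit_cache[[key]])) {
    co <- preprocess_cohort(
      phantom_cohort(tiny_phantom(n_patients_per_class = 6L,
                                  slices_per_patient = 2L)),
      window = 32L)
    small_fit_cache[[key]] <- drlroi_fit(
      co, backbone = tiny_backbone(), rl = tiny_rl(),
      train = train_config(epochs = 3L, batch_size = 8L, seed = 1L),
      rl_enabled = rl_enabled)
    small_fit_cache[[paste0(key, "_cohort")]] <- co
  }
  small_fit_cache[[key]]
}

test_that("the learning-rate schedule decays stepwise", {
  tc <- train_config(epochs = 600L)
  expect_equal(lr_schedule(0, 0.1, tc), 0.1)
  expect_equal(lr_schedule(99, 0.1, tc), 0.1)
  expect_equal(lr_schedule(100, 0.1, tc), 0.01)
  expect_equal(lr_schedule(150, 0.1, tc), 0.01)
  expect_equal(lr_schedule(200, 0.1, tc), 0.001)
  expect_equal(lr_schedule(350, 0.01, tc), 1e-5)
  expect_equal(lr_schedule(0, 0.01, tc), 0.01)
  expect_error(lr_schedule(-1, 0.1, tc))
})

test_that("alternating training freezes each component in the other's phase", {
  co <- preprocess_cohort(
    phantom_cohort(tiny_phantom(n_patients_per_class = 6L,
                                slices_per_patient = 2L)),
    window = 32L)
  bb <- tiny_backbone()
  rl <- tiny_rl()
  fit <- drlroi_fit(co, backbone = bb, rl = rl,
                    train = train_config(epochs = 3L, batch_size = 8L,
                                         seed = 1L),
                    trace_freeze = TRUE)
  tr <- attr(fit, "freeze_trace")
  expect_equal(nrow(tr), 3L)
  # generator (and critic) checksums are bit-identical across every
  # classifier phase; classifier checksums across every agent phase
  expect_true(all(tr$agent_frozen_in_phase1))
  expect_true(all(tr$net_frozen_in_phase2))
  # while the phases themselves do change their own component
  expect_false(any(duplicated(tr$net_hash_after_p1)))
  expect_true(all(is.finite(fit$history$loss)))
  # both components end up different from their initializations
  net0 <- backbone_init(bb, seed = 1L)
  pol0 <- policy_init(bb$stage_channels[3], bb$stage_channels[3],
                      hidden = rl$hidden, seed = 1L)
  expect_false(identical(fit$net$params$head, net0$params$head))
  expect_false(identical(fit$policy$params, pol0$params))
})

test_that("with the agent disabled the loop is plain classifier training", {
  fit <- small_fit(FALSE)
  expect_null(fit$policy)
  expect_null(fit$critic)
  expect_true(all(is.na(fit$history$reward_rate)))
  # and predictions work without a gate
  co <- small_fit_cache$plain_cohort
  pr <- predict(fit, co, type = "slice")
  expect_equal(nrow(pr), length(co$samples))
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
})

test_that("patient predictions average the patient's slice probabilities", {
  fit <- small_fit(TRUE)
  co <- small_fit_cache$rl_cohort
  sl <- predict(fit, co, type = "slice")
  pa <- predict(fit, co, type = "patient")
  for (pid in pa$patient_id[1:3]) {
    expect_equal(pa$prob[pa$patient_id == pid],
                 mean(sl$prob[sl$patient_id == pid]), tolerance = 1e-12)
  }
})

test_that("checkpoints round-trip bit-exactly and resume the schedule", {
  fit <- small_fit(TRUE)
  co <- small_fit_cache$rl_cohort
  path <- withr::local_tempfile(fileext = ".rds")
  drlroi_checkpoint(fit, path)
  back <- drlroi_restore(path)
  X <- drlroi:::images_to_batch(co$samples[1:4], fit$backbone_config)
  expect_identical(
    backbone_forward(fit$net, X, policy = fit$policy)$logits,
    backbone_forward(back$net, X, policy = back$policy)$logits)
  # optimizer state and epoch counter survive, so the lr schedule resumes
  expect_identical(back$epochs_trained, fit$epochs_trained)
  expect_identical(back$classifier_opt, fit$classifier_opt)
  expect_error(drlroi_restore(withr::local_tempfile(fileext = ".rds")),
               "not found")
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not an rds", bad)
  expect_error(drlroi_restore(bad), "corrupt")
})

test_that("evaluation reports are internally consistent", {
  fit <- small_fit(TRUE)
  co <- small_fit_cache$rl_cohort
  rep <- suppressWarnings(eval_report(fit, co))
  expect_s3_class(rep, "drlroi_eval")
  expect_true(rep$patient$auc >= 0 && rep$patient$auc <= 1)
  expect_equal(sum(rep$patient$confusion),
               nrow(rep$patient_scores))
  expect_output(print(rep), "patient-level")
})

test_that("an easily separable phantom is learned within a few epochs", {
  hits <- vapply(1:5, function(seed) {
    co <- preprocess_cohort(
      phantom_cohort(tiny_phantom(seed = seed, n_patients_per_class = 8L,
                                  slices_per_patient = 3L,
                                  roi_contrast = 0.35, noise_sigma = 0.03,
                                  background_distractor_count = 2L)),
      window = 32L)
    fit <- drlroi_fit(co, backbone = tiny_backbone(), rl = tiny_rl(),
                      train = train_config(epochs = 12L, batch_size = 16L,
                                           seed = seed))
    any(fit$history$train_acc > 0.9)
  }, TRUE)
  expect_gte(sum(hits), 4L)
})

test_that("training diverges loudly on a pathological learning rate", {
  co <- preprocess_cohort(
    phantom_cohort(tiny_phantom(n_patients_per_class = 4L,
                                slices_per_patient = 2L)),
    window = 32L)
  expect_error(
    drlroi_fit(co, backbone = tiny_backbone(), rl = tiny_rl(),
               train = train_config(epochs = 6L, batch_size = 8L,
                                    classifier_lr = 1e4, seed = 1L),
               rl_enabled = FALSE),
    "diverged")
})
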