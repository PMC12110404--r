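test_that("patient probabilities are slice means, order-invariant", {
  expect_equal(patient_probability(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(patient_probability(0.7), 0.7)
  expect_equal(patient_probability(c(0.6, 0.2, 0.4)),
               patient_probability(c(0.2, 0.4, 0.6)))
  expect_error(patient_probability(numeric(0)), "no slice")
})

test_that("confusion metrics follow their standard definitions", {
  # 9 TP, 1 FN, 9 TN, 1 FP
  probs <- c(rep(0.9, 9), 0.1, rep(0.1, 9), 0.9)
  labels <- c(rep(1, 10), rep(0, 10))
  cm <- confusion_metrics(probs, labels)
  expect_equal(cm$accuracy, 0.9)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.9)
  expect_equal(sum(cm$confusion), 20)
  # all correct
  all_ok <- confusion_metrics(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(unlist(all_ok[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  # threshold 0 calls everything positive: sensitivity 1
  expect_equal(confusion_metrics(c(0.2, 0.8, 0.5), c(1, 1, 0),
                                 threshold = 0)$sensitivity, 1)
  expect_error(confusion_metrics(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("AUC equals brute-force pair counting, including ties", {
  brute_auc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    total <- 0
    for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
    total / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  set.seed(77)
  for (rep in 1:100) {
    n1 <- sample(3:12, 1)
    n0 <- sample(3:12, 1)
    # discrete score grid forces ties
    scores <- sample(seq(0, 1, by = 0.125), n1 + n0, replace = TRUE)
    labels <- c(rep(1, n1), rep(0, n0))
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an independent implementation and its invariances hold", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (rep in 1:20) {
    sim <- simulate_scores(15, sep = runif(1, 0, 2))
    ours <- roc_auc(sim$scores, sim$labels)$auc
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(sim$labels, sim$scores, quiet = TRUE,
                          direction = "<", levels = c(0, 1)))))
    expect_equal(ours, ref, tolerance = 1e-12)
    # complement and monotone-transform invariances
    expect_equal(roc_auc(-sim$scores, sim$labels)$auc, 1 - ours,
                 tolerance = 1e-12)
    expect_equal(roc_auc(exp(3 * sim$scores), sim$labels)$auc, ours,
                 tolerance = 1e-12)
  }
})

test_that("the ROC step curve is monotone from (0,0) to (1,1)", {
  set.seed(13)
  sim <- simulate_scores(20, sep = 1)
  roc <- roc_auc(sim$scores, sim$labels)$roc
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("AUC confidence intervals behave and cover", {
  set.seed(21)
  sim <- simulate_scores(30, sep = 1.2)
  ci <- auc_ci(sim$scores, sim$labels)
  expect_true(ci$lo <= ci$auc && ci$auc <= ci$hi)
  expect_true(ci$lo >= 0 && ci$hi <= 1)
  # near-perfect AUC: the normal upper bound exceeds 1 and is truncated
  near <- simulate_scores(30, sep = 2.5, seed = 99)
  ci_hi <- auc_ci(near$scores, near$labels)
  expect_equal(ci_hi$hi, 1)
  expect_lt(ci_hi$lo, ci_hi$auc)
  # exactly separated scores have zero DeLong variance: degenerate path
  expect_warning(perf <- auc_ci(c(1, 2, 3, 10, 11, 12),
                                c(0, 0, 0, 1, 1, 1)), "degenerate")
  expect_equal(perf$hi, 1)
  # bootstrap alternative gives a sane interval around the same point
  cib <- withr::with_seed(5, auc_ci(sim$scores, sim$labels,
                                    method = "bootstrap", n_boot = 300))
  expect_true(cib$lo <= cib$auc && cib$auc <= cib$hi)
  # degenerate variance falls back to the widest interval with a warning
  expect_warning(w <- auc_ci(rep(0.5, 20), rep(c(0, 1), 10)), "degenerate")
  expect_equal(c(w$lo, w$hi), c(0, 1))

  # coverage of the DeLong interval under a binormal model
  mu <- 1
  true_auc <- stats::pnorm(mu / sqrt(2))
  set.seed(31)
  hits <- vapply(1:1000, function(i) {
    labels <- rep(c(0L, 1L), each = 50)
    scores <- stats::rnorm(100) + mu * labels
    ci <- auc_ci(scores, labels)
    ci$lo <= true_auc && true_auc <= ci$hi
  }, TRUE)
  expect_lt(abs(mean(hits) - 0.95), 0.03)
})

test_that("the paired DeLong test has its documented exact properties", {
  set.seed(41)
  latent <- rnorm(60)
  labels <- rep(c(0L, 1L), 30)
  a <- latent + labels + rnorm(60, 0, 0.5)
  b <- latent + labels + rnorm(60, 0, 0.5)
  # self-comparison: zero difference, p = 1
  self <- delong_test(a, a, labels)
  expect_equal(self$delta, 0)
  expect_equal(self$p_value, 1)
  # antisymmetry in the two score sets
  ab <- delong_test(a, b, labels)
  ba <- delong_test(b, a, labels)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_true(ab$p_value > 0 && ab$p_value <= 1)
  # degenerate nonzero difference signals explicitly
  expect_error(delong_test(c(1, 2, 3, 4), c(4, 3, 2, 1), c(0, 0, 1, 1)),
               "degenerate")
})

test_that("DeLong agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(51)
  for (rep in 1:10) {
    latent <- rnorm(80)
    labels <- rep(c(0L, 1L), 40)
    a <- latent + 0.8 * labels + rnorm(80, 0, 0.6)
    b <- latent + 0.8 * labels + rnorm(80, 0, 0.6)
    ours <- delong_test(a, b, labels)
    ref <- suppressMessages(pROC::roc.test(
      pROC::roc(labels, a, quiet = TRUE, direction = "<", levels = c(0, 1)),
      pROC::roc(labels, b, quiet = TRUE, direction = "<", levels = c(0, 1)),
      method = "delong"))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)),
                 tolerance = 1e-9)
  }
})
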