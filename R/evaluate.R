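#' Patient-level probability from slice probabilities
#'
#' The arithmetic mean of the positive-class probabilities of all of a
#' patient's slices; the reported, patient-level score.
#'
#' @param slice_probs numeric vector of slice probabilities.
#' @return scalar mean probability.
#' @export
patient_probability <- function(slice_probs) {
  if (length(slice_probs) == 0) {
    stop("patient has no slice probabilities", call. = FALSE)
  }
  mean(slice_probs)
}

#' Accuracy, sensitivity, specificity and the confusion matrix
#'
#' A subject is called positive when its probability exceeds the
#' threshold.  Sensitivity is the true-positive rate among label-1
#' subjects, specificity the true-negative rate among label-0 subjects.
#'
#' @param scores data.frame with columns `prob` and `label`, or a numeric
#'   vector of probabilities (then `labels` must be given).
#' @param labels 0/1 labels when `scores` is a vector.
#' @param threshold decision threshold on the probability.
#' @return list with `accuracy`, `sensitivity`, `specificity` and the 2x2
#'   `confusion` table (rows = truth, columns = call).
#' @export
confusion_metrics <- function(scores, labels = NULL, threshold = 0.5) {
  if (is.data.frame(scores)) {
    labels <- scores$label
    scores <- scores$prob
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present: sensitivity or specificity is ",
         "undefined on one-class input", call. = FALSE)
  }
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  confusion <- matrix(c(tn, fn, fp, tp), 2, 2,
                      dimnames = list(truth = c("0", "1"),
                                      call = c("0", "1")))
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       confusion = confusion)
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney statistic: the probability that a random
#' positive scores above a random negative, with ties counting one half.
#' Computed from midranks, so tied scores are handled exactly.  The ROC is
#' the step curve over the unique score thresholds, starting at (0,0) and
#' ending at (1,1).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return list with `auc` and `roc` (data.frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (anyNA(scores) || anyNA(labels)) {
    stop("ROC/AUC scores and labels must not contain missing values",
         call. = FALSE)
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC/AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, 0)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (utils::tail(roc$fpr, 1) != 1 || utils::tail(roc$tpr, 1) != 1) {
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  }
  list(auc = auc, roc = roc)
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties = 1/2), and symmetrically for negatives.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Confidence interval for an AUC
#'
#' Default method: normal interval with the DeLong variance of the
#' placement values, truncated to [0,1].  Alternatively a subject-level
#' bootstrap percentile interval.  A degenerate (zero) variance falls back
#' to the widest interval [0,1] with a warning.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param level confidence level.
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates.
#' @return list with `auc`, `lo`, `hi` and `level`.
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   method = c("delong", "bootstrap"), n_boot = 2000L) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  pl <- delong_placements(scores, labels)
  if (method == "delong") {
    v <- stats::var(pl$v10) / length(pl$v10) +
      stats::var(pl$v01) / length(pl$v01)
    if (!is.finite(v) || v <= 0) {
      warning("degenerate AUC variance; falling back to the widest interval")
      return(list(auc = pl$auc, lo = 0, hi = 1, level = level))
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    list(auc = pl$auc, lo = max(0, pl$auc - z * sqrt(v)),
         hi = min(1, pl$auc + z * sqrt(v)), level = level)
  } else {
    ip <- which(labels == 1L)
    ineg <- which(labels == 0L)
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
      roc_auc(scores[i], labels[i])$auc
    }, 0)
    qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    list(auc = pl$auc, lo = max(0, qs[1]), hi = min(1, qs[2]), level = level)
  }
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score sets obtained on the same subjects,
#' using the DeLong covariance of the placement values.  The z statistic
#' is antisymmetric in the two score sets; identical scores give a zero
#' difference and p = 1.
#'
#' @param scores_a,scores_b paired score vectors on identical subjects.
#' @param labels 0/1 labels.
#' @return list with `auc_a`, `auc_b`, `delta` (a minus b), `z` and the
#'   two-sided normal `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  delta <- pa$auc - pb$auc
  n1 <- length(pa$v10)
  n0 <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (!is.finite(v) || v <= 0) {
    if (abs(delta) < .Machine$double.eps^0.5) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                  z = 0, p_value = 1))
    }
    stop("degenerate DeLong variance: the AUC difference has zero ",
         "estimated variance but is nonzero", call. = FALSE)
  }
  z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
       p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Evaluate a fitted model on a cohort
#'
#' Computes slice- and patient-level probabilities, the confusion metrics
#' at the given threshold, the ROC curve and AUC with its confidence
#' interval.  The patient level is the headline result.
#'
#' @param fit a `drlroi_fit`.
#' @param cohort a `drlroi_cohort` of evaluation slices (already cropped
#'   to the input size).
#' @param threshold decision threshold on the patient probability.
#' @param level confidence level of the AUC interval.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @return object of class `drlroi_eval`: list with `patient` and `slice`
#'   sublists (each with `accuracy`, `sensitivity`, `specificity`,
#'   `confusion`, `auc`, `auc_ci`, `roc`) and the score data frames.
#' @export
eval_report <- function(fit, cohort, threshold = 0.5, level = 0.95,
                        ci_method = "delong") {
  slice_df <- predict(fit, cohort, type = "slice")
  patient_df <- aggregate_patients(slice_df)
  level_report <- function(df) {
    cm <- confusion_metrics(df, threshold = threshold)
    ra <- roc_auc(df$prob, df$label)
    ci <- auc_ci(df$prob, df$label, level = level, method = ci_method)
    list(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
         specificity = cm$specificity, confusion = cm$confusion,
         auc = ra$auc, auc_ci = c(lo = ci$lo, hi = ci$hi), roc = ra$roc)
  }
  structure(list(patient = level_report(patient_df),
                 slice = level_report(slice_df),
                 patient_scores = patient_df, slice_scores = slice_df,
                 threshold = threshold, level = level),
            class = "drlroi_eval")
}

#' @export
print.drlroi_eval <- function(x, ...) {
  p <- x$patient
  cat("patient-level evaluation (threshold", x$threshold, ")\n")
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
              p$accuracy, p$sensitivity, p$specificity))
  cat(sprintf("  AUC %.3f  (%d%% CI %.3f-%.3f)\n", p$auc,
              round(100 * x$level), p$auc_ci["lo"], p$auc_ci["hi"]))
  cat(sprintf("slice-level AUC %.3f over %d slices\n", x$slice$auc,
              nrow(x$slice_scores)))
  invisible(x)
}
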