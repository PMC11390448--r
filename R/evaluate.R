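#' Confusion counts at a decision threshold
#'
#' A prediction is positive iff its probability is `>= threshold`.
#'
#' @param probabilities numeric vector of scores.
#' @param labels vector in \{0, 1\}, same length.
#' @param threshold decision threshold tau.
#' @return list of class `confusion_counts` with integers `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_at_threshold <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) != length(labels)) {
    stop("probabilities/labels length mismatch", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  pred <- as.integer(probabilities >= threshold)
  structure(list(TP = sum(pred == 1L & labels == 1),
                 FP = sum(pred == 1L & labels == 0),
                 TN = sum(pred == 0L & labels == 0),
                 FN = sum(pred == 0L & labels == 1)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Undefined metrics (zero denominator) raise an error rather than silently
#' returning 0.
#'
#' @param counts a `confusion_counts` object or list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @return list with `sensitivity`, `specificity`, `accuracy`.
#' @export
summary_metrics <- function(counts) {
  with(counts, {
    total <- TP + FP + TN + FN
    if (TP + FN == 0) stop("sensitivity undefined: no positive labels", call. = FALSE)
    if (TN + FP == 0) stop("specificity undefined: no negative labels", call. = FALSE)
    if (total == 0) stop("accuracy undefined: empty cohort", call. = FALSE)
    list(sensitivity = TP / (TP + FN),
         specificity = TN / (TN + FP),
         accuracy = (TP + TN) / total)
  })
}

#' ROC area under the curve (Mann-Whitney form)
#'
#' `AUC = (# case/control pairs with case score > control score + 0.5 * ties)
#' / (n1 * n0)`, computed from mid-ranks; identical to trapezoidal ROC
#' integration.
#'
#' @param probabilities numeric scores.
#' @param labels vector in \{0, 1\}; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  if (length(probabilities) != length(labels)) {
    stop("probabilities/labels length mismatch", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class only", call. = FALSE)
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param probabilities,labels as in [roc_auc()].
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, one row per
#'   distinct score plus the endpoints, suitable for plotting or CSV export.
#' @export
roc_points <- function(probabilities, labels) {
  th <- c(Inf, sort(unique(probabilities), decreasing = TRUE), -Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  do.call(rbind, lapply(th, function(t) {
    pred <- probabilities >= t
    data.frame(threshold = t,
               fpr = sum(pred & labels == 0) / n0,
               tpr = sum(pred & labels == 1) / n1)
  }))
}

#' DeLong variance and confidence interval for the AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC from the placement-value
#' components: with `V10[i]` the mean over controls of the kernel
#' `psi(case_i, control_j)` (1 if case > control, 1/2 on ties, else 0) and
#' `V01[j]` its control-side analogue, `var = S10/n1 + S01/n0` where `S10`,
#' `S01` are the sample variances of the placements. The two-sided
#' `(1 - alpha)` interval is `auc +/- z * sqrt(var)`, clipped to `[0, 1]`.
#' Perfectly separated scores give zero variance and a degenerate interval.
#'
#' @param probabilities numeric scores.
#' @param labels vector in \{0, 1\}; at least two of each class.
#' @param alpha two-sided error rate (default 0.05 for a 95% CI).
#' @return object of class `auc_estimate`: `auc`, `variance`, `ci_low`,
#'   `ci_high`, `alpha`.
#' @export
delong_ci <- function(probabilities, labels, alpha = 0.05) {
  if (length(probabilities) != length(labels)) {
    stop("probabilities/labels length mismatch", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  cases <- probabilities[labels == 1]
  controls <- probabilities[labels == 0]
  n1 <- length(cases); n0 <- length(controls)
  if (n1 < 2L || n0 < 2L) {
    stop("DeLong CI requires at least 2 cases and 2 controls", call. = FALSE)
  }
  psi <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  auc <- mean(psi)
  variance <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(max(variance, 0))
  structure(list(auc = auc, variance = variance,
                 ci_low = max(0, auc - half), ci_high = min(1, auc + half),
                 alpha = alpha),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.4f (%.0f%% CI %.4f-%.4f, DeLong var %.3e)\n",
              x$auc, 100 * (1 - x$alpha), x$ci_low, x$ci_high, x$variance))
  invisible(x)
}

#' Dice similarity coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks score 1 by the agreement
#' convention (stated explicitly because conventions differ).
#'
#' @param maskA,maskB arrays of identical shape; values are binarized as
#'   `> 0`.
#' @return dice coefficient in `[0, 1]`.
#' @export
dice_score <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stop("mask shape mismatch", call. = FALSE)
  a <- maskA > 0; b <- maskB > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
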