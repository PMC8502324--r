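#' Confusion counts of a binary classifier
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return named integer vector `c(tp, fp, tn, fn)`; the counts sum to
#'   `length(y_true)`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop_los("y_true and y_pred must have equal length")
  if (!is_binary01(as.numeric(y_true)) || !is_binary01(as.numeric(y_pred)))
    stop_los("y_true and y_pred must be binary 0/1")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  c(tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == 0 & y_pred == 1),
    tn = sum(y_true == 0 & y_pred == 0),
    fn = sum(y_true == 1 & y_pred == 0))
}

#' Positive and negative likelihood ratios
#'
#' LR+ = sens / (1 − spec) measures how much a positive prediction
#' raises the pre-test odds (1 to +Inf, higher is better); LR− =
#' (1 − sens) / spec measures how much a negative prediction lowers
#' them (0 to 1, lower is better).
#'
#' @param sens,spec sensitivity and specificity in \[0, 1\].
#' @return named numeric vector `c(lr_pos, lr_neg)`; `lr_pos` is `Inf`
#'   when `spec == 1`, `lr_neg` is `NaN` when `spec == 0`.
#' @export
likelihood_ratios <- function(sens, spec) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1)
    stop_los("sensitivity and specificity must lie in [0, 1]")
  lr_pos <- if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- if (spec == 0) NaN else (1 - sens) / spec
  c(lr_pos = lr_pos, lr_neg = lr_neg)
}

#' Incorrect-classification proportion
#'
#' Proportion of all patients (actual positives and actual negatives)
#' not correctly identified:
#' `((1 - sens) * occurrence + (1 - spec) * (n - occurrence)) / n`.
#'
#' @param sens,spec sensitivity and specificity in \[0, 1\].
#' @param occurrence number of actual positives.
#' @param n total number of observations.
#' @return proportion in \[0, 1\].
#' @export
incorrect_classification <- function(sens, spec, occurrence, n) {
  if (n <= 0) stop_los("n must be positive")
  if (occurrence < 0 || occurrence > n)
    stop_los("occurrence must lie in [0, n]")
  ((1 - sens) * occurrence + (1 - spec) * (n - occurrence)) / n
}

#' AUC of a single-cutoff binary classifier
#'
#' A classifier evaluated at one cutoff yields a single ROC point
#' (1 − spec, sens); the area under the piecewise-linear ROC through
#' (0,0), that point and (1,1) is `(sens + spec) / 2`.  This is the AUC
#' definition used in the reporting layer; a score-based trapezoidal AUC
#' is available as [auc_trapezoid()].
#'
#' @inheritParams likelihood_ratios
#' @return AUC in \[0, 1\].
#' @export
auc_binary <- function(sens, spec) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1)
    stop_los("sensitivity and specificity must lie in [0, 1]")
  (sens + spec) / 2
}

#' Trapezoidal ROC AUC from continuous scores
#'
#' Rank-based (Mann-Whitney) AUC, equal to the area under the empirical
#' ROC curve with ties handled by the midrank convention.
#'
#' @param y_true 0/1 outcome vector.
#' @param scores numeric prediction scores, higher means more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_los("both classes must be present to compute a ROC AUC")
  r <- rank(scores)
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Wald standard error and 95% confidence interval for a proportion
#'
#' Normal-approximation interval with z = 1.96.  The interval is built
#' from the standard error rounded to three decimals, matching the
#' precision at which such tables are typically reported, so that
#' printed (SE, CI) pairs are mutually consistent.
#'
#' @param p proportion in \[0, 1\].
#' @param m denominator count (e.g., number of actual positives for a
#'   sensitivity).
#' @return named numeric vector `c(se, lo, hi)`.
#' @export
wald_interval <- function(p, m) {
  if (m < 1) stop_los("denominator m must be at least 1")
  if (p < 0 || p > 1) stop_los("p must lie in [0, 1]")
  se <- sqrt(p * (1 - p) / m)
  se3 <- round_half_away(se, 3)
  c(se = se, lo = p - 1.96 * se3, hi = p + 1.96 * se3)
}

#' Diagnostic evaluation report
#'
#' Computes the full set of diagnostic indexes for a binary prediction:
#' confusion counts, sensitivity, specificity, false positive/negative
#' rates, incorrect classification, positive/negative likelihood ratios,
#' single-cutoff AUC, and Wald standard errors and 95% confidence
#' intervals for sensitivity (denominator: actual positives) and
#' specificity (denominator: actual negatives).
#'
#' @inheritParams confusion
#' @param scores optional numeric scores backing `y_pred`; when given, a
#'   score-based trapezoidal ROC AUC (`auc_roc`) is added.
#' @return object of class `evaluation_report` (a list).
#' @export
evaluate <- function(y_true, y_pred, scores = NULL) {
  cm <- confusion(y_true, y_pred)
  n <- sum(cm)
  occurrence <- cm[["tp"]] + cm[["fn"]]
  n_neg <- n - occurrence
  if (occurrence == 0 || n_neg == 0)
    stop_los("both classes must be present in y_true")
  sens <- cm[["tp"]] / occurrence
  spec <- cm[["tn"]] / n_neg
  lr <- likelihood_ratios(sens, spec)
  sens_ci <- wald_interval(sens, occurrence)
  spec_ci <- wald_interval(spec, n_neg)
  report <- list(
    tp = cm[["tp"]], fp = cm[["fp"]], tn = cm[["tn"]], fn = cm[["fn"]],
    n = n, occurrence = occurrence,
    sensitivity = sens, specificity = spec,
    fpr = 1 - spec, fnr = 1 - sens,
    incorrect_classification = (cm[["fp"]] + cm[["fn"]]) / n,
    lr_pos = lr[["lr_pos"]], lr_neg = lr[["lr_neg"]],
    auc_binary = auc_binary(sens, spec),
    auc_roc = if (!is.null(scores)) auc_trapezoid(y_true, scores) else NA_real_,
    sens_se = sens_ci[["se"]], spec_se = spec_ci[["se"]],
    sens_ci = c(sens_ci[["lo"]], sens_ci[["hi"]]),
    spec_ci = c(spec_ci[["lo"]], spec_ci[["hi"]])
  )
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Diagnostic evaluation (n =", x$n, ", positives =", x$occurrence, ")\n")
  cat(sprintf("  incorrect classification  %6.2f%%\n",
              100 * x$incorrect_classification))
  cat(sprintf("  sensitivity               %6.2f%%  (SE %.3f, 95%% CI %.3f-%.3f)\n",
              100 * x$sensitivity, x$sens_se, x$sens_ci[1], x$sens_ci[2]))
  cat(sprintf("  specificity               %6.2f%%  (SE %.3f, 95%% CI %.3f-%.3f)\n",
              100 * x$specificity, x$spec_se, x$spec_ci[1], x$spec_ci[2]))
  cat(sprintf("  false positive rate       %6.2f%%\n", 100 * x$fpr))
  cat(sprintf("  false negative rate       %6.2f%%\n", 100 * x$fnr))
  cat(sprintf("  LR+ %.2f   LR- %.2f   AUC %.2f\n",
              x$lr_pos, x$lr_neg, x$auc_binary))
  invisible(x)
}
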