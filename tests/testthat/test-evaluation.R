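test_that("confusion counts match a brute-force loop oracle", {
  expect_equal(confusion(c(1, 0, 1), c(1, 0, 1)),
               c(tp = 2L, fp = 0L, tn = 1L, fn = 0L))
  y <- c(1, 0, 1, 0)
  expect_equal(confusion(y, 1 - y)[c("tp", "tn")], c(tp = 0L, tn = 0L))

  set.seed(61)
  y_true <- rbinom(50, 1, 0.4); y_pred <- rbinom(50, 1, 0.5)
  oracle <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in seq_along(y_true)) {
    key <- if (y_true[i] == 1 && y_pred[i] == 1) "tp"
           else if (y_true[i] == 0 && y_pred[i] == 1) "fp"
           else if (y_true[i] == 0 && y_pred[i] == 0) "tn" else "fn"
    oracle[key] <- oracle[key] + 1L
  }
  expect_equal(confusion(y_true, y_pred), oracle)
  expect_error(confusion(c(1, 2), c(0, 1)), "binary")
})

# Printed diagnostic indexes per clinical unit, rebuilt from each unit's
# (sensitivity, specificity, occurrence, n); the malformed cardiology
# long-outcome SE entry in the source table is excluded.
published_index_table <- function() {
  rbind(
    data.frame(outcome = "long",
      unit = c("DIEM", "internal medicine", "cardiology", "emergency medicine",
               "geriatrics", "respiratory diseases", "neurology", "oncology"),
      sens = c(69.34, 68.98, 77.50, 63.51, 70.86, 62.07, 70.45, 67.21),
      spec = c(48.59, 40.46, 53.17, 54.22, 52.07, 54.84, 49.31, 57.14),
      occurrence = c(1148, 187, 80, 148, 175, 116, 88, 61),
      n = c(2819, 449, 411, 373, 296, 240, 232, 166),
      incorrect = c(42.96, 47.66, 42.09, 42.09, 36.82, 41.67, 42.67, 39.16),
      lr_pos = c(1.35, 1.16, 1.66, 1.39, 1.48, 1.37, 1.39, 1.57),
      lr_neg = c(0.63, 0.77, 0.42, 0.67, 0.56, 0.69, 0.60, 0.57),
      auc = c(0.59, 0.55, 0.65, 0.59, 0.61, 0.58, 0.60, 0.62)),
    data.frame(outcome = "outlier",
      unit = c("DIEM", "internal medicine", "cardiology", "emergency medicine",
               "geriatrics", "respiratory diseases", "neurology", "oncology"),
      sens = c(62.73, 73.68, 71.43, 77.78, 77.78, 66.67, 85.71, 75.00),
      spec = c(51.72, 52.44, 81.68, 61.41, 58.27, 66.67, 54.67, 64.81),
      occurrence = c(110, 19, 7, 18, 18, 6, 7, 4),
      n = c(2819, 449, 411, 373, 296, 240, 232, 166),
      incorrect = c(47.85, 46.67, 18.49, 37.80, 40.54, 33.33, 44.40, 34.94),
      lr_pos = c(1.30, 1.55, 3.90, 2.02, 1.86, 2.00, 1.89, 2.13),
      lr_neg = c(0.72, 0.50, 0.35, 0.36, 0.38, 0.50, 0.26, 0.39),
      auc = c(0.57, 0.63, 0.77, 0.70, 0.68, 0.67, 0.70, 0.70))
  )
}

test_that("every published index column is reproduced at printed precision", {
  tab <- published_index_table()
  # the published table computed its indexes from unrounded sensitivities
  # and specificities, so one unit in the last printed digit is the exact
  # reproduction tolerance given the rounded inputs
  ulp <- 0.01 + 1e-9
  for (i in seq_len(nrow(tab))) {
    sens <- tab$sens[i] / 100; spec <- tab$spec[i] / 100
    inc <- round_half_away(100 * incorrect_classification(
      sens, spec, tab$occurrence[i], tab$n[i]), 2)
    expect_lte(abs(inc - tab$incorrect[i]), ulp)
    expect_equal(round_half_away(100 * (1 - spec), 2),
                 round_half_away(100 - tab$spec[i], 2))  # FPR identity
    lr <- likelihood_ratios(sens, spec)
    expect_lte(abs(round_half_away(lr[["lr_pos"]], 2) - tab$lr_pos[i]), ulp)
    expect_lte(abs(round_half_away(lr[["lr_neg"]], 2) - tab$lr_neg[i]), ulp)
    expect_lte(abs(round_half_away(auc_binary(sens, spec), 2) - tab$auc[i]),
               ulp)
  }

  # the headline department-level long-stay column reproduces exactly
  expect_equal(round_half_away(
    100 * incorrect_classification(0.6934, 0.4859, 1148, 2819), 2), 42.96)
  expect_equal(round_half_away(likelihood_ratios(0.6934, 0.4859)[["lr_pos"]], 2), 1.35)
  expect_equal(round_half_away(likelihood_ratios(0.6934, 0.4859)[["lr_neg"]], 2), 0.63)
  expect_equal(round_half_away(auc_binary(0.6934, 0.4859), 2), 0.59)
  # cardiology outlier column
  expect_equal(round_half_away(likelihood_ratios(0.7143, 0.8168)[["lr_pos"]], 2), 3.90)
  expect_equal(round_half_away(auc_binary(0.7143, 0.8168), 2), 0.77)
  expect_equal(round_half_away(
    100 * incorrect_classification(0.6273, 0.5172, 110, 2819), 2), 47.85)
})

test_that("Wald intervals use the 3-dp-rounded standard error", {
  ci <- wald_interval(0.6934, 1148)
  expect_equal(round_half_away(ci[["se"]], 3), 0.014)
  expect_equal(round_half_away(ci[["lo"]], 3), 0.666)
  expect_equal(round_half_away(ci[["hi"]], 2), 0.72)

  expect_equal(wald_interval(0, 50), c(se = 0, lo = 0, hi = 0))
  expect_equal(wald_interval(1, 50), c(se = 0, lo = 1, hi = 1))
  expect_error(wald_interval(0.5, 0), "at least 1")
})

test_that("likelihood ratios behave at the boundaries", {
  expect_equal(likelihood_ratios(0.5, 0.5), c(lr_pos = 1, lr_neg = 1))
  expect_equal(likelihood_ratios(0.8, 1)[["lr_pos"]], Inf)
  expect_true(is.nan(likelihood_ratios(0.8, 0)[["lr_neg"]]))
  expect_error(likelihood_ratios(1.2, 0.5), "\\[0, 1\\]")
})

test_that("LR identities link to sens + spec > 1", {
  set.seed(8)
  for (i in 1:25) {
    sens <- runif(1, 0.01, 0.99); spec <- runif(1, 0.01, 0.99)
    lr <- likelihood_ratios(sens, spec)
    expect_equal(lr[["lr_pos"]] > 1, sens + spec > 1)
    expect_equal(lr[["lr_neg"]] < 1, sens + spec > 1)
  }
})

test_that("single-cutoff AUC equals the trapezoidal area of the 3-point ROC", {
  trap3 <- function(sens, spec) {
    fpr <- 1 - spec
    # trapezoids over {(0,0), (fpr, sens), (1,1)}
    fpr * sens / 2 + (1 - fpr) * (sens + 1) / 2
  }
  set.seed(9)
  for (i in 1:20) {
    sens <- runif(1); spec <- runif(1)
    expect_equal(auc_binary(sens, spec), trap3(sens, spec), tolerance = 1e-12)
  }
})

test_that("score-based ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  y <- rbinom(150, 1, 0.4)
  s <- rnorm(150) + y
  expect_equal(auc_trapezoid(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("the full report matches a brute-force recomputation on random cases", {
  set.seed(73)
  for (rep in 1:3) {
    y_true <- rbinom(200, 1, 0.35)
    y_pred <- rbinom(200, 1, 0.5)
    rp <- evaluate(y_true, y_pred)

    tp <- sum(y_true == 1 & y_pred == 1); fn <- sum(y_true == 1 & y_pred == 0)
    tn <- sum(y_true == 0 & y_pred == 0); fp <- sum(y_true == 0 & y_pred == 1)
    occ <- tp + fn; n <- length(y_true)
    sens <- tp / occ; spec <- tn / (n - occ)
    expect_equal(rp$n, n)
    expect_equal(rp$occurrence, occ)
    expect_equal(rp$sensitivity, sens)
    expect_equal(rp$specificity, spec)
    expect_equal(rp$fpr, 1 - spec)
    expect_equal(rp$fnr, 1 - sens)
    expect_equal(rp$incorrect_classification, (fp + fn) / n)
    expect_equal(rp$incorrect_classification,
                 incorrect_classification(sens, spec, occ, n))
    expect_equal(rp$lr_pos, sens / (1 - spec))
    expect_equal(rp$lr_neg, (1 - sens) / spec)
    expect_equal(rp$auc_binary, (sens + spec) / 2)
    expect_equal(rp$sens_se, sqrt(sens * (1 - sens) / occ))
    expect_equal(rp$spec_se, sqrt(spec * (1 - spec) / (n - occ)))
  }
})

test_that("forced prediction patterns yield the forced indexes", {
  y <- c(rep(1, 5), rep(0, 5))
  perfect <- evaluate(y, y)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$incorrect_classification, 0)
  expect_equal(perfect$auc_binary, 1)

  all_pos <- evaluate(y, rep(1, 10))
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$lr_pos, 1)
})
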