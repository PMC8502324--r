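test_that("the stratified split has the documented sizes and class balance", {
  y <- c(rep(1, 3), rep(0, 6))
  sp <- split_train_validation(y, seed = 4)
  expect_length(sp$train, 6)   # ceiling(2 * 9 / 3)
  expect_length(sp$valid, 3)
  expect_equal(sum(y[sp$train]), 2)
  expect_equal(sum(y[sp$valid]), 1)

  # partition: disjoint and exhaustive
  expect_equal(sort(c(sp$train, sp$valid)), 1:9)
  expect_length(intersect(sp$train, sp$valid), 0)

  expect_identical(split_train_validation(y, seed = 4), sp)  # determinism

  set.seed(1)
  y2 <- rbinom(100, 1, 0.3)
  sp2 <- split_train_validation(y2, seed = 9)
  expect_length(sp2$train, ceiling(2 * 100 / 3))
  expect_gt(sum(y2[sp2$train]), 0)
  expect_gt(sum(y2[sp2$valid]), 0)
  expect_gt(sum(1 - y2[sp2$valid]), 0)

  expect_error(split_train_validation(c(1, 0, 0, 0)), "at least 2")
})

# A small, well-separated training problem reused across selection tests.
separable_problem <- function(n = 240, seed = 5) {
  set.seed(seed)
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5),
             c = rbinom(n, 1, 0.5))
  y <- as.integer(X[, "a"] == 1)  # perfectly separable by one column
  sp <- split_train_validation(y, seed = seed)
  list(Xt = X[sp$train, ], yt = y[sp$train],
       Xv = X[sp$valid, ], yv = y[sp$valid])
}

test_that("constrained bootstrap selection meets attainable floors", {
  pr <- separable_problem()
  model <- bootstrap_select(pr$Xt, pr$yt, pr$Xv, pr$yv,
                            fast_control(),
                            selection_policy(n_replications = 8, seed = 2))
  expect_true(model$floors_met)
  expect_gte(model$training_sens, 0.80)
  expect_gte(model$training_spec, 0.70)
  expect_s3_class(model$validation_report, "evaluation_report")
  expect_equal(nrow(model$replication_log), 8)
})

test_that("a single replication is returned as-is", {
  pr <- separable_problem()
  model <- bootstrap_select(pr$Xt, pr$yt, pr$Xv, pr$yv, fast_control(),
                            selection_policy(n_replications = 1, seed = 3))
  expect_equal(model$replication_id, 1L)
})

test_that("orientation ordering holds on the same replication pool", {
  pr <- separable_problem(n = 200, seed = 13)
  # noisy labels so sens and spec trade off across replications
  set.seed(13)
  yt <- pr$yt; flip <- sample(length(yt), 40)
  yt[flip] <- 1 - yt[flip]
  pol <- function(orient) selection_policy(orient, sens_floor = 0,
                                           spec_floor = 0,
                                           n_replications = 10, seed = 21)
  m_sens <- bootstrap_select(pr$Xt, yt, pr$Xv, pr$yv, fast_control(),
                             pol("maximize_sensitivity"))
  m_spec <- bootstrap_select(pr$Xt, yt, pr$Xv, pr$yv, fast_control(),
                             pol("maximize_specificity"))
  expect_gte(m_sens$training_sens, m_spec$training_sens)
  expect_gte(m_spec$training_spec, m_sens$training_spec)
})

test_that("with floors at zero the selection is plain oriented maximization", {
  pr <- separable_problem(n = 150, seed = 23)
  model <- bootstrap_select(pr$Xt, pr$yt, pr$Xv, pr$yv, fast_control(),
                            selection_policy("maximize_sensitivity",
                                             sens_floor = 0, spec_floor = 0,
                                             n_replications = 6, seed = 31))
  log <- model$replication_log
  expect_equal(model$replication_id,
               log$replication[which.max(log$sens)])
  expect_true(model$floors_met)
})

test_that("unattainable floors trigger the fallback with a warning", {
  set.seed(41)
  X <- cbind(a = rbinom(120, 1, 0.5), b = rbinom(120, 1, 0.5))
  y <- rbinom(120, 1, 0.5)  # pure noise: floors of 0.99 unattainable
  sp <- split_train_validation(y, seed = 41)
  expect_warning(
    model <- bootstrap_select(X[sp$train, ], y[sp$train],
                              X[sp$valid, ], y[sp$valid],
                              fast_control(),
                              selection_policy(sens_floor = 0.99,
                                               spec_floor = 0.99,
                                               n_replications = 4, seed = 5)),
    "floors")
  expect_false(model$floors_met)
})

test_that("a longer replication stream never lowers the oriented metric", {
  pr <- separable_problem(n = 200, seed = 55)
  set.seed(55)
  yt <- pr$yt; flip <- sample(length(yt), 30); yt[flip] <- 1 - yt[flip]
  oriented <- sapply(c(3, 6, 12), function(R) {
    suppressWarnings(bootstrap_select(
      pr$Xt, yt, pr$Xv, pr$yv, fast_control(),
      selection_policy("maximize_sensitivity", sens_floor = 0, spec_floor = 0,
                       n_replications = R, seed = 77)))$training_sens
  })
  expect_true(all(diff(oriented) >= 0))
})

test_that("macro and micro fits compose encoding, labeling, split and selection", {
  cohort <- generate_cohort(config_parameter_recovery(1200, seed = 3))
  model <- fit_macro(cohort$records, cohort$drg_ref, "long", fast_control(),
                     selection_policy(n_replications = 3, seed = 3))
  expect_equal(ncol(model$net$W_in), 30)
  expect_gt(model$validation_report$sensitivity, 0.5)

  # validation rows never enter training
  expect_length(intersect(model$split$train, model$split$valid), 0)

  # seed-fixed fits serialize byte-identically
  model2 <- fit_macro(cohort$records, cohort$drg_ref, "long", fast_control(),
                      selection_policy(n_replications = 3, seed = 3))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_network(model$net, f1); write_network(model2$net, f2)
  expect_identical(readLines(f1), readLines(f2))

  unit <- "internal medicine"
  micro <- fit_micro(cohort$records, cohort$drg_ref, unit, "long",
                     fast_control(),
                     selection_policy(n_replications = 3, seed = 3))
  expect_equal(ncol(micro$net$W_in), 31)
  expect_equal(micro$encoding$unit, unit)
  expect_error(fit_micro(cohort$records[1:40, ], cohort$drg_ref,
                         "rheumatology", "long"),
               "records after filtering")
})

test_that("the rare-outlier path runs to completion (warning tolerated)", {
  cohort <- generate_cohort(cohort_config(1500, seed = 19))
  model <- suppressWarnings(
    fit_macro(cohort$records, cohort$drg_ref, "outlier", fast_control(),
              selection_policy(n_replications = 2, seed = 7)))
  expect_s3_class(model, "selected_model")
  expect_equal(model$outcome, "outlier")
})
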