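#' Stratified 2/3 - 1/3 train/validation split
#'
#' Partitions the records into a training sample of size `ceiling(2n/3)`
#' and a validation sample of size `floor(n/3)`, stratified by the
#' outcome so that both classes appear in both parts: the training set
#' must represent all types of patients.  Per class the training share
#' is `floor(2/3)` of the class, and the remaining seats up to the
#' global training size go to the classes with the largest fractional
#' remainders (ties: positives first).
#'
#' @param y 0/1 outcome vector, one element per record.
#' @param seed integer seed; the split is deterministic given it.
#' @return list with integer index vectors `train` and `valid`
#'   (disjoint, exhaustive).
#' @export
split_train_validation <- function(y, seed = 1) {
  y <- as.integer(y)
  n <- length(y)
  if (n < 3) stop_los("need at least 3 records to split")
  counts <- c(`1` = sum(y == 1), `0` = sum(y == 0))
  if (any(counts < 2))
    stop_los("each outcome class needs at least 2 records (got %d positives, %d negatives)",
             counts[["1"]], counts[["0"]])
  n_train <- ceiling(2 * n / 3)
  base <- floor(2 * counts / 3)
  rem <- 2 * counts / 3 - base
  deficit <- n_train - sum(base)
  take <- base
  if (deficit > 0) {
    extra_order <- names(sort(rem, decreasing = TRUE))  # ties: "1" before "0"
    for (cls in rep(extra_order, length.out = deficit))
      take[cls] <- take[cls] + 1
  }
  take <- pmin(pmax(take, 1), counts - 1)  # both classes in both parts

  set.seed(seed)
  train <- integer(0)
  for (cls in c("1", "0")) {
    rows <- which(y == as.integer(cls))
    train <- c(train, sort(sample(rows, take[[cls]])))
  }
  train <- sort(train)
  list(train = train, valid = setdiff(seq_len(n), train))
}

#' Empirical hidden-layer size selection
#'
#' The number of hidden neurons must be found empirically; this rule
#' trains one network per candidate size on the grid
#' \{ceiling(p/2), p, 2p+1\} (p = number of inputs) and keeps the size
#' with the best balanced accuracy on the validation split (ties: the
#' smaller size).
#'
#' @param X_train,y_train,X_valid,y_valid split design matrices/labels.
#' @param control a [training_control()]; its `n_hidden` is ignored.
#' @return the selected hidden-layer size (integer).
#' @export
choose_hidden_size <- function(X_train, y_train, X_valid, y_valid,
                               control = training_control()) {
  p <- ncol(X_train)
  grid <- sort(unique(c(ceiling(p / 2), p, 2 * p + 1)))
  balanced <- vapply(grid, function(h) {
    ctl <- control
    ctl$n_hidden <- h
    net <- mlp_train(X_train, y_train, ctl)
    pred <- predict(net, X_valid)
    cm <- confusion(y_valid, pred)
    sens <- cm[["tp"]] / max(1, cm[["tp"]] + cm[["fn"]])
    spec <- cm[["tn"]] / max(1, cm[["tn"]] + cm[["fp"]])
    (sens + spec) / 2
  }, numeric(1))
  grid[which.max(balanced)]
}

#' Selection policy for the constrained bootstrap
#'
#' @param orientation `"maximize_sensitivity"` or
#'   `"maximize_specificity"`: which ability of the network the
#'   selection favors (identifying true positives or true negatives).
#' @param sens_floor,spec_floor minimum sensitivity and specificity
#'   levels set ex ante (defaults 0.80 and 0.70).
#' @param n_replications number of bootstrap training replications
#'   (default 100).
#' @param seed integer seed driving resampling and weight
#'   initialization.
#' @return list of class `selection_policy`.
#' @export
selection_policy <- function(orientation = c("maximize_sensitivity",
                                             "maximize_specificity"),
                             sens_floor = 0.80, spec_floor = 0.70,
                             n_replications = 100, seed = 1) {
  orientation <- match.arg(orientation)
  if (sens_floor < 0 || sens_floor > 1 || spec_floor < 0 || spec_floor > 1)
    stop_los("floors must lie in [0, 1]")
  if (n_replications < 1) stop_los("n_replications must be >= 1")
  structure(list(orientation = orientation, sens_floor = sens_floor,
                 spec_floor = spec_floor,
                 n_replications = as.integer(n_replications),
                 seed = as.integer(seed)),
            class = "selection_policy")
}

training_metrics <- function(net, X, y) {
  cm <- confusion(y, predict(net, X))
  c(sens = cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]),
    spec = cm[["tn"]] / (cm[["tn"]] + cm[["fp"]]))
}

#' Sensitivity/specificity-constrained bootstrap model selection
#'
#' Runs `n_replications` training replications: each resamples the
#' training rows with replacement (seeded), re-initializes the weights
#' (seeded) and trains by back-propagation.  Sensitivity and specificity
#' of every replication are measured on the full training sample; the
#' replications meeting both ex-ante floors form the eligible set, and
#' the eligible replication maximizing the oriented metric is selected
#' (ties: the smaller replication id).  If no replication meets the
#' floors, the overall oriented maximum is returned with
#' `floors_met = FALSE` and a warning.  The untouched validation sample
#' is used once, to compute the reported [evaluate()] report.
#'
#' @param X_train,y_train training design matrix and 0/1 labels.
#' @param X_valid,y_valid validation design matrix and labels.
#' @param control a [training_control()]; a `NULL` `n_hidden` is
#'   resolved once with [choose_hidden_size()].
#' @param policy a [selection_policy()].
#' @return object of class `selected_model`: the network (`net`), the
#'   selected `replication_id`, `training_sens`/`training_spec`,
#'   `floors_met`, the `validation_report`, and a `replication_log`
#'   data.frame with the per-replication training metrics.
#' @export
bootstrap_select <- function(X_train, y_train, X_valid, y_valid,
                             control = training_control(),
                             policy = selection_policy()) {
  X_train <- as.matrix(X_train); X_valid <- as.matrix(X_valid)
  y_train <- as.integer(y_train); y_valid <- as.integer(y_valid)
  if (length(unique(y_train)) < 2 || length(unique(y_valid)) < 2)
    stop_los("both classes must be present in training and validation sets")
  if (is.null(control$n_hidden))
    control$n_hidden <- choose_hidden_size(X_train, y_train,
                                           X_valid, y_valid, control)

  R <- policy$n_replications
  log <- data.frame(replication = seq_len(R),
                    sens = NA_real_, spec = NA_real_, skipped = FALSE)
  nets <- vector("list", R)
  n <- nrow(X_train)
  for (r in seq_len(R)) {
    set.seed(policy$seed + 1000L + r)
    boot <- sample.int(n, n, replace = TRUE)
    attempts <- 1L
    while (length(unique(y_train[boot])) < 2 && attempts < 10L) {
      boot <- sample.int(n, n, replace = TRUE)
      attempts <- attempts + 1L
    }
    if (length(unique(y_train[boot])) < 2) {
      warning(sprintf("replication %d skipped: bootstrap sample single-class after 10 draws", r))
      log$skipped[r] <- TRUE
      next
    }
    ctl <- control
    ctl$seed <- policy$seed + 2000L + r
    net <- mlp_train(X_train[boot, , drop = FALSE], y_train[boot], ctl)
    m <- training_metrics(net, X_train, y_train)
    nets[[r]] <- net
    log$sens[r] <- m[["sens"]]
    log$spec[r] <- m[["spec"]]
  }
  done <- which(!log$skipped)
  if (length(done) == 0) stop_los("all bootstrap replications were skipped")

  oriented <- if (policy$orientation == "maximize_sensitivity")
    log$sens else log$spec
  eligible <- done[log$sens[done] >= policy$sens_floor &
                     log$spec[done] >= policy$spec_floor]
  if (length(eligible) > 0) {
    pick <- eligible[which.max(oriented[eligible])]
    floors_met <- TRUE
  } else {
    pick <- done[which.max(oriented[done])]
    floors_met <- FALSE
    warning(sprintf(
      "no replication met the floors (sens >= %.2f, spec >= %.2f); returning the oriented maximum",
      policy$sens_floor, policy$spec_floor))
  }

  net <- nets[[pick]]
  structure(list(
    net = net,
    replication_id = pick,
    training_sens = log$sens[pick],
    training_spec = log$spec[pick],
    floors_met = floors_met,
    validation_report = evaluate(y_valid, predict(net, X_valid),
                                 scores = mlp_forward(net, X_valid)),
    replication_log = log,
    policy = policy,
    control = control
  ), class = "selected_model")
}

#' @export
print.selected_model <- function(x, ...) {
  cat(sprintf("Selected network: replication %d (training sens %.3f, spec %.3f, floors %s)\n",
              x$replication_id, x$training_sens, x$training_spec,
              if (x$floors_met) "met" else "NOT met"))
  print(x$net)
  invisible(x)
}

fit_engine <- function(records, drg_ref, outcome, spec, control, policy) {
  labels <- label_outcomes(records, drg_ref)
  y <- labels[[outcome]]
  X <- encode_design_matrix(records, spec)
  split <- split_train_validation(y, seed = policy$seed)
  model <- bootstrap_select(X[split$train, , drop = FALSE], y[split$train],
                            X[split$valid, , drop = FALSE], y[split$valid],
                            control, policy)
  model$encoding <- spec
  model$outcome <- outcome
  model$split <- split
  model
}

#' Fit the macro (whole-department) model
#'
#' Composes the macro one-hot encoding (top-10 diagnosis groups plus
#' residual), the outcome labeling, the stratified 2/3 - 1/3 split and
#' the constrained bootstrap selection.
#'
#' @param records validated hospitalization data.frame.
#' @param drg_ref DRG reference table.
#' @param outcome `"long"` or `"outlier"`.
#' @param control a [training_control()].
#' @param policy a [selection_policy()].
#' @return a `selected_model` carrying its `encoding` spec, so it can
#'   score new record sets via [predict_records()].
#' @export
fit_macro <- function(records, drg_ref, outcome = c("long", "outlier"),
                      control = training_control(),
                      policy = selection_policy()) {
  outcome <- match.arg(outcome)
  spec <- encoding_spec("macro", diagnoses = select_top_diagnoses(records))
  fit_engine(records, drg_ref, outcome, spec, control, policy)
}

#' Fit a micro (single clinical unit) model
#'
#' Filters the records to the unit patients are first admitted to,
#' recomputes the unit-specific top-10 diagnosis groups, and adds the
#' internal-transfer indicator to the design matrix.
#'
#' @inheritParams fit_macro
#' @param unit clinical unit name.
#' @param min_records smallest admissible unit size after filtering.
#' @export
fit_micro <- function(records, drg_ref, unit,
                      outcome = c("long", "outlier"),
                      control = training_control(),
                      policy = selection_policy(),
                      min_records = 30) {
  outcome <- match.arg(outcome)
  if (!(unit %in% los_units())) stop_los("unknown unit '%s'", unit)
  sub <- records[as.character(records$unit) == unit, , drop = FALSE]
  if (nrow(sub) < min_records)
    stop_los("unit '%s' has only %d records after filtering (need >= %d)",
             unit, nrow(sub), min_records)
  spec <- encoding_spec("micro", diagnoses = select_top_diagnoses(sub),
                        unit = unit)
  fit_engine(sub, drg_ref, outcome, spec, control, policy)
}

#' Score new records with a fitted model
#'
#' Re-encodes the records with the model's stored encoding spec (for
#' micro models the records are first filtered to the model's unit) and
#' returns binary predictions.
#'
#' @param model a `selected_model` from [fit_macro()]/[fit_micro()].
#' @param records hospitalization data.frame.
#' @param cutoff classification cutoff (default 0.5).
#' @return list with `predictions` (0/1), `scores`, and the row `index`
#'   of the scored records in `records`.
#' @export
predict_records <- function(model, records, cutoff = 0.5) {
  stopifnot(inherits(model, "selected_model"))
  spec <- model$encoding
  idx <- seq_len(nrow(records))
  if (spec$mode == "micro")
    idx <- which(as.character(records$unit) == spec$unit)
  X <- encode_design_matrix(records[idx, , drop = FALSE], spec)
  scores <- mlp_forward(model$net, X)
  list(predictions = as.integer(scores >= cutoff), scores = scores,
       index = idx)
}
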