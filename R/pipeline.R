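#' Run configuration for the full study pipeline
#'
#' @param out_dir directory receiving every artifact.
#' @param train_records,test_records validated record data.frames: the
#'   models are trained on the first year and applied, frozen, to the
#'   second.
#' @param drg_ref DRG reference table used for labeling both years.
#' @param outcomes subset of `c("long", "outlier")`.
#' @param modes subset of `c("macro", "micro")`.
#' @param units clinical units for the micro analysis.
#' @param control a [training_control()].
#' @param policy a [selection_policy()].
#' @param seed global seed; it overrides `policy$seed` so that every
#'   stage draws from one seeded stream.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, train_records, test_records, drg_ref,
                       outcomes = c("long", "outlier"),
                       modes = c("macro", "micro"),
                       units = micro_units_default(),
                       control = training_control(),
                       policy = selection_policy(),
                       seed = 1) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(drg_ref)) stop_los("config requires a DRG reference table")
  validate_drg_reference(drg_ref)
  validate_hospitalizations(train_records)
  validate_hospitalizations(test_records)
  policy$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, train_records = train_records,
                 test_records = test_records, drg_ref = drg_ref,
                 outcomes = outcomes, modes = modes, units = units,
                 control = control, policy = policy,
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_tag <- function(mode, unit, outcome) {
  if (mode == "macro") sprintf("macro_%s", outcome)
  else sprintf("micro_%s_%s", gsub(" ", "-", unit), outcome)
}

report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  path
}

#' Run the full two-year study
#'
#' Trains one model per outcome and per mode/unit on the first year's
#' records (constrained bootstrap selection), freezes it, applies it to
#' the second year, and writes per-model artifacts: the plain-text
#' weight file, the validation and test evaluation reports (JSON), the
#' Garson/sign importance table (CSV) and the per-unit and
#' per-diagnosis-group impact tables (CSV).  A manifest lists every file
#' with its MD5 hash; train and test record ids are written alongside so
#' the year separation is auditable.
#'
#' @param config a [run_config()].
#' @return the manifest data.frame (`file`, `md5`), invisibly; warnings
#'   about unmet selection floors are re-raised per model.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(path) artifacts <<- c(artifacts, path)

  ids_train <- file.path(config$out_dir, "train_record_ids.txt")
  ids_test <- file.path(config$out_dir, "test_record_ids.txt")
  writeLines(config$train_records$record_id, ids_train); emit(ids_train)
  writeLines(config$test_records$record_id, ids_test); emit(ids_test)

  jobs <- list()
  for (mode in config$modes) {
    targets <- if (mode == "macro") list(NULL) else as.list(config$units)
    for (unit in targets)
      for (outcome in config$outcomes)
        jobs[[length(jobs) + 1]] <- list(mode = mode, unit = unit,
                                         outcome = outcome)
  }

  for (job in jobs) {
    tag <- pipeline_tag(job$mode, job$unit, job$outcome)
    model <- tryCatch({
      if (job$mode == "macro")
        fit_macro(config$train_records, config$drg_ref, job$outcome,
                  config$control, config$policy)
      else
        fit_micro(config$train_records, config$drg_ref, job$unit,
                  job$outcome, config$control, config$policy)
    }, error = function(e)
      stop_los("stage '%s' failed during training: %s", tag, conditionMessage(e)))

    weight_path <- file.path(config$out_dir, paste0(tag, ".weights"))
    write_network(model$net, weight_path); emit(weight_path)

    pred <- predict_records(model, config$test_records)
    test_records <- config$test_records[pred$index, , drop = FALSE]
    y_test <- label_outcomes(test_records, config$drg_ref)[[job$outcome]]

    report <- list(
      tag = tag, outcome = job$outcome, mode = job$mode,
      unit = job$unit %||% "all",
      replication_id = model$replication_id,
      floors_met = model$floors_met,
      training_sens = model$training_sens,
      training_spec = model$training_spec,
      validation = unclass(model$validation_report),
      test = unclass(evaluate(y_test, pred$predictions,
                              scores = pred$scores))
    )
    report_path <- file.path(config$out_dir, paste0(tag, "_report.json"))
    report_to_json(report, report_path); emit(report_path)

    imp_path <- file.path(config$out_dir, paste0(tag, "_importance.csv"))
    utils::write.csv(importance_report(model$net), imp_path,
                     row.names = FALSE)
    emit(imp_path)

    for (grouping in c("unit", "diagnosis_group")) {
      impact <- impact_by_group(test_records, pred$predictions,
                                config$drg_ref, grouping)
      path <- file.path(config$out_dir,
                        paste0(tag, "_impact_", grouping, ".csv"))
      utils::write.csv(impact, path, row.names = FALSE); emit(path)
    }
  }

  manifest <- data.frame(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(config$out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest)
}
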