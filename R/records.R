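#' Validate a hospitalization record table
#'
#' Checks every categorical field against its admissible levels, binary
#' fields against \{0, 1\}, and the length of stay against non-negativity.
#' The first offending row and field are named in the error.
#'
#' @param records data.frame with the columns of [read_hospitalizations()].
#' @return the validated data.frame, invisibly unchanged (row order kept).
#' @export
validate_hospitalizations <- function(records) {
  if (!is.data.frame(records)) stop_los("records must be a data.frame")
  missing <- setdiff(record_columns(), names(records))
  if (length(missing) > 0)
    stop_los("records are missing columns: %s", paste(missing, collapse = ", "))

  check_enum <- function(field, levels) {
    x <- as.character(records[[field]])
    bad <- which(!(x %in% levels))
    if (length(bad) > 0)
      stop_los("row %d: invalid %s '%s' (expected one of: %s)",
               bad[1], field, x[bad[1]], paste(levels, collapse = ", "))
  }
  check_binary <- function(field) {
    x <- suppressWarnings(as.numeric(records[[field]]))
    bad <- which(is.na(x) | !(x %in% c(0, 1)))
    if (length(bad) > 0)
      stop_los("row %d: invalid %s '%s' (expected 0 or 1)",
               bad[1], field, as.character(records[[field]][bad[1]]))
  }

  check_enum("unit", los_units())
  check_binary("sex")
  check_enum("age_class", los_age_classes())
  check_binary("cancer")
  check_enum("admission_type", los_admission_types())
  check_enum("time_slot", los_time_slots())
  check_enum("weekday", los_weekdays())
  check_binary("transfer")
  check_enum("discharge_mode", los_discharge_modes())

  los <- suppressWarnings(as.numeric(records$los_days))
  if (anyNA(los))
    stop_los("row %d: missing or non-numeric los_days",
             which(is.na(los))[1])
  if (any(los < 0))
    stop_los("row %d: negative los_days", which(los < 0)[1])
  invisible(records)
}

#' Read hospitalization records from CSV
#'
#' One row per hospitalization, UTF-8, header row.  All categorical
#' fields are validated against their domains ([validate_hospitalizations()]);
#' row order is preserved.
#'
#' @param path path to a CSV file.
#' @return data.frame of validated hospitalization records.
#' @seealso [write_hospitalizations()]
#' @export
read_hospitalizations <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  missing <- setdiff(record_columns(), names(records))
  if (length(missing) > 0)
    stop_los("'%s' is missing columns: %s", path, paste(missing, collapse = ", "))
  records <- records[, record_columns()]
  for (col in c("sex", "cancer", "transfer", "los_days"))
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  records$year <- suppressWarnings(as.integer(records$year))
  validate_hospitalizations(records)
  records
}

#' Write hospitalization records to CSV
#'
#' Emits the same dialect [read_hospitalizations()] reads, so that
#' write-then-read is the identity on valid record tables.
#'
#' @param records validated record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hospitalizations <- function(records, path) {
  validate_hospitalizations(records)
  utils::write.csv(records[, record_columns()], path, row.names = FALSE)
  invisible(path)
}

#' Read a DRG reference table from CSV
#'
#' The reference carries, per DRG code, the national mean LOS
#' (`benchmark_los`, the dynamic annual reference), the national outlier
#' cutoff (`threshold_los`, the fixed ministerial value) and the mean
#' reimbursement in EUR.  The threshold must strictly exceed the
#' benchmark for every DRG — outlier stays are a subset of long stays.
#'
#' @param path path to a CSV with columns `drg_code`, `benchmark_los`,
#'   `threshold_los`, `mean_reimbursement`.
#' @return data.frame keyed by `drg_code` (row names set to the codes).
#' @export
read_drg_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(ref) == 0) {
    warning("empty DRG reference table: ", path)
    ref <- data.frame(drg_code = character(), benchmark_los = numeric(),
                      threshold_los = numeric(), mean_reimbursement = numeric())
    rownames(ref) <- ref$drg_code
    return(ref)
  }
  needed <- c("drg_code", "benchmark_los", "threshold_los", "mean_reimbursement")
  missing <- setdiff(needed, names(ref))
  if (length(missing) > 0)
    stop_los("'%s' is missing columns: %s", path, paste(missing, collapse = ", "))
  ref <- ref[, needed]
  ref$drg_code <- as.character(ref$drg_code)
  validate_drg_reference(ref)
  rownames(ref) <- ref$drg_code
  ref
}

#' @rdname read_drg_reference
#' @param ref DRG reference data.frame.
#' @export
validate_drg_reference <- function(ref) {
  if (anyDuplicated(ref$drg_code))
    stop_los("duplicate drg_code: %s",
             ref$drg_code[duplicated(ref$drg_code)][1])
  bad <- which(!(ref$threshold_los > ref$benchmark_los))
  if (length(bad) > 0)
    stop_los("DRG %s: threshold_los (%g) must exceed benchmark_los (%g)",
             ref$drg_code[bad[1]], ref$threshold_los[bad[1]],
             ref$benchmark_los[bad[1]])
  if (any(ref$benchmark_los <= 0))
    stop_los("benchmark_los must be positive")
  if (any(ref$mean_reimbursement < 0))
    stop_los("mean_reimbursement must be non-negative")
  invisible(ref)
}

#' @rdname read_drg_reference
#' @export
write_drg_reference <- function(ref, path) {
  validate_drg_reference(ref)
  utils::write.csv(ref, path, row.names = FALSE)
  invisible(path)
}

drg_lookup <- function(ref, codes, field) {
  idx <- match(codes, ref$drg_code)
  if (anyNA(idx))
    stop_los("unknown DRG code '%s' (not in reference table)",
             codes[which(is.na(idx))[1]])
  ref[[field]][idx]
}
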