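#' Select the most frequent diagnosis groups
#'
#' Picks the `k` diagnosis groups with the highest number of cases; all
#' remaining groups fall into a single residual class.  Ties at the rank
#' boundary are broken lexicographically by group name, so the encoding
#' is deterministic.  With fewer than `k` distinct groups all of them are
#' kept (plus the residual class).
#'
#' @param records hospitalization record data.frame.
#' @param k number of named diagnosis classes to keep (default 10).
#' @return character vector of the selected group names, most frequent
#'   first; the residual class is implicit (see [encoding_spec()]).
#' @export
select_top_diagnoses <- function(records, k = 10) {
  if (nrow(records) == 0) stop_los("records must be non-empty")
  counts <- table(as.character(records$diagnosis_group))
  ord <- order(-as.integer(counts), names(counts))
  head(names(counts)[ord], k)
}

#' Encoding specification for the design matrix
#'
#' Describes how admission records are one-hot encoded.  The macro mode
#' covers the whole department; the micro mode targets a single clinical
#' unit and additionally encodes the internal-transfer indicator.
#'
#' @param mode `"macro"` or `"micro"`.
#' @param diagnoses character vector of named diagnosis classes (the
#'   top-`k` groups from [select_top_diagnoses()]); a residual indicator
#'   is always appended.
#' @param unit clinical unit name, required when `mode = "micro"`.
#' @return an object of class `encoding_spec`.
#' @export
encoding_spec <- function(mode = c("macro", "micro"), diagnoses, unit = NULL) {
  mode <- match.arg(mode)
  if (mode == "micro" && is.null(unit))
    stop_los("micro encoding requires a unit")
  if (mode == "micro" && !(unit %in% los_units()))
    stop_los("unknown unit '%s'", unit)
  structure(list(mode = mode, diagnoses = as.character(diagnoses),
                 unit = unit),
            class = "encoding_spec")
}

#' One-hot design matrix for the neural network
#'
#' Encodes records as a binary matrix with a fixed, documented column
#' order: sex (1), age class (4), cancer (1), admission type (3), time
#' slot (3), weekday (7), diagnosis group (k named + 1 residual), and —
#' in micro mode only — the internal-transfer indicator (1).  The full
#' dummy coding is used (no reference level dropped): a neural network
#' needs no identifiability constraint, and every categorical block then
#' sums to exactly 1 per row.
#'
#' @param records validated record data.frame (for micro specs, already
#'   restricted to the spec's unit).
#' @param spec an [encoding_spec()].
#' @return numeric 0/1 matrix with named columns, one row per record.
#' @export
encode_design_matrix <- function(records, spec) {
  stopifnot(inherits(spec, "encoding_spec"))
  if (spec$mode == "micro" &&
      any(as.character(records$unit) != spec$unit))
    stop_los("micro encoding for unit '%s' received records from other units",
             spec$unit)
  n <- nrow(records)

  block <- function(values, levels, prefix) {
    m <- matrix(0, n, length(levels),
                dimnames = list(NULL, paste0(prefix, levels)))
    m[cbind(seq_len(n), match(as.character(values), levels))] <- 1
    m
  }

  diag_levels <- c(spec$diagnoses, "__residual__")
  dg <- as.character(records$diagnosis_group)
  dg[!(dg %in% spec$diagnoses)] <- "__residual__"
  diag_block <- block(dg, diag_levels,
                      prefix = "diag:")
  colnames(diag_block) <- c(paste0("diag:", spec$diagnoses), "diag:residual")

  X <- cbind(
    sex_male = as.numeric(records$sex),
    block(records$age_class, los_age_classes(), "age:"),
    cancer = as.numeric(records$cancer),
    block(records$admission_type, los_admission_types(), "admission:"),
    block(records$time_slot, los_time_slots(), "slot:"),
    block(records$weekday, los_weekdays(), "day:"),
    diag_block
  )
  if (spec$mode == "micro")
    X <- cbind(X, transfer = as.numeric(records$transfer))
  X
}
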