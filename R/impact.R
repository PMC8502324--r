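#' Theoretical LOS under fully efficient interventions
#'
#' Assumes the department intervenes on every predicted-positive stay
#' and that the interventions are completely efficient: each such stay
#' is shortened to its DRG reference value (the national benchmark by
#' default, optionally the outlier threshold).  Stays already at or
#' below the reference, and all predicted negatives, are unchanged —
#' false positives cost nothing in days.
#'
#' @param records hospitalization data.frame.
#' @param predictions 0/1 vector aligned with `records`.
#' @param drg_ref DRG reference table.
#' @param reduce_to `"benchmark"` or `"threshold"`.
#' @return numeric vector of adjusted LOS, one per record.
#' @export
theoretical_los <- function(records, predictions, drg_ref,
                            reduce_to = c("benchmark", "threshold")) {
  reduce_to <- match.arg(reduce_to)
  if (nrow(records) != length(predictions))
    stop_los("predictions must align with records")
  field <- if (reduce_to == "benchmark") "benchmark_los" else "threshold_los"
  ref <- drg_lookup(drg_ref, as.character(records$drg_code), field)
  los <- as.numeric(records$los_days)
  ifelse(predictions == 1, pmin(los, ref), los)
}

#' Freed bed-days of a group
#'
#' `round(n * (mean_obs - mean_supported))`, rounded half away from
#' zero: the bed-days gained when the group's mean LOS drops from the
#' observed to the intervention-supported value.
#'
#' @param n number of hospitalizations in the group.
#' @param mean_obs observed mean LOS (days).
#' @param mean_supported post-intervention mean LOS (days).
#' @return integer day count.
#' @export
additional_days <- function(n, mean_obs, mean_supported) {
  if (n < 0) stop_los("n must be non-negative")
  if (mean_supported > mean_obs + 1e-9)
    stop_los("mean_supported must not exceed mean_obs")
  as.integer(round_half_away(n * (mean_obs - mean_supported)))
}

#' Additional hospitalizations from freed bed-days
#'
#' Converts unrounded freed days into admissions using the
#' post-intervention mean LOS as the per-admission bed occupancy:
#' `round(days_unrounded / mean_supported)`.
#'
#' @param days_unrounded freed bed-days before integer rounding.
#' @param mean_supported post-intervention mean LOS (days), positive.
#' @return integer hospitalization count.
#' @export
additional_hospitalizations <- function(days_unrounded, mean_supported) {
  if (mean_supported <= 0) stop_los("mean_supported must be positive")
  as.integer(round_half_away(days_unrounded / mean_supported))
}

#' Additional revenue from additional hospitalizations
#'
#' @param additional_hosp integer count of additional hospitalizations.
#' @param mean_reimbursement the group's case-mix mean reimbursement in
#'   EUR per hospitalization.
#' @return revenue in EUR.
#' @export
additional_revenue <- function(additional_hosp, mean_reimbursement) {
  if (additional_hosp < 0 || mean_reimbursement < 0)
    stop_los("inputs must be non-negative")
  additional_hosp * mean_reimbursement
}

#' Bed-day and revenue impact by group
#'
#' For each group (clinical unit, diagnosis group, diagnosis code, or
#' the whole cohort) computes the observed, benchmark and
#' intervention-supported mean LOS, then the freed bed-days
#' ([additional_days()] from the unrounded means), the additional
#' hospitalizations ([additional_hospitalizations()] from the unrounded
#' days and the supported mean) and the additional revenue at the
#' group's case-mix mean reimbursement.  An overall row is appended.
#'
#' @inheritParams theoretical_los
#' @param grouping `"unit"`, `"diagnosis_group"`, `"diagnosis_code"` or
#'   `"overall"`.
#' @return data.frame of class `impact_report`, one row per non-empty
#'   group plus `"(overall)"`.
#' @export
impact_by_group <- function(records, predictions, drg_ref,
                            grouping = c("unit", "diagnosis_group",
                                         "diagnosis_code", "overall"),
                            reduce_to = c("benchmark", "threshold")) {
  grouping <- match.arg(grouping)
  reduce_to <- match.arg(reduce_to)
  supported <- theoretical_los(records, predictions, drg_ref, reduce_to)
  benchmark <- drg_lookup(drg_ref, as.character(records$drg_code),
                          "benchmark_los")
  tariff <- drg_lookup(drg_ref, as.character(records$drg_code),
                       "mean_reimbursement")
  los <- as.numeric(records$los_days)

  keys <- if (grouping == "overall") rep("(overall)", nrow(records))
          else as.character(records[[grouping]])
  groups <- unique(keys)
  one_row <- function(rows, label) {
    n <- length(rows)
    mean_obs <- mean(los[rows])
    mean_sup <- mean(supported[rows])
    days_unrounded <- n * (mean_obs - mean_sup)
    hosp <- additional_hospitalizations(days_unrounded, mean_sup)
    data.frame(
      group = label, n_hosp = n,
      mean_los_observed = mean_obs,
      mean_los_benchmark = mean(benchmark[rows]),
      mean_los_supported = mean_sup,
      additional_days = additional_days(n, mean_obs, mean_sup),
      additional_hospitalizations = hosp,
      additional_revenue = additional_revenue(hosp, mean(tariff[rows])),
      stringsAsFactors = FALSE
    )
  }
  rows_list <- lapply(groups, function(g) one_row(which(keys == g), g))
  out <- do.call(rbind, rows_list)
  if (grouping != "overall")
    out <- rbind(out[order(out$group), , drop = FALSE],
                 one_row(seq_len(nrow(records)), "(overall)"))
  rownames(out) <- NULL
  class(out) <- c("impact_report", class(out))
  out
}
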