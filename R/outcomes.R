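#' Label hospitalizations as long and/or outlier stays
#'
#' A stay is *long* when its LOS strictly exceeds the national mean LOS
#' for its DRG (the benchmark) and an *outlier* when it strictly exceeds
#' the DRG's fixed national cutoff (the threshold).  Ties are labeled 0:
#' "longer than" means strict exceedance.  Because every threshold is
#' above its benchmark, outliers are always a subset of the long stays.
#'
#' @param records validated hospitalization data.frame.
#' @param drg_ref DRG reference table ([read_drg_reference()]); every
#'   `drg_code` in `records` must be present, otherwise an error names
#'   the missing code.
#' @return data.frame with integer columns `long` and `outlier`, one row
#'   per record, in the input order.
#' @export
label_outcomes <- function(records, drg_ref) {
  benchmark <- drg_lookup(drg_ref, as.character(records$drg_code),
                          "benchmark_los")
  threshold <- drg_lookup(drg_ref, as.character(records$drg_code),
                          "threshold_los")
  los <- as.numeric(records$los_days)
  data.frame(long = as.integer(los > benchmark),
             outlier = as.integer(los > threshold))
}

#' Outcome prevalences of a record set
#'
#' @inheritParams label_outcomes
#' @return named numeric vector `c(long = ..., outlier = ...)` of
#'   fractions in \[0, 1\]; the outlier fraction never exceeds the long
#'   fraction.
#' @export
outcome_rates <- function(records, drg_ref) {
  if (nrow(records) == 0) stop_los("records must be non-empty")
  labels <- label_outcomes(records, drg_ref)
  c(long = mean(labels$long), outlier = mean(labels$outlier))
}
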