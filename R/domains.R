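# Categorical domains of the admission record. Exactly one level of each
# categorical field is active per hospitalization; patients under 18 are
# outside the department's remit, so the age classes cover adults only.

los_units <- function() {
  c("cardiology", "hematology", "geriatrics", "infectious diseases",
    "internal medicine", "emergency medicine", "nephrology", "neurology",
    "coronary care", "gastroenterology", "oncology",
    "respiratory diseases", "rheumatology")
}

los_age_classes <- function() c("18-40", "41-65", "66-75", ">75")

los_admission_types <- function() c("urgent_direct", "urgent_from_ER", "planned")

los_time_slots <- function() c("morning", "afternoon", "night")

los_weekdays <- function() c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

los_discharge_modes <- function() c("home", "transfer", "death", "other")

# Units large enough to carry their own model in the micro analysis.
micro_units_default <- function() {
  c("internal medicine", "cardiology", "emergency medicine", "geriatrics",
    "respiratory diseases", "neurology", "oncology")
}

record_columns <- function() {
  c("record_id", "unit", "sex", "age_class", "cancer", "admission_type",
    "time_slot", "weekday", "diagnosis_code", "diagnosis_group", "drg_code",
    "transfer", "los_days", "discharge_mode", "year")
}

#' Round half away from zero
#'
#' Commercial rounding used throughout the reporting layer: exact halves
#' move away from zero instead of to the even digit as in [round()].
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return rounded numeric vector.
#' @examples
#' round_half_away(0.5)   # 1
#' round_half_away(-0.5)  # -1
#' round_half_away(2.345, 2)
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_los <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_binary01 <- function(x) is.numeric(x) && all(x %in% c(0, 1))
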