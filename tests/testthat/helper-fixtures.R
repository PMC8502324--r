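# Small in-code fixtures shared across test files.

# A hand-written 3-row record table with valid levels everywhere.
toy_records <- function() {
  data.frame(
    record_id = c("r1", "r2", "r3"),
    unit = c("cardiology", "internal medicine", "geriatrics"),
    sex = c(1, 0, 1),
    age_class = c("41-65", ">75", "66-75"),
    cancer = c(0, 1, 0),
    admission_type = c("planned", "urgent_from_ER", "urgent_direct"),
    time_slot = c("morning", "afternoon", "night"),
    weekday = c("Mon", "Wed", "Sun"),
    diagnosis_code = c("4280", "486", "0389"),
    diagnosis_group = c("heart failure", "pneumonia", "sepsis"),
    drg_code = c("X01", "X02", "X01"),
    transfer = c(0, 0, 1),
    los_days = c(6, 12.5, 3),
    discharge_mode = c("home", "death", "transfer"),
    year = c(2018L, 2018L, 2018L),
    stringsAsFactors = FALSE
  )
}

toy_drg_ref <- function() {
  ref <- data.frame(
    drg_code = c("X01", "X02"),
    benchmark_los = c(5.764, 9.0),
    threshold_los = c(12.0, 20.0),
    mean_reimbursement = c(3000, 4500),
    stringsAsFactors = FALSE
  )
  rownames(ref) <- ref$drg_code
  ref
}

# A quickly generated valid cohort for plumbing tests.
small_cohort <- function(n = 400, seed = 1) {
  generate_cohort(cohort_config(n, seed = seed))
}

# Training settings sized for unit tests: few hidden nodes, short runs.
fast_control <- function(...) {
  training_control(n_hidden = 6, learning_rate = 0.3, max_epochs = 60, ...)
}
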