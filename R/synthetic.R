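# Synthetic admission cohorts.
#
# Length of stay is generated log-normally:
#   log LOS = mu_drg + v(x) + sd * Z,   v(x) = sum of covariate level effects
# with independent categorical covariates whose per-unit prevalences default
# to the department's published marginals.  The DRG reference table is derived
# from the generating model itself: the benchmark is the exact marginal mean
# LOS per DRG and the threshold is the upper quantile attaining a configured
# overall outlier fraction, both in closed form from the discrete distribution
# of v(x) (no Monte Carlo).

# Published per-unit covariate prevalences (percent).  Column 1 is the whole
# department (used for units without their own column).
table1_prevalences <- function() {
  cols <- c("DIEM", "internal medicine", "cardiology", "emergency medicine",
            "geriatrics", "respiratory diseases", "neurology", "oncology")
  m <- function(...) setNames(list(...), cols)
  list(
    sex_male = setNames(c(55.55, 50.26, 65.69, 55.59, 39.80, 61.34, 54.24, 56.43) / 100, cols),
    cancer   = setNames(c(15.73, 10.23,  1.14,  5.00,  6.20, 20.17,  8.35, 94.98) / 100, cols),
    transfer = setNames(c(NA,     0.09,  0.20,  0.16,  0.04,  0.06,  0.09,  0.08) / 100, cols),
    age = m(c(`18-40` = 4.72, `41-65` = 24.57, `66-75` = 21.88, `>75` = 48.84),
            c(`18-40` = 2.30, `41-65` = 15.27, `66-75` = 18.46, `>75` = 63.97),
            c(`18-40` = 1.46, `41-65` = 29.12, `66-75` = 32.36, `>75` = 37.06),
            c(`18-40` = 4.83, `41-65` = 19.93, `66-75` = 20.64, `>75` = 54.60),
            c(`18-40` = 0.00, `41-65` = 0.23,  `66-75` = 6.54,  `>75` = 93.24),
            c(`18-40` = 1.95, `41-65` = 21.84, `66-75` = 25.59, `>75` = 50.63),
            c(`18-40` = 6.33, `41-65` = 25.18, `66-75` = 19.42, `>75` = 49.06),
            c(`18-40` = 1.61, `41-65` = 42.97, `66-75` = 31.53, `>75` = 23.90)),
    admission = m(c(urgent_direct = 12.8, urgent_from_ER = 69.0, planned = 18.2),
                  c(urgent_direct = 2.40, urgent_from_ER = 93.60, planned = 4.10),
                  c(urgent_direct = 4.00, urgent_from_ER = 24.70, planned = 71.40),
                  c(urgent_direct = 3.40, urgent_from_ER = 96.20, planned = 0.40),
                  c(urgent_direct = 1.80, urgent_from_ER = 96.60, planned = 1.60),
                  c(urgent_direct = 21.30, urgent_from_ER = 62.40, planned = 16.30),
                  c(urgent_direct = 12.40, urgent_from_ER = 86.00, planned = 1.60),
                  c(urgent_direct = 18.50, urgent_from_ER = 42.00, planned = 39.60)),
    time_slot = m(c(morning = 33.20, afternoon = 48.80, night = 18.10),
                  c(morning = 16.50, afternoon = 60.60, night = 22.90),
                  c(morning = 74.10, afternoon = 16.70, night = 9.20),
                  c(morning = 12.70, afternoon = 68.40, night = 18.90),
                  c(morning = 19.50, afternoon = 56.80, night = 23.70),
                  c(morning = 31.30, afternoon = 54.80, night = 13.90),
                  c(morning = 34.20, afternoon = 43.70, night = 22.00),
                  c(morning = 57.20, afternoon = 33.50, night = 9.20)),
    weekday = m(c(Mon = 13.90, Tue = 16.30, Wed = 16.60, Thu = 15.80, Fri = 16.30, Sat = 11.70, Sun = 10.15),
                c(Mon = 13.20, Tue = 14.00, Wed = 16.10, Thu = 14.20, Fri = 15.90, Sat = 14.90, Sun = 11.70),
                c(Mon = 14.50, Tue = 19.80, Wed = 17.30, Thu = 20.20, Fri = 17.80, Sat = 4.10, Sun = 6.30),
                c(Mon = 13.80, Tue = 15.90, Wed = 14.30, Thu = 15.50, Fri = 15.10, Sat = 13.20, Sun = 12.20),
                c(Mon = 12.40, Tue = 13.90, Wed = 15.30, Thu = 15.90, Fri = 15.60, Sat = 15.10, Sun = 11.80),
                c(Mon = 12.20, Tue = 18.20, Wed = 16.10, Thu = 15.30, Fri = 17.50, Sat = 11.80, Sun = 8.80),
                c(Mon = 12.50, Tue = 14.20, Wed = 17.00, Thu = 16.40, Fri = 14.20, Sat = 13.50, Sun = 12.10),
                c(Mon = 17.10, Tue = 17.70, Wed = 16.10, Thu = 16.70, Fri = 16.70, Sat = 8.80, Sun = 7.00))
  )
}

# Validation-set sizes are the only published per-unit volumes; the default
# unit mix is proportional to them, with the six small units sharing the rest.
default_unit_mix <- function() {
  big <- c("internal medicine" = 449, "cardiology" = 411,
           "emergency medicine" = 373, "geriatrics" = 296,
           "respiratory diseases" = 240, "neurology" = 232, "oncology" = 166)
  small_units <- setdiff(los_units(), names(big))
  small <- setNames(rep((2819 - sum(big)) / length(small_units),
                        length(small_units)), small_units)
  mix <- c(big, small)[los_units()]
  mix / sum(mix)
}

default_diagnosis_mix <- function() {
  c("heart failure" = 0.14, "pneumonia" = 0.12, "sepsis" = 0.09,
    "copd" = 0.08, "stroke" = 0.08, "atrial fibrillation" = 0.07,
    "urinary tract infection" = 0.06, "gastrointestinal bleeding" = 0.06,
    "renal failure" = 0.05, "cancer chemotherapy" = 0.05,
    "cellulitis" = 0.04, "syncope" = 0.04, "anemia" = 0.03,
    "delirium" = 0.03, "other" = 0.06)
}

default_diagnosis_codes <- function() {
  c("heart failure" = "4280", "pneumonia" = "486", "sepsis" = "0389",
    "copd" = "49121", "stroke" = "43491", "atrial fibrillation" = "42731",
    "urinary tract infection" = "5990", "gastrointestinal bleeding" = "5789",
    "renal failure" = "5849", "cancer chemotherapy" = "V5811",
    "cellulitis" = "68210", "syncope" = "7802", "anemia" = "2859",
    "delirium" = "2930", "other" = "7999")
}

#' Zero covariate-effect structure
#'
#' @param diagnosis_groups names of the diagnosis groups in the mix.
#' @return effect list with every level effect set to 0, in the layout
#'   [cohort_config()] expects.
#' @export
zero_effects <- function(diagnosis_groups = names(default_diagnosis_mix())) {
  list(
    sex_male = 0,
    age = setNames(rep(0, 4), los_age_classes()),
    cancer = 0,
    admission = setNames(rep(0, 3), los_admission_types()),
    time_slot = setNames(rep(0, 3), los_time_slots()),
    weekday = setNames(rep(0, 7), los_weekdays()),
    diagnosis = setNames(rep(0, length(diagnosis_groups)), diagnosis_groups)
  )
}

# Moderate, clinically plausible log-scale effects: older, urgent,
# oncological and septic admissions stay longer; planned ones shorter.
default_effects <- function() {
  e <- zero_effects()
  e$sex_male <- 0.03
  e$age[] <- c(-0.15, -0.05, 0.05, 0.15)
  e$cancer <- 0.20
  e$admission[] <- c(0.05, 0.10, -0.15)
  e$time_slot[] <- c(-0.05, 0.02, 0.08)
  e$weekday[c("Fri", "Sat", "Sun")] <- c(0.05, 0.08, 0.08)
  e$diagnosis[c("heart failure", "pneumonia", "sepsis", "stroke")] <-
    c(0.10, 0.12, 0.25, 0.15)
  e
}

normalize_probs <- function(p, what) {
  if (any(p < 0)) stop_los("negative probability in %s", what)
  s <- sum(p)
  if (abs(s - 1) > 0.05)
    stop_los("%s probabilities sum to %.3f, expected ~1", what, s)
  p / s
}

unit_prevalences <- function(prev, unit) {
  pick <- function(x) if (unit %in% names(x)) x[[unit]] else x[["DIEM"]]
  list(sex_male = pick(prev$sex_male),
       cancer = pick(prev$cancer),
       transfer = {
         tr <- pick(prev$transfer)
         if (is.na(tr)) 0 else tr
       },
       age = normalize_probs(pick(prev$age) / 100, "age"),
       admission = normalize_probs(pick(prev$admission) / 100, "admission"),
       time_slot = normalize_probs(pick(prev$time_slot) / 100, "time_slot"),
       weekday = normalize_probs(pick(prev$weekday) / 100, "weekday"))
}

# Exact discrete distribution of v(x) under the configured unit mix:
# enumerate all covariate level combinations (values shared across units,
# probabilities mixed over units).
effect_distribution <- function(config) {
  eff <- config$effects
  blocks <- list(
    sex = c(0, eff$sex_male),         # female, male
    age = eff$age,
    cancer = c(0, eff$cancer),
    admission = eff$admission,
    time_slot = eff$time_slot,
    weekday = eff$weekday,
    diagnosis = eff$diagnosis
  )
  idx <- expand.grid(lapply(blocks, seq_along), KEEP.OUT.ATTRS = FALSE)
  v <- rowSums(mapply(function(b, i) b[i], blocks, idx))

  q <- numeric(nrow(idx))
  for (unit in names(config$unit_mix)) {
    pu <- unit_prevalences(config$prevalences, unit)
    bp <- list(
      sex = c(1 - pu$sex_male, pu$sex_male),
      age = pu$age,
      cancer = c(1 - config$cancer_prob(unit), config$cancer_prob(unit)),
      admission = pu$admission,
      time_slot = pu$time_slot,
      weekday = pu$weekday,
      diagnosis = config$diagnosis_mix
    )
    pr <- Reduce(`*`, mapply(function(b, i) b[i], bp, idx, SIMPLIFY = FALSE))
    q <- q + config$unit_mix[[unit]] * pr
  }
  list(v = v, q = q)
}

#' Configure a synthetic admission cohort
#'
#' Builds a fully specified generating model for [generate_cohort()].
#' Covariates are drawn independently within each clinical unit at the
#' configured prevalences; log LOS is the DRG baseline plus additive
#' covariate level effects plus Gaussian noise.  The DRG reference table
#' implied by the model is computed in closed form: the benchmark is the
#' exact marginal mean LOS of each DRG and the threshold the upper
#' quantile at which the configured overall outlier fraction is attained
#' in expectation.  When `los_sd` is `NULL` the noise SD is calibrated
#' (1-D root finding on the exact exceedance probability) so that the
#' expected long-stay fraction equals `target_long_fraction`.
#'
#' @param n_records number of hospitalizations to generate.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @param year calendar year stamped on the records.
#' @param unit_mix named probability vector over clinical units
#'   (default: proportional to the department's published unit volumes).
#' @param effects covariate level effects on log LOS (see
#'   [zero_effects()] for the layout); default: moderate clinically
#'   plausible values.
#' @param diagnosis_mix named probability vector over diagnosis groups.
#' @param n_drg number of DRG codes; baselines `drg_mu` are evenly
#'   spaced on the log scale between `log(4)` and `log(12)` days.
#' @param los_sd log-scale noise SD, or `NULL` to calibrate it to
#'   `target_long_fraction`.
#' @param target_long_fraction expected fraction of stays exceeding
#'   their DRG benchmark (default 0.4006).
#' @param target_outlier_fraction expected fraction exceeding the DRG
#'   threshold (default 0.0374).
#' @param reimbursement_base,reimbursement_per_day per-DRG mean tariff
#'   in EUR: `base + per_day * benchmark_los`.
#' @param cancer_override optional single probability replacing the
#'   per-unit cancer prevalences (used to plant a dominant effect on a
#'   covariate with a controlled prevalence).
#' @return object of class `cohort_config`, including the calibrated
#'   `los_sd` and the implied `drg_ref` table.
#' @export
cohort_config <- function(n_records, seed = 1, year = 2018,
                          unit_mix = NULL, effects = NULL,
                          diagnosis_mix = NULL, n_drg = 20,
                          los_sd = NULL,
                          target_long_fraction = 0.4006,
                          target_outlier_fraction = 0.0374,
                          reimbursement_base = 2000,
                          reimbursement_per_day = 450,
                          cancer_override = NULL) {
  if (n_records < 1) stop_los("n_records must be at least 1")
  prevalences <- table1_prevalences()
  unit_mix <- normalize_probs(unit_mix %||% default_unit_mix(), "unit_mix")
  diagnosis_mix <- normalize_probs(diagnosis_mix %||% default_diagnosis_mix(),
                                   "diagnosis_mix")
  effects <- effects %||% default_effects()
  if (!setequal(names(effects$diagnosis), names(diagnosis_mix)))
    stop_los("effects$diagnosis must name the same groups as diagnosis_mix")
  effects$diagnosis <- effects$diagnosis[names(diagnosis_mix)]

  config <- list(
    n_records = as.integer(n_records), seed = as.integer(seed),
    year = as.integer(year),
    unit_mix = unit_mix, prevalences = prevalences,
    diagnosis_mix = diagnosis_mix,
    diagnosis_codes = default_diagnosis_codes()[names(diagnosis_mix)],
    effects = effects,
    n_drg = as.integer(n_drg),
    drg_mu = seq(log(4), log(12), length.out = n_drg),
    target_long_fraction = target_long_fraction,
    target_outlier_fraction = target_outlier_fraction,
    reimbursement_base = reimbursement_base,
    reimbursement_per_day = reimbursement_per_day,
    cancer_prob = function(unit) {
      if (!is.null(cancer_override)) return(cancer_override)
      p <- table1_prevalences()$cancer
      if (unit %in% names(p)) p[[unit]] else p[["DIEM"]]
    }
  )
  if (anyNA(config$diagnosis_codes))
    config$diagnosis_codes <- setNames(
      ifelse(is.na(config$diagnosis_codes),
             sprintf("X%03d", seq_along(config$diagnosis_codes)),
             config$diagnosis_codes),
      names(diagnosis_mix))

  dist <- effect_distribution(config)
  long_frac <- function(sd) {
    lnA <- log(sum(dist$q * exp(dist$v))) + sd^2 / 2
    sum(dist$q * pnorm((lnA - dist$v) / sd, lower.tail = FALSE))
  }
  if (is.null(los_sd)) {
    f <- function(sd) long_frac(sd) - target_long_fraction
    if (f(0.02) < 0)
      stop_los("target_long_fraction %.4f unattainable under these effects",
               target_long_fraction)
    los_sd <- uniroot(f, c(0.02, 5), tol = 1e-10)$root
  }
  if (los_sd <= 0) stop_los("los_sd must be positive")
  config$los_sd <- los_sd
  config$expected_long_fraction <- long_frac(los_sd)

  lnA <- log(sum(dist$q * exp(dist$v))) + los_sd^2 / 2
  if (config$expected_long_fraction <= target_outlier_fraction)
    stop_los("outlier target must be below the expected long fraction")
  g <- function(lnB)
    sum(dist$q * pnorm((lnB - dist$v) / los_sd, lower.tail = FALSE)) -
      target_outlier_fraction
  lnB <- uniroot(g, c(lnA, max(dist$v) + 12 * los_sd), tol = 1e-10)$root
  config$benchmark_factor <- exp(lnA)
  config$threshold_factor <- exp(lnB)

  benchmark <- exp(config$drg_mu) * config$benchmark_factor
  config$drg_ref <- data.frame(
    drg_code = sprintf("D%02d", seq_len(n_drg)),
    benchmark_los = benchmark,
    threshold_los = exp(config$drg_mu) * config$threshold_factor,
    mean_reimbursement = reimbursement_base + reimbursement_per_day * benchmark,
    stringsAsFactors = FALSE
  )
  rownames(config$drg_ref) <- config$drg_ref$drg_code
  validate_drg_reference(config$drg_ref)
  class(config) <- "cohort_config"
  config
}

sample_level <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic admission cohort
#'
#' Draws `config$n_records` hospitalizations from the generating model
#' of a [cohort_config()]: unit, covariates (per-unit prevalences),
#' diagnosis group, DRG, and a log-normal LOS shifted by the planted
#' covariate effects.  Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `records` (validated data.frame) and `drg_ref`
#'   (the model-implied DRG reference table).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_records
  set.seed(config$seed)

  unit <- sample_level(n, config$unit_mix)
  sex <- cancer <- transfer <- numeric(n)
  age_class <- admission <- slot <- wday <- character(n)
  for (u in unique(unit)) {
    rows <- which(unit == u)
    pu <- unit_prevalences(config$prevalences, u)
    sex[rows] <- rbinom(length(rows), 1, pu$sex_male)
    cancer[rows] <- rbinom(length(rows), 1, config$cancer_prob(u))
    transfer[rows] <- rbinom(length(rows), 1, pu$transfer)
    age_class[rows] <- sample_level(length(rows), pu$age)
    admission[rows] <- sample_level(length(rows), pu$admission)
    slot[rows] <- sample_level(length(rows), pu$time_slot)
    wday[rows] <- sample_level(length(rows), pu$weekday)
  }
  diagnosis_group <- sample_level(n, config$diagnosis_mix)
  drg_idx <- sample.int(config$n_drg, n, replace = TRUE)

  eff <- config$effects
  v <- eff$sex_male * sex + eff$cancer * cancer +
    eff$age[age_class] + eff$admission[admission] +
    eff$time_slot[slot] + eff$weekday[wday] +
    eff$diagnosis[diagnosis_group]
  los <- exp(config$drg_mu[drg_idx] + v + config$los_sd * rnorm(n))

  records <- data.frame(
    record_id = sprintf("%d-%06d", config$year, seq_len(n)),
    unit = unit, sex = sex, age_class = age_class, cancer = cancer,
    admission_type = admission, time_slot = slot, weekday = wday,
    diagnosis_code = unname(config$diagnosis_codes[diagnosis_group]),
    diagnosis_group = diagnosis_group,
    drg_code = config$drg_ref$drg_code[drg_idx],
    transfer = transfer, los_days = los,
    discharge_mode = sample_level(n, c(home = 0.85, transfer = 0.05,
                                       death = 0.07, other = 0.03)),
    year = config$year,
    stringsAsFactors = FALSE
  )
  validate_hospitalizations(records)
  list(records = records, drg_ref = config$drg_ref)
}

#' Well-separated benchmark cohort with one dominant covariate
#'
#' A frozen generating model for parameter-recovery studies: the cancer
#' indicator carries a dominant log-scale effect (+2.0, at a 30%
#' prevalence) while age, admission type, time slot and diagnosis group
#' carry moderate supporting effects, against a small noise SD (0.3).
#' The resulting long-stay outcome is nearly determined by the
#' covariates, so the selection floors (sensitivity 0.80, specificity
#' 0.70) are attainable and the dominant covariate should be recovered
#' as the top Garson contributor with a positive sign.
#'
#' @param n_records cohort size (default 10000).
#' @param seed integer seed.
#' @return a [cohort_config()].
#' @export
config_parameter_recovery <- function(n_records = 10000, seed = 1) {
  eff <- zero_effects()
  eff$cancer <- 2.0
  eff$age[] <- c(-0.3, -0.1, 0.1, 0.3)
  eff$admission[] <- c(0.05, 0.2, -0.25)
  eff$time_slot[] <- c(-0.05, 0.02, 0.1)
  eff$diagnosis[c("sepsis", "pneumonia", "heart failure", "stroke")] <-
    c(0.35, 0.2, 0.15, 0.25)
  cohort_config(n_records, seed = seed, effects = eff, los_sd = 0.3,
                cancer_override = 0.3)
}

#' Ground-truth covariate effects of a generating model
#'
#' Flattens the planted effect structure to one value per design-matrix
#' column, ordered by decreasing absolute effect (ties keep the design
#' column order), for parameter-recovery tests against [garson()] and
#' [contribution_signs()].
#'
#' @param config a [cohort_config()].
#' @return named numeric vector of log-scale effects.
#' @export
planted_truth <- function(config) {
  eff <- config$effects
  flat <- c(
    sex_male = unname(eff$sex_male),
    setNames(eff$age, paste0("age:", names(eff$age))),
    cancer = unname(eff$cancer),
    setNames(eff$admission, paste0("admission:", names(eff$admission))),
    setNames(eff$time_slot, paste0("slot:", names(eff$time_slot))),
    setNames(eff$weekday, paste0("day:", names(eff$weekday))),
    setNames(eff$diagnosis, paste0("diag:", names(eff$diagnosis)))
  )
  flat[order(-abs(flat))]
}
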