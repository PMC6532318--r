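# Published summary tables of the MSNS validation cohort (n = 585,
# 95 expired / 490 discharged). These counts drive the default
# synthetic-cohort model and the packaged descriptive checks.

.table2_baseline <- function() {
  tibble::tribble(
    ~attribute, ~category, ~count, ~percent,
    "gestational_age", "preterm", 240L, 41.0,
    "gestational_age", "term", 342L, 58.5,
    "gestational_age", "postterm", 3L, 0.5,
    "birth_weight", "normal_gt2500g", 93L, 15.9,
    "birth_weight", "low_1500_2500g", 211L, 36.1,
    "birth_weight", "very_low_lt1500g", 281L, 48.0,
    "sex", "male", 320L, 54.7,
    "sex", "female", 265L, 45.3,
    "referral", "inborn", 381L, 65.1,
    "referral", "referred", 204L, 34.9,
    "mode_of_delivery", "vaginal", 438L, 74.9,
    "mode_of_delivery", "caesarean", 120L, 20.5,
    "mode_of_delivery", "forceps_vacuum", 27L, 4.6,
    "outcome", "discharged", 490L, 83.8,
    "outcome", "expired", 95L, 16.2
  )
}

.table3_score_counts <- function() {
  tibble::tribble(
    ~parameter, ~score, ~discharged, ~expired,
    "respiratory_effort", 0L, 54L, 56L,
    "respiratory_effort", 1L, 87L, 16L,
    "respiratory_effort", 2L, 349L, 23L,
    "heart_rate", 0L, 7L, 20L,
    "heart_rate", 1L, 45L, 21L,
    "heart_rate", 2L, 438L, 54L,
    "axillary_temperature", 0L, 26L, 25L,
    "axillary_temperature", 1L, 314L, 62L,
    "axillary_temperature", 2L, 150L, 8L,
    "capillary_refill_time", 0L, 4L, 8L,
    "capillary_refill_time", 1L, 38L, 46L,
    "capillary_refill_time", 2L, 448L, 41L,
    "random_blood_sugar", 0L, 2L, 4L,
    "random_blood_sugar", 1L, 72L, 13L,
    "random_blood_sugar", 2L, 416L, 78L,
    "spo2", 0L, 15L, 37L,
    "spo2", 1L, 44L, 34L,
    "spo2", 2L, 431L, 24L,
    "gestational_age", 0L, 24L, 39L,
    "gestational_age", 1L, 146L, 31L,
    "gestational_age", 2L, 320L, 25L,
    "birth_weight", 0L, 40L, 53L,
    "birth_weight", 1L, 183L, 28L,
    "birth_weight", 2L, 267L, 14L
  )
}

#' Published summary tables of the MSNS validation cohort
#'
#' Immutable packaged constants: the baseline characteristics of the
#' 585-neonate validation cohort and the per-parameter score-category
#' counts split by outcome (95 expired, 490 discharged). These counts
#' parameterise [default_cohort_model()] and the descriptive
#' recomputations in the package tests.
#'
#' @return A list with elements `baseline` (tibble: attribute, category,
#'   count, percent as printed), `score_counts` (tibble: parameter, score, discharged,
#'   expired), `n_total` (585), `n_expired` (95), `n_discharged` (490).
#' @export
#' @examples
#' tabs <- msns_study_tables()
#' sum(tabs$score_counts$expired) / 8  # each parameter column sums to 95
msns_study_tables <- function() {
  list(
    baseline = .table2_baseline(),
    score_counts = .table3_score_counts(),
    n_total = 585L,
    n_expired = 95L,
    n_discharged = 490L
  )
}
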