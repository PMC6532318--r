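# Scoring rubric for the Modified Sick Neonatal Score (MSNS).
#
# Eight clinical parameters are each scored 0 (worst), 1, or 2 (best);
# the total ranges 0-16. Two physiologic regions fall outside the
# published rubric (axillary temperature above 37.5 degC, and a
# respiratory rate below 40/min without apnea or grunting); `mode`
# controls whether these raise an error ("strict", the default) or are
# assigned a conservative score with a recorded warning ("lenient").

#' Names of the eight scored parameters
#'
#' Order matches the published rubric; the per-parameter score columns
#' produced by [msns_score()] use these names.
#'
#' @format Character vector of length 8.
#' @export
MSNS_PARAMETERS <- c(
  "respiratory_effort", "heart_rate", "axillary_temperature",
  "capillary_refill_time", "random_blood_sugar", "spo2",
  "gestational_age", "birth_weight"
)

# Internal scorers: each returns list(score = integer vector,
# note = character vector, NA where the value is inside the rubric).
# Notes mark rubric-undefined inputs; strict mode turns them into errors.

.score_respiratory_effort <- function(apnea, grunt, respiratory_rate) {
  distress <- apnea | grunt
  score <- dplyr::case_when(
    distress ~ 0L,
    respiratory_rate > 60 ~ 1L,
    respiratory_rate >= 40 ~ 2L,
    TRUE ~ 0L
  )
  note <- ifelse(
    !distress & respiratory_rate < 40,
    sprintf(
      "respiratory_rate %g < 40/min without apnea/grunt is outside the rubric; scored 0",
      respiratory_rate
    ),
    NA_character_
  )
  list(score = score, note = note)
}

.score_heart_rate <- function(heart_rate, asystole) {
  score <- dplyr::case_when(
    asystole | heart_rate < 100 ~ 0L,
    heart_rate > 160 ~ 1L,
    TRUE ~ 2L
  )
  list(score = score, note = rep(NA_character_, length(score)))
}

.score_temperature <- function(axillary_temperature) {
  t <- axillary_temperature
  score <- dplyr::case_when(
    t < 36 ~ 0L,
    t < 36.5 ~ 1L,
    t <= 37.5 ~ 2L,
    TRUE ~ 1L
  )
  note <- ifelse(
    t > 37.5,
    sprintf("axillary_temperature %g > 37.5 degC (fever) is outside the rubric; scored 1", t),
    NA_character_
  )
  list(score = score, note = note)
}

.score_crt <- function(capillary_refill_time) {
  score <- dplyr::case_when(
    capillary_refill_time > 5 ~ 0L,
    capillary_refill_time >= 3 ~ 1L,
    TRUE ~ 2L
  )
  list(score = score, note = rep(NA_character_, length(score)))
}

.score_rbs <- function(random_blood_sugar) {
  score <- dplyr::case_when(
    random_blood_sugar < 40 ~ 0L,
    random_blood_sugar <= 60 ~ 1L,
    TRUE ~ 2L
  )
  list(score = score, note = rep(NA_character_, length(score)))
}

.score_spo2 <- function(spo2_room_air) {
  score <- dplyr::case_when(
    spo2_room_air < 85 ~ 0L,
    spo2_room_air <= 92 ~ 1L,
    TRUE ~ 2L
  )
  list(score = score, note = rep(NA_character_, length(score)))
}

.score_gestational_age <- function(gestational_age_days) {
  score <- dplyr::case_when(
    gestational_age_days < 224 ~ 0L,   # below 32 weeks
    gestational_age_days <= 258 ~ 1L,  # 32w0d - 36w6d
    TRUE ~ 2L                          # 37w0d and above
  )
  list(score = score, note = rep(NA_character_, length(score)))
}

.score_birth_weight <- function(birth_weight_kg) {
  score <- dplyr::case_when(
    birth_weight_kg < 1.5 ~ 0L,
    birth_weight_kg < 2.5 ~ 1L,
    TRUE ~ 2L
  )
  list(score = score, note = rep(NA_character_, length(score)))
}

.apply_mode <- function(res, mode, parameter) {
  bad <- !is.na(res$note)
  if (any(bad)) {
    if (mode == "strict") {
      stop(
        "rubric-undefined value(s) for ", parameter, ": ",
        paste(res$note[which(bad)[seq_len(min(5L, sum(bad)))]], collapse = "; "),
        call. = FALSE
      )
    }
    warning(
      sum(bad), " ", parameter,
      " value(s) outside the rubric scored leniently", call. = FALSE
    )
  }
  res$score
}

#' Score respiratory effort
#'
#' Apnea or grunting scores 0 regardless of rate; tachypnea (rate above
#' 60/min) scores 1; a normal rate of 40-60/min scores 2. A rate below
#' 40/min without apnea or grunting is not covered by the rubric: in
#' strict mode this is an error, in lenient mode it scores 0 with a
#' warning (bradypnea is at least as ominous as tachypnea).
#'
#' @param apnea,grunt Logical vectors: apneic episodes / grunting present.
#' @param respiratory_rate Breaths per minute, non-negative.
#' @param mode `"strict"` (default) or `"lenient"` handling of
#'   rubric-undefined values.
#' @return Integer vector of scores in 0, 1, 2.
#' @export
#' @examples
#' score_respiratory_effort(FALSE, FALSE, c(50, 70))
score_respiratory_effort <- function(apnea, grunt, respiratory_rate,
                                     mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(all(respiratory_rate >= 0))
  .apply_mode(
    .score_respiratory_effort(apnea, grunt, respiratory_rate),
    mode, "respiratory_effort"
  )
}

#' Score heart rate
#'
#' Bradycardia (below 100/min) or asystole scores 0; tachycardia (above
#' 160/min) scores 1; 100-160/min scores 2. Bradycardia is taken as the
#' complement of the normal band so every rate maps to one category.
#'
#' @param heart_rate Beats per minute, non-negative (0 encodes asystole).
#' @param asystole Logical vector.
#' @return Integer vector of scores in 0, 1, 2.
#' @export
score_heart_rate <- function(heart_rate, asystole = FALSE) {
  stopifnot(all(heart_rate >= 0))
  .score_heart_rate(heart_rate, asystole)$score
}

#' Score axillary temperature
#'
#' Below 36 degC scores 0, \[36, 36.5) scores 1, \[36.5, 37.5\] scores 2.
#' The shared 36.5 endpoint is assigned to the higher category so each
#' measurement maps to exactly one score. Temperatures above 37.5 degC
#' (fever) are outside the rubric: strict mode errors, lenient mode
#' scores 1 with a warning.
#'
#' @param axillary_temperature Degrees Celsius.
#' @inheritParams score_respiratory_effort
#' @return Integer vector of scores in 0, 1, 2.
#' @export
score_temperature <- function(axillary_temperature,
                              mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  .apply_mode(.score_temperature(axillary_temperature), mode,
              "axillary_temperature")
}

#' Score capillary refill time
#'
#' Above 5 s scores 0, 3-5 s scores 1, below 3 s scores 2.
#'
#' @param capillary_refill_time Seconds, positive.
#' @return Integer vector of scores in 0, 1, 2.
#' @export
score_crt <- function(capillary_refill_time) {
  stopifnot(all(capillary_refill_time > 0))
  .score_crt(capillary_refill_time)$score
}

#' Score random blood sugar
#'
#' Below 40 mg/dL scores 0, 40-60 scores 1, above 60 scores 2.
#'
#' @param random_blood_sugar mg/dL, non-negative.
#' @return Integer vector of scores in 0, 1, 2.
#' @export
score_rbs <- function(random_blood_sugar) {
  stopifnot(all(random_blood_sugar >= 0))
  .score_rbs(random_blood_sugar)$score
}

#' Score oxygen saturation in room air
#'
#' Below 85% scores 0, 85-92% scores 1, above 92% scores 2.
#'
#' @param spo2_room_air Percent saturation, 0-100.
#' @return Integer vector of scores in 0, 1, 2.
#' @export
score_spo2 <- function(spo2_room_air) {
  stopifnot(all(spo2_room_air >= 0 & spo2_room_air <= 100))
  .score_spo2(spo2_room_air)$score
}

#' Score gestational age
#'
#' Below 32 weeks (224 days) scores 0, 32w0d-36w6d (224-258 days) scores
#' 1, 37 weeks (259 days) and above scores 2. Gestational age is handled
#' in completed days (weeks * 7 + days) to avoid floating-point week
#' arithmetic at the 36+6 / 37+0 boundary.
#'
#' @param gestational_age_days Completed gestation in days.
#' @return Integer vector of scores in 0, 1, 2.
#' @export
score_gestational_age <- function(gestational_age_days) {
  .score_gestational_age(gestational_age_days)$score
}

#' Score birth weight
#'
#' Below 1.5 kg scores 0, \[1.5, 2.5) kg scores 1, 2.5 kg and above
#' scores 2 (the recorded band "1.5-2.49" reflects two-decimal rounding;
#' the half-open interval makes the categories a partition).
#'
#' @param birth_weight_kg Kilograms, positive.
#' @return Integer vector of scores in 0, 1, 2.
#' @export
score_birth_weight <- function(birth_weight_kg) {
  stopifnot(all(birth_weight_kg > 0))
  .score_birth_weight(birth_weight_kg)$score
}

#' Classify total score into mortality-risk strata
#'
#' Totals at or below the cutoff (default 10) are labelled `high_risk`
#' (predicted mortality); lower totals indicate more severe disease.
#'
#' @param total Integer total scores in \[0, 16\].
#' @param cutoff Integer cutoff in \[0, 16\]; the comparison is
#'   inclusive (`total <= cutoff` is high risk).
#' @return Character vector, `"high_risk"` or `"low_risk"`.
#' @export
#' @examples
#' classify_risk(c(10, 11))
classify_risk <- function(total, cutoff = 10L) {
  if (any(total < 0 | total > 16)) {
    stop("total score(s) outside [0, 16]", call. = FALSE)
  }
  if (length(cutoff) != 1L || cutoff < 0 || cutoff > 16) {
    stop("cutoff must be a single value in [0, 16]", call. = FALSE)
  }
  ifelse(total <= cutoff, "high_risk", "low_risk")
}

.required_obs_columns <- c(
  "id", "apnea", "grunt", "respiratory_rate", "heart_rate", "asystole",
  "axillary_temperature", "capillary_refill_time", "random_blood_sugar",
  "spo2_room_air", "gestational_age_days", "birth_weight_kg"
)

#' Validate a table of neonatal observations
#'
#' Checks schema and physiologic-plausibility invariants: SpO2 within
#' 0-100, asystole implies heart rate 0, gestational age within 140-320
#' days (about 20-45 weeks), birth weight within (0, 8\] kg, temperature
#' within 30-43 degC, positive capillary refill time, non-negative rates
#' and glucose, unique ids, and no missing values in required fields
#' (no imputation is performed). Rows with `gestational_weeks` /
#' `gestational_days` columns are converted to `gestational_age_days`.
#'
#' @param data A data frame of observations, one row per neonate.
#' @return The validated tibble (invisibly unchanged apart from the
#'   gestational-age conversion), or an error naming offending rows.
#' @export
validate_observations <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"gestational_age_days" %in% names(data) &&
      all(c("gestational_weeks", "gestational_days") %in% names(data))) {
    data <- dplyr::mutate(
      data,
      gestational_age_days = .data$gestational_weeks * 7L + .data$gestational_days
    )
  }
  missing_cols <- setdiff(.required_obs_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  na_counts <- vapply(data[.required_obs_columns],
                      function(x) sum(is.na(x)), integer(1))
  if (any(na_counts > 0)) {
    bad <- na_counts[na_counts > 0]
    stop("missing values (no imputation is performed) in: ",
         paste(sprintf("%s (%d row(s))", names(bad), bad), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(data$id)) {
    stop("duplicated id(s): ",
         paste(unique(data$id[duplicated(data$id)]), collapse = ", "),
         call. = FALSE)
  }
  check <- function(ok, what) {
    if (!all(ok)) {
      stop(what, " in row(s) ", paste(which(!ok), collapse = ", "),
           call. = FALSE)
    }
  }
  check(data$spo2_room_air >= 0 & data$spo2_room_air <= 100,
        "spo2_room_air outside [0, 100]")
  check(!data$asystole | data$heart_rate == 0,
        "asystole recorded with non-zero heart rate")
  check(data$heart_rate >= 0, "negative heart_rate")
  check(data$respiratory_rate >= 0, "negative respiratory_rate")
  check(data$random_blood_sugar >= 0, "negative random_blood_sugar")
  check(data$capillary_refill_time > 0, "non-positive capillary_refill_time")
  check(data$axillary_temperature >= 30 & data$axillary_temperature <= 43,
        "axillary_temperature outside the plausible 30-43 degC range")
  check(data$gestational_age_days >= 140 & data$gestational_age_days <= 320,
        "gestational_age_days outside [140, 320]")
  check(data$birth_weight_kg > 0 & data$birth_weight_kg <= 8,
        "birth_weight_kg outside (0, 8]")
  if ("outcome" %in% names(data)) {
    out <- tolower(as.character(data$outcome))
    check(is.na(out) | out %in% c("discharged", "expired"),
          "outcome not 'discharged'/'expired'")
    data$outcome <- out
  }
  data
}

#' Score a cohort of neonatal observations
#'
#' Applies the full eight-parameter rubric to each row and returns the
#' per-parameter scores, the total (0-16), and any data-quality
#' warnings. All eight inputs must be present for every row; missing
#' values are an error, never imputed.
#'
#' @param data A data frame of observations (see
#'   [validate_observations()] for the schema).
#' @param mode `"strict"` (default) errors on rubric-undefined values
#'   (fever above 37.5 degC, bradypnea without apnea/grunt); `"lenient"`
#'   scores them conservatively and records a per-row warning.
#' @return A tibble with `id`, one column per parameter
#'   (`respiratory_effort`, `heart_rate`, `axillary_temperature`,
#'   `capillary_refill_time`, `random_blood_sugar`, `spo2`,
#'   `gestational_age`, `birth_weight`), `total`, `warnings`
#'   (semicolon-joined, `""` when clean), and `outcome` when present in
#'   the input.
#' @export
#' @examples
#' obs <- tibble::tibble(
#'   id = "a", apnea = FALSE, grunt = FALSE, respiratory_rate = 50,
#'   heart_rate = 120, asystole = FALSE, axillary_temperature = 37,
#'   capillary_refill_time = 2, random_blood_sugar = 90,
#'   spo2_room_air = 98, gestational_age_days = 273, birth_weight_kg = 3
#' )
#' msns_score(obs)
msns_score <- function(data, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  data <- validate_observations(data)

  parts <- list(
    respiratory_effort = .score_respiratory_effort(
      data$apnea, data$grunt, data$respiratory_rate),
    heart_rate = .score_heart_rate(data$heart_rate, data$asystole),
    axillary_temperature = .score_temperature(data$axillary_temperature),
    capillary_refill_time = .score_crt(data$capillary_refill_time),
    random_blood_sugar = .score_rbs(data$random_blood_sugar),
    spo2 = .score_spo2(data$spo2_room_air),
    gestational_age = .score_gestational_age(data$gestational_age_days),
    birth_weight = .score_birth_weight(data$birth_weight_kg)
  )

  notes <- purrr::map(parts, "note")
  any_note <- Reduce(`|`, purrr::map(notes, ~ !is.na(.x)))
  if (mode == "strict" && any(any_note)) {
    first_bad <- purrr::compact(purrr::map(notes, ~ .x[!is.na(.x)]))
    stop(
      "rubric-undefined value(s) in row(s) ",
      paste(utils::head(which(any_note), 5), collapse = ", "), ": ",
      first_bad[[1]][1],
      " (use mode = \"lenient\" to score with warnings)",
      call. = FALSE
    )
  }
  if (any(any_note)) {
    warning(sum(any_note), " row(s) contained rubric-undefined values and ",
            "were scored leniently; see the warnings column",
            call. = FALSE)
  }
  warning_col <- purrr::pmap_chr(notes, function(...) {
    notes_i <- c(...)
    paste(notes_i[!is.na(notes_i)], collapse = "; ")
  })

  scores <- tibble::as_tibble(purrr::map(parts, "score"))
  result <- dplyr::bind_cols(
    tibble::tibble(id = data$id),
    scores,
    tibble::tibble(
      total = as.integer(rowSums(scores)),
      warnings = warning_col
    )
  )
  if ("outcome" %in% names(data)) {
    result$outcome <- data$outcome
  }
  stopifnot(all(result$total >= 0 & result$total <= 16))
  result
}
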