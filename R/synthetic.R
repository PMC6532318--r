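# Synthetic neonatal cohorts matching the published score-category
# structure. Outcome is Bernoulli(prevalence); each parameter's score
# category is drawn independently given outcome from the published
# conditional frequencies; a raw clinical value consistent with the
# category is then drawn uniformly from a bounded range. Conditional
# independence of the parameters given outcome is a simulation
# assumption (only marginal frequencies are published), not a claim
# about the real cohort.

# Raw-value ranges per (parameter, score): strictly inside the rubric
# category so rescoring a generated value always recovers the sampled
# category. Unbounded rubric categories use physiologically plausible
# fallback bounds.
.value_ranges <- function() {
  tibble::tribble(
    ~parameter, ~score, ~lower, ~upper,
    "respiratory_effort", 0L, 40, 60,     # apnea = TRUE, normal rate
    "respiratory_effort", 1L, 61, 90,
    "respiratory_effort", 2L, 40, 60,
    "heart_rate", 0L, 40, 99,             # bradycardia, no asystole
    "heart_rate", 1L, 161, 220,
    "heart_rate", 2L, 100, 160,
    "axillary_temperature", 0L, 33, 35.9,
    "axillary_temperature", 1L, 36, 36.49,
    "axillary_temperature", 2L, 36.5, 37.5,
    "capillary_refill_time", 0L, 5.5, 10,
    "capillary_refill_time", 1L, 3, 5,
    "capillary_refill_time", 2L, 0.5, 2.9,
    "random_blood_sugar", 0L, 10, 39,
    "random_blood_sugar", 1L, 40, 60,
    "random_blood_sugar", 2L, 61, 200,
    "spo2", 0L, 60, 84,
    "spo2", 1L, 85, 92,
    "spo2", 2L, 93, 100,
    "gestational_age", 0L, 182, 223,      # days
    "gestational_age", 1L, 224, 258,
    "gestational_age", 2L, 259, 294,
    "birth_weight", 0L, 0.6, 1.49,
    "birth_weight", 1L, 1.5, 2.49,
    "birth_weight", 2L, 2.5, 4.5
  )
}

#' Construct a cohort model for synthetic data generation
#'
#' @param prevalence Probability that a neonate expires.
#' @param category_probs Tibble with columns `parameter`, `outcome`
#'   (`"discharged"`/`"expired"`), `p0`, `p1`, `p2`; one row per
#'   parameter and outcome, each probability triple summing to 1.
#' @param value_ranges Tibble with columns `parameter`, `score`,
#'   `lower`, `upper` giving the raw-value interval for each of the 24
#'   (parameter, category) cells; defaults to the built-in
#'   physiologically plausible ranges.
#' @return A validated object of class `cohort_model`.
#' @export
cohort_model <- function(prevalence, category_probs,
                         value_ranges = .value_ranges()) {
  stopifnot(prevalence > 0, prevalence < 1)
  category_probs <- tibble::as_tibble(category_probs)
  needed <- tidyr::expand_grid(
    parameter = MSNS_PARAMETERS,
    outcome = c("discharged", "expired")
  )
  got <- dplyr::distinct(category_probs, .data$parameter, .data$outcome)
  if (nrow(dplyr::anti_join(needed, got, by = c("parameter", "outcome"))) > 0) {
    stop("category_probs must cover all 8 parameters for both outcomes",
         call. = FALSE)
  }
  sums <- category_probs$p0 + category_probs$p1 + category_probs$p2
  if (any(abs(sums - 1) > 1e-9)) {
    stop("each probability triple must sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  if (any(category_probs$p0 < 0 | category_probs$p1 < 0 |
            category_probs$p2 < 0)) {
    stop("category probabilities must be non-negative", call. = FALSE)
  }
  structure(
    list(
      prevalence = prevalence,
      category_probs = category_probs,
      value_ranges = tibble::as_tibble(value_ranges)
    ),
    class = "cohort_model"
  )
}

#' Default cohort model from the published validation-study tables
#'
#' Category probabilities equal the published per-parameter score
#' counts normalized within outcome (e.g. respiratory effort given
#' expired: 56/95, 16/95, 23/95), and the prevalence equals the study
#' mortality 95/585.
#'
#' @return A `cohort_model` object.
#' @export
#' @examples
#' m <- default_cohort_model()
#' m$prevalence  # 95/585
default_cohort_model <- function() {
  tabs <- msns_study_tables()
  probs <- tabs$score_counts |>
    tidyr::pivot_longer(c("discharged", "expired"),
                        names_to = "outcome", values_to = "count") |>
    dplyr::group_by(.data$parameter, .data$outcome) |>
    dplyr::mutate(p = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select(-"count") |>
    tidyr::pivot_wider(names_from = "score", values_from = "p",
                       names_prefix = "p")
  cohort_model(
    prevalence = tabs$n_expired / tabs$n_total,
    category_probs = probs
  )
}

#' Simulate a synthetic neonatal cohort
#'
#' Draws `n` observations from a [cohort_model()]: outcome first, then
#' each parameter's score category conditional on outcome, then a raw
#' clinical value uniformly within the category's range. Respiratory
#' score 0 is realized as apnea with a normal rate (the rubric's
#' bradypnea region is never generated); cardiac score 0 is realized
#' as bradycardia without asystole. Rescoring the generated raw values
#' with [msns_score()] recovers the sampled categories exactly.
#'
#' @param model A `cohort_model` (default [default_cohort_model()]).
#' @param n Number of neonates (at least 1).
#' @param seed Optional integer seed; given the same seed the cohort
#'   is reproduced exactly.
#' @return A tibble in the raw-observation schema accepted by
#'   [msns_score()] (including `outcome`), with the seed recorded in
#'   attribute `"seed"`.
#' @export
#' @examples
#' cohort <- sample_cohort(n = 50, seed = 1)
#' table(cohort$outcome)
sample_cohort <- function(model = default_cohort_model(), n, seed = NULL) {
  stopifnot(inherits(model, "cohort_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)

  outcome <- ifelse(stats::runif(n) < model$prevalence,
                    "expired", "discharged")

  draw_category <- function(parameter) {
    out <- integer(n)
    for (oc in c("discharged", "expired")) {
      rows <- which(outcome == oc)
      if (length(rows) == 0) next
      p <- dplyr::filter(model$category_probs,
                         .data$parameter == !!parameter,
                         .data$outcome == oc)
      out[rows] <- sample(0:2, length(rows), replace = TRUE,
                          prob = c(p$p0, p$p1, p$p2))
    }
    out
  }

  draw_value <- function(parameter, category) {
    lo <- numeric(n); hi <- numeric(n)
    for (s in 0:2) {
      r <- dplyr::filter(model$value_ranges,
                         .data$parameter == !!parameter, .data$score == s)
      lo[category == s] <- r$lower
      hi[category == s] <- r$upper
    }
    stats::runif(n, lo, hi)
  }

  cats <- purrr::map(rlang::set_names(MSNS_PARAMETERS), draw_category)

  obs <- tibble::tibble(
    id = sprintf("syn%0*d", nchar(n), seq_len(n)),
    apnea = cats$respiratory_effort == 0L,
    grunt = FALSE,
    respiratory_rate = draw_value("respiratory_effort",
                                  cats$respiratory_effort),
    heart_rate = draw_value("heart_rate", cats$heart_rate),
    asystole = FALSE,
    axillary_temperature = draw_value("axillary_temperature",
                                      cats$axillary_temperature),
    capillary_refill_time = draw_value("capillary_refill_time",
                                       cats$capillary_refill_time),
    random_blood_sugar = draw_value("random_blood_sugar",
                                    cats$random_blood_sugar),
    spo2_room_air = draw_value("spo2", cats$spo2),
    gestational_age_days = as.integer(round(
      draw_value("gestational_age", cats$gestational_age))),
    birth_weight_kg = draw_value("birth_weight", cats$birth_weight),
    outcome = outcome
  )
  attr(obs, "seed") <- seed
  obs
}

#' Exact distribution of the total score under a cohort model
#'
#' Distribution of the sum of the 8 independent per-parameter
#' categorical scores for one outcome group, computed by successive
#' convolution of the probability triples (equivalently, enumeration of
#' all 3^8 = 6561 score combinations).
#'
#' @param model A `cohort_model`.
#' @param outcome `"discharged"` or `"expired"`.
#' @return A tibble with columns `total` (0-16) and `probability`
#'   (summing to 1).
#' @export
exact_total_distribution <- function(model,
                                     outcome = c("discharged", "expired")) {
  stopifnot(inherits(model, "cohort_model"))
  outcome <- match.arg(outcome)
  triples <- model$category_probs |>
    dplyr::filter(.data$outcome == !!outcome) |>
    dplyr::arrange(match(.data$parameter, MSNS_PARAMETERS))
  dist <- 1
  for (i in seq_len(nrow(triples))) {
    tri <- c(triples$p0[i], triples$p1[i], triples$p2[i])
    new <- numeric(length(dist) + 2)
    for (s in 0:2) {
      new[seq_along(dist) + s] <- new[seq_along(dist) + s] + dist * tri[s + 1]
    }
    dist <- new
  }
  tibble::tibble(total = 0:16, probability = dist)
}

#' Analytic AUC implied by a cohort model
#'
#' The concordance probability
#' \eqn{P(T_{expired} < T_{discharged}) + \frac12 P(T_{expired} = T_{discharged})}
#' computed from the two exact total-score distributions (a 17 x 17
#' outer sum). Serves as the analytic oracle for the empirical ROC AUC
#' on simulated cohorts.
#'
#' @param model A `cohort_model`.
#' @return A single proportion.
#' @export
analytic_auc <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  pe <- exact_total_distribution(model, "expired")$probability
  pd <- exact_total_distribution(model, "discharged")$probability
  joint <- outer(pe, pd)  # rows: expired total 0:16, cols: discharged
  # upper triangle: discharged total exceeds expired total
  sum(joint[upper.tri(joint)]) + 0.5 * sum(diag(joint))
}

#' @export
print.cohort_model <- function(x, ...) {
  cat("<cohort_model>\n")
  cat(sprintf("  prevalence (expired): %.4f\n", x$prevalence))
  cat(sprintf("  parameters: %d, outcome-conditional category triples: %d\n",
              length(unique(x$category_probs$parameter)),
              nrow(x$category_probs)))
  invisible(x)
}
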