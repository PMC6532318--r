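# CSV input/output and report rendering. The observation CSV has one
# row per neonate with header columns: id, apnea, grunt,
# respiratory_rate, heart_rate, asystole, axillary_temperature,
# capillary_refill_time, random_blood_sugar, spo2_room_air,
# gestational_weeks, gestational_days (or a single
# gestational_age_days), birth_weight_kg, and an optional outcome
# (discharged/expired, case-insensitive). Booleans may be 0/1 or
# true/false.

.parse_bool <- function(x, column) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    v %in% c("1", "true", "t", "yes") ~ TRUE,
    v %in% c("0", "false", "f", "no") ~ FALSE,
    TRUE ~ NA
  )
  if (any(is.na(out) & !is.na(x))) {
    stop("column '", column, "' contains non-boolean values: ",
         paste(unique(v[is.na(out) & !is.na(x)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Read a cohort observation CSV
#'
#' Reads, types and validates a per-neonate observation file. Boolean
#' columns accept 0/1 or true/false; outcome labels are
#' case-insensitive and canonicalized to lowercase. Gestational age may
#' be given as `gestational_weeks` + `gestational_days` or directly as
#' `gestational_age_days`. Validation failures abort with the offending
#' rows; a file without an outcome column is returned flagged as
#' unlabeled (attribute `"labeled"` = FALSE) and is refused by
#' [msns_evaluate()].
#'
#' @param path Path to the CSV file.
#' @return A validated observation tibble with attributes
#'   `"provenance"` (the file path) and `"labeled"`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess(),
                                                 id = readr::col_character()))
  known <- c(.required_obs_columns, "gestational_weeks", "gestational_days",
             "outcome", "warnings")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (b in c("apnea", "grunt", "asystole")) {
    if (b %in% names(raw)) raw[[b]] <- .parse_bool(raw[[b]], b)
  }
  out <- validate_observations(raw)
  attr(out, "provenance") <- path
  attr(out, "labeled") <- "outcome" %in% names(out)
  out
}

#' Write a cohort or scored-cohort table to CSV
#'
#' @param data An observation or scored tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Write the ROC operating points to CSV
#'
#' Emits `threshold`, `sensitivity`, `specificity` (the finite
#' thresholds only).
#'
#' @param roc An [msns_roc()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_roc_points <- function(roc, path) {
  stopifnot(inherits(roc, "msns_roc"))
  roc$points |>
    dplyr::filter(is.finite(.data$threshold)) |>
    dplyr::select("threshold", "sensitivity", "specificity") |>
    readr::write_csv(path)
  invisible(path)
}

.eval_report_list <- function(ev) {
  stopifnot(inherits(ev, "msns_eval"))
  fmt_metric <- function(row) {
    list(
      estimate = row$estimate, lower = row$lower, upper = row$upper,
      numerator = row$numerator, denominator = row$denominator
    )
  }
  metrics <- purrr::map(
    rlang::set_names(ev$metrics$metric),
    ~ fmt_metric(ev$metrics[ev$metrics$metric == .x, ])
  )
  list(
    n = list(total = ev$n_pos + ev$n_neg, expired = ev$n_pos,
             discharged = ev$n_neg),
    auc = list(estimate = ev$auc$auc, lower = ev$auc$lower,
               upper = ev$auc$upper, method = ev$auc$method,
               level = ev$auc$level),
    cutoff = list(value = ev$cutoff$cutoff, youden_j = ev$cutoff$youden_j,
                  sensitivity = ev$cutoff$sensitivity,
                  specificity = ev$cutoff$specificity),
    confusion = list(tp = ev$confusion$tp, fn = ev$confusion$fn,
                     fp = ev$confusion$fp, tn = ev$confusion$tn),
    metrics = metrics,
    totals_by_group = ev$totals_by_group,
    mann_whitney_total = as.list(ev$mann_whitney_total),
    chi_square_by_parameter = ev$chi_square
  )
}

#' Write an evaluation report
#'
#' JSON reports are stable-key-ordered and keep full numeric
#' precision; text reports mirror the study's result layout (group
#' means/SD, cutoff metrics, ROC summary, per-parameter association
#' tests) with percentages printed to one decimal. Undefined metrics
#' (zero denominators) render as `"undefined"`, never 0.
#'
#' @param ev An [msns_evaluate()] result.
#' @param path Output path.
#' @param format `"json"` or `"text"`.
#' @return The path, invisibly.
#' @export
write_report <- function(ev, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(.eval_report_list(ev), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    return(invisible(path))
  }
  writeLines(render_text_report(ev), path)
  invisible(path)
}

#' Render an evaluation as a plain-text report
#'
#' @param ev An [msns_evaluate()] result.
#' @return A character vector of report lines.
#' @export
render_text_report <- function(ev) {
  stopifnot(inherits(ev, "msns_eval"))
  pct <- function(x) {
    if (is.na(x)) "undefined" else sprintf("%.1f%%", 100 * x)
  }
  lines <- c(
    "Severity-score evaluation report",
    "================================",
    sprintf("Cohort: n = %d (expired %d, discharged %d)",
            ev$n_pos + ev$n_neg, ev$n_pos, ev$n_neg),
    "",
    "Total score by outcome:"
  )
  for (i in seq_len(nrow(ev$totals_by_group))) {
    g <- ev$totals_by_group[i, ]
    lines <- c(lines, sprintf(
      "  %-10s n=%-4d mean (SD) %.2f (%.2f), median (IQR) %g (%g-%g)",
      g$outcome, g$n, g$mean, g$sd, g$median, g$q1, g$q3))
  }
  mw <- ev$mann_whitney_total
  lines <- c(
    lines,
    sprintf("  Mann-Whitney U = %g, Z = %.2f, p = %.3g",
            mw$u, mw$z, mw$p_value),
    "",
    sprintf("ROC: AUC %.3f (%d%% CI %.3f-%.3f, %s)",
            ev$auc$auc, round(100 * ev$level), ev$auc$lower,
            ev$auc$upper, ev$auc$method),
    sprintf("Cutoff: total <= %g (Youden J = %.3f)",
            ev$cutoff$cutoff, ev$cutoff$youden_j),
    sprintf("  confusion: tp %d, fn %d, fp %d, tn %d",
            ev$confusion$tp, ev$confusion$fn, ev$confusion$fp,
            ev$confusion$tn)
  )
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    row <- ev$metrics[ev$metrics$metric == m, ]
    ci <- if (is.na(row$estimate)) {
      ""
    } else {
      sprintf(" (%s-%s)", pct(row$lower), pct(row$upper))
    }
    lines <- c(lines, sprintf("  %-12s %s%s", m, pct(row$estimate), ci))
  }
  if (nrow(ev$chi_square) > 0) {
    lines <- c(lines, "", "Per-parameter association with outcome (chi-square):")
    for (i in seq_len(nrow(ev$chi_square))) {
      r <- ev$chi_square[i, ]
      lines <- c(lines, sprintf(
        "  %-22s X2 = %6.2f, df = %g, p = %.3g%s",
        r$parameter, r$statistic, r$df, r$p_value,
        ifelse(isTRUE(r$low_expected), " (expected count < 5)", "")))
    }
  }
  lines
}
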