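# One-call evaluation of a scored cohort, mirroring the validation
# workflow: ROC + AUC with CI, Youden cutoff (or a fixed one),
# confusion matrix and diagnostic metrics at that cutoff, per-group
# summaries of the total, a Mann-Whitney comparison, and per-parameter
# chi-square association tables when the parameter score columns are
# present.

#' Evaluate a scored cohort against its outcomes
#'
#' @param data A data frame with a `total` score column and an
#'   `outcome` column (`"discharged"`/`"expired"`); per-parameter score
#'   columns, when present, get chi-square association tests.
#' @param cutoff Integer cutoff for the classification metrics; `NULL`
#'   (default) selects the Youden-optimal cutoff from the ROC curve.
#' @param level Confidence level for all intervals.
#' @param auc_ci_method `"hanley_mcneil"` (default) or `"delong"`.
#' @return An object of class `msns_eval` with components `roc`, `auc`
#'   (tibble with CI), `cutoff` (tibble from [optimal_cutoff()] or the
#'   fixed value), `confusion`, `metrics`, `totals_by_group`,
#'   `mann_whitney_total`, `chi_square` (per-parameter tibble, possibly
#'   empty), and group sizes. Supports `tidy()`, `glance()`, `print()`.
#' @export
#' @examples
#' cohort <- sample_cohort(n = 200, seed = 42)
#' scored <- msns_score(cohort)
#' ev <- msns_evaluate(scored)
#' generics::glance(ev)
msns_evaluate <- function(data, cutoff = NULL, level = 0.95,
                          auc_ci_method = c("hanley_mcneil", "delong")) {
  auc_ci_method <- match.arg(auc_ci_method)
  if (!all(c("total", "outcome") %in% names(data))) {
    stop("data must contain 'total' and 'outcome' columns; ",
         "an unlabeled cohort cannot be evaluated", call. = FALSE)
  }
  if (any(is.na(data$outcome))) {
    stop("outcome contains missing labels; evaluation needs a fully ",
         "labeled cohort", call. = FALSE)
  }

  roc <- msns_roc(data)
  auc_tbl <- auc_ci(roc, level = level, method = auc_ci_method)
  cut_tbl <- optimal_cutoff(roc)
  if (!is.null(cutoff)) {
    p <- roc$points
    idx <- max(which(p$threshold <= cutoff))
    cut_tbl <- tibble::tibble(
      cutoff = cutoff,
      youden_j = p$sensitivity[idx] + p$specificity[idx] - 1,
      sensitivity = p$sensitivity[idx],
      specificity = p$specificity[idx],
      informative = NA
    )
  }
  confusion <- confusion_at_cutoff(data, cut_tbl$cutoff)
  metrics <- diagnostic_metrics(confusion, level = level)

  totals <- group_summary(data, total, outcome)
  mw <- mann_whitney(data$total[data$outcome == "expired"],
                     data$total[data$outcome == "discharged"])

  param_cols <- intersect(MSNS_PARAMETERS, names(data))
  param_cols <- setdiff(param_cols, character(0))
  chi <- purrr::map_dfr(param_cols, function(p) {
    tab <- table(factor(data$outcome, c("discharged", "expired")),
                 factor(data[[p]], 0:2))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) {
      return(tibble::tibble(parameter = p, statistic = NA_real_,
                            df = NA_real_, p_value = NA_real_,
                            min_expected = NA_real_, low_expected = NA))
    }
    dplyr::bind_cols(tibble::tibble(parameter = p),
                     chi_square_test(unclass(tab)))
  })

  structure(
    list(
      roc = roc,
      auc = auc_tbl,
      cutoff = cut_tbl,
      confusion = confusion,
      metrics = metrics,
      totals_by_group = totals,
      mann_whitney_total = mw,
      chi_square = chi,
      n_pos = length(roc$pos_scores),
      n_neg = length(roc$neg_scores),
      level = level
    ),
    class = "msns_eval"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the operating points of an ROC curve
#'
#' @param x An `msns_roc` object.
#' @param ... Unused.
#' @return The operating-points tibble (`threshold`, `sensitivity`,
#'   `fpr`, `specificity`).
#' @export
tidy.msns_roc <- function(x, ...) x$points

#' One-row summary of an ROC curve
#'
#' @param x An `msns_roc` object.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `n_pos`, `n_neg`.
#' @export
glance.msns_roc <- function(x, ...) {
  tibble::tibble(
    auc = roc_auc(x),
    n_pos = length(x$pos_scores),
    n_neg = length(x$neg_scores)
  )
}

#' Tidy the diagnostic metrics of an evaluation
#'
#' @param x An `msns_eval` object.
#' @param ... Unused.
#' @return A tibble with one row per metric (sensitivity, specificity,
#'   ppv, npv) plus the AUC row, each with its confidence interval.
#' @export
tidy.msns_eval <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$metrics, metric = .data$metric,
                     estimate = .data$estimate,
                     lower = .data$lower, upper = .data$upper),
    dplyr::transmute(x$auc, metric = "auc", estimate = .data$auc,
                     lower = .data$lower, upper = .data$upper)
  )
}

#' One-row summary of an evaluation
#'
#' @param x An `msns_eval` object.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `auc_lower`, `auc_upper`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden_j`, `n`, `n_pos`, `n_neg`.
#' @export
glance.msns_eval <- function(x, ...) {
  tibble::tibble(
    auc = x$auc$auc, auc_lower = x$auc$lower, auc_upper = x$auc$upper,
    cutoff = x$cutoff$cutoff,
    sensitivity = x$cutoff$sensitivity,
    specificity = x$cutoff$specificity,
    youden_j = x$cutoff$youden_j,
    n = x$n_pos + x$n_neg, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @export
print.msns_roc <- function(x, ...) {
  cat("<msns_roc> ", length(x$pos_scores), " positive (",
      x$positive, ") vs ", length(x$neg_scores), " negative; AUC ",
      sprintf("%.3f", roc_auc(x)), "\n", sep = "")
  cat("  orientation:", x$orientation, "\n")
  invisible(x)
}

#' @export
print.msns_eval <- function(x, ...) {
  g <- glance(x)
  cat("<msns_eval>\n")
  cat(sprintf("  n = %d (%d expired, %d discharged)\n",
              g$n, g$n_pos, g$n_neg))
  cat(sprintf("  AUC %.3f (%d%% CI %.3f-%.3f, %s)\n",
              g$auc, round(100 * x$level), g$auc_lower, g$auc_upper,
              x$auc$method))
  cat(sprintf("  cutoff <= %g: sensitivity %.1f%%, specificity %.1f%%\n",
              g$cutoff, 100 * g$sensitivity, 100 * g$specificity))
  ppv <- x$metrics$estimate[x$metrics$metric == "ppv"]
  npv <- x$metrics$estimate[x$metrics$metric == "npv"]
  cat(sprintf("  PPV %.1f%%, NPV %.1f%%\n", 100 * ppv, 100 * npv))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param object An `msns_roc` object.
#' @param ... Unused.
#' @return A ggplot of sensitivity against the false positive rate
#'   with the chance diagonal and the AUC in the subtitle.
#' @export
autoplot.msns_roc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = "ROC curve (score <= threshold is test-positive)",
      subtitle = sprintf("AUC = %.3f", roc_auc(object))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot total-score distributions by outcome
#'
#' @param data A scored cohort with `total` and `outcome` columns.
#' @return A ggplot bar chart of the total-score distribution per
#'   outcome group.
#' @export
plot_score_distribution <- function(data) {
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data$total, fill = .data$outcome)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = 0:16, limits = c(-0.5, 16.5)) +
    ggplot2::labs(x = "Total score", y = "Neonates", fill = "Outcome") +
    ggplot2::theme_minimal()
}
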