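# Diagnostic-validation statistics for a severity score in which LOW
# totals indicate the positive (expired) class: ROC test-positivity is
# score <= threshold throughout.

.split_scores <- function(data, score, outcome, positive) {
  score <- rlang::enquo(score)
  outcome <- rlang::enquo(outcome)
  s <- dplyr::pull(data, !!score)
  o <- tolower(as.character(dplyr::pull(data, !!outcome)))
  if (length(s) != length(o)) stop("scores and outcomes differ in length")
  keep <- !is.na(s) & !is.na(o)
  s <- s[keep]; o <- o[keep]
  pos <- s[o == positive]
  neg <- s[o != positive]
  if (length(pos) == 0) {
    stop("no observations in the positive class ('", positive, "')",
         call. = FALSE)
  }
  if (length(neg) == 0) {
    stop("no observations in the negative class (non-'", positive, "')",
         call. = FALSE)
  }
  list(pos = pos, neg = neg)
}

#' ROC curve for a low-score-indicates-risk severity score
#'
#' Builds the receiver operating characteristic curve with the total
#' score as test variable and the expired outcome as the positive
#' class. Because lower totals indicate higher mortality risk, an
#' observation tests positive when its score is at or below the
#' threshold. One operating point is produced per distinct score, plus
#' the (0, 0) endpoint.
#'
#' @param data A data frame with one row per subject.
#' @param score,outcome Columns (unquoted) holding the numeric score
#'   and the outcome label.
#' @param positive Label of the positive class (default `"expired"`).
#' @return An object of class `msns_roc`: operating points
#'   (`threshold`, `sensitivity`, `specificity`, `fpr`), the raw scores
#'   per class, and the orientation note. Supports [roc_auc()],
#'   [auc_ci()], [optimal_cutoff()], `tidy()`, `glance()` and
#'   `autoplot()`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   total = c(1, 2, 9, 9),
#'   outcome = c("expired", "expired", "discharged", "discharged")
#' )
#' msns_roc(d)
msns_roc <- function(data, score = total, outcome = outcome,
                     positive = "expired") {
  g <- .split_scores(data, {{ score }}, {{ outcome }}, positive)
  thresholds <- sort(unique(c(g$pos, g$neg)))
  sens <- vapply(thresholds, function(t) mean(g$pos <= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(g$neg <= t), numeric(1))
  points <- tibble::tibble(
    threshold = c(-Inf, thresholds),
    sensitivity = c(0, sens),
    fpr = c(0, fpr)
  )
  points$specificity <- 1 - points$fpr
  structure(
    list(
      points = points,
      pos_scores = g$pos,
      neg_scores = g$neg,
      positive = positive,
      orientation = "lower score indicates the positive class"
    ),
    class = "msns_roc"
  )
}

#' Area under an ROC curve
#'
#' Trapezoidal area over the ordered operating points. Equals the
#' concordance probability that a randomly chosen positive case scores
#' lower than a randomly chosen negative case, with half credit for
#' ties.
#'
#' @param roc An [msns_roc()] object.
#' @return A single proportion in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "msns_roc"))
  p <- roc$points
  sum(diff(p$fpr) * (utils::head(p$sensitivity, -1) +
                       utils::tail(p$sensitivity, -1)) / 2)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal-approximation interval on the Hanley-McNeil standard error
#' \eqn{SE^2 = (A(1-A) + (n_+-1)(Q_1-A^2) + (n_--1)(Q_2-A^2)) / (n_+ n_-)}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}, truncated to
#' \[0, 1\].
#'
#' @param auc The AUC point estimate, in \[0, 1\].
#' @param n_pos,n_neg Group sizes (at least 2 each).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `auc`, `se`, `lower`, `upper`, `method`,
#'   `level`.
#' @export
hanley_mcneil_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 2, n_neg >= 2,
            level > 0, level < 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    auc = auc, se = se,
    lower = max(0, auc - z * se), upper = min(1, auc + z * se),
    method = "hanley_mcneil", level = level
  )
}

# DeLong placement-value variance for the low-score-positive orientation.
.delong_se <- function(pos, neg) {
  v10 <- vapply(pos, function(x) mean(x < neg) + 0.5 * mean(x == neg),
                numeric(1))
  v01 <- vapply(neg, function(y) mean(pos < y) + 0.5 * mean(pos == y),
                numeric(1))
  sqrt(stats::var(v10) / length(pos) + stats::var(v01) / length(neg))
}

#' Confidence interval for the AUC of an ROC curve
#'
#' Either the Hanley-McNeil interval (default; needs only the point
#' estimate and group sizes) or the DeLong interval based on the
#' placement-value variance of the raw scores. Both are symmetric
#' normal-approximation intervals truncated to \[0, 1\].
#'
#' @param roc An [msns_roc()] object.
#' @param level Confidence level (default 0.95).
#' @param method `"hanley_mcneil"` or `"delong"`.
#' @return A one-row tibble: `auc`, `se`, `lower`, `upper`, `method`,
#'   `level`.
#' @export
auc_ci <- function(roc, level = 0.95,
                   method = c("hanley_mcneil", "delong")) {
  stopifnot(inherits(roc, "msns_roc"))
  method <- match.arg(method)
  a <- roc_auc(roc)
  n_pos <- length(roc$pos_scores)
  n_neg <- length(roc$neg_scores)
  if (n_pos < 2 || n_neg < 2) {
    stop("confidence interval requires at least 2 cases per class",
         call. = FALSE)
  }
  if (method == "hanley_mcneil") {
    return(hanley_mcneil_ci(a, n_pos, n_neg, level))
  }
  se <- .delong_se(roc$pos_scores, roc$neg_scores)
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    auc = a, se = se,
    lower = max(0, a - z * se), upper = min(1, a + z * se),
    method = "delong", level = level
  )
}

#' Optimal cutoff by the Youden index
#'
#' Selects the threshold maximizing Youden's J = sensitivity +
#' specificity - 1 over the finite operating points. Ties are broken
#' toward the lower threshold (the more specific rule). An
#' uninformative curve (max J = 0) is flagged via `informative`.
#'
#' @param roc An [msns_roc()] object.
#' @return A one-row tibble: `cutoff`, `youden_j`, `sensitivity`,
#'   `specificity`, `informative`.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "msns_roc"))
  p <- dplyr::filter(roc$points, is.finite(.data$threshold))
  j <- p$sensitivity + p$specificity - 1
  best <- which(j == max(j))[1]  # points are threshold-ordered: lowest wins
  tibble::tibble(
    cutoff = p$threshold[best],
    youden_j = j[best],
    sensitivity = p$sensitivity[best],
    specificity = p$specificity[best],
    informative = max(j) > 0
  )
}

#' Confusion matrix at a score cutoff
#'
#' Counts test positives (score at or below the cutoff) against the
#' outcome labels: `tp` expired with score <= cutoff, `fp` discharged
#' with score <= cutoff, and their complements.
#'
#' @inheritParams msns_roc
#' @param cutoff Integer score cutoff; inclusive.
#' @return A one-row tibble: `tp`, `fn`, `fp`, `tn`, `cutoff`.
#' @export
confusion_at_cutoff <- function(data, cutoff, score = total,
                                outcome = outcome, positive = "expired") {
  g <- .split_scores(data, {{ score }}, {{ outcome }}, positive)
  tibble::tibble(
    tp = sum(g$pos <= cutoff),
    fn = sum(g$pos > cutoff),
    fp = sum(g$neg <= cutoff),
    tn = sum(g$neg > cutoff),
    cutoff = cutoff
  )
}

# Wilson score interval for a binomial proportion.
.wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive value,
#' each with a Wilson score confidence interval. A metric with a zero
#' denominator is reported as `NA` (undefined), never 0.
#'
#' @param confusion A data frame (e.g. from [confusion_at_cutoff()])
#'   with columns `tp`, `fn`, `fp`, `tn`, or a named numeric vector
#'   with those elements.
#' @param level Confidence level for the Wilson intervals.
#' @return A tibble with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate`, `lower`, `upper`.
#' @export
#' @examples
#' diagnostic_metrics(tibble::tibble(tp = 76, fn = 19, fp = 55, tn = 435))
diagnostic_metrics <- function(confusion, level = 0.95) {
  m <- as.list(confusion)
  for (nm in c("tp", "fn", "fp", "tn")) {
    if (is.null(m[[nm]]) || m[[nm]] < 0) {
      stop("confusion matrix needs non-negative tp, fn, fp, tn",
           call. = FALSE)
    }
  }
  cells <- list(
    sensitivity = c(m$tp, m$tp + m$fn),
    specificity = c(m$tn, m$tn + m$fp),
    ppv = c(m$tp, m$tp + m$fp),
    npv = c(m$tn, m$tn + m$fn)
  )
  purrr::imap_dfr(cells, function(cell, name) {
    x <- cell[1]; n <- cell[2]
    if (n == 0) {
      return(tibble::tibble(metric = name, numerator = x, denominator = n,
                            estimate = NA_real_, lower = NA_real_,
                            upper = NA_real_))
    }
    ci <- .wilson_ci(x, n, level)
    tibble::tibble(metric = name, numerator = x, denominator = n,
                   estimate = x / n, lower = ci[1], upper = ci[2])
  })
}

#' Pearson chi-square test of association for a contingency table
#'
#' Pearson statistic with expected counts from the row/column
#' marginals, (r-1)(c-1) degrees of freedom, and an upper-tail
#' chi-square p-value (no continuity correction). Tables with any
#' expected count below 5 are flagged, not refused.
#'
#' @param counts A matrix (or data frame of counts) with at least two
#'   rows and two columns of non-negative integers.
#' @return A one-row tibble: `statistic`, `df`, `p_value`,
#'   `min_expected`, `low_expected` (TRUE if any expected count < 5).
#' @export
#' @examples
#' chi_square_test(rbind(discharged = c(54, 87, 349),
#'                       expired = c(56, 16, 23)))
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has an empty row or column marginal",
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = unname(fit$p.value),
    min_expected = min(fit$expected),
    low_expected = min(fit$expected) < 5
  )
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' U is computed from midrank sums; the Z statistic uses the
#' tie-corrected variance
#' \eqn{n_a n_b / 12 \, ((N+1) - \sum(t^3 - t)/(N(N-1)))} with no
#' continuity correction, and the p-value is the two-sided normal tail.
#' When every value is identical across both groups the variance is 0
#' and Z is defined as 0 with p = 1.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A one-row tibble: `u` (for `group_a`), `z`, `p_value`,
#'   `n_a`, `n_b`. The complementary statistic for `group_b` is
#'   `n_a * n_b - u`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  n <- n_a + n_b
  r <- rank(c(group_a, group_b))  # midranks for ties
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- table(c(group_a, group_b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n_a * n_b / 12 * ((n + 1) - tie_term)
  mu <- n_a * n_b / 2
  if (v <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- (u - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(u = u, z = z, p_value = p, n_a = n_a, n_b = n_b)
}

#' Per-group summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), median and
#' quartiles (linear interpolation between order statistics) for a
#' numeric variable split by a grouping column.
#'
#' @param data A data frame.
#' @param value Column (unquoted) holding the numeric values.
#' @param by Column (unquoted) holding the group labels.
#' @return A tibble with one row per group: group label, `n`, `mean`,
#'   `sd`, `median`, `q1`, `q3`.
#' @export
group_summary <- function(data, value, by) {
  data |>
    dplyr::group_by({{ by }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sd = stats::sd({{ value }}),
      median = stats::median({{ value }}),
      q1 = unname(stats::quantile({{ value }}, 0.25, type = 7)),
      q3 = unname(stats::quantile({{ value }}, 0.75, type = 7)),
      .groups = "drop"
    )
}

#' Sample size for a diagnostic accuracy study (Buderer formula)
#'
#' \eqn{n = \lceil z^2 \, acc(1-acc) / d^2 / prev \rceil} for the
#' sensitivity-driven requirement, where `acc` is the anticipated
#' sensitivity (or specificity), `d` the absolute precision
#' (confidence-interval half-width), and `prev` the outcome prevalence
#' (replaced by 1 - prevalence for the specificity-driven requirement).
#' With `which = "both"` the larger of the two requirements is
#' returned.
#'
#' @param target_accuracy Anticipated sensitivity/specificity, in (0, 1).
#' @param precision Absolute half-width, in (0, 1) and below
#'   `target_accuracy`.
#' @param prevalence Outcome prevalence, in (0, 1\].
#' @param confidence Confidence level (default 0.95).
#' @param which Which requirement drives the size: `"sensitivity"`
#'   (default), `"specificity"`, or `"both"` (the maximum).
#' @return Integer sample size.
#' @export
#' @examples
#' diagnostic_sample_size(0.90, 0.035, 0.5)  # 565
diagnostic_sample_size <- function(target_accuracy, precision, prevalence,
                                   confidence = 0.95,
                                   which = c("sensitivity", "specificity",
                                             "both")) {
  which <- match.arg(which)
  stopifnot(target_accuracy > 0, target_accuracy < 1,
            precision > 0, precision < target_accuracy,
            prevalence > 0, prevalence <= 1,
            confidence > 0, confidence < 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  core <- z^2 * target_accuracy * (1 - target_accuracy) / precision^2
  n_sens <- ceiling(core / prevalence)
  if (which == "sensitivity") return(as.integer(n_sens))
  if (prevalence >= 1 && which != "sensitivity") {
    stop("specificity-driven size needs prevalence < 1", call. = FALSE)
  }
  n_spec <- ceiling(core / (1 - prevalence))
  if (which == "specificity") return(as.integer(n_spec))
  as.integer(max(n_sens, n_spec))
}
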