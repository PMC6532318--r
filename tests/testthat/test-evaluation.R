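# ROC/AUC machinery, diagnostic metrics, rank and contingency tests,
# and the sample-size formula.

test_that("ROC points are normalized, monotone, and oriented low-score-positive", {
  d <- tibble::tibble(
    total = c(1, 2, 9, 9),
    outcome = c("expired", "expired", "discharged", "discharged")
  )
  roc <- msns_roc(d)
  p <- roc$points
  expect_equal(c(p$sensitivity[1], p$fpr[1]), c(0, 0))
  expect_equal(c(dplyr::last(p$sensitivity), dplyr::last(p$fpr)), c(1, 1))
  expect_true(all(diff(p$sensitivity) >= 0))
  expect_true(all(diff(p$fpr) >= 0))
  # perfect separation: at threshold 2 sensitivity 1, FPR 0
  at2 <- dplyr::filter(p, threshold == 2)
  expect_equal(c(at2$sensitivity, at2$fpr), c(1, 0))
  expect_equal(roc_auc(roc), 1)

  # all scores equal: diagonal with one interior point, AUC 1/2
  d2 <- tibble::tibble(total = rep(7, 6),
                       outcome = rep(c("expired", "discharged"), 3))
  roc2 <- msns_roc(d2)
  expect_equal(nrow(roc2$points), 2L)
  expect_equal(roc_auc(roc2), 0.5)

  # degenerate single-class input names the missing class
  expect_error(msns_roc(dplyr::filter(d, outcome == "expired")),
               "negative class")
  expect_error(msns_roc(dplyr::filter(d, outcome == "discharged")),
               "positive class")
})

test_that("trapezoidal AUC equals the pairwise-concordance oracle and hand example", {
  # expired [3, 5] vs discharged [4, 6, 7]: of the 6 pairs only
  # (5, 4) is discordant and there are no ties, so AUC = 5/6
  d <- tibble::tibble(
    total = c(3, 5, 4, 6, 7),
    outcome = c("expired", "expired", rep("discharged", 3))
  )
  expect_equal(roc_auc(msns_roc(d)), 5 / 6)
  expect_equal(roc_auc(msns_roc(d)),
               oracle_concordance(c(3, 5), c(4, 6, 7)))

  set.seed(2024)
  for (i in 1:200) {
    cohort <- random_cohort()
    a_trap <- roc_auc(msns_roc(cohort))
    a_pair <- oracle_concordance(cohort$total[cohort$outcome == "expired"],
                                 cohort$total[cohort$outcome == "discharged"])
    expect_equal(a_trap, a_pair, tolerance = 1e-12)
  }
})

test_that("AUC and DeLong interval agree with pROC on a seeded cohort", {
  cohort <- msns_score(sample_cohort(n = 300, seed = 11))
  roc <- msns_roc(cohort)
  # low totals indicate the expired class: controls (discharged) > cases
  proc <- pROC::roc(response = cohort$outcome, predictor = cohort$total,
                    levels = c("discharged", "expired"), direction = ">",
                    quiet = TRUE)
  expect_equal(roc_auc(roc), as.numeric(pROC::auc(proc)), tolerance = 1e-12)
  ours <- auc_ci(roc, method = "delong")
  theirs <- as.numeric(pROC::ci.auc(proc, method = "delong"))
  expect_equal(c(ours$lower, ours$upper), theirs[c(1, 3)], tolerance = 1e-8)
})

test_that("Hanley-McNeil interval matches an independent computation and its limits", {
  # frozen from a standalone evaluation of the Hanley-McNeil variance
  # formula at AUC 0.913 with 95 positives / 490 negatives
  ci <- hanley_mcneil_ci(0.913, 95, 490)
  expect_equal(ci$se, 0.020316865666210, tolerance = 1e-12)
  expect_equal(ci$lower, 0.873179675015490, tolerance = 1e-12)
  expect_equal(ci$upper, 0.952820324984510, tolerance = 1e-12)

  # AUC 1 has zero standard error: degenerate (1, 1) interval
  ci1 <- hanley_mcneil_ci(1, 50, 50)
  expect_equal(c(ci1$se, ci1$lower, ci1$upper), c(0, 1, 1))

  # interval shrinks toward the point estimate as n grows
  w <- function(n) {
    ci <- hanley_mcneil_ci(0.5, n, n)
    ci$upper - ci$lower
  }
  expect_true(w(10000) < w(100))
  expect_lt(w(1e6), 0.005)
})

test_that("Youden cutoff maximizes J with ties broken toward the lower threshold", {
  # perfect separation at score 5
  d <- tibble::tibble(
    total = c(2, 4, 5, 8, 9, 12),
    outcome = c(rep("expired", 3), rep("discharged", 3))
  )
  cut <- optimal_cutoff(msns_roc(d))
  expect_equal(cut$cutoff, 5)
  expect_equal(cut$youden_j, 1)
  expect_true(cut$informative)

  # uninformative scores: lowest threshold, J = 0, flagged
  d2 <- tibble::tibble(total = rep(7, 10),
                       outcome = rep(c("expired", "discharged"), 5))
  cut2 <- optimal_cutoff(msns_roc(d2))
  expect_equal(cut2$cutoff, 7)
  expect_equal(cut2$youden_j, 0)
  expect_false(cut2$informative)

  # exact tie in J between thresholds 3 and 5: lower one wins
  d3 <- tibble::tibble(
    total = c(3, 5, 4, 6),
    outcome = c("expired", "expired", "discharged", "discharged")
  )
  j <- with(dplyr::filter(msns_roc(d3)$points, is.finite(threshold)),
            sensitivity + specificity - 1)
  expect_equal(j[1], j[3])  # J at threshold 3 equals J at threshold 5
  expect_equal(optimal_cutoff(msns_roc(d3))$cutoff, 3)
})

test_that("confusion matrix and diagnostic metrics reproduce count identities", {
  d <- tibble::tibble(total = c(8, 14), outcome = c("expired", "discharged"))
  cm <- confusion_at_cutoff(d, 10)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 0L, fp = 0L, tn = 1L))
  expect_true(all(diagnostic_metrics(cm)$estimate == 1))

  # all scores below cutoff: fn = tn = 0, NPV undefined (never 0)
  d2 <- tibble::tibble(total = c(1, 2), outcome = c("expired", "discharged"))
  cm2 <- confusion_at_cutoff(d2, 10)
  expect_equal(c(cm2$fn, cm2$tn), c(0L, 0L))
  npv <- diagnostic_metrics(cm2)
  expect_true(is.na(npv$estimate[npv$metric == "npv"]))

  # metric-times-denominator returns the integer numerator
  cm3 <- tibble::tibble(tp = 76, fn = 19, fp = 55, tn = 435)
  m <- diagnostic_metrics(cm3)
  sens <- m[m$metric == "sensitivity", ]
  spec <- m[m$metric == "specificity", ]
  expect_equal(sens$estimate * sens$denominator, 76)
  expect_equal(spec$estimate * spec$denominator, 435)
  expect_true(all(m$lower <= m$estimate & m$estimate <= m$upper))
})

test_that("chi-square test matches the explicit cell-sum oracle and known values", {
  # identical row proportions: no association
  flat <- rbind(c(10, 20, 30), c(20, 40, 60))
  res <- chi_square_test(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # hand computation: all expected counts 5, statistic 20, df 1
  res2 <- chi_square_test(rbind(c(10, 0), c(0, 10)))
  expect_equal(res2$statistic, 20)
  expect_equal(res2$df, 1)

  set.seed(99)
  for (i in 1:100) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    tab <- matrix(stats::rpois(r * c, 8) + 1, r, c)
    ours <- chi_square_test(tab)
    theirs <- oracle_chisq(tab)
    expect_equal(ours$statistic, theirs$statistic, tolerance = 1e-12)
    expect_equal(ours$df, theirs$df)
    expect_equal(ours$p_value, theirs$p_value, tolerance = 1e-12)
  }

  # published respiratory-effort association: overwhelming evidence
  resp <- rbind(discharged = c(54, 87, 349), expired = c(56, 16, 23))
  expect_lt(chi_square_test(resp)$p_value, 0.001)

  expect_error(chi_square_test(rbind(c(0, 0), c(3, 4))), "marginal")
  expect_error(chi_square_test(matrix(1:3, 1)), "2x2")
})

test_that("Mann-Whitney U agrees with exhaustive pair counting and wilcox.test", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$z, 0)
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$u, 0)
  expect_equal(mann_whitney(rep(5, 4), rep(5, 6))$p_value, 1)

  set.seed(7)
  for (i in 1:60) {
    a <- sample(0:6, sample(2:8, 1), replace = TRUE)
    b <- sample(0:6, sample(2:8, 1), replace = TRUE)
    res <- mann_whitney(a, b)
    expect_equal(res$u, oracle_u(a, b))
    # algebraic identity: U_a + U_b = n_a * n_b
    expect_equal(res$u + oracle_u(b, a), length(a) * length(b))
  }

  # tie-corrected normal approximation matches the base-R reference
  a <- c(0, 1, 1, 2, 2, 2, 3); b <- c(1, 2, 2, 3, 3, 4, 4, 5)
  ours <- mann_whitney(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = FALSE))
  expect_equal(ours$u, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("group summaries use sample SD and interpolated quartiles", {
  d <- tibble::tibble(v = c(1, 2, 3, 1, 1, 1, 1),
                      g = c(rep("x", 3), rep("y", 4)))
  s <- group_summary(d, v, g)
  sx <- s[s$g == "x", ]
  expect_equal(c(sx$mean, sx$median, sx$sd), c(2, 2, 1))
  sy <- s[s$g == "y", ]
  expect_equal(c(sy$sd, sy$q1, sy$q3), c(0, 1, 1))
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
})

test_that("Buderer sample-size formula reproduces hand calculations", {
  expect_equal(diagnostic_sample_size(0.90, 0.035, 0.5), 565L)
  # maximal-variance case: z^2 * 0.25 / 0.098^2 with prevalence 1
  expect_equal(diagnostic_sample_size(0.50, 0.098, 1), 100L)
  # vanishing confidence collapses the requirement to a single subject
  expect_equal(diagnostic_sample_size(0.90, 0.035, 0.5, confidence = 1e-9),
               1L)
  # the specificity-driven arm scales by 1 - prevalence
  expect_equal(
    diagnostic_sample_size(0.90, 0.035, 0.2, which = "specificity"),
    ceiling(qnorm(0.975)^2 * 0.09 / 0.035^2 / 0.8)
  )
  expect_equal(
    diagnostic_sample_size(0.90, 0.035, 0.2, which = "both"),
    diagnostic_sample_size(0.90, 0.035, 0.2, which = "sensitivity")
  )
  expect_error(diagnostic_sample_size(0.90, 0.035, 0), "prevalence")
})

test_that("msns_evaluate assembles a coherent report with broom methods", {
  scored <- msns_score(sample_cohort(n = 400, seed = 5))
  ev <- msns_evaluate(scored)
  g <- generics::glance(ev)
  expect_equal(g$n, 400)
  expect_equal(g$n_pos + g$n_neg, 400)
  expect_true(g$auc_lower <= g$auc && g$auc <= g$auc_upper)
  td <- generics::tidy(ev)
  expect_setequal(td$metric, c("sensitivity", "specificity", "ppv", "npv", "auc"))
  expect_true(all(td$estimate >= 0 & td$estimate <= 1, na.rm = TRUE))
  expect_equal(nrow(ev$chi_square), 8)
  # fixed-cutoff evaluation matches direct confusion counts
  ev10 <- msns_evaluate(scored, cutoff = 10)
  cm <- confusion_at_cutoff(scored, 10)
  expect_equal(ev10$confusion$tp, cm$tp)
  expect_equal(ev10$cutoff$sensitivity, cm$tp / (cm$tp + cm$fn))
  # unlabeled or partially labeled cohorts are refused
  expect_error(msns_evaluate(dplyr::select(scored, -outcome)), "outcome")
  scored$outcome[1] <- NA
  expect_error(msns_evaluate(scored), "missing labels")
})

test_that("autoplot returns a ggplot of the ROC operating points", {
  roc <- msns_roc(msns_score(sample_cohort(n = 100, seed = 3)))
  p <- ggplot2::autoplot(roc)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_score_distribution(
    msns_score(sample_cohort(n = 100, seed = 3))), "ggplot")
})
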