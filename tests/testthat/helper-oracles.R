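# Independent brute-force oracles, kept deliberately separate from the
# package's own code paths.

# Concordance probability: P(pos < neg) + 1/2 P(pos == neg) by direct
# pairwise enumeration (low scores indicate the positive class).
oracle_concordance <- function(pos, neg) {
  grid <- expand.grid(p = pos, n = neg)
  mean((grid$p < grid$n) + 0.5 * (grid$p == grid$n))
}

# Pearson chi-square by explicit sum over cells.
oracle_chisq <- function(counts) {
  counts <- as.matrix(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Mann-Whitney U for group a by exhaustive pair counting
# (a > b counts 1, ties count 1/2).
oracle_u <- function(a, b) {
  grid <- expand.grid(a = a, b = b)
  sum((grid$a > grid$b) + 0.5 * (grid$a == grid$b))
}

# Distribution of the sum of 8 independent categorical scores by full
# 3^8 enumeration over all score combinations.
oracle_total_distribution <- function(triples) {
  stopifnot(nrow(triples) == 8)
  combos <- expand.grid(rep(list(0:2), 8))
  prob <- rep(1, nrow(combos))
  for (i in 1:8) {
    tri <- c(triples$p0[i], triples$p1[i], triples$p2[i])
    prob <- prob * tri[combos[[i]] + 1]
  }
  totals <- rowSums(combos)
  vapply(0:16, function(t) sum(prob[totals == t]), numeric(1))
}

# Small random labeled cohort of integer scores for property tests.
random_cohort <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:30, 1)
  n_pos <- sample(2:(n - 2), 1)
  tibble::tibble(
    total = sample(0:16, n, replace = TRUE),
    outcome = c(rep("expired", n_pos), rep("discharged", n - n_pos))
  )
}

# One fully valid observation row; fields overridable.
make_obs <- function(id = "x", ...) {
  base <- tibble::tibble(
    id = id, apnea = FALSE, grunt = FALSE, respiratory_rate = 50,
    heart_rate = 120, asystole = FALSE, axillary_temperature = 37,
    capillary_refill_time = 2, random_blood_sugar = 90,
    spo2_room_air = 98, gestational_age_days = 273, birth_weight_kg = 3
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}
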