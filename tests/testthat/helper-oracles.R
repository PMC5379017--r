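# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: the trimmed mean is a literal sort-and-average, the
# Fisher p enumerates table probabilities from binomial coefficients rather
# than dhyper, and the funnel recount filters with plain subsetting.

# Trimmed mean by explicit sort and average, dropping floor(n * trim)
# values from each end.
oracle_trimmed_mean <- function(x, trim) {
  s <- sort(x)
  k <- floor(length(x) * trim)
  if (k > 0) s <- s[(k + 1):(length(s) - k)]
  sum(s) / length(s)
}

# Two-pass standardization.
oracle_z <- function(x) {
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / (length(x) - 1)
  (x - m) / sqrt(v)
}

# Two-sided Fisher p by direct enumeration of every table with the observed
# margins; probabilities from log binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; m1 <- a + c; n <- r1 + r2
  support <- max(0, m1 - r2):min(r1, m1)
  logp <- lchoose(r1, support) + lchoose(r2, m1 - support) - lchoose(n, m1)
  p <- exp(logp)
  p_obs <- p[support == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# A 10-patient hand-written funnel fixture with known attrition at every
# stage: counts are recomputed filter-by-filter in the tests.
funnel_fixture <- function() {
  patients <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    consent_active = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    alive          = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    has_ffpe       = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    has_expression = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    tissue_type = rep(c("lung", "breast"), 5),
    disease_setting = rep("primary", 10))
  zscores <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    z = c(1.5, 0.2, 2.0, 0.0, 3.0, -1.2, 1.1, 0.4, 2.2, 0.9))
  list(patients = patients, zscores = zscores)
}

# Random valid staining profiles (percentages summing to 100), for the
# scoring property tests.
random_profiles <- function(n) {
  w <- matrix(stats::rexp(4 * n), ncol = 4)
  w <- 100 * w / rowSums(w)
  tibble::tibble(pct_0 = w[, 1], pct_1 = w[, 2], pct_2 = w[, 3],
                 pct_3 = w[, 4])
}
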