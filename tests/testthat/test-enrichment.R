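test_that("fisher_exact_2x2 reproduces known exact p-values", {
  # balanced table carries no evidence
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p, 1)
  # diagonal 5/5 table: the two extreme tables out of choose(10,5) = 252
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p, 2 / 252, tolerance = 1e-12)
  # pooled RNA-group comparisons
  expect_equal(fisher_exact_2x2(12, 27, 0, 39)$p, 0.00018, tolerance = 0.01)
  expect_equal(fisher_exact_2x2(12, 27, 1, 38)$p, 0.0015, tolerance = 0.03)

  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "margin")
})

test_that("fisher_exact_2x2 odds ratio is the sample odds ratio", {
  expect_equal(fisher_exact_2x2(10, 5, 2, 4)$odds_ratio, (10 * 4) / (5 * 2))
  expect_identical(fisher_exact_2x2(3, 0, 2, 5)$odds_ratio, Inf)
  expect_identical(fisher_exact_2x2(0, 3, 2, 5)$odds_ratio, 0)
})

test_that("fisher_exact_2x2 agrees with stats::fisher.test on random tables", {
  withr::with_seed(41, {
    for (i in 1:200) {
      t <- matrix(rpois(4, sample(1:30, 1)), 2)
      p_ref <- stats::fisher.test(t)$p.value
      p_own <- fisher_exact_2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2])$p
      expect_equal(p_own, p_ref, tolerance = 1e-10)
    }
  })
})

test_that("fisher p is invariant to swapping rows and to transposition", {
  withr::with_seed(43, {
    for (i in 1:50) {
      x <- rpois(4, 8)
      p0 <- fisher_exact_2x2(x[1], x[2], x[3], x[4])$p
      expect_equal(fisher_exact_2x2(x[3], x[4], x[1], x[2])$p, p0,
                   tolerance = 1e-12)
      expect_equal(fisher_exact_2x2(x[1], x[3], x[2], x[4])$p, p0,
                   tolerance = 1e-12)
    }
  })
})

test_that("per-tissue summaries match an independent recount", {
  withr::with_seed(47, {
    z_a <- rnorm(60, 0.8, 1)
    z_b <- rnorm(60, -0.5, 0.7)
  })
  df <- tibble::tibble(tissue_type = rep(c("a", "b"), each = 60),
                       z = c(z_a, z_b))
  out <- summarize_tissue_enrichment(df, min_n = 50)
  expect_equal(nrow(out), 2)
  row_a <- out[out$tissue_type == "a", ]
  expect_equal(row_a$n, 60)
  expect_equal(row_a$n_high, sum(z_a >= 1))
  expect_equal(row_a$mean_z, mean(z_a))
  expect_equal(row_a$median_z, median(z_a))
  expect_equal(row_a$sd_z, sd(z_a))
  expect_equal(row_a$pct_high, round_half_away(100 * sum(z_a >= 1) / 60))
  # Fisher table: tissue high / not-high vs background high / not-high
  expect_equal(row_a$fisher_p,
               oracle_fisher_p(sum(z_a >= 1), sum(z_a < 1),
                               sum(z_b >= 1), sum(z_b < 1)),
               tolerance = 1e-12)
  # rows sorted by fraction high, descending
  expect_true(all(diff(out$n_high / out$n) <= 0))
})

test_that("extreme separation sets enrichment direction", {
  df <- tibble::tibble(
    tissue_type = rep(c("hot", "cold"), each = 50),
    z = c(rep(2, 50), rep(-2, 50)))
  out <- summarize_tissue_enrichment(df, min_n = 50)
  expect_identical(out$direction[out$tissue_type == "hot"], "over")
  expect_identical(out$direction[out$tissue_type == "cold"], "under")
})

test_that("tissues below min_n are excluded but still count in the background", {
  df <- tibble::tibble(
    tissue_type = c(rep("big", 60), rep("small", 49)),
    z = c(rep(0, 30), rep(2, 30), rep(2, 49)))
  out <- summarize_tissue_enrichment(df, min_n = 50)
  expect_identical(out$tissue_type, "big")
  # background for "big" is the 49 small-tissue samples
  expect_equal(out$fisher_p, oracle_fisher_p(30, 30, 49, 0), tolerance = 1e-12)
})

test_that("high counts are conserved between reported and excluded tissues", {
  wh <- simulate_warehouse(simulation_config(n_patients = 3000, seed = 53))
  scored <- add_z_scores(wh$expression)
  out <- summarize_tissue_enrichment(scored, min_n = 50)
  excluded <- dplyr::anti_join(scored, out, by = "tissue_type")
  expect_equal(sum(out$n_high) + sum(excluded$z >= 1), sum(scored$z >= 1))
})

test_that("type-I error is calibrated when no tissue is enriched", {
  # 40 exchangeable tissues, 200 samples each, identical normal expression:
  # about 5% of tissues should reach p < 0.05
  n_tissue <- 40
  reps <- 10
  hits <- 0
  for (r in seq_len(reps)) {
    withr::with_seed(600 + r, {
      df <- tibble::tibble(
        tissue_type = rep(sprintf("t%02d", seq_len(n_tissue)), each = 200),
        z = rnorm(n_tissue * 200))
    })
    out <- summarize_tissue_enrichment(df, min_n = 50)
    hits <- hits + sum(out$fisher_p < 0.05)
  }
  n_tests <- n_tissue * reps
  # exact tests are conservative, so 3 SE around a rate at or below 0.05
  se <- sqrt(0.05 * 0.95 / n_tests)
  expect_lt(hits / n_tests, 0.05 + 3 * se)
})

test_that("per-tissue densities integrate to one on the shared grid", {
  wh <- simulate_warehouse(simulation_config(n_patients = 4000, seed = 59))
  scored <- add_z_scores(wh$expression)
  den <- tissue_density(scored, min_n = 50)
  integrals <- den |>
    dplyr::group_by(tissue_type) |>
    dplyr::summarise(area = sum(diff(z) * (head(density, -1) + tail(density, -1)) / 2))
  expect_true(all(abs(integrals$area - 1) < 1e-3))
})

test_that("density recovers the shape of a known distribution", {
  withr::with_seed(61, z <- rnorm(5000))
  df <- tibble::tibble(tissue_type = "only", z = z)
  den <- tissue_density(df, min_n = 50)
  peak <- den$z[which.max(den$density)]
  expect_lt(abs(peak - 0), 0.1)
  med <- attr(den, "medians")
  expect_equal(med$median_z, median(z))
  # symmetric sample: median close to mean
  expect_lt(abs(med$median_z - mean(z)), 0.05)
})
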