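test_that("sample_per_group is exhaustive, deterministic and uniform", {
  df <- tibble::tibble(
    sample_id = as.character(1:5),
    rna_group = factor(rep("high", 5), levels = c("low", "medium", "high")))
  # group smaller than the request: taken in full
  expect_setequal(sample_per_group(df, 10, seed = 1)$sample_id, df$sample_id)

  big <- tibble::tibble(
    sample_id = as.character(1:300),
    rna_group = factor(rep(c("low", "medium", "high"), each = 100),
                       levels = c("low", "medium", "high")))
  s1 <- sample_per_group(big, 10, seed = 99)
  s2 <- sample_per_group(big, 10, seed = 99)
  expect_identical(s1, s2)
  expect_equal(as.integer(table(s1$rna_group)), c(10L, 10L, 10L))

  expect_error(sample_per_group(big, 0, seed = 1), "positive")

  # uniformity: over many draws of 10 from 100, each member appears ~10%
  grp <- big[big$rna_group == "high", ]
  reps <- 4000
  tally <- integer(100)
  for (r in seq_len(reps)) {
    ids <- as.integer(sample_per_group(grp, 10, seed = 10000 + r)$sample_id)
    tally[ids - 200L] <- tally[ids - 200L] + 1L
  }
  freq <- tally / reps
  se <- sqrt(0.1 * 0.9 / reps)
  # 100 simultaneous frequency checks: 4 SE keeps the family-wise false
  # alarm rate below 1%
  expect_true(all(abs(freq - 0.1) < 4 * se))
})

test_that("build_confusion reproduces the reference per-tumor metrics", {
  # lung: low 9/0, medium 10/0, high 10/4
  lung <- build_confusion(
    dplyr::filter(cd30_screen_counts(), tissue_type == "lung"))
  expect_equal(lung[, c("tp", "fp", "fn", "tn")],
               tibble::tibble(tp = 4L, fp = 6L, fn = 0L, tn = 19L),
               ignore_attr = TRUE)
  m <- tidy(lung)
  expect_equal(m$reported[m$metric == "sensitivity"], 100)
  expect_equal(m$reported[m$metric == "specificity"], 76)
  expect_equal(m$reported[m$metric == "ppv"], 40)
  expect_equal(m$reported[m$metric == "npv"], 100)
  expect_equal(m$reported[m$metric == "accuracy"], 79)

  # skin: low 10/0, medium 10/1, high 9/3
  skin <- build_confusion(
    dplyr::filter(cd30_screen_counts(), tissue_type == "skin"))
  expect_equal(skin[, c("tp", "fp", "fn", "tn")],
               tibble::tibble(tp = 3L, fp = 6L, fn = 1L, tn = 19L),
               ignore_attr = TRUE)
  ms <- tidy(skin)
  expect_equal(ms$reported[ms$metric == "sensitivity"], 75)
  expect_equal(ms$reported[ms$metric == "npv"], 95)
})

test_that("build_confusion agrees with an independent metric oracle", {
  skip_if_not_installed("caret")
  withr::with_seed(81, {
    for (i in 1:20) {
      n <- sample(5:30, 3, replace = TRUE)
      pos <- vapply(n, function(k) sample(0:k, 1), integer(1))
      gc <- tibble::tibble(
        rna_group = factor(c("low", "medium", "high"),
                           levels = c("low", "medium", "high")),
        n_screened = n, n_positive = pos)
      ct <- build_confusion(gc)
      truth <- factor(rep(rep(c("pos", "neg"), 3),
                          times = c(rbind(pos, n - pos))),
                      levels = c("pos", "neg"))
      call <- factor(rep(c("neg", "neg", "pos"), times = n),
                     levels = c("pos", "neg"))
      cm <- caret::confusionMatrix(call, truth, positive = "pos")
      pairs <- list(
        c("sensitivity", "Sensitivity"), c("specificity", "Specificity"),
        c("ppv", "Pos Pred Value"), c("npv", "Neg Pred Value"))
      for (pr in pairs) {
        if (!is.na(ct[[pr[1]]])) {
          expect_equal(ct[[pr[1]]] / 100, unname(cm$byClass[pr[2]]),
                       tolerance = 1e-12)
        }
      }
      expect_equal(ct$accuracy / 100, unname(cm$overall["Accuracy"]),
                   tolerance = 1e-12)
    }
  })
})

test_that("zero-denominator metrics are NA, never 0 or 100", {
  gc <- tibble::tibble(rna_group = "high", n_screened = 10L, n_positive = 3L)
  ct <- build_confusion(gc)  # no screen-negative groups at all
  expect_true(is.na(ct$specificity))
  expect_true(is.na(ct$npv))
  expect_false(is.na(ct$sensitivity))
  expect_error(build_confusion(gc, positive_groups = character(0)),
               "nonempty")
})

test_that("screen-positive-everything degenerates to the positivity rate", {
  gc <- tibble::tibble(
    rna_group = c("low", "medium", "high"),
    n_screened = c(10L, 10L, 10L), n_positive = c(1L, 2L, 5L))
  ct <- build_confusion(gc, positive_groups = c("low", "medium", "high"))
  expect_true(is.na(ct$specificity))
  expect_equal(ct$sensitivity, 100)
  expect_equal(ct$ppv, 100 * 8 / 30)  # overall positivity rate
})

test_that("accuracy lies between sensitivity and specificity when defined", {
  withr::with_seed(83, {
    for (i in 1:50) {
      n <- sample(3:20, 3, replace = TRUE)
      pos <- vapply(n, function(k) sample(0:k, 1), integer(1))
      gc <- tibble::tibble(rna_group = c("low", "medium", "high"),
                           n_screened = n, n_positive = pos)
      ct <- build_confusion(gc)
      if (!is.na(ct$sensitivity) && !is.na(ct$specificity)) {
        expect_gte(ct$accuracy, min(ct$sensitivity, ct$specificity) - 1e-9)
        expect_lte(ct$accuracy, max(ct$sensitivity, ct$specificity) + 1e-9)
      }
    }
  })
})

test_that("metric_ranges reproduces the published four-tumor ranges", {
  tabs <- cd30_screen_counts() |>
    dplyr::group_by(tissue_type) |>
    dplyr::group_map(~ build_confusion(.x))
  rng <- metric_ranges(tabs)
  expected <- tibble::tribble(
    ~metric,       ~min, ~max,
    "accuracy",      72,   79,
    "sensitivity",   75,  100,
    "specificity",   70,   76,
    "ppv",           20,   40,
    "npv",           95,  100)
  expect_equal(dplyr::arrange(rng, metric), dplyr::arrange(expected, metric),
               ignore_attr = TRUE)

  # singleton: min equals max
  one <- metric_ranges(tabs[1])
  expect_equal(one$min, one$max)

  # two hand-built tables with known metrics
  t1 <- build_confusion(tibble::tibble(
    rna_group = c("low", "high"), n_screened = c(10L, 10L),
    n_positive = c(0L, 5L)))  # sens 100, spec 67, ppv 50, npv 100, acc 75
  t2 <- build_confusion(tibble::tibble(
    rna_group = c("low", "high"), n_screened = c(10L, 10L),
    n_positive = c(2L, 8L)))  # sens 80, spec 80, ppv 80, npv 80, acc 80
  rng2 <- metric_ranges(list(t1, t2))
  expect_equal(rng2$min[rng2$metric == "sensitivity"], 80)
  expect_equal(rng2$max[rng2$metric == "sensitivity"], 100)
  expect_equal(rng2$min[rng2$metric == "ppv"], 50)
  expect_equal(rng2$max[rng2$metric == "ppv"], 80)

  expect_error(metric_ranges(list()), "nonempty")
})

test_that("compare_groups reproduces the pooled exact comparisons", {
  expect_equal(signif(compare_groups(12, 39, 0, 39), 2), 1.8e-4)
  expect_equal(signif(compare_groups(12, 39, 1, 39), 2), 1.5e-3)
  expect_equal(compare_groups(5, 10, 5, 10), 1)
  expect_error(compare_groups(11, 10, 0, 10), "exceed")
})

test_that("high-group PPV and pooled NPV recover the simulated positivity", {
  pi_cfg <- c(low = 0.02, medium = 1 / 39, high = 12 / 39)
  wh <- simulate_warehouse(
    simulation_config(n_patients = 60000, seed = 87,
                      ihc_positivity_by_group = pi_cfg))
  scored <- add_z_scores(wh$expression)
  ihc <- score_ihc(wh$staining)
  joined <- dplyr::inner_join(scored, ihc, by = "sample_id")
  chosen <- sample_per_group(joined, 2000, seed = 87)
  counts <- count_groups(chosen)
  ct <- build_confusion(counts)

  n_high <- counts$n_screened[counts$rna_group == "high"]
  se_hi <- sqrt(pi_cfg[["high"]] * (1 - pi_cfg[["high"]]) / n_high)
  expect_lt(abs(ct$ppv / 100 - pi_cfg[["high"]]), 3 * se_hi)

  neg <- counts[counts$rna_group != "high", ]
  pi_neg <- sum(neg$n_screened * pi_cfg[as.character(neg$rna_group)]) /
    sum(neg$n_screened)
  se_neg <- sqrt(pi_neg * (1 - pi_neg) / sum(neg$n_screened))
  expect_lt(abs(ct$npv / 100 - (1 - pi_neg)), 3 * se_neg)
})
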