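#' Draw a fixed number of samples per RNA group
#'
#' Uniform random selection without replacement of up to `n_per_group`
#' samples from each RNA group, mirroring the protein-confirmation design in
#' which a handful of samples per group are sent for IHC staining.  Groups
#' smaller than `n_per_group` are taken in full.  Reproducible under `seed`.
#'
#' @param data data frame with an `rna_group` column (and typically
#'   `sample_id`), e.g. [add_z_scores()] output.
#' @param n_per_group number of samples to draw per group (> 0).
#' @param seed integer seed for the draw.
#' @return A tibble: the selected rows of `data`.
#' @examples
#' wh <- simulate_warehouse(simulation_config(n_patients = 1000, seed = 3))
#' scored <- add_z_scores(wh$expression)
#' nrow(sample_per_group(scored, 10, seed = 1))
#' @export
sample_per_group <- function(data, n_per_group, seed) {
  check_columns(data, "rna_group", "data")
  if (!is_scalar_number(n_per_group) || n_per_group <= 0) {
    stop("`n_per_group` must be a positive number", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    out <- tibble::as_tibble(data) |>
      dplyr::group_by(.data$rna_group) |>
      dplyr::slice_sample(n = n_per_group) |>
      dplyr::ungroup()
  })
  out
}

#' Tabulate screened and protein-positive counts by RNA group
#'
#' Collapses per-sample screening results into the per-group counts that
#' [build_confusion()] consumes.
#'
#' @param data data frame with `rna_group` and a logical truth column.
#' @param truth name of the logical protein-truth column (default
#'   `"positive_by_hscore"`, the protein-expression-group call; use
#'   `"positive_by_fraction"` for the trial-eligibility rule).
#' @return A tibble with `rna_group`, `n_screened`, `n_positive`.
#' @export
count_groups <- function(data, truth = "positive_by_hscore") {
  check_columns(data, c("rna_group", truth), "data")
  data |>
    dplyr::group_by(.data$rna_group) |>
    dplyr::summarise(n_screened = dplyr::n(),
                     n_positive = sum(.data[[truth]]),
                     .groups = "drop")
}

#' Confusion table of RNA-group screening against protein truth
#'
#' Treats membership of the RNA groups in `positive_groups` (default:
#' `high`) as the screen-positive call and protein positivity as truth, and
#' tabulates true/false positives/negatives with the standard diagnostic
#' metrics.  Screen-negative pools every remaining group (at the default,
#' low and medium together).  Metrics are percentages; a metric whose
#' denominator is zero is `NA`, never 0 or 100.
#'
#' @param group_counts data frame with `rna_group`, `n_screened`,
#'   `n_positive` (one row per group), e.g. from [count_groups()] or
#'   [cd30_screen_counts()] filtered to one tumor type.
#' @param positive_groups character vector of screen-positive RNA groups
#'   (default `"high"`).
#' @return A one-row tibble of class `"confusion_table"`: `tp`, `fp`, `fn`,
#'   `tn` and unrounded percent metrics `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`.  Use [tidy()] for rounded reporting.
#' @examples
#' lung <- dplyr::filter(cd30_screen_counts(), tissue_type == "lung")
#' build_confusion(lung)
#' @export
build_confusion <- function(group_counts, positive_groups = "high") {
  check_columns(group_counts, c("rna_group", "n_screened", "n_positive"),
                "group_counts")
  if (length(positive_groups) == 0) {
    stop("`positive_groups` must be nonempty", call. = FALSE)
  }
  gc <- group_counts
  if (any(gc$n_positive < 0 | gc$n_positive > gc$n_screened)) {
    stop("`n_positive` must lie in [0, n_screened] for every group",
         call. = FALSE)
  }
  pos <- as.character(gc$rna_group) %in% positive_groups
  tp <- sum(gc$n_positive[pos])
  fp <- sum(gc$n_screened[pos] - gc$n_positive[pos])
  fn <- sum(gc$n_positive[!pos])
  tn <- sum(gc$n_screened[!pos] - gc$n_positive[!pos])
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  # a metric is undefined when its denominator is zero, and also when the
  # screen arm it conditions on is empty: with no screen-negative samples at
  # all, specificity = tn/(tn+fp) would be a misleading 0, not an estimate
  arm_pos <- tp + fp > 0
  arm_neg <- tn + fn > 0
  out <- tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = pct(tp + tn, tp + fp + fn + tn),
    sensitivity = if (arm_pos) pct(tp, tp + fn) else NA_real_,
    specificity = if (arm_neg) pct(tn, tn + fp) else NA_real_,
    ppv = if (arm_pos) pct(tp, tp + fp) else NA_real_,
    npv = if (arm_neg) pct(tn, tn + fn) else NA_real_)
  class(out) <- c("confusion_table", class(out))
  out
}

confusion_metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")

#' Tidy a confusion table
#'
#' @param x a `confusion_table` from [build_confusion()].
#' @param ... unused.
#' @return A long tibble with `metric`, `estimate` (unrounded percent) and
#'   `reported` (integer percent, rounded half away from zero; `NA` when the
#'   metric is undefined).
#' @method tidy confusion_table
#' @export
tidy.confusion_table <- function(x, ...) {
  est <- unlist(x[1, confusion_metrics])
  tibble::tibble(metric = confusion_metrics,
                 estimate = unname(est),
                 reported = round_half_away(unname(est)))
}

#' Glance at a confusion table
#'
#' @param x a `confusion_table` from [build_confusion()].
#' @param ... unused.
#' @return A one-row tibble with the total screened, prevalence of protein
#'   positivity (percent) and screen-positive fraction (percent).
#' @method glance confusion_table
#' @export
glance.confusion_table <- function(x, ...) {
  total <- x$tp + x$fp + x$fn + x$tn
  tibble::tibble(
    n_screened = total,
    prevalence = 100 * (x$tp + x$fn) / total,
    screen_positive_rate = 100 * (x$tp + x$fp) / total)
}

#' Range of diagnostic metrics across strata
#'
#' Elementwise minimum and maximum of each diagnostic metric over a set of
#' confusion tables (e.g. one per tumor type), after rounding each metric
#' half away from zero to integer percent as reported.  Undefined (`NA`)
#' metrics are skipped; a metric undefined in every table is dropped.
#'
#' @param tables a named list of `confusion_table` objects, or a data frame
#'   of their rows (`dplyr::bind_rows()` output).
#' @return A tibble with `metric`, `min`, `max` (integer percent).
#' @examples
#' tabs <- cd30_screen_counts() |>
#'   dplyr::group_by(tissue_type) |>
#'   dplyr::group_map(~ build_confusion(.x))
#' metric_ranges(tabs)
#' @export
metric_ranges <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0) stop("`tables` must be nonempty", call. = FALSE)
  df <- dplyr::bind_rows(tables)
  check_columns(df, confusion_metrics, "tables")
  purrr::map(confusion_metrics, function(m) {
    v <- round_half_away(df[[m]][!is.na(df[[m]])])
    if (length(v) == 0) return(NULL)
    tibble::tibble(metric = m, min = min(v), max = max(v))
  }) |>
    purrr::list_rbind()
}

#' Exact comparison of positivity between two groups
#'
#' Two-sided Fisher exact test of the protein-positivity proportion in one
#' RNA group against another (e.g. pooled RNA-high vs pooled RNA-low),
#' delegating to [fisher_exact_2x2()] on the table
#' `[[pos_a, n_a - pos_a], [pos_b, n_b - pos_b]]`.
#'
#' @param pos_a,n_a positives and total screened in the first group.
#' @param pos_b,n_b positives and total screened in the second group.
#' @return The two-sided p-value.
#' @examples
#' compare_groups(12, 39, 0, 39)  # ~0.00018
#' compare_groups(12, 39, 1, 39)  # ~0.0015
#' @export
compare_groups <- function(pos_a, n_a, pos_b, n_b) {
  if (pos_a > n_a || pos_b > n_b) {
    stop("positives cannot exceed totals", call. = FALSE)
  }
  fisher_exact_2x2(pos_a, n_a - pos_a, pos_b, n_b - pos_b)$p
}
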