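#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]` by the
#' minimum-likelihood rule: conditioning on the margins, the p-value sums the
#' hypergeometric probabilities of every table whose probability does not
#' exceed that of the observed table (with the customary 1 + 1e-7 relative
#' tolerance on the comparison, so mathematically tied tables are included
#' despite floating-point rounding).  This is the convention of mainstream
#' statistical software, and [stats::fisher.test()] agrees with it; the
#' enumeration here is vectorized over the support so that large batches of
#' tables are cheap.
#'
#' The odds ratio is the sample odds ratio `(a d) / (b c)`; a single zero
#' cell gives 0 or `Inf` rather than a continuity correction, and `0/0`
#' gives `NaN`.  The p-value is the primary quantity.
#'
#' @param a,b,c,d non-negative counts: `a`, `b` are the first row (e.g.
#'   biomarker-high and not-high in the tissue of interest), `c`, `d` the
#'   second (the same split in the background).
#' @return A list with elements `p` and `odds_ratio`.
#' @examples
#' fisher_exact_2x2(12, 27, 0, 39)$p   # ~1.8e-4
#' fisher_exact_2x2(1, 1, 1, 1)$p      # exactly 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("`a`, `b`, `c`, `d` must be non-negative integers", call. = FALSE)
  }
  n <- a + b + c + d
  if (n == 0 || (a + b == 0 && c + d == 0) || (a + c == 0 && b + d == 0)) {
    stop("at least one margin must be positive", call. = FALSE)
  }
  r1 <- a + b       # first row total
  m1 <- a + c       # first column total
  lo <- max(0, r1 + m1 - n)
  hi <- min(r1, m1)
  support <- lo:hi
  dens <- stats::dhyper(support, m1, n - m1, r1)
  d_obs <- dens[support == a]
  p <- min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c)
  list(p = p, odds_ratio = or)
}

#' Per-tissue enrichment of biomarker-high samples
#'
#' Summarizes global Z-scores by tumor site of origin and tests, for each
#' tissue with at least `min_n` samples, whether biomarker-high samples
#' (Z >= `z_threshold`) are over- or under-represented in that tissue
#' relative to all other samples in the input, by a two-sided Fisher exact
#' test on the 2x2 table (tissue high / tissue not-high / rest high / rest
#' not-high).  The background for each tissue's test is every other sample
#' supplied, so the caller controls whether small tissues contribute to the
#' background by filtering the input beforehand.
#'
#' @param data data frame with `tissue_type` and `z` columns, e.g.
#'   [add_z_scores()] output.
#' @param z_threshold biomarker-high cut (default 1).
#' @param min_n minimum per-tissue sample count for a tissue to be reported
#'   (default 50).
#' @return A tibble of class `"tissue_enrichment"`, one row per qualifying
#'   tissue, sorted by the fraction of high samples descending: `tissue_type`,
#'   `n`, `n_high`, `pct_high` (integer percent, rounded half away from
#'   zero), `fisher_p`, `odds_ratio`, `direction` (`"over"` if the odds
#'   ratio exceeds 1, else `"under"`), `mean_z`, `median_z`, `sd_z`.
#' @examples
#' wh <- simulate_warehouse(simulation_config(n_patients = 5000, seed = 1))
#' scored <- add_z_scores(wh$expression)
#' summarize_tissue_enrichment(scored)
#' @export
summarize_tissue_enrichment <- function(data, z_threshold = 1, min_n = 50) {
  check_columns(data, c("tissue_type", "z"), "data")
  if (nrow(data) == 0) stop("`data` is empty", call. = FALSE)
  total_n <- nrow(data)
  total_high <- sum(data$z >= z_threshold)

  out <- data |>
    dplyr::group_by(.data$tissue_type) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_high = sum(.data$z >= z_threshold),
      mean_z = mean(.data$z),
      median_z = stats::median(.data$z),
      sd_z = stats::sd(.data$z),
      .groups = "drop") |>
    dplyr::filter(.data$n >= min_n)

  test <- purrr::map2(out$n_high, out$n, function(nh, nn) {
    fisher_exact_2x2(nh, nn - nh, total_high - nh,
                     (total_n - nn) - (total_high - nh))
  })
  out$fisher_p <- purrr::map_dbl(test, "p")
  out$odds_ratio <- purrr::map_dbl(test, "odds_ratio")
  out$direction <- ifelse(out$odds_ratio > 1, "over", "under")
  out$pct_high <- round_half_away(100 * out$n_high / out$n)
  out <- out |>
    dplyr::arrange(dplyr::desc(.data$n_high / .data$n)) |>
    dplyr::select("tissue_type", "n", "n_high", "pct_high", "fisher_p",
                  "odds_ratio", "direction", "mean_z", "median_z", "sd_z")
  class(out) <- c("tissue_enrichment", class(out))
  out
}

#' Per-tissue kernel density of Z-scores on a shared grid
#'
#' Gaussian kernel density estimate of the Z-score distribution for every
#' tissue with at least `min_n` samples, evaluated on one shared grid so the
#' curves are directly comparable, plus each tissue's median (the "dot" of
#' the classic per-tissue density display).  The grid spans the pooled data
#' extended by three times the largest per-tissue bandwidth, so each curve
#' integrates to 1 (within 1e-3) on the grid.
#'
#' @param data data frame with `tissue_type` and `z` columns.
#' @param min_n minimum per-tissue sample count (default 50).
#' @param n_grid number of grid points (default 512).
#' @return A tibble of class `"tissue_density"` with columns `tissue_type`,
#'   `z`, `density`; the per-tissue medians are in `attr(, "medians")`.
#' @seealso [autoplot.tissue_density()]
#' @export
tissue_density <- function(data, min_n = 50, n_grid = 512) {
  check_columns(data, c("tissue_type", "z"), "data")
  keep <- data |>
    dplyr::count(.data$tissue_type) |>
    dplyr::filter(.data$n >= min_n)
  df <- dplyr::semi_join(tibble::as_tibble(data), keep, by = "tissue_type")
  if (nrow(df) == 0) stop("no tissue reaches `min_n` samples", call. = FALSE)

  split_z <- split(df$z, df$tissue_type, drop = TRUE)
  bws <- vapply(split_z, stats::bw.nrd0, numeric(1))
  from <- min(df$z) - 3 * max(bws)
  to <- max(df$z) + 3 * max(bws)

  out <- purrr::imap(split_z, function(z, tissue) {
    den <- stats::density(z, bw = bws[[tissue]], from = from, to = to,
                          n = n_grid)
    tibble::tibble(tissue_type = tissue, z = den$x, density = den$y)
  }) |>
    purrr::list_rbind()
  medians <- tibble::tibble(
    tissue_type = names(split_z),
    median_z = unname(vapply(split_z, stats::median, numeric(1))))
  attr(out, "medians") <- medians
  class(out) <- c("tissue_density", class(out))
  out
}
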