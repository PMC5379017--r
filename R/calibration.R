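#' Reference per-tissue CD30 expression summaries
#'
#' Per-tissue summaries of global CD30 expression Z-scores from the
#' multi-tissue solid-tumor screening cohort that this package's simulator
#' emulates: all primary tumor types with at least 50 profiled samples
#' (13,670 samples across 24 tissues).  For each tissue the table carries the
#' sample count, the number and reported integer percentage of samples in the
#' RNA-high group (Z-score >= 1), the reported two-sided Fisher exact p-value
#' for enrichment of high samples against all other listed tissues, and the
#' mean, median and standard deviation of the tissue's Z-scores.
#'
#' These values serve two purposes: they are the default calibration for
#' [simulation_config()] (each tissue's log2 expression is drawn from a
#' normal with the tissue's mean and SD, mixed in proportion to `n`), and
#' they are reference points for consistency checks on
#' [summarize_tissue_enrichment()].
#'
#' @return A tibble with columns `tissue_type`, `n`, `n_high`, `pct_high`
#'   (reported integer percent), `fisher_p` (reported), `mean_z`, `median_z`,
#'   `sd_z`, sorted by `pct_high` descending.
#' @seealso [simulation_config()], [summarize_tissue_enrichment()]
#' @export
cd30_tissue_summary <- function() {
  tibble::tribble(
    ~tissue_type,             ~n, ~n_high, ~pct_high, ~fisher_p, ~mean_z, ~median_z, ~sd_z,
    "lymph nodes",            50L,    25L,       50L,  8.12e-10,   1.271,     1.011, 1.382,
    "soft tissue",            94L,    30L,       32L,  5.03e-06,   0.512,     0.399, 1.237,
    "ovary",                 668L,   141L,       21L,  6.23e-08,   0.182,     0.092, 1.104,
    "oral cavity",            96L,    20L,       21L,     0.051,   0.444,     0.475, 0.887,
    "lung",                 2667L,   503L,       19L,  2.71e-17,   0.178,     0.202, 0.986,
    "esophagus",              89L,    16L,       18L,     0.217,   0.092,     0.099, 0.988,
    "skin",                  562L,   101L,       18L,     0.003,   0.062,     0.152, 1.132,
    "cervix",                 75L,    13L,       17L,     0.315,   0.204,     0.183, 0.939,
    "bladder",               208L,    35L,       17L,     0.185,   0.087,     0.107, 0.996,
    "breast",               3676L,   529L,       14L,     0.122,   0.065,     0.015, 0.913,
    "rectum-anus",           180L,    26L,       14L,     0.743,   0.084,    -0.003, 0.961,
    "larynx",                 54L,     7L,       13L,     1.000,   0.285,     0.317, 0.648,
    "small intestine",        50L,     6L,       12L,     1.000,  -0.721,    -0.713, 1.356,
    "stomach",               128L,    15L,       12L,     0.606,  -0.061,     0.040, 1.125,
    "uterus",                374L,    43L,       11L,     0.252,  -0.251,    -0.329, 1.036,
    "pancreas",              457L,    49L,       11L,     0.071,  -0.046,    -0.026, 0.940,
    "thyroid",                70L,     7L,       10L,     0.485,   0.024,     0.274, 0.946,
    "endometrium",           334L,    30L,        9L,     0.012,  -0.293,    -0.339, 0.986,
    "large bowel/colorectal", 2077L,  178L,        9L,  1.76e-14,  -0.152,    -0.193, 0.871,
    "kidney",                846L,    53L,        6L,  2.72e-12,  -0.154,    -0.123, 0.866,
    "brain",                 435L,    24L,        6L,  3.51e-08,  -0.500,    -0.520, 1.059,
    "renal pelvis",           62L,     3L,        5L,     0.041,  -0.612,    -0.643, 1.022,
    "prostate",              305L,     9L,        3L,  1.92e-10,  -0.636,    -0.655, 0.802,
    "liver",                 113L,     2L,        2L,  2.22e-05,  -0.826,    -0.784, 0.915
  )
}

#' Reference IHC screening counts by RNA expression group
#'
#' Group-level counts from the IHC confirmation arm of the screening cohort:
#' for each of four tumor types (breast, lung, ovary, skin), 9 or 10 samples
#' were drawn at random from each of the RNA-low, RNA-medium and RNA-high
#' groups and stained for CD30 protein; the table records how many were
#' screened and how many were called CD30 protein positive per group.
#'
#' Pooled over the four tumor types, 0/39 RNA-low, 1/39 RNA-medium and 12/39
#' RNA-high samples were protein positive.  These counts calibrate the
#' simulator's default group-conditional positivity rates and feed the
#' worked concordance examples.
#'
#' @return A tibble with columns `tissue_type`, `rna_group` (factor
#'   low/medium/high), `n_screened`, `n_positive`.
#' @seealso [build_confusion()], [metric_ranges()], [simulation_config()]
#' @export
cd30_screen_counts <- function() {
  out <- tibble::tribble(
    ~tissue_type, ~rna_group, ~n_screened, ~n_positive,
    "breast", "low",    10L, 0L,
    "breast", "medium", 10L, 0L,
    "breast", "high",   10L, 3L,
    "lung",   "low",     9L, 0L,
    "lung",   "medium", 10L, 0L,
    "lung",   "high",   10L, 4L,
    "ovary",  "low",    10L, 0L,
    "ovary",  "medium",  9L, 0L,
    "ovary",  "high",   10L, 2L,
    "skin",   "low",    10L, 0L,
    "skin",   "medium", 10L, 1L,
    "skin",   "high",    9L, 3L
  )
  out$rna_group <- factor(out$rna_group, levels = c("low", "medium", "high"))
  out
}

#' Reference eligibility-funnel counts
#'
#' Patient counts at each stage of the cohort-identification funnel in the
#' screening warehouse: all consented patients, those with an active consent,
#' alive, with archival FFPE tissue, with an expression profile, and finally
#' those whose CD30 Z-score is at least 1.  The stage-to-stage ratios are the
#' default per-stage retention probabilities of [simulation_config()].
#'
#' @return A tibble with columns `stage` and `n`.
#' @seealso [apply_funnel()], [simulation_config()]
#' @export
cd30_funnel_counts <- function() {
  tibble::tibble(
    stage = c("consented", "active_consent", "alive",
              "ffpe_available", "expression_available", "z_above_threshold"),
    n = c(120887L, 99241L, 49562L, 12802L, 8307L, 1138L)
  )
}
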