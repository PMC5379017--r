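#' Configure an end-to-end pipeline run
#'
#' Collects every tunable of the pipeline — thresholds, sampling sizes, the
#' standardization scope and the seed — plus optional paths to input tables.
#' When no input paths are given, [run_pipeline()] simulates a warehouse
#' from `simulation`; when `group_counts` is given, the concordance stage
#' uses those pre-tabulated per-group counts instead of drawing and staining
#' samples.
#'
#' @param seed integer seed used for every stochastic stage.
#' @param simulation a [simulation_config()] (its own seed is overridden by
#'   `seed`), or `NULL` for the calibrated defaults.
#' @param z_low,z_high trichotomization cuts (defaults -1, +1).
#' @param z_threshold biomarker-high cut for the funnel and enrichment
#'   stages (default 1).
#' @param z_scope `"global"` to standardize over every expression record, or
#'   `"survivors"` to take the mean/SD from eligibility-funnel survivors.
#' @param min_n minimum per-tissue sample count for enrichment/density
#'   (default 50).
#' @param min_pct,min_h IHC positivity thresholds (defaults 10, 10).
#' @param n_per_group samples drawn per RNA group for concordance
#'   (default 10).
#' @param truth protein-truth call, `"hscore"` or `"fraction"`.
#' @param inputs optional named list of paths: `patients`, `expression`,
#'   `staining` (TSV) and/or `group_counts` (TSV mirroring
#'   [cd30_screen_counts()]).
#' @return A list of class `"run_config"`.
#' @seealso [run_pipeline()], [read_run_config()]
#' @export
run_config <- function(seed = 1L,
                       simulation = NULL,
                       z_low = -1, z_high = 1, z_threshold = 1,
                       z_scope = c("global", "survivors"),
                       min_n = 50, min_pct = 10, min_h = 10,
                       n_per_group = 10,
                       truth = c("hscore", "fraction"),
                       inputs = list()) {
  z_scope <- match.arg(z_scope)
  truth <- match.arg(truth)
  stopifnot(is_scalar_number(z_low), is_scalar_number(z_high),
            is_scalar_number(z_threshold), is_scalar_number(min_n),
            is_scalar_number(min_pct), is_scalar_number(min_h),
            is_scalar_number(n_per_group))
  if (is.null(simulation)) simulation <- simulation_config(seed = seed)
  simulation$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), simulation = simulation,
                 z_low = z_low, z_high = z_high, z_threshold = z_threshold,
                 z_scope = z_scope, min_n = min_n, min_pct = min_pct,
                 min_h = min_h, n_per_group = n_per_group, truth = truth,
                 inputs = inputs),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the arguments of [run_config()]; a `simulation` block
#' mirrors [simulation_config()] (with `tissue_expr_params` as a list of
#' `tissue_type`/`mean`/`sd` records).  Missing keys take the defaults.
#'
#' @param path path to a YAML configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulation)) {
    sa <- raw$simulation
    if (!is.null(sa$tissue_mix)) sa$tissue_mix <- unlist(sa$tissue_mix)
    if (!is.null(sa$funnel_rates)) sa$funnel_rates <- unlist(sa$funnel_rates)
    if (!is.null(sa$ihc_positivity_by_group)) {
      sa$ihc_positivity_by_group <- unlist(sa$ihc_positivity_by_group)
    }
    if (!is.null(sa$tissue_expr_params)) {
      sa$tissue_expr_params <- purrr::list_rbind(
        purrr::map(sa$tissue_expr_params, tibble::as_tibble))
    }
    sim <- do.call(simulation_config, sa)
  }
  args <- raw[setdiff(names(raw), "simulation")]
  do.call(run_config, c(args, list(simulation = sim)))
}

read_table_tsv <- function(path, required, what) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, required, what)
  df
}

#' Run the full prescreening pipeline
#'
#' Executes simulate (unless input tables are supplied) -> Z-scoring ->
#' eligibility funnel -> tissue enrichment and density -> IHC scoring ->
#' RNA-vs-protein concordance, writing every result table as TSV under
#' `output_dir` along with a deterministic run log.  Re-running with an
#' identical config produces byte-identical outputs.
#'
#' Files written: `patients.tsv`, `expression.tsv`, `staining.tsv`,
#' `zscores.tsv`, `funnel.tsv`, `candidates.txt`, `enrichment.tsv`,
#' `density.tsv`, `ihc.tsv`, `concordance.tsv`, `ranges.tsv`,
#' `run_log.txt`.
#'
#' @param config a [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @param output_dir directory for the report bundle (created if needed).
#' @param quiet suppress progress messages (default `FALSE`); messages go to
#'   standard error.
#' @return Invisibly, a list with the in-memory results: `warehouse` (or
#'   `NULL`), `zscores`, `funnel`, `enrichment`, `density`, `ihc`,
#'   `concordance` (per-stratum confusion rows), `ranges`, `comparisons`.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[cd30screen] ", ...)
  log_lines <- c(
    paste0("cd30screen ", as.character(utils::packageVersion("cd30screen"))),
    paste0("R ", R.version$major, ".", R.version$minor),
    paste0("seed: ", config$seed),
    sprintf("thresholds: z_low=%g z_high=%g z_threshold=%g min_n=%g min_pct=%g min_h=%g n_per_group=%g",
            config$z_low, config$z_high, config$z_threshold, config$min_n,
            config$min_pct, config$min_h, config$n_per_group),
    paste0("z_scope: ", config$z_scope),
    paste0("truth: ", config$truth))
  out_path <- function(f) file.path(output_dir, f)
  emit <- function(df, file) {
    readr::write_tsv(tibble::as_tibble(df), out_path(file), progress = FALSE)
    log_lines <<- c(log_lines, sprintf("%s: %d rows", file, nrow(df)))
  }

  # --- inputs ---------------------------------------------------------------
  warehouse <- NULL
  if (!is.null(config$inputs$patients) && !is.null(config$inputs$expression)) {
    say("reading input tables")
    patients <- read_table_tsv(config$inputs$patients,
                               c("patient_id", "consent_active", "alive",
                                 "has_ffpe", "has_expression", "tissue_type"),
                               "patients.tsv")
    expression <- read_table_tsv(config$inputs$expression,
                                 c("sample_id", "patient_id", "tissue_type",
                                   "log2_expression"), "expression.tsv")
    staining <- if (!is.null(config$inputs$staining)) {
      read_table_tsv(config$inputs$staining,
                     c("sample_id", "pct_0", "pct_1", "pct_2", "pct_3"),
                     "staining.tsv")
    }
  } else {
    say("simulating warehouse (n = ", config$simulation$n_patients, ")")
    warehouse <- simulate_warehouse(config$simulation)
    patients <- warehouse$patients
    expression <- warehouse$expression
    staining <- warehouse$staining
  }
  emit(patients, "patients.tsv")
  emit(expression, "expression.tsv")
  if (!is.null(staining)) emit(staining, "staining.tsv")

  # --- scoring --------------------------------------------------------------
  say("computing global Z-scores (scope: ", config$z_scope, ")")
  reference <- NULL
  if (config$z_scope == "survivors") {
    eligible <- patients$consent_active & patients$alive &
      patients$has_ffpe & patients$has_expression
    reference <- expression$patient_id %in% patients$patient_id[eligible]
  }
  scored <- add_z_scores(expression, z_low = config$z_low,
                         z_high = config$z_high, reference = reference)
  emit(scored[, intersect(c("sample_id", "patient_id", "tissue_type", "z",
                            "rna_group"), names(scored))], "zscores.tsv")

  # --- funnel ---------------------------------------------------------------
  say("applying eligibility funnel")
  funnel <- apply_funnel(patients,
                         scored[, c("patient_id", "z")],
                         z_threshold = config$z_threshold)
  emit(funnel, "funnel.tsv")
  writeLines(funnel_candidates(funnel), out_path("candidates.txt"))
  log_lines <- c(log_lines,
                 sprintf("candidates.txt: %d ids", length(funnel_candidates(funnel))))

  # --- tissue enrichment ----------------------------------------------------
  say("summarizing tissue enrichment")
  enrichment <- summarize_tissue_enrichment(scored,
                                            z_threshold = config$z_threshold,
                                            min_n = config$min_n)
  emit(enrichment, "enrichment.tsv")
  density <- tissue_density(scored, min_n = config$min_n)
  emit(density, "density.tsv")

  # --- IHC scoring ----------------------------------------------------------
  ihc <- NULL
  if (!is.null(staining)) {
    say("scoring IHC staining profiles")
    ihc <- score_ihc(staining, min_pct = config$min_pct, min_h = config$min_h)
    emit(ihc, "ihc.tsv")
  }

  # --- concordance ----------------------------------------------------------
  truth_col <- switch(config$truth, hscore = "positive_by_hscore",
                      fraction = "positive_by_fraction")
  concordance <- NULL
  comparisons <- NULL
  ranges <- NULL
  if (!is.null(config$inputs$group_counts)) {
    say("evaluating concordance from supplied group counts")
    gc <- read_table_tsv(config$inputs$group_counts,
                         c("rna_group", "n_screened", "n_positive"),
                         "group_counts")
    strata <- if ("tissue_type" %in% names(gc)) {
      split(gc, gc$tissue_type)
    } else {
      list(all = gc)
    }
    concordance <- purrr::imap(strata, function(g, nm) {
      dplyr::bind_cols(tibble::tibble(stratum = nm), build_confusion(g))
    }) |> purrr::list_rbind()
    pooled <- gc |>
      dplyr::group_by(.data$rna_group) |>
      dplyr::summarise(n_screened = sum(.data$n_screened),
                       n_positive = sum(.data$n_positive), .groups = "drop")
    comparisons <- pooled_comparisons(pooled)
  } else if (!is.null(ihc)) {
    say("evaluating concordance on ", config$n_per_group,
        " samples per RNA group")
    joined <- dplyr::inner_join(scored, ihc, by = "sample_id")
    chosen <- sample_per_group(joined, config$n_per_group, seed = config$seed)
    counts <- count_groups(chosen, truth = truth_col)
    concordance <- dplyr::bind_cols(tibble::tibble(stratum = "all"),
                                    build_confusion(counts))
    comparisons <- pooled_comparisons(counts)
  }
  if (!is.null(concordance)) {
    emit(concordance, "concordance.tsv")
    ranges <- metric_ranges(concordance[, confusion_metrics])
    emit(ranges, "ranges.tsv")
    emit(comparisons, "comparisons.tsv")
  }

  writeLines(log_lines, out_path("run_log.txt"))
  say("done; report bundle in ", output_dir)
  invisible(list(warehouse = warehouse, zscores = scored, funnel = funnel,
                 enrichment = enrichment, density = density, ihc = ihc,
                 concordance = concordance, ranges = ranges,
                 comparisons = comparisons))
}

# Pairwise high-vs-other exact comparisons from pooled per-group counts.
pooled_comparisons <- function(pooled) {
  g <- function(grp, col) {
    v <- pooled[[col]][as.character(pooled$rna_group) == grp]
    if (length(v) == 0) 0L else v
  }
  tibble::tibble(
    comparison = c("high_vs_low", "high_vs_medium"),
    p = c(compare_groups(g("high", "n_positive"), g("high", "n_screened"),
                         g("low", "n_positive"), g("low", "n_screened")),
          compare_groups(g("high", "n_positive"), g("high", "n_screened"),
                         g("medium", "n_positive"), g("medium", "n_screened"))))
}
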