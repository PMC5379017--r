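#' Configure a synthetic warehouse simulation
#'
#' Builds and validates the parameter set for [simulate_warehouse()].  The
#' defaults reproduce the statistical structure of the screening cohort the
#' package emulates: the tissue mixture and per-tissue log2-expression
#' normals come from [cd30_tissue_summary()], the per-stage eligibility
#' retention probabilities from the stage ratios of [cd30_funnel_counts()],
#' and the RNA-group-conditional protein-positivity rates from the pooled
#' counts of [cd30_screen_counts()] (0/39 low, 1/39 medium, 12/39 high).
#'
#' Because global Z-scores are invariant to a common location/scale change of
#' the log2 values, the per-tissue means and SDs are used on the Z scale
#' directly; only their relative positions matter downstream.
#'
#' @param n_patients number of consented patients to simulate.  Defaults to
#'   the size of the emulated warehouse (120,887).
#' @param tissue_mix named numeric vector of tissue proportions; must sum
#'   to 1 (within 1e-9).
#' @param tissue_expr_params data frame with columns `tissue_type`, `mean`,
#'   `sd` giving the per-tissue normal on the log2 expression scale; every
#'   tissue in `tissue_mix` must appear and every `sd` must be positive.
#' @param funnel_rates named numeric vector of per-stage retention
#'   probabilities, in funnel order: `active_consent`, `alive`,
#'   `ffpe_available`, `expression_available`.  All in \[0, 1\].
#' @param ihc_positivity_by_group named numeric vector of
#'   protein-positivity probabilities for the `low`, `medium` and `high`
#'   RNA groups.  All in \[0, 1\].
#' @param prop_metastatic probability that a simulated sample is from
#'   metastatic rather than primary disease.
#' @param seed integer seed; the warehouse is drawn from a single RNG stream
#'   seeded with this value, so equal configs give bit-identical warehouses.
#' @return A validated list of class `"simulation_config"`.
#' @examples
#' cfg <- simulation_config(n_patients = 500, seed = 1)
#' wh <- simulate_warehouse(cfg)
#' nrow(wh$patients)
#' @export
simulation_config <- function(n_patients = 120887,
                              tissue_mix = NULL,
                              tissue_expr_params = NULL,
                              funnel_rates = NULL,
                              ihc_positivity_by_group =
                                c(low = 0, medium = 1 / 39, high = 12 / 39),
                              prop_metastatic = 0.2,
                              seed = 1L) {
  ref <- cd30_tissue_summary()
  if (is.null(tissue_mix)) {
    tissue_mix <- stats::setNames(ref$n / sum(ref$n), ref$tissue_type)
  }
  if (is.null(tissue_expr_params)) {
    tissue_expr_params <- tibble::tibble(
      tissue_type = ref$tissue_type, mean = ref$mean_z, sd = ref$sd_z)
  }
  if (is.null(funnel_rates)) {
    fc <- cd30_funnel_counts()$n
    funnel_rates <- c(
      active_consent       = fc[2] / fc[1],
      alive                = fc[3] / fc[2],
      ffpe_available       = fc[4] / fc[3],
      expression_available = fc[5] / fc[4])
  }
  cfg <- structure(
    list(n_patients = n_patients,
         tissue_mix = tissue_mix,
         tissue_expr_params = tibble::as_tibble(tissue_expr_params),
         funnel_rates = funnel_rates,
         ihc_positivity_by_group = ihc_positivity_by_group,
         prop_metastatic = prop_metastatic,
         seed = as.integer(seed)),
    class = "simulation_config")
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is_scalar_number(cfg$n_patients) || cfg$n_patients <= 0) {
    stop("`n_patients` must be a positive number", call. = FALSE)
  }
  if (abs(sum(cfg$tissue_mix) - 1) > 1e-9) {
    stop("`tissue_mix` proportions must sum to 1", call. = FALSE)
  }
  check_columns(cfg$tissue_expr_params, c("tissue_type", "mean", "sd"),
                "tissue_expr_params")
  missing <- setdiff(names(cfg$tissue_mix), cfg$tissue_expr_params$tissue_type)
  if (length(missing) > 0) {
    stop("tissue(s) in `tissue_mix` without expression parameters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(cfg$tissue_expr_params$sd <= 0)) {
    stop("all per-tissue `sd` must be > 0", call. = FALSE)
  }
  if (!is_probability(cfg$funnel_rates)) {
    stop("`funnel_rates` must all lie in [0, 1]", call. = FALSE)
  }
  groups <- c("low", "medium", "high")
  if (!all(groups %in% names(cfg$ihc_positivity_by_group)) ||
      !is_probability(cfg$ihc_positivity_by_group[groups])) {
    stop("`ihc_positivity_by_group` must give probabilities in [0, 1] for ",
         "groups low, medium, high", call. = FALSE)
  }
  if (!is_probability(cfg$prop_metastatic)) {
    stop("`prop_metastatic` must lie in [0, 1]", call. = FALSE)
  }
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat("  patients:            ", x$n_patients, "\n")
  cat("  tissues:             ", length(x$tissue_mix), "\n")
  cat("  funnel retention:    ",
      paste(sprintf("%s=%.3f", names(x$funnel_rates), x$funnel_rates),
            collapse = ", "), "\n")
  cat("  IHC positivity:      ",
      paste(sprintf("%s=%.3f", names(x$ihc_positivity_by_group),
                    x$ihc_positivity_by_group), collapse = ", "), "\n")
  cat("  seed:                ", x$seed, "\n")
  invisible(x)
}
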