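#' Simulate a synthetic clinical-genomic warehouse
#'
#' Draws a complete synthetic warehouse from a [simulation_config()]: one
#' patient record per consented subject (eligibility booleans drawn
#' independently with the configured per-stage retention probabilities), one
#' expression record per patient (log2 expression from the patient tissue's
#' normal distribution), a latent protein-positivity flag per sample
#' (Bernoulli with the configured probability for the sample's RNA group,
#' where groups come from trichotomizing the warehouse-wide global Z-score),
#' and a staining profile per sample consistent with that latent flag via
#' [simulate_staining()].
#'
#' All randomness comes from a single RNG stream seeded with `config$seed`,
#' so identical configs yield bit-identical warehouses.
#'
#' @param config a [simulation_config()].
#' @return An object of class `"warehouse"`: a list of tibbles
#'   \describe{
#'     \item{patients}{`patient_id`, `consent_active`, `alive`, `has_ffpe`,
#'       `has_expression`, `tissue_type`, `disease_setting`}
#'     \item{expression}{`sample_id`, `patient_id`, `tissue_type`,
#'       `log2_expression`}
#'     \item{truth}{`sample_id`, `z`, `rna_group`, `ihc_positive` — the
#'       latent protein status used to generate staining}
#'     \item{staining}{`sample_id`, `pct_0`, `pct_1`, `pct_2`, `pct_3`}
#'   }
#' @examples
#' wh <- simulate_warehouse(simulation_config(n_patients = 200, seed = 42))
#' dplyr::count(wh$truth, rna_group, ihc_positive)
#' @export
simulate_warehouse <- function(config) {
  config <- validate_simulation_config(config)
  n <- config$n_patients
  withr::with_seed(config$seed, {
    id_width <- max(6L, nchar(as.character(n)))
    patient_id <- sprintf("P%0*d", id_width, seq_len(n))
    tissue <- sample(names(config$tissue_mix), n, replace = TRUE,
                     prob = config$tissue_mix)
    r <- config$funnel_rates
    patients <- tibble::tibble(
      patient_id = patient_id,
      consent_active = stats::runif(n) < r[["active_consent"]],
      alive = stats::runif(n) < r[["alive"]],
      has_ffpe = stats::runif(n) < r[["ffpe_available"]],
      has_expression = stats::runif(n) < r[["expression_available"]],
      tissue_type = tissue,
      disease_setting = ifelse(stats::runif(n) < config$prop_metastatic,
                               "metastatic", "primary"))

    pars <- config$tissue_expr_params
    mu <- stats::setNames(pars$mean, pars$tissue_type)[tissue]
    sigma <- stats::setNames(pars$sd, pars$tissue_type)[tissue]
    expression <- tibble::tibble(
      sample_id = sprintf("S%0*d", id_width, seq_len(n)),
      patient_id = patient_id,
      tissue_type = tissue,
      log2_expression = stats::rnorm(n, mu, sigma))

    # Latent protein truth keyed on the RNA group each sample lands in under
    # warehouse-wide standardization -- the same trichotomy the scorer applies.
    z <- global_z(expression$log2_expression)
    grp <- categorize_z(z)
    pi_grp <- config$ihc_positivity_by_group[as.character(grp)]
    truth <- tibble::tibble(
      sample_id = expression$sample_id,
      z = z,
      rna_group = grp,
      ihc_positive = stats::runif(n) < unname(pi_grp))

    staining <- simulate_staining(truth$ihc_positive)
    staining$sample_id <- truth$sample_id
    staining <- staining[, c("sample_id", "pct_0", "pct_1", "pct_2", "pct_3")]
  })
  structure(list(patients = patients, expression = expression,
                 truth = truth, staining = staining, config = config),
            class = "warehouse")
}

#' @export
print.warehouse <- function(x, ...) {
  cat("<warehouse> ", nrow(x$patients), " patients, ",
      nrow(x$expression), " expression records, ",
      sum(x$truth$ihc_positive), " latent protein-positive samples\n",
      sep = "")
  invisible(x)
}

#' Simulate IHC staining profiles consistent with positivity flags
#'
#' Inverse model of the H-score positivity rules: generates, for each latent
#' protein status, a per-intensity staining profile (percent of cells at
#' intensities 0 through 3+) that the scorer will call the same way.
#'
#' A positive sample draws its stained fraction `s` uniformly on
#' \[10, 100\]; since the H-score is at least the stained fraction, both the
#' at-least-10\%-stained rule and the H-score >= 10 rule then hold.  A
#' negative sample first draws random intensity proportions with mean
#' per-cell intensity `m` (between 1 and 3), then draws `s` uniformly on
#' \[0, 10 / m\), so that both the stained fraction (`s < 10`) and the
#' H-score (`s * m < 10`) fall below threshold.  The round trip through
#' [score_ihc()] therefore reproduces the input flags exactly.
#'
#' @param is_positive logical vector of latent protein-positivity flags.
#' @return A tibble with one row per flag and columns `pct_0`, `pct_1`,
#'   `pct_2`, `pct_3` summing to 100.
#' @examples
#' withr::with_seed(1, {
#'   prof <- simulate_staining(c(TRUE, FALSE))
#'   h_score(prof$pct_0, prof$pct_1, prof$pct_2, prof$pct_3)
#' })
#' @export
simulate_staining <- function(is_positive) {
  stopifnot(is.logical(is_positive), !anyNA(is_positive))
  n <- length(is_positive)
  # Random proportions of stained cells across intensities 1+, 2+, 3+.
  w <- matrix(stats::rexp(3 * n), ncol = 3)
  w <- w / rowSums(w)
  m <- drop(w %*% c(1, 2, 3))  # mean intensity among stained cells, in [1, 3]
  s <- ifelse(is_positive,
              stats::runif(n, 10, 100),
              stats::runif(n, 0, 10 / m))
  tibble::tibble(
    pct_0 = 100 - s,
    pct_1 = s * w[, 1],
    pct_2 = s * w[, 2],
    pct_3 = s * w[, 3])
}
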