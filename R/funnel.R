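#' Apply the cohort-eligibility funnel
#'
#' Runs the ordered eligibility filters over a patient table and reports
#' attrition: all consented patients, then (cumulatively) those with an
#' active consent, alive, with FFPE tissue available, with an expression
#' profile, and finally those whose global Z-score meets the biomarker
#' threshold.  Each stage filters the survivors of the previous one, so the
#' counts are monotonically non-increasing.
#'
#' @param patients data frame of patient records with logical columns
#'   `consent_active`, `alive`, `has_ffpe`, `has_expression` and a
#'   `patient_id` column.
#' @param zscores data frame with `patient_id` and `z` columns — typically
#'   [add_z_scores()] output joined back to patients.  Every patient with
#'   `has_expression = TRUE` must appear here.  May carry Z-scores
#'   standardized over the full warehouse or recomputed within the funnel
#'   survivors; the funnel uses whichever table it is given.
#' @param z_threshold biomarker-high cut applied at the final stage
#'   (default 1).
#' @return A `funnel_report`: a tibble with columns `stage` and
#'   `n_remaining`, carrying the surviving patient identifiers in
#'   `attr(, "final_ids")`.
#' @examples
#' wh <- simulate_warehouse(simulation_config(n_patients = 500, seed = 7))
#' zs <- add_z_scores(wh$expression)[, c("patient_id", "z")]
#' apply_funnel(wh$patients, zs)
#' @export
apply_funnel <- function(patients, zscores, z_threshold = 1) {
  check_columns(patients,
                c("patient_id", "consent_active", "alive", "has_ffpe",
                  "has_expression"), "patients")
  check_columns(zscores, c("patient_id", "z"), "zscores")
  needs_z <- patients$patient_id[patients$has_expression]
  missing_z <- setdiff(needs_z, zscores$patient_id)
  if (length(missing_z) > 0) {
    stop(length(missing_z), " patient(s) with expression have no Z-score ",
         "assignment (first: ", missing_z[1], ")", call. = FALSE)
  }

  cur <- tibble::as_tibble(patients)
  stages <- list(
    consented            = function(p) p,
    active_consent       = function(p) p[p$consent_active, , drop = FALSE],
    alive                = function(p) p[p$alive, , drop = FALSE],
    ffpe_available       = function(p) p[p$has_ffpe, , drop = FALSE],
    expression_available = function(p) p[p$has_expression, , drop = FALSE],
    z_above_threshold    = function(p) {
      z <- zscores$z[match(p$patient_id, zscores$patient_id)]
      p[!is.na(z) & z >= z_threshold, , drop = FALSE]
    })
  n_remaining <- integer(length(stages))
  for (i in seq_along(stages)) {
    cur <- stages[[i]](cur)
    n_remaining[i] <- nrow(cur)
  }
  out <- tibble::tibble(stage = names(stages), n_remaining = n_remaining)
  attr(out, "final_ids") <- cur$patient_id
  attr(out, "z_threshold") <- z_threshold
  class(out) <- c("funnel_report", class(out))
  out
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report> (z threshold ", attr(x, "z_threshold"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$retained <- sprintf("%.1f%%", 100 * df$n_remaining / df$n_remaining[1])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tidy a funnel report
#'
#' @param x a `funnel_report` from [apply_funnel()].
#' @param ... unused.
#' @return A tibble with `stage`, `n_remaining`, `prop_of_start` (fraction of
#'   the initial cohort) and `retention` (fraction of the previous stage).
#' @method tidy funnel_report
#' @export
tidy.funnel_report <- function(x, ...) {
  n <- x$n_remaining
  tibble::tibble(
    stage = x$stage,
    n_remaining = n,
    prop_of_start = if (n[1] > 0) n / n[1] else rep(NA_real_, length(n)),
    retention = c(NA_real_, ifelse(utils::head(n, -1) > 0,
                                   n[-1] / utils::head(n, -1), NA_real_)))
}

#' Glance at a funnel report
#'
#' @param x a `funnel_report` from [apply_funnel()].
#' @param ... unused.
#' @return A one-row tibble with `n_start`, `n_final` and `overall_yield`.
#' @method glance funnel_report
#' @export
glance.funnel_report <- function(x, ...) {
  n <- x$n_remaining
  tibble::tibble(
    n_start = n[1],
    n_final = n[length(n)],
    overall_yield = if (n[1] > 0) n[length(n)] / n[1] else NA_real_)
}

#' Surviving patient identifiers of a funnel report
#'
#' @param report a `funnel_report`.
#' @return Character vector of patient identifiers surviving every stage.
#' @export
funnel_candidates <- function(report) {
  stopifnot(inherits(report, "funnel_report"))
  attr(report, "final_ids")
}
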