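#' Scale raw intensities to a trimmed mean and log2 transform
#'
#' Multiplies a vector of raw (non-negative) probe intensities by a single
#' factor chosen so that its trimmed mean — excluding the lowest and highest
#' `trim_fraction` of sorted values — equals `target_trimmed_mean`, then
#' returns log2 of the scaled values.  This is the standard post-summarization
#' array scaling (trimmed mean of 500, log2) that the downstream Z-scores
#' assume.
#'
#' Scaled values below 1 are floored at 1 before the log2, so zeros map to 0
#' rather than -Inf; this affects only degenerate inputs.
#'
#' @param raw_intensities non-negative numeric vector of probe intensities.
#' @param target_trimmed_mean target for the trimmed mean after scaling
#'   (default 500).
#' @param trim_fraction fraction trimmed from each tail (default 0.02).
#' @return Numeric vector of log2-scaled intensities, same length as input.
#' @examples
#' scale_and_log(c(100, 100, 100, 100))  # log2(500) each
#' @export
scale_and_log <- function(raw_intensities, target_trimmed_mean = 500,
                          trim_fraction = 0.02) {
  x <- raw_intensities
  if (length(x) == 0) stop("`raw_intensities` must be nonempty", call. = FALSE)
  if (anyNA(x) || any(x < 0)) {
    stop("`raw_intensities` must be non-negative and non-missing",
         call. = FALSE)
  }
  tm <- mean(x, trim = trim_fraction)
  if (tm <= 0) {
    stop("trimmed mean of `raw_intensities` is not positive; ",
         "scale factor undefined", call. = FALSE)
  }
  scaled <- x * (target_trimmed_mean / tm)
  log2(pmax(scaled, 1))
}

#' Global Z-score of log2 expression values
#'
#' Standardizes a vector against its own mean and sample (n - 1) standard
#' deviation.  Applied to the log2 expression of an entire multi-tissue
#' warehouse this yields the "global" Z-score used to compare one sample's
#' target-gene expression to the whole collection, deliberately not
#' re-standardized within tissues.
#'
#' @param log2_values numeric vector, length >= 2, with positive spread.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @examples
#' global_z(c(1, 2, 3))  # -1 0 1
#' @export
global_z <- function(log2_values) {
  x <- log2_values
  if (length(x) < 2 || anyNA(x) || any(!is.finite(x))) {
    stop("`log2_values` must be >= 2 finite values", call. = FALSE)
  }
  s <- stats::sd(x)
  if (s == 0) stop("`log2_values` has zero variance", call. = FALSE)
  (x - mean(x)) / s
}

#' Trichotomize Z-scores into RNA expression groups
#'
#' Assigns each Z-score to the low (Z <= `low`), medium (`low` < Z < `high`)
#' or high (Z >= `high`) RNA group.  Both cut points belong to the outer
#' groups, so exactly -1 is low and exactly +1 is high at the defaults.
#'
#' @param z finite numeric vector of Z-scores.
#' @param low,high group boundaries (defaults -1 and +1).
#' @return Factor with levels `low`, `medium`, `high`.
#' @examples
#' categorize_z(c(-1, -0.999, 0.999, 1))
#' @export
categorize_z <- function(z, low = -1, high = 1) {
  if (anyNA(z) || any(!is.finite(z))) {
    stop("`z` must be finite and non-missing", call. = FALSE)
  }
  stopifnot(low < high)
  out <- rep("medium", length(z))
  out[z <= low] <- "low"
  out[z >= high] <- "high"
  factor(out, levels = c("low", "medium", "high"))
}

#' Add global Z-scores and RNA groups to an expression table
#'
#' Tidy wrapper over [global_z()] and [categorize_z()]: takes a per-sample
#' expression table and returns it with `z` and `rna_group` columns appended.
#' The Z-score is computed globally over every row supplied — pass the whole
#' warehouse for warehouse-wide standardization, or a survivor subset to
#' re-standardize within that subset.
#'
#' The optional `reference` argument selects which rows define the
#' standardization: with `reference = NULL` (the default) the mean and SD
#' come from all rows ("global" scope); passing a logical vector restricts
#' them to a subset (e.g. eligibility-funnel survivors) while still scoring
#' every row against that subset's mean and SD.
#'
#' @param expression data frame with a `log2_expression` column (typically
#'   also `sample_id`, `patient_id`, `tissue_type`).
#' @param z_low,z_high trichotomization cut points (defaults -1, +1).
#' @param reference optional logical vector (length `nrow(expression)`)
#'   marking the rows whose mean/SD define the standardization.
#' @return The input as a tibble with `z` and `rna_group` columns added.
#' @examples
#' wh <- simulate_warehouse(simulation_config(n_patients = 100, seed = 1))
#' scored <- add_z_scores(wh$expression)
#' table(scored$rna_group)
#' @export
add_z_scores <- function(expression, z_low = -1, z_high = 1,
                         reference = NULL) {
  check_columns(expression, "log2_expression", "expression")
  out <- tibble::as_tibble(expression)
  if (is.null(reference)) {
    out$z <- global_z(out$log2_expression)
  } else {
    stopifnot(is.logical(reference), length(reference) == nrow(out))
    ref <- out$log2_expression[reference]
    if (length(ref) < 2 || stats::sd(ref) == 0) {
      stop("`reference` subset must contain >= 2 values with spread",
           call. = FALSE)
    }
    out$z <- (out$log2_expression - mean(ref)) / stats::sd(ref)
  }
  out$rna_group <- categorize_z(out$z, low = z_low, high = z_high)
  out
}
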