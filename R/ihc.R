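#' Composite H-score of an IHC staining profile
#'
#' The H-score summarizes semiquantitative immunohistochemistry staining as
#' the sum over intensities 0-3+ of intensity times the percent of cells
#' stained at that intensity: `1*pct_1 + 2*pct_2 + 3*pct_3`, ranging from 0
#' (no staining) to 300 (all cells at 3+).  `h / 100` is the mean per-cell
#' staining intensity.  Fractional percentages are allowed.
#'
#' All arguments are vectorized; the four percentages of each profile must
#' sum to 100 (within 1e-6).
#'
#' @param pct_0,pct_1,pct_2,pct_3 percent of cells at staining intensity 0,
#'   1+, 2+ and 3+ respectively, each in \[0, 100\].
#' @return Numeric vector of H-scores in \[0, 300\].
#' @examples
#' h_score(30, 20, 40, 10)  # 130: 70% of cells stained
#' @export
h_score <- function(pct_0, pct_1, pct_2, pct_3) {
  p <- cbind(pct_0, pct_1, pct_2, pct_3)
  if (anyNA(p) || any(p < 0) || any(p > 100)) {
    stop("staining percentages must lie in [0, 100]", call. = FALSE)
  }
  if (any(abs(rowSums(p) - 100) > 1e-6)) {
    stop("staining percentages must sum to 100 for every profile",
         call. = FALSE)
  }
  drop(p %*% c(0, 1, 2, 3))
}

#' Positivity by stained-cell fraction
#'
#' The trial-eligibility style call: a sample is positive when at least
#' `min_pct` percent of cells stain at any intensity above 0, i.e. when
#' `100 - pct_0 >= min_pct`.
#'
#' @param pct_0 percent of unstained cells, in \[0, 100\]; vectorized.
#' @param min_pct minimum stained percent (default 10).
#' @return Logical vector.
#' @examples
#' call_positive_fraction(c(91, 90))  # FALSE TRUE
#' @export
call_positive_fraction <- function(pct_0, min_pct = 10) {
  if (anyNA(pct_0) || any(pct_0 < 0) || any(pct_0 > 100)) {
    stop("`pct_0` must lie in [0, 100]", call. = FALSE)
  }
  (100 - pct_0) >= min_pct
}

#' Positivity by H-score
#'
#' The protein-expression-group call: a sample is protein positive when its
#' H-score is at least `min_h` (default 10) and protein negative otherwise.
#'
#' @param h numeric vector of H-scores in \[0, 300\].
#' @param min_h positivity threshold (default 10).
#' @return Logical vector.
#' @examples
#' call_positive_hscore(c(9.9, 10))  # FALSE TRUE
#' @export
call_positive_hscore <- function(h, min_h = 10) {
  if (anyNA(h) || any(h < 0) || any(h > 300)) {
    stop("`h` must lie in [0, 300]", call. = FALSE)
  }
  h >= min_h
}

#' Score a table of staining profiles
#'
#' Tidy wrapper applying [h_score()], [call_positive_fraction()] and
#' [call_positive_hscore()] to a per-sample staining table.
#'
#' @param staining data frame with columns `sample_id`, `pct_0`, `pct_1`,
#'   `pct_2`, `pct_3`.
#' @param min_pct stained-fraction threshold (default 10).
#' @param min_h H-score threshold (default 10).
#' @return A tibble with columns `sample_id`, `h_score`,
#'   `positive_by_fraction`, `positive_by_hscore`.
#' @examples
#' prof <- withr::with_seed(1, simulate_staining(c(TRUE, FALSE)))
#' prof$sample_id <- c("a", "b")
#' score_ihc(prof)
#' @export
score_ihc <- function(staining, min_pct = 10, min_h = 10) {
  check_columns(staining, c("sample_id", "pct_0", "pct_1", "pct_2", "pct_3"),
                "staining")
  h <- h_score(staining$pct_0, staining$pct_1, staining$pct_2, staining$pct_3)
  tibble::tibble(
    sample_id = staining$sample_id,
    h_score = h,
    positive_by_fraction = call_positive_fraction(staining$pct_0, min_pct),
    positive_by_hscore = call_positive_hscore(h, min_h))
}
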