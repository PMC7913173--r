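#' Substitute values below the limit of detection
#'
#' Replaces below-LOD measurements by `LOD / sqrt(2)`, the standard
#' single-value substitution for assay values too low to quantify. Entries to
#' replace are taken from the `below_lod` flag vector when supplied (the
#' assay's own censoring record); otherwise any value below `lod` is treated
#' as censored.
#'
#' @param values Nonnegative numeric vector of measured concentrations.
#' @param lod Positive limit of detection.
#' @param below_lod Optional logical vector flagging censored entries.
#' @return `values` with flagged entries replaced by `lod / sqrt(2)`; the
#'   number of substitutions is attached as `attr(, "n_imputed")`.
#' @examples
#' impute_below_lod(c(0.5, 3, 8), lod = 2)
#' @export
impute_below_lod <- function(values, lod, below_lod = NULL) {
  if (!is.numeric(lod) || length(lod) != 1 || lod <= 0)
    abort("`lod` must be a single positive number.")
  if (any(values < 0, na.rm = TRUE))
    abort("Negative measured values are not valid concentrations.")
  if (is.null(below_lod)) below_lod <- values < lod
  stopifnot(length(below_lod) == length(values))
  values[below_lod] <- lod / sqrt(2)
  attr(values, "n_imputed") <- sum(below_lod, na.rm = TRUE)
  values
}

#' Z-score standardization
#'
#' Centers to mean 0 and scales to sample SD 1 (n - 1 denominator).
#'
#' @param values Numeric vector with nonzero variance.
#' @return Standardized numeric vector.
#' @examples
#' zscore(c(1, 2, 3))
#' @export
zscore <- function(values) {
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    abort("Cannot z-score a constant (zero-variance) vector.")
  (values - mean(values)) / s
}

#' Preprocess exposure and outcome columns
#'
#' Applies the standard biomarker pipeline in a fixed, recorded order:
#' below-LOD substitution by LOD/sqrt(2), then natural-log transform of the
#' exposures, then optional z-scoring of exposures and/or outcome. The order
#' matters (log of the substituted value, z-score of the logged value), so it
#' is recorded in the returned object's `"preprocess_steps"` attribute as run
#' provenance.
#'
#' @param data Data frame.
#' @param exposures Character vector of exposure columns.
#' @param lod Named numeric vector of LODs (names matching exposure columns),
#'   or `NULL` to skip substitution. If `data` has `below_lod_<col>` flag
#'   columns they take precedence over thresholding at the LOD value.
#' @param log_transform Natural-log transform the exposures.
#' @param zscore_exposures Z-score each exposure after any log transform.
#' @param zscore_outcome Optional outcome column name to z-score.
#' @return The preprocessed tibble, with attributes `preprocess_steps` and
#'   `n_imputed` (named count of substitutions per exposure).
#' @export
bws_preprocess <- function(data, exposures, lod = NULL,
                           log_transform = TRUE, zscore_exposures = FALSE,
                           zscore_outcome = NULL) {
  stopifnot(is.data.frame(data), all(exposures %in% names(data)))
  out <- tibble::as_tibble(data)
  steps <- character(0)
  n_imputed <- stats::setNames(integer(length(exposures)), exposures)

  if (!is.null(lod)) {
    if (is.null(names(lod)) || !all(exposures %in% names(lod)))
      abort("`lod` must be a named vector covering every exposure column.")
    for (j in exposures) {
      flag_col <- paste0("below_lod_", j)
      flags <- if (flag_col %in% names(out)) out[[flag_col]] else NULL
      v <- impute_below_lod(out[[j]], lod[[j]], flags)
      n_imputed[[j]] <- attr(v, "n_imputed")
      out[[j]] <- as.numeric(v)
    }
    steps <- c(steps, "lod_substitution")
  }
  if (log_transform) {
    for (j in exposures) {
      if (any(out[[j]] <= 0))
        abort(sprintf("Column '%s' has non-positive values; cannot log.", j))
      out[[j]] <- log(out[[j]])
    }
    steps <- c(steps, "log_transform")
  }
  if (zscore_exposures) {
    for (j in exposures) out[[j]] <- zscore(out[[j]])
    steps <- c(steps, "zscore_exposures")
  }
  if (!is.null(zscore_outcome)) {
    out[[zscore_outcome]] <- zscore(out[[zscore_outcome]])
    steps <- c(steps, "zscore_outcome")
  }
  attr(out, "preprocess_steps") <- steps
  attr(out, "n_imputed") <- n_imputed
  out
}
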