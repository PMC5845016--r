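## Phosphosite occupancy (stoichiometry) from the phosphatase-reference
## SILAC design: dephosphorylating one channel folds the phosphorylated pool
## back into the unmodified peptide, so the unmodified-peptide ratio r
## (phosphatase-treated / untreated) relates to occupancy o by
## r = 1 / (1 - o), i.e. o = (1 - 1/r) x 100%.

#' Occupancy from an unmodified-peptide ratio
#'
#' Applies \code{(1 - 1/r) * 100} for \code{r >= 1}. Ratios below 1 would
#' imply negative occupancy (measurement noise); they are returned as
#' \code{NA} with \code{valid = FALSE} rather than clamped, so QC can count
#' them.
#'
#' @param ratio_r positive unmodified-peptide ratio(s),
#'   phosphatase-treated over untreated.
#' @return data.frame with \code{occupancy_pct} in [0, 100] (\code{NA} when
#'   flagged) and \code{valid}.
#' @export
occupancy_from_ratio <- function(ratio_r) {
  if (any(!is.na(ratio_r) & ratio_r <= 0))
    stopf("unmodified-peptide ratio must be > 0")
  valid <- !is.na(ratio_r) & ratio_r >= 1
  occ <- ifelse(valid, (1 - 1 / ratio_r) * 100, NA_real_)
  data.frame(occupancy_pct = occ, valid = valid)
}

#' Per-site occupancy across conditions
#'
#' @param occ data.frame with columns \code{site_id}, \code{condition},
#'   \code{ratio} (unmodified-peptide ratio). Rows with missing ratios are
#'   skipped with a warning.
#' @return the input with \code{occupancy_pct} and \code{valid} columns
#'   appended (missing-ratio rows dropped).
#' @export
compute_site_occupancy <- function(occ) {
  miss <- setdiff(c("site_id", "condition", "ratio"), names(occ))
  if (length(miss))
    stopf("occupancy table is missing column(s): %s", paste(miss, collapse = ", "))
  drop <- is.na(occ$ratio)
  if (any(drop)) {
    warnf("skipping %d site/condition row(s) with missing unmodified-peptide ratio",
          sum(drop))
    occ <- occ[!drop, , drop = FALSE]
  }
  cbind(occ, occupancy_from_ratio(occ$ratio))
}
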