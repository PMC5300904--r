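# Exactly specified normalisation arithmetic for the bench assays:
# relative qPCR expression (2^-dCt against a reference transcript),
# amiRNA knockdown efficiency, glucose-stimulated insulin secretion
# (GSIS) normalisation, and 3C contact normalisation.

#' Relative qPCR expression (2^-dCt) with a baseline
#'
#' rel = 2^-(ct_target - ct_reference); fold = rel / mean(rel over the
#' baseline rows). Baseline is either the control group (e.g.
#' non-targeting amiRNA) or the time-zero measurements of a decay
#' course. With two reference transcripts (e.g. TBP and histone H3 for
#' protein blots) supply `ct_reference2`; the mean of the two reference
#' Cts is used.
#'
#' @param measurements Data frame with `ct_target`, `ct_reference`,
#'   optional `ct_reference2`, `group` (and `timepoint` for decay data).
#' @param baseline "control_group" (rows with `group == control_label`)
#'   or "time_zero" (rows with `timepoint == 0`).
#' @param control_label Group label treated as baseline (default
#'   "control").
#' @param percent If TRUE, fold values are multiplied by 100 (decay
#'   courses reported as a percentage of time 0).
#' @return The input with added `rel` and `fold` columns.
#' @export
qpcr_relative_expression <- function(measurements,
                                     baseline = c("control_group", "time_zero"),
                                     control_label = "control",
                                     percent = FALSE) {
  baseline <- match.arg(baseline)
  m <- measurements
  if (any(!is.finite(m$ct_target)) || any(!is.finite(m$ct_reference)))
    stopf("Ct values must be finite")
  ct_ref <- if (!is.null(m$ct_reference2))
    (m$ct_reference + m$ct_reference2) / 2 else m$ct_reference
  m$rel <- 2^(-(m$ct_target - ct_ref))
  base_rows <- if (baseline == "control_group") m$group == control_label
               else m$timepoint == 0
  if (!any(base_rows)) stopf("empty baseline")
  m$fold <- m$rel / mean(m$rel[base_rows])
  if (percent) m$fold <- 100 * m$fold
  m
}

#' amiRNA knockdown efficiency
#'
#' Percent knockdown = 100 * (1 - fold_remaining); an amiRNA is
#' efficient when knockdown strictly exceeds 50%.
#'
#' @param fold_remaining Fraction of target transcript remaining
#'   (>= 0; vectorised).
#' @return Data frame with `fold_remaining`, `percent_knockdown`,
#'   `efficient`.
#' @export
amirna_efficiency <- function(fold_remaining) {
  if (any(!is.finite(fold_remaining)) || any(fold_remaining < 0))
    stopf("`fold_remaining` must be non-negative")
  pct <- 100 * (1 - fold_remaining)
  data.frame(fold_remaining = fold_remaining, percent_knockdown = pct,
             efficient = pct > 50)
}

#' Glucose-stimulated insulin secretion summary
#'
#' Secreted insulin and insulin content are normalised to cells per
#' well and expressed as fold over the mean of control wells at basal
#' glucose; the secretion index (secreted / content) is the
#' content-corrected secretion measure.
#'
#' @param measurements Data frame with `secreted_insulin`,
#'   `insulin_content`, `cells_per_well`, `glucose_mM`, `group`.
#' @param control_label Control group label (default "control").
#' @param basal_glucose Basal glucose in mM (default 2.8).
#' @return Input with added `secreted_per_cell`, `content_per_cell`,
#'   `fold_secreted`, `fold_content`, `secretion_index` columns.
#' @export
gsis_summary <- function(measurements, control_label = "control",
                         basal_glucose = 2.8) {
  m <- measurements
  if (any(m$cells_per_well <= 0)) stopf("zero or negative cells per well")
  if (any(m$insulin_content <= 0)) stopf("zero or negative insulin content")
  base <- m$group == control_label & m$glucose_mM == basal_glucose
  if (!any(base)) stopf("no control wells at basal glucose present")
  m$secreted_per_cell <- m$secreted_insulin / m$cells_per_well
  m$content_per_cell <- m$insulin_content / m$cells_per_well
  m$fold_secreted <- m$secreted_per_cell / mean(m$secreted_per_cell[base])
  m$fold_content <- m$content_per_cell / mean(m$content_per_cell[base])
  m$secretion_index <- m$secreted_insulin / m$insulin_content
  m
}

#' 3C contact normalisation
#'
#' Per-sample interaction = region signal / control-region signal (a
#' control region within the PDX1 intron in the assay this models);
#' reported values are each sample's interaction as a fraction of the
#' mean interaction of the control (non-targeting amiRNA) group, per
#' region.
#'
#' @param measurements Data frame with `region`, `region_signal`,
#'   `control_signal`, `group`.
#' @param control_label Control group label (default "control").
#' @return Input with added `interaction` and `normalized` columns.
#' @export
contact_normalization <- function(measurements, control_label = "control") {
  m <- measurements
  if (any(m$control_signal <= 0)) stopf("control-region signal must be positive")
  if (!any(m$group == control_label)) stopf("control sample group missing")
  m$interaction <- m$region_signal / m$control_signal
  m$normalized <- NA_real_
  for (rg in unique(m$region)) {
    rows <- m$region == rg
    ctrl <- rows & m$group == control_label
    if (!any(ctrl)) stopf("region '%s' lacks control samples", rg)
    m$normalized[rows] <- m$interaction[rows] / mean(m$interaction[ctrl])
  }
  m
}
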