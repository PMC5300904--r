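# Candidate-retention filters for de-novo lncRNA annotation: a candidate
# transcript must be expressed in sorted beta cells, not enriched in the
# exocrine fraction (acinar contaminant guard), and carry promoter-like
# H3K4me3 signal near its 5' end. Thresholds are configurable; the
# defaults are placeholders, not published values.

#' Filter lncRNA transcript candidates
#'
#' Applies the three retention rules in order; each rejected candidate
#' carries the first failing rule. Records missing the expression or
#' exocrine fields are rejected as incomplete; a missing H3K4me3
#' distance means no peak was found and fails the promoter rule.
#'
#' @param candidates Data frame with columns `id`, `beta_expression`
#'   (abundance in FACS-purified beta cells), `exocrine_ratio`
#'   (exocrine / islet abundance), `tss_h3k4me3_distance` (bp from the
#'   5' end to the nearest H3K4me3 peak; NA when absent). Extra columns
#'   are carried through.
#' @param min_beta_expr Minimum beta-cell abundance (default 0.5).
#' @param max_exocrine_ratio Maximum exocrine/islet ratio (default 1.0).
#' @param max_h3k4me3_distance Maximum promoter-mark distance in bp
#'   (default 2000).
#' @return List with `retained` and `rejected` data frames (input order
#'   preserved; `rejected` has a `reason` column) plus a `decision`
#'   data frame covering every input row.
#' @export
filter_candidates <- function(candidates, min_beta_expr = 0.5,
                              max_exocrine_ratio = 1.0,
                              max_h3k4me3_distance = 2000) {
  check_number(min_beta_expr, "min_beta_expr", min = 0, strict_min = TRUE)
  check_number(max_exocrine_ratio, "max_exocrine_ratio", min = 0,
               strict_min = TRUE)
  check_number(max_h3k4me3_distance, "max_h3k4me3_distance", min = 0,
               strict_min = TRUE)
  need <- c("id", "beta_expression", "exocrine_ratio", "tss_h3k4me3_distance")
  if (!all(need %in% names(candidates)))
    stopf("candidates must have columns: %s", paste(need, collapse = ", "))

  reason <- vapply(seq_len(nrow(candidates)), function(i) {
    x <- candidates[i, ]
    if (is.na(x$beta_expression) || is.na(x$exocrine_ratio))
      return("incomplete record")
    if (x$beta_expression < min_beta_expr)
      return("below beta-cell expression threshold")
    if (x$exocrine_ratio > max_exocrine_ratio)
      return("exocrine-enriched (possible acinar contaminant)")
    if (is.na(x$tss_h3k4me3_distance) ||
        x$tss_h3k4me3_distance > max_h3k4me3_distance)
      return("no H3K4me3 enrichment near the 5' end")
    ""
  }, character(1))

  keep <- reason == ""
  rejected <- candidates[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  decision <- data.frame(id = candidates$id, retained = keep,
                         reason = reason, stringsAsFactors = FALSE)
  list(retained = candidates[keep, , drop = FALSE],
       rejected = rejected, decision = decision)
}

#' Distance from candidate 5' ends to the nearest H3K4me3 peak
#'
#' Strand-aware: the 5' end is `start` on "+" and `end` on "-"
#' (0-based half-open). Distance is 0 when the TSS lies inside a peak.
#'
#' @param candidates Data frame with chrom, start, end, strand.
#' @param peaks Data frame of peak intervals with chrom, start, end.
#' @return Numeric vector of distances (NA when the chromosome has no
#'   peak), suitable for `tss_h3k4me3_distance`.
#' @export
h3k4me3_tss_distance <- function(candidates, peaks) {
  vapply(seq_len(nrow(candidates)), function(i) {
    x <- candidates[i, ]
    tss <- if (identical(x$strand, "-")) x$end else x$start
    pk <- peaks[peaks$chrom == x$chrom, , drop = FALSE]
    if (!nrow(pk)) return(NA_real_)
    d <- ifelse(tss < pk$start, pk$start - tss,
                ifelse(tss >= pk$end, tss - pk$end + 1, 0))
    min(d)
  }, numeric(1))
}
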