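# G4 peak refinement: the multi-step M/A filter and its canonical-motif
# enrichment readout.

#' M/A transform of paired ATAC and G4 signals
#'
#' `M = (log2(ATAC) + log2(G4Q)) / 2` is the average signal and
#' `A = (log2(G4Q) - log2(ATAC)) / 2` the half-difference. Values at or
#' below zero are replaced by the pseudocount before the logarithm.
#'
#' @param atac_norm,g4_norm non-negative normalized signals (vectorized).
#' @param pseudocount replacement for zeros (default 1e-4).
#' @return data frame with columns `M` and `A`.
#' @export
ma_transform <- function(atac_norm, g4_norm, pseudocount = 1e-4) {
  if (any(atac_norm < 0, na.rm = TRUE) || any(g4_norm < 0, na.rm = TRUE)) {
    stopf("negative signal values")
  }
  a <- ifelse(atac_norm <= 0, pseudocount, atac_norm)
  g <- ifelse(g4_norm <= 0, pseudocount, g4_norm)
  data.frame(M = (log2(a) + log2(g)) / 2, A = (log2(g) - log2(a)) / 2)
}

#' Multi-step refinement of G4 peaks
#'
#' Step 1 retains peaks with mean normalized signal strictly greater than
#' `signal_min` in both assays (`signal_pass`). Step 2 retains remaining
#' peaks with `M >= m_min` and `A >= a_min` (inclusive; `ma_pass`); all
#' others are `excluded`. Step 3 flags retained peaks with
#' `log2(G4Q + pseudocount) >= hc_log2_g4` as high confidence. By default
#' the high-confidence threshold applies to the union of the two retained
#' tiers; `hc_tiers = "ma_pass"` restricts it to step-2 survivors.
#'
#' @param peak_id peak identifiers.
#' @param atac_mean_norm,g4_mean_norm per-peak mean normalized signal; a
#'   missing (`NA`) value in either assay is an error naming the peak.
#' @param signal_min step-1 threshold (strict, default 0.5).
#' @param m_min,a_min step-2 thresholds (inclusive, defaults 1.0 and 0.25).
#' @param hc_log2_g4 step-3 log2 G4 threshold (default 3.0).
#' @param pseudocount pseudocount for logs of zero.
#' @param hc_tiers tiers eligible for the high-confidence flag.
#' @return data frame `peak_id`, `atac_mean_norm`, `g4_mean_norm`, `M`, `A`,
#'   `tier`, `high_confidence`.
#' @export
refine_g4_peaks <- function(peak_id, atac_mean_norm, g4_mean_norm,
                            signal_min = 0.5, m_min = 1.0, a_min = 0.25,
                            hc_log2_g4 = 3.0, pseudocount = 1e-4,
                            hc_tiers = c("any", "ma_pass")) {
  hc_tiers <- match.arg(hc_tiers)
  bad <- which(is.na(atac_mean_norm) | is.na(g4_mean_norm))
  if (length(bad)) {
    stopf("peak %s missing in one assay summary", peak_id[bad[1]])
  }
  ma <- ma_transform(atac_mean_norm, g4_mean_norm, pseudocount)
  tier <- ifelse(atac_mean_norm > signal_min & g4_mean_norm > signal_min,
                 "signal_pass",
                 ifelse(ma$M >= m_min & ma$A >= a_min, "ma_pass", "excluded"))
  eligible <- if (hc_tiers == "any") tier != "excluded" else tier == "ma_pass"
  hc <- eligible & log2(g4_mean_norm + pseudocount) >= hc_log2_g4
  data.frame(peak_id = peak_id, atac_mean_norm = atac_mean_norm,
             g4_mean_norm = g4_mean_norm, M = ma$M, A = ma$A, tier = tier,
             high_confidence = hc, stringsAsFactors = FALSE)
}

#' Canonical-motif enrichment of the refined peak set
#'
#' The ratio of the canonical-motif fraction among high-confidence refined
#' peaks to the fraction among the unfiltered peak universe.
#'
#' @param canonical logical vector over the unfiltered universe.
#' @param refined logical vector: membership in the refined set.
#' @return the enrichment fold (1 when refined equals the universe).
#' @export
motif_enrichment_fold <- function(canonical, refined) {
  stopifnot(length(canonical) == length(refined))
  if (!any(refined)) stopf("refined set is empty")
  base <- mean(canonical)
  if (base == 0) stopf("no canonical peaks in the unfiltered set")
  mean(canonical[refined]) / base
}
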