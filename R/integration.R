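# Integration module: conservative confidence-bound effect-size shrinkage,
# ATAC x G4 quadrant classification, FDR-threshold gain/loss counts, and
# top-peak selection with z-scoring.

#' Conservative shrinkage of a log2 fold-change
#'
#' The two-sided z equivalent of the differential p-value,
#' `z_obs = qnorm(1 - p/2)`, implies a standard error `|logfc| / z_obs`.
#' The shrunk estimate is the confidence bound of the `confidence`-level
#' interval nearest zero, clamped at zero when the interval contains zero:
#' `shrunk = sign(logfc) * |logfc| * max(0, 1 - z_c / z_obs)` with
#' `z_c = qnorm((1 + confidence) / 2)`. Normal (not t) quantiles are used on
#' both sides; p-values of exactly 1 (or a zero effect) shrink to 0, and
#' p-values numerically 0 are floored at 1e-300.
#'
#' @param logfc log2 fold-changes (vectorized).
#' @param p_value two-sided p-values in `(0, 1]`.
#' @param confidence confidence level in `(0, 1)` (default 0.70).
#' @return data frame `raw_logfc`, `p_value`, `z_obs`, `implied_se`,
#'   `shrunk_logfc`.
#' @export
shrink_effect <- function(logfc, p_value, confidence = 0.70) {
  if (any(!is.finite(logfc))) stopf("non-finite logfc")
  if (any(p_value <= 0 | p_value > 1)) stopf("p-values must be in (0, 1]")
  if (confidence <= 0 || confidence >= 1) stopf("confidence must be in (0, 1)")
  p <- pmax(p_value, 1e-300)
  z_obs <- qnorm(p / 2, lower.tail = FALSE)
  z_c <- qnorm((1 + confidence) / 2)
  keep <- pmax(0, 1 - z_c / z_obs)     # z_obs = 0 -> -Inf -> clamp to 0
  keep[z_obs == 0] <- 0
  shrunk <- sign(logfc) * abs(logfc) * keep
  implied_se <- ifelse(z_obs > 0, abs(logfc) / z_obs, NA_real_)
  data.frame(raw_logfc = logfc, p_value = p_value, z_obs = z_obs,
             implied_se = implied_se, shrunk_logfc = shrunk)
}

#' Joint ATAC x G4 quadrant classification
#'
#' Each modality is called gain when its shrunk log2 effect strictly exceeds
#' `threshold`, loss when strictly below `-threshold`, and neutral otherwise
#' (a value exactly at the threshold is neutral). The compound label follows
#' the style `"<prefix>ATAC Gain | <prefix>G4 Loss"`.
#'
#' @param shrunk_atac,shrunk_g4 shrunk log2 effects (vectorized).
#' @param threshold positive log2 threshold (0.25 for knockdown contrasts,
#'   0.05 for age-associated analyses).
#' @param label_prefix prefix for the compound label, e.g. `"Age "`.
#' @return data frame `atac_state`, `g4_state`, `label`.
#' @export
classify_quadrant <- function(shrunk_atac, shrunk_g4, threshold = 0.05,
                              label_prefix = "") {
  if (threshold <= 0) stopf("threshold must be positive")
  state <- function(x) ifelse(x > threshold, "gain",
                              ifelse(x < -threshold, "loss", "neutral"))
  a <- state(shrunk_atac)
  g <- state(shrunk_g4)
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  data.frame(atac_state = a, g4_state = g,
             label = sprintf("%sATAC %s | %sG4 %s", label_prefix, cap(a),
                             label_prefix, cap(g)),
             stringsAsFactors = FALSE)
}

#' Gain/loss counts across FDR cutoffs
#'
#' For each cutoff, the number of peaks with `fdr <= cutoff`, split by the
#' sign of the effect; zero effects count in neither direction. Counts are
#' monotone non-increasing as the cutoff tightens.
#'
#' @param fdr BH-adjusted p-values.
#' @param logfc effect sizes giving the direction.
#' @param cutoffs FDR cutoffs (default 0.1, 0.05, 0.01, 0.005, 0.001).
#' @return data frame `cutoff`, `gain`, `loss`.
#' @export
count_by_fdr <- function(fdr, logfc,
                         cutoffs = c(0.1, 0.05, 0.01, 0.005, 0.001)) {
  data.frame(
    cutoff = cutoffs,
    gain = vapply(cutoffs, function(ct) sum(fdr <= ct & logfc > 0), 0L),
    loss = vapply(cutoffs, function(ct) sum(fdr <= ct & logfc < 0), 0L)
  )
}

#' Select top differential peaks and z-score across samples
#'
#' Keeps rows with `fdr <= fdr_max` and scales each surviving row to mean 0
#' and unit SD across samples (the representation behind the clustered
#' heat maps). Constant rows are dropped with a warning; when no peak passes,
#' an empty matrix is returned with a warning.
#'
#' @param mat peaks x samples matrix.
#' @param fdr per-peak FDR aligned with the rows of `mat`.
#' @param fdr_max selection threshold (default 0.10).
#' @return the z-scored submatrix.
#' @export
select_top_and_zscore <- function(mat, fdr, fdr_max = 0.10) {
  mat <- as.matrix(mat)
  stopifnot(length(fdr) == nrow(mat))
  keep <- which(fdr <= fdr_max)
  if (!length(keep)) {
    warnf("no peak passes fdr <= %g", fdr_max)
    return(mat[integer(0), , drop = FALSE])
  }
  sub <- mat[keep, , drop = FALSE]
  sds <- apply(sub, 1L, sd)
  if (any(sds == 0)) {
    warnf("dropping %d constant rows", sum(sds == 0))
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (sub - rowMeans(sub)) / sds
}
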