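# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Convert 0-based half-open intervals to a GRanges object
#'
#' All coordinates in this package are 0-based half-open (BED convention);
#' GRanges is 1-based inclusive, so start shifts by +1.
#' @noRd
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
}

# deterministic seed derivation for sub-tasks; keeps values < 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}
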