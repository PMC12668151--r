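#' Read a genome FASTA into a sequence accessor
#'
#' @param path FASTA file.
#' @return A `DNAStringSet` named by chromosome (description text after the
#'   first whitespace is stripped).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a genome FASTA
#' @param genome a `DNAStringSet`.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome
#' @param genome a `DNAStringSet`.
#' @return named integer vector of lengths.
#' @export
chrom_sizes <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Fetch an uppercased subsequence by 0-based half-open range
#'
#' Out-of-range requests are clipped to the chromosome bounds; a fully
#' out-of-range request returns the empty string.
#'
#' @param genome a `DNAStringSet`.
#' @param chrom chromosome name; unknown names are an error.
#' @param start,end 0-based half-open coordinates.
#' @return A character string of `min(end, len) - max(start, 0)` bases.
#' @export
genome_fetch <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stopf("unknown chromosome: %s", chrom)
  len <- length(genome[[chrom]])
  s <- max(0L, as.integer(start))
  e <- min(len, as.integer(end))
  if (e <= s) return("")
  toupper(as.character(Biostrings::subseq(genome[[chrom]], s + 1L, e)))
}
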