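# Coverage module: cutsite processing, background-anchored trimmed-mean
# normalization, per-peak coverage summaries, blacklist/chromosome filters,
# moderate-abundance presence calls, and exact-subset intersection counts.

#' Convert fragments to fixed-width cutsite intervals
#'
#' Each fragment yields two intervals of width `width` centered at its start
#' and at its end coordinate (the two transposition events), clipped to
#' chromosome bounds. Intervals clipped to empty are removed.
#'
#' @param fragments data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param width cutsite width in bp; must be even and >= 2.
#' @param chrom_lengths optional named vector for right-side clipping.
#' @return data frame of cutsite intervals, two per fragment (start cutsite
#'   then end cutsite), before removal of empty intervals.
#' @export
fragments_to_cutsites <- function(fragments, width = 50L,
                                  chrom_lengths = NULL) {
  width <- as.integer(width)
  if (width < 2L || width %% 2L != 0L) stopf("width must be even and >= 2")
  half <- width %/% 2L
  n <- nrow(fragments)
  idx <- rep(seq_len(n), each = 2L)
  cen <- as.vector(rbind(fragments$start, fragments$end))
  out <- data.frame(chrom = fragments$chrom[idx],
                    start = cen - half, end = cen + half,
                    stringsAsFactors = FALSE)
  out$start <- pmax(0L, out$start)
  if (!is.null(chrom_lengths)) {
    out$end <- pmin(as.integer(chrom_lengths[out$chrom]), out$end)
  }
  out[out$end > out$start, , drop = FALSE]
}

#' Sample background (non-peak) regions
#'
#' Draws `n` intervals of length `length` uniformly over peak-free space;
#' regions may overlap each other but never a peak. Deterministic given
#' `seed`.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param peaks a [peak_set()] (or any data frame of intervals) to avoid.
#' @param n number of regions.
#' @param length region length in bp (default 1000).
#' @param seed integer seed.
#' @return data frame of background intervals.
#' @export
sample_background_regions <- function(chrom_lengths, peaks, n = 5000L,
                                      length = 1000L, seed = 1L) {
  set.seed(seed)
  chroms <- names(chrom_lengths)
  usable <- chrom_lengths[chrom_lengths > length]
  if (!length(usable)) stopf("no chromosome longer than the region length")
  pk_gr <- if (nrow(peaks)) as_granges0(peaks$chrom, peaks$start, peaks$end)
           else NULL
  got_chrom <- character(0); got_start <- integer(0)
  attempts <- 0L
  max_attempts <- 50L * n
  while (length(got_start) < n) {
    todo <- n - length(got_start)
    attempts <- attempts + todo
    if (attempts > max_attempts) {
      stopf("could not place %d peak-free regions (placed %d)", n,
            length(got_start))
    }
    chrom <- sample(names(usable), todo, replace = TRUE,
                    prob = as.numeric(usable))
    start <- vapply(usable[chrom] - length, function(m) sample.int(m, 1L) - 1L, 0L)
    cand <- data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(start + length))
    if (!is.null(pk_gr)) {
      hit <- GenomicRanges::countOverlaps(
        as_granges0(cand$chrom, cand$start, cand$end), pk_gr) > 0L
      cand <- cand[!hit, , drop = FALSE]
    }
    got_chrom <- c(got_chrom, cand$chrom)
    got_start <- c(got_start, cand$start)
  }
  data.frame(chrom = got_chrom[seq_len(n)], start = got_start[seq_len(n)],
             end = got_start[seq_len(n)] + length, stringsAsFactors = FALSE)
}

#' Symmetric trimmed mean
#'
#' Sorts the values, removes `floor(n * trim)` from each tail, and averages
#' the remainder (the common statistical definition).
#'
#' @param values non-negative numeric vector.
#' @param trim fraction trimmed from each tail, in `[0, 0.5)`.
#' @return the trimmed mean.
#' @export
trimmed_mean <- function(values, trim = 0.20) {
  if (!length(values)) stopf("empty input")
  if (trim < 0 || trim >= 0.5) stopf("trim must be in [0, 0.5)")
  n <- length(values)
  k <- floor(n * trim)
  s <- sort(values)
  mean(s[(k + 1L):(n - k)])
}

#' Background-anchored normalization factor
#'
#' The factor is the reciprocal of the 20% trimmed-mean per-base coverage
#' over sampled non-peak regions; `norm_depth = max_depth * factor`.
#'
#' @param values per-base background coverage values for one sample.
#' @param trim trim fraction (default 0.20).
#' @return the normalization factor (> 0).
#' @export
compute_normalization <- function(values, trim = 0.20) {
  tm <- trimmed_mean(values, trim)
  if (tm <= 0) stopf("trimmed-mean background coverage is zero")
  1 / tm
}

#' Normalization factors for a background matrix
#' @param background values x samples matrix of background coverage.
#' @param trim trim fraction.
#' @return named vector of per-sample factors.
#' @export
normalization_factors <- function(background, trim = 0.20) {
  apply(background, 2L, compute_normalization, trim = trim)
}

#' Per-peak coverage summary from an interval track
#'
#' Computes per-base depth from the given intervals (cutsites or fragments)
#' and summarizes each peak: raw maximum depth, mean per-base depth, and
#' normalized depth `max_depth * factor`. Peaks on chromosomes without any
#' coverage are all-zero, not an error.
#'
#' @param peaks a [peak_set()].
#' @param intervals data frame of depth-contributing intervals (`chrom`,
#'   `start`, `end`, 0-based half-open).
#' @param factor normalization factor for this sample (default 1).
#' @return data frame `peak_id`, `max_depth`, `avg_depth`, `norm_depth`.
#' @export
summarize_peak_coverage <- function(peaks, intervals, factor = 1) {
  max_depth <- numeric(nrow(peaks))
  avg_depth <- numeric(nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == chrom)
    iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
    if (!nrow(iv)) next
    track_len <- max(peaks$end[pk], iv$end)
    cov <- IRanges::coverage(IRanges::IRanges(iv$start + 1L, iv$end),
                             width = track_len)
    v <- IRanges::Views(cov, start = peaks$start[pk] + 1L, end = peaks$end[pk])
    max_depth[pk] <- IRanges::viewMaxs(v)
    avg_depth[pk] <- IRanges::viewMeans(v)
  }
  data.frame(peak_id = peaks$peak_id, max_depth = max_depth,
             avg_depth = avg_depth, norm_depth = max_depth * factor,
             stringsAsFactors = FALSE)
}

#' Cross-replicate summary statistics of normalized depth
#'
#' Per peak: mean, SD, and log-space SD `exp(sd(log(1e-4 + norm_depth)))`
#' (undefined with a single replicate).
#'
#' @param norm_matrix peaks x samples matrix of normalized depth.
#' @return data frame `peak_id`, `mean_norm`, `sd_norm`, `logspace_sd`.
#' @export
coverage_replicate_stats <- function(norm_matrix) {
  m <- as.matrix(norm_matrix)
  data.frame(
    peak_id = rownames(m),
    mean_norm = rowMeans(m),
    sd_norm = apply(m, 1L, sd),
    logspace_sd = exp(apply(log(1e-4 + m), 1L, sd)),
    stringsAsFactors = FALSE
  )
}

#' Blacklist and chromosome filtering of peaks
#'
#' Removes any peak overlapping the blacklist by at least 1 bp and any peak
#' on a chromosome outside the allowed set (default autosomes plus chrX).
#'
#' @param peaks a [peak_set()].
#' @param blacklist optional data frame of intervals to exclude.
#' @param allowed_chroms allowed chromosome names.
#' @return the filtered [peak_set()].
#' @export
filter_peaks <- function(peaks, blacklist = NULL,
                         allowed_chroms = c(paste0("chr", 1:22), "chrX")) {
  keep <- peaks$chrom %in% allowed_chroms
  if (!is.null(blacklist) && nrow(blacklist)) {
    hit <- GenomicRanges::countOverlaps(
      as_granges0(peaks$chrom, peaks$start, peaks$end),
      as_granges0(blacklist$chrom, blacklist$start, blacklist$end)) > 0L
    keep <- keep & !hit
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(peaks)
  attr(out, "genome_id") <- attr(peaks, "genome_id")
  out
}

#' Moderate-abundance presence matrix
#'
#' A peak is present in a culture when the mean of the given per-sample
#' statistic across the culture's replicates reaches the threshold
#' (inclusive). For ATAC the statistic is normalized depth with threshold 5;
#' for G4 CUT&Tag it is raw depth with threshold 2.
#'
#' @param mat peaks x samples matrix (normalized or raw depth).
#' @param samples a [sample_sheet()] matching the columns of `mat`.
#' @param threshold presence threshold (inclusive).
#' @return binary integer matrix, peaks x cultures.
#' @export
presence_matrix <- function(mat, samples, threshold) {
  mat <- as.matrix(mat)
  stopifnot(identical(colnames(mat), samples$sample_id))
  cultures <- unique(samples$culture_id)
  out <- matrix(0L, nrow(mat), length(cultures),
                dimnames = list(rownames(mat), cultures))
  for (cu in cultures) {
    cols <- which(samples$culture_id == cu)
    out[, cu] <- as.integer(rowMeans(mat[, cols, drop = FALSE]) >= threshold)
  }
  out
}

#' Exact-subset intersection counts of a presence matrix
#'
#' For every non-empty subset of cultures, the number of peaks present in
#' exactly that subset (the counts behind an UpSet plot). All-zero rows
#' contribute to no subset, so the counts sum to the number of peaks present
#' in at least one culture.
#'
#' @param presence binary peaks x cultures matrix.
#' @return data frame `subset` (culture names joined by `&`), `count`,
#'   ordered by decreasing count.
#' @export
intersection_counts <- function(presence) {
  presence <- as.matrix(presence)
  cultures <- colnames(presence)
  keep <- rowSums(presence) > 0L
  if (!any(keep)) {
    return(data.frame(subset = character(0), count = integer(0)))
  }
  pat <- apply(presence[keep, , drop = FALSE], 1L, function(r) {
    paste(cultures[r > 0L], collapse = "&")
  })
  tab <- table(pat)
  out <- data.frame(subset = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
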