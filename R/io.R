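#' Construct a peak set
#'
#' A peak set is the universe over which every downstream computation runs:
#' a data frame of genomic intervals (0-based half-open) with unique peak ids
#' and an assay label. Rows are kept sorted by (chrom, start).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param peak_id unique identifiers; autogenerated as `peak_<n>` when `NULL`.
#' @param assay assay provenance, `"ATAC"` or `"G4Q"`.
#' @param summit_offset optional integer offset of the peak summit within the
#'   interval (`NA` when absent); must lie in `[0, end - start)`.
#' @param genome_id label of the genome build the coordinates refer to.
#' @return A `peak_set`: a data frame with columns `chrom`, `start`, `end`,
#'   `peak_id`, `assay`, `summit_offset`, sorted by position.
#' @export
peak_set <- function(chrom, start, end, peak_id = NULL,
                     assay = c("ATAC", "G4Q"), summit_offset = NA_integer_,
                     genome_id = "synthetic") {
  assay <- match.arg(assay)
  n <- length(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) stopf("non-integer coordinates")
  bad <- which(start < 0L | start >= end)
  if (length(bad)) stopf("start >= end (or start < 0) at row %d", bad[1])
  if (any(!nzchar(chrom))) stopf("empty chromosome name")
  df <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    peak_id = if (is.null(peak_id)) NA_character_ else as.character(peak_id),
    assay = assay,
    summit_offset = as.integer(rep_len(summit_offset, n)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  if (all(is.na(df$peak_id))) {
    df$peak_id <- sprintf("peak_%d", seq_len(n))
  }
  if (anyDuplicated(df$peak_id)) {
    stopf("duplicate peak_id: %s", df$peak_id[anyDuplicated(df$peak_id)])
  }
  so <- df$summit_offset
  bad <- which(!is.na(so) & (so < 0L | so >= df$end - df$start))
  if (length(bad)) stopf("summit_offset outside interval for %s", df$peak_id[bad[1]])
  attr(df, "genome_id") <- genome_id
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Read peak intervals from BED or MACS2 narrowPeak
#'
#' Coordinates are taken 0-based half-open exactly as in the file. For
#' narrowPeak the 10th column becomes the summit offset (-1 maps to absent).
#' When the name column is absent, ids `peak_<n>` are generated after sorting.
#'
#' @param path file path.
#' @param format `"auto"` guesses from the column count (10 columns with an
#'   integer final field is treated as narrowPeak).
#' @param assay assay label to attach.
#' @param genome_id genome build label.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak"),
                       assay = c("ATAC", "G4Q"), genome_id = "unknown") {
  format <- match.arg(format)
  assay <- match.arg(assay)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) stopf("no intervals in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (format == "auto") {
    format <- if (all(ncols == 10L)) "narrowPeak" else "bed"
  }
  need <- if (format == "narrowPeak") 10L else 3L
  bad <- which(ncols < need)
  if (length(bad)) stopf("malformed line %d in %s (%d fields, need >= %d)",
                         bad[1], path, ncols[bad[1]], need)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stopf("malformed line %d in %s: non-numeric coordinates",
                         bad[1], path)
  bad <- which(start >= end)
  if (length(bad)) stopf("start >= end at line %d in %s", bad[1], path)
  ids <- if (all(ncols >= 4L)) {
    nm <- vapply(fields, `[[`, "", 4L)
    if (all(nm == ".") || !any(nzchar(nm))) NULL else nm
  } else NULL
  summit <- NA_integer_
  if (format == "narrowPeak") {
    summit <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 10L)))
    bad <- which(is.na(summit))
    if (length(bad)) stopf("malformed line %d in %s: bad summit field",
                           bad[1], path)
    summit[summit < 0L] <- NA_integer_
  }
  peak_set(chrom, start, end, peak_id = ids, assay = assay,
           summit_offset = summit, genome_id = genome_id)
}

#' Write a peak set as a 10-column narrowPeak file
#'
#' Round trip through [read_peaks()] reproduces coordinates, ids, and summit
#' offsets exactly. Absent summits are encoded as -1 per the format.
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  summit <- peaks$summit_offset
  summit[is.na(summit)] <- -1L
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                   0L, ".", -1, -1, -1, summit)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript models from a refFlat-like table
#'
#' Expects the 11 tab-delimited columns gene_name, transcript_id, chrom,
#' strand, tx_start, tx_end, cds_start, cds_end, exon_count, exon_starts,
#' exon_ends (the two last comma-separated). Coordinates are 0-based
#' half-open. Exons are stored in ascending genomic order regardless of
#' strand; `cds_start == cds_end` denotes a non-coding transcript.
#'
#' @param path file path.
#' @return A `transcript_set` data frame with list columns `exon_starts` and
#'   `exon_ends`.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "character", "integer", "integer",
                                  "integer", "integer", "integer",
                                  "character", "character"))
  names(df) <- c("gene_name", "transcript_id", "chrom", "strand",
                 "tx_start", "tx_end", "cds_start", "cds_end",
                 "exon_count", "exon_starts", "exon_ends")
  parse_list <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                   function(v) as.integer(v[nzchar(v)]))
  es <- parse_list(df$exon_starts)
  ee <- parse_list(df$exon_ends)
  df$exon_starts <- es
  df$exon_ends <- ee
  transcript_set(df)
}

#' Validate and class a transcript table
#' @param df data frame with the columns of [read_transcripts()].
#' @return the validated `transcript_set`.
#' @export
transcript_set <- function(df) {
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]
    ee <- df$exon_ends[[i]]
    id <- df$transcript_id[i]
    if (length(es) < 1L) stopf("transcript %s has no exons", id)
    if (length(es) != df$exon_count[i] || length(ee) != df$exon_count[i]) {
      stopf("transcript %s: exon_count mismatch with exon lists", id)
    }
    if (any(es >= ee)) stopf("transcript %s: empty exon", id)
    if (is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)])) {
      stopf("transcript %s: exons unsorted or overlapping", id)
    }
    if (es[1] < df$tx_start[i] || ee[length(ee)] > df$tx_end[i]) {
      stopf("transcript %s: exon outside transcript bounds", id)
    }
    if (!df$strand[i] %in% c("+", "-")) {
      stopf("transcript %s: strand must be + or -", id)
    }
  }
  if (anyDuplicated(df$transcript_id)) stopf("duplicate transcript_id")
  rownames(df) <- NULL
  class(df) <- c("transcript_set", "data.frame")
  df
}

#' Write transcript models in refFlat-like format
#' @param tx a `transcript_set`.
#' @param path output path.
#' @export
write_transcripts <- function(tx, path) {
  fmt <- function(l) vapply(l, function(v) paste0(paste(v, collapse = ","), ","), "")
  df <- data.frame(tx$gene_name, tx$transcript_id, tx$chrom, tx$strand,
                   tx$tx_start, tx$tx_end, tx$cds_start, tx$cds_end,
                   tx$exon_count, fmt(tx$exon_starts), fmt(tx$exon_ends))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build sample metadata
#'
#' Each sample belongs to one culture (the random-effect block); all samples
#' of a culture share one age.
#'
#' @param sample_id,culture_id,age_years,condition parallel vectors.
#' @return A `sample_sheet` data frame.
#' @export
sample_sheet <- function(sample_id, culture_id, age_years,
                         condition = "none") {
  df <- data.frame(sample_id = as.character(sample_id),
                   culture_id = as.character(culture_id),
                   age_years = as.integer(age_years),
                   condition = rep_len(as.character(condition),
                                       length(sample_id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id")
  if (!all(df$condition %in% c("none", "control", "DDX5_KD"))) {
    stopf("condition must be one of none, control, DDX5_KD")
  }
  ok <- tapply(df$age_years, df$culture_id, function(a) length(unique(a)) == 1L)
  if (!all(ok)) stopf("samples of one culture must share age_years")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Default study design: 8 cultures, ages 22-73, replicated
#'
#' The default emulates the study design: eight cultures with ages
#' 22, 24, 32, 34, 53, 56, 72 and 73 years and two replicates per culture.
#'
#' @param ages integer ages, one per culture.
#' @param replicates replicates per culture.
#' @param condition condition label for all samples.
#' @return A [sample_sheet()].
#' @export
default_sample_sheet <- function(ages = c(22L, 24L, 32L, 34L, 53L, 56L, 72L, 73L),
                                 replicates = 2L, condition = "none") {
  culture <- rep(sprintf("cult%02d", ages), each = replicates)
  rep_id <- rep(seq_len(replicates), times = length(ages))
  sample_sheet(
    sample_id = sprintf("%s_r%d", culture, rep_id),
    culture_id = culture,
    age_years = rep(ages, each = replicates),
    condition = condition
  )
}
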