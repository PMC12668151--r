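# Annotation module: strand-aware feature geometry, hierarchical peak
# annotation (first exon > promoter > exon > 5'UTR > 3'UTR > intron >
# downstream > intergenic), TSS distance context, and canonical G4 motif
# scanning.

annotation_priority <- c(first_exon = 1L, promoter = 2L, exon = 3L,
                         utr5 = 4L, utr3 = 5L, intron = 6L,
                         downstream = 7L, intergenic = 8L)

# exonic sub-intervals of [lo, hi), used for the UTR features
exonic_intersect <- function(es, ee, lo, hi) {
  s <- pmax(es, lo)
  e <- pmin(ee, hi)
  keep <- e > s
  list(start = s[keep], end = e[keep])
}

#' Build the strand-aware feature index used for hierarchical annotation
#'
#' Per transcript: a promoter spanning `promoter_up` bp upstream to
#' `promoter_down` bp downstream of the TSS, the 5'-most (first) exon, all
#' exons, 5'/3' UTRs derived from CDS bounds when present, introns, and a
#' `downstream_len` bp region past the 3' end. All features are clipped at
#' chromosome bounds when lengths are supplied.
#'
#' @param transcripts a `transcript_set`.
#' @param promoter_up,promoter_down promoter extent around the TSS in bp
#'   (defaults 2500 upstream / 250 downstream).
#' @param downstream_len downstream region length in bp (default 3000).
#' @param chrom_lengths optional named vector for clipping.
#' @return data frame of features: `chrom`, `start`, `end`, `category`,
#'   `priority`, `gene_name`, `transcript_id`.
#' @export
build_feature_index <- function(transcripts, promoter_up = 2500L,
                                promoter_down = 250L, downstream_len = 3000L,
                                chrom_lengths = NULL) {
  rows <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    es <- transcripts$exon_starts[[i]]
    ee <- transcripts$exon_ends[[i]]
    if (!length(es)) stopf("transcript %s has no exons",
                           transcripts$transcript_id[i])
    plus <- transcripts$strand[i] == "+"
    s0 <- transcripts$tx_start[i]; e0 <- transcripts$tx_end[i]
    cs <- transcripts$cds_start[i]; ce <- transcripts$cds_end[i]
    has_cds <- !is.na(cs) && !is.na(ce) && cs < ce
    n_ex <- length(es)
    feat <- list()
    add <- function(cat, fs, fe) {
      keep <- fe > fs
      if (any(keep)) {
        feat[[length(feat) + 1L]] <<- data.frame(
          start = fs[keep], end = fe[keep], category = cat,
          stringsAsFactors = FALSE)
      }
    }
    if (plus) {
      add("promoter", s0 - promoter_up, s0 + promoter_down)
      add("first_exon", es[1], ee[1])
      add("downstream", e0, e0 + downstream_len)
      if (has_cds) {
        u5 <- exonic_intersect(es, ee, s0, cs)
        add("utr5", u5$start, u5$end)
        u3 <- exonic_intersect(es, ee, ce, e0)
        add("utr3", u3$start, u3$end)
      }
    } else {
      add("promoter", e0 - promoter_down, e0 + promoter_up)
      add("first_exon", es[n_ex], ee[n_ex])
      add("downstream", s0 - downstream_len, s0)
      if (has_cds) {
        u5 <- exonic_intersect(es, ee, ce, e0)
        add("utr5", u5$start, u5$end)
        u3 <- exonic_intersect(es, ee, s0, cs)
        add("utr3", u3$start, u3$end)
      }
    }
    add("exon", es, ee)
    if (n_ex > 1L) add("intron", ee[-n_ex], es[-1])
    f <- do.call(rbind, feat)
    f$chrom <- transcripts$chrom[i]
    f$gene_name <- transcripts$gene_name[i]
    f$transcript_id <- transcripts$transcript_id[i]
    rows[[i]] <- f
  }
  out <- do.call(rbind, rows)
  out$start <- pmax(0L, as.integer(out$start))
  if (!is.null(chrom_lengths)) {
    out$end <- pmin(as.integer(chrom_lengths[out$chrom]), as.integer(out$end))
  }
  out <- out[out$end > out$start, , drop = FALSE]
  out$priority <- annotation_priority[out$category]
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "category", "priority",
          "gene_name", "transcript_id")]
}

#' Hierarchically annotate peaks against a feature index
#'
#' Among all features of all transcripts a peak overlaps by at least 1 bp,
#' the single highest-priority category wins; no overlap gives
#' `"intergenic"`. Gene ties at equal priority break lexicographically.
#'
#' @param peaks a [peak_set()].
#' @param index output of [build_feature_index()].
#' @return data frame `peak_id`, `category`, `gene_overlap` (gene of the
#'   winning feature, `NA` for intergenic).
#' @export
annotate_peaks <- function(peaks, index) {
  category <- rep("intergenic", nrow(peaks))
  gene <- rep(NA_character_, nrow(peaks))
  if (!is.null(index) && nrow(index)) {
    hits <- GenomicRanges::findOverlaps(
      as_granges0(peaks$chrom, peaks$start, peaks$end),
      as_granges0(index$chrom, index$start, index$end))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (length(qh)) {
      ord <- order(qh, index$priority[sh], index$gene_name[sh])
      first <- !duplicated(qh[ord])
      q <- qh[ord][first]
      s <- sh[ord][first]
      category[q] <- index$category[s]
      gene[q] <- index$gene_name[s]
    }
  }
  data.frame(peak_id = peaks$peak_id, category = category,
             gene_overlap = gene, stringsAsFactors = FALSE)
}

#' TSS distance context and enrichment-gene assignment
#'
#' For each peak, the distance to the nearest TSS strictly left (upstream in
#' genomic coordinates) and strictly right (downstream); both 0 when a TSS
#' falls inside the peak. The enrichment gene is the overlapped gene for
#' genic peaks, otherwise the nearer of the upstream/downstream genes (ties
#' broken lexicographically by gene name).
#'
#' @param peaks a [peak_set()].
#' @param transcripts a `transcript_set`.
#' @param annotation optional output of [annotate_peaks()] for the same
#'   peaks (computed when `NULL`).
#' @param index optional feature index (built with defaults when needed).
#' @return data frame with `peak_id`, `tss_distance_upstream`,
#'   `tss_distance_downstream`, `gene_upstream`, `gene_downstream`,
#'   `enrichment_gene`.
#' @export
tss_context <- function(peaks, transcripts, annotation = NULL, index = NULL) {
  if (is.null(annotation)) {
    if (is.null(index)) index <- build_feature_index(transcripts)
    annotation <- annotate_peaks(peaks, index)
  }
  tss <- ifelse(transcripts$strand == "+", transcripts$tx_start,
                transcripts$tx_end - 1L)
  n <- nrow(peaks)
  up_d <- rep(NA_real_, n); dn_d <- rep(NA_real_, n)
  up_g <- rep(NA_character_, n); dn_g <- rep(NA_character_, n)
  for (chrom in unique(peaks$chrom)) {
    sel <- which(transcripts$chrom == chrom)
    pk <- which(peaks$chrom == chrom)
    if (!length(sel)) next
    t_pos <- tss[sel]
    t_gene <- transcripts$gene_name[sel]
    ord <- order(t_pos, t_gene)
    t_pos <- t_pos[ord]; t_gene <- t_gene[ord]
    for (i in pk) {
      s <- peaks$start[i]; e <- peaks$end[i]
      inside <- t_pos >= s & t_pos < e
      if (any(inside)) {
        g <- sort(t_gene[inside])[1]
        up_d[i] <- 0; dn_d[i] <- 0
        up_g[i] <- g; dn_g[i] <- g
        next
      }
      left <- t_pos < s
      if (any(left)) {
        d <- s - t_pos[left]
        j <- which(d == min(d))
        up_d[i] <- min(d)
        up_g[i] <- sort(t_gene[left][j])[1]
      }
      right <- t_pos >= e
      if (any(right)) {
        d <- t_pos[right] - e
        j <- which(d == min(d))
        dn_d[i] <- min(d)
        dn_g[i] <- sort(t_gene[right][j])[1]
      }
    }
  }
  enrich <- annotation$gene_overlap
  inter <- annotation$category == "intergenic"
  pick <- function(i) {
    du <- up_d[i]; dd <- dn_d[i]
    if (is.na(du) && is.na(dd)) return(NA_character_)
    if (is.na(dd) || (!is.na(du) && du < dd)) return(up_g[i])
    if (is.na(du) || dd < du) return(dn_g[i])
    sort(c(up_g[i], dn_g[i]))[1]
  }
  enrich[inter] <- vapply(which(inter), pick, "")
  data.frame(peak_id = peaks$peak_id,
             tss_distance_upstream = up_d, tss_distance_downstream = dn_d,
             gene_upstream = up_g, gene_downstream = dn_g,
             enrichment_gene = enrich, stringsAsFactors = FALSE)
}

#' Expand an interval symmetrically, clipped to the chromosome
#'
#' @param start,end 0-based half-open coordinates (vectorized).
#' @param pad bp added on each end (default 15).
#' @param chrom_length upper clipping bound (default unbounded).
#' @return data frame `start`, `end`.
#' @export
slop_interval <- function(start, end, pad = 15L, chrom_length = Inf) {
  if (any(pad < 0)) stopf("pad must be >= 0")
  data.frame(start = pmax(0, start - pad),
             end = pmin(chrom_length, end + pad))
}

canonical_g4_pattern <- "G{3,}[ATGC]{1,7}G{3,}[ATGC]{1,7}G{3,}[ATGC]{1,7}G{3,}"

#' Scan a sequence for canonical G4 motifs
#'
#' Counts non-overlapping, leftmost-greedy matches of the canonical pattern
#' `G{3,}[ATGC]{1,7}G{3,}[ATGC]{1,7}G{3,}[ATGC]{1,7}G{3,}` (four runs of at
#' least three guanines separated by loops of one to seven nucleotides).
#' `N` never matches.
#'
#' @param sequence DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @return list with `count` and `spans` (0-based half-open local
#'   coordinates).
#' @export
scan_g4_motifs <- function(sequence) {
  sequence <- toupper(sequence)
  m <- gregexpr(canonical_g4_pattern, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(list(count = 0L,
                spans = data.frame(start = integer(0), end = integer(0))))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  list(count = length(start), spans = data.frame(start = start, end = end))
}

#' Flag peaks containing canonical G4 motifs
#'
#' Each peak is expanded by `pad` bp on each end, its sequence extracted,
#' and scanned with [scan_g4_motifs()]. By default the reverse complement is
#' scanned as well and the counts summed (the canonical pattern itself only
#' matches the G-rich strand); set `both_strands = FALSE` for forward-only
#' scanning. A peak is canonical iff it has at least one match.
#'
#' @param peaks a [peak_set()].
#' @param genome a `DNAStringSet`.
#' @param pad slop padding in bp (default 15).
#' @param both_strands also scan the reverse complement (default `TRUE`).
#' @return data frame `peak_id`, `canonical_g4`, `motif_count`.
#' @export
annotate_canonical_g4 <- function(peaks, genome, pad = 15L,
                                  both_strands = TRUE) {
  sizes <- chrom_sizes(genome)
  counts <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    sl <- slop_interval(peaks$start[i], peaks$end[i], pad,
                        sizes[[peaks$chrom[i]]])
    seq <- genome_fetch(genome, peaks$chrom[i], sl$start, sl$end)
    k <- scan_g4_motifs(seq)$count
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
      k <- k + scan_g4_motifs(rc)$count
    }
    counts[i] <- k
  }
  data.frame(peak_id = peaks$peak_id, canonical_g4 = counts >= 1L,
             motif_count = counts, stringsAsFactors = FALSE)
}

#' Full annotation table for a peak set
#'
#' Combines the hierarchical category, TSS context and enrichment gene, and
#' (when a genome is given) the canonical G4 flag into one table.
#'
#' @inheritParams annotate_canonical_g4
#' @param transcripts a `transcript_set` (or `NULL`: everything intergenic).
#' @param promoter_up,promoter_down,downstream_len feature geometry, see
#'   [build_feature_index()].
#' @return data frame with one row per peak.
#' @export
annotate_peak_set <- function(peaks, transcripts, genome = NULL,
                              promoter_up = 2500L, promoter_down = 250L,
                              downstream_len = 3000L, pad = 15L,
                              both_strands = TRUE) {
  sizes <- if (is.null(genome)) NULL else chrom_sizes(genome)
  if (is.null(transcripts) || nrow(transcripts) == 0L) {
    ann <- data.frame(peak_id = peaks$peak_id, category = "intergenic",
                      gene_overlap = NA_character_, stringsAsFactors = FALSE)
    ctx <- data.frame(peak_id = peaks$peak_id,
                      tss_distance_upstream = NA_real_,
                      tss_distance_downstream = NA_real_,
                      gene_upstream = NA_character_,
                      gene_downstream = NA_character_,
                      enrichment_gene = NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    index <- build_feature_index(transcripts, promoter_up, promoter_down,
                                 downstream_len, chrom_lengths = sizes)
    ann <- annotate_peaks(peaks, index)
    ctx <- tss_context(peaks, transcripts, annotation = ann)
  }
  out <- merge(ann, ctx, by = "peak_id", sort = FALSE)
  if (!is.null(genome)) {
    g4 <- annotate_canonical_g4(peaks, genome, pad, both_strands)
    out <- merge(out, g4, by = "peak_id", sort = FALSE)
  }
  out[match(peaks$peak_id, out$peak_id), , drop = FALSE]
}
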