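# Independent oracles used to cross-check the implementation. Each is a
# deliberate re-derivation from first principles, sharing no code with the
# package paths it checks.

# Upper-half inverse normal: z with P(|Z| >= z) = p, solved by bisection on
# pnorm (the package path uses qnorm only).
oracle_z_twosided <- function(p) {
  lo <- rep(0, length(p))
  hi <- rep(40, length(p))
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    too_small <- pnorm(mid, lower.tail = FALSE) > p / 2
    lo <- ifelse(too_small, mid, lo)
    hi <- ifelse(too_small, hi, mid)
  }
  (lo + hi) / 2
}

# Shrinkage recomputed from the definition with the bisection inverse.
oracle_shrink <- function(logfc, p, confidence) {
  z_obs <- oracle_z_twosided(pmax(p, 1e-300))
  z_c <- oracle_z_twosided(1 - confidence)
  keep <- pmax(0, 1 - z_c / z_obs)
  keep[z_obs == 0] <- 0
  sign(logfc) * abs(logfc) * keep
}

# Brute-force canonical-G4 matcher with explicit greedy backtracking
# (earlier quantifiers try their longest extent first), counting
# non-overlapping leftmost matches.
oracle_g4_count <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < 15L) return(0L)
  is_g <- chars == "G"
  is_acgt <- chars %in% c("A", "C", "G", "T")
  grun <- integer(n)
  for (i in n:1) grun[i] <- if (is_g[i]) (if (i < n) grun[i + 1] + 1L else 1L) else 0L
  try_run <- function(pos, run_idx) {
    if (pos > n) return(NA_integer_)
    maxr <- min(grun[pos], n - pos + 1L)
    if (maxr < 3L) return(NA_integer_)
    for (r in maxr:3) {
      after <- pos + r
      if (run_idx == 4L) return(after - 1L)
      for (l in 7:1) {
        lp_end <- after + l - 1L
        if (lp_end > n) next
        if (!all(is_acgt[after:lp_end])) next
        res <- try_run(lp_end + 1L, run_idx + 1L)
        if (!is.na(res)) return(res)
      }
    }
    NA_integer_
  }
  count <- 0L
  i <- 1L
  while (i <= n - 14L) {
    if (is_g[i] && grun[i] >= 3L) {
      e <- try_run(i, 1L)
      if (!is.na(e)) {
        count <- count + 1L
        i <- e + 1L
        next
      }
    }
    i <- i + 1L
  }
  count
}

# Exhaustive feature-overlap annotation: enumerates every feature of every
# transcript with plain arithmetic and takes the highest-priority overlap.
oracle_annotate <- function(peak, transcripts, promoter_up = 2500,
                            promoter_down = 250, downstream_len = 3000) {
  prio <- c(first_exon = 1, promoter = 2, exon = 3, utr5 = 4, utr3 = 5,
            intron = 6, downstream = 7, intergenic = 8)
  overlaps <- function(s1, e1, s2, e2) max(s1, s2) < min(e1, e2)
  best <- "intergenic"
  for (i in seq_len(nrow(transcripts))) {
    if (transcripts$chrom[i] != peak$chrom) next
    es <- transcripts$exon_starts[[i]]
    ee <- transcripts$exon_ends[[i]]
    plus <- transcripts$strand[i] == "+"
    s0 <- transcripts$tx_start[i]; e0 <- transcripts$tx_end[i]
    cs <- transcripts$cds_start[i]; ce <- transcripts$cds_end[i]
    feats <- list()
    add <- function(cat, s, e) {
      if (e > s) feats[[length(feats) + 1]] <<- list(cat = cat, s = s, e = e)
    }
    if (plus) add("promoter", s0 - promoter_up, s0 + promoter_down)
    else add("promoter", e0 - promoter_down, e0 + promoter_up)
    if (plus) add("first_exon", es[1], ee[1])
    else add("first_exon", es[length(es)], ee[length(ee)])
    for (k in seq_along(es)) add("exon", es[k], ee[k])
    if (!is.na(cs) && !is.na(ce) && cs < ce) {
      for (k in seq_along(es)) {
        lo5 <- if (plus) s0 else ce
        hi5 <- if (plus) cs else e0
        add("utr5", max(es[k], lo5), min(ee[k], hi5))
        lo3 <- if (plus) ce else s0
        hi3 <- if (plus) e0 else cs
        add("utr3", max(es[k], lo3), min(ee[k], hi3))
      }
    }
    if (length(es) > 1) {
      for (k in seq_len(length(es) - 1)) add("intron", ee[k], es[k + 1])
    }
    if (plus) add("downstream", e0, e0 + downstream_len)
    else add("downstream", s0 - downstream_len, s0)
    for (f in feats) {
      if (overlaps(peak$start, peak$end, max(0, f$s), f$e) &&
          prio[[f$cat]] < prio[[best]]) {
        best <- f$cat
      }
    }
  }
  best
}

# sort-then-slice trimmed mean
oracle_trimmed_mean <- function(x, trim) {
  k <- floor(length(x) * trim)
  s <- sort(x)
  mean(s[(k + 1):(length(x) - k)])
}

# full running-sum enrichment score
oracle_es <- function(scores, hit_idx) {
  N <- length(scores)
  k <- length(hit_idx)
  step <- rep(-1 / (N - k), N)
  w <- abs(scores[hit_idx])
  if (sum(w) == 0) w <- rep(1, k)
  step[hit_idx] <- w / sum(w)
  r <- cumsum(step)
  r[which.max(abs(r))]
}

# brute-force exact-subset counts of a binary matrix
oracle_intersections <- function(m) {
  cultures <- colnames(m)
  out <- list()
  for (i in seq_len(nrow(m))) {
    members <- cultures[m[i, ] > 0]
    if (!length(members)) next
    key <- paste(members, collapse = "&")
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random DNA sequence with a mild G bias so G4-like context occurs
random_dna <- function(n, g_bias = 0.35) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - g_bias) / 3, (1 - g_bias) / 3, g_bias,
                        (1 - g_bias) / 3)),
        collapse = "")
}

# small transcript builder for annotation tests
make_tx <- function(gene, chrom, strand, exons, cds = NULL, id = gene) {
  es <- as.integer(vapply(exons, `[[`, 0, 1))
  ee <- as.integer(vapply(exons, `[[`, 0, 2))
  df <- data.frame(gene_name = gene, transcript_id = id, chrom = chrom,
                   strand = strand, tx_start = min(es), tx_end = max(ee),
                   cds_start = if (is.null(cds)) min(es) else cds[1],
                   cds_end = if (is.null(cds)) min(es) else cds[2],
                   exon_count = length(es), stringsAsFactors = FALSE)
  df$exon_starts <- list(es)
  df$exon_ends <- list(ee)
  transcript_set(df)
}

rbind_tx <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  transcript_set(out)
}
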