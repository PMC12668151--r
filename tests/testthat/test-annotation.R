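test_that("promoter and first-exon geometry is strand-aware", {
  plus <- make_tx("GP", "chr1", "+", list(c(10000, 10500), c(12000, 12400)))
  idx <- build_feature_index(plus)
  pr <- idx[idx$category == "promoter", ]
  expect_equal(c(pr$start, pr$end), c(7500L, 10250L))
  fe <- idx[idx$category == "first_exon", ]
  expect_equal(c(fe$start, fe$end), c(10000L, 10500L))

  minus <- make_tx("GM", "chr1", "-", list(c(8000, 8400), c(9600, 10000)))
  idxm <- build_feature_index(minus)
  prm <- idxm[idxm$category == "promoter", ]
  expect_equal(c(prm$start, prm$end), c(9750L, 12500L))
  fem <- idxm[idxm$category == "first_exon", ]
  expect_equal(c(fem$start, fem$end), c(9600L, 10000L))  # largest start
  dn <- idxm[idxm$category == "downstream", ]
  expect_equal(c(dn$start, dn$end), c(5000L, 8000L))
})

test_that("the annotation hierarchy resolves conflicting overlaps", {
  # peak overlapping one gene's promoter and another gene's intron
  g1 <- make_tx("AAA", "chr1", "+", list(c(10000, 10200), c(29000, 29200)))
  g2 <- make_tx("BBB", "chr1", "+", list(c(30000, 30200), c(30900, 31100)))
  idx <- build_feature_index(rbind_tx(g1, g2))
  pk <- peak_set("chr1", c(10300L, 28000L, 50000L),
                 c(10600L, 28400L, 50200L), c("pA", "pB", "pC"))
  ann <- annotate_peaks(pk, idx)
  # pB lies inside g1's intron AND g2's promoter: promoter wins
  expect_equal(ann$category[ann$peak_id == "pB"], "promoter")
  expect_equal(ann$category[ann$peak_id == "pA"], "intron")
  # first exon beats promoter of the same transcript
  pk2 <- peak_set("chr1", 9900L, 10100L, "pX")
  expect_equal(annotate_peaks(pk2, idx)$category, "first_exon")
  expect_equal(ann$category[ann$peak_id == "pC"], "intergenic")
})

test_that("annotation agrees with exhaustive feature enumeration", {
  set.seed(31)
  n_cases <- 1000
  mismatches <- 0
  for (case in seq_len(n_cases)) {
    n_tx <- sample(1:3, 1)
    txs <- lapply(seq_len(n_tx), function(j) {
      n_ex <- sample(1:4, 1)
      s <- sort(sample.int(50000, 2 * n_ex))
      exons <- split(s, rep(seq_len(n_ex), each = 2))
      exons <- lapply(exons, function(p) c(p[1], p[2]))
      exons <- Filter(function(p) p[2] > p[1], exons)
      if (!length(exons)) exons <- list(c(s[1], s[1] + 100))
      cds <- if (runif(1) < 0.5) {
        lo <- min(vapply(exons, `[[`, 0, 1))
        hi <- max(vapply(exons, `[[`, 0, 2))
        sort(sample(seq(lo, hi), 2))
      } else NULL
      make_tx(sprintf("G%d_%d", case, j), "chr1", sample(c("+", "-"), 1),
              exons, cds, id = sprintf("t%d_%d", case, j))
    })
    tx <- do.call(rbind_tx, txs)
    ps <- sample.int(60000, 1)
    pk <- peak_set("chr1", ps, ps + sample(50:2000, 1), "p")
    got <- annotate_peaks(pk, build_feature_index(tx))$category
    want <- oracle_annotate(list(chrom = "chr1", start = pk$start,
                                 end = pk$end), tx)
    if (got != want) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("TSS distances and the enrichment gene follow the stated rules", {
  g1 <- make_tx("LEFT", "chr1", "+", list(c(500, 700)))
  g2 <- make_tx("RIGHT", "chr1", "+", list(c(1500, 1700)))
  tx <- rbind_tx(g1, g2)
  pk <- peak_set("chr1", 1000L, 1100L, "p")
  ctx <- tss_context(pk, tx)
  expect_equal(ctx$tss_distance_upstream, 500)
  expect_equal(ctx$tss_distance_downstream, 400)
  expect_equal(ctx$gene_upstream, "LEFT")
  expect_equal(ctx$gene_downstream, "RIGHT")
  expect_equal(ctx$enrichment_gene, "RIGHT")       # nearer

  # genic peak keeps its own gene
  pk2 <- peak_set("chr1", 550L, 600L, "pg")
  ctx2 <- tss_context(pk2, tx)
  expect_equal(ctx2$enrichment_gene, "LEFT")
  expect_equal(ctx2$tss_distance_upstream, 50)
  # TSS inside the peak: both distances zero
  pk2b <- peak_set("chr1", 450L, 600L, "pz")
  ctx2b <- tss_context(pk2b, tx)
  expect_equal(ctx2b$tss_distance_upstream, 0)
  expect_equal(ctx2b$tss_distance_downstream, 0)
  # equidistant intergenic peak: lexicographic tie-break
  g3 <- make_tx("AZZ", "chr1", "+", list(c(10000, 10100)))
  g4x <- make_tx("ABB", "chr1", "+", list(c(30000, 30100)))
  pk3 <- peak_set("chr1", 19950L, 20050L, "pt")
  ctx3 <- tss_context(pk3, rbind_tx(g3, g4x))
  expect_equal(ctx3$tss_distance_upstream, ctx3$tss_distance_downstream)
  expect_equal(ctx3$enrichment_gene, "ABB")
})

test_that("slop expands symmetrically with clipping", {
  s <- slop_interval(100, 200, 15)
  expect_equal(c(s$start, s$end), c(85, 215))
  s2 <- slop_interval(5, 30, 15, chrom_length = 1000)
  expect_equal(c(s2$start, s2$end), c(0, 45))
  s3 <- slop_interval(100, 200, 0)
  expect_equal(c(s3$start, s3$end), c(100, 200))
})

test_that("canonical G4 scanning matches the printed pattern semantics", {
  expect_equal(scan_g4_motifs("GGGAGGGAGGGAGGG")$count, 1L)
  sp <- scan_g4_motifs("GGGAGGGAGGGAGGG")$spans
  expect_equal(c(sp$start, sp$end), c(0L, 15L))
  expect_equal(scan_g4_motifs("ACACACAC")$count, 0L)
  expect_equal(scan_g4_motifs(strrep("G", 14))$count, 0L)
  expect_equal(scan_g4_motifs(strrep("G", 15))$count, 1L)
  expect_equal(scan_g4_motifs("NNNGGGAGGGAGGGAGGGNN")$count, 1L)
  expect_equal(scan_g4_motifs("GGGNGGGNGGGNGGG")$count, 0L)  # N never matches
  # invariance to non-G4 flanks
  core <- "GGGTAGGGTTAGGGCAGGG"
  expect_equal(scan_g4_motifs(paste0("ACTACT", core, "TCATCA"))$count,
               scan_g4_motifs(core)$count)
})

test_that("scanner agrees with the backtracking oracle on random sequence", {
  set.seed(17)
  for (i in 1:60) {
    s <- random_dna(300, g_bias = 0.4)
    expect_equal(scan_g4_motifs(s)$count, oracle_g4_count(s),
                 label = sprintf("sequence %d", i))
  }
})

test_that("peak-level G4 flags use the 15 bp slop and both strands", {
  motif <- "GGGAGGGAGGGAGGG"
  left <- random_dna(100, 0.1)
  chrom <- paste0(left, motif, random_dna(100, 0.1))
  g <- Biostrings::DNAStringSet(chrom)
  names(g) <- "chr1"
  # motif begins 10 bp before the peak start: found only through the slop
  pk <- peak_set("chr1", 110L, 200L, "p")
  expect_true(annotate_canonical_g4(pk, g, pad = 15)$canonical_g4)
  expect_false(annotate_canonical_g4(pk, g, pad = 0)$canonical_g4)
  # C-rich (minus-strand) motif found only when both strands are scanned
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  g2 <- Biostrings::DNAStringSet(paste0(left, rc, random_dna(100, 0.1)))
  names(g2) <- "chr1"
  pk2 <- peak_set("chr1", 90L, 130L, "p")
  expect_true(annotate_canonical_g4(pk2, g2, pad = 15)$canonical_g4)
  expect_false(annotate_canonical_g4(pk2, g2, pad = 15,
                                     both_strands = FALSE)$canonical_g4)
  # all-N peak never matches
  gn <- Biostrings::DNAStringSet(strrep("N", 200))
  names(gn) <- "chr1"
  expect_false(annotate_canonical_g4(peak_set("chr1", 50L, 150L, "p"),
                                     gn)$canonical_g4)
})

test_that("canonical flags cover all planted-motif peaks on synthetic data", {
  gs <- simulate_genome(1, 60000, motifs_per_chrom = 20, seed = 23)
  pk <- simulate_peaks_and_transcripts(gs, n_genes = 0, n_peaks = 60,
                                       motif_peak_fraction = 0.3, seed = 24)
  ann <- annotate_canonical_g4(pk$peaks_g4, gs$genome)
  eff <- pk$truth$peak_effects
  motif_ids <- eff$peak_id[eff$is_motif_peak]
  expect_true(all(ann$canonical_g4[ann$peak_id %in% motif_ids]))
})
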