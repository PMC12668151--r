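# Synthetic-data generators. These define the study conditions used by the
# recovery tests: a genome with planted canonical G4 motifs, transcript models
# and peaks covering every annotation category, and negative-binomial coverage
# with multiplicative ordinal-age effects, a shared culture random intercept,
# and library-size variation that the normalization is expected to remove.

quadrant_categories <- c("ATAC_gain|G4_gain", "ATAC_gain|G4_loss",
                         "ATAC_loss|G4_gain", "ATAC_loss|G4_loss")

# one random canonical G4 motif: four G-runs of 3-5, loops of 1-7 non-G bases
# (non-G so the planted string matches the canonical pattern exactly and the
# match cannot silently extend into flanking sequence)
random_g4_motif <- function() {
  runs <- sample(3:5, 4L, replace = TRUE)
  loops <- vapply(sample(1:7, 3L, replace = TRUE), function(k) {
    paste(sample(c("A", "C", "T"), k, replace = TRUE), collapse = "")
  }, "")
  paste0(strrep("G", runs[1]), loops[1], strrep("G", runs[2]), loops[2],
         strrep("G", runs[3]), loops[3], strrep("G", runs[4]))
}

#' Simulate a genome with planted canonical G4 motifs
#'
#' Background bases are i.i.d. with the stated GC fraction; each planted
#' motif matches the canonical G4 pattern (four runs of 3-5 G separated by
#' 1-7 non-G bases) and is inserted at a recorded, non-overlapping position.
#' Deterministic given `seed`.
#'
#' @param n_chrom number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length length of each chromosome in bp (>= 10000).
#' @param gc_fraction background GC content in `[0, 1]`.
#' @param motifs_per_chrom planted motifs per chromosome.
#' @param seed integer seed.
#' @return list with `genome` (`DNAStringSet`), `motifs` (data frame of
#'   0-based half-open motif positions and sequences), and `params`.
#' @export
simulate_genome <- function(n_chrom = 2L, chrom_length = 100000L,
                            gc_fraction = 0.41, motifs_per_chrom = 20L,
                            seed = 1L) {
  if (chrom_length < 10000L) stopf("chrom_length must be >= 10000")
  if (gc_fraction < 0 || gc_fraction > 1) stopf("gc_fraction must be in [0,1]")
  set.seed(seed)
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- character(n_chrom)
  motif_rows <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    bases <- sample(names(probs), chrom_length, replace = TRUE, prob = probs)
    placed_start <- integer(0)
    placed_end <- integer(0)
    motifs <- character(0)
    attempts <- 0L
    while (length(placed_start) < motifs_per_chrom) {
      attempts <- attempts + 1L
      if (attempts > 200L * motifs_per_chrom) {
        stopf("could not place %d non-overlapping motifs on a %d bp chromosome",
              motifs_per_chrom, chrom_length)
      }
      m <- random_g4_motif()
      w <- nchar(m)
      if (w >= chrom_length) stopf("motif longer than chromosome")
      # keep a 20 bp guard so neighbouring motifs never merge into one match
      s <- sample.int(chrom_length - w - 20L, 1L) + 10L
      e <- s + w
      if (any(s < placed_end + 20L & e > placed_start - 20L)) next
      placed_start <- c(placed_start, s)
      placed_end <- c(placed_end, e)
      motifs <- c(motifs, m)
      bases[(s + 1L):e] <- strsplit(m, "")[[1]]
    }
    ord <- order(placed_start)
    motif_rows[[i]] <- data.frame(
      chrom = sprintf("chr%d", i),
      start = placed_start[ord], end = placed_end[ord],
      motif = motifs[ord], stringsAsFactors = FALSE
    )
    seqs[i] <- paste(bases, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- sprintf("chr%d", seq_len(n_chrom))
  list(genome = genome,
       motifs = do.call(rbind, motif_rows),
       params = list(n_chrom = n_chrom, chrom_length = chrom_length,
                     gc_fraction = gc_fraction,
                     motifs_per_chrom = motifs_per_chrom, seed = seed))
}

place_genes <- function(chrom_lengths, n_genes) {
  rows <- list()
  g <- 0L
  for (chrom in names(chrom_lengths)) {
    pos <- 3000L
    len <- chrom_lengths[[chrom]]
    repeat {
      if (g >= n_genes) break
      pos <- pos + sample(5500:9000, 1L)
      n_ex <- sample(2:5, 1L)
      widths <- sample(150:400, n_ex, replace = TRUE)
      introns <- if (n_ex > 1L) sample(500:2000, n_ex - 1L, replace = TRUE) else integer(0)
      tx_len <- sum(widths) + sum(introns)
      if (pos + tx_len + 3500L > len) break
      es <- integer(n_ex); ee <- integer(n_ex)
      cur <- pos
      for (k in seq_len(n_ex)) {
        es[k] <- cur
        ee[k] <- cur + widths[k]
        cur <- ee[k] + if (k < n_ex) introns[k] else 0L
      }
      g <- g + 1L
      cds_start <- es[1] + min(50L, widths[1] - 1L)
      cds_end <- ee[n_ex] - min(50L, widths[n_ex] - 1L)
      rows[[g]] <- data.frame(
        gene_name = sprintf("GENE%04d", g),
        transcript_id = sprintf("tx%04d", g),
        chrom = chrom, strand = sample(c("+", "-"), 1L),
        tx_start = pos, tx_end = pos + tx_len,
        cds_start = cds_start, cds_end = cds_end,
        exon_count = n_ex, stringsAsFactors = FALSE
      )
      rows[[g]]$exon_starts <- list(es)
      rows[[g]]$exon_ends <- list(ee)
      pos <- pos + tx_len
    }
    if (g >= n_genes) break
  }
  if (g < n_genes) stopf("genome too small: placed only %d of %d genes", g, n_genes)
  transcript_set(do.call(rbind, rows))
}

#' Simulate peaks and transcript models over a synthetic genome
#'
#' Gene bodies with 2-5 exons are placed without overlap; peaks are placed to
#' cover every annotation category (promoter, first exon, exon, intron,
#' downstream, intergenic), and a configurable fraction of peaks is centered
#' on planted canonical G4 motifs. Age effect categories are assigned to a
#' `1 - null_fraction` subset of peaks, round-robin across the four gain/loss
#' quadrants.
#'
#' @param sim output of [simulate_genome()].
#' @param n_genes number of gene models.
#' @param n_peaks number of peaks (shared universe for both assays); must be
#'   at least 8 times the number of effect categories.
#' @param motif_peak_fraction fraction of peaks centered on planted motifs.
#' @param null_fraction fraction of peaks with zero age effect (default 0.8).
#' @param beta_step |log2 change| per ordinal-age step at non-null peaks.
#' @param peak_width peak width in bp.
#' @param seed integer seed.
#' @return list with `peaks_atac` and `peaks_g4` ([peak_set()]s sharing
#'   coordinates), `transcripts`, and `truth` (per-peak effect table, planted
#'   categories, motif table, parameters).
#' @export
simulate_peaks_and_transcripts <- function(sim, n_genes = 60L, n_peaks = 500L,
                                           motif_peak_fraction = 0.25,
                                           null_fraction = 0.8,
                                           beta_step = 0.2,
                                           peak_width = 300L, seed = 1L) {
  if (n_peaks < 8L * (length(quadrant_categories) + 1L)) {
    stopf("n_peaks must be >= %d", 8L * (length(quadrant_categories) + 1L))
  }
  set.seed(seed)
  sizes <- chrom_sizes(sim$genome)
  tx <- if (n_genes > 0L) place_genes(sizes, n_genes) else NULL

  half <- peak_width %/% 2L
  motifs <- sim$motifs
  n_motif <- min(round(motif_peak_fraction * n_peaks), nrow(motifs))
  chosen <- if (n_motif > 0L) sample.int(nrow(motifs), n_motif) else integer(0)
  rows <- list()
  for (j in chosen) {
    cen <- (motifs$start[j] + motifs$end[j]) %/% 2L
    s <- max(0L, cen - half)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = motifs$chrom[j], start = s,
      end = min(sizes[[motifs$chrom[j]]], s + peak_width),
      planted_category = "motif", is_motif_peak = TRUE,
      stringsAsFactors = FALSE
    )
  }

  genic_cats <- c("promoter", "first_exon", "exon", "intron", "downstream")
  cats <- if (is.null(tx)) "intergenic" else c(genic_cats, "intergenic")
  # gene spans padded by promoter/downstream margins, for intergenic rejection
  if (!is.null(tx)) {
    pad_lo <- ifelse(tx$strand == "+", tx$tx_start - 2600L, tx$tx_start - 3100L)
    pad_hi <- ifelse(tx$strand == "+", tx$tx_end + 3100L, tx$tx_end + 2600L)
  }
  k <- 0L
  while (length(rows) < n_peaks) {
    k <- k + 1L
    cat_k <- cats[(k - 1L) %% length(cats) + 1L]
    if (cat_k == "intergenic") {
      ok <- FALSE
      for (try in 1:200) {
        chrom <- sample(names(sizes), 1L)
        s <- sample.int(sizes[[chrom]] - peak_width, 1L)
        if (is.null(tx) ||
            !any(tx$chrom == chrom & s < pad_hi & s + peak_width > pad_lo)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stopf("genome too small to place intergenic peaks")
      cen <- s + half
      chrom_k <- chrom
    } else {
      i <- sample.int(nrow(tx), 1L)
      es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
      plus <- tx$strand[i] == "+"
      n_ex <- tx$exon_count[i]
      cen <- switch(cat_k,
        promoter = if (plus) tx$tx_start[i] - 800L else tx$tx_end[i] + 800L,
        first_exon = if (plus) (es[1] + ee[1]) %/% 2L
                     else (es[n_ex] + ee[n_ex]) %/% 2L,
        exon = {
          j <- if (n_ex > 1L) (if (plus) n_ex else 1L) else 1L
          (es[j] + ee[j]) %/% 2L
        },
        intron = (ee[1] + es[2]) %/% 2L,
        downstream = if (plus) tx$tx_end[i] + 1500L else tx$tx_start[i] - 1500L
      )
      chrom_k <- tx$chrom[i]
    }
    s <- max(0L, cen - half)
    e <- min(sizes[[chrom_k]], s + peak_width)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom_k, start = s, end = e, planted_category = cat_k,
      is_motif_peak = FALSE, stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  df$peak_id <- sprintf("peak_%05d", seq_len(nrow(df)))

  # planted effects: round-robin quadrants over a (1 - null_fraction) subset
  n <- nrow(df)
  n_nonnull <- round((1 - null_fraction) * n)
  nonnull <- sample(df$peak_id, n_nonnull)
  eff <- data.frame(peak_id = df$peak_id, category = "null",
                    beta_atac = 0, beta_g4 = 0,
                    is_motif_peak = df$is_motif_peak,
                    planted_category = df$planted_category,
                    stringsAsFactors = FALSE)
  if (n_nonnull > 0L) {
    cat_i <- quadrant_categories[(seq_len(n_nonnull) - 1L) %% 4L + 1L]
    idx <- match(nonnull, eff$peak_id)
    eff$category[idx] <- cat_i
    eff$beta_atac[idx] <- ifelse(grepl("ATAC_gain", cat_i), beta_step, -beta_step)
    eff$beta_g4[idx] <- ifelse(grepl("G4_gain", cat_i), beta_step, -beta_step)
  }

  mk <- function(assay) peak_set(df$chrom, df$start, df$end,
                                 peak_id = df$peak_id, assay = assay,
                                 genome_id = "synthetic")
  list(
    peaks_atac = mk("ATAC"), peaks_g4 = mk("G4Q"),
    transcripts = tx,
    truth = list(peak_effects = eff, motifs = sim$motifs,
                 params = list(n_genes = n_genes, n_peaks = n_peaks,
                               motif_peak_fraction = motif_peak_fraction,
                               null_fraction = null_fraction,
                               beta_step = beta_step,
                               peak_width = peak_width, seed = seed))
  )
}

#' Simulate per-peak coverage for one assay
#'
#' Depth is negative binomial with mean
#' `base_mean_peak * 2^(beta * ordinal_age + u_culture) * lib_factor`, where
#' `u ~ N(0, culture_sd^2)` is shared by all replicates of a culture and the
#' library factor models sequencing-depth variation (removed downstream by the
#' trimmed-mean background normalization). `dispersion = Inf` gives the
#' Poisson limit. Also simulates per-base background coverage for the
#' normalization. Deterministic given `seed`.
#'
#' @param peaks a [peak_set()] (ids define the rows).
#' @param samples a [sample_sheet()].
#' @param beta per-peak log2 change per ordinal-age step (recycled if scalar).
#' @param base_mean expected depth at ordinal 0 for an average peak.
#' @param base_spread_log2 SD of per-peak log2 base means around `base_mean`.
#' @param dispersion negative binomial size parameter (`Inf` = Poisson).
#' @param culture_sd SD of the culture random intercept (log2 scale).
#' @param libsize_log2_sd SD of per-sample log2 library-size factors.
#' @param motif_boost multiplicative signal boost applied at `boost_peaks`.
#' @param boost_peaks peak ids receiving `motif_boost` (e.g. planted-motif
#'   peaks in the G4 assay).
#' @param background_mean expected background depth per base.
#' @param n_background number of background per-base values per sample.
#' @param seed integer seed.
#' @return list with `counts` (peaks x samples integer matrix), `background`
#'   (values x samples matrix), `culture_effects`, `lib_factors`,
#'   `base_mean_peak`, and `params`.
#' @export
simulate_coverage <- function(peaks, samples, beta = 0, base_mean = 50,
                              base_spread_log2 = 1, dispersion = 20,
                              culture_sd = 0.25, libsize_log2_sd = 0.25,
                              motif_boost = 1, boost_peaks = character(0),
                              background_mean = 2, n_background = 20000L,
                              seed = 1L) {
  if (base_mean <= 0) stopf("base_mean must be positive")
  if (dispersion <= 0) stopf("dispersion must be positive")
  set.seed(seed)
  ids <- peaks$peak_id
  n_pk <- length(ids)
  n_s <- nrow(samples)
  beta <- rep_len(beta, n_pk)
  ordinal <- encode_ordinal_age(samples$age_years)
  cultures <- unique(samples$culture_id)
  base_pk <- base_mean * 2^rnorm(n_pk, 0, base_spread_log2)
  base_pk[ids %in% boost_peaks] <- base_pk[ids %in% boost_peaks] * motif_boost
  u <- matrix(rnorm(length(cultures) * n_pk, 0, culture_sd),
              nrow = length(cultures), dimnames = list(cultures, ids))
  lib <- 2^rnorm(n_s, 0, libsize_log2_sd)
  names(lib) <- samples$sample_id
  draw <- function(mu) {
    if (is.infinite(dispersion)) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = dispersion)
  }
  counts <- matrix(0L, n_pk, n_s, dimnames = list(ids, samples$sample_id))
  for (s in seq_len(n_s)) {
    mu <- base_pk * 2^(beta * ordinal[s] + u[samples$culture_id[s], ]) * lib[s]
    counts[, s] <- draw(mu)
  }
  background <- matrix(0L, n_background, n_s,
                       dimnames = list(NULL, samples$sample_id))
  for (s in seq_len(n_s)) {
    background[, s] <- draw(rep(background_mean * lib[s], n_background))
  }
  list(counts = counts, background = background, culture_effects = u,
       lib_factors = lib, base_mean_peak = setNames(base_pk, ids),
       params = list(base_mean = base_mean, base_spread_log2 = base_spread_log2,
                     dispersion = dispersion, culture_sd = culture_sd,
                     libsize_log2_sd = libsize_log2_sd,
                     motif_boost = motif_boost,
                     background_mean = background_mean,
                     n_background = n_background, seed = seed))
}

#' Simulate a complete two-assay study with ground truth
#'
#' Convenience wrapper chaining [simulate_genome()],
#' [simulate_peaks_and_transcripts()] and [simulate_coverage()] for both
#' assays under one seed. Planted-motif peaks receive `g4_motif_boost` times
#' the base G4 signal, emulating G4 occupancy concentrating at canonical
#' motif loci.
#'
#' @param config a [pipeline_config()].
#' @return list with `genome_sim`, `peaks`, `samples`, `atac`, `g4`, `truth`.
#' @export
simulate_study <- function(config = pipeline_config()) {
  gs <- simulate_genome(config$n_chrom, config$chrom_length,
                        config$gc_fraction, config$motifs_per_chrom,
                        seed = derive_seed(config$seed, 1L))
  pk <- simulate_peaks_and_transcripts(gs, config$n_genes, config$n_peaks,
                                       config$motif_peak_fraction,
                                       config$null_fraction, config$beta_step,
                                       config$peak_width,
                                       seed = derive_seed(config$seed, 2L))
  samples <- default_sample_sheet(config$ages, config$replicates)
  eff <- pk$truth$peak_effects
  motif_ids <- eff$peak_id[eff$is_motif_peak]
  atac <- simulate_coverage(pk$peaks_atac, samples, beta = eff$beta_atac,
                            base_mean = config$atac_base_mean,
                            base_spread_log2 = config$base_spread_log2,
                            dispersion = config$dispersion,
                            culture_sd = config$culture_sd,
                            libsize_log2_sd = config$libsize_log2_sd,
                            background_mean = config$background_mean,
                            n_background = config$n_background,
                            seed = derive_seed(config$seed, 3L))
  g4 <- simulate_coverage(pk$peaks_g4, samples, beta = eff$beta_g4,
                          base_mean = config$g4_base_mean,
                          base_spread_log2 = config$base_spread_log2,
                          dispersion = config$dispersion,
                          culture_sd = config$culture_sd,
                          libsize_log2_sd = config$libsize_log2_sd,
                          motif_boost = config$g4_motif_boost,
                          boost_peaks = motif_ids,
                          background_mean = config$background_mean,
                          n_background = config$n_background,
                          seed = derive_seed(config$seed, 4L))
  truth <- pk$truth
  truth$culture_effects <- list(ATAC = atac$culture_effects,
                                G4Q = g4$culture_effects)
  truth$params$seed <- config$seed
  list(genome_sim = gs, peaks = pk, samples = samples,
       atac = atac, g4 = g4, truth = truth)
}
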