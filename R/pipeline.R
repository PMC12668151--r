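# End-to-end pipeline on synthetic data: chains every stage, writes each
# module's CSV outputs plus a JSON run manifest, deterministically for a
# given seed.

#' Pipeline configuration with study defaults
#'
#' Every tunable of the pipeline with its default: the study design (8
#' cultures aged 22-73, 2 replicates, two assays), the analysis constants
#' (log offset 0.1, trimmed-mean fraction 0.2, 15 bp slop, promoter
#' -2500/+250, 3 kb downstream, refinement thresholds 0.5 / 1.0 / 0.25 /
#' 3.0, presence thresholds 5 and 2, shrinkage confidence 0.70, age quadrant
#' threshold 0.05, ORA set sizes 50-200, GSEA set sizes 40-350, FDR cutoffs
#' 0.1-0.001) and the synthetic-data generator settings. Unknown keys are
#' rejected (as unused arguments).
#'
#' @param seed master seed for every source of randomness.
#' @param n_chrom,chrom_length,gc_fraction,motifs_per_chrom genome settings.
#' @param n_genes,n_peaks,motif_peak_fraction,null_fraction,beta_step,peak_width
#'   peak/transcript settings.
#' @param ages,replicates study design.
#' @param atac_base_mean,g4_base_mean,base_spread_log2,dispersion,culture_sd,libsize_log2_sd,g4_motif_boost,background_mean,n_background
#'   coverage generator settings.
#' @param offset,lowess_span differential settings.
#' @param promoter_up,promoter_down,downstream_len,slop_pad annotation
#'   settings.
#' @param signal_min,m_min,a_min,hc_log2_g4 refinement thresholds.
#' @param presence_atac,presence_g4 presence thresholds.
#' @param confidence,quadrant_threshold,fdr_cutoffs,fdr_max integration
#'   settings.
#' @param p_cut,ora_sizes,gsea_sizes,n_perm,n_gene_sets,gene_set_sizes
#'   enrichment settings.
#' @param trim trimmed-mean fraction for normalization.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_chrom = 2L, chrom_length = 2500000L,
                            gc_fraction = 0.41, motifs_per_chrom = 300L,
                            n_genes = 400L, n_peaks = 2000L,
                            motif_peak_fraction = 0.25, null_fraction = 0.8,
                            beta_step = 0.2, peak_width = 300L,
                            ages = c(22L, 24L, 32L, 34L, 53L, 56L, 72L, 73L),
                            replicates = 2L,
                            atac_base_mean = 50, g4_base_mean = 10,
                            base_spread_log2 = 1, dispersion = 20,
                            culture_sd = 0.25, libsize_log2_sd = 0.25,
                            g4_motif_boost = 8, background_mean = 2,
                            n_background = 20000L,
                            trim = 0.20, offset = 0.1, lowess_span = 0.5,
                            promoter_up = 2500L, promoter_down = 250L,
                            downstream_len = 3000L, slop_pad = 15L,
                            signal_min = 0.5, m_min = 1.0, a_min = 0.25,
                            hc_log2_g4 = 3.0,
                            presence_atac = 5, presence_g4 = 2,
                            confidence = 0.70, quadrant_threshold = 0.05,
                            fdr_cutoffs = c(0.1, 0.05, 0.01, 0.005, 0.001),
                            fdr_max = 0.10,
                            p_cut = 0.05, ora_sizes = c(50L, 200L),
                            gsea_sizes = c(40L, 350L), n_perm = 1000L,
                            n_gene_sets = 25L, gene_set_sizes = c(50L, 150L)) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full synthetic-data pipeline
#'
#' Simulates the study, then runs coverage normalization and summaries,
#' presence and intersection counts, annotation with canonical G4 flags, G4
#' peak refinement, per-assay ordinal-age differential analysis, shrinkage
#' and quadrant classification with FDR gain/loss counts and z-scored top
#' peaks, and context-split ORA + GSEA over simulated gene sets. Every stage
#' writes CSV (or FASTA/BED/GMT/JSON) outputs under `out_dir` and a manifest
#' with md5 checksums; the run is byte-identical for a given config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  files <- character(0)

  say("simulate: genome, transcripts, peaks, coverage")
  study <- simulate_study(config)
  write_genome(study$genome_sim$genome, file.path(out_dir, "genome.fa"))
  write_transcripts(study$peaks$transcripts,
                    file.path(out_dir, "transcripts.refflat"))
  write_peaks(study$peaks$peaks_atac, file.path(out_dir, "peaks_atac.narrowPeak"))
  write_peaks(study$peaks$peaks_g4, file.path(out_dir, "peaks_g4.narrowPeak"))
  atac_counts <- study$atac$counts
  g4_counts <- study$g4$counts
  files <- c(files, "genome.fa", "transcripts.refflat", "peaks_atac.narrowPeak",
             "peaks_g4.narrowPeak")
  write_stage_csv(data.frame(peak_id = rownames(atac_counts), atac_counts),
                  out_dir, "coverage_atac.csv")
  write_stage_csv(data.frame(peak_id = rownames(g4_counts), g4_counts),
                  out_dir, "coverage_g4.csv")
  truth_json <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(peak_effects = study$truth$peak_effects,
                            motifs = study$truth$motifs,
                            params = study$truth$params),
                       truth_json, auto_unbox = TRUE, digits = NA)
  files <- c(files, "coverage_atac.csv", "coverage_g4.csv", "truth.json")

  say("coverage: normalization, summaries, presence, intersections")
  f_atac <- normalization_factors(study$atac$background, config$trim)
  f_g4 <- normalization_factors(study$g4$background, config$trim)
  atac_norm <- sweep(atac_counts, 2L, f_atac, `*`)
  g4_norm <- sweep(g4_counts, 2L, f_g4, `*`)
  write_stage_csv(data.frame(sample_id = study$samples$sample_id,
                             factor_atac = f_atac, factor_g4 = f_g4),
                  out_dir, "normalization_factors.csv")
  write_stage_csv(coverage_replicate_stats(atac_norm), out_dir,
                  "coverage_summary_atac.csv")
  write_stage_csv(coverage_replicate_stats(g4_norm), out_dir,
                  "coverage_summary_g4.csv")
  pres_atac <- presence_matrix(atac_norm, study$samples, config$presence_atac)
  pres_g4 <- presence_matrix(g4_counts, study$samples, config$presence_g4)
  write_stage_csv(data.frame(peak_id = rownames(pres_atac), pres_atac),
                  out_dir, "presence_atac.csv")
  write_stage_csv(data.frame(peak_id = rownames(pres_g4), pres_g4),
                  out_dir, "presence_g4.csv")
  write_stage_csv(intersection_counts(pres_atac), out_dir,
                  "intersections_atac.csv")
  write_stage_csv(intersection_counts(pres_g4), out_dir,
                  "intersections_g4.csv")
  files <- c(files, "normalization_factors.csv", "coverage_summary_atac.csv",
             "coverage_summary_g4.csv", "presence_atac.csv", "presence_g4.csv",
             "intersections_atac.csv", "intersections_g4.csv")

  say("annotate: hierarchy, TSS context, canonical G4 motifs")
  annotation <- annotate_peak_set(study$peaks$peaks_atac,
                                  study$peaks$transcripts,
                                  genome = study$genome_sim$genome,
                                  promoter_up = config$promoter_up,
                                  promoter_down = config$promoter_down,
                                  downstream_len = config$downstream_len,
                                  pad = config$slop_pad)
  write_stage_csv(annotation, out_dir, "annotation.csv")
  files <- c(files, "annotation.csv")

  say("refine: M/A filter")
  refinement <- refine_g4_peaks(rownames(atac_norm), rowMeans(atac_norm),
                                rowMeans(g4_norm),
                                signal_min = config$signal_min,
                                m_min = config$m_min, a_min = config$a_min,
                                hc_log2_g4 = config$hc_log2_g4)
  write_stage_csv(refinement, out_dir, "refinement.csv")
  canon <- annotation$canonical_g4[match(refinement$peak_id,
                                         annotation$peak_id)]
  fold <- motif_enrichment_fold(canon, refinement$high_confidence)
  files <- c(files, "refinement.csv")

  say("differential: ordinal-age regression per assay")
  diff_atac <- age_regression(atac_norm, study$samples,
                              offset = config$offset,
                              span = config$lowess_span)
  diff_g4 <- age_regression(g4_norm, study$samples, offset = config$offset,
                            span = config$lowess_span)
  write_stage_csv(diff_atac$table, out_dir, "differential_atac.csv")
  write_stage_csv(diff_g4$table, out_dir, "differential_g4.csv")
  jsonlite::write_json(
    list(atac = list(d0 = diff_atac$d0, s0_2 = diff_atac$s0_2,
                     rho = diff_atac$rho, ordinal_map = diff_atac$ordinal_map),
         g4 = list(d0 = diff_g4$d0, s0_2 = diff_g4$s0_2, rho = diff_g4$rho,
                   ordinal_map = diff_g4$ordinal_map)),
    file.path(out_dir, "differential_model.json"),
    auto_unbox = TRUE, digits = NA)
  files <- c(files, "differential_atac.csv", "differential_g4.csv",
             "differential_model.json")

  say("integrate: shrinkage, quadrants, FDR counts, z-scored top peaks")
  sh_atac <- shrink_effect(diff_atac$table$logFC, diff_atac$table$p_value,
                           config$confidence)
  sh_g4 <- shrink_effect(diff_g4$table$logFC, diff_g4$table$p_value,
                         config$confidence)
  quad <- classify_quadrant(sh_atac$shrunk_logfc, sh_g4$shrunk_logfc,
                            config$quadrant_threshold, "Age ")
  write_stage_csv(data.frame(peak_id = diff_atac$table$peak_id,
                             atac_raw_logfc = sh_atac$raw_logfc,
                             atac_p = sh_atac$p_value,
                             atac_shrunk = sh_atac$shrunk_logfc,
                             g4_raw_logfc = sh_g4$raw_logfc,
                             g4_p = sh_g4$p_value,
                             g4_shrunk = sh_g4$shrunk_logfc,
                             quad), out_dir, "quadrants.csv")
  write_stage_csv(count_by_fdr(diff_atac$table$fdr, diff_atac$table$logFC,
                               config$fdr_cutoffs),
                  out_dir, "fdr_counts_atac.csv")
  write_stage_csv(count_by_fdr(diff_g4$table$fdr, diff_g4$table$logFC,
                               config$fdr_cutoffs),
                  out_dir, "fdr_counts_g4.csv")
  ztop <- suppressWarnings(
    select_top_and_zscore(log(config$offset + atac_norm),
                          diff_atac$table$fdr, config$fdr_max))
  write_stage_csv(data.frame(peak_id = rownames(ztop), ztop), out_dir,
                  "zscore_top_atac.csv")
  files <- c(files, "quadrants.csv", "fdr_counts_atac.csv",
             "fdr_counts_g4.csv", "zscore_top_atac.csv")

  say("enrich: context-split ORA and preranked GSEA")
  genes <- study$peaks$transcripts$gene_name
  set.seed(derive_seed(config$seed, 7L))
  sizes <- sample(config$gene_set_sizes[1]:config$gene_set_sizes[2],
                  config$n_gene_sets, replace = TRUE)
  gene_sets <- lapply(sizes, function(k) sample(genes, min(k, length(genes))))
  names(gene_sets) <- sprintf("SET_%03d", seq_along(gene_sets))
  write_gmt(gene_sets, file.path(out_dir, "gene_sets.gmt"))
  contexts <- split_contexts(diff_atac$table, annotation, config$p_cut)
  ora_res <- ora(contexts, gene_sets, config$ora_sizes)
  gsea_res <- gsea_contexts(contexts, gene_sets, config$n_perm,
                            derive_seed(config$seed, 8L), config$gsea_sizes)
  write_stage_csv(ora_res, out_dir, "ora.csv")
  write_stage_csv(gsea_res, out_dir, "gsea.csv")
  files <- c(files, "gene_sets.gmt", "ora.csv", "gsea.csv")

  manifest <- list(
    package = "g4atac",
    version = as.character(utils::packageVersion("g4atac")),
    seed = config$seed,
    config = config[setdiff(names(config), "class")],
    motif_enrichment_fold = fold,
    files = lapply(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(study = study, factors = list(atac = f_atac, g4 = f_g4),
                 atac_norm = atac_norm, g4_norm = g4_norm,
                 presence = list(atac = pres_atac, g4 = pres_g4),
                 annotation = annotation, refinement = refinement,
                 motif_enrichment_fold = fold,
                 differential = list(atac = diff_atac, g4 = diff_g4),
                 shrunk = list(atac = sh_atac, g4 = sh_g4),
                 quadrants = quad, ora = ora_res, gsea = gsea_res,
                 files = file.path(out_dir, files)))
}
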