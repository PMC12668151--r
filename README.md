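# g4atac

Integrative analysis of chromatin accessibility (ATAC-seq) and
G-quadruplex occupancy (G4 CUT&Tag) across an ordinal age series.

Aging cells remodel both their accessible chromatin and the landscape of
G-quadruplex (G4) DNA structures, and the two do not move in lockstep: a
locus can close while gaining G4 occupancy, or open while losing it.
`g4atac` provides a tested, reusable implementation of the analysis chain
needed to ask these questions on paired ATAC-seq / G4 CUT&Tag profiles of
the same donors:

* **Coverage**: 50 bp cutsite intervals, per-peak `max_depth` / `avg_depth`
  / `norm_depth` with a background-anchored normalization factor
  `f = 1 / (20% trimmed-mean non-peak coverage)`, blacklist and chromosome
  filters, moderate-abundance presence calls (ATAC mean normalized depth
  ≥ 5, G4 mean raw depth ≥ 2 per culture), and UpSet-style exact-subset
  intersection counts.
* **Annotation**: hierarchical labels
  `first exon > promoter > exon > 5'UTR > 3'UTR > intron > downstream >
  intergenic` (promoter = TSS −2.5 kb / +250 bp, downstream = 3 kb), TSS
  distances, and canonical G4 motif detection with the pattern
  `G{3,}[ATGC]{1,7}G{3,}[ATGC]{1,7}G{3,}[ATGC]{1,7}G{3,}` on peaks slopped
  by 15 bp.
* **Refinement**: the multi-step M/A filter — keep peaks with mean
  normalized signal > 0.5 in both assays, else `M = ½(log₂ATAC + log₂G4Q)
  ≥ 1.0` and `A = ½(log₂G4Q − log₂ATAC) ≥ 0.25`, then flag
  `log₂(G4Q) ≥ 3.0` as high confidence — with its canonical-motif
  enrichment-fold readout.
* **Differential**: `log(0.1 + x)` transform, lowess variance-trend inverse
  weights, ordinal age encoding (1 for the youngest age, 2 for the next, …)
  as a continuous predictor, a consensus culture (block) correlation fed
  into per-peak GLS, empirical-Bayes moderated t statistics, per-culture
  contrasts, and BH FDR.
* **Integration**: conservative effect shrinkage
  `shrunk = sign(lfc)·|lfc|·max(0, 1 − z_c/z_obs)` with
  `z_obs = Φ⁻¹(1 − p/2)` and 70% confidence by default, gain/loss/neutral
  quadrant classification (±0.05 log₂ per age step; ±0.25 for knockdown
  contrasts), FDR-cutoff gain/loss counts, and z-scored top-peak matrices.
* **Enrichment**: genic/intergenic context splitting, hypergeometric ORA
  (set sizes 50–200), permutation preranked GSEA (set sizes 40–350), and
  Fisher combination of the per-context p-values.
* **Synthetic data**: genomes with planted canonical G4 motifs, transcript
  models, peaks covering every annotation category, and negative-binomial
  coverage with planted age effects in all four gain/loss quadrants, a
  culture random intercept, and library-size variation — with full ground
  truth for recovery tests.

## Worked example

```r
library(g4atac)

out <- file.path(tempdir(), "demo")
res <- run_pipeline(pipeline_config(seed = 11), out)

res$motif_enrichment_fold
#> [1] 1.942557

table(res$quadrants$label)["Age ATAC Loss | Age G4 Gain"]
#> Age ATAC Loss | Age G4 Gain
#>                          81

head(res$differential$atac$table, 3)
#>      peak_id      logFC        t    p_value       fdr
#> 1 peak_00001  0.2188815  4.05449 0.00009237 0.0016949
#> 2 peak_00002 -0.0075828 -0.11742 0.90673776 0.9756918
#> 3 peak_00003 -0.0290943 -0.50516 0.61442678 0.9062342
```

`run_pipeline()` simulates the default study (8 cultures aged 22–73 years,
2 replicates, 2,000 shared peaks, two assays), then chains normalization,
annotation, refinement, differential regression, quadrant integration and
enrichment, writing each stage's CSV plus a JSON manifest into `out`. In
the output above: the refined high-confidence G4 set is ~1.9× enriched for
canonical motifs relative to the unfiltered universe (planted-motif peaks
carry boosted G4 signal); 81 peaks are classified as losing accessibility
while gaining G4 with age; and the differential table reports each peak's
log₂ change per ordinal-age step with its moderated statistic, p-value and
FDR — `peak_00001` is a planted age-gain peak (true slope +0.2 log₂/step)
recovered at 0.219.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R --seed 11 --out pipeline_out
```

## Layout

```
R/                      implementation (io, synthetic, coverage, annotation,
                        refinement, differential, integration, enrichment,
                        pipeline)
tests/testthat/         unit, property and acceptance tests with
                        independent oracles
scripts/acceptance.R    headline-quantity reproduction script
vignettes/              methods vignette (model, assumptions, design choices)
inst/scripts/           command-line pipeline wrapper
```
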