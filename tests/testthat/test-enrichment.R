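make_diff_annot <- function(n_genic = 120, n_inter = 80, seed = 161) {
  set.seed(seed)
  n <- n_genic + n_inter
  genes <- sprintf("GENE%04d", seq_len(n))
  diff <- data.frame(peak_id = sprintf("p%04d", seq_len(n)),
                     logFC = rnorm(n), t = rnorm(n),
                     p_value = runif(n), stringsAsFactors = FALSE)
  annot <- data.frame(peak_id = diff$peak_id,
                      category = c(rep("exon", n_genic),
                                   rep("intergenic", n_inter)),
                      enrichment_gene = genes, stringsAsFactors = FALSE)
  list(diff = diff, annot = annot)
}

test_that("context splitting dedups genes by best |t| and ranks them", {
  d <- data.frame(peak_id = c("a", "b", "c"),
                  logFC = c(1, -0.5, 2), t = c(3, -1, 5),
                  p_value = c(0.01, 0.2, 0.001))
  an <- data.frame(peak_id = c("a", "b", "c"),
                   category = c("exon", "exon", "intergenic"),
                   enrichment_gene = c("G1", "G1", "G2"))
  ctx <- split_contexts(d, an)
  # gene hit by two peaks keeps the t = +3 peak
  expect_equal(ctx$genic$universe, "G1")
  expect_equal(unname(ctx$genic$ranks["G1"]), 3)
  expect_equal(ctx$genic$up, "G1")
  expect_equal(length(ctx$genic$down), 0L)
  expect_equal(ctx$intergenic$universe, "G2")
  # non-significant peaks enter no directional list
  d2 <- d
  d2$p_value <- c(0.5, 0.5, 0.5)
  ctx2 <- split_contexts(d2, an)
  expect_equal(length(ctx2$genic$up), 0L)
  # dropped peaks without an enrichment gene are counted
  an3 <- an
  an3$enrichment_gene[3] <- NA
  expect_equal(split_contexts(d, an3)$n_dropped, 1L)
})

test_that("hypergeometric p matches exhaustive enumeration", {
  expect_equal(hypergeom_p(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeom_p(0, 5, 4, 10), 1.0)
  expect_equal(hypergeom_p(4, 10, 4, 10), 1.0)      # K = N
  expect_error(hypergeom_p(5, 4, 4, 10), "inconsistent")
  # full enumeration over all N <= 12 configurations
  for (N in 2:12) {
    for (K in 1:N) {
      for (n in 1:N) {
        for (k in 0:min(K, n)) {
          want <- sum(dhyper(k:min(K, n), K, N - K, n))
          expect_equal(hypergeom_p(k, K, n, N), want, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("Fisher combination matches the even-df closed form", {
  x <- -4 * log(0.05)
  expect_equal(fisher_combine(c(0.05, 0.05)), exp(-x / 2) * (1 + x / 2),
               tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1, 1)), 1.0)
  expect_equal(fisher_combine(0.37), 0.37, tolerance = 1e-12)
  expect_error(fisher_combine(numeric(0)), "no p-values")
  # combining more copies of the same small p grows the evidence
  ps <- vapply(1:4, function(k) fisher_combine(rep(0.05, k)), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("ORA enforces size limits and detects a planted set", {
  # 300 genic genes; 50 of them strongly up-regulated, all inside one set
  set.seed(162)
  n <- 300
  diff <- data.frame(peak_id = sprintf("p%04d", 1:n),
                     logFC = c(rep(2, 50), rnorm(n - 50)),
                     t = c(rep(8, 50), rnorm(n - 50)),
                     p_value = c(rep(1e-6, 50), runif(n - 50, 0.2, 1)))
  annot <- data.frame(peak_id = diff$peak_id, category = "exon",
                      enrichment_gene = sprintf("GENE%04d", 1:n))
  ctx <- split_contexts(diff, annot)
  planted <- unique(c(ctx$genic$up, sample(ctx$genic$universe, 20)))
  sets <- c(list(PLANTED = planted,
                 TINY = sample(ctx$genic$universe, 10),
                 HUGE = ctx$genic$universe),            # 300 > 200: skipped
            lapply(1:20, function(i) sample(ctx$genic$universe, 60)))
  names(sets)[4:23] <- sprintf("DECOY%02d", 1:20)
  res <- ora(ctx, sets, size_limits = c(50, 200))
  expect_true(is.na(res$p_up_genic[res$set == "TINY"]))
  expect_true(is.na(res$p_up_genic[res$set == "HUGE"]))
  p_planted <- res$p_up_genic[res$set == "PLANTED"]
  expect_lt(p_planted, 1e-10)
  expect_true(all(p_planted < res$p_up_genic[grepl("DECOY", res$set)],
                  na.rm = TRUE))
  # universe order does not matter
  ctx_perm <- ctx
  perm <- sample(seq_along(ctx$genic$universe))
  ctx_perm$genic$universe <- ctx$genic$universe[perm]
  res2 <- ora(ctx_perm, sets, size_limits = c(50, 200))
  expect_equal(res2$p_up_genic, res$p_up_genic)
})

test_that("the running-sum enrichment score matches hand enumeration", {
  # 4 genes scored (4, 3, 2, 1); the set holding only the top gene reaches 1
  scores <- c(4, 3, 2, 1)
  expect_equal(gsea_es(scores, 1L), 1.0)
  # oracle comparison on random configurations
  set.seed(171)
  for (i in 1:200) {
    N <- sample(10:80, 1)
    k <- sample(2:(N - 1), 1)
    sc <- sort(rnorm(N), decreasing = TRUE)
    hits <- sort(sample.int(N, k))
    expect_equal(gsea_es(sc, hits), oracle_es(sc, hits), tolerance = 1e-12)
  }
})

test_that("preranked GSEA is reproducible, bounded, and skips degenerate
           sets", {
  set.seed(172)
  genes <- sprintf("g%03d", 1:200)
  ranks <- setNames(rnorm(200), genes)
  sets <- list(TOP = names(sort(ranks, decreasing = TRUE))[1:45],
               RAND = sample(genes, 45),
               ALL = genes,
               SMALL = genes[1:5])
  r1 <- preranked_gsea(ranks, sets, n_perm = 200, seed = 3,
                       size_limits = c(40, 350))
  r2 <- preranked_gsea(ranks, sets, n_perm = 200, seed = 3,
                       size_limits = c(40, 350))
  expect_identical(r1, r2)
  expect_false("ALL" %in% r1$set)      # empty complement
  expect_false("SMALL" %in% r1$set)
  expect_gte(min(r1$p_pos), 1 / 201)   # +1 correction floor
  expect_gt(r1$es[r1$set == "TOP"], 0)
  expect_lt(r1$p_pos[r1$set == "TOP"], 0.05)
})

test_that("GSEA empirical p-values are calibrated under a random ranking", {
  set.seed(173)
  genes <- sprintf("g%04d", 1:1000)
  ranks <- setNames(rnorm(1000), genes)
  sets <- lapply(1:1000, function(i) sample(genes, 50))
  names(sets) <- sprintf("S%04d", seq_along(sets))
  res <- preranked_gsea(ranks, sets, n_perm = 1000, seed = 174,
                        size_limits = c(40, 350))
  expect_equal(nrow(res), 1000L)
  expect_lt(abs(mean(res$p_pos < 0.05) - 0.05), 0.02)
})

test_that("context-combined GSEA reports Fisher p-values per direction", {
  ma <- make_diff_annot(n_genic = 150, n_inter = 120, seed = 175)
  ctx <- split_contexts(ma$diff, ma$annot)
  sets <- lapply(1:5, function(i)
    sample(c(ctx$genic$universe, ctx$intergenic$universe), 60))
  names(sets) <- sprintf("S%d", 1:5)
  res <- gsea_contexts(ctx, sets, n_perm = 200, seed = 9,
                       size_limits = c(10, 350))
  expect_true(all(c("fisher_up", "fisher_down") %in% names(res)))
  expect_true(all(res$fisher_up > 0 & res$fisher_up <= 1))
  # Fisher combination uses exactly the context p-values present
  i <- 1
  want <- fisher_combine(c(res$p_pos_genic[i], res$p_pos_intergenic[i]))
  expect_equal(res$fisher_up[i], want)
})

test_that("GMT round trip preserves the gene sets", {
  sets <- list(A = c("G1", "G2", "G3"), B = c("G9", "G2"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
})
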