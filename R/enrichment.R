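# Enrichment module: context-split (genic vs intergenic) over-representation
# with hypergeometric tests, Fisher combination across contexts, and a
# permutation preranked GSEA.

#' Read gene sets from a GMT file
#' @param path GMT file (set name, description, member genes per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stopf("malformed GMT line %d", bad[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Split differential results into genic/intergenic gene lists and ranks
#'
#' Merges per-peak differential statistics with the annotation, assigns each
#' peak's enrichment gene to the genic or intergenic context, deduplicates
#' genes hit by several peaks by keeping the peak with the largest
#' |moderated t|, and builds directional lists (up: positive effect with
#' `p < p_cut`; down: symmetric) plus a moderated-t rank vector per context.
#'
#' @param diff_table data frame with `peak_id`, `logFC`, `t`, `p_value`.
#' @param annotation data frame with `peak_id`, `category`,
#'   `enrichment_gene`.
#' @param p_cut significance cut defining the directional lists (default
#'   0.05).
#' @return list with one element per context (`genic`, `intergenic`), each
#'   holding `universe`, `up`, `down`, and `ranks` (named t vector, sorted
#'   decreasing with ties broken by gene name), plus `n_dropped` (peaks
#'   without an enrichment gene).
#' @export
split_contexts <- function(diff_table, annotation, p_cut = 0.05) {
  m <- merge(diff_table, annotation[, c("peak_id", "category",
                                        "enrichment_gene")], by = "peak_id")
  dropped <- sum(is.na(m$enrichment_gene))
  m <- m[!is.na(m$enrichment_gene), , drop = FALSE]
  if (!nrow(m)) stopf("empty enrichment universe")
  m$context <- ifelse(m$category == "intergenic", "intergenic", "genic")
  out <- list()
  for (ctx in c("genic", "intergenic")) {
    sub <- m[m$context == ctx, , drop = FALSE]
    if (!nrow(sub)) {
      out[[ctx]] <- list(universe = character(0), up = character(0),
                         down = character(0), ranks = numeric(0))
      next
    }
    sub <- sub[order(-abs(sub$t), sub$peak_id), , drop = FALSE]
    sub <- sub[!duplicated(sub$enrichment_gene), , drop = FALSE]
    ranks <- setNames(sub$t, sub$enrichment_gene)
    ranks <- ranks[order(-ranks, names(ranks))]
    out[[ctx]] <- list(
      universe = sub$enrichment_gene,
      up = sub$enrichment_gene[sub$logFC > 0 & sub$p_value < p_cut],
      down = sub$enrichment_gene[sub$logFC < 0 & sub$p_value < p_cut],
      ranks = ranks
    )
  }
  out$n_dropped <- dropped
  out
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for the overlap of a size-`n` selection with a size-`K` set
#' in a universe of `N` genes.
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n selection (list) size.
#' @param N universe size.
#' @return the upper-tail p-value.
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0 || k > min(K, n) || K > N || n > N) {
    stopf("inconsistent hypergeometric counts")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher's method for combining p-values
#'
#' `X2 = -2 sum(log p)` referred to a chi-squared distribution with `2k`
#' degrees of freedom. Zeros are floored at 1e-300.
#'
#' @param p p-values in `(0, 1]`.
#' @return the combined p-value.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stopf("no p-values to combine")
  if (any(p <= 0 | p > 1)) {
    if (any(p > 1)) stopf("p-values must be in (0, 1]")
  }
  p <- pmax(p, 1e-300)
  x2 <- -2 * sum(log(p))
  pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Context-split over-representation analysis
#'
#' For each gene set and each context, hypergeometric tests of the up- and
#' down-regulated lists against the context universe; sets whose
#' intersection with a context universe falls outside `size_limits` are
#' skipped in that context. The per-context directional p-values are
#' combined with Fisher's method into one up and one down p-value per set,
#' BH-adjusted across sets.
#'
#' @param contexts output of [split_contexts()].
#' @param gene_sets named list of gene vectors.
#' @param size_limits inclusive set-size limits after universe intersection
#'   (default `c(50, 200)`).
#' @return data frame with the four context p-values, `fisher_up`,
#'   `fisher_down`, `fdr_up`, `fdr_down` per retained set.
#' @export
ora <- function(contexts, gene_sets, size_limits = c(50L, 200L)) {
  rows <- lapply(names(gene_sets), function(nm) {
    set <- gene_sets[[nm]]
    ps <- list(up_genic = NA_real_, up_intergenic = NA_real_,
               down_genic = NA_real_, down_intergenic = NA_real_)
    for (ctx in c("genic", "intergenic")) {
      U <- contexts[[ctx]]$universe
      S <- intersect(set, U)
      if (length(S) < size_limits[1] || length(S) > size_limits[2]) next
      for (dir in c("up", "down")) {
        sel <- contexts[[ctx]][[dir]]
        ps[[paste0(dir, "_", ctx)]] <- hypergeom_p(
          length(intersect(S, sel)), length(S), length(sel), length(U))
      }
    }
    data.frame(set = nm, p_up_genic = ps$up_genic,
               p_up_intergenic = ps$up_intergenic,
               p_down_genic = ps$down_genic,
               p_down_intergenic = ps$down_intergenic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  comb <- function(a, b) {
    vapply(seq_along(a), function(i) {
      p <- c(a[i], b[i])
      if (all(is.na(p))) NA_real_ else fisher_combine(p[!is.na(p)])
    }, 0)
  }
  out$fisher_up <- comb(out$p_up_genic, out$p_up_intergenic)
  out$fisher_down <- comb(out$p_down_genic, out$p_down_intergenic)
  out$fdr_up <- NA_real_
  out$fdr_down <- NA_real_
  keep <- !is.na(out$fisher_up)
  out$fdr_up[keep] <- bh_fdr(out$fisher_up[keep])
  keep <- !is.na(out$fisher_down)
  out$fdr_down[keep] <- bh_fdr(out$fisher_down[keep])
  out
}

# weighted Kolmogorov-Smirnov running-sum enrichment score for hit positions
# (1-based indices into the decreasing-score ranking); weight = |score|
gsea_es <- function(scores, hit_idx) {
  N <- length(scores)
  k <- length(hit_idx)
  hit_idx <- sort(hit_idx)
  w <- abs(scores[hit_idx])
  W <- sum(w)
  if (W == 0) w <- rep(1, k)                 # all-zero scores: unweighted
  cw <- cumsum(if (W == 0) w / k else w / W)
  miss <- 1 / (N - k)
  at_hit <- cw - (hit_idx - seq_len(k)) * miss
  before_hit <- c(0, cw[-k]) - (hit_idx - 1 - (seq_len(k) - 1)) * miss
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' Permutation preranked gene-set enrichment
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment score with
#' weight `|score|`, against a gene-label permutation null (equivalently,
#' random hit positions of the same set size on the fixed ranking; one null
#' distribution is shared per distinct set size). One-sided empirical
#' p-values for positive and negative scores carry the +1 correction, so the
#' smallest attainable p is `1 / (n_perm + 1)`. Ties in score are broken
#' deterministically by gene name.
#'
#' @param ranks named numeric vector (gene -> score); names must be unique.
#' @param gene_sets named list of gene vectors.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param size_limits inclusive set-size limits after intersection with the
#'   ranked genes (default `c(40, 350)`); sets equal to the whole ranking
#'   are skipped (empty complement).
#' @return data frame `set`, `size`, `es`, `p_pos`, `p_neg`, `p` (the
#'   one-sided p on the side of the observed score sign).
#' @export
preranked_gsea <- function(ranks, gene_sets, n_perm = 1000L, seed = 1L,
                           size_limits = c(40L, 350L)) {
  if (anyDuplicated(names(ranks))) stopf("duplicate genes in rank vector")
  ord <- order(-ranks, names(ranks))
  scores <- as.numeric(ranks[ord])
  genes <- names(ranks)[ord]
  N <- length(scores)
  sizes <- vapply(gene_sets, function(s) length(intersect(s, genes)), 0L)
  keep <- which(sizes >= size_limits[1] & sizes <= size_limits[2] & sizes < N)
  if (!length(keep)) {
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      p_pos = numeric(0), p_neg = numeric(0), p = numeric(0)))
  }
  set.seed(seed)
  nulls <- list()
  for (k in sort(unique(sizes[keep]))) {
    nulls[[as.character(k)]] <- vapply(seq_len(n_perm), function(i) {
      gsea_es(scores, sample.int(N, k))
    }, 0)
  }
  rows <- lapply(keep, function(j) {
    k <- sizes[j]
    es <- gsea_es(scores, which(genes %in% gene_sets[[j]]))
    null <- nulls[[as.character(k)]]
    p_pos <- (1 + sum(null >= es)) / (n_perm + 1)
    p_neg <- (1 + sum(null <= es)) / (n_perm + 1)
    data.frame(set = names(gene_sets)[j], size = k, es = es,
               p_pos = p_pos, p_neg = p_neg,
               p = if (es >= 0) p_pos else p_neg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Context-split preranked GSEA with Fisher combination
#'
#' Runs [preranked_gsea()] on the genic and intergenic rank vectors and
#' combines, per set, the directional p-values across contexts with
#' Fisher's method (up uses the positive-side p, down the negative side).
#'
#' @param contexts output of [split_contexts()].
#' @param gene_sets named list of gene vectors.
#' @inheritParams preranked_gsea
#' @return data frame per set: per-context ES and p-values, `fisher_up`,
#'   `fisher_down`.
#' @export
gsea_contexts <- function(contexts, gene_sets, n_perm = 1000L, seed = 1L,
                          size_limits = c(40L, 350L)) {
  res <- list()
  for (ctx in c("genic", "intergenic")) {
    r <- contexts[[ctx]]$ranks
    res[[ctx]] <- if (length(r) >= 2L) {
      preranked_gsea(r, gene_sets, n_perm, derive_seed(seed, match(ctx, c("genic", "intergenic"))),
                     size_limits)
    } else {
      data.frame(set = character(0), size = integer(0), es = numeric(0),
                 p_pos = numeric(0), p_neg = numeric(0), p = numeric(0))
    }
  }
  all_sets <- union(res$genic$set, res$intergenic$set)
  if (!length(all_sets)) {
    return(data.frame(set = character(0)))
  }
  get <- function(df, set, col) {
    i <- match(set, df$set)
    if (is.na(i)) NA_real_ else df[[col]][i]
  }
  rows <- lapply(all_sets, function(nm) {
    pug <- get(res$genic, nm, "p_pos"); pui <- get(res$intergenic, nm, "p_pos")
    pdg <- get(res$genic, nm, "p_neg"); pdi <- get(res$intergenic, nm, "p_neg")
    data.frame(set = nm,
               es_genic = get(res$genic, nm, "es"),
               es_intergenic = get(res$intergenic, nm, "es"),
               p_pos_genic = pug, p_pos_intergenic = pui,
               p_neg_genic = pdg, p_neg_intergenic = pdi,
               fisher_up = fisher_combine(c(pug, pui)),
               fisher_down = fisher_combine(c(pdg, pdi)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
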