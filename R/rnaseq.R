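# Count-level transcriptomics stage: expression filtering, log-CPM
# normalisation, moderated differential-expression calls, DE-set
# comparison, hierarchical clustering and classical MDS.

#' Counts per million
#'
#' @param counts non-negative integer matrix (genes x samples).
#' @param lib_size per-sample library sizes; defaults to column sums.
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(counts, lib_size = colSums(counts)) {
  if (any(counts < 0)) stop_arginet("counts must be non-negative",
                                    "invalid_counts")
  if (any(lib_size <= 0)) stop_arginet("library sizes must be positive",
                                       "degenerate_sample")
  t(t(counts) / lib_size) * 1e6
}

#' Expression filter
#'
#' Keeps genes with `log(CPM + 0.25) > 0` — equivalently `CPM > 0.75`,
#' independent of the logarithm base — in at least `min_samples` samples.
#'
#' @param counts count matrix.
#' @param min_samples minimum number of samples above threshold (default 3).
#' @return logical gene mask (length `nrow(counts)`).
#' @export
filter_expressed <- function(counts, min_samples = 3L) {
  if (min_samples > ncol(counts)) {
    stop_arginet("min_samples exceeds the number of samples",
                 "invalid_threshold")
  }
  rowSums(cpm(counts) > 0.75) >= min_samples
}

#' Log2 counts-per-million
#'
#' `log2(CPM + prior)`: the prior makes zero counts finite and matches the
#' constant used by the expression filter. Scale-invariant: multiplying a
#' sample's column by a positive constant leaves its log-CPM unchanged.
#'
#' @param counts count matrix.
#' @param prior prior added to CPM before the log (default 0.25).
#' @return numeric matrix of log2-CPM values.
#' @export
normalize_logcpm <- function(counts, prior = 0.25) {
  log2(cpm(counts) + prior)
}

#' Moderated differential-expression test
#'
#' Per-gene two-sample t-test on log2-CPM values with empirical-Bayes
#' variance shrinkage toward the mean pooled variance:
#' `s2_shrunk = (d0 * s0^2 + d * s2) / (d0 + d)` with prior df `d0 = 4`,
#' `s0^2` the across-gene mean of the pooled variances, and `d` the
#' residual df. P-values use a t reference with `d0 + d` df;
#' Benjamini-Hochberg adjustment across tested genes. A gene is `called`
#' iff `|log2fc| > lfc_threshold` and `fdr < fdr_threshold`. This
#' moderated test is an operational approximation of a voom/limma fit,
#' not a reimplementation of it.
#'
#' @param expr log2-CPM matrix (genes x samples).
#' @param design sample design table.
#' @param contrast length-2 character `(A, B)`; log2fc is `mean(A) - mean(B)`.
#' @param lfc_threshold absolute log2 fold-change threshold (default 1).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param d0 prior degrees of freedom of the variance shrinkage.
#' @return data.frame (`gene_id`, `log2fc`, `statistic`, `p`, `fdr`,
#'   `called`), one row per gene of `expr`.
#' @export
test_de <- function(expr, design, contrast, lfc_threshold = 1,
                    fdr_threshold = 0.05, d0 = 4) {
  stopifnot(length(contrast) == 2L)
  sa <- design_samples(design, contrast[1L])
  sb <- design_samples(design, contrast[2L])
  if (length(sa) < 2 || length(sb) < 2) {
    stop_arginet("both conditions need >= 2 replicates", "invalid_design")
  }
  a <- expr[, sa, drop = FALSE]
  b <- expr[, sb, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var)
  vb <- apply(b, 1L, stats::var)
  d <- na + nb - 2L
  s2 <- ((na - 1L) * va + (nb - 1L) * vb) / d
  s2_prior <- mean(s2)
  s2_shrunk <- (d0 * s2_prior + d * s2) / (d0 + d)
  se <- sqrt(s2_shrunk * (1 / na + 1 / nb))
  lfc <- ma - mb
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(stat), df = d0 + d)
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(
    gene_id = rownames(expr),
    log2fc = lfc,
    statistic = stat,
    p = p,
    fdr = fdr,
    called = abs(lfc) > lfc_threshold & fdr < fdr_threshold,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Jaccard coefficient of two sets
#'
#' `|A intersect B| / |A union B|`. Both sets empty returns 1 by
#' convention (identical sets).
#'
#' @param set_a,set_b vectors treated as sets (duplicates ignored).
#' @return a proportion in `[0, 1]`.
#' @examples
#' jaccard(c("a", "b"), c("b", "c"))  # 1/3
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) return(1)
  length(intersect(set_a, set_b)) / u
}

#' Hierarchical clustering of the top differential genes
#'
#' Selects the `k` genes with largest absolute log2 fold change, z-scores
#' each gene's expression across samples (constant genes become all-zero
#' rows), and agglomerates samples and genes with complete linkage on
#' Euclidean distances.
#'
#' @param expr log2-CPM matrix.
#' @param de result of [test_de()] on the same genes.
#' @param k number of top genes (default 40).
#' @return list with `genes` (selected ids), `z` (z-scored submatrix),
#'   `gene_hclust`, `sample_hclust` and `sample_order` (leaf order).
#' @export
cluster_top_genes <- function(expr, de, k = 40L) {
  if (k < 1) stop_arginet("k must be positive", "invalid_k")
  if (k > nrow(expr)) stop_arginet("k exceeds the number of genes",
                                   "invalid_k")
  top <- de$gene_id[order(-abs(de$log2fc))][seq_len(k)]
  z <- zscore_rows(expr[top, , drop = FALSE])
  hs <- stats::hclust(stats::dist(t(z)), method = "complete")
  hg <- stats::hclust(stats::dist(z), method = "complete")
  list(genes = top, z = z, gene_hclust = hg, sample_hclust = hs,
       sample_order = hs$labels[hs$order])
}

#' Classical multidimensional scaling of samples
#'
#' Principal-coordinates embedding of Euclidean distances between sample
#' expression profiles; coordinates are centred at the origin.
#'
#' @param expr log2-CPM matrix (genes x samples).
#' @param dims embedding dimension (default 2).
#' @return numeric matrix (samples x dims).
#' @export
mds_coordinates <- function(expr, dims = 2L) {
  if (ncol(expr) < dims + 1L) {
    stop_arginet("need at least dims + 1 samples", "insufficient_samples")
  }
  coords <- stats::cmdscale(stats::dist(t(expr)), k = dims)
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  coords
}
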