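# Small in-code fixtures shared across the suite.

design_ab <- function(replicates = 4L) {
  gen_design(c("A", "B"), replicates = replicates)
}

# expression matrix with named genes/samples filled from a vector
make_expr <- function(values, n_genes, samples) {
  matrix(values, n_genes, length(samples),
         dimnames = list(sprintf("g%d", seq_len(n_genes)), samples))
}

# one perfectly separated gene: group A ranks 5-8, group B ranks 1-4
separated_expr <- function(n_genes = 1L) {
  e <- matrix(rep(c(10, 11, 12, 13, 1, 2, 3, 4), each = n_genes),
              n_genes, 8, byrow = FALSE)
  dimnames(e) <- list(sprintf("g%d", seq_len(n_genes)), paste0("s", 1:8))
  e
}

groups_ab <- function() list(a = paste0("s", 1:4), b = paste0("s", 5:8))

# independent brute-force complete-linkage agglomeration: returns sorted
# merge heights (oracle for hclust comparisons)
naive_complete_linkage_heights <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  sort(heights)
}

# small connected weighted graph used by the netint tests
toy_network <- function() {
  el <- data.frame(
    from = c("a", "b", "c", "a", "d"),
    to   = c("b", "c", "d", "c", "e"),
    weight = c(0.9, 0.8, 0.95, 0.5, 0.7)
  )
  igraph::graph_from_data_frame(el, directed = FALSE)
}

# minimal DE / SAM result tables for hit-set algebra
de_table <- function(ids, called, lfc = 2) {
  data.frame(gene_id = ids, log2fc = rep_len(lfc, length(ids)),
             statistic = rep_len(1, length(ids)),
             p = rep_len(0.01, length(ids)),
             fdr = rep_len(0.01, length(ids)),
             called = rep_len(called, length(ids)),
             stringsAsFactors = FALSE)
}
prot_table <- function(ids, significant, d = 3) {
  data.frame(protein_id = ids, d_stat = rep_len(d, length(ids)),
             q_value = rep_len(0.01, length(ids)),
             significant = rep_len(significant, length(ids)),
             stringsAsFactors = FALSE)
}
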