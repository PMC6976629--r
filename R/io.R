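# Readers and writers for the pipeline's plain-text interchange formats:
# counts TSV, design CSV, GMT gene sets, weighted edge lists (BioGRID-tab
# like), long-format isotopologue CSV, result tables and Newick dendrograms.

#' Read / write a gene x sample count matrix (TSV, header = sample ids)
#' @param path file path.
#' @return integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) {
    stop_arginet("counts must be non-negative", "invalid_counts")
  }
  m
}

#' @rdname read_counts_tsv
#' @param counts integer matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(data.frame(gene_id = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a sample design table (CSV: sample_id, condition, replicate)
#' @param path file path.
#' @export
read_design_csv <- function(path) {
  assert_design(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_design_csv
#' @param design design data.frame.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(assert_design(design), path, row.names = FALSE,
                   quote = FALSE)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional descriptions (default `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read / write a weighted undirected edge list (TSV: node_a, node_b, weight)
#'
#' On read, the graph is simplified (self-loops and duplicate edges
#' removed) and the largest connected component retained (reported via
#' [message()]), since the Steiner and subgraph stages require
#' connectivity.
#' @param path file path.
#' @return igraph with edge attribute `weight`.
#' @export
read_edges_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("node_a", "node_b", "weight")
  if (any(df$weight <= 0 | df$weight > 1)) {
    stop_arginet("edge weights must lie in (0, 1]", "invalid_interval")
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    keep <- which(comp$membership == which.max(comp$csize))
    message(sprintf("read_edges_tsv: retained largest component (%d of %d nodes)",
                    length(keep), igraph::vcount(g)))
    g <- igraph::induced_subgraph(g, keep)
  }
  g
}

#' @rdname read_edges_tsv
#' @param network igraph with edge attribute `weight`.
#' @export
write_edges_tsv <- function(network, path) {
  el <- igraph::as_data_frame(network, what = "edges")
  names(el)[1:2] <- c("node_a", "node_b")
  utils::write.table(el[, c("node_a", "node_b", "weight")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a long-format isotopologue table (CSV)
#' @param path file path.
#' @export
read_isotopologue_csv <- function(path) {
  assert_iso_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_isotopologue_csv
#' @param table isotopologue data.frame.
#' @export
write_isotopologue_csv <- function(table, path) {
  utils::write.csv(assert_iso_table(table), path, row.names = FALSE,
                   quote = FALSE)
}

#' Write a differential-expression or -abundance result table (TSV)
#' @param result data.frame from [test_de()] or [sam_test()].
#' @param path file path.
#' @export
write_result_tsv <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Export a dendrogram in Newick format
#' @param hc an `hclust` object (e.g. from [cluster_top_genes()]).
#' @param path file path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
}
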