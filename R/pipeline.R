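# End-to-end synthetic run: generators -> transcriptomics -> pathway
# permutation test -> proteomics -> network integration. One master seed
# drives every stage through deterministic substreams, so two invocations
# with the same seed are bit-identical.

#' Run the full synthetic multi-omics pipeline
#'
#' Generates a two-condition synthetic study (counts, pathways, proteome,
#' interactome), then runs expression filtering, log-CPM normalisation and
#' moderated DE calls, the rank-sum pathway permutation test with
#' Bonferroni correction, the proteomics pipeline (detection filter,
#' left-censored imputation, CV filter, s0-moderated permutation-FDR
#' test), and the network integration (hit prizes, PCST heuristic for both
#' hit layers, tree overlap and its connected-subgraph null).
#'
#' Sizes default to desk scale; they are arguments, not constants, so the
#' pipeline scales up unchanged.
#'
#' @param seed master seed; all stages derive substreams from it.
#' @param n_genes,n_proteins,n_pathways,n_network_nodes problem sizes.
#' @param n_perm_pathway,n_perm_sam,n_draws_null randomization counts.
#' @param conditions two condition labels for the synthetic contrast.
#' @return list with all intermediate and final objects (`design`,
#'   `counts`, `expr`, `de`, `pathperm`, `proteome`, `netint`).
#' @export
run_pipeline <- function(seed = 1, n_genes = 2000L, n_proteins = 600L,
                         n_pathways = 10L, n_network_nodes = 300L,
                         n_perm_pathway = 2000L, n_perm_sam = 250L,
                         n_draws_null = 200L,
                         conditions = c("RANKL", "RANKL/Arg-Depletion")) {
  design <- gen_design(conditions, replicates = 4L)
  sim <- gen_counts(n_genes, design, de_fraction = 0.1, lfc_magnitude = 3,
                    dispersion = 0.05, seed = derive_seed(seed, 1))
  keep <- filter_expressed(sim$counts)
  expr <- normalize_logcpm(sim$counts[keep, , drop = FALSE])
  de <- test_de(expr, design, contrast = conditions)
  pathways <- gen_pathways(rownames(expr), n_pathways,
                           size_range = c(10L, 30L),
                           seed = derive_seed(seed, 2))
  pp <- pathperm_collection(expr, pathways, design, contrast = conditions,
                            n_perm = n_perm_pathway,
                            seed = derive_seed(seed, 3))
  prot <- gen_proteome(n_proteins, design, effect_magnitude = 1.5,
                       missing_rate = 0.1, seed = derive_seed(seed, 4))
  prot_res <- proteome_pipeline(prot$intensity, design,
                                contrast = conditions,
                                n_perm = n_perm_sam,
                                seed = derive_seed(seed, 5))
  net <- gen_network(n_network_nodes, "scale_free",
                     seed = derive_seed(seed, 6))
  # map hits onto the network namespace: synthetic node ids stand in for
  # gene symbols, so hits are assigned to nodes deterministically by rank
  hits <- recarg1_effect_set(de, prot_res$result)
  nodes <- igraph::V(net)$name
  if (nrow(hits)) {
    # strongest hits only: the Steiner step integrates the top-scoring
    # changes, keeping the desk-scale tree search tractable
    hits <- hits[order(-hits$score), , drop = FALSE][seq_len(min(30L, nrow(hits))), ]
    hits$node <- nodes[((seq_len(nrow(hits)) - 1L) %% length(nodes)) + 1L]
    hits <- hits[!duplicated(hits$node), , drop = FALSE]
  }
  pc <- build_prizes_costs(net, hits)
  sol_a <- pcst_heuristic(net, pc$prizes, pc$costs)
  # second tree: the top half of hits by score, emulating the second hit set
  hits_b <- hits[hits$score >= stats::median(hits$score), , drop = FALSE]
  pc_b <- build_prizes_costs(net, hits_b)
  sol_b <- pcst_heuristic(net, pc_b$prizes, pc_b$costs)
  ov <- tree_overlap(sol_a, sol_b)
  null <- if (length(sol_a$nodes) && length(sol_b$nodes)) {
    overlap_null(net, length(sol_a$nodes), length(sol_b$nodes),
                 length(ov), n_draws = n_draws_null,
                 seed = derive_seed(seed, 7))
  } else NULL
  list(design = design, counts = sim$counts, truth = sim$truth,
       expr = expr, de = de, pathways = pathways, pathperm = pp,
       proteome = prot_res, network = net,
       netint = list(hits = hits, solution_a = sol_a, solution_b = sol_b,
                     overlap = ov, null = null))
}

#' Canonical form of a pipeline result for determinism checks
#'
#' igraph objects carry an internal environment whose identity differs
#' between constructions; this helper replaces each graph by its sorted
#' node and edge tables so two same-seed runs can be compared with
#' [identical()].
#'
#' @param result output of [run_pipeline()].
#' @return the result list with graphs replaced by plain data structures.
#' @export
pipeline_fingerprint <- function(result) {
  canon <- function(x) {
    if (inherits(x, "igraph")) {
      return(list(nodes = sort(igraph::V(x)$name),
                  edges = igraph::as_data_frame(x, what = "edges")))
    }
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, canon))
    x
  }
  canon(result)
}
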