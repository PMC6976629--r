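# Multi-omics network integration: hit sets from the transcriptomic and
# proteomic stages (including the exclusive-disjunction rule for the
# arginine-dependent RANKL program), prize/cost assignment, a greedy
# prize-collecting Steiner tree (PCST) heuristic with a brute-force oracle
# for small instances, and a connected-subgraph randomization null for the
# overlap between two trees.

#' Hit set for the arginase (recArg1) effect
#'
#' Union of significantly changed genes (RANKL vs RANKL/Arg-Depletion
#' expression) and proteins (RANKL/Arg-Rescue vs RANKL/Arg-Depletion
#' abundance), each scored by its effect size and tagged by omics layer.
#'
#' @param de_genes [test_de()] result (needs `gene_id`, `log2fc`, `called`).
#' @param da_proteins [sam_test()] result (needs `protein_id`, `d_stat`,
#'   `significant`).
#' @return data.frame (`node`, `score`, `layer`); a node present in both
#'   layers appears once per layer.
#' @export
recarg1_effect_set <- function(de_genes, da_proteins) {
  g <- de_genes[de_genes$called, , drop = FALSE]
  p <- da_proteins[da_proteins$significant, , drop = FALSE]
  rbind(
    if (nrow(g)) data.frame(node = g$gene_id, score = abs(g$log2fc),
                            layer = "transcriptome",
                            stringsAsFactors = FALSE),
    if (nrow(p)) data.frame(node = p$protein_id, score = abs(p$d_stat),
                            layer = "proteome", stringsAsFactors = FALSE)
  ) %||% data.frame(node = character(), score = numeric(),
                    layer = character(), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hit set for the arginine-dependent RANKL effect (exclusive disjunction)
#'
#' Genes: called in (M-CSF vs RANKL) or (M-CSF/Arg-Rescue vs
#' RANKL/Arg-Rescue) but NOT in (M-CSF/Arg-Starvation vs
#' RANKL/Arg-Starvation). Proteins: significant in the Arg-Rescue contrast
#' but not in the Arg-Starvation contrast.
#'
#' @param de_mcsf_rankl,de_rescue,de_starv [test_de()] results for the
#'   three gene contrasts.
#' @param prot_rescue,prot_starv [sam_test()] results for the two protein
#'   contrasts.
#' @return data.frame (`node`, `score`, `layer`); gene scores are the
#'   largest |log2fc| over the contrasts where the gene is called.
#' @export
arg_dependent_set <- function(de_mcsf_rankl, de_rescue, de_starv,
                              prot_rescue, prot_starv) {
  for (d in list(de_mcsf_rankl, de_rescue, de_starv)) {
    if (!all(c("gene_id", "log2fc", "called") %in% names(d))) {
      stop_arginet("a required gene contrast is missing or malformed",
                   "missing_contrast")
    }
  }
  for (d in list(prot_rescue, prot_starv)) {
    if (!all(c("protein_id", "d_stat", "significant") %in% names(d))) {
      stop_arginet("a required protein contrast is missing or malformed",
                   "missing_contrast")
    }
  }
  pos <- rbind(
    de_mcsf_rankl[de_mcsf_rankl$called, c("gene_id", "log2fc")],
    de_rescue[de_rescue$called, c("gene_id", "log2fc")]
  )
  excl <- de_starv$gene_id[de_starv$called]
  pos <- pos[!pos$gene_id %in% excl, , drop = FALSE]
  gene_score <- tapply(abs(pos$log2fc), pos$gene_id, max)
  pr <- prot_rescue[prot_rescue$significant, , drop = FALSE]
  pr <- pr[!pr$protein_id %in%
             prot_starv$protein_id[prot_starv$significant], , drop = FALSE]
  rbind(
    if (length(gene_score)) data.frame(node = names(gene_score),
                                       score = as.numeric(gene_score),
                                       layer = "transcriptome",
                                       stringsAsFactors = FALSE),
    if (nrow(pr)) data.frame(node = pr$protein_id, score = abs(pr$d_stat),
                             layer = "proteome", stringsAsFactors = FALSE)
  ) %||% data.frame(node = character(), score = numeric(),
                    layer = character(), stringsAsFactors = FALSE)
}

#' Node prizes and edge costs for the Steiner step
#'
#' Prize `beta * score` for hit nodes (maximum over layers when a node is
#' hit in both), 0 for all others; edge cost `1 - weight`, clamped to
#' `[1e-6, 1]` so fully confident edges still carry a strictly positive
#' penalty. Hits absent from the network are dropped with a message.
#'
#' @param network igraph with edge attribute `weight` in `(0, 1]`.
#' @param hits scored hit set (`node`, `score`).
#' @param beta prize scale (> 0).
#' @return list with `prizes` (named vector over all network nodes) and
#'   `costs` (numeric vector aligned with `E(network)`).
#' @export
build_prizes_costs <- function(network, hits, beta = 1) {
  if (beta <= 0) stop_arginet("beta must be positive", "invalid_beta")
  nodes <- igraph::V(network)$name
  prizes <- stats::setNames(rep(0, length(nodes)), nodes)
  if (nrow(hits)) {
    unmapped <- setdiff(hits$node, nodes)
    if (length(unmapped)) {
      message(sprintf("build_prizes_costs: %d hit(s) not in the network, dropped",
                      length(unmapped)))
      hits <- hits[hits$node %in% nodes, , drop = FALSE]
    }
    if (nrow(hits)) {
      sc <- tapply(hits$score, hits$node, max)
      prizes[names(sc)] <- beta * as.numeric(sc)
    }
  }
  w <- igraph::E(network)$weight
  list(prizes = prizes, costs = pmin(pmax(1 - w, 1e-6), 1))
}

# objective of a connected node set: collected prizes minus lambda times
# the cost of a minimum spanning tree of the induced subgraph
subset_objective <- function(g, prizes, lambda, ns) {
  pr <- sum(prizes[ns])
  if (length(ns) <= 1L) {
    return(list(objective = pr, edges = data.frame(from = character(),
                                                   to = character(),
                                                   cost = numeric())))
  }
  sub <- igraph::induced_subgraph(g, ns)
  mt <- igraph::mst(sub, weights = igraph::E(sub)$cost)
  el <- igraph::as_data_frame(mt, what = "edges")
  list(objective = pr - lambda * sum(el$cost),
       edges = data.frame(from = el$from, to = el$to, cost = el$cost,
                          stringsAsFactors = FALSE))
}

#' Greedy prize-collecting Steiner tree heuristic
#'
#' Starts from the maximum-prize node and repeatedly attaches the prized
#' node whose shortest cost-path to the current tree yields the largest
#' increase of `sum(prizes) - lambda * sum(tree edge costs)` (the tree is
#' re-extracted as a minimum spanning tree of the induced subgraph after
#' each attachment); stops when no attachment improves the objective, then
#' prunes zero-prize leaves. The greedy objective trace is monotone
#' non-decreasing by construction.
#'
#' @param network connected igraph with named nodes.
#' @param prizes named non-negative prize vector (from
#'   [build_prizes_costs()]).
#' @param costs edge costs aligned with `E(network)`.
#' @param lambda edge-cost scale (> 0).
#' @param n_roots number of greedy restarts, one from each of the
#'   top-prize nodes; the best tree is returned. Restarts guard against
#'   the single-root trap where the heaviest prize sits far from a
#'   cluster of cheaply connectable prizes.
#' @return object of class `steiner_solution`: `nodes`, `edges`
#'   (data.frame `from`, `to`, `cost`), `objective`, `trace`.
#' @export
pcst_heuristic <- function(network, prizes, costs, lambda = 1,
                           n_roots = 5L) {
  p <- stats::setNames(rep(0, igraph::vcount(network)),
                       igraph::V(network)$name)
  common <- intersect(names(prizes), names(p))
  p[common] <- prizes[common]
  if (all(p <= 0)) {
    message("pcst_heuristic: all prizes zero, returning empty solution")
    return(structure(list(nodes = character(),
                          edges = data.frame(from = character(),
                                             to = character(),
                                             cost = numeric()),
                          objective = 0, trace = numeric()),
                     class = "steiner_solution"))
  }
  g <- network
  igraph::E(g)$cost <- costs
  prized <- names(p)[p > 0]
  roots <- prized[order(-p[prized])][seq_len(min(n_roots, length(prized)))]
  best <- NULL
  for (root in roots) {
    sol <- pcst_greedy_from(g, p, lambda, root)
    if (is.null(best) || sol$objective > best$objective) best <- sol
  }
  best
}

# one greedy growth from a fixed root (best-improvement attachment, then
# zero-prize leaf pruning)
pcst_greedy_from <- function(g, p, lambda, root) {
  tree <- root
  cur <- subset_objective(g, p, lambda, tree)
  trace <- cur$objective
  cand <- setdiff(names(p)[p > 0], tree)
  while (length(cand)) {
    best <- NULL
    for (v in cand) {
      dv <- igraph::distances(g, v = v, to = tree,
                              weights = igraph::E(g)$cost)
      tgt <- tree[which.min(dv)]
      path <- igraph::shortest_paths(g, from = v, to = tgt,
                                     weights = igraph::E(g)$cost,
                                     output = "vpath")$vpath[[1]]
      ns <- union(tree, names(path))
      ob <- subset_objective(g, p, lambda, ns)
      if (ob$objective > cur$objective + 1e-12 &&
          (is.null(best) || ob$objective > best$ob$objective)) {
        best <- list(v = v, ns = ns, ob = ob)
      }
    }
    if (is.null(best)) break
    tree <- best$ns
    cur <- best$ob
    trace <- c(trace, cur$objective)
    cand <- setdiff(cand, tree)
  }
  # prune zero-prize leaves: each removal deletes one tree edge of positive
  # cost without losing any prize
  repeat {
    if (length(tree) <= 1L) break
    deg <- table(c(cur$edges$from, cur$edges$to))
    leaves <- names(deg)[deg == 1 & p[names(deg)] <= 0]
    if (!length(leaves)) break
    tree <- setdiff(tree, leaves)
    cur <- subset_objective(g, p, lambda, tree)
    trace <- c(trace, cur$objective)
  }
  structure(list(nodes = tree, edges = cur$edges,
                 objective = cur$objective, trace = trace),
            class = "steiner_solution")
}

#' Exact PCST by exhaustive enumeration (oracle for small graphs)
#'
#' Enumerates every non-empty node subset inducing a connected subgraph
#' and scores it as `sum(prizes) - lambda * MST cost`. Intended as an
#' independent optimum for validating the heuristic; limited to 15 nodes.
#'
#' @inheritParams pcst_heuristic
#' @return list (`nodes`, `objective`).
#' @export
pcst_exact <- function(network, prizes, costs, lambda = 1) {
  n <- igraph::vcount(network)
  if (n > 15) stop_arginet("pcst_exact is limited to 15 nodes", "too_large")
  nodes <- igraph::V(network)$name
  p <- stats::setNames(rep(0, n), nodes)
  common <- intersect(names(prizes), nodes)
  p[common] <- prizes[common]
  g <- network
  igraph::E(g)$cost <- costs
  best <- list(nodes = character(), objective = 0)
  for (mask in seq_len(2^n - 1)) {
    ns <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(ns) > 1L) {
      sub <- igraph::induced_subgraph(g, ns)
      if (!igraph::is_connected(sub)) next
    }
    ob <- subset_objective(g, p, lambda, ns)
    if (ob$objective > best$objective) {
      best <- list(nodes = ns, objective = ob$objective)
    }
  }
  best
}

#' Overlap between two Steiner solutions
#'
#' @param sol_a,sol_b `steiner_solution` objects (or anything with a
#'   `nodes` element).
#' @return character vector of shared nodes.
#' @export
tree_overlap <- function(sol_a, sol_b) {
  intersect(sol_a$nodes, sol_b$nodes)
}

#' Sample a random connected subgraph by neighbour expansion
#'
#' Grows a node set from a uniformly chosen start node by repeatedly adding
#' a uniformly chosen frontier neighbour until `size` nodes are reached.
#' The induced subgraph is connected by construction; the distribution over
#' connected subgraphs is not uniform (uniform sampling is computationally
#' hard), which the overlap null inherits.
#'
#' @param network connected igraph with named nodes.
#' @param size target node count (<= number of nodes).
#' @param seed RNG seed.
#' @return character vector of `size` node names.
#' @export
sample_connected_subgraph <- function(network, size, seed = NULL) {
  n <- igraph::vcount(network)
  if (size < 1 || size > n) {
    stop_arginet("size must lie in [1, number of nodes]", "invalid_size")
  }
  with_seed(seed, {
    nodes <- igraph::V(network)$name
    cur <- sample(nodes, 1)
    frontier <- setdiff(igraph::neighbors(network, cur)$name, cur)
    while (length(cur) < size) {
      if (!length(frontier)) {
        stop_arginet("frontier exhausted on a connected network",
                     "internal_assertion")  # cannot occur when connected
      }
      nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1)
      cur <- c(cur, nxt)
      frontier <- setdiff(union(frontier,
                                igraph::neighbors(network, nxt)$name), cur)
    }
    cur
  })
}

#' Connected-subgraph randomization null for tree overlap
#'
#' Draws `n_draws` independent pairs of connected subgraphs of the two
#' matched sizes and counts their shared nodes; the empirical p-value of
#' the observed overlap is the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_draws)`.
#'
#' @param network connected igraph with named nodes.
#' @param size_a,size_b node counts of the two observed trees.
#' @param observed_overlap observed shared-node count.
#' @param n_draws number of null pairs (default 2000).
#' @param seed RNG seed governing the whole sequence of draws.
#' @return object of class `overlap_null`: `observed_overlap`,
#'   `null_overlaps`, `p_empirical`, `n_draws`.
#' @export
overlap_null <- function(network, size_a, size_b, observed_overlap,
                         n_draws = 2000L, seed = 1) {
  if (n_draws < 1) stop_arginet("n_draws must be >= 1", "invalid_draws")
  if (observed_overlap > min(size_a, size_b) || observed_overlap < 0) {
    stop_arginet("observed_overlap must lie in [0, min(size_a, size_b)]",
                 "invalid_size")
  }
  nulls <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      a <- sample_connected_subgraph(network, size_a)
      b <- sample_connected_subgraph(network, size_b)
      length(intersect(a, b))
    }, numeric(1))
  })
  structure(list(observed_overlap = observed_overlap,
                 null_overlaps = nulls,
                 p_empirical = (1 + sum(nulls >= observed_overlap)) /
                   (1 + n_draws),
                 n_draws = n_draws),
            class = "overlap_null")
}
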