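# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth, so downstream stages are testable without any download.
#
# Default condition labels mirror the seven-arm osteoclastogenesis design:
# M-CSF-only precursors, RANKL-driven differentiation, and arginine
# depletion / starvation / rescue arms, n = 4 biological replicates each.

#' Study condition labels
#'
#' The seven experimental arms of the giant-cell formation study design:
#' M-CSF-only precursors, RANKL-induced osteoclastogenesis, and arginine
#' depletion (arginase), starvation (arginine-free medium) and rescue arms.
#' @return character vector of condition labels.
#' @export
default_conditions <- function() {
  c("M-CSF", "RANKL", "RANKL/Arg-Depletion", "RANKL/Arg-Starvation",
    "RANKL/Arg-Rescue", "M-CSF/Arg-Starvation", "M-CSF/Arg-Rescue")
}

#' Generate a sample design table
#'
#' @param conditions character vector of distinct condition labels.
#' @param replicates replicates per condition (>= 2; study default 4).
#' @param seed unused placeholder kept for interface symmetry with the other
#'   generators (the design is deterministic).
#' @return data.frame with columns `sample_id`, `condition`, `replicate`.
#' @examples
#' gen_design(c("M-CSF", "RANKL"), replicates = 4)
#' @export
gen_design <- function(conditions = default_conditions(), replicates = 4L,
                       seed = NULL) {
  if (length(conditions) == 0 || anyDuplicated(conditions) ||
      any(!nzchar(conditions))) {
    stop_arginet("condition labels must be non-empty and distinct",
                 "invalid_design")
  }
  if (replicates < 2) {
    stop_arginet("at least 2 replicates per condition are required",
                 "invalid_design")
  }
  slug <- gsub("[^A-Za-z0-9]+", ".", conditions)
  design <- data.frame(
    sample_id = paste0(rep(slug, each = replicates), "_", seq_len(replicates)),
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), times = length(conditions)),
    stringsAsFactors = FALSE
  )
  assert_design(design)
}

#' Simulate an RNA-seq count matrix with planted differential expression
#'
#' Counts are negative-binomial with variance `mu + dispersion * mu^2`;
#' per-gene baseline abundances are log-normal and per-sample expected
#' library sizes are drawn around `lib_size_mean`. A fraction of genes
#' carries a planted log2 fold change of +/- `lfc_magnitude` between the two
#' conditions of `contrast`.
#'
#' @param n_genes number of genes (> 0).
#' @param design sample design from [gen_design()].
#' @param de_fraction fraction of genes with a planted effect, in `[0, 1]`.
#' @param lfc_magnitude absolute planted log2 fold change.
#' @param dispersion NB dispersion (0 gives Poisson counts).
#' @param lib_size_mean mean library size (counts per sample).
#' @param seed RNG seed.
#' @param contrast length-2 character: conditions the effect is planted
#'   between (default: first two conditions of the design). The fold change
#'   is applied to the second condition.
#' @return list with `counts` (integer matrix genes x samples) and `truth`
#'   (see [sim_truth]); `truth$de_genes` records planted genes and their
#'   signed log2 fold changes.
#' @export
gen_counts <- function(n_genes, design, de_fraction = 0.1,
                       lfc_magnitude = 2, dispersion = 0.1,
                       lib_size_mean = 1e6, seed = 1,
                       contrast = NULL) {
  if (n_genes < 1) stop_arginet("n_genes must be positive", "empty_input")
  if (de_fraction < 0 || de_fraction > 1) {
    stop_arginet("de_fraction must lie in [0, 1]", "invalid_fraction")
  }
  assert_design(design)
  conds <- unique(design$condition)
  if (is.null(contrast)) contrast <- conds[seq_len(min(2L, length(conds)))]
  genes <- sprintf("gene%05d", seq_len(n_genes))
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = log(200), sdlog = 1.5)
    n_de <- if (length(contrast) == 2L) floor(de_fraction * n_genes) else 0L
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    lfc <- numeric(n_genes)
    if (n_de > 0) {
      lfc[de_idx] <- lfc_magnitude *
        sample(c(-1, 1), n_de, replace = TRUE)
    }
    n_samp <- nrow(design)
    lib <- pmax(round(stats::rnorm(n_samp, lib_size_mean,
                                   0.05 * lib_size_mean)), 1000)
    counts <- matrix(0L, n_genes, n_samp,
                     dimnames = list(genes, design$sample_id))
    w <- base / sum(base)
    for (j in seq_len(n_samp)) {
      fc <- rep(1, n_genes)
      if (length(contrast) == 2L && design$condition[j] == contrast[2L]) {
        fc <- 2^lfc
      }
      mu <- lib[j] * w * fc
      counts[, j] <- if (dispersion > 0) {
        stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
      } else {
        stats::rpois(n_genes, mu)
      }
    }
    truth <- sim_truth(de_genes = data.frame(
      gene_id = genes[de_idx],
      log2fc = lfc[de_idx],
      stringsAsFactors = FALSE
    ))
    list(counts = counts, truth = truth, contrast = contrast)
  })
}

#' Ground-truth container for synthetic data
#'
#' @param de_genes data.frame (`gene_id`, `log2fc`) of planted DE genes.
#' @param shifted_pathways data.frame (`pathway_id`, `shift`) of pathways
#'   carrying planted coordinated shifts.
#' @param da_proteins data.frame (`protein_id`, `effect`) of planted
#'   differentially abundant proteins.
#' @param label_fractions named list metabolite -> true isotopologue
#'   fraction vector.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(de_genes = NULL, shifted_pathways = NULL,
                      da_proteins = NULL, label_fractions = NULL) {
  structure(list(de_genes = de_genes, shifted_pathways = shifted_pathways,
                 da_proteins = da_proteins,
                 label_fractions = label_fractions),
            class = "sim_truth")
}

#' Generate random pathway gene sets
#'
#' Emulates curated KEGG-style gene sets: each set draws members from the
#' gene universe without replacement, with sizes uniform over `size_range`.
#'
#' @param gene_universe character vector of gene ids.
#' @param n_sets number of sets.
#' @param size_range length-2 integer interval of allowed set sizes.
#' @param seed RNG seed.
#' @return named list of character vectors (a pathway collection).
#' @export
gen_pathways <- function(gene_universe, n_sets, size_range = c(10L, 50L),
                         seed = 1) {
  size_range <- as.integer(round(size_range))
  if (length(size_range) != 2L || size_range[1] > size_range[2] ||
      size_range[1] < 1L) {
    stop_arginet("size_range must be a non-empty positive interval",
                 "invalid_size")
  }
  if (max(size_range) > length(gene_universe)) {
    stop_arginet("size_range exceeds the gene universe", "invalid_size")
  }
  with_seed(seed, {
    choices <- seq(size_range[1], size_range[2])
    sizes <- if (length(choices) == 1L) rep(choices, n_sets) else {
      sample(choices, n_sets, replace = TRUE)
    }
    sets <- lapply(sizes, function(k) sample(gene_universe, k))
    names(sets) <- sprintf("PW%03d", seq_len(n_sets))
    sets
  })
}

#' Simulate a label-free proteomics intensity matrix
#'
#' Per-protein log2 intensities are Gaussian around a log-normal-like
#' baseline (mean 27, SD 2 on the log2 scale, typical of LFQ data) with
#' within-replicate noise `noise_sd`. Missingness is left-censored: the
#' probability that a cell is missing is logistic in
#' `(detection_limit - true value)`, rescaled so the expected overall
#' missing fraction equals `missing_rate`. A fraction `da_fraction` of
#' proteins carries a planted log2 shift of magnitude `effect_magnitude`
#' (random sign) in the second condition of `contrast`.
#'
#' @param n_proteins number of proteins.
#' @param design sample design.
#' @param effect_magnitude planted |log2| effect (0 plants nothing).
#' @param da_fraction fraction of proteins with a planted effect.
#' @param missing_rate target overall missing fraction, in `[0, 1)`.
#' @param detection_limit log2 intensity around which censoring acts.
#' @param noise_sd within-replicate log2 SD.
#' @param seed RNG seed.
#' @param contrast length-2 character; defaults to the design's first two
#'   conditions.
#' @return list with `intensity` (numeric matrix, `NA` = missing) and
#'   `truth` (`da_proteins` records planted signed effects).
#' @export
gen_proteome <- function(n_proteins, design, effect_magnitude = 1.5,
                         da_fraction = 0.05, missing_rate = 0.1,
                         detection_limit = 23, noise_sd = 0.3, seed = 1,
                         contrast = NULL) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_arginet("missing_rate must lie in [0, 1)", "invalid_rate")
  }
  if (n_proteins < 1) stop_arginet("n_proteins must be positive",
                                   "empty_input")
  assert_design(design)
  conds <- unique(design$condition)
  if (is.null(contrast)) contrast <- conds[seq_len(min(2L, length(conds)))]
  prots <- sprintf("prot%05d", seq_len(n_proteins))
  with_seed(seed, {
    mu <- stats::rnorm(n_proteins, 27, 2)
    n_da <- if (effect_magnitude > 0 && length(contrast) == 2L) {
      floor(da_fraction * n_proteins)
    } else 0L
    da_idx <- if (n_da > 0) sort(sample.int(n_proteins, n_da)) else integer(0)
    eff <- numeric(n_proteins)
    if (n_da > 0) {
      eff[da_idx] <- effect_magnitude * sample(c(-1, 1), n_da, replace = TRUE)
    }
    n_samp <- nrow(design)
    x <- matrix(stats::rnorm(n_proteins * n_samp, sd = noise_sd),
                n_proteins, n_samp,
                dimnames = list(prots, design$sample_id))
    x <- x + mu
    in_b <- design$condition == contrast[2L]
    if (any(in_b)) x[, in_b] <- x[, in_b] + eff
    if (missing_rate > 0) {
      s <- stats::plogis((detection_limit - x) / 1.5)
      p <- pmin(missing_rate * s / mean(s), 0.95)
      x[matrix(stats::runif(length(x)) < p, n_proteins, n_samp)] <- NA_real_
    }
    truth <- sim_truth(da_proteins = data.frame(
      protein_id = prots[da_idx],
      effect = eff[da_idx],
      stringsAsFactors = FALSE
    ))
    list(intensity = x, truth = truth, contrast = contrast)
  })
}

#' Simulate a weighted protein-interaction network
#'
#' Generates a scale-free (Barabasi-Albert preferential attachment) or
#' Erdos-Renyi graph, keeps the largest connected component, and assigns
#' edge confidence weights uniform over `weight_interval` — a synthetic
#' stand-in for a BioGRID-style weighted interactome.
#'
#' @param n_nodes number of nodes (>= 2) before component extraction.
#' @param model `"scale_free"` or `"erdos_renyi"`.
#' @param weight_interval length-2 sub-interval of `(0, 1]`.
#' @param seed RNG seed.
#' @param edges_per_node attachment edges per new node (scale-free) and the
#'   value matched by the Erdos-Renyi edge probability `2 m / (n - 1)`.
#' @return an `igraph` object with edge attribute `weight`; attribute
#'   `dropped_nodes` records how many nodes fell outside the largest
#'   component (also reported via [message()]).
#' @export
gen_network <- function(n_nodes, model = c("scale_free", "erdos_renyi"),
                        weight_interval = c(0.1, 1), seed = 1,
                        edges_per_node = 2) {
  model <- match.arg(model)
  if (n_nodes < 2) stop_arginet("n_nodes must be >= 2", "empty_input")
  if (length(weight_interval) != 2L ||
      weight_interval[1] > weight_interval[2] ||
      weight_interval[1] <= 0 || weight_interval[2] > 1) {
    stop_arginet("weight_interval must be a non-empty subinterval of (0, 1]",
                 "invalid_interval")
  }
  with_seed(seed, {
    g <- if (model == "scale_free") {
      igraph::sample_pa(n_nodes, power = 1, m = edges_per_node,
                        directed = FALSE)
    } else {
      igraph::sample_gnp(n_nodes,
                         p = min(1, 2 * edges_per_node / (n_nodes - 1)))
    }
    g <- igraph::simplify(g)
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    dropped <- igraph::vcount(g) - length(keep)
    g <- igraph::induced_subgraph(g, keep)
    if (dropped > 0) {
      message(sprintf("gen_network: retained largest component (%d of %d nodes)",
                      igraph::vcount(g), n_nodes))
    }
    igraph::V(g)$name <- sprintf("node%04d", seq_len(igraph::vcount(g)))
    igraph::E(g)$weight <- stats::runif(igraph::ecount(g),
                                        weight_interval[1],
                                        weight_interval[2])
    g$dropped_nodes <- dropped
    g
  })
}

#' Simulate an isotopologue intensity table
#'
#' Emulates LC-MS isotopologue measurements from a stable-isotope tracing
#' experiment: per metabolite, intensities are
#' `total_pool * fraction * (1 + e)` with multiplicative Gaussian noise
#' `e ~ N(0, noise_cv^2)` (truncated so intensities stay non-negative).
#'
#' @param metabolites character vector of metabolite names.
#' @param true_fractions named list metabolite -> non-negative fraction
#'   vector summing to 1; element `k` is the fraction of isotopologue
#'   `m+(k-1)`.
#' @param total_pool total pool intensity per metabolite and sample.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_samples number of replicate samples.
#' @param seed RNG seed.
#' @return list with `table` (long data.frame: `metabolite`, `isotopologue`,
#'   `sample`, `intensity`) and `truth` (`label_fractions`).
#' @export
gen_isotopologues <- function(metabolites, true_fractions, total_pool = 1e5,
                              noise_cv = 0.05, n_samples = 4L, seed = 1) {
  if (!all(metabolites %in% names(true_fractions))) {
    stop_arginet("every metabolite needs a fraction vector",
                 "invalid_fraction")
  }
  for (m in metabolites) {
    f <- true_fractions[[m]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-6) {
      stop_arginet("fractions for '%s' must be non-negative and sum to 1",
                   "invalid_fraction", m)
    }
  }
  with_seed(seed, {
    rows <- lapply(metabolites, function(m) {
      f <- true_fractions[[m]]
      k <- seq_along(f) - 1L
      do.call(rbind, lapply(seq_len(n_samples), function(s) {
        noise <- 1 + stats::rnorm(length(f), sd = noise_cv)
        data.frame(metabolite = m, isotopologue = k,
                   sample = sprintf("s%d", s),
                   intensity = pmax(total_pool * f * noise, 0),
                   stringsAsFactors = FALSE)
      }))
    })
    list(table = do.call(rbind, rows),
         truth = sim_truth(label_fractions = true_fractions[metabolites]))
  })
}

#' Plant a coordinated pathway shift into an expression matrix
#'
#' Adds `shift` (in the units of `expr`, i.e. log2-CPM or z-units) to all
#' genes of a pathway in the given samples — the alternative the rank-sum
#' pathway permutation test is designed to detect.
#'
#' @param expr numeric matrix (genes x samples).
#' @param genes pathway member gene ids (must exist in `expr`).
#' @param samples sample ids receiving the shift.
#' @param shift shift size.
#' @return the shifted matrix.
#' @export
plant_pathway_shift <- function(expr, genes, samples, shift) {
  genes <- intersect(genes, rownames(expr))
  samples <- intersect(samples, colnames(expr))
  expr[genes, samples] <- expr[genes, samples] + shift
  expr
}
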