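# Rank-sum pathway permutation test: samples are ranked per gene within the
# two compared conditions; the statistic sums, over the pathway's genes, the
# absolute difference between the rank sums of the two replicate groups.
# Significance comes from randomizing the sample-condition association
# (12,000 times by default), with Bonferroni correction across pathways.

# Rank matrix (midranks for ties) over the pooled samples, one row per gene.
rank_matrix <- function(expr, genes, samples) {
  genes <- intersect(genes, rownames(expr))
  if (length(genes) == 0) {
    stop_arginet("no pathway gene present in the expression matrix",
                 "empty_pathway")
  }
  x <- expr[genes, samples, drop = FALSE]
  t(apply(x, 1L, rank, ties.method = "average"))
}

# T for one assignment, from precomputed ranks: per gene the total rank sum
# is constant, so |sum_A - sum_B| = |2 * sum_A - total|.
rank_stat <- function(R, idx_a) {
  tot <- (ncol(R) * (ncol(R) + 1)) / 2
  sum(abs(2 * rowSums(R[, idx_a, drop = FALSE]) - tot))
}

#' Rank-sum pathway statistic
#'
#' For each pathway gene, samples of the two groups are ranked jointly
#' (midranks for ties); the statistic is the sum over genes of the absolute
#' difference between the two groups' rank sums.
#'
#' @param expr expression matrix (genes x samples).
#' @param genes pathway member gene ids.
#' @param group_a,group_b disjoint sample-id sets, each of size >= 2.
#' @return non-negative scalar `T`.
#' @examples
#' e <- rbind(g1 = c(10, 11, 12, 13, 1, 2, 3, 4))
#' colnames(e) <- paste0("s", 1:8)
#' pathway_statistic(e, "g1", paste0("s", 1:4), paste0("s", 5:8))  # 16
#' @export
pathway_statistic <- function(expr, genes, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0) {
    stop_arginet("groups must be disjoint", "invalid_groups")
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_arginet("each group needs >= 2 samples", "invalid_groups")
  }
  R <- rank_matrix(expr, genes, c(group_a, group_b))
  rank_stat(R, seq_along(group_a))
}

#' Pathway permutation test
#'
#' Randomizes the association between samples and conditions: group labels
#' are permuted over the pooled samples (the same permutation applied to all
#' genes) and the rank-sum statistic recomputed. In `"sample"` mode the
#' empirical p-value is the add-one estimator
#' `(1 + #(T* >= t_obs)) / (1 + n_perm)`; in `"exhaustive"` mode all
#' `choose(nA+nB, nA)` assignments are enumerated and the p-value is the
#' exact proportion with `T* >= t_obs` (the identity assignment included).
#' Mode `"auto"` enumerates whenever the assignment count does not exceed
#' `n_perm` (for the study's 4v4 designs: 70 assignments).
#'
#' @param expr expression matrix.
#' @param pathway pathway member gene ids.
#' @param group_a,group_b sample-id sets.
#' @param n_perm number of randomizations (default 12000).
#' @param seed RNG seed (used in `"sample"` mode).
#' @param mode `"auto"`, `"exhaustive"` or `"sample"`.
#' @param pathway_id optional label stored in the result.
#' @return object of class `rank_perm_result`: `pathway_id`, `t_obs`,
#'   `null_sample`, `p_empirical`, `n_perm`, `mode`.
#' @export
permutation_test <- function(expr, pathway, group_a, group_b,
                             n_perm = 12000L, seed = 1,
                             mode = c("auto", "exhaustive", "sample"),
                             pathway_id = NA_character_) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop_arginet("n_perm must be >= 1", "invalid_permutations")
  if (length(intersect(group_a, group_b)) > 0) {
    stop_arginet("groups must be disjoint", "invalid_groups")
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_arginet("each group needs >= 2 samples", "invalid_groups")
  }
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  R <- rank_matrix(expr, pathway, pooled)
  t_obs <- rank_stat(R, seq_len(na))
  n_assign <- choose(length(pooled), na)
  exhaustive <- switch(mode,
    auto = n_assign <= n_perm,
    exhaustive = TRUE,
    sample = FALSE
  )
  if (exhaustive) {
    if (n_assign > 1e5) {
      stop_arginet("assignment space too large for exhaustive enumeration",
                   "too_large")
    }
    idx <- utils::combn(length(pooled), na)
    null_sample <- apply(idx, 2L, function(i) rank_stat(R, i))
    p <- mean(null_sample >= t_obs)
    n_used <- n_assign
  } else {
    null_sample <- with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) rank_stat(R, sample.int(length(pooled), na)),
             numeric(1))
    })
    p <- (1 + sum(null_sample >= t_obs)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(pathway_id = pathway_id, t_obs = t_obs,
                 null_sample = null_sample, p_empirical = p,
                 n_perm = n_used,
                 mode = if (exhaustive) "exhaustive" else "sample",
                 n_genes = nrow(R)),
            class = "rank_perm_result")
}

#' Exact pathway permutation p-value
#'
#' Brute-force enumeration over all distinct group-label assignments;
#' counts assignments with `T* >= t_obs`, the identity included. Limited to
#' `choose(nA+nB, nA) <= 1e5`.
#'
#' @inheritParams permutation_test
#' @return the exact permutation p-value.
#' @export
exact_test <- function(expr, pathway, group_a, group_b) {
  res <- permutation_test(expr, pathway, group_a, group_b,
                          n_perm = 1L, mode = "exhaustive")
  res$p_empirical
}

#' Bonferroni correction
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @return `min(1, m * p)` with `m = length(p_values)`.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | is.na(p_values))) {
    stop_arginet("p-values must lie in [0, 1]", "invalid_p")
  }
  pmin(1, p_values * length(p_values))
}

#' Run the pathway permutation test over a pathway collection
#'
#' Applies [permutation_test()] to each set of a pathway collection for one
#' condition contrast and reports empirical and Bonferroni-corrected
#' p-values (multiplicity = number of pathways tested in this invocation).
#'
#' @param expr expression matrix.
#' @param pathways named list of gene-id vectors.
#' @param design sample design.
#' @param contrast length-2 character condition pair.
#' @param n_perm randomizations per pathway (default 12000).
#' @param seed master seed; each pathway uses a derived substream.
#' @param mode passed to [permutation_test()].
#' @return data.frame (`pathway_id`, `n_genes`, `t_obs`, `p_empirical`,
#'   `p_bonferroni`, `n_perm`).
#' @export
pathperm_collection <- function(expr, pathways, design, contrast,
                                n_perm = 12000L, seed = 1,
                                mode = c("auto", "exhaustive", "sample")) {
  mode <- match.arg(mode)
  ga <- design_samples(design, contrast[1L])
  gb <- design_samples(design, contrast[2L])
  res <- lapply(seq_along(pathways), function(i) {
    r <- permutation_test(expr, pathways[[i]], ga, gb, n_perm = n_perm,
                          seed = derive_seed(seed, i), mode = mode,
                          pathway_id = names(pathways)[i])
    data.frame(pathway_id = r$pathway_id, n_genes = r$n_genes,
               t_obs = r$t_obs, p_empirical = r$p_empirical,
               n_perm = r$n_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- bonferroni(out$p_empirical)
  out[, c("pathway_id", "n_genes", "t_obs", "p_empirical",
          "p_bonferroni", "n_perm")]
}
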