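test_that("expression filter keeps CPM > 0.75 in enough samples", {
  # library sums fixed at 1e6 so CPM equals the raw count value
  counts <- rbind(
    gA = c(0.8, 0.8, 0.8, 0.1),      # above 0.75 in exactly 3 samples
    gB = rep(0, 4),                  # all-zero gene
    gC = rep(0.75, 4)                # boundary: log(CPM + 0.25) == 0
  )
  m <- rbind(counts, filler = 1e6 - colSums(counts))
  mask <- filter_expressed(m, min_samples = 3)
  expect_true(mask[["gA"]])
  expect_false(mask[["gB"]])
  expect_false(mask[["gC"]])

  expect_error(filter_expressed(m, min_samples = 5),
               class = "invalid_threshold")
})

test_that("log-CPM is finite, monotone and scale-invariant", {
  counts <- rbind(g1 = c(0, 10), g2 = c(100, 20), g3 = c(5, 0))
  colnames(counts) <- c("s1", "s2")
  e <- normalize_logcpm(counts)
  expect_true(all(is.finite(e)))
  # doubling a count strictly increases its value
  counts2 <- counts; counts2["g1", "s2"] <- 20
  expect_gt(normalize_logcpm(counts2)["g1", "s2"], e["g1", "s2"])
  # proportional columns give identical log-CPM columns
  counts3 <- cbind(counts, s3 = 2 * counts[, "s2"])
  e3 <- normalize_logcpm(counts3)
  expect_equal(e3[, "s3"], e3[, "s2"])
  # all-zero sample errors (zero library size)
  expect_error(normalize_logcpm(cbind(counts, s4 = c(0, 0, 0))),
               class = "degenerate_sample")
})

test_that("moderated DE test is calibrated under the null and recovers
          planted fold changes", {
  d <- design_ab()
  e <- make_expr(0, 3, d$sample_id)
  e[, d$sample_id[d$condition == "A"]] <- 1
  e[, d$sample_id[d$condition == "B"]] <- 5
  de0 <- test_de(e, d, c("A", "B"))
  expect_equal(de0$log2fc, rep(-4, 3))
  e_flat <- make_expr(5, 3, d$sample_id)
  expect_true(all(test_de(e_flat, d, c("A", "B"))$log2fc == 0))
  expect_false(any(test_de(e_flat, d, c("A", "B"))$called))

  expect_error(test_de(e, d, c("A", "C")), class = "unknown_condition")

  # complete null via the generator: few false calls, p approximately uniform
  sim <- gen_counts(2000, d, de_fraction = 0, seed = 11)
  keep <- filter_expressed(sim$counts)
  expr <- normalize_logcpm(sim$counts[keep, , drop = FALSE])
  den <- test_de(expr, d, c("A", "B"))
  expect_lte(mean(den$fdr < 0.05), 0.01)

  gnull <- make_expr(rnorm(2000 * 8), 2000, d$sample_id)
  set.seed(1)
  pn <- test_de(gnull, d, c("A", "B"))$p
  ks <- suppressWarnings(stats::ks.test(pn, "punif"))
  expect_lt(unname(ks$statistic), 0.05)

  # parameter recovery at planted |log2fc| = 3, dispersion 0.05
  simde <- gen_counts(2000, d, de_fraction = 0.1, lfc_magnitude = 3,
                      dispersion = 0.05, seed = 12)
  keep <- filter_expressed(simde$counts)
  expr <- normalize_logcpm(simde$counts[keep, , drop = FALSE])
  de <- test_de(expr, d, c("A", "B"))
  truth <- simde$truth$de_genes$gene_id
  called <- de$gene_id[de$called]
  sens <- length(intersect(called, truth)) /
    sum(truth %in% de$gene_id)
  prec <- length(intersect(called, truth)) / length(called)
  expect_gte(sens, 0.8)
  expect_gte(prec, 0.8)
})

test_that("jaccard matches set arithmetic and its published worked example", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(letters[1:5], letters[1:5]), 1)
  expect_equal(jaccard(character(0), character(0)), 1)
  expect_equal(jaccard(character(0), "a"), 0)
  # symmetry on random sets
  set.seed(42)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    expect_equal(jaccard(a, b), jaccard(b, a))
    expect_gte(jaccard(a, b), 0)
    expect_lte(jaccard(a, b), 1)
  }
  # 393 shared of 469 total differentially expressed genes
  a <- paste0("g", 1:469)
  b <- paste0("g", c(1:393, 470:545))
  expect_equal(floor(jaccard(a, paste0("g", 1:393)) * 1000) / 1000, 0.837)
})

test_that("complete-linkage clustering matches a brute-force oracle and
          separates duplicated blocks", {
  d <- design_ab(3)
  set.seed(7)
  x <- matrix(rnorm(5 * 6), 5, 6,
              dimnames = list(paste0("g", 1:5), d$sample_id))
  de <- de_table(paste0("g", 1:5), called = TRUE, lfc = 5:1)
  cl <- cluster_top_genes(x, de, k = 5)
  expect_equal(sort(cl$gene_hclust$height),
               naive_complete_linkage_heights(cl$z),
               tolerance = 1e-10)

  # duplicated sample blocks: cutting at 2 recovers the blocks exactly
  blk <- cbind(matrix(rep(c(1, 2, 3), 3), 3), matrix(rep(c(9, 1, 4), 3), 3))
  dimnames(blk) <- list(paste0("g", 1:3), paste0("s", 1:6))
  deb <- de_table(paste0("g", 1:3), TRUE, 3:1)
  clb <- cluster_top_genes(blk, deb, k = 3)
  grp <- stats::cutree(clb$sample_hclust, 2)
  expect_equal(length(unique(grp[paste0("s", 1:3)])), 1)
  expect_equal(length(unique(grp[paste0("s", 4:6)])), 1)
  expect_false(grp[["s1"]] == grp[["s4"]])

  # constant gene rows z-score to zeros, keeping distances finite
  cst <- rbind(blk, g4 = rep(2, 6))
  dec <- de_table(paste0("g", 1:4), TRUE, 4:1)
  clc <- cluster_top_genes(cst, dec, k = 4)
  expect_true(all(clc$z["g4", ] == 0))
  expect_error(cluster_top_genes(blk, deb, k = 0), class = "invalid_k")
})

test_that("classical MDS embeds samples at their pairwise distances", {
  # three samples realizing distances (3, 4, 5)
  coords <- rbind(c(0, 3, 0), c(0, 0, 4))
  dimnames(coords) <- list(c("g1", "g2"), c("s1", "s2", "s3"))
  emb <- mds_coordinates(coords, dims = 2)
  expect_equal(colMeans(emb), c(MDS1 = 0, MDS2 = 0), tolerance = 1e-9)
  expect_equal(sort(as.vector(dist(emb))), c(3, 4, 5), tolerance = 1e-6)

  # identical samples land on coincident points
  dup <- cbind(coords, s4 = coords[, "s3"])
  emb2 <- mds_coordinates(dup, dims = 2)
  expect_equal(emb2["s3", ], emb2["s4", ], tolerance = 1e-9)

  expect_error(mds_coordinates(coords, dims = 3),
               class = "insufficient_samples")
})
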