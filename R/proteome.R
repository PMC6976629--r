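# Label-free proteomics stage. Pipeline order is fixed: log2 intensities in,
# detection filter -> left-censored imputation -> CV-discordance filter ->
# per-protein z-scores -> s0-moderated permutation-FDR test.

#' Detection filter
#'
#' Keeps proteins identified (non-missing) in at least `min_reps` replicates
#' of at least one condition — the "three out of four replicates" rule.
#'
#' @param mat log2 intensity matrix with `NA` for missing values.
#' @param design sample design.
#' @param min_reps minimum detections within a condition (default 3).
#' @return logical protein mask.
#' @export
detection_filter <- function(mat, design, min_reps = 3L) {
  assert_design(design)
  tab <- table(design$condition)
  if (any(tab < min_reps)) {
    stop_arginet("min_reps exceeds the replicate count of some condition",
                 "invalid_threshold")
  }
  conds <- unique(design$condition)
  keep <- rep(FALSE, nrow(mat))
  for (cc in conds) {
    s <- design$sample_id[design$condition == cc]
    keep <- keep | rowSums(!is.na(mat[, s, drop = FALSE])) >= min_reps
  }
  keep
}

#' Left-censored imputation from a downshifted normal
#'
#' Missing values of each sample are drawn from a normal distribution
#' centred on that sample's detection limit — operationalised as the
#' sample's observed minimum shifted down by `downshift` observed SDs —
#' with SD `width_factor` times the sample's observed SD. With the default
#' `downshift = 0` the centre is the observed minimum itself; Perseus-style
#' defaults are reached with `downshift = 1.8`, `width_factor = 0.3`.
#'
#' @param mat log2 intensity matrix with `NA` for missing values.
#' @param width_factor imputation SD as a fraction of the sample SD.
#' @param downshift centre shift in sample-SD units (default 0).
#' @param seed RNG seed.
#' @return the matrix with all `NA` cells imputed; observed cells unchanged.
#' @export
impute_missing <- function(mat, width_factor = 0.3, downshift = 0,
                           seed = 1) {
  if (downshift < 0) stop_arginet("downshift must be >= 0", "invalid_rate")
  with_seed(seed, {
    for (j in seq_len(ncol(mat))) {
      obs <- mat[, j][!is.na(mat[, j])]
      miss <- which(is.na(mat[, j]))
      if (length(obs) == 0) {
        stop_arginet("sample '%s' has no observed values",
                     "degenerate_sample", colnames(mat)[j])
      }
      if (length(miss) > 0) {
        sdv <- stats::sd(obs)
        if (!is.finite(sdv)) sdv <- 0
        centre <- min(obs) - downshift * sdv
        mat[miss, j] <- stats::rnorm(length(miss), centre,
                                     width_factor * sdv)
      }
    }
    mat
  })
}

#' Coefficient-of-variation discordance filter
#'
#' Keeps proteins whose overall CV (across all samples) strictly exceeds the
#' CV within every condition — proteins that vary consistently between
#' conditions but not between replicates. CV is computed on the linear
#' intensity scale (`2^log2`) by default; the log2 scale is available as a
#' configuration switch.
#'
#' @param mat fully observed log2 intensity matrix (post-imputation).
#' @param design sample design.
#' @param cv_scale `"linear"` (default) or `"log2"`.
#' @return logical protein mask.
#' @export
cv_filter <- function(mat, design, cv_scale = c("linear", "log2")) {
  cv_scale <- match.arg(cv_scale)
  assert_design(design)
  if (anyNA(mat)) {
    stop_arginet("cv_filter requires a fully observed matrix (impute first)",
                 "missing_values")
  }
  x <- if (cv_scale == "linear") 2^mat else mat
  cv_of <- function(m) {
    mu <- rowMeans(m)
    if (any(mu == 0)) stop_arginet("zero mean abundance: CV undefined",
                                   "undefined_cv")
    apply(m, 1L, stats::sd) / mu
  }
  overall <- cv_of(x[, design$sample_id, drop = FALSE])
  conds <- unique(design$condition)
  within_max <- rep(-Inf, nrow(mat))
  for (cc in conds) {
    s <- design$sample_id[design$condition == cc]
    within_max <- pmax(within_max, cv_of(x[, s, drop = FALSE]))
  }
  overall > within_max
}

#' s0-moderated permutation-FDR differential-abundance test
#'
#' SAM-style two-sample test: values are z-scored per protein across the
#' samples of the two compared conditions, the statistic is
#' `d = (mean_A - mean_B) / (se_pooled + s0)` with the pooled standard
#' error and stabilisation constant `s0`, and the null distribution of
#' `|d|` is built by permuting condition labels (one permutation applied to
#' all proteins). The q-value at threshold `|d_i|` is the median
#' false-positive count over permutations divided by the observed positive
#' count, capped at 1 and monotonised to be non-increasing in `|d|`.
#'
#' @param mat fully observed log2 intensity (or z-score) matrix.
#' @param design sample design.
#' @param contrast length-2 character `(A, B)`.
#' @param s0 stabilisation constant (default 0.05).
#' @param n_perm number of label permutations (default 1000).
#' @param fdr significance threshold on the q-value (default 0.05).
#' @param seed RNG seed.
#' @param zscore z-score per protein before testing (default TRUE, matching
#'   the pipeline's published order).
#' @return data.frame (`protein_id`, `d_stat`, `q_value`, `significant`).
#' @export
sam_test <- function(mat, design, contrast, s0 = 0.05, n_perm = 1000L,
                     fdr = 0.05, seed = 1, zscore = TRUE) {
  if (s0 < 0) stop_arginet("s0 must be >= 0", "invalid_s0")
  if (anyNA(mat)) stop_arginet("sam_test requires a fully observed matrix",
                               "missing_values")
  sa <- design_samples(design, contrast[1L])
  sb <- design_samples(design, contrast[2L])
  if (length(sa) < 2 || length(sb) < 2) {
    stop_arginet("both conditions need >= 2 replicates", "invalid_design")
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("protein%05d", seq_len(nrow(mat)))
  }
  x <- mat[, c(sa, sb), drop = FALSE]
  if (zscore) x <- zscore_rows(x)
  na <- length(sa); nb <- length(sb); n <- na + nb
  x2 <- x^2
  d_of <- function(ia) {
    a <- x[, ia, drop = FALSE]
    b <- x[, -ia, drop = FALSE]
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- (rowSums(x2[, ia, drop = FALSE]) - na * ma^2) / (na - 1)
    vb <- (rowSums(x2[, -ia, drop = FALSE]) - nb * mb^2) / (nb - 1)
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(pmax(s2, 0) * (1 / na + 1 / nb))
    (ma - mb) / (se + s0)
  }
  d_obs <- d_of(seq_len(na))
  abs_obs <- abs(d_obs)
  # permutation null: same label shuffle for every protein
  fp <- with_seed(seed, {
    counts <- matrix(0L, nrow(x), n_perm)
    for (p in seq_len(n_perm)) {
      dstar <- sort(abs(d_of(sample.int(n, na))))
      # false positives at each observed threshold: #{|d*| >= |d_i|}
      counts[, p] <- length(dstar) -
        findInterval(abs_obs, dstar, left.open = TRUE)
    }
    apply(counts, 1L, stats::median)
  })
  pos <- vapply(abs_obs, function(t) sum(abs_obs >= t), numeric(1))
  q_raw <- pmin(1, fp / pos)
  # monotonise: q non-increasing in |d|
  ord <- order(-abs_obs)
  q <- numeric(length(q_raw))
  q[ord] <- cummax(q_raw[ord])
  data.frame(
    protein_id = rownames(mat),
    d_stat = d_obs,
    q_value = q,
    significant = q <= fdr,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Full proteomics processing pipeline
#'
#' Applies the fixed stage order: detection filter, left-censored
#' imputation, CV-discordance filter, per-protein z-scoring inside the
#' s0-moderated test.
#'
#' @param mat log2 intensity matrix with `NA` for missing values.
#' @param design sample design.
#' @param contrast condition pair passed to [sam_test()].
#' @param min_reps,width_factor,downshift,s0,n_perm,fdr,cv_scale stage
#'   parameters (see the individual functions).
#' @param seed master seed; imputation and permutation use derived
#'   substreams.
#' @return list with the processed `matrix`, the two `masks`, and the
#'   [sam_test()] `result`.
#' @export
proteome_pipeline <- function(mat, design, contrast, min_reps = 3L,
                              width_factor = 0.3, downshift = 0,
                              s0 = 0.05, n_perm = 1000L, fdr = 0.05,
                              cv_scale = "linear", seed = 1) {
  keep1 <- detection_filter(mat, design, min_reps)
  m <- impute_missing(mat[keep1, , drop = FALSE], width_factor, downshift,
                      seed = derive_seed(seed, 101))
  keep2 <- cv_filter(m, design, cv_scale)
  m2 <- m[keep2, , drop = FALSE]
  res <- sam_test(m2, design, contrast, s0 = s0, n_perm = n_perm,
                  fdr = fdr, seed = derive_seed(seed, 102))
  list(matrix = m2, masks = list(detection = keep1, cv = keep2),
       result = res)
}
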