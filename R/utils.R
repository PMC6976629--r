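# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generator calls do not disturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a per-stage substream seed from a master seed
#'
#' Deterministic integer mixing so each pipeline stage gets its own
#' reproducible stream from one master seed. Result is always a valid
#' 32-bit seed.
#'
#' @param seed master seed (integer).
#' @param stream stage index (integer, distinct per generator call site).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(stream), length(stream) == 1L)
  x <- (abs(seed) %% 1000003) * 10007 + abs(stream) * 97 + 1
  as.integer(x %% 2147483629)
}

stop_arginet <- function(msg, class, ...) {
  stop(structure(class = c(class, "arginet_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

#' @noRd
assert_design <- function(design) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "condition", "replicate") %in% names(design))) {
    stop_arginet("design must have columns sample_id, condition, replicate",
                 "invalid_design")
  }
  if (anyDuplicated(design$sample_id)) {
    stop_arginet("sample_ids must be unique", "invalid_design")
  }
  tab <- table(design$condition)
  if (any(tab < 2)) {
    stop_arginet("every condition needs at least 2 replicates",
                 "invalid_design")
  }
  invisible(design)
}

#' @noRd
design_samples <- function(design, condition) {
  assert_design(design)
  if (!condition %in% design$condition) {
    stop_arginet("condition '%s' not present in design", "unknown_condition",
                 condition)
  }
  design$sample_id[design$condition == condition]
}

# z-score rows of a matrix; constant rows map to all-zero rows so that
# downstream distance computations stay total.
zscore_rows <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  z <- (x - mu) / sdv
  z[sdv == 0 | !is.finite(sdv), ] <- 0
  z
}
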