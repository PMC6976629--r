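# Stable-isotope tracer arithmetic on long-format isotopologue tables:
# fractions of the metabolite pool, labelled:unlabelled ratios, and
# normalization of a target isotopologue to the tracer input. No
# natural-abundance isotope correction is applied; a correction matrix can
# be hooked in upstream of these functions if required.

iso_intensity <- function(table, metabolite, k, sample) {
  hit <- table$metabolite == metabolite & table$isotopologue == k &
    table$sample == sample
  if (!any(hit)) return(0)
  sum(table$intensity[hit])
}

assert_iso_table <- function(table) {
  need <- c("metabolite", "isotopologue", "sample", "intensity")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop_arginet("isotopologue table needs columns %s", "invalid_table",
                 paste(need, collapse = ", "))
  }
  if (any(table$intensity < 0)) {
    stop_arginet("intensities must be non-negative", "invalid_table")
  }
  key <- paste(table$metabolite, table$isotopologue, table$sample)
  if (anyDuplicated(key)) {
    stop_arginet("(metabolite, isotopologue, sample) must be unique",
                 "invalid_table")
  }
  invisible(table)
}

#' Isotopologue fraction of the metabolite pool
#'
#' `intensity(m+k) / sum_j intensity(m+j)` for one metabolite and sample —
#' e.g. the percent m+5 citrulline of the labelled arginine-derived pool
#' (returned as a proportion; multiply by 100 for percent display).
#'
#' @param table long-format isotopologue table (`metabolite`,
#'   `isotopologue`, `sample`, `intensity`).
#' @param metabolite metabolite name.
#' @param k isotopologue index (`m+k`).
#' @param sample sample id.
#' @return proportion in `[0, 1]`.
#' @export
isotopologue_fraction <- function(table, metabolite, k, sample) {
  assert_iso_table(table)
  pool <- table$metabolite == metabolite & table$sample == sample
  tot <- sum(table$intensity[pool])
  if (tot <= 0) {
    stop_arginet("zero total pool for %s in %s", "undefined_fraction",
                 metabolite, sample)
  }
  iso_intensity(table, metabolite, k, sample) / tot
}

#' Labelled to unlabelled ratio
#'
#' `intensity(m+labelled_k) / intensity(m+0)` — e.g. the ratio of
#' intracellular 13C6-labelled to unlabelled 12C arginine.
#'
#' @inheritParams isotopologue_fraction
#' @param labelled_k index of the labelled isotopologue.
#' @return non-negative ratio.
#' @export
label_ratio <- function(table, metabolite, labelled_k, sample) {
  assert_iso_table(table)
  m0 <- iso_intensity(table, metabolite, 0L, sample)
  if (m0 <= 0) {
    stop_arginet("unlabelled (m+0) intensity of %s in %s is zero: ratio undefined",
                 "division_error", metabolite, sample)
  }
  iso_intensity(table, metabolite, labelled_k, sample) / m0
}

#' Normalize a target isotopologue to the tracer input
#'
#' `intensity(target, m+target_k) / intensity(tracer, m+tracer_k)` — e.g.
#' m+5 ornithine normalized to the 13C6-labelled arginine input, or m+4
#' fumarate normalized to the 13C4-labelled aspartate input.
#'
#' @inheritParams isotopologue_fraction
#' @param target_metabolite,target_k target metabolite and isotopologue.
#' @param tracer_metabolite,tracer_k tracer metabolite and isotopologue.
#' @return non-negative ratio.
#' @export
normalize_to_tracer <- function(table, target_metabolite, target_k,
                                tracer_metabolite, tracer_k, sample) {
  assert_iso_table(table)
  tr <- iso_intensity(table, tracer_metabolite, tracer_k, sample)
  if (tr <= 0) {
    stop_arginet("tracer intensity (%s m+%d) in %s is zero",
                 "undefined_normalization", tracer_metabolite, tracer_k,
                 sample)
  }
  iso_intensity(table, target_metabolite, target_k, sample) / tr
}

#' All isotopologue fractions of a table
#'
#' @param table long-format isotopologue table.
#' @return the table with an added `fraction` column (per metabolite and
#'   sample); rows whose pool is zero get `NA`.
#' @export
isotopologue_fractions <- function(table) {
  assert_iso_table(table)
  key <- paste(table$metabolite, table$sample, sep = "\r")
  tot <- stats::ave(table$intensity, key, FUN = sum)
  table$fraction <- ifelse(tot > 0, table$intensity / tot, NA_real_)
  table
}

#' Mass-balance check on a fraction table
#'
#' Flags (metabolite, sample) pairs whose isotopologue fractions fail to
#' sum to 1 within `tol`.
#'
#' @param table output of [isotopologue_fractions()] (or any table with a
#'   `fraction` column).
#' @param tol absolute tolerance (default 1e-9).
#' @return data.frame of violations (`metabolite`, `sample`, `total`);
#'   zero rows when all pools balance.
#' @export
check_mass_balance <- function(table, tol = 1e-9) {
  if (!"fraction" %in% names(table)) table <- isotopologue_fractions(table)
  agg <- stats::aggregate(fraction ~ metabolite + sample, data = table,
                          FUN = sum)
  names(agg)[3] <- "total"
  agg[is.na(agg$total) | abs(agg$total - 1) > tol, , drop = FALSE]
}
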