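#' Normalize an omics table
#'
#' Omics-aware column normalizations applied before correlation. Counts per
#' million (`cpm`) rescales every sample column to sum to 1e6; `acpm` is
#' `asinh(cpm)`, which tames the heavy right tail of sequencing counts while
#' behaving linearly near zero; `pa` is presence/absence encoding
#' (1 when a value exceeds zero); `log` is `log2(x + 1)` (the transcriptomics
#' convention) and `log1` is `ln(x + 1)` (the mass-spectrometry convention).
#' The transform name is appended to `norm_history`.
#'
#' @param table an [omics_table()].
#' @param method one of `"cpm"`, `"acpm"`, `"pa"`, `"log"`, `"log1"`.
#' @return The transformed [omics_table()].
#' @export
#' @examples
#' m <- matrix(c(1, 3, 0, 2), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' trans(omics_table(m), "cpm")$values
trans <- function(table, method = c("cpm", "acpm", "pa", "log", "log1")) {
  stopifnot(inherits(table, "omics_table"))
  method <- match.arg(method)
  v <- table$values
  if (method %in% c("cpm", "acpm", "pa")) {
    if (any(v < 0))
      abort(sprintf("method \"%s\" requires non-negative values", method))
  }
  if (method %in% c("cpm", "acpm")) {
    cs <- colSums(v)
    if (any(cs == 0))
      abort(sprintf("all-zero sample column(s): %s",
                    paste(table$sample_ids[cs == 0], collapse = ", ")))
    v <- sweep(v, 2L, cs, "/") * 1e6
    if (method == "acpm") v <- asinh(v)
  } else if (method == "pa") {
    v <- (v > 0) + 0
  } else if (method == "log") {
    v <- log2(v + 1)
  } else {
    v <- log1p(v)
  }
  dimnames(v) <- list(table$feature_ids, table$sample_ids)
  out <- table
  out$values <- v
  out$norm_history <- c(table$norm_history, method)
  out
}

#' Filter features by prevalence
#'
#' Keeps features whose prevalence — the fraction of samples in which the
#' feature is present (value strictly greater than zero) — strictly exceeds
#' `min_prev`. A message reports how many features were dropped.
#'
#' @param table an [omics_table()].
#' @param min_prev prevalence threshold in `[0, 1)`; features with
#'   prevalence `> min_prev` are kept.
#' @return The filtered [omics_table()].
#' @export
filter_prevalence <- function(table, min_prev = 0.1) {
  stopifnot(inherits(table, "omics_table"))
  stop_if_not_scalar_number(min_prev, "min_prev")
  if (min_prev < 0 || min_prev >= 1) abort("`min_prev` must be in [0, 1)")
  prev <- rowMeans(table$values > 0)
  keep <- prev > min_prev
  if (!any(keep)) abort("no features pass the prevalence filter")
  message(sprintf("filter_prevalence: dropped %d of %d features",
                  sum(!keep), length(keep)))
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  out$feature_ids <- table$feature_ids[keep]
  if (!is.null(table$feature_meta))
    out$feature_meta <- table$feature_meta[
      table$feature_meta$feature %in% out$feature_ids, , drop = FALSE]
  out
}
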