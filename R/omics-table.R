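#' Feature-by-sample omics table
#'
#' An `omics_table` holds a numeric feature x sample matrix together with
#' the omics layer it came from (e.g. `"micro"`, `"gene"`, `"chem"`),
#' optional per-feature metadata and the ordered history of normalizations
#' applied by [trans()]. Values must be finite: any missing-data policy is
#' applied at read time ([read_abundance_table()]), never downstream.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param layer single string naming the omics layer.
#' @param feature_meta optional data frame of per-feature metadata with a
#'   `feature` column matching the rownames of `values`.
#' @param norm_history character vector of transform names already applied.
#'
#' @return An object of class `omics_table`.
#' @export
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
#' omics_table(m, layer = "micro")
omics_table <- function(values, layer = "feature", feature_meta = NULL,
                        norm_history = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix (features x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("`values` must have feature rownames and sample colnames")
  if (!is_string(layer)) abort("`layer` must be a single string")
  fid <- rownames(values)
  sid <- colnames(values)
  if (anyDuplicated(fid))
    abort(sprintf("duplicate feature ids: %s",
                  paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  if (anyDuplicated(sid))
    abort(sprintf("duplicate sample ids: %s",
                  paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  if (nrow(values) == 0L || ncol(values) == 0L) abort("empty table")
  if (!all(is.finite(values)))
    abort("`values` must be finite (apply a missing policy at read time)")
  if (!is.null(feature_meta)) {
    feature_meta <- as_tibble(feature_meta)
    if (!"feature" %in% names(feature_meta))
      abort("`feature_meta` must have a `feature` column")
  }
  structure(
    list(values = values, feature_ids = fid, sample_ids = sid, layer = layer,
         feature_meta = feature_meta, norm_history = as.character(norm_history)),
    class = "omics_table"
  )
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("<omics_table> layer '%s': %d features x %d samples\n",
              x$layer, length(x$feature_ids), length(x$sample_ids)))
  if (length(x$norm_history))
    cat("  transforms:", paste(x$norm_history, collapse = " -> "), "\n")
  if (!is.null(x$feature_meta))
    cat("  feature_meta:", paste(setdiff(names(x$feature_meta), "feature"),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.omics_table <- function(x) dim(x$values)

#' Tidy an omics table to long format
#'
#' @param x an [omics_table()].
#' @param ... unused.
#' @return A tibble with columns `feature`, `sample`, `value`.
#' @export
tidy.omics_table <- function(x, ...) {
  tibble(
    feature = rep(x$feature_ids, times = length(x$sample_ids)),
    sample = rep(x$sample_ids, each = length(x$feature_ids)),
    value = as.vector(x$values)
  )
}

#' Read a feature-by-sample abundance table from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids,
#' with a numeric body. Missing cells are handled by `missing_policy`:
#' `"error"` refuses them, `"zero"` replaces them with 0 and
#' `"drop_feature"` removes any feature row containing one.
#'
#' @param path path to a TSV file.
#' @param layer omics layer tag stored on the result.
#' @param missing_policy one of `"error"`, `"zero"`, `"drop_feature"`.
#' @return An [omics_table()].
#' @export
read_abundance_table <- function(path, layer = "feature",
                                 missing_policy = c("error", "zero", "drop_feature")) {
  missing_policy <- match.arg(missing_policy)
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL)
  if (nrow(raw) == 0L || ncol(raw) < 2L) abort(sprintf("empty table: %s", path))
  fid <- raw[[1L]]
  if (anyDuplicated(fid))
    abort(sprintf("duplicate feature id(s) in %s: %s", path,
                  paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  sid <- colnames(body)
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  missing <- is.na(num) | trimws(body) == ""
  bad <- is.na(num) & trimws(body) != "" & body != "NA"
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    abort(sprintf("non-numeric value '%s' at feature '%s' (row %d), sample '%s' (column %d)",
                  body[ij[1L], ij[2L]], fid[ij[1L]], ij[1L], sid[ij[2L]], ij[2L]))
  }
  if (any(missing)) {
    if (missing_policy == "error") {
      ij <- which(missing, arr.ind = TRUE)[1L, ]
      abort(sprintf("missing value at feature '%s', sample '%s' (missing_policy = \"error\")",
                    fid[ij[1L]], sid[ij[2L]]))
    } else if (missing_policy == "zero") {
      num[missing] <- 0
    } else {
      keep <- rowSums(missing) == 0L
      num <- num[keep, , drop = FALSE]
      fid <- fid[keep]
      if (nrow(num) == 0L) abort("all features dropped by missing_policy = \"drop_feature\"")
    }
  }
  dimnames(num) <- list(fid, sid)
  omics_table(num, layer = layer)
}

#' Write an abundance table to TSV
#'
#' @param table an [omics_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "omics_table"))
  df <- data.frame(feature = table$feature_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
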