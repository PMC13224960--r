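#' All-pairs correlation with analytic p-values
#'
#' Vectorized Pearson or Spearman correlation for one feature table
#' (intra-omics mode: all feature pairs within `tableA`) or two tables
#' (inter-omics mode: every row of `tableA` against every row of `tableB`,
#' aligned on shared sample ids). Two-sided p-values are computed
#' analytically from the t statistic `t = r * sqrt((n - 2) / (1 - r^2))`
#' with `n - 2` degrees of freedom, so no permutation loop is needed;
#' `|r| = 1` maps to `p = 0`. Spearman is Pearson on midranks (ties receive
#' average ranks). Zero-variance features yield `NA` rows/columns.
#'
#' Multiple-testing correction is applied over the tests actually
#' performed: the strict upper triangle in intra mode (then mirrored), all
#' rows x columns in inter mode.
#'
#' @param tableA an [omics_table()] or numeric feature x sample matrix with
#'   dimnames.
#' @param tableB optional second table; triggers inter-omics mode.
#' @param method `"pearson"`, `"spearman"`, or `"bray"` (reserved;
#'   currently errors).
#' @param adjust adjustment method: `"BH"`, `"bonferroni"`, `"holm"` or
#'   `"none"`.
#' @param use `"complete"` (default) uses the aligned sample set as is;
#'   `"pairwise"` uses pairwise-complete observations with per-pair `n` in
#'   the t formula (only relevant for plain matrices containing `NA`).
#' @return A `cor_res` object: list with matrices `r`, `p`, `p_adj`, sample
#'   count `n`, `method`, `adjust`, `mode` (`"intra"`/`"inter"`), the
#'   row/column ids and layers. Use [tidy.cor_res()] for a long tibble.
#' @export
#' @examples
#' m <- matrix(rnorm(40), 4, 10, dimnames = list(letters[1:4], paste0("s", 1:10)))
#' res <- c_net_calculate(m, method = "pearson")
#' tidy(res)
c_net_calculate <- function(tableA, tableB = NULL,
                            method = c("spearman", "pearson", "bray"),
                            adjust = c("BH", "bonferroni", "holm", "none"),
                            use = c("complete", "pairwise")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  use <- match.arg(use)
  if (method == "bray")
    abort(paste("method \"bray\" (Bray-Curtis dissimilarity mode) is not",
                "implemented in this version; use \"spearman\" or \"pearson\""))
  A <- cor_input(tableA)
  mode <- if (is.null(tableB)) "intra" else "inter"
  if (mode == "inter") {
    B <- cor_input(tableB)
    shared <- intersect(colnames(A$values), colnames(B$values))
    if (length(shared) < 3L)
      abort(sprintf("only %d shared sample id(s); need at least 3", length(shared)))
    va <- A$values[, shared, drop = FALSE]
    vb <- B$values[, shared, drop = FALSE]
  } else {
    va <- A$values
    vb <- NULL
  }
  n <- ncol(va)
  if (n < 3L) abort(sprintf("n = %d samples; need at least 3", n))
  if (n == 3L) warn("n = 3 gives df = 1: p-values have very heavy tails")

  cor_method <- if (method == "spearman") "spearman" else "pearson"
  cor_use <- if (use == "pairwise") "pairwise.complete.obs" else "everything"
  r <- suppressWarnings(
    if (mode == "intra") cor(t(va), method = cor_method, use = cor_use)
    else cor(t(va), t(vb), method = cor_method, use = cor_use)
  )
  r[is.nan(r)] <- NA_real_

  if (use == "pairwise") {
    oa <- !is.na(va)
    n_mat <- if (mode == "intra") tcrossprod(oa + 0) else tcrossprod(oa + 0, !is.na(vb) + 0)
    p <- r_to_p(r, n_mat)
  } else {
    p <- r_to_p(r, n)
  }

  if (mode == "intra") {
    diag(p) <- 0
    ut <- upper.tri(r)
    p_adj <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
    p_adj[ut] <- adjust_p(p[ut], method = adjust)
    p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
    diag(p_adj) <- 0
    diag(p_adj)[is.na(diag(r))] <- NA_real_
    diag(p)[is.na(diag(r))] <- NA_real_
  } else {
    p_adj <- matrix(adjust_p(as.vector(p), method = adjust),
                    nrow(r), ncol(r), dimnames = dimnames(r))
  }

  structure(
    list(r = r, p = p, p_adj = p_adj, n = n, method = method, adjust = adjust,
         mode = mode,
         row_ids = rownames(r), col_ids = colnames(r),
         row_layer = A$layer,
         col_layer = if (mode == "inter") B$layer else A$layer),
    class = "cor_res"
  )
}

cor_input <- function(x) {
  if (inherits(x, "omics_table")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) abort("table must be an omics_table or numeric matrix")
  if (is.null(rownames(x))) rownames(x) <- paste0("f", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  list(values = x, layer = "feature")
}

# analytic two-sided p from r and df = n - 2; r is clipped away from +-1
# inside the formula except for the exact |r| >= 1 branch (p = 0)
r_to_p <- function(r, n) {
  df <- n - 2
  eps <- 1e-15
  rc <- pmin(pmax(r, -1 + eps), 1 - eps)
  tstat <- rc * sqrt(df / (1 - rc^2))
  p <- 2 * pt(-abs(tstat), df)
  p[!is.na(r) & abs(r) >= 1] <- 0
  p[is.na(r)] <- NA_real_
  if (is.matrix(r) && !is.matrix(p)) p <- matrix(p, nrow(r), ncol(r), dimnames = dimnames(r))
  if (is.matrix(p)) dimnames(p) <- dimnames(r)
  p
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] adding the test-universe argument
#' `m` and `NA` handling: `NA` entries are excluded from the universe
#' unless `m` is given explicitly, and are returned as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (may contain `NA`).
#' @param method `"BH"`, `"bonferroni"`, `"holm"` or `"none"`.
#' @param m number of tests; defaults to the number of non-`NA` p-values.
#' @return Adjusted p-values, capped at 1.
#' @export
#' @examples
#' adjust_p(c(0.01, 0.02, 0.03, 0.04), "BH")
adjust_p <- function(p, method = c("BH", "bonferroni", "holm", "none"), m = NULL) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must be in [0, 1]")
  if (method == "none") return(p)
  if (is.null(m)) m <- sum(ok)
  out <- p
  out[ok] <- p.adjust(p[ok], method = method, n = max(m, sum(ok)))
  out
}

#' @export
print.cor_res <- function(x, ...) {
  cat(sprintf("<cor_res> %s/%s %s: %d x %d, n = %d samples\n",
              x$method, x$adjust, x$mode, nrow(x$r), ncol(x$r), x$n))
  invisible(x)
}

#' Tidy a correlation result into long format
#'
#' @param x a `cor_res` from [c_net_calculate()].
#' @param ... unused.
#' @return A tibble with columns `row`, `col`, `r`, `p`, `p_adj`; in intra
#'   mode only the strict upper triangle (each unordered pair once).
#' @export
tidy.cor_res <- function(x, ...) {
  if (x$mode == "intra") {
    idx <- which(upper.tri(x$r), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_len(nrow(x$r)), col = seq_len(ncol(x$r))))
  }
  tibble(
    row = x$row_ids[idx[, 1L]],
    col = x$col_ids[idx[, 2L]],
    r = x$r[idx],
    p = x$p[idx],
    p_adj = x$p_adj[idx]
  )
}

#' Export a correlation result as long-format TSV
#'
#' Columns `row, col, r, p, p_adj`, one line per tested pair.
#'
#' @param x a `cor_res`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cor_tsv <- function(x, path) {
  stopifnot(inherits(x, "cor_res"))
  write.table(as.data.frame(tidy.cor_res(x)), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
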