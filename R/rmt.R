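#' Nearest-neighbour spacing distribution of a spectrum
#'
#' Computes the unfolded nearest-neighbour eigenvalue spacings used to
#' distinguish correlated (GOE/Wigner) from uncorrelated (Poisson) spectra.
#' Eigenvalues are sorted, near-duplicates (closer than `tol`) collapsed,
#' and the spectrum unfolded with a parameter-light empirical-CDF mapping:
#' the ECDF is linearly interpolated through quantile knots (one knot per
#' ~`knots_per` eigenvalues), evaluated at each eigenvalue, and scaled by
#' the spectrum size; spacings are finally normalized to mean exactly 1.
#' The knot smoothing removes the global spectral-density trend while
#' leaving spacing-scale fluctuations intact.
#'
#' @param eigenvalues numeric vector of at least 20 finite eigenvalues.
#' @param knots_per target number of eigenvalues per unfolding knot.
#' @param tol eigenvalues closer than this are collapsed before unfolding.
#' @return Numeric vector of unfolded spacings with mean 1.
#' @export
#' @examples
#' nnsd(1:100) # uniform spectrum: every spacing is exactly 1
nnsd <- function(eigenvalues, knots_per = 20, tol = 1e-8) {
  ev <- eigenvalues
  if (!is.numeric(ev) || any(!is.finite(ev))) abort("eigenvalues must be finite numbers")
  if (length(ev) < 20L) abort(sprintf("need at least 20 eigenvalues, got %d", length(ev)))
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > tol)]
  if (length(ev) < 2L) abort("degenerate spectrum: all eigenvalues identical")
  if (length(ev) < 20L)
    abort(sprintf("only %d distinct eigenvalues after collapsing duplicates", length(ev)))
  n <- length(ev)
  k <- max(5L, ceiling(n / knots_per))
  probs <- seq(0, 1, length.out = k + 1L)
  knots <- cummax(quantile(ev, probs, names = FALSE, type = 7))
  fi <- approx(knots, probs, xout = ev, ties = "ordered", rule = 2)$y
  s <- n * diff(fi)
  s / mean(s)
}

# chi-square distance between observed spacings and a reference pdf on
# `nbins` equal bins over [0, smax]; spacings beyond smax are dropped and
# the reference probabilities renormalized over the window
nnsd_chi2 <- function(s, pdf, nbins = 20L, smax = 3) {
  s <- s[s <= smax]
  if (length(s) == 0L) return(NA_real_)
  br <- seq(0, smax, length.out = nbins + 1L)
  obs <- tabulate(findInterval(s, br, rightmost.closed = TRUE), nbins)
  pr <- vapply(seq_len(nbins), function(i)
    stats::integrate(pdf, br[i], br[i + 1L])$value, numeric(1))
  pr <- pr / sum(pr)
  expd <- pr * length(s)
  sum((obs - expd)^2 / pmax(expd, 1e-10))
}

nnsd_poisson <- function(s) exp(-s)
nnsd_wigner <- function(s) (pi * s / 2) * exp(-pi * s^2 / 4)

#' RMT scan for a data-driven correlation threshold
#'
#' Scans a grid of candidate thresholds `t`. At each `t` the correlation
#' matrix is sparsified (entries with `|r| < t` zeroed, unit diagonal
#' kept), eigendecomposed, and the nearest-neighbour spacing distribution
#' ([nnsd()]) of the spectrum is compared by chi-square distance to the
#' Poisson law `exp(-s)` and to the Wigner surmise
#' `(pi*s/2) exp(-pi*s^2/4)`. Random-matrix theory predicts GOE (Wigner)
#' spacings while spurious noise correlations still couple the features
#' and Poisson spacings once only genuine block structure remains; the
#' chosen threshold is the smallest grid point at which the Poisson fit
#' wins for two consecutive grid points (with at least 20 usable
#' eigenvalues), i.e. the onset of the GOE-to-Poisson transition.
#'
#' @param r_matrix symmetric correlation matrix with unit diagonal, or a
#'   `cor_res` from [c_net_calculate()] (intra mode).
#' @param t_min,t_max,step ascending scan grid within `[0, 1)`.
#' @param nbins,smax chi-square binning of the spacing histogram.
#' @param min_eigen minimum distinct eigenvalues for a usable fit.
#' @return An `rmt_scan` object: tibble with columns `threshold`,
#'   `chi2_poisson`, `chi2_goe`, `n_eigen`, plus attributes `chosen`
#'   (selected threshold, or `NA` if no grid point qualifies) and the scan
#'   parameters.
#' @export
rmt_scan <- function(r_matrix, t_min = 0.3, t_max = 0.9, step = 0.01,
                     nbins = 20L, smax = 3, min_eigen = 20L) {
  if (inherits(r_matrix, "cor_res")) {
    if (r_matrix$mode != "intra") abort("rmt_scan needs an intra-omics correlation matrix")
    r_matrix <- r_matrix$r
  }
  if (!is.matrix(r_matrix) || nrow(r_matrix) != ncol(r_matrix))
    abort("r_matrix must be a square matrix")
  if (anyNA(r_matrix)) {
    keep <- !apply(is.na(r_matrix), 1L, any)
    r_matrix <- r_matrix[keep, keep, drop = FALSE]
  }
  if (max(abs(r_matrix - t(r_matrix))) > 1e-8) abort("r_matrix must be symmetric")
  if (step <= 0 || t_max <= t_min) abort("threshold grid must be ascending (step > 0, t_max > t_min)")
  if (t_min < 0 || t_max >= 1) abort("threshold grid must lie within [0, 1)")
  grid <- seq(t_min, t_max, by = step)

  rows <- purrr::map(grid, function(t) {
    a <- r_matrix
    a[abs(a) < t] <- 0
    diag(a) <- 1
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    ev <- sort(ev)
    ev <- ev[c(TRUE, diff(ev) > 1e-8)]
    if (length(ev) < min_eigen)
      return(tibble(threshold = t, chi2_poisson = NA_real_,
                    chi2_goe = NA_real_, n_eigen = length(ev)))
    s <- nnsd(ev)
    tibble(threshold = t,
           chi2_poisson = nnsd_chi2(s, nnsd_poisson, nbins, smax),
           chi2_goe = nnsd_chi2(s, nnsd_wigner, nbins, smax),
           n_eigen = length(ev))
  })
  tab <- dplyr::bind_rows(rows)

  ok <- !is.na(tab$chi2_poisson) & tab$chi2_poisson < tab$chi2_goe
  chosen <- NA_real_
  for (i in seq_len(length(grid) - 1L)) {
    if (ok[i] && ok[i + 1L]) { chosen <- grid[i]; break }
  }
  if (is.na(chosen))
    warn("no threshold qualified (degenerate or persistently GOE spectrum); chosen = NA")
  structure(tab, class = c("rmt_scan", class(tab)),
            chosen = chosen,
            params = list(t_min = t_min, t_max = t_max, step = step,
                          nbins = nbins, smax = smax, min_eigen = min_eigen))
}

#' Chosen threshold of an RMT scan
#' @param scan an `rmt_scan`.
#' @return The selected threshold (numeric scalar, `NA` if none).
#' @export
rmt_chosen <- function(scan) {
  stopifnot(inherits(scan, "rmt_scan"))
  attr(scan, "chosen")
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat(sprintf("<rmt_scan> %d thresholds in [%.2f, %.2f], chosen = %s\n",
              nrow(x), min(x$threshold), max(x$threshold),
              format(attr(x, "chosen"))))
  NextMethod()
}

#' Plot an RMT threshold scan
#'
#' Chi-square distance of the spacing distribution to the Poisson and GOE
#' references along the threshold grid, with the chosen threshold marked.
#'
#' @param object an `rmt_scan`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rmt_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("chi2_poisson", "chi2_goe"),
                              names_to = "reference", values_to = "chi2")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$chi2,
                                          colour = .data$reference)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "correlation threshold", y = "chi-square distance",
                  colour = NULL)
  ch <- attr(object, "chosen")
  if (!is.na(ch)) p <- p + ggplot2::geom_vline(xintercept = ch, linetype = 2)
  p
}
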