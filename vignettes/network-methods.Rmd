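---
title: "Methods: correlation networks, RMT thresholding, modules and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation networks, RMT thresholding, modules and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicnet)
```

omicnet builds and analyses correlation-based association networks from
feature × sample omics tables. This vignette is the package's account of
the statistical machinery: the models and conventions implemented, the
tunable parameters and their defaults, what the synthetic-data generators
do and do not emulate, and the numerical choices made where the design was
genuinely open.

## Correlation engine

`c_net_calculate()` computes all pairwise correlations of one table
(intra mode: every unordered feature pair once) or across two tables
aligned on shared sample ids (inter mode). Spearman is Pearson on
midranks, so ties receive average ranks. The two-sided p-value is
analytic: with $n$ samples and correlation $r$,

$$t = r\sqrt{\frac{n-2}{1-r^2}}, \qquad p = 2\,P(T_{n-2} > |t|).$$

This replaces permutation loops and makes a $10^4$-feature screen a
matrix-product problem. Conventions worth knowing:

* $|r| = 1$ maps to $p = 0$ exactly; inside the formula $r$ is clipped to
  $\pm(1 - 10^{-15})$ so the square root never overflows.
* $n \ge 3$ is required ($df = n - 2 \ge 1$); $n = 3$ is allowed with a
  warning because a $t_1$ (Cauchy) reference has no moments and the
  resulting p-values are extremely heavy-tailed.
* Zero-variance features produce `NA` rows/columns in $r$, $p$ and
  $p_{adj}$ alike, never silent zeros.
* Missing data: the default is complete-case over the aligned sample set
  (the `omics_table` container refuses non-finite values at ingestion, so
  this only matters for raw matrices). `use = "pairwise"` switches to
  pairwise-complete observations with the per-pair $n$ entering the t
  formula.

Multiple-testing correction (`adjust_p()`, backed by `stats::p.adjust`)
is applied over the tests actually performed: $\binom{k}{2}$
upper-triangle tests in intra mode (then mirrored; the diagonal is never
adjusted), rows × columns in inter mode. `NA` p-values are excluded from
the test universe unless an explicit `m` is supplied.

A Bray–Curtis dissimilarity mode is reserved in the interface but
deliberately unimplemented in this version; requesting it raises an
informative error rather than silently falling back.

## RMT threshold selection

Fixed cutoffs like $|r| > 0.6$ are arbitrary and dataset-dependent.
`rmt_scan()` selects a cutoff from the data using the spectral signature
of noise: for each candidate threshold $t$ on a grid (default 0.3–0.9 in
steps of 0.01), entries with $|r| < t$ are zeroed (unit diagonal kept),
the matrix eigendecomposed, and the nearest-neighbour spacing
distribution (NNSD) of the unfolded spectrum compared by a chi-square
distance against two references: the Wigner surmise
$(\pi s/2)e^{-\pi s^2/4}$, characteristic of the Gaussian orthogonal
ensemble (GOE) and of spectra whose eigenvectors mix many features, and
the Poisson law $e^{-s}$, characteristic of superpositions of decoupled
blocks. The chosen threshold is the smallest grid point at which the
Poisson fit beats the GOE fit at two consecutive grid points with at
least 20 usable eigenvalues — the onset of the GOE → Poisson transition,
i.e. the point where spurious noise couplings have been removed.

Numerical choices (all exposed as arguments):

* **Unfolding.** The spectrum is unfolded with a parameter-light
  empirical-CDF mapping: the ECDF is interpolated linearly through
  quantile knots (one knot per ~20 eigenvalues, minimum 5 knots),
  evaluated at each eigenvalue and scaled by the spectrum size; spacings
  are normalized to mean exactly 1. The knot smoothing removes the global
  spectral-density trend while preserving spacing-scale fluctuations. A
  literal same-sample midrank-ECDF mapping would be degenerate (every
  spacing identically 1), which is why a smoothed CDF is required.
* **Duplicate collapse.** Thresholded correlation matrices produce exact
  zero blocks and hence (near-)degenerate eigenvalues; eigenvalues closer
  than $10^{-8}$ are collapsed before spacing computation.
* **Binning.** The chi-square uses 20 equal bins on $[0, 3]$; spacings
  beyond 3 are dropped and the reference probabilities renormalized over
  the window. Renormalizing (rather than clipping the tail into the last
  bin) matters: outlier eigenvalues otherwise inflate the last bin, whose
  expected count under the Wigner surmise is nearly zero, and the
  statistic would spuriously favour Poisson for any spectrum with large
  module eigenvalues.
* **Two-consecutive-points rule.** Requiring the Poisson verdict at two
  adjacent grid points stabilizes the transition estimate against grid
  noise.

A caveat the tests make explicit: on the package's own planted-block
fixture (every feature loading on a strong block factor), between-block
residual correlations are attenuated by $(1 - \rho_{within})$ and
essentially never reach the scan grid, so the thresholded matrix is
block-diagonal — Poisson — at every grid point and the scan returns the
grid minimum. A GOE phase inside the window requires data with a dense
unstructured noise floor in the scanned range, which real small-sample
tables have but this deliberately clean generator does not. The NNSD
discrimination itself is validated directly on GOE and independent-eigenvalue
ensembles.

## Network construction and modules

`c_net_build()` keeps an edge iff $|r| > r_t$ **and** $p_{adj} < p_t$,
both strict, mirroring the usual "greater than / less than" reporting
conventions; isolated nodes are dropped by default. Edge attributes store
$r$, its sign, $|r|$ as weight, and $p_{adj}$; construction parameters
are graph attributes, so a network is self-describing.

`detect_modules()` runs fast greedy (Clauset–Newman–Moore) modularity
optimization with weights $|r|$: negative correlations contribute their
magnitude to community structure and keep their sign as an edge
attribute; signed-modularity null models are out of scope. The dendrogram
is cut at the maximum-modularity step explicitly (the underlying
library's default cut can disagree with its own modularity trace when
merges tie). Module ids are relabelled 1…k by descending size, ties
broken by smallest member name, so labellings are deterministic. The
reported $Q$ is recomputed from the returned partition, and the test
suite checks it against an independent evaluation of
$Q = \sum_c (w_c/W - (s_c/2W)^2)$.

`zipi()` uses unweighted degrees (the common convention in co-occurrence
work, and the one that makes $Z_i$ a true count z-score):
$Z_i = (k_{is} - \bar k_s)/\sigma_s$ within the node's own module
($\sigma_s = 0 \Rightarrow Z_i = 0$), and
$P_i = 1 - \sum_m (k_{im}/k_i)^2$. Role cutoffs default to the
Guimerà–Amaral values $Z_i \ge 2.5$, $P_i \ge 0.62$ and are arguments,
not constants. Isolated nodes have undefined $P_i$ (`NA`) and are
classified peripheral.

`assemble_multiomics()` unions inter-omics correlation blocks (e.g.
biological exposome × transcriptome at $|\rho| > 0.5$, chemical exposome
× transcriptome at $|\rho| > 0.6$, each with its own adjusted-p cutoff),
tags nodes with their omics layer, refuses feature ids that appear under
two layers, and tallies positive/negative edges per block — the summary
used to contrast microbially- versus chemically-associated transcription.

## Topology, null models and robustness

The 17-metric registry (`topology_metrics()`, version 1) pins the
headline report. All metrics are computed on the simple unweighted graph
(edge presence), the standard choice for co-occurrence networks; weighted
variants are deliberately deferred. On disconnected graphs, average path
length and diameter are computed on the largest connected component and
the report is flagged, while global efficiency keeps the $1/\infty = 0$
convention and stays a whole-graph quantity. Average local clustering
counts nodes of degree < 2 as 0; transitivity (the triangle ratio) is
reported separately. Natural connectivity is
$\ln\!\big(\tfrac1N\sum_i e^{\lambda_i}\big)$ over adjacency eigenvalues,
computed with a max-shift to avoid overflow; it is the robustness
headline because it strictly increases with redundant paths and is
insensitive to degree-preserving rewiring artifacts.

`compare_random()` reports z-scores against Erdős–Rényi $G(n,m)$ or
degree-preserving double-edge-swap nulls ($10m$ swaps, multi-edges and
self-loops rejected); a zero null standard deviation yields `NA`, never
an infinity. `fit_powerlaw_degree()` is a Clauset-style discrete MLE with
KS-minimal $x_{min}$ — reported as a fit, never as a verdict of
scale-freeness. `robustness()` removes cumulative node sets (targeted
orders ranked once on the intact network, ties by node id; random orders
per seeded trajectory) and tracks largest-component fraction (relative to
the intact node count), natural connectivity and efficiency.

## Layouts

All angular conventions are fixed once: circles start at 90° and proceed
counter-clockwise; grids fill row-major; group circles use scale 0.3 and
packed module interiors 0.8 of the module radius. `as_polygon()` spaces a
group's $k$ nodes at fractions $1/(k{+}1), \dots, k/(k{+}1)$ of its side,
keeping vertices free. `spatstat_layout()` samples uniformly inside an
arbitrary simple polygon by ear-clip triangulation and area-weighted
barycentric sampling — exact for concave shapes where rejection sampling
is merely used as the test oracle — or places nodes at equal arc-length
steps along the boundary. `g_layout()` applies per-group similarity
transforms (anchor, scale, inner algorithm), so nested compositions
preserve inner geometry exactly. `g_layout_circlepack()` packs module
circles of radius $\propto \sqrt{size}$ greedily along an Archimedean
spiral with a hard non-overlap guarantee. Classical force-directed and
tree layouts delegate to igraph behind a seed wrapper, making every
stochastic layout bit-reproducible.

## Synthetic data: what it does and does not emulate

`planted_block_data()` draws each block's features as a shared latent
Gaussian factor plus independent noise, with the factor variance
$v = \rho\,\sigma^2/(1-\rho)$ chosen so the within-block population
correlation is exactly the requested $\rho$; memory stays O(features ×
samples). Defaults (100 features, 50 samples, 5 blocks, $\rho = 0.7$,
unit noise) give a strongly modular screen of the size used throughout
the tests; $\rho = 0$ is the calibrated null used to verify the 5%
false-positive rate of the analytic p-values. `planted_module_network()`
is a stochastic block model with the planted partition attached for
recovery scoring. These generators produce Gaussian, compositionally
unconstrained data with equal block sizes and a single factor per block:
they validate the statistical machinery (calibration, recovery,
invariances), not the compositional, zero-inflated, heavy-tailed
character of real sequencing data — conclusions about real microbiome
tables still require the usual compositional caution.

Problem sizes in the test-suite and acceptance script (200 × 50 oracle
checks, 1000 × 1000 spectral ensembles, 100-node module recovery, 100
seeded layout runs) were chosen as the smallest sizes at which the
statistical properties under test are stable.

## Known limitations

Correlation networks capture marginal association, not causation or
conditional dependence; partial correlations, mutual information and
compositionality-aware estimators (e.g. SparCC-style) are out of scope in
this version, as are signed-modularity community models, weighted
topology variants, and statistical comparisons across groups of
subnetworks. Pajek output is intentionally lossy (ids, labels,
coordinates, weights only); GraphML is the lossless interchange format,
with canonical lexicographic attribute order so repeated writes are
byte-identical.
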