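# omicnet

Correlation-based network construction and analysis for high-dimensional
omics data.

Microbial ecologists and multi-omics researchers routinely summarize a
feature × sample abundance table (taxa, genes, metabolites, chemical
exposures) as a **co-occurrence network**: nodes are features, edges are
statistically significant pairwise correlations. omicnet implements the
full workflow for that kind of analysis — at the scale of thousands of
features — as a tested R library with a thin command-line wrapper:

- **Vectorized all-pairs correlation** (Pearson, or Spearman on midranks)
  with analytic two-sided p-values from
  `t = r·√((n−2)/(1−r²))` on `n−2` degrees of freedom — no permutation
  loops — and Benjamini–Hochberg / Holm / Bonferroni correction over the
  tests actually performed (upper triangle within one table, rows ×
  columns between two tables).
- **Random-matrix-theory (RMT) threshold selection**: scanning candidate
  cutoffs `t`, sparsifying the correlation matrix at each, and locating
  the transition of the eigenvalue nearest-neighbour spacing distribution
  (NNSD) from the Wigner surmise `(πs/2)·e^(−πs²/4)` (GOE: noise still
  couples features) to the Poisson law `e^(−s)` (only block structure
  left). The chosen cutoff replaces an arbitrary `|r| > 0.6`-style rule.
- **Module and role analysis**: fast greedy (Clauset–Newman–Moore)
  modularity optimization, and Zi–Pi classification — within-module
  degree z-score `Zi` and participation coefficient
  `Pi = 1 − Σ_m (k_im/k_i)²` with the Guimerà–Amaral cutoffs
  (`Zi ≥ 2.5`, `Pi ≥ 0.62`) separating module hubs, connectors, network
  hubs and peripherals.
- **Topology and stability**: a versioned 17-metric registry (density,
  proportion of negative edges, average path length, diameter,
  clustering, transitivity, global efficiency, modularity, natural
  connectivity `ln((1/N)·Σ e^{λᵢ})`, component structure, centralization,
  plus four per-node centralities), comparison against Erdős–Rényi and
  degree-preserving null models, discrete power-law degree fits, and
  robustness curves under random or targeted node removal.
- **Multi-omics assembly**: independent per-block thresholds for, e.g.,
  microbial-exposome–transcriptome and chemical-exposome–transcriptome
  correlation blocks, united into one layered network with per-block
  positive/negative edge tallies.
- **Layouts**: grouped placement on polygon sides (`as_polygon`), group
  circles (`as_polycircle`), packing module circles with radius ∝ √size
  (`g_layout_circlepack`), pseudo-3D layer stacks
  (`g_layout_multi_layer`), arbitrary per-group anchors/scales
  (`g_layout`), and placement inside or along a user polygon
  (`spatstat_layout`, triangulation-based, concave-safe), plus exact
  affine transforms. All stochastic layouts are bit-reproducible given a
  seed.
- **I/O**: GraphML (attribute-lossless, canonical byte-stable output),
  Pajek (documented id/label/coordinate/weight subset), edge-list TSV,
  and abundance TSV with explicit missing-data policies.

The graph container is an igraph-backed `metanet` object, so every igraph
operation still applies; tabular accessors (`net_nodes()`, `net_edges()`,
`tidy()`, `glance()`) and `autoplot()` methods keep the workflow
pipe-friendly.

## Worked example

```r
library(omicnet)

tab <- planted_block_data(n_features = 100, n_samples = 50, n_blocks = 5,
                          within_r = 0.7, seed = 42)
res <- c_net_calculate(tab, method = "spearman", adjust = "BH")
net <- c_net_build(res, r_threshold = 0.6, p_threshold = 0.05)
net
#> <metanet> 100 nodes, 797 edges
#>   graph attrs: method, r_threshold, p_threshold, n_samples

mod <- detect_modules(net)
c(modules = max(mod$module), Q = round(modularity_q(mod), 3))
#> modules      Q
#>   5      0.795

glance(topology_report(net))[, c("edge_density", "average_path_length",
                                 "modularity", "natural_connectivity")]
#> # A tibble: 1 × 4
#>   edge_density average_path_length modularity natural_connectivity
#>          <dbl>               <dbl>      <dbl>                <dbl>
#> 1        0.161                1.02      0.795                 14.7
```

The generator planted five equally sized correlated blocks
(within-block ρ = 0.7); the built network recovers exactly five modules
at high modularity (Q = 0.795), and the short average path length (1.02)
reflects that each module is a near-clique at these thresholds. The same
steps run from a shell:

```sh
inst/cli/omicnet fixtures --recipe planted_block --seed 42 --out tab.tsv
inst/cli/omicnet calc  --in tab.tsv --method spearman --adjust BH --out corr.rds
inst/cli/omicnet build --corr corr.rds --rt 0.6 --pt 0.05 --out net.graphml
inst/cli/omicnet topo  --net net.graphml --out topo.json
```

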