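# ductnet

Two analysis chains for studying how overexpression of a membrane estrogen
receptor variant (ERα36) disrupts normal mammary epithelium, packaged for
anyone who needs either half on its own:

* **Transcriptomics** — screen a two-group expression matrix for
  differentially expressed genes (DEGs), test gene-set over-representation,
  layer a relation-typed regulator digraph into per-function hierarchical
  networks, and extract the intermediate regulators common to all
  functions.
* **Whole-mount morphometry** — quantify the ductal tree of a stained
  mammary gland whole mount: vesselness enhancement, hard-threshold
  segmentation, skeletonization, and extension / branching / sprout counts
  with unpaired group comparison.

A synthetic-data module (`sim_expression`, `sim_geneset_collection`,
`sim_regulatory_graph`, `sim_wholemount`) generates every input with known
ground truth, so the whole pipeline is testable offline.

## The methods in brief

**DEG screen.** A gene is a DEG when its folded linear ratio of group means
`max(r, 1/r)` (r = mean_B / mean_A) is ≥ 2.3 **and** its
Benjamini–Hochberg-adjusted p from a pooled-variance t-test on log2
intensities is < 0.05.

**Enrichment.** For a DEG list of size *n* from a universe of *N* genes and
a set with *K* members, the overlap *k* is scored by the upper-tail
hypergeometric probability P(X ≥ k), alongside the *affected proportion*
k/K of the set.

**Hierarchy.** Level 0 is one function's DEG set; level i+1 is every
unassigned regulator with an outgoing edge (any relation: affected /
activated / inhibited) into level i; iteration stops at the fixpoint. This
equals reverse-BFS distance to the DEG layer, giving each regulator its
minimal level. Nodes present at level ≥ 1 in all function networks —
optionally intersected with a pathway gene list — are the *common
intermediates*.

**Morphometry.** Frangi vesselness from the scale-normalized Hessian
eigenvalues (|λ1| ≤ λ2 < 0 on ridges):
`exp(-Rb²/2β²)·(1-exp(-S²/2c²))`, max over scales; Otsu (or fixed)
threshold; Guo–Hall thinning; then sprouts = endpoint pixels, branch points
= merged ≥3-neighbour clusters, extension = Σ steps (1 orthogonal, √2
diagonal), in px and mm.

## Worked example

```r
library(ductnet)

# 1000 genes, 100 planted at fold 4, triplicates, log2 noise SD 0.25
sim  <- sim_expression(n_genes = 1000, n_de = 100, effect = 4,
                       n_per_group = 3, noise_sd = 0.25, seed = 1)
degs <- select_degs(gene_stats(sim$expr, sim$groups))
glance(degs)
#>   n_genes n_deg  n_up n_down fc_threshold alpha
#> 1    1000    95    41     54          2.3  0.05
```

95 of the 100 planted genes survive the dual criterion (41 up, 54 down).
Enrichment against a collection with one planted set:

```r
u    <- sim$expr$gene_id
coll <- sim_geneset_collection(u, n_sets = 8, size_range = c(25, 40),
          planted = list(set_index = 1, fraction = 0.6,
                         deg_list = deg_ids(degs)), seed = 2)
head(rank_sets(coll, deg_ids(degs), u), 3)
#>   set_id     K     n     N     k  p_hyper affected_proportion
#> 1 SET001    29    95  1000    17 2.12e-11               0.586
#> 2 SET003    30    95  1000     6 5.70e- 2               0.2
#> 3 SET002    39    95  1000     7 6.81e- 2               0.179
```

The planted set ranks first (17 of its 29 members are DEGs, 59% affected,
p ≈ 2×10⁻¹¹); the unplanted sets sit at chance level. And the imaging arm,
on a simulated whole mount whose true topology is known:

```r
tree <- sim_wholemount(depth = 3, seed = 3)   # truth: 6 branches, 8 endpoints, 10.0 mm
q    <- quantify_wholemount(tree, sigmas = c(1, 2, 3))
q$metrics[, c("extension_mm", "n_branch", "n_sprout")]
#>   extension_mm n_branch n_sprout
#> 1         10.7        6        8
```

Both counts are exact and the extension is within 7% (typically 3–4%) of
the true 10.0 mm. `autoplot(q)` draws the skeleton overlay (white) with
branch clusters (green) and sprouts (red); `compare_groups()` runs the
per-metric unpaired t-test across animals. Closed-form assay helpers are
included, e.g. `doubling_time(100, 800, 72)` → 24 h.

End-to-end runs with on-disk inputs, TSV/GraphML outputs and a JSON
manifest go through `run_transcriptomics(config, out_dir)` and
`run_wholemount(config, out_dir)`; see the methods vignette
(`vignettes/ductnet-methods.Rmd`) for every model, parameter and design
decision.

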