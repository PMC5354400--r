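---
title: "Methods: regulator hierarchies and ductal tree morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulator hierarchies and ductal tree morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductnet)
```

ductnet implements two analysis chains used to characterize how
overexpression of a membrane estrogen receptor variant (ERα36) disrupts
mammary epithelium: a transcriptomics chain that goes from a two-group
expression matrix to hierarchical regulator networks and their common
intermediates, and an imaging chain that quantifies the architecture of
whole-mounted mammary ductal trees. This vignette explains the models,
their assumptions, the tunable parameters, and the design decisions taken
where the methods left room for choice.

## The DEG screen

The screen takes a genes × samples intensity matrix with a two-group design
(typically triplicates per group, the smallest design the test supports) and
flags a gene as differentially expressed when **both** of the following hold:

* the *variation factor* — the folded linear ratio of group means,
  $\max(r, 1/r)$ with $r = \bar{x}_B / \bar{x}_A$ — is at least 2.3
  (non-strict, so a gene exactly at 2.3 passes), and
* the Benjamini–Hochberg adjusted p-value of a two-sample t-test on log2
  intensities is strictly below 0.05.

Folding the ratio treats up- and down-regulation symmetrically, which is
what a single "absolute" threshold implies. Intensities are modelled as
log-normal around a per-gene baseline, so the test operates on the log2
scale while the ratio is reported on the linear scale; multiplying the whole
matrix by a constant changes neither (`gene_stats` is scale equivariant).

**Pooled versus per-gene variances.** The per-gene test defaults to the
pooled-variance (Student) t-test, the same unpaired test used for every
other group comparison in the package. The Welch variant is available
(`var_equal = FALSE`) but is *not* the default for a concrete reason: with
n = 3 per group, the Welch–Satterthwaite degrees of freedom fluctuate
between 2 and 4 per gene, and the heavy tails of the t distribution at 2 df
roughly halve the screen's sensitivity at fold 4 and log2 noise SD 0.25
(about 0.55 versus 0.99 pooled, at matched false-discovery proportion).
With equal group sizes and a common noise model the pooled test is the
better-calibrated choice; moderated-variance (empirical Bayes) tests are
deliberately out of scope.

Degenerate genes — zero variance in both groups — get p = 1 when the means
agree and p = 0 with a warning when they do not, so a saturated probe cannot
propagate NaN through the screen.

`bh_adjust` is the standard step-up rule
$q_{(i)} = \min_{j \ge i} p_{(j)} \, m / j$ capped at 1; the test suite
checks it against a brute-force enumeration of that formula.

## Gene-set over-representation

For a DEG list of size $n$ drawn from a universe of $N$ genes and a set
with $K$ members inside the universe, the overlap $k$ is scored with the
one-sided upper-tail hypergeometric probability
$P(X \ge k)$, plus the *affected proportion* $k / K$ — the fraction of a
function's gene set touched by the perturbation, the quantity used to rank
biological functions by how broadly they respond.

Conventions, all configurable:

* the universe is every gene on the array (all matrix rows), the standard
  background for chip-based enrichment;
* only over-representation is tested (depletion is out of scope);
* raw overlap p-values are reported; BH across sets is available
  (`adjust = TRUE`) but off by default, matching how such overlaps are
  usually reported by online tools;
* set members absent from the universe are dropped with a note, and ties in
  the ranking break by descending affected proportion, then set id, so the
  output is deterministic.

Note one property that surprises people: for fixed $k, K, n$, *adding* an
inert gene to the universe makes $\ge k$ overlaps rarer under the null, so
the p-value shrinks. Choosing a smaller, curated universe is therefore the
conservative option.

## Hierarchical regulator networks

The substrate is a directed graph over genes/regulators whose edges carry
exactly one of three relation labels — *affected*, *activated*, *inhibited* —
the three adjacency matrices of a knowledge-base export sharing one node
index. The three matrices are unioned for connectivity: a regulator
regulates, whatever the sign; labels are preserved as edge attributes in all
exports but never influence the algorithm.

Given the DEG set of one cellular function (level 0), the layering is
iterative minimal-level identification:

1. level 1 = every not-yet-assigned candidate or upstream regulator with at
   least one outgoing edge into level 0;
2. level i+1 = likewise, into level i;
3. stop when a pass adds nothing (the fixpoint; `iterations` counts all
   passes including the final empty one).

This is exactly breadth-first distance to the DEG layer along reversed
edges, which the test suite verifies against an independent igraph oracle on
random graphs up to 1000 nodes. Consequences worth stating: each node gets
the *smallest* level at which it can act (a node regulating both level 0 and
level 1 sits at level 1); nodes with no directed path into the function's
DEG set are excluded entirely; adding an edge can only lower levels and
deleting one can only raise them. Declared upstream regulators (the
receptor gene and its agonist, in the motivating study) are eligible for any
level and additionally tagged for export. Genes tagged as DEGs but outside
the current function's DEG set are *not* eligible as intermediates — the
candidate regulator set is an explicit input (`candidates`), defaulting to
every non-DEG node, because the original procedure layered a predicted
regulator list rather than the whole interactome.

**Common intermediates.** Each node appearing at level ≥ 1 in a network is
an intermediate there; its multiplicity is the number of per-function
networks containing it. DEG-layer membership deliberately does not count —
the object of interest is shared *regulators*, not shared targets. The
default selection takes nodes present in all networks (multiplicity equal
to the number of functions), with the threshold configurable because the
membership rule behind a published common-intermediate count can rarely be
pinned down exactly; an optional intersection with a pathway membership
list (e.g. the union of the best signaling-pathway overlaps) mirrors the
usual final filter.

## Whole-mount quantification

### Vesselness enhancement

Ducts in a stained whole mount are dark, elongated, and locally tubular.
`frangi_vesselness` scores ridge-likeness from the eigenvalues
$|\lambda_1| \le |\lambda_2|$ of the scale-normalized Gaussian Hessian
($\sigma^2 H$, computed by Gaussian-derivative filtering):

$$V_\sigma = \begin{cases} 0 & \lambda_2 > 0 \\
\exp\!\left(-\frac{R_b^2}{2\beta^2}\right)
\left(1 - \exp\!\left(-\frac{S^2}{2c^2}\right)\right) & \text{otherwise}
\end{cases}$$

with blobness $R_b = \lambda_1/\lambda_2$, structureness
$S = \sqrt{\lambda_1^2 + \lambda_2^2}$, and the final response the
pixel-wise maximum over scales. Parameters:

* `sigmas` — the scale ladder, default a 7-point geometric series from 1 to
  8 px. The response of a tube is widest at the largest responding scale,
  so when the goal is a width-accurate segmentation (rather than gap-free
  enhancement) the ladder should stop near the expected duct *radius*; the
  synthetic-tree analyses use `c(1, 2, 3)` px for 5 px-wide tubes for
  exactly this reason.
* `beta = 0.5` — the standard blobness sensitivity from the original
  formulation; isotropic structures ($R_b \approx 1$) are suppressed.
* `c` — structureness sensitivity; the default policy takes half the
  maximum Hessian Frobenius norm per scale, which adapts to image contrast.
  A scale whose maximum norm is numerically zero (below 1e-8) is skipped,
  which makes the response on a constant image exactly zero rather than an
  amplification of FFT dust.
* polarity is an explicit input, never guessed: `ducts_dark` images are
  inverted so the bright-ridge convention ($\lambda_2 < 0$) applies.

The discrete second-derivative kernels are mean-subtracted so a constant
image has an exactly zero Hessian despite kernel truncation, and kernel
radius (3σ) is capped at half the image extent.

### Segmentation and skeletonization

Segmentation is a hard threshold on the response — Otsu's histogram split by
default (reproducible and parameter-free), a fixed value as override —
followed by removal of 8-connected components smaller than `min_object_px`
(default 50 px, suppressing noise speckle while keeping any realistic duct
fragment).

Skeletonization uses two-subiteration Guo–Hall thinning, which preserves
the mask's connected components and holes and yields an 8-connected,
1 px-wide skeleton. Dense junctions can survive thinning as a solid 2×2
block; a cleanup pass removes a *simple* pixel of any such block (one whose
deletion does not change local connectivity), falling back to a global
component-count check when no block pixel is locally simple.

### Morphometry

On the thinned skeleton (a solid 2×2 block anywhere is rejected with advice
to re-skeletonize):

* a **sprout** (end bud) is a skeleton pixel with at most one 8-connected
  skeleton neighbour;
* a **branch point** is a cluster: pixels with ≥ 3 neighbours are merged by
  8-connectivity and each cluster counts once, because thinning routinely
  leaves two adjacent high-degree pixels at one anatomical junction;
* **extension** sums skeleton adjacencies, 1 per orthogonal and $\sqrt 2$
  per diagonal step, reported in px and mm. The geodesic diameter (longest
  path through the skeleton) is reported alongside, since "total extension"
  can also be read as the tree's reach; both are in the output so the
  choice is the reader's.

Two systematic effects partially cancel in the extension estimate: digital
staircase inflation (an 8-connected line at 30° from an axis measures about
7% long under these step weights) and tip retraction (a skeleton ends about
one mask half-width short of the true tip). On noiseless synthetic trees
the net error averages 3–4% with occasional single trees near 6%; counts
are exact. Whether the tree's root entry point should count as a sprout is
a definitional choice; `exclude_root = TRUE` subtracts one endpoint per
connected component, and both conventions are available.

Group comparison (`compare_groups`) is the unpaired pooled-variance Student
t-test per metric with group means ± SEM, significance strictly below the
5% level; groups of fewer than two animals raise an error naming the group.

## The synthetic-data generators

Everything above is testable without any external data because each stage
has a generator producing inputs with known ground truth:

* `sim_expression` — RMA-like intensities: per-gene log2 baselines uniform
  in [6, 12], Gaussian log2 noise (default SD 0.25), a planted gene subset
  shifted by log2 of the effect (default fold 4) in group B, triplicates
  per group. It emulates normalized two-channel-free array data; it does
  **not** model probe-level effects, batch structure, or correlated genes,
  so a passing screen here says nothing about robustness to those.
* `sim_geneset_collection` — random subsets of the universe in a size
  range, optionally with one set planted to overlap a DEG list by an exact
  fraction of its size.
* `sim_regulatory_graph` — planted consecutive levels above a DEG layer,
  every planted edge from level i+1 to level i, relation labels uniform.
  Optional noise edges are constrained to level(target) ≥ level(source) − 1
  (sources above level 0), which provably leaves every reverse-BFS distance
  at its planted value — noise obscures the picture without changing the
  right answer, so recovery must be exact even with noise.
* `sim_wholemount` — a random binary tree grown from a root at the bottom
  edge: per generation, a node branches with probability 0.9 into children
  at the parent heading ± (30° + uniform jitter, default half-width 10°);
  segment lengths are uniform in 25–45 px on a 384×384 canvas. Segments
  render as tubes of Gaussian cross-section (FWHM = `tube_width`, default
  5 px) subtracted from a light background (0.85 − 0.6 at centerline), with
  optional additive Gaussian noise; ducts are darker than background as in
  a carmine-stained mount, and the analysis inverts internally. A candidate
  segment that would pass within about one tube diameter (2 × width + 2 px)
  of existing ducts is re-drawn and then dropped, keeping the tree *open* —
  without this, Gaussian tails of nearby tubes fuse above any threshold and
  the rendered topology stops matching the recorded one. The truth stores
  the full segment tree; branch and tip counts and total length are
  recomputed from it, never cached independently. Not modelled:
  lobulo-alveolar structures, lymph nodes, uneven staining, 3-D overlap of
  a real flattened gland.

Every generator takes an explicit seed and touches no global RNG state; the
same call with the same seed is bit-identical.

## Orchestration and reproducibility

`run_transcriptomics` and `run_wholemount` chain the stages from a single
config (R list or YAML), write all tables as TSV, networks as GraphML
(level as node attribute, relation as edge attribute), overlays as PNG
(white skeleton, green branch clusters, red endpoints), and a
`manifest.json` recording the package version, every parameter actually
used, and MD5 digests of all file inputs. Outputs contain no timestamps,
so a rerun with the same config and inputs is byte-identical — the test
suite asserts this at file level.

## Problem sizes and known limitations

The shipped tests and the acceptance script run the screen at 1000 genes
(100 planted, 10 replicate simulations), layering on graphs up to 1000
nodes, exhaustive hypergeometric checks for universes up to 15 genes, and
ten noiseless depth-3/4 trees for morphometry — sizes chosen so the whole
suite exercises every claim in minutes on one core while keeping every
check at full strength; all scale linearly if enlarged.

Limitations worth restating: the screen assumes independent genes and a
common noise scale; enrichment ignores the GO graph (no parent-term
propagation); layering does not use edge signs, so activating and
inhibiting chains are not distinguished; the morphometry is 2-D and
assumes ducts resolve as ridges at the chosen scales; and the extension
measure inherits the digital-length bias discussed above.
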