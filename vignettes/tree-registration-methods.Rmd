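---
title: "Registering and clustering cancer subclonal evolutionary trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering and clustering cancer subclonal evolutionary trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneclust)
```

## The problem

Multi-region sequencing of a tumor yields, per patient, a rooted evolutionary
tree: the root is the normal cell, its single child is the founder clone, the
remaining nodes are sub-clones, and each edge length counts the somatic single
nucleotide variants (SSNVs) newly acquired by the child clone.  Cohorts of such
trees are hard to compare directly: trees differ in topology, in number of
nodes, in SSNV content, and in total SSNV count, so classical phylogenetic
distances (which assume a shared leaf set) do not apply.

`cloneclust` makes a cohort of heterogeneous clone trees comparable by
*registration*: every tree is embedded into one fixed *reference tree* — the
complete bifurcated tree whose depth $D$ is the maximum (post-binarization)
terminal depth in the cohort.  The reference has

$$m = 2\,(2^{D} - 1)$$

edges, indexed in level order (edges 1 and 2 leave the root; edge $k$ has
child edges $2k+1$ and $2k+2$).  A registered tree is the length-$m$ vector
$z$ of its edge lengths laid onto the reference; reference edges that receive
no observed edge are *degenerate* and carry 0.  Because all registered trees
then share a single topology, they occupy one orthant of tree space and plain
Euclidean geometry applies to the vectors.

## Registration rules

**Binarization.**  Observed trees may multifurcate.  A node with more than two
children keeps its canonically first child on the original edge; the remaining
children hang off a chain of zero-length "spine" edges, recursively.  This
conserves total edge length exactly, never decreases a terminal depth, and is
the identity on binary trees.  Spine nodes are bookkeeping, not sub-clones;
interpretation tools skip them.  The depth used for the reference is computed
*after* binarization so every mapped edge fits.

**Canonical child order.**  Children are ranked by (1) subtree depth,
deepest first, and (2) connecting edge length, longest first — the mapping
rule for sub-trees.  Two further keys, subtree total length and a canonical
subtree string, only break residual ties so that registration is a
deterministic function of the tree; genuinely identical siblings keep input
order.  The registered vector is therefore invariant to sibling order in the
input Newick.

**Mapping.**  The trunk (normal → founder edge) maps to reference edge 1; the
sibling root slot stays degenerate.  Below any mapped edge $k$, the
canonically first child takes slot $2k+1$ and the second $2k+2$.  Whether the
trunk occupies root slot 1 or is distributed at the root is a pure convention:
distances are unchanged as long as one convention is applied to every tree,
which is what the package does.

**Normalization.**  Each vector is divided by its own total,
$z_k \leftarrow z_k / \sum_k z_k$, removing between-patient differences in the
number of detected SSNVs.  Rows of the registered matrix $Z$ ($n \times m$)
sum to one, and uniform rescaling of one tree's edge lengths leaves its row
unchanged.

## Distances, clustering, interpretation

The dissimilarity between trees is the squared Euclidean form
$s(x_i, x_j) = (z_i - z_j)'(z_i - z_j)$.  One printed formula squares the
distance matrix a second time inside the classical-MDS double-centering; to
keep the MDS textbook-correct the pipeline treats the *square root* of $s$ as
its working distance, and CMDS re-squares it when forming
$B = -\tfrac12 H S^{\circ 2} H$.  Ward clustering runs on the same Euclidean
distances (`ward.D2`), which is exactly the geometry Ward's objective assumes.

The number of clusters, when not fixed by the user, is chosen by the gap
statistic: `cluster::clusGap` with the uniform-over-range reference
(`spaceH0 = "original"`), squared-distance dispersion (`d.power = 2`,
matching the original proposal), `n_boot = 100` reference draws, and the
1-SE rule (`cluster::maxSE`, `"Tibs2001SEmax"`).  `k_max` defaults to
$\min(n - 1, 10)$.  Cohorts whose registered vectors are all identical return
$K = 1$ with a warning rather than a degenerate gap curve.

Summary statistics use the population convention of the underlying model: the
tree mean is $\mu = \frac1n \sum_i z_i$ and the tree variance
$\sigma^2 = \frac1n \sum_i (z_i - \mu)'(z_i - \mu)$ — for two trees at
Euclidean distance $d$ this gives $d^2/4$, and in general it equals the mean
squared dissimilarity to $\mu$.

**Sub-clonal diversity curves.**  For interpretation the package draws a
lineage-through-time style step function: $y(x)$ is the number of extant
clones (counting the normal cell) once a fraction $x$ of the tree's SSNVs has
accumulated.  A clone is born when the SSNVs along its whole root path have
accumulated, so each non-root node steps the curve at its normalized root
distance: $y(x) = 1 + \#\{v : d_{\mathrm{root}}(v) \le x\}$.  Thus $y(0) = 1$
(normal cell only) and the founder appears exactly at the trunk fraction: a
tree whose trunk carries 30% of SSNVs has $y(0.3) = 2$.  Ties merge into one
step of the tie's multiplicity, and binarization spine nodes are not counted.
The per-cluster "first expansion" statistic is the median trunk fraction of
the member trees.

## The cohort simulator

The simulator provides labeled benchmark cohorts in three designs: **I**
topology classes only (monoclonal `MC`, polyclonal-low `PL`, polyclonal-high
`PH`, mutator `MT`; all edge lengths 1), **II** one topology (`PM`) with three
SSNV-accumulation classes (trunk `TR`, balanced `BL`, branch `BR`), and
**III** the nine products $\{PL, PM, PH\} \times \{TR, BL, BR\}$, ten trees
per class by default.

The generative details are this package's own reconstruction; the published
description of the benchmark is qualitative, so the constants below were fixed
once, a priori, to make the lowest index a near-noiseless regime and the
spread grow geometrically:

* *Topology noise.*  Each tree receives $E \sim \mathrm{Poisson}(\lambda)$
  edits, $\lambda(i) = 0.05 \cdot 3^{\,i-1}$ for dispersion index $i$; an edit
  is a leaf insertion, leaf deletion (never shrinking below two nodes), or
  leaf regraft, drawn uniformly among the feasible ones.  At index 1 roughly
  one tree in twenty is altered, matching the near-perfect low-index regime;
  by index 5 ($\lambda = 4.05$) class structure is heavily blurred.
* *Edge lengths.*  The trunk fraction is
  $p \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ with $\mu = 0.8/0.5/0.2$ for
  TR/BL/BR and $\phi(v) = 400/2^{\,v-1}$ for variance index $v$ (standard
  deviation about 0.02 at $v = 1$, 0.11 at $v = 5$); the remaining mass is
  split over non-trunk edges by a symmetric Dirichlet with
  $\alpha(v) = 30/2^{\,v-1}$.
* *Totals.*  Per-tree SSNV totals are uniform on 100–1000 (the order of
  magnitude seen in multi-region studies) and integer counts are produced by
  largest-remainder rounding, conserving the total exactly.

At the lowest indices the cohort satisfies a separability sanity check (mean
between-class distance at least three times the mean within-class distance),
which is what makes parameter-recovery tests meaningful.  What the simulator
does **not** emulate: reconstruction error from real VAF pipelines, uneven
region sampling, driver/passenger structure, or correlated class sizes — so
passing recovery tests shows the pipeline separates the encoded signal, not
that every real cohort will separate.

## Numerical choices and edge cases

* Edge lengths are accepted as non-negative reals, not only integers;
  normalization produces reals regardless, and upstream reconstruction tools
  may emit fractional lengths.  Zero-length edges are legal and serialized
  explicitly (`:0`).
* Newick I/O is implemented in the package because clone trees routinely
  contain unbranched (singleton) chains — the trunk is one — and the usual
  phylogenetics readers mis-handle chains of singletons.  Parse errors report
  the character offset.  A branch length on the root is dropped with a
  warning; a multi-child root is rejected (the trunk convention requires the
  root's single child to be the founder).
* Registered-tree CMDS axes whose eigenvalues are zero up to a relative
  tolerance of $10^{-9}$ carry no signal and are zero-padded (with a warning
  when that truncates the requested dimension).
* NMI uses the arithmetic-mean normalization
  $I/((H_p + H_t)/2)$ by default; the geometric-mean (`"sqrt"`) variant is one
  flag away.  The $0/0$ case (both partitions trivial) is defined as 1.
* All randomness (gap reference draws, simulator) flows through explicit
  `seed` arguments; a fixed seed reproduces byte-identical cohorts.

## Problem sizes used in the checks

The test-suite recovery and plateau checks run desk-scale versions of the
benchmark: 20 replicates of the 90-tree design-III cohort with gap-selected
$K$ (100 bootstrap references each), 20 seeds of the 40-tree design-I
recovery, and 8-seed Monte-Carlo trend checks at indices 1/3/5 with forced
$K$ equal to the class count (forcing $K$ isolates the degradation trend from
$K$-selection noise).  Monotone within-class-variance checks use 30 seeds of
a reduced design-II cohort (3 classes × 5 trees).  These sizes are the
package's own choices for a reproducible desk benchmark; the trends they
probe are not sensitive to them.

## Known limitations

* Registration compares tree *shapes and SSNV allocations*; it deliberately
  ignores SSNV identity, so two trees with identical shapes but disjoint
  mutations are identical after registration.
* The reference grows as $2(2^D - 1)$: cohorts containing one very deep tree
  (depth ≳ 20) produce long, sparse vectors; distances remain exact but
  memory grows accordingly.
* Attributes are univariate (SSNV counts); copy-number or methylation edge
  attributes are out of scope.
* The simulator's constants are non-canonical reconstructions (see above);
  absolute benchmark scores should be read against its definitions, while
  trends (degradation with dispersion/variance) are the robust part.
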