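---
title: "Exploring landscapes of phylogenetic trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring landscapes of phylogenetic trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeislands)
```

## The problem

Bootstrap resampling, Bayesian posterior sampling and the comparison of
inference methods all yield *sets* of phylogenetic trees rather than a
single phylogeny. When the trees disagree — because of incomplete lineage
sorting, reassortment, or plain statistical uncertainty — a single
consensus tree with support values hides the structure of that
disagreement. A more informative question is geometric: where does each
tree sit relative to the others, do the trees fall into distinct groups
("tree islands") of mutually similar topologies, and which tree best
represents each group?

`treeislands` answers this with a four-step pipeline:

1. map every rooted, labelled tree on a common tip set to a metric
   feature vector;
2. compute pairwise distances between all trees;
3. project the distance matrix into a low-dimensional Euclidean space by
   metric multidimensional scaling (MDS / principal coordinate analysis),
   applying the Cailliez additive correction when the metric is not
   Euclidean;
4. cut the landscape into islands by hierarchical clustering and
   summarise each island by its geometric median tree.

## Tree metrics

All vector metrics share one convention: tip labels are sorted
lexicographically (C collation, so results are locale-independent) and
unordered pairs $(i, j)$ with $\mathrm{label}_i < \mathrm{label}_j$ are
enumerated in a fixed order. Any fixed order gives identical distances;
fixing one makes vectors comparable across trees and runs.

**Kendall–Colijn (`kc`).** For a rooted tree $T$ and tip pair $(i, j)$,
let $m_{i,j}$ be the number of edges from the root to the most recent
common ancestor (MRCA) of $i$ and $j$, and $M_{i,j}$ the sum of branch
lengths along that path. The topological vector $m(T)$ is completed by
$n$ per-tip entries equal to 1, the length vector $M(T)$ by the pendant
branch lengths. The metric vector is the blend

$$v_\lambda(T) = (1 - \lambda)\, m(T) + \lambda\, M(T), \qquad
  \lambda \in [0, 1],$$

and the distance between two trees is the Euclidean norm
$\lVert v_\lambda(T_1) - v_\lambda(T_2) \rVert$. $\lambda = 0$ (the
package default, reflecting the emphasis on topological incongruence)
compares pure topology; $\lambda = 1$ pure branch lengths. The MRCA depth
of the root itself is 0, forced by the edge-count definition. The
construction needs a well-defined root-to-MRCA path, so trees with a
basal polytomy are rejected for this metric (a clear error), while
multifurcations elsewhere are accepted — the MRCA depth remains well
defined there, a deliberate design choice worth flagging since different
implementations could disagree on non-binary trees. The per-tip slots are
constant in $m(T)$ and cancel in every $\lambda = 0$ distance; they are
kept for fidelity to the published vector layout.

**Robinson–Foulds (`rf`).** The size of the symmetric difference of the
two trees' non-trivial split sets, computed on the unrooted topologies
and reported as the raw count (not halved, not normalised). RF distances
are integers and — unlike the vector metrics — not Euclidean in general,
which is why the landscape step watches for negative eigenvalues.

**Branch score (`bs`).** Each tree is a sparse map from splits to branch
lengths; the Kuhner–Felsenstein distance is the square root of the sum of
squared length differences over the union of splits, with length 0 for a
split absent from a tree. On a rooted tree the two root-adjacent edges
induce the same unrooted split, so their lengths are summed — this makes
the distance identical to the classical statistic on unrooted trees.

**Path difference (`path`, `path_l1`).** The vector of tip-to-tip edge
counts; distances are the l2 norm (Steel–Penny) or the l1 norm
(Williams–Clifford variant) of the vector difference.

**Direct-descendant metrics (`abouheif`, `sumdd`).** For each tip pair,
the product (Abouheif) or sum (`sumdd`) of the number of children of each
internal node on the path between the tips, the MRCA counted once. Both
are purely topological. For `((A,B),C)` the path from `A` to `C` passes
the cherry node (2 children) and the root (2 children), giving
$2 \times 2 = 4$ and $2 + 2 = 4$ respectively; the test suite pins these
values with an independent path-walk oracle built on graph shortest
paths.

## The landscape: PCoA and the Cailliez correction

Classical metric MDS double-centres the squared-distance matrix
($B = -\tfrac12 J D^{(2)} J$ with $J = I - \tfrac1n \mathbf{1}\mathbf{1}^\top$),
eigendecomposes $B$, and scales eigenvectors by the square roots of their
positive eigenvalues. When $D$ is Euclidean — always true for the vector
metrics, by construction — the full-rank coordinates reproduce $D$
exactly (to numerical precision; the suite checks $10^{-8}$).

For non-Euclidean inputs such as RF, some eigenvalues of $B$ are
negative. The Cailliez correction finds the smallest constant $c$ such
that adding $c$ to every off-diagonal distance makes the matrix
Euclidean; $c$ is the largest real eigenvalue of the standard
$2n \times 2n$ companion matrix of the construction. Numerical policy
(configurable, `tol = 1e-8`): the correction is applied automatically iff
the most negative centred eigenvalue falls below $-10^{-8}$ times the
largest one, and eigenvalues within that relative band of zero are
treated as exactly zero. The constant actually applied is recorded in the
embedding (`cailliez_constant`, 0 when no correction was needed).

Two further determinism choices: axes are ordered by descending
eigenvalue, and each axis is oriented so that its largest-magnitude
coordinate is positive (eigenvector signs are otherwise arbitrary, which
would break byte-identical reproducibility). The default of 3 retained
axes matches the dimensionality typically inspected visually; asking for
more axes than there are positive eigenvalues truncates with a warning
rather than failing, since the extra axes carry no information. The scree
proportions (`scree()`) are taken relative to the sum of *positive*
eigenvalues.

## Islands

`find_islands()` performs agglomerative clustering — single, complete,
UPGMA (average) linkage, or Ward's method in its squared-Euclidean
"ward.D2" form, coherent with the Euclidean embedding — and cuts the
dendrogram at a user-chosen `k`. The default basis is the retained MDS
coordinates (clustering "the projected distances", and on all retained
axes); clustering on the raw distance matrix is available by passing the
`tree_distmat` directly. When the metric is Euclidean and all axes are
retained the two are equivalent, which the suite checks via the merge
heights. The clustering is delegated to `stats::hclust`, which is
deterministic given its input; no additional tie-breaking layer is added
on top. `k` is never chosen automatically — a silhouette-width helper
(`silhouette_widths()`) supports choosing it by inspection, mirroring how
island counts are picked in practice.

## Median trees

The geometric median tree of an island is the member tree whose KC
vector is closest (Euclidean) to the *mean* of the members' vectors. The
mean vector generally corresponds to no tree and is never converted back
into one; because the median is an argmin over the sample, it is always
an actual sampled tree and cannot exhibit artefacts such as negative
branch lengths, unlike some consensus constructions. All co-minimal
members are reported (distances within a relative $10^{-9}$ of the
minimum count as tied — an exact-equality test would be brittle in
floating point); file output takes the lowest index. Medians under other
metrics are intentionally out of scope.

## The synthetic generator

`random_tree()` draws rooted binary topologies by uniform sequential
pair-joining (a coalescent-style scheme: every labelled history equally
likely, so all labelled shapes have positive probability) with i.i.d.
exponential branch lengths, rate 1 by default — a scale typical of
substitutions-per-site trees and irrelevant to topology-only analyses.

`nni_perturb()` applies nearest-neighbour interchanges across internal
edges of the *unrooted* topology, the two root-adjacent edges treated as
one merged edge (a naive sibling–nephew swap across a root edge would
only re-root the tree, changing no split). One move therefore replaces
exactly one non-trivial split — RF distance exactly 2 — making island
tightness directly controllable in units of topological steps. NNI was
chosen over SPR precisely because it is the smallest such step. Branch
lengths on the edges a move touches are redrawn.

`make_islands()` rejection-samples base trees until all pairwise RF
distances reach `min_rf` (default 4, i.e. at least two splits apart, so
islands cannot overlap by construction) and populates each island with
NNI-perturbed copies. The defaults — 4 islands of 50 trees on 20 tips,
2 NNI moves per member — emulate the structure of a posterior-style
sample containing a few distinct topology clusters.

What the generator does *not* emulate: real posterior samples are
autocorrelated, island sizes are uneven, branch lengths are correlated
with topology, and islands can blend into each other. Passing the
recovery tests therefore shows that the pipeline separates genuinely
distinct topology clusters; it does not guarantee sharp islands in real
data, where the scree plot and silhouette widths must guide
interpretation.

## Worked example

```{r pipeline}
sim <- make_islands(n_tips = 20, n_islands = 4, trees_per_island = 50,
                    nni_moves = 2, seed = 42)
dm  <- distance_matrix(sim$collection, metric = "kc", lambda = 0)
emb <- tree_pcoa(dm, n_axes = 3)
emb
part <- find_islands(emb, k = 4, linkage = "ward")
adjusted_rand_index(part$labels, sim$labels)
med <- median_tree(sim$collection, part)
med
```

```{r plot, fig.width = 5, fig.height = 4}
plot(emb$coordinates[, 1:2], col = part$labels, pch = 19,
     xlab = "Axis 1", ylab = "Axis 2",
     main = "Tree landscape, coloured by island")
```

The same pipeline is available from a shell through the
`exec/treeislands` script (`simulate`, `dist`, `mds`, `islands`,
`median`, `pipeline` subcommands), every run writing a JSON provenance
sidecar sufficient to reproduce its outputs byte-for-byte.

## Problem sizes and numerical contracts exercised by the test suite

The suite verifies, among others: metric axioms (symmetry exact, zero
self-distance, triangle inequality within $10^{-9}$) on 30 random 10-tip
trees for every metric; KC entries against a brute-force ancestor-set
MRCA oracle on 200 random trees (up to 20 tips); RF against a
graph-deletion split oracle on 200 random pairs; PCoA reconstruction
within $10^{-8}$ and Cailliez behaviour on 100 random RF matrices;
recovery of the generating 4-island partition (ARI $\ge 0.9$) in at
least 95 of 100 seeded replicates; the median-tree argmin contract; and
byte-identical reproduction of all pipeline outputs under a fixed seed.
These sizes keep the full suite around a minute on one CPU while leaving
each property enough replicates to be meaningful.

## Limitations

* The Billera–Holmes–Vogtmann geodesic metric is not implemented (it has
  no vector representation and needs the Owen–Provan algorithm); the
  metric layer is an extension point for it.
* Median trees are defined through the KC vector only.
* Hierarchical clustering on MDS coordinates can struggle when a metric
  distorts the space; nonlinear embeddings are out of scope.
* Trees must share an identical tip set; no pruning to a common subset
  is attempted.
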