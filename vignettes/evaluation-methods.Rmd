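---
title: "Multi-level evaluation of single-cell embeddings and clusterings"
author: "scEvalMetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level evaluation of single-cell embeddings and clusterings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scEvalMetrics)
```

# Why three levels

A single-cell chromatin-accessibility (or similar) processing pipeline turns
fragment counts into a cell embedding, the embedding into a
shared-nearest-neighbor (SNN) graph, and the graph into a clustering. Judging
the pipeline only by its final partition confounds every upstream choice with
the clustering resolution, which is itself a free parameter. This package
therefore scores each intermediate product against ground-truth cell types:

* **embedding level** — silhouette widths (ASW), the fraction of negative
  silhouettes (FNS), and the cluster-level Local Inverse Simpson Index
  (cLISI);
* **graph level** — the Proportion of Weakly Connected cells (PWC) and
  Geary's C;
* **partition level** — chance-adjusted Wallace indices (AW, AV) with
  per-class/per-cluster decompositions, ARI and its class-size-debiased
  variant ARI2, mutual information (MI), variation of information (VI), and
  the evenness of the ground truth;

plus sweep summaries (normalized AUC over cluster numbers, seed stability),
library-size bias measures, and FOSCTTM for paired cross-modality
integrations.

# The partition-level model

With ground truth $U = \{U_1,\dots,U_I\}$ and prediction
$Z = \{Z_1,\dots,Z_J\}$, let $n_{ij}$ be the contingency counts,
$N = \binom{n}{2}$ the number of object pairs,
$P = \sum_i \binom{n_{i+}}{2}$ and $Q = \sum_j \binom{n_{+j}}{2}$ the
same-group pair counts. The Wallace index $W$ (proportion of same-class pairs
also co-clustered) and its converse $V$ are adjusted for chance as
$(S - E(S))/(1 - E(S))$ under the hypergeometric model with fixed margins:

$$\mathrm{AW} = \frac{N\sum_{ij}\binom{n_{ij}}{2} - PQ}{P(N-Q)},\qquad
  \mathrm{AV} = \frac{N\sum_{ij}\binom{n_{ij}}{2} - PQ}{Q(N-P)}.$$

AW reads as class completeness, AV as cluster homogeneity; both decompose
into per-class $\mathrm{AW}_i$ and per-cluster $\mathrm{AV}_j$ terms. ARI is
their harmonic mean, which coincides with the classical pair-counting ARI.

**A corrected decomposition.** ARI is often quoted as the weighted average
$(\sum_i \mathrm{AW}_i P_i + \sum_j \mathrm{AV}_j Q_j)/(\sum_i P_i + \sum_j Q_j)$.
With weights $P_i$ and $Q_j$ this identity is false whenever $P \neq Q$ (the
discrepancy is exactly $N(P-Q)^2$ in the cross-multiplied comparison); the
weights that make the decomposition agree with the harmonic mean to machine
precision are $P_i(N-Q)$ and $Q_j(N-P)$. `ari()` implements the corrected
weights and returns both routes; the test suite asserts their agreement at
$10^{-12}$ on random partition pairs.

**ARI2.** The weighted decomposition is dominated by large classes, so ARI2
uses unweighted means $\mathrm{AW}' = \mathrm{mean}_i\,\mathrm{AW}_i$,
$\mathrm{AV}' = \mathrm{mean}_j\,\mathrm{AV}_j$ combined as the harmonic mean
$2\,\mathrm{AW}'\mathrm{AV}'/(\mathrm{AW}'+\mathrm{AV}')$. (A printed form of
this statistic circulates with numerator $2\mathrm{AW}' \times 2\mathrm{AV}'$;
that form cannot equal 1 for identical partitions, so the harmonic mean is
the only consistent reading and is what we implement.) Two caveats we
document rather than hide: singleton classes or clusters have $0/0$
components and are excluded from the means with a warning; and when
$\mathrm{AW}'$ and $\mathrm{AV}'$ have opposite signs — which happens
when one dominant cluster drives the chance expectation $Q/N$ high while a
scattered rare class sits far below it — the harmonic mean is not a
meaningful summary and can exceed 1. ARI2 should be interpreted only where
both means are positive, i.e. for predictions that are at least
chance-level on every class.

MI and VI use natural logarithms throughout, so the identities
$\mathrm{MI} = H(Z) - H(Z|U)$ and $\mathrm{VI} = H(U|Z) + H(Z|U)$ hold
exactly (asserted at $10^{-12}$); $0\log 0 = 0$.

# Embedding-level choices

**Silhouettes.** $s(i) = (b_i - a_i)/\max(a_i, b_i)$ with Euclidean
distances; singleton classes take $s = 0$ by the standard convention. ASW
and FNS are reported per class and as unweighted class means, so rare cell
types count as much as abundant ones. FNS depends only on the sign of
$s(i)$, hence is invariant to positive rescaling of the space — the property
that makes it comparable across dimensional-reduction methods whose output
scales differ. The widths themselves are computed by `cluster::silhouette()`;
an independent brute-force oracle validates them in the tests.

**cLISI.** For each cell, weights $w_j \propto \exp(-\beta d_j)$ over its
`kNeighbors` nearest neighbors are calibrated by bisection so the weight
entropy equals $\log(\texttt{perplexity})$; the score is the inverse Simpson
index of the class-summed weights. Defaults are perplexity 30 and
$k = 3 \times$ perplexity $= 90$, the conventions of the reference LISI
implementation, including its use of raw (not squared) neighbor distances in
the kernel. If the bisection fails to converge in 100 iterations (possible
when all neighbor distances tie), uniform weights are used with a warning.

A consequence worth stating plainly: the calibrated weights have entropy
$\log(30)$ but inverse-Simpson effective size $1/\sum_j w_j^2 \approx 13$,
so under complete mixing of $K = 4$ classes the expected cLISI is
$\approx 1/(1/K + (1 - 1/K)\sum_j w_j^2) \approx 3.3$, not $4$. The upper
bound $K$ is attained only in the infinite-perplexity limit. Our mixing-limit
test records this measured plateau; claims that cLISI "reaches K" under
mixing should be read as "approaches its plateau just below K".

# Graph-level choices

**PWC** splits each cell's degree into within-class and out-of-class parts;
a cell is weak iff $k^{in} < k^{out}$ strictly, so ties and isolated cells
(degree 0) are not weak. Edge counts are the default (the definition speaks
of numbers of edges); `weighted = TRUE` honors SNN Jaccard weights for
sensitivity analyses.

**Geary's C** is implemented in its standard form,
$C = (N-1)\sum_{ij} w_{ij}(x_i-x_j)^2 / (2 S_0 \sum_i (x_i-\bar x)^2)$, with
both the numerator and $S_0$ summing each symmetric edge in both directions.
Only this form satisfies $E[C] \approx 1$ for i.i.d. $x$, which the tests
assert by simulation. Library sizes are `log1p`-transformed before scoring
so zero-count cells are tolerated.

**Graph construction.** kNN search is exact (no approximate index), with
distance ties broken by ascending cell index for reproducibility. SNN
weights are Jaccard overlaps of self-inclusive neighbor sets
($|N| = k + 1$), pruned at weight $\le 1/15$ — the documented conventions of
the dominant single-cell implementation. Defaults $k = 20$, prune $= 1/15$.

# Sweep summaries

Partition metrics are compared across clustering resolutions by averaging
each metric at every observed cluster number, integrating the mean curve
with the trapezoidal rule over the observed range, and normalizing by (upper
bound × range width). ARI/ARI2/AW/AV use upper bound 1; MI and VI use their
empirical per-sweep maximum, and VI (smaller is better) is reported as
$1 -$ normalized AUC. Integrating the averaged curve (rather than the raw
scatter) follows the framing of metric-versus-cluster-number plots where the
line is the per-cluster-number mean. The clustering itself is a pluggable
callback (typically Leiden on the SNN graph, e.g. via
`igraph::cluster_leiden`); embedding a community-detection heuristic in the
package would make every downstream number hostage to a third-party
implementation's tie-breaking. Seed stability is the mean over resolutions
of the mean pairwise $1 - \mathrm{ARI}$ between seeds' partitions.

The AUC heatmap transform centers each metric column at its median and
scales all deviations by the single matrix-wise median absolute deviation,
giving outlier-robust scores comparable across datasets; a constant matrix
maps to zeros with a warning.

# Library-size bias

Depth differences between cell types can be biology; within a cell type they
are technical. Hence the per-dimension bias statistic correlates
$\sqrt{\text{library size}}$ with the dimension's coordinates *within* each
class and averages absolute values over classes (classes under 3 cells or
with zero variance are skipped with a warning); the summary averages the
first $\min(\text{dims}, 5)$ dimensions. The component filter instead uses
the correlation across *all* cells against raw total counts with the
conventional 0.75 cutoff — two deliberately different procedures, matching
how each is used in practice.

# The synthetic generator

`simulateEmbedding()` emulates the regimes the metrics are designed to
separate: class means sit on a randomly rotated regular simplex with edge
length `separation` (in units of the within-class standard deviation;
isotropic unit noise), so separation is an exact difficulty dial for every
class pair; class proportions may include rare classes (default
0.4/0.3/0.2/0.1, 2000 cells, 15 dimensions — the dimensionality most
pipelines retain); library sizes are log-normal (meanlog $\log 10^4$, sdlog
0.5, typical of fragment counts per nucleus); `biasLoading` injects
$\sqrt{\text{depth}}$ into dimension 1 to mimic LSI-style leakage; an
optional hierarchy splits classes into displaced subclasses; and
`simulatePaired()` adds isotropic noise to produce a second modality.
`perturbPartition()` generates the canonical failure modes — merges
(under-clustering), splits (over-clustering; parts are balanced-random so
the cluster count moves by exactly the stated amount), and random relabels.
All randomness flows through a private seeded generator; the caller's RNG
state is untouched and outputs are bit-reproducible.

What the generator does **not** emulate: anisotropic or heavy-tailed
within-class scatter, doublets, batch structure, and the near-binary
sparsity of the underlying count matrices. Passing tests on these fixtures
therefore validate the *metrics*, not any claim about real-data method
rankings.

Problem sizes in the test and acceptance suites (up to 2000 cells, 15
dimensions, 1000-replicate chance-correction loops) were chosen as the
smallest at which the asymptotic anchors (chance level 0, separation limits,
independence limits) are comfortably resolved.

# Numerical conventions and edge cases

* Undefined metric components (e.g. AW with a single predicted cluster,
  $\mathrm{AW}_i$ of a singleton class) are `NA` in R and `null` in JSON —
  never silently imputed, never the text "NaN".
* Graph symmetrization is by elementwise maximum, idempotent on symmetric
  inputs and tolerant of writers that emit a single triangle; nonzero
  diagonals are dropped with a warning.
* Cell-identifier matching is exact and case-sensitive (barcodes are
  case-significant); metric functions refuse misaligned inputs rather than
  reordering silently — `alignCells()` is the explicit intersection step
  and is idempotent.
* FOSCTTM counts ties ($d_{i,j} = d_{i,i}$) against the true match, the
  conservative convention; cosine distance is $1 -$ cosine similarity, and
  all-zero rows are rejected.

# A worked example

```{r example}
sim <- simulateEmbedding(simConfig(nCells = 600, separation = 6, seed = 7))
truth <- sim$labels

pred <- perturbPartition(truth, "merge",
                         classes = c("class3", "class4"), seed = 1)
ps <- partitionScores(truth, pred)
round(ps$scores, 3)
round(ps$AVj, 3)
```

Merging the two rarest classes leaves every class complete
($\mathrm{AW}_i = 1$, so AW $= 1$) but the merged cluster impure: AV and the
merged cluster's $\mathrm{AV}_j$ drop, and ARI2 drops further than ARI
because the unweighted mean feels the damaged (small) cluster at full
weight.

# Known limitations

* Silhouette and exact kNN use dense distance matrices: memory is
  $O(n^2)$, comfortable to tens of thousands of cells but not beyond.
* cLISI's plateau below $K$ (see above) means its dynamic range compresses
  as $K$ grows at fixed perplexity.
* ARI2 is unreliable when any decomposition component is strongly negative
  (mixed-sign means); inspect `AWprime`/`AVprime` before trusting it.
* The package evaluates library-size bias but does not correct it;
  correction is an open problem upstream of this toolkit's scope.
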