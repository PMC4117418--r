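---
title: "Model and methods: automated gating-strategy trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: automated gating-strategy trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatetree)
```

Gating — isolating cell subpopulations by sequential thresholds on one or
two markers at a time — is how cytometrists both analyse heterogeneous
single-cell data and physically sort cells at a FACS instrument. Done by
hand it requires choosing the gating markers, the order in which to gate
them, and the cut-offs, all from expert judgement. This package derives all
three from the data: a clustering step proposes candidate subpopulations, a
silhouette step cleans them up, and a recursive-partitioning step turns the
cleaned clustering into a binary decision tree whose internal nodes *are*
the gates. This vignette records the model, the parameter choices, and the
numerical decisions, in enough detail to reimplement them.

## The mixture model

Cells are vectors $x_i \in \mathbb{R}^r$ of arcsinh-transformed marker
intensities. We model them as a finite mixture of $m$ components whose
coordinates are independent *conditional on the component*, with the
univariate component densities left completely unspecified:

$$ f(x_i) = \sum_{j=1}^{m} \lambda_j \prod_{k=1}^{r} f_{jk}(x_{ik}), $$

estimated by an EM-like algorithm whose density update is a weighted kernel
density estimate. One iteration is:

* **M-step** $\lambda_j = \tfrac1n \sum_i p_{ij}$;
* **KDE-step** $f_{jk}(u) = \tfrac{1}{n \lambda_j h}
  \sum_i p_{ij}\, K\!\left(\tfrac{u - x_{ik}}{h}\right)$ with standard
  normal kernel $K$;
* **E-step** $p_{ij} \propto \lambda_j \prod_k f_{jk}(x_{ik})$, rows
  normalised.

The first iteration starts from a hard k-means partition, so the whole fit
is deterministic given the seed. The bandwidth follows the pooled
Silverman rule
$h = 0.9 \min(\hat\sigma, \mathrm{IQR}/1.34)\, N^{-1/5}$ computed on the
pooled vector of all $N = n r$ values. Because the component densities are
free, a component can be multimodal — this is what lets the model assign a
biologically coherent but spatially split population to one component, and
it is also the source of the degeneracies discussed next.

### Numerical and algorithmic safeguards

Three guards depart from the textbook loop, all motivated by reproducible
failure modes we observed while iterating the fitter on the synthetic
design:

* **Restarted k-means initialisation.** A single random k-means start
  regularly places one centre across two well-separated modes while several
  centres subdivide a heavy mode; the mixture then inherits the merged
  component permanently (its KDE simply becomes bimodal). We take the best
  of 10 starts under one seed — still deterministic given the seed.
* **Component death.** Components whose mixing proportion falls below
  $1/n$, or that win no cell under the posterior-maximum (MAP) rule, are
  dropped as iterations proceed. Without the MAP rule, duplicate
  components that tie on one mode persist with $\lambda_j \approx 0.1$
  and slowly diffuse posterior mass until the boundary between two
  *distinct* modes collapses.
* **MAP-stability stopping.** Iterating to a tight tolerance
  (`tol = 1e-8` on $\max|\Delta\lambda|, |\Delta p|$, up to 500
  iterations) is supported but is *not* the default way the fit ends: the
  loop stops once the MAP partition has been unchanged for 10 consecutive
  iterations. Kernel-density mixtures exhibit a slow mass-bridging
  degeneracy — posterior mass leaks through kernel tails onto the cells of
  a neighbouring mode, the component's density grows a bridge toward that
  mode, and over tens to hundreds of iterations the neighbour is annexed
  even when the iteration-5 partition was exactly right. The MAP labels
  are the quantity every downstream step consumes, so their stability is
  the meaningful convergence criterion.

The practical protocol is to start with *more* components than expected
(`components = 10` by default); MAP collapse, component death and the
silhouette refinement bring the count down to what the data support.
Hierarchical clustering (`hclust`, Ward/average/complete on Euclidean
distances) is available as a drop-in alternative clusterer; there the
expected cluster count is supplied directly.

## Silhouette refinement

For each cell, $a_i$ is its mean distance to its own cluster, $b_i$ the
smallest mean distance to any other cluster, and
$s_i = (b_i - a_i)/\max(a_i, b_i)$. Negative $s_i$ means the cell sits
closer to a neighbouring cluster than to its own. The refinement loop
reassigns *all* negative-silhouette cells to their nearest neighbouring
cluster (the cluster attaining $b_i$) in one batch, recomputes silhouettes,
and repeats. The cost $\lvert \sum_{s_i<0} s_i \rvert$ is tracked; the loop
stops when no negative silhouettes remain, the first time the cost would
fail to decrease (the previous labels are kept), or when fewer than two
clusters would remain. Emptied clusters are removed, which is the main
mechanism by which an over-provisioned clustering shrinks to the number of
modes present. Conventions: singleton-cluster cells get $s_i = 0$;
coincident points ($a_i = b_i = 0$) get $s_i = 0$; neighbour ties resolve
to the lower cluster id.

## The gating tree

Given hard cluster labels, the tree is grown by conditional-inference
recursive partitioning, which separates *whether and on what to split*
from *where to split* and thereby avoids the variable-selection bias of
impurity-based trees.

**Variable selection.** For each marker the linear statistic
$T_j = \sum_i w_i x_i \mathbf{1}(y_i = j)$ is compared with its exact
conditional moments under random permutation of the marker against the
labels: $\mu_j = \bar{x} n_j$ and
$\Sigma = V\!g \tfrac{n}{n-1}\left(\mathrm{diag}(n_j) - n n^\top / n\right)$
with $Vg$ the population variance of $x$. The test statistic is the
quadratic form $(T-\mu)^\top \Sigma^{+} (T-\mu)$ with a $\chi^2$ reference
on $\mathrm{rank}(\Sigma)$ degrees of freedom; p-values are
Bonferroni-adjusted over the $r$ markers. If even the smallest adjusted
p-value exceeds `alpha` (default 0.05) the node stops — this is the tree's
size control. The raw marker values serve as the influence function so
that split points live in intensity units.

**Split selection.** On the selected marker, every observed value $v$
leaving at least `minbucket` cells on each side of $\{x \le v\}$ is a
candidate cut. The candidate's score is the same quadratic form applied to
the two-sample statistic $T_j = \#\{x \le v, y = j\}$. Scoring the whole
class vector matters: the per-class standardised statistic of a class
lying fully on one side grows with the left-group size, so a max-over-
classes criterion near-ties valley cuts with cuts through a neighbouring
cluster's fringe; the quadratic form penalises the damage to the class
being cut and peaks cleanly in the density valley. Because
$\Sigma(v)$ factorises into a scalar in $v$ times a fixed class matrix,
one pseudo-inverse serves every candidate and the whole profile is $O(n
\cdot \text{classes})$ after sorting.

Two tie rules keep the tree deterministic. Any cut that separates the
classes perfectly attains the $\chi^2$ bound $n - 1$, so several
candidates can tie to machine precision; scores within a relative
$10^{-8}$ of the maximum resolve to the smallest candidate. Likewise two
markers that separate the same clusters equally well can tie on adjusted
p-values; near-exact ties resolve to column order. When two markers are
*statistically* close but not tied, the choice remains data-driven, and on
resampled data the hierarchy can legitimately alternate — see
*Limitations*.

**Split points are gap midpoints.** The reported threshold is the midpoint
between the winning candidate and the next larger observed value — the
centre of the empty interval the cut passes through. A threshold pinned to
the largest left-hand observation sits on the edge of a population, which
is both where a physical sorting gate should not be and an extreme order
statistic whose resampling behaviour is one-sided (a bootstrap replicate
can never exceed the training sample's edge cell). The midpoint keeps the
routing identical (`value <= split` goes left, boundary values inclusive)
while centring the estimate in the valley. `minbucket` defaults to
$\max(20, \lceil 0.01 n \rceil)$.

## Pruning and purification

The raw tree can be far deeper than a sorting protocol wants. The pruning
height $L$ is the smallest height at which every cluster is the dominant
(modal) label of at least one leaf; growth is then capped at $L$. The
filter-retrain loop makes the leaves pure: in each round, every leaf keeps
only the cells of its dominant cluster (dominance ties toward the lower
cluster id), the removed cells go to an *extra bin* tagged with the round
number, and the tree is regrown on the retained cells. The loop ends when
all leaves reach the purity threshold (default exactly 1) or a round
removes nothing. The retained set shrinks monotonically; if a round would
empty a cluster entirely the run aborts with a diagnostic, since the
clustering is then not gateable at the requested purity. A cluster may
finish spread over several pure leaves — that happens exactly when no
axis-aligned box can contain it without also containing foreign cells, and
it is why the final tree can have more bins than clusters.

## Bootstrap stability

Split-point uncertainty is assessed by a strata bootstrap: each of $B$
resamples draws cells with replacement *within each cluster*, preserving
per-cluster counts. The full grow-and-purify pipeline is rerun per
resample and each internal node's split point is recorded, keyed by its
path signature (the sequence of marker/side edges from the root). Ranges
are reported as empirical minima and maxima — split-point distributions
are typically multimodal, so normal intervals would be misleading.
Replicates whose hierarchy diverges from the original still contribute
samples for the nodes they share; the fraction of replicates with an
identical hierarchy is reported alongside.

## The synthetic study design

`default_sim_spec()` encodes the five-component, three-marker, 850-cell
design used throughout the tests: component sizes 100/300/150/100/200 and
qualitative levels per marker (celltype 1 low/low/high, celltype 2
"high low"/low-mid/high, celltype 3 mid/mid/high, celltype 4
"low high"/"low high"/high, celltype 5 high/high/high). Marker 3 is high
everywhere and should never be selected for gating.

Choices a reimplementer needs to know:

* **Level placement.** Levels map to normals with means low = 0,
  low-mid = 4, mid = 7, high = 10 and common sd 0.3 on the arcsinh scale.
  The placement is driven by the bandwidth analysis above: the pooled
  Silverman bandwidth on this design is $h \approx 0.73$, and the
  weighted-KDE mixture keeps two modes distinct only when they are at
  least roughly $5h$ apart; adjacent levels are therefore spaced at least
  4 units. Compressing the ladder (e.g. unit spacing) makes the mixture
  merge the two closest components on every seed — not an estimation
  error but the model's fixed point under an over-wide kernel.
* **Two-part levels.** A level such as `"low high"` is an equal mixture of
  the two named normals. The part is drawn once per cell and shared across
  all two-part markers of the component, so celltype 4 sits at (low, low)
  or (high, high) — a population straddling two expression states — and
  overlaps celltypes 1 and 5 there. Independent per-marker draws would
  scatter it over four corners and destroy the five-mode structure the
  design is meant to have.
* **What the generator does not emulate.** Real cytometry data carry
  spillover residues, zero point masses from unstained cells, heavy and
  asymmetric tails, debris and doublets, and cluster shapes far from
  product-of-normals. Passing tests on this generator shows the pipeline
  recovers a known separable structure and honours its contracts; it does
  not show robustness to those artefacts.

## Problem sizes in the test-suite

The bundled tests run the full pipeline at the design's native size
(850 cells, 20 replicate seeds), the bootstrap at $B = 50$ on 850 and on
425-cell halves, and the brute-force oracle comparisons at $n \le 20$
(exact permutation enumeration at $n \le 8$). These sizes were chosen so
the whole suite exercises every code path at the scale the design
specifies.

## Known limitations

* **Hierarchy non-uniqueness.** When two markers separate the same pair of
  clusters essentially perfectly, their test statistics differ only by
  sampling noise and resampled trees alternate between them. The gating
  *partitions* agree; the marker labels differ. Consumers comparing
  hierarchies across runs should treat such nodes as equivalent or rely on
  the reported identical-hierarchy fraction.
* **Bootstrap ranges are not prediction intervals.** The min/max range of
  $B$ bootstrap split points describes resampling variability of the
  training data. A tree retrained on an *independent* sample deviates with
  roughly $\sqrt{2}$ times the functional's standard deviation, so its
  split points will fall outside a $B = 50$ range at an appreciable rate
  even in the best case — and when clusters are cleanly separated the
  split is an empty-gap midpoint, an extreme-value-driven functional for
  which the bootstrap is known to under-cover. Containment of an
  independent replicate's splits should be read as a qualitative, not a
  calibrated, check.
* **Scalability.** Silhouette refinement and the mixture fit build
  $n \times n$ distance/kernel matrices; beyond a few tens of thousands of
  cells, subsample for clustering (the tree and purification steps scale
  comfortably) — the same practice used for the million-cell analyses this
  methodology targets.
* **Induction statistic.** Cross-condition signalling induction defaults
  to the difference of mean arcsinh intensities per population; a
  fold-change-style alternative (difference of absolute means) is provided
  as an option, and neither is asserted to be the only convention in use.
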