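---
title: "Spherical sketching by radius thresholding: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spherical sketching by radius thresholding: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheresketch)
```

## The problem

Large single-cell RNA-seq experiments are routinely subsampled before
clustering, trajectory inference or visualization. Uniform subsampling keeps
cells in proportion to their abundance, so rare cell states — often the
biologically interesting ones — are easily lost. A *sketch* that instead
covers the occupied gene-expression space evenly keeps one representative
near every transcriptomic state, abundant or not.

`spheresketch` formalizes this as a covering problem. Given an embedding of
$n$ cells (typically PCA scores) and a distance $d(\cdot,\cdot)$, a sketch
$S$ of size at most $k$ is *spherical with radius* $r$ if every cell lies in
a closed ball of radius $r$ centered at some sketch cell:
$\max_i \min_{c \in S} d(x_i, x_c) \le r$. The package seeks the smallest
such $r$ — the $k$-center objective — and returns the centers, the radius,
and the assignment of every cell to its nearest center.

## The thresholding search

Minimizing the radius directly is a bottleneck (min–max) problem. It is
solved by *thresholding*: guess a radius $r$, test whether a sketch of at
most $k$ balls of radius $r$ can cover everything, and shrink or grow the
guess accordingly. The feasibility test is a minimum set cover over the
candidate sets $B_r(i) = \{j : d(i,j) \le r\}$, solved greedily: repeatedly
select the cell whose ball contains the most still-uncovered cells. Greedy
set cover is within a factor $1 + \ln n$ of the optimal cover size, which
gives the search a bicriteria guarantee: accepting a modestly larger sketch,
the returned radius is no worse than the optimum for the reduced budget.

Two search modes are provided:

* **ladder** (default for $n \le 20{,}000$): the optimal radius must be one
  of the $O(n^2)$ pairwise distances, so the candidate set is the sorted
  distinct distances (plus 0) and the search is a binary search over that
  ladder.
* **bisect** (default above $20{,}000$, selectable anywhere): continuous
  bisection of $[0, \max d]$ to a relative tolerance (default $10^{-3}$),
  which avoids extracting and sorting the full ladder when $n^2$ gets large.
  We use it in the package's own large-scale test workloads ($n = 5{,}000$).

Greedy feasibility is not provably monotone in $r$: a larger radius could in
principle make the randomized greedy pick a worse cover. The binary search
treats feasibility as monotone — any thresholding implementation must — then
*verifies* feasibility at the returned radius and tightens it by a downward
linear scan over up to 32 ladder neighbors. The returned object records
whether the preceding candidate radius was tested infeasible
(`$prev_infeasible`), so the frontier property is checkable rather than
assumed. This is an approximation by design, not a defect.

Two radii are reported. `radius_threshold` is the candidate radius at which
feasibility held — the quantity the search reasons about. `radius` is the
*realized* covering radius, the largest distance of any cell to its assigned
nearest center; it is what the metadata reports and it never exceeds the
threshold. They differ when the greedy cover at threshold $r$ happens to
cover everything more tightly than $r$.

## Greedy engines

`engine = "exact"` maintains exact residual coverage counts (via an inverted
element-to-sets index) and selects a maximum-residual set each step, breaking
ties *uniformly at random* — the only source of randomness in the whole
pipeline, driven by R's RNG so `set.seed()` reproduces runs bit for bit.

`engine = "dfg"` (the default) is the disk-friendly greedy: sets are grouped
into geometric buckets by residual size, bucket $k$ holding sizes in
$[p^k, p^{k+1})$; buckets are processed from the largest downward in a
seeded random order; each popped set has its residual recomputed lazily and
is either selected (if it still belongs to the bucket) or demoted to the
bucket of its new size. Bucketing relaxes the greedy's guarantee by at most
the factor $p$, in exchange for a sequential access pattern that scales to
very large set systems. The default $p = 1.05$ keeps near-greedy quality; as
$p \to 1$ the bucket boundaries separate all distinct sizes and DFG
degenerates to the exact greedy, which the tests exercise at
$p = 1 + 10^{-9}$.

## Fairness quotas

A `fairness_spec()` demands at least $c_j$ selected centers of class $j$
(for example, a collection time point of a differentiation time course).
Rather than a post-hoc top-up, quotas are folded into the cover itself as
per-class demand: while class $j$ has remaining demand, every unselected
candidate of class $j$ counts one extra unit of residual coverage, and
selecting it consumes one unit. The greedy cannot terminate before all
demand is consumed, so quota satisfaction is structural, and with all quotas
zero the selection sequence is bit-identical to the unconstrained run —
both properties are asserted in the tests. One useful side effect: cells
whose label disagrees with their transcriptomic neighborhood ("outlier"
cells in a time course) are implicitly discouraged as centers, because each
quota can be met by a well-placed cell of the same label that also covers
many neighbors.

## Grid presampling and the hybrid pipeline

For inputs too large for an $n \times n$ distance matrix, a fast reduction
runs first: partition the coordinate space into axis-aligned hypercubes of
side $s$ and keep one cell per occupied cube, chosen uniformly at random.
Either $s$ is given, or a target count $m$ is given and $s$ is found by
bisection so the number of occupied cubes lands in $[m, 1.1m]$ (falling back
to the closest achievable count when duplicates or discreteness prevent an
exact landing). The radius search then runs on the representatives only, and
all original cells are assigned to their nearest selected center; the
reported radius is always measured on the full data. Because every cell
shares a cube with its representative, the hybrid radius exceeds the direct
one by at most the cube diagonal $s\sqrt{d}$ under the euclidean metric —
the additive, self-evident geometric bound, asserted over 500 random
instances. For cosine and Pearson metrics the grid is still built on the raw
coordinates (axis-aligned boxes); the inflation bound is only proven for
euclidean, which is why the bound tests restrict to it.

## Distance metrics

Four dissimilarities are supported: euclidean, manhattan, cosine
($1 - $ cosine similarity) and pearson ($1 - $ Pearson correlation of the
two coordinate rows). The package default is `pearson`, the correlation
distance most commonly used with this sketching approach; the covering
machinery never relies on the triangle inequality, so the two
non-metric dissimilarities are first-class citizens. The
theoretical-optimality tests (brute-force $k$-center comparisons, hybrid
inflation bounds) are restricted to euclidean/manhattan where the geometry
supports them. Distances are computed in double precision and ball
membership is the exact closed condition $d \le r$ — no epsilon slack — so
radius 0 is always feasible with $k = n$ centers and boundary ties behave
predictably.

## The synthetic generator

`simulate_mixture()` emulates what a dimensionality-reduced scRNA-seq
dataset presents to the sketcher: a Gaussian mixture in low dimension with
very unequal component abundances. The defaults are the package's study
conditions: five isotropic components in 10 dimensions, four equally
abundant and one *rare* at 1% abundance, component means drawn as
$N(0, 5^2)$ vectors against unit within-component noise — well-separated
populations, as distinct cell types are after PCA. On this geometry the
embedding axes are PCA-like scores, so euclidean distance is the natural
metric and is what the mixture-based tests use. Labels can be reported as
component names or as synthetic time points `t0/t24/t48/t72` cycling over
components, mirroring a differentiation experiment sampled every 24 hours;
`simulate_outlier_timepoints()` additionally plants cells whose coordinates
come from one component but whose recorded time point belongs to another.

What the generator does *not* emulate: count noise, dropout, library-size
variation, anisotropic or non-Gaussian population shapes, and continuous
trajectories. Tests passing on these mixtures show that the covering
machinery does what it claims on well-separated geometry; they do not certify
behavior on raw counts, which should be reduced first (see below).

```{r example}
cells <- simulate_mixture(n_cells = 1000, seed = 1)
sk <- sketch_spherical(cells, size = 0.05, metric = "euclidean", seed = 1)
glance(sk)
composition_report(cells$label, sk)
```

## Preprocessing raw counts

`read_cells(..., preprocess = "lognorm_pca")` provides a documented default
for raw count input: per-cell totals scaled to the median total, `log1p`,
then PCA to 100 components (centered, unscaled), with a deterministic sign
convention (the largest-magnitude loading of each component is made
positive). Users with their own embedding keep `preprocessing = none`; the
metrics are computed on whatever matrix is supplied — the tool does not
second-guess the feature space.

## Evaluation

`robust_hausdorff()` scores a sketch by the directed Hausdorff distance from
the full data to the sketch after discarding the largest
$\lfloor \alpha n \rfloor$ nearest-sketch distances. Only the directed
distance is needed because the sketch is a subset of the data. The default
$\alpha = 0.01$ is the conventional 1% trimming; $\alpha = 0$ recovers the
exact directed Hausdorff distance, which for a spherical sketch equals the
covering radius. `composition_report()` tabulates per-class counts and
fractions in the data and the sketch, keeping classes the sketch missed.

## Numerical and design choices

* Closed balls ($\le r$) everywhere; duplicates collapse at radius 0.
* Sketch sizes given as fractions resolve as $\lceil f \cdot n\rceil$
  (so "10%" of 2,126 cells is 213).
* The greedy may cover with fewer than $k$ centers; the sketch is *not*
  padded to exactly $k$ by default, because the objective is coverage, not a
  count. `pad_to_size = TRUE` opts into farthest-point padding.
* Tie-breaking is uniform among all maximal candidates (exact engine) or a
  seeded within-bucket permutation (DFG); both flow from R's RNG.
* The final sketch reuses the greedy run that proved feasibility at the
  chosen radius, so the returned cover is exactly the one the search
  accepted.
* Quotas on grid representatives: in hybrid mode fairness labels are
  restricted to the representatives; if a quota becomes unsatisfiable there,
  the run errors and asks for a larger `presample` rather than silently
  relaxing the quota.

## Problem sizes in the test suite

The packaged tests run the full pipeline at the study conditions the
generator defines: 500 random covering instances up to $n = 500$ across all
four metrics; brute-force oracle comparisons up to $n = 12$ (set cover) and
$n = 10$ ($k$-center); thresholding frontier checks on 200 instances up to
$n = 60$; rare-population retention on 100 seeded mixtures of
$n = 5{,}000$; Hausdorff comparisons against uniform and box-grid baselines
on 10 such mixtures; and 500 hybrid-versus-direct euclidean instances up to
$n = 2{,}000$. The `scripts/acceptance.R` script recomputes the headline
quantities (retention rates, median Hausdorff distances, covering radius,
hybrid inflation) from scratch at those same sizes.

## Limitations

* The full pairwise distance matrix bounds the direct path to about
  $n \le 20{,}000$; beyond that the hybrid pipeline is mandatory.
* Cover quality under quotas inherits greedy behavior; an individual
  constrained run can occasionally produce a smaller cover than an
  unconstrained one because the tie-break streams differ.
* The grid-side search assumes occupancy decreases with side length, which
  holds up to plateaus; the fallback returns the closest achievable
  representative count.
* No streaming or out-of-core execution: DFG's sequential access pattern is
  honored as a contract, but all data lives in memory.
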