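---
title: "The Structure Index: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Structure Index: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structindex)
```

## The model

Given a point cloud $P = \{p \in \mathbb{R}^D\}$ and a feature
$F = \{f_p \mid p \in P\}$, the Structure Index asks how non-randomly $F$ is
arranged over $P$. The cloud is partitioned into bin-groups
$B_i = \{p \mid t_i \le f_p < t_{i+1}\}$ by feature value, with uniform bin
limits $t_i = (i-1)\,(\max F - \min F)/n + \min F$ by default. For every
ordered pair of groups $(U, V)$ the directed overlap score is

$$\mathrm{OS}_{U \to V}(k) \;=\; \frac{1}{|U|\,k}
  \sum_{u \in U} \bigl|\{N_u^j(U \cup V - \{u\})\}_{j=1}^{k} \cap V\bigr|,$$

the fraction of the $k$ nearest neighbors of the points of $U$ that fall in
$V$. Two points of emphasis, because both are easy to get wrong:

* the neighbor search runs **only within $U \cup V - \{u\}$**, never the
  whole cloud. Restricting per pair is what makes the score a pairwise
  mixing probe rather than a global density estimate, and it is why all
  $n(n-1)$ ordered scores are computed independently;
* the score is **directed**: $\mathrm{OS}_{U\to V}$ and
  $\mathrm{OS}_{V\to U}$ differ whenever one group infiltrates the other
  asymmetrically, and that asymmetry is diagnostic, so nothing in the
  package ever symmetrizes the matrix.

The scores form an $n \times n$ adjacency matrix $\mathcal{M}$ with zero
diagonal (no self-edges) — a weighted directed graph whose nodes are the
bin-groups. The index is one minus its scaled mean weighted out-degree:

$$\mathrm{SI}(\mathcal{M}) = 1 - \frac{2}{n^2 - n}\sum_i \sum_j
  \mathcal{M}_{i,j}.$$

If the feature is randomly distributed, any two groups interleave and each
directed score concentrates near $0.5$ (more precisely
$|V| / (|U| + |V| - 1)$), so the SI is near 0; perfectly separated groups
give exactly 1. With small groups and small $k$ the asymmetry of
$k$-neighborhoods can push the raw value slightly below 0; the reported SI
is clipped at 0 and the raw value kept in `si_raw` for diagnostics.

For clouds of uneven density, a radius neighborhood replaces the $k$-NN
one: $\beta_u(r) = \{x \in U \cup V - \{u\} : d(u, x) \le r\}$ and

$$\mathrm{OS}_{U \to V}(r) = \frac{1}{|U|}\sum_{u \in U}
  \frac{|\beta_u(r) \cap V|}{|\beta_u(r)|}.$$

The inner term is undefined for an empty $\beta_u(r)$; such points are
excluded from the average with a warning (and a pair whose neighborhoods
are all empty scores 0, loudly).

## Parameters that matter

* **`n_bins`** (default 10, continuous features). Must be large enough to
  resolve the feature's continuity and small enough that every group keeps
  a meaningful population. The index is stable over a wide band (see the
  robustness checks below); for strongly skewed features, pass
  `custom_edges` (e.g. log-spaced). Categorical features get one group per
  label; vector features one group per occupied cell of the per-dimension
  bin product.
* **`k`** (default 3) / **`r`**. The locality dial. Small values probe
  neighborhood-scale organization, large values the global trend; the
  profile over a grid (`si_sweep()`) is more informative than any single
  value. Feasibility requires every group pair to hold at least $k+1$
  points.
* **`min_points`** (default 3). Groups below this are dropped with a
  warning before scoring, since a $u$ with fewer than $k$ candidates in
  $U \cup V - \{u\}$ has no well-defined score. The floor of 3 matches the
  default $k$.
* **`metric`**. `"euclidean"` by default. `"geodesic"` builds the
  symmetrized `graph_k`-nearest-neighbor graph of the full cloud
  (`graph_k` default 15), takes shortest-path distances along it, and
  slices the resulting matrix per pair — distances then follow the sampled
  manifold rather than cutting across ambient space. Any other metric can
  be supplied as a precomputed $N \times N$ distance matrix.
* **`n_shuffles`** (default 100 in the CLI) and **`seed`**. The null
  permutes feature values over points, leaving the cloud untouched; this
  preserves the marginal feature distribution exactly, so uniform bin edges
  — and hence group sizes — are reproduced in every shuffle and only the
  point-to-group assignment is destroyed. (Re-binning per shuffle or
  reusing the labels are therefore observationally equivalent here; the
  package re-bins.) The 99th percentile of the null, by linear
  interpolation of order statistics (`quantile(..., type = 7)`), is the
  significance threshold. All shuffles derive from the single user seed.

## Numerical choices

* **Interval convention**: bins are half-open $[t_i, t_{i+1})$ with the
  last bin closed at $\max F$, so the groups are disjoint and cover every
  point.
* **Tie-breaking**: ties at the $k$-th distance are broken by ascending
  point index (group-$U$ points first). Ties have measure zero for
  continuous data but occur on lattices and duplicated points; the rule
  makes every result bit-reproducible and independent of evaluation order.
* **Squared distances**: the Euclidean path ranks neighbors by squared
  distance (rank-equivalent, saves the square root); radius mode compares
  against $r^2$. Geodesic and user-supplied matrices are used as given.
* **Empty cells**: vector-feature product cells with no points are dropped
  silently (no empty graph nodes); scalar bins left empty by skewed
  features likewise.
* **Degenerate input**: a constant feature cannot be binned and errors; a
  partition with fewer than two surviving groups errors; a grid value of
  $k$ infeasible for the smallest group pair errors naming that value.

## What the toy generators emulate

All validation inputs are generated in code, seeded, and bit-reproducible
(`gradient_ellipsoid()`, `radial_ball()`, `ndim_sphere()`,
`local_and_global_patterns()`, `two_feature_cloud()`,
`discontinuous_multipart()`, plus `embed_and_rotate()` and
`add_noise_snr()` as transformations):

* a 2:1 **ellipse** with the feature ramping along the major axis, with an
  optional monotone power transform `f^exp(skewness)` to skew the feature
  marginal without touching its rank order;
* a solid **ball** with the feature on the radius (concentric shells), and
  a unit **D-sphere** parameterized by hyperspherical angles — the first
  (polar) angle fully determines the first coordinate while the last
  (azimuthal) angle influences ever fewer coordinates as $D$ grows, which
  sets the expected ordering of single-angle and vector-feature SIs;
* one cloud with **two feature layouts** — a ramp repeating across
  `n_tiles` regions (local) versus a single global ramp — on identical
  coordinates, so SI-profile differences are attributable to feature
  organization alone;
* a **two-latent-feature** cloud $(x, y) = (b, \alpha a)$ + noise, for
  studying interdependent features: $b$'s imprint on position is constant
  while $\alpha$ dials $a$'s in and out;
* a **disconnected stack** of discs with one continuous feature across the
  parts, exercising clouds whose support is not connected;
* **dimensionality expansion** by zero-padding, white noise, and a random
  orthogonal rotation (QR of a Gaussian matrix, sign-fixed) — an exact
  isometry at zero noise — and **SNR-controlled noise**, defined as the
  per-coordinate variance ratio (noise variance = mean per-coordinate
  signal variance / SNR).

What they deliberately do not emulate: real neural manifolds' temporal
autocorrelation (consecutive samples are not independent), non-uniform
sampling densities driven by behavior, measurement noise structured across
dimensions, or categorical features with strongly unbalanced classes.
Passing the validation suite shows the metric behaves as designed on known
geometry; on real data the binning and neighborhood choices still demand
judgment.

## Design decisions taken where the method is open

* Generator noise levels default to 5% of the unit radius for spheres and
  1% of the unit square for the two-feature cloud — realistic working
  levels chosen once; every generator exposes them.
* In the cross-dimension sphere comparison the number of bins per angle
  dimension is held constant (3 per dimension), matching how one compares
  like with like across $D$; the alternative of holding the total cell
  count constant makes group sizes comparable but mixes bin resolution
  into the comparison.
* Bin-group order is first appearance (categorical) or ascending
  edges/lexicographic cells (continuous/vector); the SI is provably
  invariant to this order (the double sum is symmetric in the index set),
  so it affects only node labeling in exports.
* The validation suites run at reduced problem sizes (3,000–5,000 points
  instead of the 9,000–40,000 of the reference configurations); the
  stability of the index over point count is itself one of the properties
  verified, which is what makes the reduction sound.
* Automatic quantile/logarithmic binning is intentionally not provided —
  custom edges cover it explicitly, keeping the default behavior
  predictable.

## A compact demonstration

```{r demo}
toy <- gradient_ellipsoid(1500, seed = 1)
compute_si(toy$points, toy$feature, n_bins = 10,
           spec = neighbor_spec("knn", k = 3))$si

shuffled <- withr::with_seed(2, sample(toy$feature))
compute_si(toy$points, shuffled, n_bins = 10,
           spec = neighbor_spec("knn", k = 3))$si
```

```{r sweep}
lg <- local_and_global_patterns(1500, n_tiles = 4, seed = 11)
si_sweep(lg$points, lg$feature_local, grid = c(3, 10, 30, 100), n_bins = 10)
si_sweep(lg$points, lg$feature_global, grid = c(3, 10, 30, 100), n_bins = 10)
```

## Known limitations

* All pairwise scores are exact (no approximate neighbor index); cost
  grows with the square of the pair sizes. Clouds beyond a few tens of
  thousands of points per pair warrant subsampling.
* The geodesic metric materializes a full $N \times N$ distance matrix;
  memory is the binding constraint around $N \approx 2 \times 10^4$.
* The index quantifies *how much* structure a feature has, not *what kind*;
  two different organizations can share an SI (the exported graph is the
  tool for telling them apart).
* The permutation null tests exchangeability of feature values over
  points; with strong temporal autocorrelation in both cloud and feature,
  it is anti-conservative — block or session-wise permutations are outside
  the package's scope.
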