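# structindex

Quantifying how a feature is distributed over a point cloud in
arbitrary-dimensional space.

## The problem

Point clouds with per-point annotations are everywhere in quantitative
biology: population activity of N neurons over time (a neural manifold with
behavioral variables such as head direction or speed projected onto it),
event waveforms in a timestamp space, single cells in gene-expression space
with marker levels, images in pixel space with class labels. A recurring
question is whether such a feature is *structured* over the cloud — does it
follow any non-random spatial organization — and whether that organization
is local (repeating within neighborhoods) or global (a single trend across
the whole cloud). Visual inspection requires embedding to 2–3 dimensions and
is not quantitative; cluster-validity indices assume discrete, cohesive
clusters; correlation approaches assume linearity.

## The Structure Index

`structindex` implements a directed-graph metric of feature structure:

1. **Bin** the feature into `n` bin-groups `B_1..B_n` (equal-width bins by
   default; custom edges, categorical labels, and multi-dimensional vector
   features are supported — vector features use the Cartesian product of
   per-dimension bins).
2. **Overlap**: for every ordered pair of bin-groups, the overlap score

   `OS(U→V, k) = (1 / (|U|·k)) · Σ_{u∈U} |kNN(u, U∪V−{u}) ∩ V|`

   is the fraction of the k nearest neighbors of the points of U that belong
   to V, with the neighbor search restricted to the two groups involved. A
   radius variant (`β_u(r)` = all points within distance `r`) is available
   for clouds of uneven density. Scores for all pairs form an `n×n`
   adjacency matrix with zero diagonal — a weighted directed graph over the
   bin-groups.
3. **Index**: `SI = 1 − (2/(n²−n)) · Σ_{i,j} M_{ij}`, i.e. 1 minus the
   scaled mean weighted out-degree. Two interleaved groups overlap at ≈ 0.5
   in each direction, so a randomly distributed feature gives SI ≈ 0;
   perfectly separated groups give SI = 1. Small samples with small k can
   push the raw value slightly below 0; it is clipped, with the raw value
   retained.

Sweeping `k` (or `r`) profiles local versus global organization: a locally
repeating pattern collapses as the neighborhood grows, a global gradient
decays smoothly. Significance comes from a permutation null — feature
values shuffled over points, SI recomputed, 99th percentile as threshold.
The directed graph itself is exportable (GraphML / edge list): its topology
and edge asymmetries carry information the scalar index cannot.

## Worked example

```r
library(structindex)

# 2D ellipsoid cloud, feature ramping along the major axis
toy <- gradient_ellipsoid(n_points = 4000, seed = 1)
res <- compute_si(toy$points, toy$feature, n_bins = 10,
                  spec = neighbor_spec("knn", k = 3),
                  n_shuffles = 100, seed = 42)
res
#> Structure Index: 0.9907 (raw 0.9907)
#>   bin-groups: 10 (continuous), sizes 227, 342, 463, 525, 516, 501, 412, 420, 371, 223
#> Neighborhood: k = 3 nearest neighbors, euclidean metric
#>   shuffle null (n = 100): 99th percentile 0.01825
#>   observed SI is above the null threshold
```

The gradient scores 0.99 — near-perfect separation of the bins at the local
scale — far above the shuffle threshold of 0.018. The same cloud with the
feature permuted over points collapses to chance:

```r
shuf <- withr::with_seed(2, sample(toy$feature))
compute_si(toy$points, shuf, n_bins = 10, spec = neighbor_spec("knn", k = 3))$si
#> [1] 0.008449864
```

A neighborhood sweep exposes locality. For a feature that repeats across
four regions of the same cloud:

```r
lg <- local_and_global_patterns(3000, seed = 11)
si_sweep(lg$points, lg$feature_local, grid = c(3, 10, 30, 100, 200), n_bins = 10)
#>   grid        si     si_raw
#> 1    3 0.9617466  0.9617466
#> 2   10 0.9229362  0.9229362
#> 3   30 0.7334901  0.7334901
#> 4  100 0.1123813  0.1123813
#> 5  200 0.0000000 -0.1075193
```

Structure is strong in small neighborhoods and gone at k = 200 — the
signature of a purely local organization (the global-gradient layout of the
same cloud, `lg$feature_global`, stays above 0.9 across the whole grid).

Export the overlap graph for downstream analysis:

```r
g <- to_graph(res$overlap)
write_graph_file(g, "overlap.graphml")
```

## Command line

```sh
Rscript inst/cli/structure_index.R generate --kind gradient_ellipsoid --n 2000 --seed 1 --out fix
Rscript inst/cli/structure_index.R compute --data fix/points.csv --feature fix/feature.csv \
    --k 3 --n-bins 10 --shuffles 100 --seed 2 --out run
Rscript inst/cli/structure_index.R sweep --data fix/points.csv --feature fix/feature.csv \
    --grid 3,10,30,100 --out sweeprun
```

`compute` writes `si_result.json`, `overlap_matrix.csv`, a graph file, the
null distribution, and a run log. Inputs are CSV/TSV (header auto-detected);
a precomputed distance matrix can replace the built-in euclidean/geodesic
metrics via `--dist-matrix`.

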