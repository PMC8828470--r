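---
title: "Models and methods behind spomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spomics)
```

This vignette documents the statistical models implemented in `spomics`,
the parameter choices that matter, and the design decisions taken where
several reasonable conventions exist. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The data model

A `spatial_dataset` couples an observations × genes matrix `X` with a
per-observation tibble (`obs_id`, `x`, `y`, plus categorical label
columns), named spatial graphs and auxiliary observation-level matrices.
The coordinate-file order is canonical: all inputs are re-aligned to it by
`obs_id`, which removes the most common silent failure mode of spatial
pipelines (expression and coordinates sorted differently). Coordinates are
dimensionless Euclidean; when they refer to an image, `(x, y)` maps to
(column, row) of the pixel array with a 0-based origin at the top left.

A `spatial_graph` stores sparse symmetric connectivity and distance
matrices with a zero diagonal. Absent edges are structural zeros;
coincident points would otherwise store an ambiguous explicit 0, so their
edge distance is set to machine epsilon with a warning.

## Spatial neighbour graphs

Four constructors cover the assay geometries:

* `grid_graph()` for spot arrays. The lattice pitch is inferred as the
  modal nearest-neighbour distance; ring-1 neighbours are the points at
  pitch ± 10%. Ring ordinals beyond 1 come from breadth-first expansion on
  the ring-1 graph rather than distance thresholds, which tolerates the
  small positional jitter of real arrays. Hexagonal arrays have 6 first
  ring neighbours and 18 spots within two rings; square arrays have 4.
  If more than 5% of points lack a pitch-distance neighbour the
  coordinates are not lattice-like and the constructor refuses, pointing
  at the generic constructors.
* `knn_graph()` symmetrizes the directed k-nearest-neighbour relation by
  union, guaranteeing minimum degree k; distance ties break toward the
  lower observation index so results are reproducible.
* `radius_graph()` connects pairs with `0 < d ≤ r`; its edge set is
  monotone in `r`.
* `delaunay_graph()` uses the Delaunay triangulation (via `deldir`);
  collinear inputs are rejected.

`transform_graph()` provides the two adjacency transforms used by graph
neural networks: the symmetric spectral normalization
`D^{-1/2} A D^{-1/2}` (isolated nodes keep zero rows) and cosine
similarity between adjacency rows. Cosine similarity is computed for all
pairs of nodes that share at least one neighbour, with the diagonal
removed; restricting it to existing edges would make the natural
"identical neighbourhoods score 1" property unattainable, since two nodes
with identical neighbourhoods are never adjacent in a simple graph.

## Neighbourhood enrichment

For labels with classes `i, j`, the statistic is the number `x_ij` of
graph edges joining a class-`i` node to a class-`j` node, each undirected
edge counted once (also for `i = j`). The null holds the graph fixed and
permutes labels uniformly; with permutation mean `μ_ij` and standard
deviation `σ_ij`,

$$Z_{ij} = \frac{x_{ij} - \mu_{ij}}{\sigma_{ij}}.$$

Degenerate pairs (`σ_ij = 0`, e.g. a single label level) are reported as
`Z = 0` with a `sigma_zero` flag rather than `NaN`, keeping downstream
heatmaps finite while preserving the information. The companion
`interaction_matrix()` counts *ordered* node pairs, so its total is twice
the edge count and its off-diagonal entries are twice the enrichment
counts — the two conventions match their respective reference
formulations and are both documented on the functions. Whether within
class edges are counted once or twice does not affect calibration: the
z-score is invariant to any fixed linear rescaling of a count.

## Group centralities

For a cluster `S` on the unweighted connectivity (hop distances — the
stored edge weights are deliberately ignored here):

* degree: `|N(S) − S| / (|V| − |S|)`;
* closeness: reachable non-members divided by the summed minimal hop
  distance from `S`; unreachable nodes are excluded from numerator and
  denominator, and a fully unreachable complement scores 0;
* betweenness: `Σ_{u<v∉S} g_uv(S)/g_uv`, computed with the identity
  `g_uv(S) = g_uv − [d_{G−S}(u,v) = d_G(u,v)]\, g_{G−S}(u,v)` (path counts
  by BFS; disconnected pairs are skipped);
* average clustering: mean over members of `2T(v)/(deg(v)(deg(v)−1))`,
  zero for degree < 2.

A cluster equal to the whole vertex set leaves degree and closeness
undefined; both are reported as 0 with a `whole_graph` flag.

## Ripley curves and co-occurrence

`ripley()` evaluates, per cluster, over a support of 50 radii from 0 to
half the bounding-box diagonal (the paper-level definition fixes no grid,
so the support is a parameter):

* `L(t) = √(K̂(t)/π)` with the unbiased estimator
  `K̂(t) = (A / (n(n−1))) Σ_{i≠j} 1[d_{ij} < t]` and `A` the bounding-box
  area of *all* coordinates, no edge correction. Under complete spatial
  randomness `L(t) ≈ t`, which is what the acceptance envelope checks.
  Because a bounding box is not rotation-invariant, `L` with the default
  area is only translation- and scale-equivariant; pass `area` explicitly
  when the observation window is known (the rotation-invariance test does
  exactly that).
* `G`: the empirical CDF of within-cluster nearest-neighbour distances.
* `F`: the empirical CDF of distances from `n_ref` seeded uniform points
  in the bounding box to the nearest cluster point (default
  `n_ref` = cluster size).

`co_occurrence()` conditions on one cluster and pools, over all its
members, the labels of points in each annular shell `(d_low, d_high]`
around a member; the score for cluster `c` is
`p̂(c | shell) / p̂(c)`. Shells (rather than cumulative balls, available
via `cumulative = TRUE`) make the curve local in distance; a point inside
several members' shells counts once per member. Default edges are 50
equal steps from the smallest positive pairwise distance to half the
maximum pairwise distance. Empty shells give `NaN`, never an imputed
value.

## Spatial autocorrelation

With weights `w_ij` (binary connectivity, row-standardized by default so
Moran's `I` lives on roughly `[−1, 1]`), `z_i = x_i − x̄`, `W = Σ w_ij`:

$$I = \frac{n}{W}\,\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},\qquad
C = \frac{(n-1)\sum_{ij} w_{ij}(x_i - x_j)^2}{2W\sum_i z_i^2}.$$

P-values are one-sided toward spatial clustering (large `I`, small `C`) by
default because that is the screening direction; `two_sided = TRUE` is
available. The permutation test uses the add-one estimator
`p = (1 + \#\{\text{as-or-more extreme}\})/(1 + n_{perms})`, which cannot
return 0; the analytic alternative (`n_perms = 0`) uses the normal
approximation with `E[I] = −1/(n−1)`, `E[C] = 1` and the standard
normality variances. Genes are BH-adjusted jointly; zero-variance genes
yield flagged `NaN`s without aborting the remaining genes.

A calibration note: on regular-degree graphs (grid lattices) the
permutation null of `I` is close to normal and analytic and permutation
p-values agree to about 0.01 at `n = 200`. On sparse irregular graphs
(e.g. kNN with k = 6) the null is right-skewed (skewness ≈ 0.27 in our
moment checks) and the mid-range disagreement can reach 0.02–0.04 even
though the analytic mean and variance match the permutation moments —
a known limitation of the normal approximation, not of either
implementation. The calibration checks therefore run on the grid
condition typical of spot arrays.

## Diffusion-based spatial variability

A gene's expression, normalized to total mass 1, is diffused on the
ring-1 grid graph by explicit Euler steps
`u ← u + D·Δu·dt` with the lattice stencil Laplacian: for hexagonal
lattices `Δu = (2/3)(\bar u_6 − u)` (6-neighbour average minus centre,
scaled 2/3), for square lattices `Δu = \bar u_4 − u`. Missing neighbours
at the boundary are replaced by the centre value, a zero-flux condition
that conserves total mass exactly (to numerical round-off; the test
budget is 1e−9 over 1000 iterations). Convergence is declared when the
entropy of the normalized pattern changes by less than `eps` in one step,
and the score is the elapsed diffusion time `t·dt`: spatially
concentrated genes diffuse slowly and score high, noise converges almost
immediately, and a constant gene converges at the first check.

Defaults `dt = 0.001`, `D = 1`, `eps = 1e−5`, `max_iters = 30000` are
package choices (the score is used for *ranking*, which the tests show is
invariant to positive rescaling of a gene and stable under these
settings); all are exposed as arguments and CLI flags. The absolute scale
of the score depends on the stencil normalization, so scores should only
be compared within one lattice type. The inner loop is compiled (Rcpp),
as iteration counts in the tens of thousands per gene are routine.

## Ligand–receptor permutation test

For each annotated interaction (ligand complex → receptor complex) and
ordered cluster pair (sender `s`, receiver `r`):

1. complex expression per cell is the `min` (default, the conservative
   subunit-limited convention) or `mean` over subunits;
2. the statistic is `m = (mean_{cells∈s} lig + mean_{cells∈r} rec)/2` —
   the symmetric sender-ligand/receiver-receptor mean; the permutation
   null makes the particular symmetric combination immaterial;
3. the null shuffles labels `n_perms` times;
   `p = (1 + \#\{m_{perm} ≥ m_{obs}\})/(1 + n_{perms})` (one-sided
   exceedance);
4. pairs where either complex is expressed (> 0) in fewer than
   `expr_frac_threshold` (default 0.1) of its cluster's cells keep their
   mean but get `p = NaN` — significance without expression is an
   artefact; BH runs over the tested hypotheses only.

Expression is used exactly as supplied; log-normalized input is
recommended. Interactions with genes missing from the matrix are dropped
with a warning. Identical seeds give bit-identical outputs.

## Image toolkit

`image_store` keeps named `(height, width, channels)` layers on one pixel
frame. Grayscale conversion uses luminance weights
(0.2125, 0.7154, 0.0721). Gaussian smoothing is a separable convolution
with the kernel truncated at radius `round(4σ)` and reflect padding —
implemented in-package so that tiled execution (each tile processed with
an `overlap`-pixel margin, core written back) is *exactly* equal to
whole-image execution whenever `overlap ≥ 4σ`, a property the tests
assert at 1e−6 and that holds because margin plus identical boundary
padding reproduce every core pixel's full kernel support. Custom
functions can be passed as `method` and tile the same way (exact for
pixel-local transforms).

`segment_watershed()` thresholds (Otsu by default), computes the
Euclidean distance transform of the foreground and floods it by
watershed, splitting touching objects whose distance-transform peaks are
at least `min_peak_distance` apart; labels are consecutive integers from
1. An empty foreground yields a zero label layer with a warning, not an
error.

`calculate_features()` evaluates everything on the square per-spot crop
(side `round(diameter × spot_scale × scale)`, zero-padded and flagged at
image borders; circular Visium capture areas can be emulated by the spot
geometry, but crops are square by default since the underlying geometry
is a parameter, not a fact about the image):

* **summary** — per-channel mean, sd, quantiles (0.9, 0.5, 0.1);
* **histogram** — per-channel bin counts (10 bins over the value range);
* **texture** — GLCM at 256 gray levels, offset distance 1, angles
  0°/45°/90°/135°, symmetrized and normalized to probabilities before the
  five properties (contrast, dissimilarity, homogeneity, angular second
  moment, correlation) are computed and averaged over angles. The
  properties are only well scaled on a probability matrix, which is why
  normalization precedes them; a zero-variance crop takes correlation 1
  by the limit convention. Float layers outside `[0, 1]` need an explicit
  `texture_range` — silently guessing a quantization range would make
  features incomparable across spots;
* **segmentation** — objects are assigned to a spot when their centroid
  falls inside its crop (a single unambiguous assignment per object);
  features are the object count, mean and sd of object pixel areas, and
  per-channel mean intensity over object pixels.

Feature extraction is independent per observation, so results do not
depend on evaluation order or parallel scheduling.

## Synthetic data as study conditions

The generators fix the simulation conditions used throughout the tests
and the acceptance script:

* point patterns: uniform Poisson in a unit window; a Thomas-style
  clustered process (points attached to uniform parents, Gaussian
  displacement — the standard clustered alternative for Ripley
  statistics); hexagonal/square lattices with unit pitch;
* labels: i.i.d. categorical or contiguous spatial blocks;
* expression: non-negative `|N(1, σ)|` noise, with optional planted
  spatial block effects (+effect inside half the window) or planted
  ligand–receptor pairs (ligand elevated in the sender cluster, receptor
  in the receiver; default effect size 3 over noise sd 0.5–1, a strong
  but not degenerate signal);
* blob images: non-overlapping disks (rejection-sampled centres) plus
  Gaussian pixel noise (default sd 0.05 on unit intensity), returning
  ground-truth centres.

Every generator is a pure function of its arguments and seed. What these
simulations do *not* emulate — segmentation errors, spatially varying
capture efficiency, anisotropic tissue deformation, realistic nuclear
morphology — bounds what passing tests show: calibration and correctness
of the statistics under their model assumptions, not robustness to every
real-data pathology.

Problem sizes used by the checks (100-node graphs × 1000 permutations ×
tens of replicates, 500-point CSR patterns with a 100–200 simulation
envelope, 9 × 9 lattices × 50–100 diffusion seeds, 128² images × 20
seeds) were chosen so the whole suite characterizes calibration behaviour
at conventional desk scale.

## Known limitations

* Ripley estimators carry no edge correction; curves near half the window
  diagonal are biased downward (the acceptance envelope restricts to a
  quarter of the window side).
* The analytic autocorrelation p-value inherits the normal
  approximation's skewness error on sparse irregular graphs (see above);
  use the permutation route when that matters.
* Grid graphs assume a single lattice pitch; mixed-resolution arrays are
  not supported.
* The diffusion score's absolute scale is stencil-dependent; compare
  rankings, not raw scores, across platforms.
* Images are processed in memory; there is no lazy/on-disk backing, and
  only 2-D (single-z) images are supported.
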