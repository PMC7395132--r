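---
title: "Methods: temporal dynamics of zoogeographical regions"
author: "zooregions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal dynamics of zoogeographical regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zooregions)
```

## The problem

Zoogeographical regions are sets of geographically coherent grid cells
whose faunas are more similar within than between regions. A single
regionalization of present-day assemblages is a snapshot; the question this
package addresses is how such regions change through time, using two
complementary currencies:

* **phylogenetic depth** — a dated phylogeny of the extant fauna is cut at
  a depth *t* (Ma before present) and every lineage crossing *t* becomes
  one analytical unit whose range is the union of its descendants' ranges;
  repeating the regionalization across a grid of depths tracks how the
  dissimilarity structure decays towards the past;
* **geological time** — fossil occurrences are binned into geological
  intervals and compositional dissimilarity is computed between coarse
  regional assemblages per interval, giving a direct (if incomplete) record
  of past faunas.

Both views feed the same downstream machinery: turnover dissimilarity
matrices, UPGMA dendrograms with data-driven cut selection, NMDS
ordinations, Procrustes trajectories anchored at the present, and Mantel
permutation tests.

## Dissimilarity model

The package uses the Simpson (turnover-only) family throughout. For two
assemblages with shared richness $a$ and unique richnesses $b$ and $c$,

$$\beta_{sim} = \frac{\min(b, c)}{a + \min(b, c)}.$$

The phylogenetic version $p\beta_{sim}$ uses the same formula with $a$,
$b$, $c$ measured as branch length: a branch of the tree is *present* in an
assemblage iff at least one of its descendant tips is, $a$ is the total
length present in both assemblages, and $b$/$c$ the lengths present in only
one. No branch above the root is counted, and tree tips absent from the
incidence matrix are pruned first (degree-2 nodes are suppressed with
length addition, so tip-to-tip path lengths are invariant).

Two consequences worth keeping in mind:

* turnover is insensitive to nestedness — a fauna strictly contained in
  another scores exactly 0 — and to richness differences;
* on a star tree with unit branch lengths $p\beta_{sim}$ collapses to
  $\beta_{sim}$, which the tests exploit as an identity.

Per-group matrices (e.g. one per vertebrate class) are combined by the
unweighted element-wise mean, restricted to the sites shared by all groups
(intersection mode). The mean is unweighted because no defensible weighting
by group richness exists once turnover has removed richness information.
The site-richness and land-fraction filters (`filter_sites()`, defaults:
keep `land_fraction >= 0.5` and richness `>= 5`) are applied per group
*before* combining, because richness thresholds are only meaningful within
a taxon set; the combined matrix then covers the intersection of surviving
sites.

## Tree slicing

`slice_tree(tree, t)` removes every branch segment younger than *t*:

* branches wholly older than *t* are kept unchanged;
* branches spanning *t* are truncated — the remaining pendant covers only
  the segment older than *t* (length = older-end age − *t*). Keeping the
  full branch length instead would double-count evolution younger than the
  slice, which is exactly what the slice is meant to discard; the
  truncation choice is therefore fixed, not a flag;
* a node whose age equals *t* sits on the older side: it becomes a
  crossing point and its child branches are removed;
* node ages are distances to the furthest descendant tip, so for the
  ultrametric trees of extant faunas the slice is a horizontal cut at *t*
  before present. Non-ultrametric trees are accepted with a warning.

`branch_site_matrix()` then merges the ranges of descendant leaves into
their crossing lineage, and `pbeta_at_depth()` evaluates
$p\beta_{sim}$ on the remaining tree. At `t = 0` the slice is the identity
and reproduces the unsliced matrix bit-for-bit. At `t >=` root age a single
lineage holds every tip; all dissimilarities are then defined as 0 and a
warning is raised. The default depth grid is 0, 5, 10, 20, 40, 60 Ma,
spanning the Cenozoic at increasing coarseness.

## Regionalization

Eight agglomerative methods are available (single, complete, UPGMA, WPGMA,
UPGMC, WPGMC and the two Ward variants — the standard octet of the
hierarchical-clustering ecosystem); `compare_linkage_methods()` scores each
by its cophenetic correlation per matrix and compares methods by paired
two-sided Wilcoxon signed-rank tests. The signed-rank test drops zero
differences, uses the exact null (via the signed-rank distribution) for up
to 25 tie-free pairs and a tie-corrected normal approximation otherwise;
when all differences vanish the comparison is undecidable and p = 1 is
reported with a warning. UPGMA is the default for the analysis chain, as
its cophenetic distances are ultrametric and it consistently tracks the
input matrix most faithfully.

Cut selection (`select_regions()`) scans `k = 2..15` and computes, per cut,

* the **explained dissimilarity** ED(k): the fraction of total pairwise
  dissimilarity falling between clusters (0 for one cluster, 1 for all
  singletons, non-decreasing along the cuts of one dendrogram);
* the **mean silhouette width** with the usual
  $s(i) = (b - a)/\max(a, b)$ and $s = 0$ for singleton clusters.

The concrete rule — the smallest k with ED(k) ≥ 0.9, silhouette as the
tie-break, and a max-silhouette fallback (with a warning) when no k reaches
the threshold — is this package's own composite of the two metrics; both
are reported for every k so users can apply any other rule. The 0.9 default
asks the partition to account for the bulk of the turnover while keeping k
small; the per-k table makes the trade-off auditable.

Spatial diagnostics use rook (4-neighbour) lattice adjacency by default
(queen optional): `geographic_coherence()` reports the largest connected
component fraction per region (flagging regions below 0.8 as fragmented)
and `boundary_strength()` the mean dissimilarity across adjacent
cross-region cell pairs — the quantity a map would scale boundary widths
by.

## Ordination, trajectories, Mantel

`nmds()` is Kruskal-style non-metric MDS (stress-1, monotone regression,
primary treatment of ties) on the `vegan::monoMDS` engine, restarted from a
classical-scaling configuration plus random configurations; the best of the
restarts wins and a seed makes the whole procedure deterministic. Stress
near zero is expected only for genuinely low-dimensional structure; a few
hundred grid cells in two dimensions typically sit near 0.2, which is a
property of the data, not a failure of the optimizer.

`procrustes_align()` is least-squares superimposition (translation,
orthogonal rotation, optional isotropic scaling) of one configuration onto
another. Reflection is allowed by default — only shape correspondence
matters for trajectory reading — and can be disabled, in which case the
improper component of the fitted rotation is projected out (the smallest
singular direction is flipped). `procrustes_trajectory()` aligns every
slice onto the present-day ordination (asymmetric, reference = depth 0),
because trajectories are read as "where was this assemblage relative to
its present position"; chaining consecutive slices instead would
accumulate alignment error with depth.

`mantel_test()` correlates lower triangles and permutes entities jointly
across rows and columns of the second matrix; the p value uses the add-one
rule $(1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$, one-sided
"greater" by default (the hypothesis of interest is positive
correspondence with the present), two-sided optionally, and never equals
exactly zero. An exhaustive mode enumerates all permutations for small
matrices and is used by the tests as its own oracle.

## Fossil pipeline

Genus is the analytical unit. Cleaning proceeds in a fixed order with
conserved counts (input = indeterminate + duplicates + unassigned +
assigned):

1. records with empty or indeterminate genus names (terminal
   "indet."/"indet" token or quotation marks) are excluded at read time;
2. exact duplicates on (genus, lon, lat, min_age, max_age) are removed;
3. localities are merged by snapping coordinates to a fixed 0.1° grid
   (floor binning). Binning is deterministic and idempotent; single-linkage
   chaining of "nearby" localities is path-dependent and was rejected;
4. each record is assigned to the interval containing its mean age
   ((min + max)/2), young bound inclusive, old bound exclusive. The
   default intervals are Eocene (56.0–33.9 Ma), Oligocene (33.9–23.0 Ma),
   Early Miocene (23.0–15.9 Ma), Mid–Late Miocene (15.9–5.33 Ma) and
   Pliocene–Pleistocene (5.33 Ma–11.8 Ka); the Miocene/Pliocene boundary
   is carried at 5.33 Ma on both sides so the intervals tile exactly.

Records are then mapped to coarse regions by a coordinate lookup (palaeo
coordinates are used when `paleo_lon`/`paleo_lat` columns are present;
plate-rotation itself is upstream of this package), and each interval
yields a region × genus incidence, a $\beta_{sim}$ matrix, a UPGMA
dendrogram and an NMDS (skipped below three regions, with a warning).
Regions represented by fewer than two genera are excluded per interval —
one genus cannot support a turnover estimate.

## The synthetic generator

`region_scenario()` plants K contiguous rectangular blocks on a lattice
grid; each region receives a clade whose stem attaches at the scheduled
split age, with within-clade nodes at ages uniform below the stem; each
species occupies home-block cells with probability p and foreign cells
with probability q < p; fossils are drawn per interval from occupied cells
with a preservation probability, ages uniform within the interval.

Defaults — and the study conditions used by the tests and the acceptance
script — are: K = 4 on a 20 × 20 grid, 15 species per region, splits at
10 Ma (R1, R2), 30 Ma (R3, R4) and a 60 Ma root, p = 0.8, q = 0.05,
preservation 0.5 per interval, minimum site richness 5. The split grid
mirrors the package's depth grid (a 40 Ma slice must merge both planted
pairs; a 5 Ma slice must not); 15 species per region gives sites an
expected richness of ~12 home species plus leakage, comfortably above the
richness filter while keeping a full 50-seed recovery study in the
minutes range; p and q are far enough apart that recovery is expected but
close enough that it is not trivial.

What the generator deliberately does **not** emulate: dispersal kernels or
range cohesion beyond the home block, extinction (every simulated lineage
survives to the present), niche evolution, spatially or taxonomically
biased preservation, and taxonomic noise in genus names. Passing
recovery tests therefore demonstrate that the inference chain recovers
planted regional structure under clean conditions — they do not certify
performance on real range maps with uneven sampling, nor on fossil data
with strongly structured preservation.

## Numerical choices and degenerate inputs

* Dissimilarity matrices are validated (symmetric, zero diagonal, values
  in [0, 1]); violations beyond 1e-8 are errors, smaller ones are
  repaired by symmetrization and clamping.
* Shared-component matrices are computed by dense matrix products;
  `min(b, c)` values below 1e-12 of the largest assemblage total are
  clamped to exact zero so identical assemblages score exactly 0.
* Agglomeration ties follow the deterministic tie-handling of
  `stats::hclust`.
* All-zero dissimilarity matrices short-circuit: region selection returns
  a single region with a warning, NMDS refuses them.
* Every stochastic routine (NMDS restarts, Mantel permutations, all
  simulators) is reproducible from an integer seed.

## Problem sizes in the test-suite

The suite exercises: oracle equivalence of the phylogenetic turnover
against direct branch-segment enumeration on 50 random trees (≤ 12 tips,
3 random depths each, absolute agreement 1e-12); UPGMA against exhaustive
agglomeration on 100 random matrices (n ≤ 8); Procrustes against a 1-D
angle-scan oracle; Mantel against exhaustive permutation enumeration on
4 × 4 matrices plus a 1000-replicate type-I calibration at 999
permutations; and the 50-seed planted-region recovery study at the default
scenario above (selected k, ARI vs truth, depth-40 merges, Mantel decay).

## Known limitations

* Slicing semantics are calibrated for ultrametric trees; trees of extant
  taxa that fail ultrametricity only get a warning, and slices of such
  trees should be interpreted with care.
* The fossil chain assumes pre-standardized genus names; no reconciliation
  against external taxonomies is attempted.
* Ordination-based trajectory reading inherits all NMDS caveats: only rank
  structure is preserved, and high stress limits the meaning of arrow
  geometry.
* Rasterization of range polygons, map projections and palaeocoordinate
  rotation are all upstream of this package: it consumes incidence
  matrices, dated trees and occurrence tables.
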