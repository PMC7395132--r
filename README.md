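# zooregions

Reconstructing the temporal dynamics of zoogeographical regions from
extant assemblages and fossil occurrences.

A zoogeographical region is a set of geographically coherent grid cells
whose faunas are more similar within than between regions. This package
asks how such regions change through time, by two complementary routes:

* **phylogenetic depth** — cut a dated phylogeny at a depth *t* (Ma) and
  treat each lineage crossing *t* as one analytical unit whose range is
  the union of its descendants' ranges; regionalize the resulting
  dissimilarity structure at a series of depths;
* **geological time** — bin fossil occurrences into geological intervals
  and compare coarse regional assemblages per interval.

Both routes use the Simpson (turnover-only) dissimilarity as their
currency. For assemblages with shared component *a* and unique components
*b*, *c*:

    beta_sim  = min(b, c) / (a + min(b, c))

computed on species counts for fossils and on branch lengths for the
phylogenetic version (a branch is present in an assemblage iff at least
one of its descendant tips is). The downstream machinery is shared: UPGMA
dendrograms with cut selection by explained dissimilarity and silhouette
width, NMDS ordination, Procrustes trajectories anchored at the present
day, and Mantel permutation tests.

A synthetic-data generator plants regional structure with known truth
(K contiguous regions on a lattice, region clades splitting at scheduled
ages, configurable occupancy/leakage/preservation), so every stage of the
pipeline has a parameter-recovery test with no external data.

## Worked example

Plant four regions on a 20 × 20 grid (region pairs splitting at 10 and
30 Ma under a 60-Ma root, occupancy 0.8, leakage 0.05), then recover them:

```r
library(zooregions)

sc  <- region_scenario(seed = 1)
st  <- simulate_regional_tree(sc)      # dated tree + species -> region map
m   <- simulate_ranges(sc, st$regions) # 400 sites x 60 species, 0/1

D   <- pairwise_pbeta_sim(st$tree, m)  # phylogenetic Simpson, present day
asg <- select_regions(linkage(D, "UPGMA"), D)
asg
#> Region assignment: k = 4 (ED = 0.907, silhouette = 0.619)
#>
#>   1   2   3   4
#>  99 100 101 100
head(asg$table, 4)
#>   k explained_dissimilarity mean_silhouette
#> 1 2               0.4871383       0.4129288
#> 2 3               0.7780410       0.4963012
#> 3 4               0.9066961       0.6194448
#> 4 5               0.9076302       0.5471971
```

The four planted regions are recovered (k = 4 is the smallest cut whose
explained dissimilarity reaches 0.9; the ~100-cell clusters match the
planted blocks). Ordination and the depth comparison:

```r
nmds(D, restarts = 10, seed = 11)
#> NMDS (2-D, 400 points): stress = 0.19168

D5 <- pbeta_at_depth(st$tree, m, 5)    # slice the tree at 5 Ma
mantel_test(D, D5, n_perm = 999, seed = 12)
#> Mantel test: r = 0.9216, p = 0.001 (greater, 999 permutations)
```

The 5-Ma slice correlates strongly with the present-day structure; by
40 Ma the planted 10- and 30-Ma splits have been absorbed and the
regionalization collapses to two regions (`pbeta_at_depth(st$tree, m, 40)`).

The building blocks work on plain objects — an `ape` tree and a labelled
0/1 matrix:

```r
tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
mm <- matrix(c(1,0, 0,1, 1,1), 2, 3,
             dimnames = list(c("s1","s2"), c("A","B","C")))
pairwise_pbeta_sim(tr, mm)
#>      s1   s2
#> s1 0.00 0.25
#> s2 0.25 0.00
```

(shared branch length a = 3, unique b = c = 1, so 1/(3+1) = 0.25).

The fossil route mirrors this: `read_fossils()` →
`clean_fossils()` (deduplication, 0.1° locality binning, mean-age interval
assignment with conserved counts) → `interval_beta_series()` or the
end-to-end `run_fossil_series()`. The orchestration functions
`run_present_day()`, `run_depth_series()` and `run_fossil_series()` run
each analysis end to end and can serialize all artifacts to CSV/Newick.

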