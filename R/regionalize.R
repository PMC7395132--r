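# Hierarchical regionalization: agglomerative clustering of dissimilarity
# matrices, comparison of linkage methods by cophenetic correlation, cut
# selection by explained dissimilarity and silhouette width, and spatial
# diagnostics (boundary strength, geographic coherence).

# the eight agglomeration methods compared (names as commonly used in
# numerical taxonomy -> stats::hclust codes)
.linkage_methods <- c(single = "single", complete = "complete",
                      UPGMA = "average", WPGMA = "mcquitty",
                      UPGMC = "centroid", WPGMC = "median",
                      ward1 = "ward.D", ward2 = "ward.D2")

#' Agglomerative clustering of a dissimilarity matrix
#'
#' @param D dissimilarity matrix.
#' @param method one of `"single"`, `"complete"`, `"UPGMA"`, `"WPGMA"`,
#'   `"UPGMC"`, `"WPGMC"`, `"ward1"`, `"ward2"`.
#' @return an `hclust` dendrogram (leaf labels = entity ids).
#' @export
linkage <- function(D, method = "UPGMA") {
  method <- match.arg(method, names(.linkage_methods))
  D <- validate_dissim(D)
  if (nrow(D) < 2L) stop("need at least two entities to cluster")
  hc <- stats::hclust(stats::as.dist(D), method = .linkage_methods[[method]])
  hc$method <- method
  hc
}

#' Cophenetic correlation between a dendrogram and its input matrix
#'
#' Pearson correlation between the lower triangle of `D` and the cophenetic
#' distances of `dend`; measures how faithfully the dendrogram preserves the
#' dissimilarity structure.
#'
#' @param dend an `hclust` object.
#' @param D the dissimilarity matrix the dendrogram was built from.
#' @return correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(dend, D) {
  D <- validate_dissim(D)
  if (!setequal(dend$labels, rownames(D)))
    stop("dendrogram and matrix have different entity sets")
  coph <- as.matrix(stats::cophenetic(dend))
  ids <- rownames(D)
  lt <- lower.tri(D)
  x <- D[lt]
  y <- coph[ids, ids][lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant distance vector")
  stats::cor(x, y)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired samples with the conventions used
#' throughout the package: zero differences are dropped; the exact
#' signed-rank null is used for n <= 25 pairs when the absolute differences
#' are tie-free, otherwise a normal approximation with tie correction. When
#' every difference is zero the test is undecidable and p = 1 is returned
#' with a warning.
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (V, the positive-rank sum), `p.value`,
#'   `n` (non-zero pairs) and `exact` flag.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p value undefined, reported as 1")
    return(list(statistic = NA_real_, p.value = 1, n = 0L, exact = FALSE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (n <= 25L && !ties) {
    p <- 2 * min(stats::psignrank(v, n),
                 stats::psignrank(v - 1, n, lower.tail = FALSE))
    return(list(statistic = v, p.value = min(1, p), n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
  z <- (v - mu) / sqrt(sigma2)
  list(statistic = v, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       n = n, exact = FALSE)
}

#' Compare linkage methods across a set of dissimilarity matrices
#'
#' Each method is scored by its cophenetic correlation on every matrix; the
#' per-matrix scores are the paired samples of pairwise two-sided Wilcoxon
#' signed-rank tests between methods.
#'
#' @param matrices list of at least two dissimilarity matrices.
#' @param methods subset of the eight linkage methods (default: all).
#' @return list of class `linkage_comparison` with `cophenetic` (method x
#'   matrix score table), `mean` (per-method mean score), `p_values`
#'   (pairwise Wilcoxon p matrix) and `best` (method with highest mean).
#' @export
compare_linkage_methods <- function(matrices,
                                    methods = names(.linkage_methods)) {
  if (length(matrices) < 2L)
    stop("need at least two matrices for paired comparison")
  methods <- match.arg(methods, names(.linkage_methods),
                       several.ok = TRUE)
  cc <- vapply(matrices, function(D) {
    D <- validate_dissim(D)
    vapply(methods,
           function(mt) cophenetic_correlation(linkage(D, mt), D),
           numeric(1))
  }, numeric(length(methods)))
  cc <- matrix(cc, nrow = length(methods),
               dimnames = list(methods,
                               names(matrices) %||%
                                 paste0("m", seq_along(matrices))))
  p <- matrix(NA_real_, length(methods), length(methods),
              dimnames = list(methods, methods))
  for (i in seq_along(methods)) for (j in seq_along(methods)) {
    if (i < j) {
      pv <- suppressWarnings(
        wilcoxon_signed_rank(cc[i, ], cc[j, ])$p.value)
      p[i, j] <- p[j, i] <- pv
    }
  }
  means <- rowMeans(cc)
  structure(list(cophenetic = cc, mean = means, p_values = p,
                 best = names(which.max(means))),
            class = "linkage_comparison")
}

#' @export
print.linkage_comparison <- function(x, ...) {
  cat("Linkage comparison over", ncol(x$cophenetic), "matrices\n")
  print(round(sort(x$mean, decreasing = TRUE), 4))
  cat("best:", x$best, "\n")
  invisible(x)
}

#' Explained dissimilarity of a partition
#'
#' Fraction of the total pairwise dissimilarity that falls between (rather
#' than within) clusters: 0 for a single cluster, 1 when all entities are
#' singletons.
#'
#' @param D dissimilarity matrix.
#' @param labels cluster labels aligned with the rows of `D`.
#' @return value in `[0, 1]`.
#' @export
explained_dissimilarity <- function(D, labels) {
  D <- validate_dissim(D)
  stopifnot(length(labels) == nrow(D))
  lt <- lower.tri(D)
  total <- sum(D[lt])
  if (total == 0) stop("explained dissimilarity undefined for all-zero matrix")
  between <- outer(labels, labels, `!=`)
  sum(D[lt & between]) / total
}

#' Mean silhouette width of a partition
#'
#' Standard silhouette on precomputed dissimilarities
#' (`s(i) = (b - a) / max(a, b)`); entities in singleton clusters get
#' `s(i) = 0`.
#'
#' @inheritParams explained_dissimilarity
#' @return mean silhouette width in `[-1, 1]`.
#' @export
mean_silhouette <- function(D, labels) {
  D <- validate_dissim(D)
  stopifnot(length(labels) == nrow(D))
  k <- length(unique(labels))
  n <- nrow(D)
  if (k < 2L || k > n - 1L)
    stop("silhouette requires 2 <= k <= n - 1")
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = D)
  mean(sil[, "sil_width"])
}

#' Select the number of regions by cutting a dendrogram
#'
#' Cuts the dendrogram at every `k` in `k_range`, computes the explained
#' dissimilarity ED(k) and the mean silhouette width, and selects the
#' smallest k with ED(k) >= `ed_threshold`; if several candidate k share
#' that ED value the one with maximal silhouette wins, and if no k reaches
#' the threshold the k with maximal silhouette is chosen (with a warning).
#' The full per-k table is always returned so other rules can be applied.
#'
#' @param dend `hclust` dendrogram.
#' @param D the dissimilarity matrix it was built from.
#' @param k_range candidate numbers of regions (default `2:15`).
#' @param ed_threshold explained-dissimilarity target (default 0.9).
#' @return object of class `region_assignment`: list with `labels` (named
#'   integer vector site -> region), `k`, `explained_dissimilarity`,
#'   `mean_silhouette`, `table` (per-k metrics) and `ed_threshold`.
#' @export
select_regions <- function(dend, D, k_range = 2:15, ed_threshold = 0.9) {
  D <- validate_dissim(D)
  n <- nrow(D)
  if (sum(D[lower.tri(D)]) == 0) {
    warning("all dissimilarities are zero; single region returned")
    labels <- stats::setNames(rep(1L, n), rownames(D))
    return(structure(list(labels = labels, k = 1L,
                          explained_dissimilarity = NA_real_,
                          mean_silhouette = NA_real_,
                          table = data.frame(k = integer(),
                                             explained_dissimilarity = numeric(),
                                             mean_silhouette = numeric()),
                          ed_threshold = ed_threshold),
                     class = "region_assignment"))
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range >= n)) {
    k_range <- k_range[k_range < n]
    warning("k values >= number of entities dropped")
  }
  if (!length(k_range)) stop("empty k range")
  cuts <- stats::cutree(dend, k = k_range)
  cuts <- matrix(cuts, nrow = n, dimnames = list(dend$labels,
                                                 as.character(k_range)))
  cuts <- cuts[rownames(D), , drop = FALSE]
  ed <- vapply(seq_along(k_range), function(i)
    explained_dissimilarity(D, cuts[, i]), numeric(1))
  sil <- vapply(seq_along(k_range), function(i) {
    ki <- length(unique(cuts[, i]))
    if (ki < 2L || ki > n - 1L) return(NA_real_)
    mean_silhouette(D, cuts[, i])
  }, numeric(1))
  tab <- data.frame(k = k_range, explained_dissimilarity = ed,
                    mean_silhouette = sil)
  cand <- which(ed >= ed_threshold)
  if (length(cand)) {
    first <- cand[which.min(k_range[cand])]
    ties <- cand[ed[cand] == ed[first]]
    pick <- if (length(ties) > 1L && !all(is.na(sil[ties])))
      ties[which.max(sil[ties])] else first
  } else {
    warning("no k reached the explained-dissimilarity threshold; ",
            "falling back to maximal silhouette")
    pick <- which.max(sil)
  }
  labels <- cuts[, pick]
  structure(list(labels = labels, k = length(unique(labels)),
                 explained_dissimilarity = ed[pick],
                 mean_silhouette = sil[pick],
                 table = tab, ed_threshold = ed_threshold),
            class = "region_assignment")
}

#' @export
print.region_assignment <- function(x, ...) {
  cat(sprintf("Region assignment: k = %d (ED = %.3f, silhouette = %.3f)\n",
              x$k, x$explained_dissimilarity, x$mean_silhouette))
  print(table(x$labels))
  invisible(x)
}

#' Lattice adjacency for grid-cell sites
#'
#' Builds the site adjacency used by the spatial diagnostics from integer
#' lattice coordinates: rook (4-neighbour) by default, queen (8-neighbour)
#' optionally.
#'
#' @param coords data frame with columns `site`, `x`, `y`.
#' @param scheme `"rook"` or `"queen"`.
#' @return two-column character matrix of adjacent site id pairs.
#' @export
grid_adjacency <- function(coords, scheme = c("rook", "queen")) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("site", "x", "y") %in% names(coords)))
  key <- paste(coords$x, coords$y)
  offsets <- list(c(1, 0), c(0, 1))
  if (scheme == "queen") offsets <- c(offsets, list(c(1, 1), c(1, -1)))
  pairs <- lapply(offsets, function(o) {
    nb <- match(paste(coords$x + o[1], coords$y + o[2]), key)
    ok <- !is.na(nb)
    cbind(coords$site[ok], coords$site[nb[ok]])
  })
  do.call(rbind, pairs)
}

#' Dissimilarity strength of region boundaries
#'
#' For each pair of regions with at least one adjacent cross-region site
#' pair, the mean dissimilarity over those adjacent pairs (the quantity a
#' map would scale boundary widths by). Non-adjacent region pairs are
#' omitted.
#'
#' @param assignment a `region_assignment` (or named label vector).
#' @param D site dissimilarity matrix.
#' @param adjacency two-column matrix of adjacent site id pairs.
#' @return data frame with `region_a`, `region_b`, `n_pairs`,
#'   `mean_dissimilarity`.
#' @export
boundary_strength <- function(assignment, D, adjacency) {
  labels <- if (inherits(assignment, "region_assignment"))
    assignment$labels else assignment
  D <- validate_dissim(D)
  a <- as.character(adjacency[, 1L])
  b <- as.character(adjacency[, 2L])
  la <- labels[a]
  lb <- labels[b]
  cross <- which(la != lb)
  if (!length(cross))
    return(data.frame(region_a = character(), region_b = character(),
                      n_pairs = integer(), mean_dissimilarity = numeric()))
  key <- paste(pmin(la[cross], lb[cross]), pmax(la[cross], lb[cross]),
               sep = "|")
  d <- D[cbind(a[cross], b[cross])]
  agg <- tapply(d, key, mean)
  cnt <- tapply(d, key, length)
  parts <- do.call(rbind, strsplit(names(agg), "|", fixed = TRUE))
  data.frame(region_a = parts[, 1L], region_b = parts[, 2L],
             n_pairs = as.integer(cnt),
             mean_dissimilarity = as.numeric(agg),
             row.names = NULL)
}

#' Geographic coherence of regions
#'
#' Per region, the fraction of its sites in the largest connected component
#' of the adjacency graph restricted to that region. Regions below
#' `coherence_threshold` are flagged as spatially fragmented.
#'
#' @inheritParams boundary_strength
#' @param coherence_threshold flag threshold (default 0.8).
#' @return data frame with `region`, `n_sites`,
#'   `largest_component_fraction`, `coherent`.
#' @export
geographic_coherence <- function(assignment, adjacency,
                                 coherence_threshold = 0.8) {
  labels <- if (inherits(assignment, "region_assignment"))
    assignment$labels else assignment
  sites <- names(labels)
  regions <- sort(unique(labels))
  res <- lapply(regions, function(r) {
    in_r <- sites[labels == r]
    if (length(in_r) == 1L)
      return(data.frame(region = as.character(r), n_sites = 1L,
                        largest_component_fraction = 1))
    keep <- adjacency[, 1L] %in% in_r & adjacency[, 2L] %in% in_r
    g <- igraph::graph_from_data_frame(
      as.data.frame(adjacency[keep, , drop = FALSE]),
      directed = FALSE,
      vertices = data.frame(name = in_r))
    comp <- igraph::components(g)
    data.frame(region = as.character(r), n_sites = length(in_r),
               largest_component_fraction = max(comp$csize) / length(in_r))
  })
  out <- do.call(rbind, res)
  out$coherent <- out$largest_component_fraction >= coherence_threshold
  out
}
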