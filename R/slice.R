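# Cutting a dated tree at a phylogenetic depth t: branch segments younger
# than t are removed, each lineage crossing t becomes a tip of the remaining
# tree, and the geographic ranges of descendant leaves are merged into their
# crossing lineage. This turns a site-by-species matrix into a
# site-by-lineage matrix on which the phylogenetic Simpson dissimilarity is
# evaluated at depth t.

#' Slice a dated tree at a phylogenetic depth
#'
#' Branches wholly younger than `depth` are removed; branches spanning
#' `depth` are truncated so the remaining pendant covers only the segment
#' older than `depth`; branches wholly older are kept unchanged. A node
#' whose age equals `depth` sits on the older side: it becomes a crossing
#' point and its child branches are removed. When `depth >= root age` the
#' slice is degenerate: a single lineage holds every tip and no tree
#' remains.
#'
#' @param tree dated `phylo`.
#' @param depth slice depth in the tree's time unit (e.g. Ma), `>= 0`.
#' @return an object of class `sliced_tree`: a list with `depth`, `tree`
#'   (the remaining `phylo`, or `NULL` when degenerate), `lineages` (named
#'   list: crossing lineage -> original tip labels), `tip_to_lineage`
#'   (named character vector) and `degenerate` flag.
#' @export
slice_tree <- function(tree, depth) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!is.finite(depth) || depth < 0) stop("depth must be >= 0")
  n_tip <- length(tree$tip.label)
  ages <- node_ages(tree)
  root <- n_tip + 1L
  root_age <- ages[root]
  if (depth >= root_age) {
    map <- stats::setNames(rep("lineage1", n_tip), tree$tip.label)
    return(structure(list(depth = depth, tree = NULL,
                          lineages = list(lineage1 = tree$tip.label),
                          tip_to_lineage = map, degenerate = TRUE),
                     class = "sliced_tree"))
  }
  desc <- descendant_tips(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  len_by_child <- numeric(n_tip + tree$Nnode)
  len_by_child[tree$edge[, 2L]] <- tree$edge.length

  lineages <- list()
  fmt <- function(x) sprintf("%.17g", x)
  quote_label <- function(x)
    ifelse(grepl("[(),:;'\"\\[\\]\\s]", x), paste0("'", x, "'"), x)
  register <- function(tips) {
    nm <- if (length(tips) == 1L) tips else
      sprintf("lineage%d", length(lineages) + 1L)
    lineages[[nm]] <<- tips
    nm
  }
  build <- function(node) {
    parts <- character()
    for (ch in kids[[as.character(node)]]) {
      l <- len_by_child[ch]
      if (ch > n_tip && ages[ch] > depth) {
        parts <- c(parts, paste0(build(ch), ":", fmt(l)))
      } else {
        nm <- register(desc[[ch]])
        parts <- c(parts,
                   paste0(quote_label(nm), ":",
                          fmt(min(l, ages[node] - depth))))
      }
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(build(root), ";")
  remaining <- ape::read.tree(text = nwk)
  map <- character(n_tip)
  names(map) <- tree$tip.label
  for (nm in names(lineages)) map[lineages[[nm]]] <- nm
  structure(list(depth = depth, tree = remaining, lineages = lineages,
                 tip_to_lineage = map, degenerate = FALSE),
            class = "sliced_tree")
}

#' @export
print.sliced_tree <- function(x, ...) {
  cat(sprintf("Tree sliced at depth %g: %d lineage(s) from %d tips%s\n",
              x$depth, length(x$lineages), length(x$tip_to_lineage),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Branch-by-site matrix of a sliced tree
#'
#' Collapses a site-by-species incidence matrix onto the lineages crossing
#' the slice: a lineage is present in a site iff any of its descendant tips
#' is.
#'
#' @param s a `sliced_tree`.
#' @param m binary site-by-taxon matrix whose taxa are tips of the original
#'   tree.
#' @return binary site-by-lineage matrix (metadata attribute carried over).
#' @export
branch_site_matrix <- function(s, m) {
  stopifnot(inherits(s, "sliced_tree"))
  check_binary(m)
  unknown <- setdiff(colnames(m), names(s$tip_to_lineage))
  if (length(unknown))
    stop("taxa absent from sliced tree: ", paste(unknown, collapse = ", "))
  lin_names <- if (s$degenerate) names(s$lineages) else s$tree$tip.label
  out <- vapply(lin_names, function(nm) {
    tips <- intersect(s$lineages[[nm]], colnames(m))
    if (!length(tips)) return(integer(nrow(m)))
    as.integer(rowSums(m[, tips, drop = FALSE]) > 0)
  }, integer(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), lin_names))
  # a non-empty species row cannot lose all lineages
  stopifnot(all(rowSums(out)[rowSums(m) > 0] > 0))
  attr(out, "sites") <- attr(m, "sites")
  out
}

#' Phylogenetic Simpson dissimilarity at a phylogenetic depth
#'
#' Slices the tree at `depth`, merges ranges into crossing lineages, and
#' computes the pairwise phylogenetic Simpson dissimilarity on the remaining
#' tree. At a degenerate depth (a single crossing lineage) all pairwise
#' values are defined as 0, with a warning.
#'
#' @inheritParams pairwise_pbeta_sim
#' @param depth slice depth (same unit as the branch lengths).
#' @return symmetric dissimilarity matrix over the sites of `m`.
#' @export
pbeta_at_depth <- function(tree, m, depth) {
  check_binary(m)
  unknown <- setdiff(colnames(m), tree$tip.label)
  if (length(unknown))
    stop("taxa absent from tree: ", paste(unknown, collapse = ", "))
  if (ncol(m) < length(tree$tip.label) && ncol(m) >= 2L)
    tree <- ape::keep.tip(tree, colnames(m))
  s <- slice_tree(tree, depth)
  if (s$degenerate || length(s$lineages) == 1L) {
    warning(sprintf(
      "depth %g leaves a single lineage; all dissimilarities set to 0",
      depth))
    D <- matrix(0, nrow(m), nrow(m),
                dimnames = list(rownames(m), rownames(m)))
    return(validate_dissim(D))
  }
  pairwise_pbeta_sim(s$tree, branch_site_matrix(s, m))
}

#' Depth series of phylogenetic dissimilarity matrices
#'
#' One [pbeta_at_depth()] matrix per depth, with identical site ordering
#' across depths.
#'
#' @inheritParams pbeta_at_depth
#' @param depths non-negative, duplicate-free depths; defaults to the
#'   0/5/10/20/40/60 Ma grid.
#' @return named list mapping depth to dissimilarity matrix.
#' @export
depth_series <- function(tree, m, depths = c(0, 5, 10, 20, 40, 60)) {
  if (any(depths < 0) || anyDuplicated(depths))
    stop("depths must be non-negative and duplicate-free")
  out <- lapply(depths, function(d) pbeta_at_depth(tree, m, d))
  names(out) <- as.character(depths)
  out
}
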