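# Simpson (turnover-only) beta dissimilarity, at the species level and at
# the phylogenetic level where the a/b/c components are measured as shared
# and unique branch length. These matrices are the currency passed between
# every stage of the pipeline.

#' Simpson dissimilarity components of two taxon sets
#'
#' `a` is the shared richness, `b` and `c` the richness unique to each
#' assemblage.
#'
#' @param set_a,set_b character vectors of taxon ids (non-empty).
#' @return list with components `a`, `b`, `c`.
#' @export
beta_sim_components <- function(set_a, set_b) {
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("undefined for empty assemblage")
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  a <- length(intersect(set_a, set_b))
  list(a = a, b = length(set_a) - a, c = length(set_b) - a)
}

#' Simpson turnover from a/b/c components
#'
#' `beta_sim = min(b, c) / (a + min(b, c))`: 0 whenever one assemblage is
#' nested in the other, 1 when nothing is shared. Insensitive to richness
#' differences.
#'
#' @param components list with `a`, `b`, `c` (e.g. from
#'   [beta_sim_components()] or [pbeta_sim_components()]).
#' @return dissimilarity in `[0, 1]`.
#' @export
beta_sim <- function(components) {
  a <- components$a
  mbc <- min(components$b, components$c)
  if (any(c(a, components$b, components$c) < 0))
    stop("components must be non-negative")
  if (a + mbc == 0)
    stop("beta_sim undefined: no shared and no minimal unique component ",
         "(empty assemblage)")
  mbc / (a + mbc)
}

# shared-richness (or shared-length) matrix -> Simpson turnover matrix
simpson_from_shared <- function(A, tot, ids) {
  B <- tot - A                    # tot recycles down columns: B[i,j] = tot_i - A[i,j]
  Mn <- pmin(B, t(B))
  # clamp rounding noise so identical assemblages give exactly zero
  Mn[Mn < 1e-12 * max(tot)] <- 0
  den <- A + Mn
  D <- ifelse(den > 0, Mn / den, 0)
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  validate_dissim(D)
}

#' Pairwise Simpson dissimilarity between all sites of an incidence matrix
#'
#' @param m binary site-by-taxon matrix; every row must be non-empty.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
pairwise_beta_sim <- function(m) {
  check_binary(m)
  empty <- which(rowSums(m) == 0)
  if (length(empty))
    stop("empty assemblage(s): ",
         paste(rownames(m)[empty] %||% empty, collapse = ", "))
  storage.mode(m) <- "double"
  A <- tcrossprod(m)              # shared richness
  simpson_from_shared(A, rowSums(m), rownames(m))
}

# site x edge presence matrix for a tree: an edge is present in a site iff
# at least one descendant tip of that edge occurs there. Returns the
# presence matrix and the edge lengths (postorder edge order).
edge_presence <- function(tree, m) {
  n_tip <- length(tree$tip.label)
  eo <- stats::reorder(tree, "postorder")
  cnt <- matrix(0, nrow(m), n_tip + tree$Nnode)
  cnt[, seq_len(n_tip)] <- m[, tree$tip.label, drop = FALSE]
  for (i in seq_len(nrow(eo$edge)))
    cnt[, eo$edge[i, 1L]] <- cnt[, eo$edge[i, 1L]] + cnt[, eo$edge[i, 2L]]
  P <- (cnt[, eo$edge[, 2L], drop = FALSE] > 0) * 1
  list(P = P, lengths = eo$edge.length)
}

#' Phylogenetic Simpson components of two tip sets
#'
#' For every branch of `tree`, the branch is present in an assemblage iff at
#' least one of its descendant tips is; `a` is the total branch length
#' present in both assemblages, `b` and `c` the length present in only one.
#' No branch above the root is counted.
#'
#' @param tree dated `phylo`.
#' @param tips_a,tips_b character vectors of tip labels (non-empty, all
#'   present in the tree).
#' @return list with components `a`, `b`, `c` (branch lengths).
#' @export
pbeta_sim_components <- function(tree, tips_a, tips_b) {
  if (length(tips_a) == 0L || length(tips_b) == 0L)
    stop("undefined for empty assemblage")
  unknown <- setdiff(c(tips_a, tips_b), tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  m <- matrix(0L, 2L, length(tree$tip.label),
              dimnames = list(c("A", "B"), tree$tip.label))
  m["A", unique(tips_a)] <- 1L
  m["B", unique(tips_b)] <- 1L
  ep <- edge_presence(tree, m)
  both <- ep$P[1L, ] > 0 & ep$P[2L, ] > 0
  only_a <- ep$P[1L, ] > 0 & !both
  only_b <- ep$P[2L, ] > 0 & !both
  list(a = sum(ep$lengths[both]),
       b = sum(ep$lengths[only_a]),
       c = sum(ep$lengths[only_b]))
}

#' Pairwise phylogenetic Simpson dissimilarity between all sites
#'
#' `pbeta_sim = min(b, c) / (a + min(b, c))` with components measured as
#' branch lengths (see [pbeta_sim_components()]). Tree tips absent from the
#' incidence matrix are pruned first; pruning suppresses degree-2 nodes with
#' length addition, so tip-to-tip path lengths are preserved.
#'
#' @param tree dated `phylo`; its tip labels must cover the taxa of `m`.
#' @param m binary site-by-taxon matrix; every row must be non-empty.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
pairwise_pbeta_sim <- function(tree, m) {
  check_binary(m)
  taxa <- colnames(m)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("taxa absent from tree: ", paste(unknown, collapse = ", "))
  empty <- which(rowSums(m) == 0)
  if (length(empty))
    stop("empty assemblage(s): ",
         paste(rownames(m)[empty] %||% empty, collapse = ", "))
  if (length(taxa) == 1L) {
    # a single shared lineage: all non-empty sites are identical
    D <- matrix(0, nrow(m), nrow(m),
                dimnames = list(rownames(m), rownames(m)))
    return(validate_dissim(D))
  }
  if (length(taxa) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, taxa)
  storage.mode(m) <- "double"
  ep <- edge_presence(tree, m)
  Pw <- ep$P * rep(ep$lengths, each = nrow(ep$P))
  A <- tcrossprod(Pw, ep$P)       # shared branch length
  simpson_from_shared(A, rowSums(Pw), rownames(m))
}

#' Element-wise mean of dissimilarity matrices
#'
#' Combines per-group matrices (e.g. one per taxonomic class) into a single
#' matrix by the unweighted arithmetic mean. In `"intersect"` mode the
#' matrices are first restricted to their shared entity ids (dropped ids are
#' reported); `"strict"` mode requires identical id sets.
#'
#' @param matrices list of dissimilarity matrices.
#' @param mode `"intersect"` (default) or `"strict"`.
#' @return combined dissimilarity matrix.
#' @export
combine_matrices <- function(matrices, mode = c("intersect", "strict")) {
  mode <- match.arg(mode)
  if (!length(matrices)) stop("no matrices to combine")
  matrices <- lapply(matrices, validate_dissim)
  ids <- Reduce(intersect, lapply(matrices, rownames))
  if (length(ids) == 0L) stop("empty intersection of entity ids")
  n_drop <- vapply(matrices, function(D) nrow(D) - length(ids), integer(1))
  if (mode == "strict" && any(n_drop > 0))
    stop("entity id sets differ (strict mode)")
  if (any(n_drop > 0))
    message("combine_matrices: restricted to ", length(ids),
            " shared ids (dropped ",
            paste(n_drop, collapse = "/"), " per matrix)")
  acc <- Reduce(`+`, lapply(matrices, function(D) D[ids, ids]))
  validate_dissim(acc / length(matrices))
}
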