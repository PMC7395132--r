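# End-to-end orchestration of the three analyses: present-day
# regionalization, the phylogenetic depth series, and the fossil interval
# series. Each run returns all intermediate artifacts and can optionally
# serialize them to a flat directory of CSV/Newick files.

as_group_list <- function(x, what) {
  if (inherits(x, "phylo") || is.matrix(x)) x <- list(combined = x)
  if (is.null(names(x))) names(x) <- paste0("group", seq_along(x))
  if (!length(x)) stop("no ", what, " supplied")
  x
}

write_run_outputs <- function(outdir, objects) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    path <- file.path(outdir, nm)
    if (is.matrix(obj)) write_dissim(obj, paste0(path, ".csv"))
    else if (is.data.frame(obj))
      utils::write.csv(obj, paste0(path, ".csv"), row.names = FALSE)
    else if (inherits(obj, "hclust"))
      ape::write.tree(ape::as.phylo(obj), paste0(path, ".nwk"))
  }
  invisible(outdir)
}

#' Present-day regionalization from trees and incidence matrices
#'
#' Runs the full present-day chain: per-group site filtering, per-group
#' phylogenetic Simpson matrices, mean-combination across groups
#' (intersection of surviving sites), UPGMA clustering, cut selection, NMDS
#' ordination, and, when lattice coordinates are available, boundary and
#' coherence diagnostics.
#'
#' @param trees a `phylo` or named list of per-group `phylo` trees.
#' @param incidences an incidence matrix or named list matching `trees`.
#' @param min_land,min_richness site filters (see [filter_sites()]).
#' @param k_range,ed_threshold cut selection (see [select_regions()]).
#' @param linkage_method clustering method (default `"UPGMA"`).
#' @param nmds_restarts,seed ordination control.
#' @param adjacency optional precomputed site adjacency; built by
#'   [grid_adjacency()] from `x`/`y` metadata when absent.
#' @param outdir optional output directory for CSV/Newick artifacts.
#' @return list with `per_group` (per-group matrices), `beta` (combined
#'   matrix), `dendrogram`, `assignment`, `ordination`, `coherence`,
#'   `boundaries`.
#' @export
run_present_day <- function(trees, incidences, min_land = 0.5,
                            min_richness = 5, k_range = 2:15,
                            ed_threshold = 0.9,
                            linkage_method = "UPGMA",
                            nmds_restarts = 20, seed = NULL,
                            adjacency = NULL, outdir = NULL) {
  trees <- as_group_list(trees, "trees")
  incidences <- as_group_list(incidences, "incidence matrices")
  if (length(incidences) == 1L && length(trees) > 1L)
    incidences <- stats::setNames(rep(incidences, length(trees)),
                                  names(trees))
  stopifnot(length(trees) == length(incidences))
  filtered <- lapply(incidences, filter_sites,
                     min_land = min_land, min_richness = min_richness)
  per_group <- mapply(function(tr, m) pairwise_pbeta_sim(tr, m),
                      trees, filtered, SIMPLIFY = FALSE)
  beta <- combine_matrices(per_group)
  dend <- linkage(beta, linkage_method)
  assignment <- select_regions(dend, beta, k_range = k_range,
                               ed_threshold = ed_threshold)
  ordination <- nmds(beta, restarts = nmds_restarts, seed = seed)
  coherence <- boundaries <- NULL
  meta <- attr(filtered[[1L]], "sites")
  if (is.null(adjacency) && !is.null(meta) &&
      all(c("x", "y") %in% names(meta)))
    adjacency <- grid_adjacency(meta[meta$site %in% rownames(beta), ])
  if (!is.null(adjacency)) {
    adjacency <- adjacency[adjacency[, 1L] %in% rownames(beta) &
                           adjacency[, 2L] %in% rownames(beta), ,
                           drop = FALSE]
    coherence <- geographic_coherence(assignment, adjacency)
    boundaries <- boundary_strength(assignment, beta, adjacency)
  }
  if (!is.null(outdir)) {
    write_run_outputs(outdir, list(
      beta_combined = beta,
      assignment = data.frame(site = names(assignment$labels),
                              region = assignment$labels),
      per_k_metrics = assignment$table,
      dendrogram = dend,
      ordination = data.frame(id = rownames(ordination$points),
                              ordination$points)))
  }
  list(per_group = per_group, beta = beta, dendrogram = dend,
       assignment = assignment, ordination = ordination,
       coherence = coherence, boundaries = boundaries)
}

#' Phylogenetic depth series: regionalization and trajectories over time
#'
#' Computes the combined phylogenetic Simpson matrix at each depth, cuts
#' each into regions, ordinates each slice, aligns all ordinations onto the
#' present day (depth 0) by Procrustes, and tabulates Mantel correlations
#' between the present-day matrix and every deeper slice.
#'
#' @inheritParams run_present_day
#' @param depths phylogenetic depths (default `c(0, 5, 10, 20, 40, 60)`).
#' @param mantel_perm permutations per Mantel test.
#' @return list with `matrices` (per depth), `assignments`, `ordinations`,
#'   `trajectory`, `mantel` (data frame: depth, r, p).
#' @export
run_depth_series <- function(trees, incidences,
                             depths = c(0, 5, 10, 20, 40, 60),
                             min_land = 0.5, min_richness = 5,
                             k_range = 2:15, ed_threshold = 0.9,
                             nmds_restarts = 20, mantel_perm = 999,
                             seed = NULL, outdir = NULL) {
  trees <- as_group_list(trees, "trees")
  incidences <- as_group_list(incidences, "incidence matrices")
  if (length(incidences) == 1L && length(trees) > 1L)
    incidences <- stats::setNames(rep(incidences, length(trees)),
                                  names(trees))
  filtered <- lapply(incidences, filter_sites,
                     min_land = min_land, min_richness = min_richness)
  series <- lapply(depths, function(d) {
    per_group <- mapply(function(tr, m) pbeta_at_depth(tr, m, d),
                        trees, filtered, SIMPLIFY = FALSE)
    combine_matrices(per_group)
  })
  names(series) <- as.character(depths)
  assignments <- lapply(series, function(D) {
    dend <- if (sum(D[lower.tri(D)]) > 0) linkage(D, "UPGMA") else NULL
    select_regions_safe(dend, D, k_range, ed_threshold)
  })
  ordinations <- lapply(series, function(D) {
    if (sum(D[lower.tri(D)]) == 0) return(NULL)
    nmds(D, restarts = nmds_restarts, seed = seed)
  })
  usable <- !vapply(ordinations, is.null, logical(1))
  trajectory <- NULL
  if (usable[[1L]] && sum(usable) >= 2L)
    trajectory <- procrustes_trajectory(ordinations[usable])
  ref <- series[[1L]]
  mantel <- do.call(rbind, lapply(seq_along(depths), function(i) {
    mt <- tryCatch(mantel_test(ref, series[[i]], n_perm = mantel_perm,
                               seed = seed),
                   error = function(e) NULL)
    data.frame(depth = depths[i],
               r = if (is.null(mt)) NA_real_ else mt$r,
               p = if (is.null(mt)) NA_real_ else mt$p.value)
  }))
  if (!is.null(outdir)) {
    objs <- stats::setNames(series, paste0("pbeta_depth_", names(series)))
    objs$mantel <- mantel
    if (!is.null(trajectory)) objs$trajectory <- trajectory$coordinates
    write_run_outputs(outdir, objs)
  }
  list(matrices = series, assignments = assignments,
       ordinations = ordinations, trajectory = trajectory,
       mantel = mantel)
}

# select_regions that tolerates all-zero matrices without a dendrogram
select_regions_safe <- function(dend, D, k_range, ed_threshold) {
  if (is.null(dend) || sum(D[lower.tri(D)]) == 0) {
    return(suppressWarnings(
      select_regions(linkage_dummy(D), D, k_range, ed_threshold)))
  }
  select_regions(dend, D, k_range, ed_threshold)
}

linkage_dummy <- function(D) {
  # an arbitrary dendrogram; select_regions short-circuits on all-zero D
  stats::hclust(stats::as.dist(matrix(1, nrow(D), nrow(D),
                                      dimnames = dimnames(D)) -
                               diag(nrow(D))),
                method = "average")
}

#' Fossil interval series with cleaning report
#'
#' Cleans the fossil table (deduplication, locality merging, interval
#' assignment), runs the interval-wise Simpson/UPGMA/NMDS chain, and, when
#' an extant region x taxon list is supplied, a matching present-day
#' analysis for comparison.
#'
#' @param fossils fossil records (from [read_fossils()] or a simulator).
#' @param lookup region lookup function (see [make_region_lookup()]).
#' @param intervals interval table.
#' @param extant_incidence optional binary region x taxon matrix for the
#'   present-day comparison.
#' @param tol locality bin width (degrees).
#' @param nmds_restarts,seed ordination control.
#' @param outdir optional output directory.
#' @return list with `records`, `report`, `intervals` (per-interval
#'   results) and `present` (present-day comparison or `NULL`).
#' @export
run_fossil_series <- function(fossils, lookup,
                              intervals = cenozoic_intervals(),
                              extant_incidence = NULL, tol = 0.1,
                              nmds_restarts = 10, seed = NULL,
                              outdir = NULL) {
  cleaned <- clean_fossils(fossils, intervals = intervals, tol = tol)
  series <- interval_beta_series(cleaned$records, lookup,
                                 intervals = intervals,
                                 nmds_restarts = nmds_restarts,
                                 seed = seed)
  present <- NULL
  if (!is.null(extant_incidence)) {
    beta <- pairwise_beta_sim(extant_incidence)
    present <- list(
      beta = beta,
      dendrogram = if (nrow(beta) >= 2L) linkage(beta, "UPGMA") else NULL,
      ordination = if (nrow(beta) >= 3L &&
                       sum(beta[lower.tri(beta)]) > 0)
        nmds(beta, restarts = nmds_restarts, seed = seed) else NULL)
  }
  if (!is.null(outdir)) {
    objs <- list(cleaning_report = data.frame(
      step = names(cleaned$report), count = as.integer(cleaned$report)))
    for (iv in names(series)) {
      if (is.null(series[[iv]])) next
      slug <- gsub("[^A-Za-z0-9]+", "_", iv)
      objs[[paste0("beta_", slug)]] <- series[[iv]]$beta
    }
    write_run_outputs(outdir, objs)
  }
  list(records = cleaned$records, report = cleaned$report,
       intervals = series, present = present)
}
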