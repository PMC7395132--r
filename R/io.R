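# Readers/writers for the on-disk formats (Newick trees, incidence tables,
# dissimilarity matrices, fossil occurrence tables) and the grid-cell
# filtering rules applied before any beta-diversity computation.

# Column names reserved for per-site metadata in incidence CSVs.
.meta_cols <- c("x", "y", "lon", "lat", "land_fraction")

#' Node ages of a dated tree
#'
#' Age of a node is its distance to the furthest descendant tip along the
#' calibrated branch lengths (tips have age 0). For an ultrametric tree this
#' is the usual time before present.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return numeric vector of ages indexed by ape node number
#'   (tips `1:Ntip`, then internal nodes).
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  n_tot <- length(tree$tip.label) + tree$Nnode
  ages <- numeric(n_tot)
  eo <- stats::reorder(tree, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    p <- eo$edge[i, 1L]
    ch <- eo$edge[i, 2L]
    ages[p] <- max(ages[p], ages[ch] + eo$edge.length[i])
  }
  ages
}

# tip label sets below every node, indexed by ape node number
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  sets[seq_len(n_tip)] <- as.list(tree$tip.label)
  eo <- stats::reorder(tree, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    p <- eo$edge[i, 1L]
    ch <- eo$edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Validate a dated phylogeny
#'
#' Checks the invariants assumed throughout the package: branch lengths
#' present, finite and non-negative; unique tip labels. Warns (does not fail)
#' when the tree is not ultrametric within `tol_factor` times the root age,
#' since depth slicing is calibrated for trees of extant taxa.
#'
#' @param tree a `phylo` object.
#' @param tol_factor relative ultrametricity tolerance.
#' @return the tree, invisibly usable downstream.
#' @export
validate_dated_tree <- function(tree, tol_factor = 1e-6) {
  if (!inherits(tree, "phylo"))
    stop("not a phylogenetic tree")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; a dated tree is required")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  root_age <- max(depths)
  if (root_age > 0 && diff(range(depths)) > tol_factor * root_age)
    warning(sprintf(
      "tree is not ultrametric (tip depths range %.6g to %.6g)",
      min(depths), max(depths)))
  tree
}

#' Read a dated tree from a Newick file
#'
#' Wraps [ape::read.tree()] with validation of the dated-tree invariants.
#' Quoted labels and polytomies are accepted; internal node labels are kept
#' but ignored by all computations; a root edge, if present, takes no part in
#' any beta-diversity computation.
#'
#' @param path path to a Newick file.
#' @return a validated `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) stop("failed to parse Newick in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("failed to parse Newick in '", path,
         "' (malformed or truncated input)", call. = FALSE)
  validate_dated_tree(tree)
}

# strict 0/1 check used by every consumer of incidence matrices
check_binary <- function(m, what = "incidence matrix") {
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf("%s has non-0/1 value %s at row '%s', column '%s'",
                 what, format(m[bad[1L]]),
                 rownames(m)[i[1L]] %||% i[1L],
                 colnames(m)[i[2L]] %||% i[2L]))
  }
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a binary site-by-taxon incidence table
#'
#' The first column holds the site id; the reserved columns `x`, `y`, `lon`,
#' `lat` and `land_fraction`, when present, are split off into the `sites`
#' attribute (a data frame of per-site metadata); every remaining column is a
#' taxon with strictly 0/1 values.
#'
#' @param path CSV (or TSV, see `sep`) file.
#' @param sep field separator.
#' @return binary integer matrix, sites in rows, taxa in columns, with a
#'   `sites` attribute holding the metadata data frame.
#' @export
read_incidence <- function(path, sep = ",") {
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("incidence table needs a site column and taxa")
  site <- as.character(df[[1L]])
  if (anyDuplicated(site))
    stop("duplicate site ids: ",
         paste(unique(site[duplicated(site)]), collapse = ", "))
  meta_here <- intersect(.meta_cols, names(df)[-1L])
  taxa <- setdiff(names(df)[-1L], meta_here)
  if (anyDuplicated(taxa))
    stop("duplicate taxon ids: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  m <- as.matrix(df[taxa])
  if (!is.numeric(m)) stop("incidence values must be numeric 0/1")
  storage.mode(m) <- "integer"
  rownames(m) <- site
  check_binary(m)
  meta <- data.frame(site = site, df[meta_here],
                     stringsAsFactors = FALSE, check.names = FALSE)
  attr(m, "sites") <- meta
  m
}

#' Write an incidence matrix (with site metadata) to CSV
#'
#' @param m incidence matrix as returned by [read_incidence()] or the
#'   simulators.
#' @param path output file.
#' @export
write_incidence <- function(m, path) {
  meta <- attr(m, "sites")
  out <- data.frame(site = rownames(m), stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    extra <- setdiff(names(meta), "site")
    out <- cbind(out, meta[match(rownames(m), meta$site), extra,
                           drop = FALSE])
  }
  out <- cbind(out, as.data.frame(m, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Filter grid cells by land fraction and species richness
#'
#' Removes sites whose land fraction is below `min_land` or whose richness
#' (row sum) is below `min_richness`; both thresholds are inclusive on the
#' keep side. Taxa left with no occurrences are retained as zero columns so
#' taxon sets stay aligned across groups; their count is reported via
#' `message()`.
#'
#' @param m incidence matrix with a `sites` metadata attribute.
#' @param min_land minimum land fraction (default 0.5); set to 0 to skip
#'   (then no `land_fraction` column is required).
#' @param min_richness minimum site richness (default 5).
#' @return the filtered incidence matrix (metadata subset accordingly).
#' @export
filter_sites <- function(m, min_land = 0.5, min_richness = 5) {
  check_binary(m)
  meta <- attr(m, "sites")
  if (min_land > 0) {
    if (is.null(meta) || is.null(meta$land_fraction))
      stop("min_land > 0 but no land_fraction metadata present")
    land <- meta$land_fraction[match(rownames(m), meta$site)]
  } else {
    land <- rep(1, nrow(m))
  }
  keep <- land >= min_land & rowSums(m) >= min_richness
  if (!any(keep)) stop("empty matrix after filtering")
  out <- m[keep, , drop = FALSE]
  n_empty <- sum(colSums(out) == 0)
  if (n_empty > 0)
    message(n_empty, " taxa have no occurrences after site filtering ",
            "(kept as zero columns)")
  if (!is.null(meta))
    attr(out, "sites") <- meta[match(rownames(out), meta$site), ,
                               drop = FALSE]
  out
}

#' Read a fossil occurrence table
#'
#' Expects columns `genus`, `lon`, `lat`, `min_age`, `max_age`; `family`,
#' `source`, `paleo_lon` and `paleo_lat` are optional. Rows whose genus is
#' empty or matches `indet_pattern` (by default a terminal "indet"/"indet."
#' token or any quotation mark, flagging open nomenclature) are excluded and
#' counted in the `n_indeterminate` attribute, since taxa unidentifiable at
#' the genus level carry no assemblage information.
#'
#' @param path CSV file.
#' @param indet_pattern regular expression flagging indeterminate genera.
#' @return data frame of validated records with attributes `n_raw`
#'   (rows read) and `n_indeterminate` (rows excluded).
#' @export
read_fossils <- function(path,
                         indet_pattern = "(^|[ _])indet\\.?$|[\"“”']") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("genus", "lon", "lat", "min_age", "max_age")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("fossil table missing columns: ", paste(miss, collapse = ", "))
  n_raw <- nrow(df)
  for (col in c("lon", "lat", "min_age", "max_age")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "")
      if (length(bad))
        stop(sprintf("unparsable number in column '%s', row %d: '%s'",
                     col, bad[1L], v[bad[1L]]))
      df[[col]] <- vn
    }
  }
  if (anyNA(df[c("lon", "lat", "min_age", "max_age")]))
    stop("missing coordinate or age values in fossil table")
  bad_age <- which(df$min_age > df$max_age)
  if (length(bad_age))
    stop("min_age > max_age in row(s): ",
         paste(utils::head(bad_age, 5L), collapse = ", "))
  if (any(abs(df$lat) > 90)) stop("latitude outside [-90, 90]")
  genus <- trimws(as.character(df$genus))
  indet <- is.na(genus) | genus == "" |
    grepl(indet_pattern, genus, ignore.case = TRUE)
  out <- df[!indet, , drop = FALSE]
  out$genus <- genus[!indet]
  rownames(out) <- NULL
  if (sum(indet) > 0)
    message(sum(indet), " records excluded as unidentifiable at genus level")
  attr(out, "n_raw") <- n_raw
  attr(out, "n_indeterminate") <- sum(indet)
  out
}

#' Validate a dissimilarity matrix
#'
#' Symmetric, zero-diagonal, values in `[0, 1]`, unique ids. Tiny numerical
#' violations (within `tol`) are repaired by symmetrization and clamping.
#'
#' @param D square numeric matrix.
#' @param tol numerical tolerance for symmetry/diagonal/range repairs.
#' @return the validated (repaired) matrix.
#' @export
validate_dissim <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D))
    stop("dissimilarity must be a square numeric matrix")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("e", seq_len(nrow(D)))
  }
  if (anyDuplicated(rownames(D))) stop("duplicate entity ids")
  if (!identical(rownames(D), colnames(D)))
    stop("row and column ids differ")
  if (max(abs(D - t(D))) > tol) stop("matrix is not symmetric")
  D <- (D + t(D)) / 2
  if (max(abs(diag(D))) > tol) stop("diagonal is not zero")
  diag(D) <- 0
  if (min(D) < -tol || max(D) > 1 + tol)
    stop("dissimilarities outside [0, 1]")
  D[D < 0] <- 0
  D[D > 1] <- 1
  D
}

#' Write / read a labelled square dissimilarity matrix as CSV
#'
#' @param D dissimilarity matrix.
#' @param path CSV file (header row and first column hold the entity ids).
#' @export
write_dissim <- function(D, path) {
  D <- validate_dissim(D)
  out <- data.frame(id = rownames(D), D, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissim
#' @export
read_dissim <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  rownames(m) <- ids
  validate_dissim(m)
}
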