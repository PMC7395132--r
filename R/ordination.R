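# NMDS ordination, least-squares Procrustes superimposition and
# depth-trajectories, and the Mantel permutation test.

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal-style NMDS (stress-1, monotone regression with primary treatment
#' of ties, via the [vegan::monoMDS()] engine), restarted from a classical
#' scaling configuration plus `restarts - 1` random configurations; the
#' solution with lowest stress wins. Deterministic for a fixed `seed`.
#'
#' @param D dissimilarity matrix (`n >= dims + 1` entities, not all zero).
#' @param dims embedding dimension (default 2).
#' @param restarts number of starting configurations (default 20).
#' @param max_iter iteration cap per start.
#' @param tol stress convergence tolerance.
#' @param seed integer seed for the random starts (optional).
#' @return object of class `nmds_fit`: list with `points` (centred n x dims
#'   coordinate matrix), `stress` (Kruskal stress-1), `restarts`, `seed`.
#' @export
nmds <- function(D, dims = 2, restarts = 20, max_iter = 500,
                 tol = 1e-7, seed = NULL) {
  D <- validate_dissim(D)
  n <- nrow(D)
  if (n < dims + 1) stop("need at least dims + 1 entities")
  if (sum(D[lower.tri(D)]) == 0)
    stop("degenerate all-zero dissimilarity matrix")
  if (!is.null(seed)) set.seed(seed)
  d <- stats::as.dist(D)
  init0 <- suppressWarnings(stats::cmdscale(d, k = dims))
  if (ncol(init0) < dims)
    init0 <- cbind(init0,
                   matrix(stats::rnorm(n * (dims - ncol(init0)), sd = 1e-4),
                          n))
  best <- NULL
  for (i in seq_len(max(1L, restarts))) {
    init <- if (i == 1L) init0 else
      matrix(stats::rnorm(n * dims), n, dims)
    fit <- vegan::monoMDS(d, y = init, k = dims, model = "global",
                          maxit = max_iter, smin = tol, sfgrmin = tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  dimnames(pts) <- list(rownames(D), paste0("NMDS", seq_len(dims)))
  structure(list(points = pts, stress = best$stress, dims = dims,
                 restarts = restarts, seed = seed),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS (%d-D, %d points): stress = %.5f\n",
              x$dims, nrow(x$points), x$stress))
  invisible(x)
}

coords_of <- function(x) {
  if (inherits(x, "nmds_fit")) return(x$points)
  if (is.matrix(x)) return(x)
  stop("expected an nmds_fit or a coordinate matrix")
}

#' Procrustes superimposition of one configuration onto another
#'
#' Least-squares alignment of `target` onto `reference` by translation,
#' orthogonal rotation (optionally including reflection) and optional
#' isotropic scaling. Rows are matched by id.
#'
#' @param reference,target `nmds_fit` objects or coordinate matrices with
#'   rownames; at least two shared ids are required.
#' @param allow_scaling fit an isotropic scale factor (default `TRUE`).
#' @param allow_reflection permit an improper (det = -1) rotation
#'   (default `TRUE`).
#' @return object of class `procrustes_fit`: list with `rotation`, `scale`,
#'   `translation`, `aligned` (target after alignment, in reference space),
#'   `ss` (residual sum of squares) and `residuals` (per-entity distances).
#' @export
procrustes_align <- function(reference, target, allow_scaling = TRUE,
                             allow_reflection = TRUE) {
  X <- coords_of(reference)
  Y <- coords_of(target)
  ids <- intersect(rownames(X), rownames(Y))
  if (length(ids) < 2L) stop("fewer than two shared entities")
  if (length(ids) < nrow(X) || length(ids) < nrow(Y))
    stop("mismatched entity ids between configurations")
  X <- X[ids, , drop = FALSE]
  Y <- Y[ids, , drop = FALSE]
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  C <- crossprod(Yc, Xc)
  sv <- svd(C)
  R <- sv$u %*% t(sv$v)
  d_signs <- rep(1, length(sv$d))
  if (!allow_reflection && det(R) < 0) {
    j <- which.min(sv$d)
    u2 <- sv$u
    u2[, j] <- -u2[, j]
    R <- u2 %*% t(sv$v)
    d_signs[j] <- -1
  }
  trace_d <- sum(sv$d * d_signs)
  s <- if (allow_scaling) trace_d / sum(Yc^2) else 1
  fitted <- s * Yc %*% R
  resid <- Xc - fitted
  aligned <- sweep(fitted, 2, cx, `+`)
  translation <- as.numeric(cx - s * (cy %*% R))
  structure(list(rotation = R, scale = s, translation = translation,
                 aligned = aligned, ss = sum(resid^2),
                 residuals = stats::setNames(sqrt(rowSums(resid^2)), ids)),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf(
    "Procrustes: scale = %.4f, residual SS = %.6g (det R = %+.0f)\n",
    x$scale, x$ss, det(x$rotation)))
  invisible(x)
}

#' Procrustes trajectories through a depth-ordered set of ordinations
#'
#' Aligns every ordination onto the reference (by default the first, meant
#' to be the present day / depth 0) and tabulates each entity's aligned
#' position per depth, its summary displacement from the deepest slice to
#' the reference, and optionally region-mean trajectories.
#'
#' @param ordinations named list (names = depths) of `nmds_fit` objects or
#'   coordinate matrices sharing one entity set.
#' @param reference name of the reference ordination (default: `"0"` if
#'   present, else the first).
#' @param groups optional named vector entity id -> group (e.g. region
#'   label) for group-mean trajectories.
#' @param allow_scaling passed to [procrustes_align()].
#' @return list with `coordinates` (data frame: id, depth, x, y),
#'   `displacement` (id, dx, dy, length: deepest slice to reference) and
#'   `group_means` (group, depth, x, y; `NULL` when `groups` is missing).
#' @export
procrustes_trajectory <- function(ordinations, reference = NULL,
                                  groups = NULL, allow_scaling = TRUE) {
  if (is.null(names(ordinations)))
    stop("ordinations must be a named list (names = depths)")
  if (is.null(reference))
    reference <- if ("0" %in% names(ordinations)) "0"
                 else names(ordinations)[1L]
  ref <- coords_of(ordinations[[reference]])
  ids <- rownames(ref)
  aligned <- lapply(names(ordinations), function(nm) {
    if (nm == reference) return(ref[ids, , drop = FALSE])
    procrustes_align(ref, ordinations[[nm]],
                     allow_scaling = allow_scaling)$aligned[ids, ,
                                                            drop = FALSE]
  })
  names(aligned) <- names(ordinations)
  depth_num <- suppressWarnings(as.numeric(names(ordinations)))
  coords <- do.call(rbind, lapply(names(aligned), function(nm) {
    data.frame(id = ids,
               depth = depth_num[match(nm, names(aligned))],
               x = aligned[[nm]][, 1L], y = aligned[[nm]][, 2L],
               row.names = NULL)
  }))
  deepest <- names(aligned)[which.max(depth_num)]
  disp <- aligned[[reference]] - aligned[[deepest]]
  displacement <- data.frame(id = ids, dx = disp[, 1L], dy = disp[, 2L],
                             length = sqrt(rowSums(disp^2)),
                             row.names = NULL)
  group_means <- NULL
  if (!is.null(groups)) {
    grp <- groups[coords$id]
    group_means <- stats::aggregate(coords[c("x", "y")],
                                    by = list(group = grp,
                                              depth = coords$depth),
                                    FUN = mean)
  }
  list(coordinates = coords, displacement = displacement,
       group_means = group_means)
}

# all permutations of 1..n as an n! x n matrix (small n only)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(rep(i, nrow(sub)), sub + (sub >= i))))
}

#' Mantel permutation test between two dissimilarity matrices
#'
#' Pearson correlation of the lower triangles; the null distribution is
#' generated by simultaneous row/column permutations of the second matrix.
#' The p value uses the add-one rule `p = (1 + #{r_perm >= r_obs}) /
#' (1 + n_perm)` (one-sided "greater" by default), so it is never exactly 0.
#' `exhaustive = TRUE` enumerates all non-identity permutations instead of
#' sampling (only sensible for very small matrices).
#'
#' @param D1,D2 dissimilarity matrices over the same entities (`n >= 3`).
#' @param n_perm number of random permutations (ignored when exhaustive).
#' @param seed integer seed for the permutations (optional).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param exhaustive enumerate every permutation (requires `n <= 8`).
#' @return object of class `mantel_test`: list with `r`, `p.value`,
#'   `n_perm`, `alternative`, `seed`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = NULL,
                        alternative = c("greater", "two.sided"),
                        exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  D1 <- validate_dissim(D1)
  D2 <- validate_dissim(D2)
  n <- nrow(D1)
  if (n < 3L) stop("need at least three entities")
  if (!setequal(rownames(D1), rownames(D2)))
    stop("entity ids differ between matrices")
  D2 <- D2[rownames(D1), rownames(D1)]
  lt <- lower.tri(D1)
  x <- D1[lt]
  y <- D2[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant lower triangle; correlation undefined")
  r_obs <- stats::cor(x, y)
  score <- function(r) switch(alternative,
                              greater = r >= r_obs,
                              two.sided = abs(r) >= abs(r_obs))
  if (exhaustive) {
    if (n > 8L) stop("exhaustive mode limited to n <= 8")
    perms <- all_permutations(n)
    ident <- seq_len(n)
    hits <- 0L
    n_used <- 0L
    for (i in seq_len(nrow(perms))) {
      p <- perms[i, ]
      if (identical(p, ident)) next
      n_used <- n_used + 1L
      if (score(stats::cor(x, D2[p, p][lt]))) hits <- hits + 1L
    }
    n_perm <- n_used
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    if (n_perm > 0) {
      for (i in seq_len(n_perm)) {
        p <- sample.int(n)
        if (score(stats::cor(x, D2[p, p][lt]))) hits <- hits + 1L
      }
    }
  }
  structure(list(r = r_obs, p.value = (1 + hits) / (1 + n_perm),
                 n_perm = n_perm, alternative = alternative, seed = seed),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p.value, x$alternative, x$n_perm))
  invisible(x)
}
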