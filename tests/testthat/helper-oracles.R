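# Independent oracles and fixture builders. Every oracle recomputes its
# quantity by a route disjoint from the package implementation (direct
# branch-segment enumeration on the original tree, exhaustive
# agglomeration, 1-D angle scans, exhaustive permutation enumeration).

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

random_coal_tree <- function(n_tip) {
  tr <- ape::rcoal(n_tip)
  tr$tip.label <- paste0("t", seq_len(n_tip))
  tr
}

random_incidence <- function(n_site, taxa, p = 0.5) {
  m <- matrix(rbinom(n_site * length(taxa), 1L, p), n_site,
              dimnames = list(paste0("s", seq_len(n_site)), taxa))
  for (i in seq_len(n_site))
    if (sum(m[i, ]) == 0) m[i, sample(length(taxa), 1L)] <- 1L
  storage.mode(m) <- "integer"
  m
}

random_dissim <- function(n, ids = paste0("e", seq_len(n))) {
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[lower.tri(D)] <- runif(n * (n - 1) / 2)
  D + t(D)
}

# --- phylogenetic Simpson oracle: direct branch-segment enumeration -----
# Works on the original (unsliced) tree: each edge contributes the part of
# its length older than `depth`; presence via phangorn::Descendants.
oracle_pbeta_matrix <- function(tree, m, depth = 0) {
  n_tip <- length(tree$tip.label)
  nd <- ape::node.depth.edgelength(tree)       # distance from root
  root_age <- max(nd[seq_len(n_tip)])
  parent_age <- root_age - nd[tree$edge[, 1L]]
  seg <- pmax(0, pmin(tree$edge.length, parent_age - depth))
  desc <- phangorn::Descendants(tree, tree$edge[, 2L], "tips")
  pres <- vapply(seq_len(nrow(tree$edge)), function(e) {
    tips <- tree$tip.label[desc[[e]]]
    as.numeric(rowSums(m[, tips, drop = FALSE]) > 0)
  }, numeric(nrow(m)))
  pres <- matrix(pres, nrow = nrow(m))
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- pres[i, ] > 0 & pres[j, ] > 0
    a <- sum(seg[both])
    b <- sum(seg[pres[i, ] > 0 & !both])
    cc <- sum(seg[pres[j, ] > 0 & !both])
    mbc <- min(b, cc)
    D[i, j] <- D[j, i] <- if (a + mbc > 0) mbc / (a + mbc) else 0
  }
  D
}

# --- UPGMA oracle: exhaustive agglomeration, cophenetic output ----------
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- seq_len(n)
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  cl_dist <- function(a, b) mean(D[clusters[[a]], clusters[[b]]])
  while (length(active) > 1L) {
    best <- NULL
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      d <- cl_dist(active[ii], active[jj])
      if (is.null(best) || d < best$d)
        best <- list(d = d, i = active[ii], j = active[jj])
    }
    mi <- clusters[[best$i]]
    mj <- clusters[[best$j]]
    coph[mi, mj] <- best$d
    coph[mj, mi] <- best$d
    clusters[[best$i]] <- c(mi, mj)
    active <- setdiff(active, best$j)
  }
  coph
}

# --- Procrustes oracle: scan over rotation angle (2-D only) -------------
oracle_procrustes_ss <- function(X, Y, allow_scaling = TRUE,
                                 allow_reflection = TRUE) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  ss_at <- function(theta, reflect) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    if (reflect) R <- R %*% diag(c(1, -1))
    tr <- sum(Xc * (Yc %*% R))
    if (allow_scaling) {
      s <- max(tr, 0) / sum(Yc^2)
      sum(Xc^2) - 2 * s * tr + s^2 * sum(Yc^2)
    } else {
      sum(Xc^2) + sum(Yc^2) - 2 * tr
    }
  }
  reflect_opts <- if (allow_reflection) c(FALSE, TRUE) else FALSE
  best <- Inf
  for (refl in reflect_opts) {
    coarse <- seq(-pi, pi, length.out = 721)
    vals <- vapply(coarse, ss_at, numeric(1), reflect = refl)
    k <- which.min(vals)
    lo <- coarse[max(1, k - 1)]
    hi <- coarse[min(length(coarse), k + 1)]
    opt <- optimize(ss_at, c(lo, hi), reflect = refl, tol = 1e-12)
    best <- min(best, opt$objective)
  }
  best
}

# --- exhaustive permutation enumeration (independent recursion) ---------
oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p + (p >= n) * 0L, n, after = pos - 1L)
    }
  }
  out
}

oracle_mantel_p <- function(D1, D2, alternative = "greater") {
  lt <- lower.tri(D1)
  x <- D1[lt]
  r_obs <- cor(x, D2[lt])
  n <- nrow(D1)
  hits <- 0L
  total <- 0L
  for (p in oracle_perms(n)) {
    if (identical(p, seq_len(n))) next
    total <- total + 1L
    r <- cor(x, D2[p, p][lt])
    ok <- if (alternative == "greater") r >= r_obs else abs(r) >= abs(r_obs)
    if (ok) hits <- hits + 1L
  }
  (1 + hits) / (1 + total)
}

# region count selected for a matrix, tolerating the all-zero degenerate case
select_regions_at <- function(D) {
  if (sum(D[lower.tri(D)]) == 0) return(1L)
  suppressWarnings(select_regions(linkage(D, "UPGMA"), D)$k)
}

# criterion-9 style planted scenario, small enough for unit tests
small_scenario <- function(seed, K = 4, grid = c(8, 8),
                           species_per_region = 8) {
  region_scenario(K = K, grid = grid,
                  species_per_region = species_per_region, seed = seed)
}

write_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
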