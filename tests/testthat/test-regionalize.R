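test_that("UPGMA linkage follows hand agglomeration on the 3-point toy", {
  D <- matrix(c(0, .1, .9,
                .1, 0, .9,
                .9, .9, 0), 3, 3,
              dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
  hc <- linkage(D, "UPGMA")
  expect_equal(hc$height, c(0.1, 0.9))
  first <- sort(abs(hc$merge[1, ]))
  expect_equal(first, c(1, 2))

  # n = 2: single merge at D12 for every method
  D2 <- matrix(c(0, .42, .42, 0), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  for (mt in c("single", "complete", "UPGMA", "WPGMA", "UPGMC",
               "WPGMC", "ward1", "ward2")) {
    hc2 <- linkage(D2, mt)
    expect_equal(length(hc2$height), 1L)
  }
  expect_equal(linkage(D2, "UPGMA")$height, 0.42)
  expect_error(linkage(matrix(c(0, 1, 2, 0), 2,
                              dimnames = list(c("a","b"), c("a","b")))),
               "symmetric")
})

test_that("UPGMA equals the exhaustive agglomeration oracle", {
  set.seed(61)
  for (rep in 1:10) {
    D <- random_dissim(sample(4:8, 1))
    hc <- linkage(D, "UPGMA")
    coph <- as.matrix(cophenetic(hc))[rownames(D), rownames(D)]
    expect_equal(unname(coph), unname(oracle_upgma_cophenetic(D)),
                 tolerance = 1e-12)
  }
})

test_that("UPGMA cophenetic distances are ultrametric", {
  set.seed(62)
  D <- random_dissim(10)
  coph <- as.matrix(cophenetic(linkage(D, "UPGMA")))
  n <- nrow(coph)
  worst <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    worst <- max(worst, coph[i, j] - max(coph[i, k], coph[k, j]))
  expect_lt(worst, 1e-12)
})

test_that("cophenetic correlation is 1 for faithfully representable input", {
  # an ultrametric matrix is reproduced exactly by UPGMA
  set.seed(63)
  tr <- random_coal_tree(8)
  U <- as.matrix(cophenetic(tr))
  U <- U / max(U)
  expect_equal(cophenetic_correlation(linkage(U, "UPGMA"), U), 1)

  D <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(cophenetic_correlation(linkage(D, "UPGMA"), D), 1)

  Dc <- matrix(0.5, 3, 3, dimnames = dimnames(D))
  diag(Dc) <- 0
  expect_error(cophenetic_correlation(linkage(Dc, "UPGMA"), Dc),
               "undefined")
})

test_that("signed-rank test reproduces the exact null and conventions", {
  # six all-positive differences: two-sided exact p = 2 / 2^6
  x <- c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6)
  y <- rep(1, 6)
  res <- wilcoxon_signed_rank(x, y)
  expect_true(res$exact)
  expect_equal(res$p.value, 0.03125)

  # agrees with the reference implementation when zero/tie free
  set.seed(64)
  for (rep in 1:5) {
    a <- rnorm(12)
    b <- rnorm(12)
    expect_equal(wilcoxon_signed_rank(a, b)$p.value,
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
  }

  expect_warning(res0 <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(res0$p.value, 1)
})

test_that("linkage comparison scores methods and runs all pairwise tests", {
  set.seed(65)
  mats <- replicate(6, random_dissim(9), simplify = FALSE)
  cmp <- compare_linkage_methods(mats)
  expect_equal(dim(cmp$cophenetic), c(8L, 6L))
  expect_equal(sum(!is.na(cmp$p_values)) / 2, choose(8, 2))
  expect_true(cmp$best %in% rownames(cmp$cophenetic))
  expect_true(all(cmp$cophenetic >= -1 & cmp$cophenetic <= 1))
  expect_error(compare_linkage_methods(mats[1]), "at least two")
})

test_that("explained dissimilarity spans 0 (lumped) to 1 (all singletons)", {
  D <- random_dissim(6)
  expect_equal(explained_dissimilarity(D, rep(1, 6)), 0)
  expect_equal(explained_dissimilarity(D, 1:6), 1)

  # planted-pairs toy: within .1, between .9
  ids <- c("a1", "a2", "b1", "b2")
  P <- matrix(.9, 4, 4, dimnames = list(ids, ids))
  P[1, 2] <- P[2, 1] <- P[3, 4] <- P[4, 3] <- .1
  diag(P) <- 0
  expect_equal(explained_dissimilarity(P, c(1, 1, 2, 2)), 3.6 / 3.8)

  Z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(explained_dissimilarity(Z, c(1, 2, 3)), "all-zero")
})

test_that("mean silhouette follows the (b - a)/max(a, b) formula", {
  ids <- c("a1", "a2", "b1", "b2")
  P <- matrix(.9, 4, 4, dimnames = list(ids, ids))
  P[1, 2] <- P[2, 1] <- P[3, 4] <- P[4, 3] <- .1
  diag(P) <- 0
  expect_equal(mean_silhouette(P, c(1, 1, 2, 2)), (0.9 - 0.1) / 0.9,
               tolerance = 1e-12)

  # all inter-point distances equal: a = b so s = 0
  E <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  diag(E) <- 0
  expect_equal(mean_silhouette(E, c(1, 1, 2, 2)), 0)

  # singleton cluster contributes s = 0
  sil3 <- mean_silhouette(P, c(1, 1, 2, 3))
  expect_equal(sil3, mean(c((0.9 - 0.1) / 0.9, (0.9 - 0.1) / 0.9, 0, 0)),
               tolerance = 1e-12)
  expect_error(mean_silhouette(P, rep(1, 4)), "silhouette requires")
})

test_that("region selection finds planted cuts and reports the k table", {
  ids <- c("a1", "a2", "b1", "b2", "c")
  D <- matrix(1, 5, 5, dimnames = list(ids, ids))
  D[1, 2] <- D[2, 1] <- D[3, 4] <- D[4, 3] <- 0
  diag(D) <- 0
  asg <- select_regions(linkage(D, "UPGMA"), D, k_range = 2:4)
  expect_equal(asg$k, 3L)
  expect_equal(asg$explained_dissimilarity, 1)
  expect_s3_class(asg, "region_assignment")
  expect_equal(nrow(asg$table), 3L)

  # ED is non-decreasing along the cuts of one dendrogram
  set.seed(66)
  for (rep in 1:5) {
    Dr <- random_dissim(12)
    tab <- suppressWarnings(
      select_regions(linkage(Dr, "UPGMA"), Dr, k_range = 2:10)$table)
    expect_true(all(diff(tab$explained_dissimilarity) >= -1e-12))
    expect_true(all(tab$explained_dissimilarity >= 0 &
                    tab$explained_dissimilarity <= 1))
    expect_true(all(tab$mean_silhouette >= -1 & tab$mean_silhouette <= 1,
                    na.rm = TRUE))
  }

  # all-zero matrix collapses to a single region
  Z <- matrix(0, 4, 4, dimnames = list(ids[1:4], ids[1:4]))
  O <- matrix(1, 4, 4, dimnames = dimnames(Z))
  diag(O) <- 0
  expect_warning(a0 <- select_regions(linkage(O, "UPGMA"), Z),
                 "single region")
  expect_equal(a0$k, 1L)
})

test_that("dendrogram cuts refine as k grows", {
  set.seed(67)
  D <- random_dissim(10)
  hc <- linkage(D, "UPGMA")
  for (k in 2:8) {
    a <- cutree(hc, k)
    b <- cutree(hc, k + 1)
    # refinement: entities sharing a cluster at k+1 share one at k
    expect_true(all(tapply(a, b, function(v) length(unique(v))) == 1))
  }
})

test_that("boundary strength averages dissimilarity over adjacent cross pairs", {
  coords <- expand.grid(x = 1:4, y = 1:2)
  coords$site <- paste0("c", coords$x, "_", coords$y)
  adj <- grid_adjacency(coords)
  labels <- setNames(ifelse(coords$x <= 2, "L", "R"), coords$site)
  ids <- coords$site
  D <- matrix(0.9, 8, 8, dimnames = list(ids, ids))
  within <- outer(labels[ids], labels[ids], `==`)
  D[within] <- 0.1
  diag(D) <- 0
  bs <- boundary_strength(labels, D, adj)
  expect_equal(nrow(bs), 1L)
  expect_equal(bs$mean_dissimilarity, 0.9)
  expect_equal(bs$n_pairs, 2L)   # two rook contacts across the x=2|3 line

  # non-adjacent regions are absent
  labels2 <- setNames(c("A", "B", "C", "C", "A", "B", "C", "C"),
                      ids)
  bs2 <- boundary_strength(labels2, D, adj)
  expect_false(any(bs2$region_a == "A" & bs2$region_b == "B" &
                   bs2$n_pairs == 0))
})

test_that("geographic coherence flags fragmented regions", {
  coords <- expand.grid(x = 1:5, y = 1:2)
  coords$site <- paste0("c", coords$x, "_", coords$y)
  adj <- grid_adjacency(coords)
  # region X: columns 1-2 plus a detached cell at x=5,y=1 (7 + 3 split)
  labels <- setNames(rep("Y", 10), coords$site)
  labels[coords$x <= 3 & !(coords$x == 3 & coords$y == 2)] <- "X"
  gc <- geographic_coherence(labels, adj)
  expect_true(all(gc$largest_component_fraction <= 1))
  x_row <- gc[gc$region == "X", ]
  expect_equal(x_row$largest_component_fraction, 1)

  labels2 <- labels
  labels2[c("c1_1", "c1_2")] <- "Y"
  labels2[c("c5_1", "c5_2")] <- "X"
  gc2 <- geographic_coherence(labels2, adj)
  x2 <- gc2[gc2$region == "X", ]
  expect_lt(x2$largest_component_fraction, 1)
  expect_false(x2$coherent)

  # singleton region is trivially coherent
  labels3 <- labels
  labels3["c5_2"] <- "Z"
  gc3 <- geographic_coherence(labels3, adj)
  expect_equal(gc3[gc3$region == "Z", "largest_component_fraction"], 1)
})
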