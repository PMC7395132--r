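planted_config <- function(n = 20, seed = 71) {
  set.seed(seed)
  X <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(paste0("p", seq_len(n)), NULL))
  X
}

dist_matrix <- function(X, trans = identity) {
  D <- trans(as.matrix(dist(X)))
  D <- D / max(D)
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

test_that("NMDS recovers embeddable configurations with near-zero stress", {
  X <- planted_config()
  fit <- nmds(dist_matrix(X), restarts = 20, seed = 1)
  expect_lte(fit$stress, 0.01)
  # rank-invariance: a monotone transform of the distances embeds equally
  fit_sqrt <- nmds(dist_matrix(X, sqrt), restarts = 20, seed = 1)
  expect_lte(fit_sqrt$stress, 0.01)
  # centred output
  expect_equal(colMeans(fit$points), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)
})

test_that("NMDS is deterministic for a fixed seed and validates input", {
  X <- planted_config(10, seed = 72)
  D <- dist_matrix(X)
  f1 <- nmds(D, restarts = 5, seed = 99)
  f2 <- nmds(D, restarts = 5, seed = 99)
  expect_identical(f1$points, f2$points)

  # equilateral simplex at n = dims + 1 embeds exactly
  S <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(S) <- 0
  expect_lte(nmds(S, restarts = 5, seed = 1)$stress, 0.01)

  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(nmds(Z), "all-zero")
})

test_that("Procrustes recovers similarity transforms exactly", {
  X <- planted_config(12, seed = 73)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  Y <- 1.7 * X %*% R + matrix(c(3, -2), 12, 2, byrow = TRUE)
  rownames(Y) <- rownames(X)
  fit <- procrustes_align(X, Y)
  expect_lt(fit$ss, 1e-10)
  expect_equal(fit$aligned, X, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(crossprod(fit$rotation), diag(2), tolerance = 1e-10)

  # reflected copy: perfect with reflection, imperfect without
  Yr <- X %*% diag(c(1, -1))
  rownames(Yr) <- rownames(X)
  expect_lt(procrustes_align(X, Yr)$ss, 1e-10)
  fit_norefl <- procrustes_align(X, Yr, allow_reflection = FALSE)
  expect_gt(fit_norefl$ss, 1e-6)
  expect_gt(det(fit_norefl$rotation), 0)
})

test_that("Procrustes residual matches the angle-scan oracle", {
  set.seed(74)
  for (rep in 1:5) {
    X <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("p", 1:8), NULL))
    Y <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("p", 1:8), NULL))
    for (scaling in c(TRUE, FALSE)) {
      got <- procrustes_align(X, Y, allow_scaling = scaling)$ss
      expect_equal(got, oracle_procrustes_ss(X, Y, allow_scaling = scaling),
                   tolerance = 1e-6)
    }
  }
})

test_that("Procrustes agrees with the vegan reference on residual SS", {
  set.seed(75)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("p", 1:10), NULL))
  Y <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("p", 1:10), NULL))
  got <- procrustes_align(X, Y, allow_scaling = TRUE)
  ref <- vegan::procrustes(X, Y, scale = TRUE, symmetric = FALSE)
  expect_equal(got$ss, ref$ss, tolerance = 1e-10)
})

test_that("trajectories collapse to zero arrows under rigid motions", {
  X <- planted_config(9, seed = 76)
  ords <- list("0" = X, "20" = X, "40" = X)
  tr <- procrustes_trajectory(ords)
  expect_true(all(tr$displacement$length < 1e-10))

  rot <- function(theta) matrix(c(cos(theta), sin(theta),
                                  -sin(theta), cos(theta)), 2)
  ords2 <- list("0" = X, "20" = X %*% rot(1.1), "40" = X %*% rot(-0.4))
  for (nm in names(ords2)) rownames(ords2[[nm]]) <- rownames(X)
  tr2 <- procrustes_trajectory(ords2)
  expect_true(all(tr2$displacement$length < 1e-8))

  # planted drift: a small group shifted in the deep slice shows the
  # longest arrows (alignment spreads some of the shift over the rest)
  set.seed(761)
  Xl <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("q", 1:30), NULL))
  grp <- setNames(rep(c("g1", "g2", "g3"), times = c(5, 13, 12)),
                  rownames(Xl))
  Xdeep <- Xl
  Xdeep[grp == "g1", 1] <- Xdeep[grp == "g1", 1] + 3
  tr3 <- procrustes_trajectory(list("0" = Xl, "40" = Xdeep), groups = grp)
  d1 <- mean(tr3$displacement$length[grp[tr3$displacement$id] == "g1"])
  d23 <- mean(tr3$displacement$length[grp[tr3$displacement$id] != "g1"])
  expect_gt(d1, d23)
  expect_equal(nrow(tr3$group_means), 3 * 2)
})

test_that("Mantel statistic and permutation p behave as specified", {
  set.seed(77)
  D <- random_dissim(8)
  self <- mantel_test(D, D, n_perm = 99, seed = 1)
  expect_equal(self$r, 1)
  expect_gt(self$p.value, 0)

  D2 <- random_dissim(8)
  expect_equal(mantel_test(D, D2, n_perm = 0)$r,
               mantel_test(D2, D, n_perm = 0)$r)

  # p can never be exactly zero under the add-one rule
  mt <- mantel_test(D, D, n_perm = 999, seed = 2)
  expect_gte(mt$p.value, 1 / 1000)

  expect_error(mantel_test(D, random_dissim(8, paste0("x", 1:8))),
               "ids differ")
  Dc <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(Dc) <- 0
  expect_error(mantel_test(Dc, random_dissim(4, letters[1:4])),
               "constant")
})

test_that("exhaustive Mantel enumeration matches the oracle", {
  set.seed(78)
  for (rep in 1:3) {
    D1 <- random_dissim(4)
    D2 <- random_dissim(4)
    mt <- mantel_test(D1, D2, exhaustive = TRUE)
    expect_equal(mt$n_perm, factorial(4) - 1)
    expect_equal(mt$p.value, oracle_mantel_p(D1, D2))
  }
})

test_that("Mantel r agrees with the vegan reference", {
  set.seed(79)
  D1 <- random_dissim(10)
  D2 <- random_dissim(10)
  got <- mantel_test(D1, D2, n_perm = 99, seed = 3)
  ref <- vegan::mantel(as.dist(D1), as.dist(D2), permutations = 99)
  expect_equal(got$r, ref$statistic, ignore_attr = TRUE)
})
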