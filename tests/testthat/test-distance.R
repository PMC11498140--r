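test_that("distance formulas match hand-evaluated values", {
  expect_equal(bray_curtis(c(2, 1, 0), c(0, 1, 3)), 5 / 7)
  expect_equal(bray_curtis(c(3, 2), c(3, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")

  expect_equal(sorensen(c(5, 9, 1, 0), c(0, 2, 3, 7)), 1 / 3)  # a=2,b=1,c=1
  expect_equal(sorensen(c(1, 2), c(9, 1)), 0)
  expect_equal(sorensen(c(1, 0), c(0, 1)), 1)

  expect_equal(hellinger_distance(c(4, 4), c(4, 4)), 0)
  expect_equal(hellinger_distance(c(1, 0), c(0, 3)), sqrt(2))
  expect_equal(hellinger_distance(c(1, 1), c(1, 0)),
               sqrt((sqrt(0.5) - 1)^2 + 0.5), tolerance = 1e-12)
  expect_error(hellinger_distance(c(0, 0), c(1, 1)), "all-zero|zero-sum")
})

test_that("sorensen is bray-curtis on presence vectors; ranges hold (property)", {
  set.seed(101)
  for (i in 1:200) {
    x <- rpois(20, 1); y <- rpois(20, 1)
    if (sum(x) == 0 || sum(y) == 0) next
    a <- sum(x > 0 & y > 0); b <- sum(x > 0 & y == 0); c_ <- sum(x == 0 & y > 0)
    expect_identical(sorensen(x, y), (b + c_) / (2 * a + b + c_))
    expect_true(bray_curtis(x, y) >= 0 && bray_curtis(x, y) <= 1)
    expect_true(hellinger_distance(x, y) <= sqrt(2) + 1e-12)
    expect_equal(bray_curtis(x, y), bray_curtis(y, x))
  }
})

test_that("distance_matrix agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  tab <- rand_table(12, 40, seed = 5)
  m <- unclass(tab); storage.mode(m) <- "double"
  expect_equal(as.vector(unclass(distance_matrix(tab, "bray"))),
               as.vector(as.matrix(vegan::vegdist(m, "bray"))),
               tolerance = 1e-12)
  expect_equal(as.vector(unclass(distance_matrix(tab, "sorensen"))),
               as.vector(as.matrix(vegan::vegdist((m > 0) * 1, "bray"))),
               tolerance = 1e-12)
  expect_equal(as.vector(unclass(distance_matrix(tab, "hellinger"))),
               as.vector(as.matrix(stats::dist(vegan::decostand(m, "hellinger")))),
               tolerance = 1e-10)
})

test_that("pcoa reproduces Euclidean configurations", {
  # points on a line at 0, 3, 4
  pts <- matrix(c(0, 3, 4), 3, 1)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  tol <- 1e-9 * max(abs(ord$eigenvalues))
  expect_identical(sum(ord$eigenvalues > tol), 1L)
  expect_equal(as.matrix(dist(ord$coordinates)), d, tolerance = 1e-8,
               ignore_attr = TRUE)

  # 10 random points in 3-D: 3 positive eigenvalues, distances reproduced
  set.seed(8)
  pts <- matrix(rnorm(30), 10, 3)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  tol <- 1e-9 * max(abs(ord$eigenvalues))
  expect_identical(sum(ord$eigenvalues > tol), 3L)
  expect_equal(as.matrix(dist(ord$coordinates)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(ord$proportion_explained), 1)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))

  # equilateral triangle: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  ord3 <- pcoa(d3)
  ev <- ord3$eigenvalues[ord3$eigenvalues > 1e-9]
  expect_length(ev, 2)
  expect_equal(ev[1], ev[2])

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("pcoa agrees with the cmdscale oracle on a non-Euclidean matrix", {
  tab <- rand_table(9, 30, seed = 13)
  d <- unclass(distance_matrix(tab, "bray"))
  ord <- pcoa(d)
  ref <- stats::cmdscale(d, k = 4, eig = TRUE)
  expect_equal(abs(ord$coordinates[, 1:4]), abs(ref$points), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(ord$eigenvalues[1:4], ref$eig[1:4], tolerance = 1e-8)
})

test_that("permanova matches an independent brute-force SS computation", {
  # independent implementation: loops over all pairs, textbook formulas
  brute_f <- function(d, groups) {
    n <- nrow(d); g <- unique(groups)
    sst <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
    sst <- sst / n
    ssw <- 0
    for (gr in g) {
      idx <- which(groups == gr)
      s <- 0
      for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]^2
      ssw <- ssw + s / length(idx)
    }
    ((sst - ssw) / (length(g) - 1)) / (ssw / (n - length(g)))
  }
  set.seed(31)
  for (rep in 1:5) {
    pts <- rbind(matrix(rnorm(8, 0), 4, 2), matrix(rnorm(8, 3), 4, 2))
    d <- as.matrix(dist(pts))
    groups <- rep(c("a", "b"), each = 4)
    res <- permanova(d, groups, n_perm = 199, seed = rep)
    expect_equal(res$statistic, brute_f(d, groups), tolerance = 1e-10)
    # minimum attainable p with the +1 convention
    expect_gte(res$permutation_p, 1 / 200)
  }
})

test_that("permanova agrees with the vegan adonis2 oracle", {
  skip_if_not_installed("vegan")
  tab <- rand_table(14, 30, seed = 4)
  d <- unclass(distance_matrix(tab, "bray"))
  groups <- rep(c("a", "b"), 7)
  res <- permanova(d, groups, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ groups, permutations = 99)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(res$r2, ref$R2[1], tolerance = 1e-10)
})

test_that("permanova is invariant to relabeling and reordering; degenerate F=0", {
  tab <- rand_table(10, 25, seed = 6)
  d <- unclass(distance_matrix(tab, "bray"))
  groups <- rep(c("a", "b"), 5)
  f1 <- permanova(d, groups, n_perm = 9, seed = 1)$statistic
  f2 <- permanova(d, ifelse(groups == "a", "zebra", "yak"),
                  n_perm = 9, seed = 1)$statistic
  expect_equal(f1, f2)
  ord <- sample(10)
  f3 <- permanova(d[ord, ord], groups[ord], n_perm = 9, seed = 1)$statistic
  expect_equal(f1, f3, tolerance = 1e-12)

  d0 <- matrix(0, 6, 6)
  expect_equal(permanova(d0, rep(c("a", "b"), 3), n_perm = 9, seed = 1)$statistic, 0)

  expect_error(permanova(d, c("a", rep("b", 9)), n_perm = 9), "singleton")
  expect_error(permanova(d, rep("a", 10), n_perm = 9), "2 groups")
})

test_that("pairwise contrasts count and adjust correctly", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(12, 0), 6, 2), matrix(rnorm(12, 2), 6, 2),
               matrix(rnorm(12, 5), 6, 2))
  d <- as.matrix(dist(pts))
  groups <- rep(c("a", "b", "c"), each = 6)
  res <- pairwise_permanova(d, groups, n_perm = 49, seed = 1)
  expect_identical(nrow(res), 3L)
  res_none <- pairwise_permanova(d, groups, n_perm = 49, seed = 1,
                                 adjust = "none")
  expect_equal(res_none$p, res_none$p_adjusted)
  expect_equal(res$p, res_none$p)
  # bonferroni closed form
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  res_bf <- pairwise_permanova(d, groups, n_perm = 49, seed = 1,
                               adjust = "bonferroni")
  expect_equal(res_bf$p_adjusted, pmin(1, res_bf$p * 3))
})

test_that("spatial_median minimizes the summed distances (optimizer oracle)", {
  set.seed(17)
  for (rep in 1:5) {
    x <- matrix(rnorm(24), 12, 2)
    m <- spatial_median(x)
    obj <- function(p) sum(sqrt(rowSums(sweep(x, 2, p)^2)))
    ref <- stats::optim(colMeans(x), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))$par
    expect_equal(m, ref, tolerance = 1e-4, ignore_attr = TRUE)
  }
  # collapses to the common point for identical rows
  expect_equal(spatial_median(matrix(2, 5, 3)), rep(2, 3), ignore_attr = TRUE)
})

test_that("permdisp reproduces the hand-computed 1-D ANOVA", {
  pts <- c(0, 0, 10, 10, 5, 5, 5, 5)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:8], letters[1:8])
  groups <- rep(c("g1", "g2"), each = 4)
  res <- permdisp(d, groups, n_perm = 99, seed = 1)
  # medians at 5 and 5: distances {5,5,5,5} and {0,0,0,0}
  expect_equal(unname(res$distances), c(5, 5, 5, 5, 0, 0, 0, 0),
               tolerance = 1e-6)
  expect_equal(unname(res$group_means), c(5, 0), tolerance = 1e-6)
  # within-group SS is 0 -> F is infinite (hand ANOVA: MSG=50, MSR=0)
  expect_true(res$anova_f > 1e10 || is.infinite(res$anova_f))
})

test_that("mirror-symmetric groups show no dispersion difference", {
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(0.5, 0.5))
  pts <- rbind(base, sweep(base, 2, c(20, 0), "+"))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("p", 1:10), paste0("p", 1:10))
  res <- permdisp(d, rep(c("a", "b"), each = 5), n_perm = 99, seed = 2)
  expect_lt(res$anova_f, 1e-10)
  expect_gt(res$anova_p, 0.99)
})

test_that("permdisp centroid mode and input validation behave", {
  tab <- rand_table(12, 30, seed = 3)
  d <- unclass(distance_matrix(tab, "bray"))
  groups <- rep(c("a", "b"), 6)
  res_med <- permdisp(d, groups, n_perm = 29, seed = 1)
  res_cen <- permdisp(d, groups, n_perm = 29, seed = 1, type = "centroid")
  expect_false(isTRUE(all.equal(res_med$distances, res_cen$distances)))
  expect_identical(res_med$anova_df, c(1, 10))
  expect_error(permdisp(d, c("a", rep("b", 11)), n_perm = 9), "singleton")
})
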