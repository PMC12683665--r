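test_that("PCA variance shares behave on symmetric and degenerate inputs", {
  set.seed(2)
  iso <- matrix(rnorm(400), ncol = 2)
  p <- pca_sti(iso, scale = TRUE)
  expect_equal(sum(p$var_explained), 1)
  expect_equal(p$var_explained, c(0.5, 0.5), tolerance = 0.1)

  v <- rnorm(20)
  rank1 <- cbind(a = v, b = 2 * v, c = -v)
  p1 <- pca_sti(rank1)
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-9)

  const <- cbind(a = rnorm(10), b = rep(3, 10))
  expect_error(pca_sti(const), "b")
})

test_that("PCA reconstructs the standardized matrix and fixes signs", {
  set.seed(3)
  x <- matrix(rnorm(60), ncol = 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  p <- pca_sti(x)
  scores <- as.matrix(p$scores[, -1])
  load <- as.matrix(p$loadings[, -1])
  z <- scale(x)
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  expect_equal(unname(scores %*% t(load)), unname(z), tolerance = 1e-10)
  # orthonormal loadings; largest loading per component positive
  expect_equal(unname(t(load) %*% load), diag(4), tolerance = 1e-10)
  for (j in seq_len(ncol(load))) {
    expect_gt(load[which.max(abs(load[, j])), j], 0)
  }
})

test_that("well-separated blobs are perfectly recovered by hkmeans", {
  set.seed(10)
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5))
  truth <- rep(1:3, times = c(12, 8, 5))
  x <- centers[truth, ] + matrix(rnorm(2 * length(truth), sd = 0.1), ncol = 2)
  colnames(x) <- c("f1", "f2")
  hk <- hkmeans(x, k = 3, seed = 1)
  expect_equal(rand_index(tidy(hk)$cluster, truth), 1)
  # labels are renumbered by decreasing size
  expect_equal(as.integer(table(tidy(hk)$cluster)), c(12, 8, 5))
})

test_that("k-means refinement never worsens the hierarchical cut", {
  set.seed(12)
  for (i in 1:10) {
    x <- matrix(rnorm(40 * 3), ncol = 3,
                dimnames = list(NULL, paste0("f", 1:3)))
    hk <- hkmeans(x, k = 4, seed = i)
    expect_lte(hk$tot_withinss, hk$hclust_withinss + 1e-9)
  }
})

test_that("hkmeans is deterministic and validates its inputs", {
  set.seed(20)
  x <- matrix(rnorm(30), ncol = 3, dimnames = list(NULL, paste0("f", 1:3)))
  a <- hkmeans(x, k = 3, seed = 7)
  b <- hkmeans(x, k = 3, seed = 7)
  expect_identical(tidy(a)$cluster, tidy(b)$cluster)
  expect_error(hkmeans(x[1:3, ], k = 3), "more rows")
  expect_error(hkmeans(x, k = 1), ">= 2")
})

test_that("hkmeans attains the exhaustively enumerated optimum on a clustered instance", {
  set.seed(33)
  # 8 points in general position around three separated centers; the Ward
  # initialization is a heuristic, so global optimality is only expected
  # when the objective has a clear basin
  centers <- rbind(c(0, 0), c(3, 0), c(0, 3))
  x <- centers[c(1, 1, 1, 2, 2, 2, 3, 3), ] +
    matrix(rnorm(16, sd = 0.5), ncol = 2)
  colnames(x) <- c("f1", "f2")
  z <- scale(x)
  # brute force over all assignments of 8 points to 3 labels
  best <- Inf
  grid <- expand.grid(rep(list(1:3), 8))
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < 3) next
    wss <- sum(sapply(unique(lab), function(g) {
      sub <- z[lab == g, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub), "-")^2)
    }))
    best <- min(best, wss)
  }
  hk <- hkmeans(x, k = 3, seed = 2)
  expect_equal(hk$tot_withinss, best, tolerance = 1e-8)
})

test_that("Kruskal-Wallis and Dunn reproduce hand-computed rank statistics", {
  df <- data.frame(y = 1:9, g = rep(c("g1", "g2", "g3"), each = 3))
  kw <- kruskal_wallis_test(df, "y", "g")
  expect_equal(kw$statistic, 7.2, tolerance = 1e-9)
  expect_equal(kw$df, 2)

  dt <- dunn_test(df, "y", "g")
  z13 <- dplyr::filter(dt$pairwise, group_a == "g1", group_b == "g3")$z
  expect_equal(abs(z13), 6 / sqrt(5), tolerance = 1e-9)
  expect_true(all(dt$pairwise$adjusted_p >= dt$pairwise$p_value - 1e-12))
})

test_that("identical groups are not separated", {
  df <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  kw <- kruskal_wallis_test(df, "y", "g")
  expect_equal(kw$statistic, 0, tolerance = 1e-9)
  dt <- dunn_test(df, "y", "g")
  expect_equal(unique(dt$letters$letters), "a")
  df2 <- data.frame(y = rep(5, 6), g = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis_test(df2, "y", "g")$p_value, 1)
})

test_that("Dunn z matches the large-sample rank-sum z on two tie-free groups", {
  set.seed(40)
  a <- rnorm(15)
  b <- rnorm(12, mean = 0.8)
  df <- data.frame(y = c(a, b), g = rep(c("a", "b"), c(15, 12)))
  z <- dunn_test(df, "y", "g")$pairwise$z
  w <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  n1 <- 15; n2 <- 12
  z_ref <- (w$statistic - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  expect_equal(abs(z), abs(unname(z_ref)), tolerance = 1e-9)
})

test_that("ANOVA contrasts separate clear effects and respect adjustment", {
  set.seed(50)
  df <- data.frame(
    y = c(rnorm(3, 0, 0.01), rnorm(3, 10, 0.01)),
    g = rep(c("a", "b"), each = 3)
  )
  res <- anova_pairwise(df, "y", "g")
  expect_true(all(res$pairwise$significant))
  expect_false(res$letters$letters[1] == res$letters$letters[2])
  expect_true(all(res$pairwise$adjusted_p >= res$pairwise$p_value - 1e-12))

  null_df <- data.frame(y = rnorm(12), g = rep(c("a", "b"), each = 6))
  res0 <- anova_pairwise(null_df, "y", "g")
  expect_equal(length(unique(res0$letters$letters)), 1)

  flat <- data.frame(y = rep(c(1, 2), each = 3), g = rep(c("a", "b"), each = 3))
  flat$y <- c(1, 1, 1, 1, 1, 1)
  resf <- anova_pairwise(flat, "y", "g")
  expect_true(is.na(resf$omnibus$statistic))
})

test_that("Sidak-adjusted all-pairs contrasts control the family-wise error", {
  set.seed(60)
  n_sims <- 1000
  fwer <- mean(replicate(n_sims, {
    df <- data.frame(y = rnorm(15), g = rep(c("a", "b", "c"), each = 5))
    any(anova_pairwise(df, "y", "g")$pairwise$significant)
  }))
  expect_lte(fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("rand index agrees with the adjusted-Rand machinery on identical partitions", {
  expect_equal(rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(rand_index(c(1, 2, 1, 2), c(1, 1, 2, 2)), 1 / 3)
  skip_if_not_installed("mclust")
  set.seed(70)
  a <- sample(1:3, 40, replace = TRUE)
  expect_equal(mclust::adjustedRandIndex(a, a), 1)
  expect_equal(rand_index(a, a), 1)
})
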