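test_that("Spearman matrix handles monotone pairs and constant genes", {
  set.seed(2)
  x <- stats::rlnorm(10)
  m <- rbind(A = x, B = 2 * x, C = -x + 10)
  rho <- spearman_matrix(m)
  expect_equal(rho["A", "B"], 1)
  expect_equal(rho["A", "C"], -1)
  expect_equal(diag(rho), c(A = 1, B = 1, C = 1))

  mc <- rbind(A = x, K = rep(5, 10))
  rho2 <- spearman_matrix(mc)
  expect_equal(rho2["A", "K"], 0)
  expect_equal(attr(rho2, "constant_genes"), "K")
  expect_error(spearman_matrix(m[, 1:2]), "at least 3 samples")
})

test_that("Spearman matrix equals the rank-then-Pearson oracle", {
  set.seed(37)
  m <- matrix(stats::rnorm(24), 4, 6,
              dimnames = list(paste0("g", 1:4), NULL))
  rho <- spearman_matrix(m)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(rho[i, j], oracle_spearman(m[i, ], m[j, ]),
                 tolerance = 1e-12)
  expect_equal(rho, t(rho))
})

test_that("sign-blind distance maps rho of either sign to the same closeness", {
  rho <- matrix(c(1, 1, -1, 0,
                  1, 1, -1, 0,
                  -1, -1, 1, 0,
                  0, 0, 0, 1), 4, 4)
  d <- correlation_distance(rho)
  expect_equal(d[1, 2], 0)  # rho = 1
  expect_equal(d[1, 3], 0)  # rho = -1: anti-correlated genes are "close"
  expect_equal(d[1, 4], 1)  # rho = 0
  expect_equal(diag(d), rep(0, 4))

  set.seed(4)
  r <- stats::runif(20, -1, 1)
  rr <- diag(4)
  rr[upper.tri(rr)] <- r[1:6]; rr[lower.tri(rr)] <- t(rr)[lower.tri(rr)]
  dd <- correlation_distance(rr)
  expect_equal(correlation_distance(-rr), dd)  # d(rho) = d(-rho) exactly
  for (i in 1:4) for (j in 1:4)
    expect_equal(dd[i, j], if (i == j) 0 else 1 - abs(rr[i, j]))
})

test_that("complete-linkage merges follow the hand-computed example", {
  D <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  D["a", "b"] <- D["b", "a"] <- 0.1
  D["a", "c"] <- D["c", "a"] <- 0.9
  D["b", "c"] <- D["c", "b"] <- 0.8
  hc <- hcluster(D)
  expect_equal(hc$height, c(0.1, 0.9))
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))

  # two leaves: single merge at their distance
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(hcluster(D2)$height, 0.4)
  expect_error(hcluster(matrix(0, 1, 1)), "at least 2")
})

test_that("merge heights match the naive O(n^3) oracle and never invert", {
  set.seed(55)
  for (rep in 1:20) {
    n <- 8
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2)
    D <- D + t(D)
    hc <- hcluster(D)
    expect_equal(sort(hc$height), sort(oracle_complete_linkage_heights(D)),
                 tolerance = 1e-12)
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("cophenetic correlation is 1 on ultrametric input and matches pair extraction", {
  # ultrametric: two tight blocks at 0.1 joined at 0.9
  n <- 6
  D <- matrix(0.9, n, n)
  D[1:3, 1:3] <- 0.1; D[4:6, 4:6] <- 0.1
  diag(D) <- 0
  hc <- hcluster(D)
  expect_equal(cophenetic_correlation(D, hc)$correlation, 1.0)

  # random matrix: cophenetic distances equal the replayed merge heights
  set.seed(6)
  R <- matrix(0, 7, 7)
  R[upper.tri(R)] <- stats::runif(21)
  R <- R + t(R)
  hcr <- hcluster(R)
  expect_equal(as.matrix(stats::cophenetic(hcr)),
               oracle_cophenetic_matrix(hcr), ignore_attr = TRUE)
  cc <- cophenetic_correlation(R, hcr)
  expect_false(cc$degenerate)
  expect_equal(cc$correlation,
               stats::cor(R[upper.tri(R)],
                          oracle_cophenetic_matrix(hcr)[upper.tri(R)]))

  # all-equal distances are degenerate
  E <- matrix(1, 4, 4); diag(E) <- 0
  expect_true(cophenetic_correlation(E, hcluster(E))$degenerate)
})

test_that("silhouette selection finds planted blocks and ties break small", {
  # two well-separated planted blocks
  D <- matrix(0.9, 8, 8); D[1:4, 1:4] <- 0.1; D[5:8, 5:8] <- 0.1; diag(D) <- 0
  hc <- hcluster(D)
  expect_equal(select_k(D, hc, 2:6)$k, 2)

  # three planted blocks, within 0.1 / between 0.9
  D3 <- matrix(0.9, 9, 9)
  for (b in 0:2) D3[b * 3 + 1:3, b * 3 + 1:3] <- 0.1
  diag(D3) <- 0
  expect_equal(select_k(D3, hcluster(D3), 2:8)$k, 3)

  # three equidistant points: every cut ties, smallest k wins
  E <- matrix(1, 3, 3); diag(E) <- 0
  expect_equal(select_k(E, hcluster(E), 2:2)$k, 2)
})

test_that("cut_clusters recovers planted memberships (adjusted Rand = 1)", {
  g <- generate_correlated_blocks(block_sizes = c(6, 6), n_samples = 60,
                                  within_block_rho = 0.95, noise_sd = 0.2,
                                  seed = 61)
  cl <- coexpression_clusters(g$matrix)
  expect_equal(cl$k, 2)
  expect_equal(adjusted_rand(cl$clusters, g$block_labels), 1)

  hc <- cl$tree
  expect_equal(length(unique(cut_clusters(hc, 1))), 1L)
  expect_equal(length(unique(cut_clusters(hc, 12))), 12L)
  expect_error(cut_clusters(hc, 13), "k must lie")
})

test_that("dendrograms export as Newick with height-difference branch lengths", {
  D <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  D["a", "b"] <- D["b", "a"] <- 0.2
  D["a", "c"] <- D["c", "a"] <- 1
  D["b", "c"] <- D["c", "b"] <- 1
  s <- dendrogram_newick(hcluster(D))
  expect_match(s, "^\\(.*\\);$")
  expect_match(s, "c:1")          # leaf joining at the root height
  expect_match(s, "a:0.2|b:0.2")  # leaves of the first merge
  f <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_newick(hcluster(D), f)
  expect_equal(readLines(f), s)
})
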