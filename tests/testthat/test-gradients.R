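test_that("fcMatrix matches the textbook Pearson formula pair by pair", {
  withr::with_seed(11, ts <- matrix(rnorm(50), 5, 10))
  fc <- fcMatrix(ts)
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:5) for (j in 1:5) {
    expected <- if (i == j) 0 else pearson(ts[i, ], ts[j, ])
    expect_equal(fc[i, j], expected, tolerance = 1e-12)
  }
  expect_identical(fc, t(fc))
})

test_that("fcMatrix rejects degenerate input", {
  ts <- matrix(rnorm(20), 4, 5)
  ts[2, ] <- 1
  expect_error(fcMatrix(ts), "constant time series.*2")
  expect_error(fcMatrix(matrix(rnorm(8), 4, 2)), "3 timepoints")
})

test_that("normalized angle maps cosine {1, 0, -1} to {1, 0.5, 0} exactly", {
  expect_identical(normalizedAngle(c(1, 0, -1)), c(1, 0.5, 0))
})

test_that("affinity matrix is a sparsity-respecting normalized-angle map", {
  withr::with_seed(3, ts <- matrix(rnorm(30 * 60), 30))
  fc <- fcMatrix(ts)
  a <- affinityMatrix(fc, density = 0.2)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(unname(diag(a)), rep(0, 30))
  expect_lt(max(abs(a - t(a))), 1e-12)
  expect_identical(attr(a, "density"), 0.2)
  # independent oracle: explicit per-row sparsification + cosine loop
  n <- nrow(fc)
  k <- ceiling(0.2 * (n - 1))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    vals <- fc[i, -i]
    thr <- sort(vals, decreasing = TRUE)[k]
    keep <- which(fc[i, ] >= thr)
    keep <- setdiff(keep, i)
    S[i, keep] <- fc[i, keep]
  }
  expected <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cosine <- sum(S[i, ] * S[j, ]) /
      sqrt(sum(S[i, ]^2) * sum(S[j, ]^2))
    expected[i, j] <- 1 - acos(min(max(cosine, -1), 1)) / pi
  }
  expect_equal(unname(a), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("affinity errors when a row retains no connections", {
  fc <- matrix(0, 12, 12)
  fc[1, 2] <- fc[2, 1] <- 0.9  # all other rows are all-zero
  expect_error(affinityMatrix(fc, 0.1), "no retained connections")
})

test_that("diffusion embedding separates a two-block affinity by sign", {
  A <- matrix(0.1, 20, 20)
  A[1:10, 1:10] <- 0.9
  A[11:20, 11:20] <- 0.9
  diag(A) <- 0
  g <- diffusionEmbedding(A, k = 3)
  s <- gradientScores(g, 1)
  expect_true(all(sign(s[1:10]) == sign(s[1])))
  expect_true(all(sign(s[11:20]) == -sign(s[1])))
  oracle <- denseEmbeddingOracle(A, k = 3)
  expect_lt(maxDevUpToSign(gradientComponents(g), oracle), 1e-8)
})

test_that("embedding equals the dense eigen-oracle on random affinities", {
  for (seed in 1:10) {
    n <- sample(20:50, 1)
    A <- randomAffinity(n, seed)
    g <- diffusionEmbedding(A, k = 5)
    expect_lt(maxDevUpToSign(gradientComponents(g),
                             denseEmbeddingOracle(A, 5)), 1e-8)
    er <- explainedRatio(g)
    expect_true(all(er >= 0 & er <= 1))
    expect_true(all(diff(er) <= 1e-12))
    expect_lte(sum(er), 1 + 1e-8)
  }
})

test_that("relabeling nodes permutes embedding components identically", {
  A <- randomAffinity(25, 42)
  perm <- withr::with_seed(1, sample(25))
  g1 <- gradientComponents(diffusionEmbedding(A, k = 3))
  g2 <- gradientComponents(diffusionEmbedding(A[perm, perm], k = 3))
  expect_lt(maxDevUpToSign(g1[perm, ], g2), 1e-8)
})

test_that("disconnected affinity is refused with advice", {
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 0.8
  A[6:10, 6:10] <- 0.8
  diag(A) <- 0
  expect_error(diffusionEmbedding(A, k = 2), "disconnected.*density")
})

test_that("Procrustes alignment exactly recovers an orthogonal transform", {
  withr::with_seed(5, {
    G <- matrix(rnorm(40 * 3), 40)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
  })
  g1 <- new("GradientSet", components = G, eigenvalues = c(3, 2, 1) / 10,
            explainedRatio = c(3, 2, 1) / 10,
            nodeIds = paste0("n", 1:40))
  g2 <- initialize(g1, components = G %*% R)
  res <- procrustesAlign(list(g1, g2))
  expect_lt(res$disparity, 1e-8)
  expect_lt(max(abs(gradientComponents(res$gradients[[1]]) -
                    gradientComponents(res$gradients[[2]]))), 1e-6)
})

test_that("a single subject is returned unchanged up to orthogonality", {
  withr::with_seed(6, G <- matrix(rnorm(30 * 2), 30))
  g <- new("GradientSet", components = G, eigenvalues = c(0.2, 0.1),
           explainedRatio = c(0.2, 0.1), nodeIds = paste0("n", 1:30))
  res <- procrustesAlign(list(g))
  A <- gradientComponents(res$gradients[[1]])
  # orthogonal transforms preserve the Gram matrix
  expect_equal(crossprod(A), crossprod(G), tolerance = 1e-10)
})

test_that("alignment disparity never increases across iterations", {
  for (seed in 1:5) {
    grads <- withr::with_seed(seed, lapply(1:4, function(i) {
      G <- matrix(rnorm(20 * 3), 20)
      new("GradientSet", components = G, eigenvalues = c(3, 2, 1) / 10,
          explainedRatio = c(3, 2, 1) / 10, nodeIds = paste0("n", 1:20))
    }))
    res <- procrustesAlign(grads, nIter = 8)
    expect_true(all(diff(res$history) <= 1e-10))
  }
})

test_that("alignment refuses mismatched shapes", {
  g1 <- makeGradientSet(rnorm(10))
  g2 <- makeGradientSet(rnorm(12))
  expect_error(procrustesAlign(list(g1, g2)), "share node count")
})

test_that("global metrics: range, variance, explained ratio", {
  expect_equal(unname(globalMetrics(makeGradientSet(c(-1, 0, 2)))["range"]), 3)
  gm <- globalMetrics(makeGradientSet(rep(0.4, 5)))
  expect_equal(unname(gm["range"]), 0)
  expect_equal(unname(gm["variance"]), 0)
  withr::with_seed(9, big <- makeGradientSet(rnorm(10000)))
  expect_equal(unname(globalMetrics(big)["variance"]), 1, tolerance = 0.05)
  expect_error(globalMetrics(big, component = 2), "exceeds")
})

test_that("orientGradient points the template's DMN mean positive", {
  part <- data.frame(node = paste0("n", 1:20),
                     network = rep(c("VN", "DMN"), each = 10))
  g <- makeGradientSet(seq(1, -1, length.out = 20))  # DMN mean negative
  res <- procrustesAlign(list(g))
  res <- orientGradient(res, part)
  expect_gt(mean(res$template[11:20, 1]), 0)
  expect_gt(mean(gradientScores(res$gradients[[1]], 1)[11:20]), 0)
})
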