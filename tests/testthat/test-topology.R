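test_that("binarization keeps the strongest edges and all cutoff ties", {
  withr::with_seed(21, {
    fc <- matrix(rnorm(30 * 30), 30)
    fc <- (fc + t(fc)) / 2
  })
  diag(fc) <- 0
  g <- binarizeAtSparsity(fc, 0.2)
  expect_identical(igraph::ecount(g), round(0.2 * choose(30, 2)))
  # tied values at the cutoff are all kept: uniform matrix -> complete graph
  u <- matrix(1, 10, 10); diag(u) <- 0
  expect_identical(igraph::ecount(binarizeAtSparsity(u, 0.3)), choose(10, 2))
  expect_error(binarizeAtSparsity(fc, 0), "\\(0, 1\\)")
})

test_that("graph metrics match closed forms on canonical graphs", {
  triangle <- igraph::make_full_graph(3)
  m <- graphMetrics(triangle)
  expect_equal(unname(m["C"]), 1)
  expect_equal(unname(m["L"]), 1)
  path3 <- igraph::make_graph(~ a - b, b - c)
  m3 <- graphMetrics(path3)
  expect_equal(unname(m3["C"]), 0)
  expect_equal(unname(m3["L"]), 4 / 3)
  # ring lattice n = 20, k = 4: C = 0.5; L = 55/19 (hand-enumerated ring
  # distances d = 1..10 mapped to ceiling(d/2) steps)
  ring <- igraph::make_lattice(20, nei = 2, periodic = TRUE)
  mr <- graphMetrics(ring)
  expect_equal(unname(mr["C"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(mr["L"]), 55 / 19, tolerance = 1e-12)
})

test_that("disconnected graphs fall back to the largest component", {
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(3)
  m <- graphMetrics(g)
  expect_true(attr(m, "disconnected"))
  expect_equal(unname(m["L"]), 1)  # largest component is complete
})

test_that("degree-preserving rewiring keeps degrees and lowers clustering", {
  lat <- igraph::make_lattice(100, nei = 3, periodic = TRUE)
  hits <- vapply(1:10, function(s) {
    r <- randomReference(lat, seed = s)
    expect_identical(sort(igraph::degree(r)), sort(igraph::degree(lat)))
    igraph::transitivity(r) < igraph::transitivity(lat)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  expect_identical(randomReference(lat, nSwaps = 0), lat)
})

test_that("sigma is exactly gamma/lambda and AUC is the trapezoid rule", {
  withr::with_seed(22, {
    fc <- matrix(rnorm(40 * 40), 40)
    fc <- (fc + t(fc)) / 2
  })
  diag(fc) <- 0
  curve <- smallWorldCurve(fc, sparsities = seq(0.1, 0.4, 0.1), nRand = 3,
                           seed = 1)
  expect_lt(max(abs(curve@sigma - curve@gamma / curve@lambda)), 1e-10)
  expect_equal(curve@aGamma, trapezoidAUC(curve@sparsities, curve@gamma),
               tolerance = 1e-12)
  # constant curve c over width w integrates to c * w
  expect_equal(trapezoidAUC(c(0.05, 0.25, 0.5), rep(3, 3)), 3 * 0.45)
  # linearity
  expect_equal(trapezoidAUC(1:5, 2 * (1:5)), 2 * trapezoidAUC(1:5, 1:5))
})

test_that("small-world curves are reproducible under a fixed seed", {
  withr::with_seed(23, {
    fc <- matrix(rnorm(30 * 30), 30)
    fc <- (fc + t(fc)) / 2
  })
  diag(fc) <- 0
  c1 <- smallWorldCurve(fc, sparsities = c(0.2, 0.3), nRand = 3, seed = 7)
  c2 <- smallWorldCurve(fc, sparsities = c(0.2, 0.3), nRand = 3, seed = 7)
  expect_identical(c1@gamma, c2@gamma)
  expect_identical(c1@aSigma, c2@aSigma)
})

test_that("gradient-topology correlations: identities and FDR calibration", {
  withr::with_seed(24, {
    gm <- data.frame(range = rnorm(30), variance = rnorm(30),
                     explainedRatio = rnorm(30))
  })
  auc <- data.frame(aGamma = gm$range, aLambda = rnorm(30),
                    aSigma = rnorm(30))
  tab <- gradientTopologyCorr(gm, auc)
  dup <- tab[tab$gradient_metric == "range" & tab$topology_metric == "aGamma", ]
  expect_equal(dup$r, 1, tolerance = 1e-12)
  # n = 3 collinear points give |r| = 1
  gm3 <- data.frame(range = 1:3, variance = 1:3, explainedRatio = 1:3)
  auc3 <- data.frame(aGamma = c(2, 4, 6), aLambda = c(3, 2, 1),
                     aSigma = c(1, 5, 9))
  tab3 <- gradientTopologyCorr(gm3, auc3)
  expect_true(all(abs(tab3$r) > 1 - 1e-10))
  expect_error(gradientTopologyCorr(gm3[1:2, ], auc3[1:2, ]), "3 subjects")
})
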