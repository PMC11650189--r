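test_that("glmCompare reproduces per-node lm() fits and Cohen's d identity", {
  d <- makeGlmData(n1 = 10, n2 = 14, nNodes = 6, seed = 2, shift = 0.8)
  stat <- glmCompare(d$y, d$subjects)
  for (j in seq_len(ncol(d$y))) {
    fit <- lm(d$y[, j] ~ I(group == "case") + age + sex, data = d$subjects)
    sm <- summary(fit)$coefficients[2, ]
    expect_equal(stat@t[j], unname(sm["t value"]), tolerance = 1e-10)
    expect_equal(stat@p[j], unname(sm["Pr(>|t|)"]), tolerance = 1e-10)
  }
  expect_equal(abs(stat@d), abs(stat@t) * sqrt(1 / 10 + 1 / 14),
               tolerance = 1e-12)
  expect_equal(stat@z, sign(stat@t) * qnorm(stat@p / 2, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("degenerate responses give t = 0 rather than NaN", {
  d <- makeGlmData(nNodes = 2)
  d$y[, 1] <- 5
  stat <- glmCompare(d$y, d$subjects)
  expect_identical(stat@t[1], 0)
  expect_identical(stat@p[1], 1)
})

test_that("group labels shuffled yield nominal false-positive rates", {
  d <- makeGlmData(n1 = 15, n2 = 15, nNodes = 1, seed = 3)
  rej <- vapply(1:200, function(b) {
    s <- d$subjects
    s$group <- withr::with_seed(b, sample(s$group))
    y <- withr::with_seed(1000 + b,
                          matrix(rnorm(30), 30, dimnames = list(s$id, "n1")))
    glmCompare(y, s)@p[1] < 0.05
  }, TRUE)
  rate <- mean(rej)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("a strong balanced age effect does not inflate group errors", {
  rej <- vapply(1:200, function(b) {
    d <- makeGlmData(n1 = 15, n2 = 15, nNodes = 1, seed = 5000 + b)
    d$y[, 1] <- d$y[, 1] + 0.5 * d$subjects$age
    glmCompare(d$y, d$subjects)@p[1] < 0.05
  }, TRUE)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("interaction test detects a planted male-only effect", {
  pows <- vapply(1:20, function(b) {
    d <- makeGlmData(n1 = 100, n2 = 100, nNodes = 1, seed = 300 + b)
    male <- d$subjects$sex == "M" & d$subjects$group == "case"
    d$y[male, 1] <- d$y[male, 1] + 1
    interactionTest(d$y, d$subjects)$p[1] < 0.05
  }, TRUE)
  expect_gte(mean(pows), 0.8)
  d <- makeGlmData(nNodes = 1)
  d$subjects$sex <- "M"
  expect_error(interactionTest(d$y, d$subjects), "single level")
})

test_that("BH mask matches hand computation and the step-up oracle", {
  expect_identical(fdrBH(c(0.001, 0.02, 0.8)), c(TRUE, TRUE, FALSE))
  expect_identical(fdrBH(rep(1, 5)), rep(FALSE, 5))
  expect_identical(fdrBH(0.04), TRUE)
  expect_error(fdrBH(numeric()), "empty")
  expect_error(fdrBH(c(0.5, 1.2)), "\\[0, 1\\]")
  bhOracle <- function(p, q) {  # literal step-up definition
    m <- length(p)
    ord <- order(p)
    ok <- which(p[ord] <= q * seq_len(m) / m)
    mask <- logical(m)
    if (length(ok)) mask[ord[seq_len(max(ok))]] <- TRUE
    mask
  }
  for (seed in 1:50) {
    p <- withr::with_seed(seed, runif(sample(1:10, 1))^2)
    expect_identical(fdrBH(p, 0.1), bhOracle(p, 0.1))
  }
})

test_that("cluster correction finds a planted contiguous effect", {
  sphere <- genSphere(60, seed = 1)
  adj <- sphereAdjacency(sphere, k = 5)
  d <- makeGlmData(n1 = 25, n2 = 25, nNodes = 60, seed = 8)
  nbrs <- unique(c(1, unlist(igraph::neighborhood(adj, 1, nodes = 1))))
  target <- nbrs[1:6]
  d$y[d$subjects$group == "case", target] <-
    d$y[d$subjects$group == "case", target] + 1.5
  res <- clusterCorrect(d$y, d$subjects, adj, voxelP = 0.01, nPerm = 200,
                        seed = 4)
  expect_gt(nrow(res), 0)
  top <- which.max(res$extent)
  expect_lt(res$cluster_p[top], 0.05)
  expect_true(any(target %in% attr(res, "members")[[top]]))
})

test_that("cluster correction returns an empty frame when nothing survives", {
  sphere <- genSphere(20, seed = 2)
  adj <- sphereAdjacency(sphere, k = 4)
  d <- makeGlmData(n1 = 6, n2 = 6, nNodes = 20, seed = 9)
  res <- clusterCorrect(d$y, d$subjects, adj, voxelP = 1e-12, nPerm = 100,
                        seed = 1)
  expect_identical(nrow(res), 0L)
  expect_error(clusterCorrect(d$y, d$subjects, adj, nPerm = 50, seed = 1),
               "strict")
})

test_that("clinical correlation handles direction, missingness, errors", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(unname(clinicalCorr(x, 2 * x)["r"]), 1)
  noisy <- clinicalCorr(x, -x + c(0.01, -0.01, 0.005, 0, 0.002))
  expect_lt(unname(noisy["r"]), -0.99)
  withMiss <- clinicalCorr(c(x, NA), c(2 * x, 1))
  expect_identical(unname(withMiss["n"]), 5)
  expect_error(clinicalCorr(c(1, 2), c(2, 4)), "3 paired")
  expect_error(clinicalCorr(rep(1, 5), x), "variance")
})

test_that("paired t test matches its closed-form power", {
  expect_identical(pairedTTest(c(1, 2, 3), c(1, 2, 3)), c(t = 0, p = 1, d = 0))
  expect_error(pairedTTest(1:2, 2:3), "3 pairs")
  hits <- vapply(1:200, function(b) {
    withr::with_seed(b, {
      pre <- rnorm(15)
      post <- pre - rnorm(15, mean = 1, sd = 1)
    })
    pairedTTest(pre, post)["p"] < 0.05
  }, TRUE)
  theory <- power.t.test(n = 15, delta = 1, sd = 1, type = "paired")$power
  expect_equal(mean(hits), theory, tolerance = 0.1)
})

test_that("network shares partition significant nodes by sign", {
  part <- data.frame(node = paste0("n", 1:6),
                     network = c("DMN", "DMN", "SMN", "SMN", "VN", "VN"))
  stat <- new("GroupStatMap", t = c(2, 3, 2.5, -2, -1, 0.5),
              z = c(2, 3, 2.5, -2, -1, 0.5), p = rep(0.01, 6),
              d = c(2, 3, 2.5, -2, -1, 0.5) * 0.3, df = 10,
              contrast = "case-control", nodeIds = part$node)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  sh <- networkShare(stat, mask, part)
  inc <- sh[sh$sign == "increase", ]
  expect_equal(inc$proportion[inc$network == "DMN"], 2 / 3, tolerance = 1e-12)
  expect_equal(inc$proportion[inc$network == "SMN"], 1 / 3, tolerance = 1e-12)
  dec <- sh[sh$sign == "decrease", ]
  expect_equal(dec$proportion[dec$network == "SMN"], 1)
  empty <- networkShare(stat, rep(FALSE, 6), part)
  expect_true(attr(empty, "empty"))
  expect_true(all(empty$proportion == 0))
})
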