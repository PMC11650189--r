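test_that("cohort generation is deterministic under a fixed seed", {
  a <- genCohort(4, 4, nNodes = 24, nTimepoints = 20, seed = 123)
  b <- genCohort(4, 4, nNodes = 24, nTimepoints = 20, seed = 123)
  expect_identical(timeseriesList(a), timeseriesList(b))
  expect_identical(subjectTable(a), subjectTable(b))
  expect_identical(parcelSphere(a), parcelSphere(b))
  c2 <- genCohort(4, 4, nNodes = 24, nTimepoints = 20, seed = 124)
  expect_false(identical(timeseriesList(a), timeseriesList(c2)))
})

test_that("cohort invariants: PANSS for cases, positive fd, full partition", {
  co <- genCohort(5, 6, nNodes = 21, nTimepoints = 15, seed = 2)
  subj <- subjectTable(co)
  cases <- subj[subj$group == "case", ]
  expect_false(anyNA(cases[, c("panss_pos", "panss_neg", "panss_total",
                               "onset_age")]))
  expect_true(all(cases$panss_pos >= 7 & cases$panss_pos <= 49))
  expect_true(all(subj$fd > 0))
  expect_true(anyNA(subj$panss_pos[subj$group == "control"]))
  part <- nodePartition(co)
  expect_identical(nrow(part), 21L)
  expect_setequal(unique(part$network),
                  c("VN", "SMN", "DAN", "VAN", "limbic", "FPN", "DMN"))
  expect_error(genCohort(0, 5, seed = 1), "positive")
  expect_error(genCohort(5, 5, compression = 1.2, seed = 1), "compression")
  expect_error(genCohort(5, 5, nNodes = 10, seed = 1), "at least 20")
})

test_that("compression = 1 plants no group difference in the latent model", {
  co <- genCohort(3, 3, nNodes = 30, nTimepoints = 12, compression = 1,
                  seed = 5)
  truth <- plantedTruth(co)
  expect_identical(truth$caseAxis, truth$latentAxis)
  co6 <- genCohort(3, 3, nNodes = 30, nTimepoints = 12, compression = 0.6,
                   seed = 5)
  t6 <- plantedTruth(co6)
  expect_true(all(abs(t6$caseAxis[t6$affectedNodes]) <
                  abs(t6$latentAxis[t6$affectedNodes])))
  expect_identical(t6$caseAxis[-t6$affectedNodes],
                   t6$latentAxis[-t6$affectedNodes])
})

test_that("groups are covariate-balanced at n = 200 per group", {
  co <- genCohort(200, 200, nNodes = 20, nTimepoints = 5, seed = 31)
  subj <- subjectTable(co)
  ageDiff <- abs(mean(subj$age[subj$group == "case"]) -
                 mean(subj$age[subj$group == "control"]))
  expect_lt(ageDiff, 1.5)  # well within sampling error of a common mean
})

test_that("planted expression genes track the reference map", {
  withr::with_seed(7, zmap <- rnorm(100))
  expr <- genExpression(zmap, nGenes = 200, nAssoc = 15, coupling = 1,
                        seed = 3, noiseSd = 0.1)
  planted <- attr(expr, "planted")
  expect_length(planted, 15)
  rs <- cor(expr[, planted], zmap)
  expect_true(all(abs(rs) > 0.9))
  # columns are z-scored
  expect_lt(max(abs(colMeans(expr))), 1e-12)
  expect_equal(unname(apply(expr, 2, sd)), rep(1, 200), tolerance = 1e-12)
})

test_that("null expression coupling leaves planted genes uncorrelated", {
  withr::with_seed(8, zmap <- rnorm(60))
  rs <- vapply(1:20, function(s) {
    expr <- genExpression(zmap, nGenes = 30, nAssoc = 5, coupling = 0,
                          seed = s, noiseSd = 1)
    mean(cor(expr[, attr(expr, "planted")], zmap))
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(genExpression(rep(1, 50), 10, 2, 1, seed = 1), "constant")
  expect_error(genExpression(rnorm(5), 10, 2, 1, seed = 1), "10 regions")
})

test_that("generated gene sets honor the planted overlap fraction", {
  bg <- sprintf("gene%03d", 1:200)
  assoc <- bg[1:20]
  gs <- genGeneSets(assoc, bg, overlapFrac = 1, setSizes = 20, seed = 4)
  expect_setequal(geneSets(gs)$set1, assoc)
  gs0 <- genGeneSets(assoc, bg, overlapFrac = 0, setSizes = c(10, 30),
                     seed = 4)
  expect_length(intersect(geneSets(gs0)$set1, assoc), 0)
  expect_length(geneSets(gs0)$set2, 30)
  expect_error(genGeneSets(assoc, character(), 0.5, 10, seed = 1),
               "non-empty")
  expect_error(genGeneSets(assoc, bg, 0.5, 300, seed = 1), "exceeds")
})

test_that("sphere centroids are unit-norm, distinct, deterministic", {
  sp <- genSphere(100, seed = 9)
  xyz <- as.matrix(sp[, c("x", "y", "z")])
  expect_lt(max(abs(sqrt(rowSums(xyz^2)) - 1)), 1e-12)
  expect_gt(min(dist(xyz)), 0)
  expect_identical(sp, genSphere(100, seed = 9))
  expect_false(identical(sp, genSphere(100, seed = 10)))
  expect_error(genSphere(5, seed = 1), "at least 10")
  lr <- genSphere(50, seed = 2, hemisphere = "LR")
  expect_setequal(unique(lr$hemisphere), c("L", "R"))
})

test_that("planted outcomes respect the instrument floor and determinism", {
  co <- genCohort(6, 4, nNodes = 30, nTimepoints = 40, seed = 12)
  w <- rep(100, 30)  # huge improvement forces clipping at the floor
  feats <- matrix(1, 6, 30,
                  dimnames = list(subjectTable(co)$id[1:6], NULL))
  out <- genOutcomes(co, w, noiseSd = 0, seed = 1, features = feats)
  wk8 <- subjectTable(out)[subjectTable(out)$timepoint == "week8", ]
  expect_identical(nrow(wk8), 6L)
  expect_true(all(wk8$panss_pos == 7))  # clipped at the PANSS minimum
  out2 <- genOutcomes(co, w, noiseSd = 0, seed = 1, features = feats)
  expect_identical(subjectTable(out), subjectTable(out2))
  expect_error(genOutcomes(co, rep(1, 5), seed = 1), "length")
  expect_identical(plantedTruth(out)$outcomeWeights, w)
})
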