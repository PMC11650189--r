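test_that("GeneSetCollection harmonizes case-insensitively to background", {
  gs <- GeneSetCollection(list(a = c("SNAP25", "gfap", "missing")),
                          background = c("Snap25", "GFAP", "AQP4"))
  expect_setequal(geneSets(gs)$a, c("Snap25", "GFAP"))
  expect_error(GeneSetCollection(list(a = "x"), character()), "non-empty")
})

test_that("GMT files round-trip", {
  gs <- GeneSetCollection(list(s1 = c("A", "B", "C"), s2 = c("B", "D")),
                          background = c("A", "B", "C", "D", "E"))
  path <- tempfile(fileext = ".gmt")
  writeGMT(gs, path)
  back <- readGMT(path, background = geneBackground(gs))
  expect_identical(geneSets(back), geneSets(gs))
  expect_identical(geneBackground(back), geneBackground(gs))
})

test_that("overlap permutation test: maximal statistic gives minimal p", {
  bg <- sprintf("g%03d", 1:200)
  z <- setNames(seq(3, -3, length.out = 200), bg)
  plsGenes <- bg[1:50]
  topSet <- bg[1:20]  # the highest-Z genes themselves
  res <- overlapPermTest(plsGenes, topSet, bg, z, nPerm = 200, seed = 1)
  expect_identical(res$n_overlap, 20L)
  expect_equal(res$p_perm, 1 / 201)
  # empty overlap is flagged, not an error
  res0 <- overlapPermTest(bg[1:10], bg[190:200], bg, z, nPerm = 100, seed = 1)
  expect_identical(res0$n_overlap, 0L)
  expect_identical(res0$p_perm, 1)
  expect_true(attr(res0, "empty"))
  expect_error(overlapPermTest(plsGenes, bg, bg, z, nPerm = 100, seed = 1),
               "smaller than the background")
  expect_error(overlapPermTest(plsGenes, c("zz1", "zz2"), bg, z, 100, 1),
               "does not intersect")
})

test_that("marker overlap test flags a contained marker set", {
  bg <- sprintf("g%03d", 1:150)
  geneList <- bg[1:40]
  markers <- GeneSetCollection(
    list(inside = bg[5:14], outside = bg[101:115]), bg)
  res <- markerOverlapTest(geneList, markers, nPerm = 300, seed = 2)
  inside <- res[res$set_name == "inside", ]
  expect_identical(inside$n_overlap, 10L)
  expect_equal(inside$p_perm, 1 / 301)
  expect_gt(res$p_perm[res$set_name == "outside"], 0.5)
  expect_error(markerOverlapTest(c("nope"), markers), "disjoint")
})

test_that("GSEA enrichment score equals the hand-enumerated running sum", {
  ranked <- paste0("g", 1:10)
  scores <- c(5, 4, 3, 2.5, 2, 1.5, 1, 0.5, 0.25, 0.1)
  set <- c("g2", "g3", "g7")
  # independent oracle: explicit walk over the ranking
  oracleES <- function(ranked, scores, set, p = 1) {
    hit <- ranked %in% set
    nh <- sum(abs(scores[hit])^p)
    run <- 0
    best <- 0
    for (i in seq_along(ranked)) {
      run <- run + if (hit[i]) abs(scores[i])^p / nh else -1 / sum(!hit)
      if (abs(run) > abs(best)) best <- run
    }
    best
  }
  res <- gseaTest(ranked, scores, set, nPerm = 100, seed = 3)
  expect_equal(res$es, oracleES(ranked, scores, set), tolerance = 1e-14)
  expect_lte(abs(res$es), 1)
  expect_identical(sign(res$nes), sign(res$es))
})

test_that("top-loaded sets give positive ES, bottom-loaded negative", {
  ranked <- paste0("g", 1:100)
  scores <- seq(5, -5, length.out = 100)
  top <- gseaTest(ranked, scores, ranked[1:5], nPerm = 100, seed = 4)
  expect_gt(top$es, 0)
  bottom <- gseaTest(ranked, scores, ranked[96:100], nPerm = 100, seed = 4)
  expect_lt(bottom$es, 0)
  expect_lt(bottom$nes, 0)
  expect_error(gseaTest(ranked, scores, c("g1", "g2"), 100, 1), "at least 3")
})

test_that("unweighted GSEA is invariant to monotone score rescaling", {
  ranked <- paste0("g", 1:50)
  scores <- seq(2, -2, length.out = 50)
  set <- c("g3", "g9", "g20", "g41")
  a <- gseaTest(ranked, scores, set, nPerm = 100, seed = 5, weightP = 0)
  b <- gseaTest(ranked, exp(scores), set, nPerm = 100, seed = 5, weightP = 0)
  expect_identical(a$es, b$es)
  expect_identical(a$p_perm, b$p_perm)
})
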