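# End-to-end pipeline driver: gradients -> group statistics -> topology ->
# decoding -> PLS -> enrichment -> prediction, on synthetic or user data,
# with a deterministic manifest.

.configDefaults <- function() list(
  # cohort
  nCase = 30L, nControl = 30L, nNodes = 120L, nTimepoints = 150L,
  compression = 0.7, severitySd = 0.4, seed = 1L,
  # gradients
  density = 0.10, alpha = 0.5, k = 10L,
  # group statistics
  q = 0.05, voxelP = 0.01, nPermCluster = 200L, adjacencyK = 6L,
  # topology
  sparsities = seq(0.05, 0.50, by = 0.05), nRand = 5L,
  # spatial
  nSpins = 200L, nTerms = 10L,
  # transcriptomics
  nGenes = 300L, nAssoc = 20L, coupling = 1, exprNoiseSd = 0.5,
  nBoot = 200L,
  # enrichment
  nPermOverlap = 200L, overlapFrac = 0.6, geneSetSize = 25L,
  # prediction
  svrC = 1, svrEpsilon = 0.1, nPermSvr = 100L, outcomeNoiseSd = 1,
  outcomeWeightNetwork = "DMN", outcomeWeight = 5,
  # io
  outDir = "gradix-run")

#' Validated pipeline configuration
#'
#' Returns the default configuration with the supplied overrides applied.
#' Unknown keys are rejected; ranges are validated. The full configuration is
#' echoed into every run's manifest.
#'
#' @param ... named overrides of the defaults (see the vignette for the
#'   meaning, unit and default of each parameter).
#' @return Named list of class `gradixConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- .configDefaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  intKeys <- c("nCase", "nControl", "nNodes", "nTimepoints", "seed", "k",
               "nPermCluster", "adjacencyK", "nRand", "nSpins", "nTerms",
               "nGenes", "nAssoc", "nBoot", "nPermOverlap", "geneSetSize",
               "nPermSvr")
  cfg[intKeys] <- lapply(cfg[intKeys], as.integer)
  stopifnot(cfg$nCase >= 3L, cfg$nControl >= 3L, cfg$nNodes >= 20L,
            cfg$compression > 0, cfg$compression <= 1,
            cfg$density > 0, cfg$density < 1,
            cfg$k >= 1L, cfg$q > 0, cfg$q < 1,
            cfg$voxelP > 0, cfg$voxelP < 1,
            all(cfg$sparsities > 0 & cfg$sparsities < 1),
            cfg$nSpins >= 100L, cfg$nBoot >= 100L,
            cfg$nAssoc <= cfg$nGenes)
  structure(cfg, class = "gradixConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of config overrides.
#' @return A validated config (see [pipelineConfig()]).
#' @export
readConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

# deterministic sub-seeds derived from the master seed (kept below 2^31)
.subSeed <- function(seed, offset) (as.integer(seed) * 97L + offset) %% 2147483629L

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates a cohort (with planted gradient compression, expression
#' coupling and outcome weights), then runs, in order: per-subject gradient
#' construction and alignment; covariate-adjusted group comparison of the
#' principal-gradient maps (FDR and permutation cluster correction) and of
#' the global metrics; network shares of significant nodes; per-subject
#' small-world topology and its correlation with global gradient metrics;
#' spin permutations; decoding of the case-control z map against synthetic
#' term maps; PLS of planted expression on the z map with spin significance
#' and bootstrap gene-weight Z ranking; overlap and GSEA enrichment against
#' generated gene sets; SVR treatment-outcome prediction with permutation
#' validation and network weight attribution. Every artifact is written to
#' `config$outDir` together with a manifest (config echo, input/output
#' hashes, package version) that is byte-identical across reruns with the
#' same config.
#'
#' @param config a config from [pipelineConfig()] / [readConfig()].
#' @param cohort optional pre-built [SyntheticCohort-class]; when supplied
#'   it is validated against the config's node count.
#' @return Invisibly, a list with all intermediate results and the run
#'   directory.
#' @export
runPipeline <- function(config = pipelineConfig(), cohort = NULL) {
  stopifnot(inherits(config, "gradixConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  ## --- synthetic inputs -------------------------------------------------
  if (is.null(cohort)) {
    cohort <- genCohort(config$nCase, config$nControl, config$nNodes,
                        config$nTimepoints, config$compression,
                        seed = .subSeed(seed, 1L),
                        severitySd = config$severitySd)
  }
  if (nrow(nodePartition(cohort)) != config$nNodes)
    stop("pre-flight check failed: cohort node count (",
         nrow(nodePartition(cohort)), ") does not match config nNodes (",
         config$nNodes, ")")

  ## --- gradients --------------------------------------------------------
  grads <- cohortGradients(cohort, density = config$density,
                           alpha = config$alpha, k = config$k)
  subjects <- subjectTable(cohort)
  base <- subjects[subjects$timepoint == "baseline", ]

  ## --- group statistics -------------------------------------------------
  stat <- glmCompare(grads$g1, base)
  sigFdr <- fdrBH(stat@p, config$q)
  adjacency <- sphereAdjacency(parcelSphere(cohort), config$adjacencyK)
  clusters <- clusterCorrect(grads$g1, base, adjacency,
                             voxelP = config$voxelP,
                             nPerm = config$nPermCluster,
                             seed = .subSeed(seed, 2L), strict = FALSE)
  shares <- networkShare(stat, sigFdr, nodePartition(cohort))
  metricMat <- as.matrix(grads$metrics[, c("range", "variance",
                                           "explainedRatio")])
  rownames(metricMat) <- grads$metrics$id
  globalStat <- glmCompare(metricMat, base)

  ## --- topology ---------------------------------------------------------
  curves <- lapply(seq_along(grads$fc), function(i)
    smallWorldCurve(grads$fc[[i]], config$sparsities, config$nRand,
                    seed = .subSeed(seed, 100L + i)))
  aucs <- data.frame(id = names(grads$fc),
                     do.call(rbind, lapply(curves, topologyAUC)),
                     row.names = NULL, stringsAsFactors = FALSE)
  aucMat <- as.matrix(aucs[, -1L])
  rownames(aucMat) <- aucs$id
  topoStat <- glmCompare(aucMat, base)
  topoCorr <- gradientTopologyCorr(grads$metrics, aucs)

  ## --- spatial: spins + decoding ---------------------------------------
  spins <- spinPermutations(parcelSphere(cohort), config$nSpins,
                            seed = .subSeed(seed, 3L))
  termMaps <- withSeed(.subSeed(seed, 4L), {
    tm <- t(smoothColumns(matrix(stats::rnorm(config$nNodes * config$nTerms),
                                 config$nNodes), bandwidth = 4))
    rownames(tm) <- paste0("term", seq_len(config$nTerms))
    tm
  })
  decoding <- decodeMaps(zMap(stat), termMaps, spins)

  ## --- transcriptomics --------------------------------------------------
  expr <- genExpression(zMap(stat), config$nGenes, config$nAssoc,
                        config$coupling, seed = .subSeed(seed, 5L),
                        noiseSd = config$exprNoiseSd)
  pls <- plsFit(expr, zMap(stat))
  plsP <- plsSignificance(pls, expr, zMap(stat), spins)
  genes <- bootstrapWeights(expr, zMap(stat), nBoot = config$nBoot,
                            seed = .subSeed(seed, 6L), q = config$q)
  ranked <- rankGenes(genes)

  ## --- enrichment -------------------------------------------------------
  planted <- colnames(expr)[attr(expr, "planted")]
  geneSetsSim <- genGeneSets(planted, colnames(expr), config$overlapFrac,
                             rep(config$geneSetSize, 3L),
                             seed = .subSeed(seed, 7L),
                             setNames = c("disorderA", "disorderB",
                                          "disorderC"))
  plsZ <- stats::setNames(genes$Z, genes$gene)
  overlaps <- do.call(rbind, lapply(names(geneSets(geneSetsSim)), function(nm)
    cbind(set_name = nm,
          overlapPermTest(genes$gene[genes$list == "PLS1+"],
                          geneSets(geneSetsSim)[[nm]],
                          geneBackground(geneSetsSim), plsZ,
                          nPerm = config$nPermOverlap,
                          seed = .subSeed(seed, 8L)))))
  overlaps$fdr_p <- stats::p.adjust(overlaps$p_perm, method = "BH")
  gsea <- gseaTest(ranked$gene, ranked$Z, geneSets(geneSetsSim)[[1L]],
                   nPerm = config$nPermOverlap, seed = .subSeed(seed, 9L))

  ## --- prediction -------------------------------------------------------
  wOut <- ifelse(nodePartition(cohort)$network == config$outcomeWeightNetwork,
                 config$outcomeWeight, 0)
  cohort <- genOutcomes(cohort, wOut, noiseSd = config$outcomeNoiseSd,
                        seed = .subSeed(seed, 10L), features = grads$g1)
  subjects <- subjectTable(cohort)
  wk8 <- subjects[subjects$timepoint == "week8", ]
  feats <- grads$g1[wk8$id, , drop = FALSE]
  svr <- svrLoocv(feats, wk8$panss_pos, C = config$svrC,
                  epsilon = config$svrEpsilon)
  svrP <- permutationValidate(feats, wk8$panss_pos,
                              nPerm = config$nPermSvr,
                              seed = .subSeed(seed, 11L),
                              C = config$svrC, epsilon = config$svrEpsilon)
  svr@pPermR <- unname(svrP["p_perm_r"])
  svr@pPermMse <- unname(svrP["p_perm_mse"])
  svr@networkShare <- networkWeightShare(svr@weights, nodePartition(cohort))

  ## --- reproducibility split -------------------------------------------
  halves <- subgroupCompare(grads$g1, base, spins, split = "random",
                            seed = .subSeed(seed, 12L))

  ## --- write artifacts + manifest ---------------------------------------
  od <- config$outDir
  writeSubjects(subjects, file.path(od, "subjects.csv"))
  writePartition(nodePartition(cohort), file.path(od, "partition.csv"))
  writeSphere(parcelSphere(cohort), file.path(od, "sphere.csv"))
  writeMatrixTSV(grads$g1, file.path(od, "gradient1.tsv"))
  writeStatMap(stat, file.path(od, "statmap.tsv"),
               extra = data.frame(sig_fdr = sigFdr))
  utils::write.csv(aucs, file.path(od, "topology_auc.csv"),
                   row.names = FALSE)
  utils::write.csv(topoCorr, file.path(od, "gradient_topology_corr.csv"),
                   row.names = FALSE)
  utils::write.csv(decoding, file.path(od, "decoding.csv"),
                   row.names = FALSE)
  utils::write.csv(ranked, file.path(od, "gene_weights.csv"),
                   row.names = FALSE)
  utils::write.csv(overlaps, file.path(od, "overlap_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(network = names(svr@networkShare),
                              share = fmtNum(svr@networkShare)),
                   file.path(od, "svr_network_share.csv"),
                   row.names = FALSE)
  outputs <- list.files(od, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "gradix",
    version = as.character(utils::packageVersion("gradix")),
    seed = seed,
    config = unclass(config),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(sort(outputs))), basename(sort(outputs)))))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, gradients = grads, stat = stat,
                 sigFdr = sigFdr, clusters = clusters, shares = shares,
                 globalStat = globalStat, curves = curves, aucs = aucs,
                 topoStat = topoStat, topoCorr = topoCorr, spins = spins,
                 decoding = decoding, expr = expr, pls = pls, plsP = plsP,
                 genes = genes, overlaps = overlaps, gsea = gsea, svr = svr,
                 halves = halves, dir = od))
}

#' Split-half / subgroup reproducibility of the case-control map
#'
#' Re-runs the covariate-adjusted group comparison in two subgroups and
#' reports the spin-corrected spatial correlation between the resulting
#' z maps. Splits: `"onset"` divides cases at onset age 18 (controls shared),
#' `"random"` halves the cases at random, `"fd"` re-estimates the map with FD
#' added to the covariates and correlates it with the unadjusted map.
#'
#' @param y subject x node matrix of gradient scores (baseline subjects).
#' @param subjects matching baseline subject table.
#' @param spins a [SpinPermutationSet-class] over the nodes.
#' @param split `"onset"`, `"random"` or `"fd"`.
#' @param seed RNG seed (used by the random split).
#' @return list with the two [GroupStatMap-class]s and `c(r, p_spin)`.
#' @export
subgroupCompare <- function(y, subjects, spins,
                            split = c("random", "onset", "fd"), seed = 1L) {
  split <- match.arg(split)
  y <- as.matrix(y)
  cases <- subjects$id[subjects$group == "case"]
  controls <- subjects$id[subjects$group == "control"]
  pick <- function(ids) {
    sel <- subjects$id %in% ids
    glmCompare(y[subjects$id[sel], , drop = FALSE], subjects[sel, ])
  }
  if (split == "fd") {
    mapA <- glmCompare(y, subjects)
    mapB <- glmCompare(y, subjects, covariates = c("age", "sex", "fd"))
  } else {
    idsA <- switch(split,
      onset = cases[subjects$onset_age[match(cases, subjects$id)] < 18],
      random = withSeed(seed, sample(cases, floor(length(cases) / 2))))
    idsB <- setdiff(cases, idsA)
    if (length(idsA) < 3L || length(idsB) < 3L)
      stop("subgroup with fewer than 3 cases")
    mapA <- pick(c(idsA, controls))
    mapB <- pick(c(idsB, controls))
  }
  list(mapA = mapA, mapB = mapB,
       similarity = spinCorr(zMap(mapA), zMap(mapB), spins))
}
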