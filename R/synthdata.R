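# Synthetic cohort, expression, gene-set, sphere and outcome generators.
# These plant known effects so every downstream stage is testable offline.

YEO7 <- c("VN", "SMN", "DAN", "VAN", "limbic", "FPN", "DMN")

# Fibonacci lattice on the unit sphere, optionally rotated
fibonacciSphere <- function(n, rotation = NULL) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  xyz <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  if (!is.null(rotation)) xyz <- xyz %*% t(rotation)
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

# Haar-ish random rotation: QR of a Gaussian matrix, sign-fixed, det +1
randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

#' Quasi-uniform spherical parcel centroids
#'
#' Places `nParcels` unit-norm centroids on the sphere by a Fibonacci lattice
#' and applies a random rotation drawn from `seed` (so different seeds give
#' different, equally uniform layouts). By default all parcels carry the
#' hemisphere label `"L"`, mirroring analyses restricted to one hemisphere's
#' spherical surface; `hemisphere = "LR"` splits the lattice into two
#' mirrored half-lattices labeled L and R.
#'
#' @param nParcels number of parcels (at least 10).
#' @param seed integer RNG seed.
#' @param hemisphere `"L"` (single sphere) or `"LR"`.
#' @return data.frame with columns `parcel`, `x`, `y`, `z`, `hemisphere`.
#' @export
genSphere <- function(nParcels, seed, hemisphere = c("L", "LR")) {
  if (nParcels < 10L) stop("nParcels must be at least 10")
  hemisphere <- match.arg(hemisphere)
  withSeed(seed, {
    if (hemisphere == "L") {
      xyz <- fibonacciSphere(nParcels, randomRotation())
      hemi <- rep("L", nParcels)
    } else {
      nL <- ceiling(nParcels / 2)
      rot <- randomRotation()
      left <- fibonacciSphere(nL, rot)
      right <- fibonacciSphere(nParcels - nL, rot)
      right[, 1L] <- -right[, 1L]  # mirror across x = 0
      xyz <- rbind(left, right)
      hemi <- rep(c("L", "R"), c(nL, nParcels - nL))
    }
    data.frame(parcel = paste0("p", seq_len(nParcels)), xyz,
               hemisphere = hemi, stringsAsFactors = FALSE)
  })
}

# contiguous 7-network partition along the latent axis (VN ... DMN)
latentPartition <- function(nNodes) {
  sizes <- diff(round(seq(0, nNodes, length.out = 8L)))
  data.frame(node = paste0("n", seq_len(nNodes)),
             network = rep(YEO7, sizes), stringsAsFactors = FALSE)
}

# factor loadings decaying in distance along the latent axis, unit row norm
latentLoadings <- function(g, centers, width) {
  L <- exp(-outer(g, centers, `-`)^2 / (2 * width^2))
  L / sqrt(rowSums(L^2))
}

#' Generate a two-group synthetic resting-state cohort
#'
#' Nodes carry a latent 1-D axis `g` in `[-1, 1]`, partitioned into 7
#' contiguous network blocks (VN ... DMN). Each subject's node x time series
#' is a mixture of shared latent signals whose loadings decay with distance
#' along the axis, plus a per-network block signal, plus white noise - so the
#' expected node-node correlation decays with `|g_i - g_j|` and the principal
#' connectome gradient recovers the axis. For cases, the axis is rescaled by
#' `compression` on the affected nodes (the extremes, `|g| > 0.6`), planting
#' the gradient-range contraction; `compression = 1` plants no effect and the
#' two groups are exchangeable. Ages and sexes are drawn from the same
#' distributions in both groups (covariate-balanced); cases carry baseline
#' PANSS scores and an onset age.
#'
#' Case heterogeneity: each case carries a latent severity factor
#' `s ~ N(1, severitySd)` scaling its compression depth,
#' `c_i = 1 - s_i (1 - compression)`, and its baseline PANSS positive score
#' is coupled to `s_i` — so symptom severity is partially encoded in the
#' connectome, as in clinical cohorts. With `compression = 1` the severity
#' factor has no effect on the brain and the groups remain exchangeable.
#'
#' @param nCase,nControl group sizes.
#' @param nNodes number of nodes (at least 20).
#' @param nTimepoints scan length.
#' @param compression mean case-axis rescaling factor in (0, 1].
#' @param seed integer RNG seed; the whole cohort is a deterministic function
#'   of it.
#' @param nFactors,factorWidth,blockWeight,noiseSd generative-model knobs:
#'   number of latent signals, kernel width of their loadings along the axis,
#'   weight of the network block signal, and white-noise SD.
#' @param severitySd SD of the per-case severity factor; the default 0
#'   plants the homogeneous mechanism (every case compressed identically),
#'   which is what the direction and calibration guarantees are stated for.
#'   The demo pipeline opts into 0.4 to make outcomes brain-predictable.
#' @return A [SyntheticCohort-class] object.
#' @export
genCohort <- function(nCase, nControl, nNodes = 200L, nTimepoints = 200L,
                      compression = 1, seed = 1L, nFactors = 12L,
                      factorWidth = 0.35, blockWeight = 0.1, noiseSd = 0.5,
                      severitySd = 0) {
  if (nCase <= 0 || nControl <= 0) stop("group sizes must be positive")
  if (nNodes < 20L) stop("nNodes must be at least 20")
  if (compression <= 0 || compression > 1)
    stop("compression must lie in (0, 1]")
  withSeed(seed, {
    g <- seq(-1, 1, length.out = nNodes)
    partition <- latentPartition(nNodes)
    affected <- which(abs(g) > 0.6)
    gCase <- g
    gCase[affected] <- compression * gCase[affected]
    centers <- seq(-1, 1, length.out = nFactors)
    Lctrl <- latentLoadings(g, centers, factorWidth)
    B <- stats::model.matrix(~ 0 + factor(partition$network, levels = YEO7))
    n <- nCase + nControl
    group <- rep(c("case", "control"), c(nCase, nControl))
    ids <- sprintf("s%03d", seq_len(n))
    age <- pmin(pmax(round(stats::rnorm(n, 17, 4), 1), 7), 30)
    sex <- sample(c("M", "F"), n, replace = TRUE)
    fd <- stats::rlnorm(n, log(0.12), 0.4)
    isCase <- group == "case"
    severity <- ifelse(isCase, pmax(stats::rnorm(n, 1, severitySd), 0.1), NA)
    subjComp <- ifelse(isCase,
                       pmin(pmax(1 - severity * (1 - compression), 0.05), 1),
                       NA)
    ts <- vector("list", n)
    names(ts) <- ids
    for (i in seq_len(n)) {
      L <- if (isCase[i]) {
        gi <- g
        gi[affected] <- subjComp[i] * gi[affected]
        latentLoadings(gi, centers, factorWidth)
      } else Lctrl
      f <- matrix(stats::rnorm(nFactors * nTimepoints), nFactors)
      u <- matrix(stats::rnorm(7L * nTimepoints), 7L)
      eps <- matrix(stats::rnorm(nNodes * nTimepoints, sd = noiseSd), nNodes)
      ts[[i]] <- L %*% f + blockWeight * (B %*% u) + eps
      rownames(ts[[i]]) <- partition$node
    }
    pos <- ifelse(isCase,
                  pmin(pmax(round(24 + 8 * (severity - 1) +
                                    stats::rnorm(n, sd = 3)), 7), 49), NA)
    neg <- ifelse(isCase,
                  pmin(pmax(round(21 + 6 * (severity - 1) +
                                    stats::rnorm(n, sd = 3)), 7), 49), NA)
    gen <- ifelse(isCase, pmin(pmax(round(stats::rnorm(n, 45, 8)), 16), 112), NA)
    subjects <- data.frame(
      id = ids, group = group, age = age, sex = sex, fd = fd,
      onset_age = ifelse(isCase, pmax(round(age - stats::runif(n), 1), 7), NA),
      panss_pos = pos, panss_neg = neg, panss_total = pos + neg + gen,
      timepoint = "baseline", stringsAsFactors = FALSE)
    sphere <- genSphere(nNodes, seed = sample.int(2^30, 1L))
    truth <- list(latentAxis = g, caseAxis = gCase, affectedNodes = affected,
                  gradientCompression = compression,
                  severity = severity[isCase],
                  subjectCompression = subjComp[isCase],
                  noiseSd = noiseSd, blockWeight = blockWeight,
                  factorWidth = factorWidth, seed = seed)
    new("SyntheticCohort", subjects = subjects, timeseries = ts,
        partition = partition, sphere = sphere, truth = truth)
  })
}

# Gaussian smoothing of columns along the region index (spatial
# autocorrelation stand-in when no geometry is supplied)
smoothColumns <- function(m, bandwidth) {
  n <- nrow(m)
  w <- stats::dnorm(outer(seq_len(n), seq_len(n), `-`), sd = bandwidth)
  w <- w / rowSums(w)
  w %*% m
}

#' Generate a regions x genes expression matrix with planted associations
#'
#' A randomly chosen subset of `nAssoc` genes follows
#' `coupling * standardize(zmap) + noise`; the remaining genes are spatially
#' autocorrelated noise (white noise smoothed along the region index). All
#' columns are z-scored, emulating a normalized expression atlas.
#'
#' @param zmap per-region reference map (non-constant, length >= 10).
#' @param nGenes total genes.
#' @param nAssoc number of planted associated genes (<= nGenes).
#' @param coupling coupling strength of planted genes to `zmap`.
#' @param seed integer RNG seed.
#' @param noiseSd SD of the noise added to planted genes.
#' @param bandwidth smoothing bandwidth (region-index units) for the
#'   autocorrelated background genes.
#' @return regions x genes numeric matrix with gene ids as colnames and
#'   attributes `planted` (gene indices) and `coupling`.
#' @export
genExpression <- function(zmap, nGenes = 500L, nAssoc = 20L, coupling = 1,
                          seed = 1L, noiseSd = 0.5, bandwidth = 4) {
  nR <- length(zmap)
  if (nR < 10L) stop("zmap must cover at least 10 regions")
  if (stats::sd(zmap) == 0) stop("zmap is constant; nothing to couple to")
  if (nAssoc > nGenes) stop("nAssoc cannot exceed nGenes")
  withSeed(seed, {
    zstd <- zscore(zmap)
    expr <- smoothColumns(matrix(stats::rnorm(nR * nGenes), nR), bandwidth)
    planted <- if (nAssoc > 0) sort(sample.int(nGenes, nAssoc)) else integer()
    for (j in planted)
      expr[, j] <- coupling * zstd + stats::rnorm(nR, sd = noiseSd)
    expr <- apply(expr, 2L, zscore)
    dimnames(expr) <- list(names(zmap) %||% paste0("r", seq_len(nR)),
                           sprintf("gene%04d", seq_len(nGenes)))
    attr(expr, "planted") <- planted
    attr(expr, "coupling") <- coupling
    expr
  })
}

#' Generate gene sets with controlled overlap with a planted gene subset
#'
#' Each emitted set draws `round(overlapFrac * size)` members from
#' `assocGenes` and the rest from the remaining background, emulating
#' disorder or cell-marker gene lists that share signal genes.
#'
#' @param assocGenes character ids of the planted genes.
#' @param background character universe of gene ids (non-empty).
#' @param overlapFrac fraction of each set drawn from `assocGenes`, in
#'   `[0, 1]`.
#' @param setSizes integer vector of set sizes.
#' @param seed integer RNG seed.
#' @param setNames optional set names (default `set1..`).
#' @return A [GeneSetCollection-class].
#' @export
genGeneSets <- function(assocGenes, background, overlapFrac, setSizes,
                        seed = 1L, setNames = NULL) {
  if (!length(background)) stop("background must be non-empty")
  if (overlapFrac < 0 || overlapFrac > 1)
    stop("overlapFrac must lie in [0, 1]")
  if (any(setSizes > length(background)))
    stop("set size exceeds the background")
  setNames <- setNames %||% paste0("set", seq_along(setSizes))
  withSeed(seed, {
    nonAssoc <- setdiff(background, assocGenes)
    sets <- lapply(setSizes, function(sz) {
      nOv <- min(round(overlapFrac * sz), length(assocGenes), sz)
      ov <- if (nOv > 0) sample(assocGenes, nOv) else character()
      if (sz - nOv > length(nonAssoc))
        stop("set size exceeds the non-planted background")
      rest <- sample(nonAssoc, sz - nOv)
      c(ov, rest)
    })
    names(sets) <- setNames
    GeneSetCollection(sets, background)
  })
}

#' Plant post-treatment outcomes in a cohort
#'
#' Adds week-8 follow-up rows for (a subset of) the cases: the week-8 PANSS
#' positive score is the baseline score minus a linear function of the
#' baseline principal-gradient features (`features %*% weights`) plus
#' Gaussian noise, rounded and clipped to the instrument range (floor 7).
#' Negative and total scores improve proportionally.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param weights per-node outcome weights (length = node count).
#' @param noiseSd SD of the outcome noise.
#' @param seed integer RNG seed.
#' @param features optional subject x node baseline feature matrix with
#'   subject ids as rownames; when `NULL` the aligned principal-gradient
#'   scores are computed via [cohortGradients()].
#' @param subset case ids to follow up (default: all cases).
#' @return The cohort with week-8 subject rows appended and
#'   `truth$outcomeWeights` recorded.
#' @export
genOutcomes <- function(cohort, weights, noiseSd = 1, seed = 1L,
                        features = NULL, subset = NULL) {
  subj <- subjectTable(cohort)
  nNodes <- nrow(nodePartition(cohort))
  if (length(weights) != nNodes)
    stop("weights length must equal the node count")
  if (is.null(features))
    features <- cohortGradients(cohort)$g1
  cases <- subj$id[subj$group == "case" & subj$timepoint == "baseline"]
  subset <- subset %||% cases
  if (!all(subset %in% cases)) stop("subset must name baseline cases")
  withSeed(seed, {
    delta <- drop(features[subset, , drop = FALSE] %*% weights)
    base <- subj[match(subset, subj$id), ]
    clip <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)
    wk8 <- base
    wk8$timepoint <- "week8"
    wk8$panss_pos <- clip(base$panss_pos - delta +
                            stats::rnorm(length(subset), sd = noiseSd), 7, 49)
    wk8$panss_neg <- clip(base$panss_neg - 0.5 * delta +
                            stats::rnorm(length(subset), sd = noiseSd), 7, 49)
    gen8 <- clip((base$panss_total - base$panss_pos - base$panss_neg) -
                   0.5 * delta +
                   stats::rnorm(length(subset), sd = noiseSd), 16, 112)
    wk8$panss_total <- wk8$panss_pos + wk8$panss_neg + gen8
    truth <- plantedTruth(cohort)
    truth$outcomeWeights <- weights
    truth$outcomeNoiseSd <- noiseSd
    truth$followedUp <- subset
    initialize(cohort, subjects = rbind(subj, wk8), truth = truth)
  })
}
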