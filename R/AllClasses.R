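#' @import methods
NULL

# ---------------------------------------------------------------- GradientSet

#' GradientSet: connectome gradient components for one subject or group
#'
#' Holds the retained diffusion-embedding components ("gradients") of one
#' connectivity matrix: a node x k score matrix, the corresponding nontrivial
#' eigenvalues, and each component's explained ratio (its eigenvalue's share
#' of the positive nontrivial spectrum).
#'
#' @slot components numeric matrix, nodes x k gradient scores.
#' @slot eigenvalues numeric, length k, nontrivial eigenvalues in decreasing
#'   order.
#' @slot explainedRatio numeric, length k, in `[0, 1]`, non-increasing.
#' @slot nodeIds character node labels.
#' @export
setClass("GradientSet",
  representation(components = "matrix", eigenvalues = "numeric",
                 explainedRatio = "numeric", nodeIds = "character"),
  validity = function(object) {
    k <- ncol(object@components)
    msg <- character()
    if (length(object@eigenvalues) != k)
      msg <- c(msg, "eigenvalues length must equal ncol(components)")
    if (length(object@explainedRatio) != k)
      msg <- c(msg, "explainedRatio length must equal ncol(components)")
    if (length(object@nodeIds) != nrow(object@components))
      msg <- c(msg, "nodeIds length must equal nrow(components)")
    er <- object@explainedRatio
    if (length(er)) {
      if (any(er < -1e-8) || any(er > 1 + 1e-8))
        msg <- c(msg, "explainedRatio must lie in [0, 1]")
      if (is.unsorted(rev(er), strictly = FALSE) && any(diff(er) > 1e-8))
        msg <- c(msg, "explainedRatio must be non-increasing")
      if (sum(er) > 1 + 1e-6)
        msg <- c(msg, "explainedRatio must sum to at most 1")
      if (any(diff(object@eigenvalues) > 1e-8))
        msg <- c(msg, "eigenvalues must be in decreasing order")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "GradientSet", function(object) {
  cat("GradientSet:", nrow(object@components), "nodes,",
      ncol(object@components), "gradients\n")
  cat("  explained ratio:",
      paste(sprintf("%.3f", object@explainedRatio), collapse = " "), "\n")
})

#' @describeIn GradientSet node x k matrix of gradient scores
#' @param x,object a `GradientSet`
#' @export
setGeneric("gradientComponents", function(x) standardGeneric("gradientComponents"))
#' @rdname GradientSet
#' @export
setMethod("gradientComponents", "GradientSet", function(x) x@components)

#' @describeIn GradientSet scores of a single gradient component
#' @param component 1-based component index
#' @export
setGeneric("gradientScores", function(x, component = 1L) standardGeneric("gradientScores"))
#' @rdname GradientSet
#' @export
setMethod("gradientScores", "GradientSet", function(x, component = 1L) {
  stats::setNames(x@components[, component], x@nodeIds)
})

#' @describeIn GradientSet per-component explained ratios
#' @export
setGeneric("explainedRatio", function(x) standardGeneric("explainedRatio"))
#' @rdname GradientSet
#' @export
setMethod("explainedRatio", "GradientSet", function(x) x@explainedRatio)

#' @describeIn GradientSet node labels
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname GradientSet
#' @export
setMethod("nodeIds", "GradientSet", function(x) x@nodeIds)

# --------------------------------------------------------------- GroupStatMap

#' GroupStatMap: per-node covariate-adjusted group comparison
#'
#' Per-node t, z (signed normal quantile of the two-sided t p-value), p, and
#' Cohen's d for the group contrast of a GLM with nuisance covariates.
#'
#' @slot t,z,p,d numeric per-node statistics.
#' @slot df numeric residual degrees of freedom.
#' @slot contrast character label, e.g. `"case-control"`.
#' @slot nodeIds character node labels.
#' @export
setClass("GroupStatMap",
  representation(t = "numeric", z = "numeric", p = "numeric", d = "numeric",
                 df = "numeric", contrast = "character", nodeIds = "character"),
  validity = function(object) {
    n <- length(object@t)
    msg <- character()
    if (any(lengths(list(object@z, object@p, object@d, object@nodeIds)) != n))
      msg <- c(msg, "t, z, p, d, nodeIds must have equal length")
    if (any(object@p < 0 | object@p > 1))
      msg <- c(msg, "p must lie in [0, 1]")
    if (any(sign(object@t) * sign(object@d) < 0))
      msg <- c(msg, "sign(t) must equal sign(d)")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "GroupStatMap", function(object) {
  cat("GroupStatMap (", object@contrast, "): ", length(object@t),
      " nodes, df = ", object@df, "\n", sep = "")
  cat("  t range: [", sprintf("%.2f", min(object@t)), ", ",
      sprintf("%.2f", max(object@t)), "]\n", sep = "")
})

#' @describeIn GroupStatMap per-node statistics as a data.frame
#' @param x,object a `GroupStatMap`
#' @export
setGeneric("statTable", function(x) standardGeneric("statTable"))
#' @rdname GroupStatMap
#' @export
setMethod("statTable", "GroupStatMap", function(x) {
  data.frame(node = x@nodeIds, t = x@t, z = x@z, p = x@p, d = x@d,
             stringsAsFactors = FALSE)
})

#' @describeIn GroupStatMap the signed z map (consumed by decoding and PLS)
#' @export
setGeneric("zMap", function(x) standardGeneric("zMap"))
#' @rdname GroupStatMap
#' @export
setMethod("zMap", "GroupStatMap", function(x) stats::setNames(x@z, x@nodeIds))

# -------------------------------------------------------------- TopologyCurve

#' TopologyCurve: small-world metrics across a sparsity range
#'
#' Normalized clustering coefficient (gamma), normalized characteristic path
#' length (lambda) and small-worldness (sigma = gamma/lambda) at each
#' sparsity, plus their trapezoid AUCs (aGamma, aLambda, aSigma).
#'
#' @slot sparsities ordered sparsity levels in (0, 1).
#' @slot gamma,lambda,sigma numeric per-sparsity curves.
#' @slot aGamma,aLambda,aSigma numeric AUCs.
#' @export
setClass("TopologyCurve",
  representation(sparsities = "numeric", gamma = "numeric", lambda = "numeric",
                 sigma = "numeric", aGamma = "numeric", aLambda = "numeric",
                 aSigma = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@sparsities)
    if (any(lengths(list(object@gamma, object@lambda, object@sigma)) != n))
      msg <- c(msg, "curves must match sparsities in length")
    if (any(object@sparsities <= 0 | object@sparsities >= 1))
      msg <- c(msg, "sparsities must lie in (0, 1)")
    if (max(abs(object@sigma - object@gamma / object@lambda)) > 1e-10)
      msg <- c(msg, "sigma must equal gamma/lambda pointwise")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "TopologyCurve", function(object) {
  cat("TopologyCurve over", length(object@sparsities), "sparsities:",
      sprintf("aGamma=%.3f aLambda=%.3f aSigma=%.3f",
              object@aGamma, object@aLambda, object@aSigma), "\n")
})

#' @describeIn TopologyCurve named vector of the three AUCs
#' @param x,object a `TopologyCurve`
#' @export
setGeneric("topologyAUC", function(x) standardGeneric("topologyAUC"))
#' @rdname TopologyCurve
#' @export
setMethod("topologyAUC", "TopologyCurve", function(x) {
  c(aGamma = x@aGamma, aLambda = x@aLambda, aSigma = x@aSigma)
})

# ------------------------------------------------------------------- PLSModel

#' PLSModel: partial least squares linking expression to a spatial map
#'
#' @slot scores regions x k component score matrix.
#' @slot weights genes x k x-weight matrix (gene weights).
#' @slot covarExplained per-component fraction of y-variance explained,
#'   non-increasing after component sorting.
#' @slot y the per-region response map the model was fit to.
#' @slot geneIds,regionIds character labels.
#' @export
setClass("PLSModel",
  representation(scores = "matrix", weights = "matrix",
                 covarExplained = "numeric", y = "numeric",
                 geneIds = "character", regionIds = "character"),
  validity = function(object) {
    msg <- character()
    k <- ncol(object@scores)
    if (ncol(object@weights) != k || length(object@covarExplained) != k)
      msg <- c(msg, "scores, weights, covarExplained disagree on k")
    if (length(object@y) != nrow(object@scores))
      msg <- c(msg, "y length must equal nrow(scores)")
    ce <- object@covarExplained
    if (any(ce < -1e-10 | ce > 1 + 1e-10))
      msg <- c(msg, "covarExplained must lie in [0, 1]")
    if (any(diff(ce) > 1e-10))
      msg <- c(msg, "covarExplained must be non-increasing")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", nrow(object@scores), "regions,", nrow(object@weights),
      "genes,", ncol(object@scores), "components\n")
  cat("  y-variance explained:",
      paste(sprintf("%.1f%%", 100 * object@covarExplained), collapse = " "), "\n")
})

#' @describeIn PLSModel region x component score matrix
#' @param x,object a `PLSModel`
#' @export
setGeneric("plsScores", function(x) standardGeneric("plsScores"))
#' @rdname PLSModel
#' @export
setMethod("plsScores", "PLSModel", function(x) x@scores)

#' @describeIn PLSModel gene x component weight matrix
#' @export
setGeneric("plsWeights", function(x) standardGeneric("plsWeights"))
#' @rdname PLSModel
#' @export
setMethod("plsWeights", "PLSModel", function(x) x@weights)

#' @describeIn PLSModel per-component explained fraction of y variance
#' @export
setGeneric("covarExplained", function(x) standardGeneric("covarExplained"))
#' @rdname PLSModel
#' @export
setMethod("covarExplained", "PLSModel", function(x) x@covarExplained)

# -------------------------------------------------------- SpinPermutationSet

#' SpinPermutationSet: parcel reassignments from random sphere rotations
#'
#' Each row is the reassignment produced by one random rotation of the parcel
#' sphere: entry `assignments[i, j]` is the source parcel whose value a spun
#' map places at parcel `j`. Shared by every spin-corrected spatial test.
#'
#' @slot assignments integer matrix, nPerm x parcels.
#' @slot nPerm integer number of permutations.
#' @slot seed integer seed the set was generated from.
#' @slot hemisphere character per-parcel hemisphere labels.
#' @export
setClass("SpinPermutationSet",
  representation(assignments = "matrix", nPerm = "integer", seed = "integer",
                 hemisphere = "character"),
  validity = function(object) {
    msg <- character()
    p <- ncol(object@assignments)
    if (nrow(object@assignments) != object@nPerm)
      msg <- c(msg, "assignments must have nPerm rows")
    if (length(object@hemisphere) != p)
      msg <- c(msg, "hemisphere must label every parcel")
    a <- object@assignments
    if (any(a < 1L) || any(a > p))
      msg <- c(msg, "assignments must be valid parcel indices")
    if (any(object@hemisphere[as.vector(a)] !=
            rep(object@hemisphere, each = nrow(a))))
      msg <- c(msg, "assignments must preserve hemisphere membership")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SpinPermutationSet", function(object) {
  cat("SpinPermutationSet:", object@nPerm, "spins x",
      ncol(object@assignments), "parcels (seed", object@seed, ")\n")
})

#' @describeIn SpinPermutationSet the nPerm x parcel reassignment matrix
#' @param x,object a `SpinPermutationSet`
#' @export
setGeneric("spinAssignments", function(x) standardGeneric("spinAssignments"))
#' @rdname SpinPermutationSet
#' @export
setMethod("spinAssignments", "SpinPermutationSet", function(x) x@assignments)

# ------------------------------------------------------------ SyntheticCohort

#' SyntheticCohort: simulated two-group resting-state cohort
#'
#' Per-subject node x time series drawn from a latent-gradient factor model,
#' a subject table with demographics and symptom scores, a 7-network node
#' partition, spherical parcel centroids, and the planted ground truth.
#'
#' @slot subjects data.frame with id, group, age, sex, fd, onset_age,
#'   panss_pos, panss_neg, panss_total, timepoint.
#' @slot timeseries named list of node x time matrices (baseline scans).
#' @slot partition data.frame with columns node, network.
#' @slot sphere data.frame with columns parcel, x, y, z, hemisphere.
#' @slot truth list of planted effects (latent axis, affected nodes,
#'   compression, generator parameters, outcome weights when planted).
#' @export
setClass("SyntheticCohort",
  representation(subjects = "data.frame", timeseries = "list",
                 partition = "data.frame", sphere = "data.frame",
                 truth = "list"),
  validity = function(object) {
    msg <- character()
    dims <- vapply(object@timeseries, nrow, 0L)
    if (length(unique(dims)) > 1L)
      msg <- c(msg, "all subjects must share the node count")
    if (length(dims) && nrow(object@partition) != dims[1L])
      msg <- c(msg, "partition must label every node")
    base <- object@subjects[object@subjects$timepoint == "baseline", ]
    if (!all(base$id %in% names(object@timeseries)))
      msg <- c(msg, "every baseline subject needs a time series")
    if (any(base$fd <= 0)) msg <- c(msg, "fd must be positive")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SyntheticCohort", function(object) {
  base <- object@subjects[object@subjects$timepoint == "baseline", ]
  cat("SyntheticCohort:", sum(base$group == "case"), "cases,",
      sum(base$group == "control"), "controls,",
      nrow(object@partition), "nodes\n")
})

#' @describeIn SyntheticCohort subject table
#' @param x,object a `SyntheticCohort`
#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))
#' @rdname SyntheticCohort
#' @export
setMethod("subjectTable", "SyntheticCohort", function(x) x@subjects)

#' @describeIn SyntheticCohort named list of node x time matrices
#' @export
setGeneric("timeseriesList", function(x) standardGeneric("timeseriesList"))
#' @rdname SyntheticCohort
#' @export
setMethod("timeseriesList", "SyntheticCohort", function(x) x@timeseries)

#' @describeIn SyntheticCohort node -> network partition
#' @export
setGeneric("nodePartition", function(x) standardGeneric("nodePartition"))
#' @rdname SyntheticCohort
#' @export
setMethod("nodePartition", "SyntheticCohort", function(x) x@partition)

#' @describeIn SyntheticCohort parcel sphere (centroids + hemisphere)
#' @export
setGeneric("parcelSphere", function(x) standardGeneric("parcelSphere"))
#' @rdname SyntheticCohort
#' @export
setMethod("parcelSphere", "SyntheticCohort", function(x) x@sphere)

#' @describeIn SyntheticCohort planted ground truth
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))
#' @rdname SyntheticCohort
#' @export
setMethod("plantedTruth", "SyntheticCohort", function(x) x@truth)

# ---------------------------------------------------------- GeneSetCollection

#' GeneSetCollection: named gene sets over a background universe
#'
#' @slot sets named list of character member vectors (deduplicated, restricted
#'   to the background).
#' @slot background character universe of gene ids.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", background = "character"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@sets)) && length(object@sets))
      msg <- c(msg, "sets must be named")
    bad <- vapply(object@sets,
                  function(s) !all(s %in% object@background), TRUE)
    if (any(bad))
      msg <- c(msg, paste("set members outside background:",
                          paste(names(object@sets)[bad], collapse = ", ")))
    if (anyDuplicated(object@background))
      msg <- c(msg, "background must be duplicate-free")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets over",
      length(object@background), "background genes\n")
})

#' @describeIn GeneSetCollection named list of member vectors
#' @param x,object a `GeneSetCollection`
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname GeneSetCollection
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection the background universe
#' @export
setGeneric("geneBackground", function(x) standardGeneric("geneBackground"))
#' @rdname GeneSetCollection
#' @export
setMethod("geneBackground", "GeneSetCollection", function(x) x@background)

#' Construct a GeneSetCollection
#'
#' Members are deduplicated and harmonized to the background by
#' case-insensitive exact match (no alias resolution).
#'
#' @param sets named list of character vectors.
#' @param background character universe of gene ids.
#' @return A [GeneSetCollection-class] object.
#' @export
GeneSetCollection <- function(sets, background) {
  background <- unique(as.character(background))
  if (!length(background)) stop("background must be non-empty")
  lut <- stats::setNames(background, toupper(background))
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    unname(lut[toupper(s)][!is.na(lut[toupper(s)])])
  })
  new("GeneSetCollection", sets = sets, background = background)
}

# -------------------------------------------------------------- SvrPrediction

#' SvrPrediction: leave-one-out SVR outcome prediction
#'
#' @slot predicted,observed per-subject outcome values.
#' @slot r Pearson correlation of predicted and observed.
#' @slot mse mean squared error.
#' @slot pPermR,pPermMse permutation p-values (NA until
#'   [permutationValidate()] is run).
#' @slot weights per-feature linear SVR weights from the all-subject fit.
#' @slot networkShare named per-network fraction of absolute weight.
#' @export
setClass("SvrPrediction",
  representation(predicted = "numeric", observed = "numeric", r = "numeric",
                 mse = "numeric", pPermR = "numeric", pPermMse = "numeric",
                 weights = "numeric", networkShare = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@predicted) != length(object@observed))
      msg <- c(msg, "predicted and observed must have equal length")
    if (object@mse < 0) msg <- c(msg, "mse must be non-negative")
    if (length(object@networkShare) &&
        abs(sum(object@networkShare) - 1) > 1e-12)
      msg <- c(msg, "networkShare must sum to 1")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SvrPrediction", function(object) {
  cat("SvrPrediction:", length(object@observed), "subjects, r =",
      sprintf("%.3f", object@r), "mse =", sprintf("%.3f", object@mse), "\n")
  if (!is.na(object@pPermR))
    cat("  permutation p (r):", sprintf("%.4f", object@pPermR),
        " p (mse):", sprintf("%.4f", object@pPermMse), "\n")
})
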