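# Connectome gradient construction: FC -> sparsified normalized-angle
# affinity -> diffusion map embedding -> Procrustes alignment.

#' Pearson functional connectivity matrix
#'
#' Pairwise Pearson correlation between node time series, with the diagonal
#' set to zero (self-connections are excluded throughout).
#'
#' @param ts numeric matrix, nodes x timepoints.
#' @param nodeIds optional node labels; defaults to rownames or `n1..`.
#' @return Symmetric node x node correlation matrix with zero diagonal.
#' @export
fcMatrix <- function(ts, nodeIds = NULL) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3L) stop("need at least 3 timepoints")
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop("constant time series at node(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  nodeIds <- nodeIds %||% rownames(ts) %||% paste0("n", seq_len(nrow(ts)))
  r <- stats::cor(t(ts))
  diag(r) <- 0
  dimnames(r) <- list(nodeIds, nodeIds)
  r
}

#' Normalized-angle transform of cosine similarity
#'
#' Maps cosine similarity into `[0, 1]` via `1 - acos(c)/pi`, so that
#' cosine 1, 0, -1 give 1, 0.5, 0.
#'
#' @param cosine numeric cosine similarities (clipped into `[-1, 1]`).
#' @return Values in `[0, 1]`.
#' @export
normalizedAngle <- function(cosine) {
  1 - acos(pmin(pmax(cosine, -1), 1)) / pi
}

#' Sparsified normalized-angle affinity matrix
#'
#' Per row, retains the `ceiling(density * (n - 1))` largest off-diagonal
#' connections (rank-based; ties at the cutoff are all kept, so the realized
#' density can slightly exceed the nominal one), zeroes the rest, computes
#' cosine similarity between the sparsified row profiles (diagonal excluded),
#' and applies the normalized-angle transform. The result is symmetric with a
#' zero diagonal.
#'
#' @param fc symmetric connectivity matrix from [fcMatrix()].
#' @param density fraction of connections retained per row, in (0, 1).
#' @return Affinity matrix in `[0, 1]` with a `density` attribute.
#' @export
affinityMatrix <- function(fc, density = 0.10) {
  if (density <= 0 || density >= 1) stop("density must lie in (0, 1)")
  checkSymmetric(fc, what = "connectivity matrix")
  n <- nrow(fc)
  k <- ceiling(density * (n - 1L))
  S <- fc
  diag(S) <- -Inf
  thr <- apply(S, 1L, function(row) sort(row, decreasing = TRUE)[k])
  S[S < thr[row(S)]] <- 0
  diag(S) <- 0
  norms <- sqrt(rowSums(S^2))
  if (any(norms == 0))
    stop("row(s) with no retained connections after sparsification: ",
         paste(utils::head(which(norms == 0), 5L), collapse = ", "))
  cosine <- tcrossprod(S) / outer(norms, norms)
  a <- normalizedAngle(cosine)
  diag(a) <- 0
  dimnames(a) <- dimnames(fc)
  attr(a, "density") <- density
  a
}

#' Diffusion map embedding of an affinity matrix
#'
#' Anisotropic normalization `W = D^-alpha A D^-alpha` followed by the
#' row-stochastic transition operator `P = Dw^-1 W`, whose nontrivial right
#' eigenvectors (computed through the conjugate symmetric operator for
#' numerical stability) give the gradient components. With
#' `diffusionTime = 0` components are scaled by `lambda / (1 - lambda)`
#' (automatic diffusion time); otherwise by `lambda^diffusionTime`. The
#' explained ratio of component i is `lambda_i` divided by the sum of the
#' positive nontrivial eigenvalues.
#'
#' @param aff affinity matrix from [affinityMatrix()] (symmetric, non-negative,
#'   zero diagonal, connected on its nonzero entries).
#' @param k number of gradient components to retain.
#' @param alpha anisotropic diffusion parameter; 0.5 approximates the
#'   Laplace-Beltrami operator.
#' @param diffusionTime diffusion time t; 0 selects automatic-time scaling.
#' @return A [GradientSet-class] object.
#' @export
diffusionEmbedding <- function(aff, k = 10L, alpha = 0.5, diffusionTime = 0) {
  checkSymmetric(aff, what = "affinity matrix")
  n <- nrow(aff)
  if (k >= n) stop("k must be smaller than the node count")
  if (any(aff < 0)) stop("affinity values must be non-negative")
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(aff > 0, mode = "undirected"))
  if (comp$no > 1L)
    stop("affinity graph is disconnected (", comp$no,
         " components); increase the retained density")
  ids <- rownames(aff) %||% paste0("n", seq_len(n))
  A <- unname(aff)
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  dW <- rowSums(W)
  S <- W / sqrt(outer(dW, dW))
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  # right eigenvectors of P, normalized so the trivial one is constant 1
  phi <- e$vectors / sqrt(dW)
  psi <- phi / phi[, 1L]
  lamNT <- lam[-1L]
  sc <- if (diffusionTime == 0) lamNT / (1 - lamNT) else lamNT^diffusionTime
  components <- psi[, 1L + seq_len(k), drop = FALSE] *
    rep(sc[seq_len(k)], each = n)
  dimnames(components) <- list(ids, paste0("g", seq_len(k)))
  posSum <- sum(lamNT[lamNT > 0])
  ratio <- if (posSum > 0) pmax(lamNT[seq_len(k)], 0) / posSum
           else rep(0, k)  # no positive nontrivial spectrum: nothing explained
  new("GradientSet", components = components,
      eigenvalues = lamNT[seq_len(k)], explainedRatio = ratio, nodeIds = ids)
}

#' Iterative Procrustes alignment of gradient sets across subjects
#'
#' Aligns each subject's components to a common template by orthogonal
#' rotation/reflection (no scaling). The template starts as the component-wise
#' mean (or a supplied reference) and is recomputed from the aligned sets
#' until the total disparity change falls below `tol` or `nIter` iterations.
#'
#' @param gradients list of [GradientSet-class] objects with identical shape.
#' @param nIter maximum number of template refinement iterations.
#' @param tol convergence tolerance on the total squared disparity.
#' @param reference optional node x k template matrix.
#' @return A list with `gradients` (aligned GradientSets), `template`,
#'   `disparity` (final total squared distance to the template), `history`
#'   (per-iteration disparity, non-increasing) and `iterations`.
#' @export
procrustesAlign <- function(gradients, nIter = 10L, tol = 1e-8,
                            reference = NULL) {
  mats <- lapply(gradients, gradientComponents)
  dims <- vapply(mats, dim, integer(2L))
  if (length(unique(dims[1L, ])) > 1L || length(unique(dims[2L, ])) > 1L)
    stop("all gradient sets must share node count and component count")
  template <- reference %||% Reduce(`+`, mats) / length(mats)
  aligned <- mats
  disparity <- Inf
  history <- numeric()
  for (it in seq_len(nIter)) {
    aligned <- lapply(mats, function(X) {
      s <- svd(crossprod(X, template))
      X %*% (s$u %*% t(s$v))
    })
    newTemplate <- if (is.null(reference))
      Reduce(`+`, aligned) / length(aligned) else reference
    newDisp <- sum(vapply(aligned,
                          function(A) sum((A - newTemplate)^2), 0))
    template <- newTemplate
    history <- c(history, newDisp)
    if (abs(disparity - newDisp) < tol) { disparity <- newDisp; break }
    disparity <- newDisp
  }
  alignedSets <- Map(function(g, A) {
    dimnames(A) <- dimnames(gradientComponents(g))
    initialize(g, components = A)
  }, gradients, aligned)
  list(gradients = alignedSets, template = template,
       disparity = disparity, history = history,
       iterations = length(history))
}

#' Orient the principal gradient by a reference network
#'
#' Flips the sign of one component in every aligned subject (and the
#' template) so that the template's mean score over the nodes of a reference
#' network is positive - by convention the primary-to-transmodal axis points
#' towards the default mode network.
#'
#' @param alignment result of [procrustesAlign()].
#' @param partition data.frame with columns `node`, `network`.
#' @param network reference network label (default `"DMN"`).
#' @param component component to orient.
#' @return The alignment list with consistently oriented components.
#' @export
orientGradient <- function(alignment, partition, network = "DMN",
                           component = 1L) {
  idx <- which(partition$network == network)
  if (!length(idx)) stop("no nodes labeled ", network)
  if (mean(alignment$template[idx, component]) < 0) {
    alignment$template[, component] <- -alignment$template[, component]
    alignment$gradients <- lapply(alignment$gradients, function(g) {
      comps <- gradientComponents(g)
      comps[, component] <- -comps[, component]
      initialize(g, components = comps)
    })
  }
  alignment
}

#' Global metrics of one gradient component
#'
#' @param g a [GradientSet-class].
#' @param component component index (default 1, the principal gradient).
#' @return Named numeric vector: `range` (max - min score), `variance`
#'   (population variance of scores) and `explainedRatio`.
#' @export
globalMetrics <- function(g, component = 1L) {
  if (component > ncol(gradientComponents(g)))
    stop("component exceeds the number of retained gradients")
  s <- gradientScores(g, component)
  c(range = max(s) - min(s),
    variance = mean((s - mean(s))^2),
    explainedRatio = explainedRatio(g)[component])
}

#' Per-subject gradients for a whole cohort
#'
#' Runs FC -> affinity -> diffusion embedding for every baseline scan,
#' aligns subjects by iterative Procrustes rotation, and orients the
#' principal gradient towards the DMN.
#'
#' @param cohort a [SyntheticCohort-class] (or any object with
#'   `timeseriesList`/`nodePartition` methods).
#' @param density,alpha,k,diffusionTime embedding parameters, see
#'   [affinityMatrix()] and [diffusionEmbedding()].
#' @param orient network label used to orient gradient 1, or `NULL` to skip.
#' @return A list with `gradients` (aligned, oriented GradientSets),
#'   `template`, `g1` (subject x node matrix of principal-gradient scores),
#'   `metrics` (per-subject data.frame of global metrics) and `fc`
#'   (per-subject connectivity matrices).
#' @export
cohortGradients <- function(cohort, density = 0.10, alpha = 0.5, k = 10L,
                            diffusionTime = 0, orient = "DMN") {
  tsl <- timeseriesList(cohort)
  fc <- lapply(tsl, fcMatrix)
  grads <- lapply(fc, function(m)
    diffusionEmbedding(affinityMatrix(m, density), k = k, alpha = alpha,
                       diffusionTime = diffusionTime))
  alignment <- procrustesAlign(grads)
  if (!is.null(orient))
    alignment <- orientGradient(alignment, nodePartition(cohort), orient)
  g1 <- t(vapply(alignment$gradients, gradientScores,
                 numeric(nrow(alignment$template)), component = 1L))
  rownames(g1) <- names(tsl)
  metrics <- do.call(rbind, lapply(alignment$gradients, globalMetrics))
  metrics <- data.frame(id = names(tsl), metrics, row.names = NULL,
                        stringsAsFactors = FALSE)
  list(gradients = alignment$gradients, template = alignment$template,
       g1 = g1, metrics = metrics, fc = fc)
}

#' Group-mean principal gradient
#'
#' Averages the subject connectivity matrices within each group and embeds
#' the group-mean connectome. Useful for comparing group-level gradient
#' geometry (e.g. the range contraction of the case group).
#'
#' @inheritParams cohortGradients
#' @return Named list of [GradientSet-class] objects, one per group.
#' @export
groupMeanGradient <- function(cohort, density = 0.10, alpha = 0.5, k = 10L) {
  subj <- subjectTable(cohort)
  base <- subj[subj$timepoint == "baseline", ]
  tsl <- timeseriesList(cohort)
  out <- list()
  for (grp in unique(base$group)) {
    ids <- base$id[base$group == grp]
    fcs <- lapply(tsl[ids], fcMatrix)
    meanFc <- Reduce(`+`, fcs) / length(fcs)
    out[[grp]] <- diffusionEmbedding(affinityMatrix(meanFc, density),
                                     k = k, alpha = alpha)
  }
  out
}
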