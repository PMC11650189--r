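# Spin-permutation spatial nulls and map decoding.

#' Parcel reassignment under one rotation
#'
#' Rotates the left-hemisphere centroids by `rotation` (and by the mirrored
#' rotation for right-hemisphere parcels, preserving hemisphere membership),
#' then maps each rotated parcel to its nearest original centroid within the
#' same hemisphere. Nearest-neighbour reassignment is not a strict
#' permutation: two parcels may map to the same source (the number of such
#' duplicates is returned as an attribute).
#'
#' @param sphere data.frame with `x`, `y`, `z`, `hemisphere` columns
#'   (unit-norm centroids).
#' @param rotation 3 x 3 rotation matrix.
#' @return Integer reassignment vector with a `duplicates` attribute.
#' @export
spinAssignment <- function(sphere, rotation) {
  xyz <- as.matrix(sphere[, c("x", "y", "z")])
  hemi <- as.character(sphere$hemisphere)
  mirror <- diag(c(-1, 1, 1))
  assignment <- integer(nrow(xyz))
  for (h in unique(hemi)) {
    idx <- which(hemi == h)
    R <- if (h == "R") mirror %*% rotation %*% mirror else rotation
    rotated <- xyz[idx, , drop = FALSE] %*% t(R)
    sim <- rotated %*% t(xyz[idx, , drop = FALSE])
    assignment[idx] <- idx[max.col(sim, ties.method = "first")]
  }
  attr(assignment, "duplicates") <-
    length(assignment) - length(unique(assignment))
  assignment
}

#' Generate a spin permutation set
#'
#' Draws `nPerm` uniform random 3-D rotations (QR decomposition of a Gaussian
#' matrix with sign fix and determinant +1) and converts each into a parcel
#' reassignment via [spinAssignment()]. The resulting set is shared by all
#' spin-corrected spatial tests so every map comparison uses the same nulls.
#'
#' @param sphere parcel sphere (see [genSphere()]); centroids must be
#'   pairwise distinct.
#' @param nPerm number of spins (>= 100).
#' @param seed integer RNG seed.
#' @return A [SpinPermutationSet-class].
#' @export
spinPermutations <- function(sphere, nPerm, seed = 1L) {
  if (nPerm < 100L) stop("nPerm must be at least 100")
  xyz <- as.matrix(sphere[, c("x", "y", "z")])
  if (min(stats::dist(xyz)) < 1e-10) stop("duplicate parcel centroids")
  assignments <- withSeed(seed, {
    t(vapply(seq_len(nPerm),
             function(i) as.integer(spinAssignment(sphere, randomRotation())),
             integer(nrow(xyz))))
  })
  new("SpinPermutationSet", assignments = assignments,
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      hemisphere = as.character(sphere$hemisphere))
}

#' Spin-corrected spatial correlation between two parcel maps
#'
#' The observed correlation is compared against the null correlations
#' obtained by spinning map `a` (value multiset preserved, only positions
#' reassigned). The add-one p-value never reaches 0; `two.sided` (default)
#' compares absolute correlations.
#'
#' @param a,b per-parcel numeric maps.
#' @param spins a [SpinPermutationSet-class] matching the parcel count.
#' @param method `"pearson"` or `"spearman"`.
#' @param alternative `"two.sided"` (|null| >= |obs|) or `"greater"`.
#' @return Named numeric vector `c(r, p_spin)`.
#' @export
spinCorr <- function(a, b, spins, method = c("pearson", "spearman"),
                     alternative = c("two.sided", "greater")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  A <- spinAssignments(spins)
  if (length(a) != ncol(A) || length(b) != ncol(A))
    stop("map length must match the spin set's parcel count")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero-variance map")
  rObs <- stats::cor(a, b, method = method)
  spun <- matrix(a[t(A)], nrow = ncol(A))  # parcels x nPerm
  rNull <- drop(stats::cor(spun, b, method = method))
  p <- addOneP(rNull, rObs,
               side = if (alternative == "two.sided") "two.sided" else "greater")
  c(r = rObs, p_spin = p)
}

#' Decode a target map against a collection of term maps
#'
#' Spin-corrected correlation of the target with every term map, ranked by
#' correlation with BH-FDR across terms. With `split = TRUE` the target z map
#' is thresholded at 0 into positive (`pmax(z, 0)`) and negative
#' (`pmax(-z, 0)`) maps that are decoded separately, mirroring
#' increase/decrease decoding of case-control maps.
#'
#' @param target per-parcel numeric map (a z map when `split = TRUE`).
#' @param termMaps term x parcel numeric matrix with term rownames.
#' @param spins a [SpinPermutationSet-class].
#' @param method correlation method passed to [spinCorr()].
#' @param split decode positive/negative halves separately.
#' @return data.frame with `term`, `r`, `p_spin`, `fdr_p` (and `map` when
#'   `split = TRUE`), ordered by decreasing r with stable term-label ties.
#' @export
decodeMaps <- function(target, termMaps, spins,
                       method = c("pearson", "spearman"), split = FALSE) {
  method <- match.arg(method)
  if (!nrow(termMaps)) stop("empty term-map collection")
  if (is.null(rownames(termMaps)))
    rownames(termMaps) <- paste0("term", seq_len(nrow(termMaps)))
  decodeOne <- function(tgt, label) {
    res <- t(apply(termMaps, 1L, function(tm)
      spinCorr(tgt, tm, spins, method = method)))
    out <- data.frame(term = rownames(termMaps), r = res[, "r"],
                      p_spin = res[, "p_spin"], row.names = NULL,
                      stringsAsFactors = FALSE)
    out$fdr_p <- stats::p.adjust(out$p_spin, method = "BH")
    out <- out[order(-out$r, out$term), ]
    if (!is.null(label)) out <- cbind(map = label, out)
    rownames(out) <- NULL
    out
  }
  if (!split) return(decodeOne(target, NULL))
  rbind(decodeOne(pmax(target, 0), "positive"),
        decodeOne(pmax(-target, 0), "negative"))
}
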