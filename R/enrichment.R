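# Permutation overlap tests and preranked GSEA for PLS gene lists.

#' Permutation test of the mean PLS-Z over shared genes
#'
#' The observed statistic is the mean PLS-Z of the genes shared between the
#' PLS gene list and the target set. The null resamples gene subsets of the
#' same size as the observed overlap from the background and recomputes the
#' mean Z, giving a one-sided add-one p (the direction chosen by `side`).
#' An empty overlap returns `n_overlap = 0`, `p_perm = 1` with the attribute
#' `empty = TRUE`.
#'
#' @param plsGenes character gene list (e.g. the PLS1+ or PLS1- genes).
#' @param targetSet character target gene set (disorder genes etc.).
#' @param background character gene universe.
#' @param plsZ named per-gene Z scores covering the background.
#' @param nPerm permutations.
#' @param seed integer RNG seed.
#' @param side `"greater"` (mean Z above chance) or `"less"`.
#' @return data.frame row: `n_overlap`, `mean_pls_z`, `p_perm`.
#' @export
overlapPermTest <- function(plsGenes, targetSet, background, plsZ,
                            nPerm = 1000L, seed = 1L,
                            side = c("greater", "less")) {
  side <- match.arg(side)
  targetSet <- intersect(targetSet, background)
  if (!length(targetSet)) stop("target set does not intersect the background")
  if (length(targetSet) >= length(background))
    stop("target set must be smaller than the background")
  shared <- intersect(intersect(plsGenes, targetSet), names(plsZ))
  if (!length(shared)) {
    out <- data.frame(n_overlap = 0L, mean_pls_z = NA_real_, p_perm = 1)
    attr(out, "empty") <- TRUE
    return(out)
  }
  obs <- mean(plsZ[shared])
  m <- length(shared)
  zBg <- plsZ[intersect(names(plsZ), background)]
  nullStats <- withSeed(seed, vapply(seq_len(nPerm), function(b)
    mean(zBg[sample.int(length(zBg), m)]), 0))
  data.frame(n_overlap = m, mean_pls_z = obs,
             p_perm = addOneP(nullStats, obs, side = side))
}

#' Marker-set overlap permutation tests
#'
#' For each marker set (e.g. the seven cortical cell types), the observed
#' statistic is the overlap count with the gene list; the null resamples
#' random gene lists of equal size from the background. One-sided add-one p
#' (greater), BH-FDR across the sets.
#'
#' @param geneList character gene list to test (must intersect the
#'   background).
#' @param markerSets a [GeneSetCollection-class].
#' @param nPerm permutations.
#' @param seed integer RNG seed.
#' @return data.frame with `set_name`, `set_size`, `n_overlap`, `p_perm`,
#'   `fdr_p`.
#' @export
markerOverlapTest <- function(geneList, markerSets, nPerm = 1000L,
                              seed = 1L) {
  background <- geneBackground(markerSets)
  geneList <- intersect(geneList, background)
  if (!length(geneList)) stop("gene list is disjoint from the background")
  sets <- geneSets(markerSets)
  m <- length(geneList)
  obs <- vapply(sets, function(s) length(intersect(geneList, s)), 0L)
  nullCounts <- withSeed(seed, {
    vapply(seq_len(nPerm), function(b) {
      draw <- background[sample.int(length(background), m)]
      vapply(sets, function(s) length(intersect(draw, s)), 0L)
    }, integer(length(sets)))
  })
  nullCounts <- matrix(nullCounts, nrow = length(sets))
  p <- vapply(seq_along(sets),
              function(i) addOneP(nullCounts[i, ], obs[i], side = "greater"),
              0)
  data.frame(set_name = names(sets),
             set_size = lengths(sets), n_overlap = unname(obs),
             p_perm = p, fdr_p = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
.gseaES <- function(hit, scores, weightP) {
  w <- abs(scores)^weightP
  nMiss <- sum(!hit)
  if (!any(hit) || !nMiss) stop("set must hit some but not all ranked genes")
  inc <- ifelse(hit, w / sum(w[hit]), -1 / nMiss)
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Preranked gene set enrichment (GSEA running sum)
#'
#' Walks the ranked gene list accumulating `|score|^weightP` (normalized) at
#' set hits and a uniform decrement at misses; the enrichment score ES is the
#' running sum's maximum deviation from zero (signed). The null permutes gene
#' labels (random hit positions of the same size); NES is ES divided by the
#' mean |null ES| of matching sign, and the add-one p is computed among
#' same-sign nulls. A top-loaded set gives ES > 0, a bottom-loaded set
#' ES < 0.
#'
#' @param rankedGenes character gene ids in ranking order (e.g. by
#'   decreasing PLS Z).
#' @param scores numeric ranking scores aligned with `rankedGenes`.
#' @param targetSet character gene set (>= 3 genes in the ranking).
#' @param nPerm permutations.
#' @param seed integer RNG seed.
#' @param weightP hit-weight exponent; 0 gives the classic unweighted KS
#'   statistic (invariant to monotone rescaling of scores).
#' @return data.frame row: `es`, `nes`, `p_perm`.
#' @export
gseaTest <- function(rankedGenes, scores, targetSet, nPerm = 1000L,
                     seed = 1L, weightP = 1) {
  if (length(rankedGenes) != length(scores))
    stop("scores must align with rankedGenes")
  hit <- rankedGenes %in% targetSet
  nHit <- sum(hit)
  if (nHit < 3L) stop("target set must hit at least 3 ranked genes")
  es <- .gseaES(hit, scores, weightP)
  n <- length(rankedGenes)
  nullEs <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    h <- logical(n)
    h[sample.int(n, nHit)] <- TRUE
    .gseaES(h, scores, weightP)
  }, 0))
  sameSign <- nullEs[sign(nullEs) == sign(es)]
  nes <- if (length(sameSign)) es / mean(abs(sameSign)) else sign(es) * abs(es)
  p <- (1 + sum(abs(sameSign) >= abs(es))) / (1 + length(sameSign))
  data.frame(es = es, nes = nes, p_perm = p)
}
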