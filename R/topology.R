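# Small-world topology: binarized graphs over a sparsity range, normalized
# clustering / path length against degree-preserving nulls, and AUCs.

#' Binarize a connectivity matrix at a target sparsity
#'
#' Keeps the `s` fraction of strongest off-diagonal edges (by value,
#' symmetric); ties at the cutoff are all kept, so the realized density can
#' slightly exceed `s`.
#'
#' @param fc symmetric connectivity matrix.
#' @param s sparsity (edge density) in (0, 1).
#' @return An undirected, unweighted igraph graph over the nodes.
#' @export
binarizeAtSparsity <- function(fc, s) {
  if (s <= 0 || s >= 1) stop("sparsity must lie in (0, 1)")
  checkSymmetric(fc, what = "connectivity matrix")
  n <- nrow(fc)
  vals <- fc[upper.tri(fc)]
  nEdges <- max(1L, round(s * length(vals)))
  thr <- sort(vals, decreasing = TRUE)[nEdges]
  adj <- fc >= thr
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Clustering coefficient and characteristic path length
#'
#' C is the mean over nodes of the local clustering coefficient (triangle
#' density among neighbours; nodes with fewer than two neighbours contribute
#' 0). L is the mean shortest-path length over connected pairs; on a
#' disconnected graph it is computed within the largest connected component
#' and the result carries `attr(, "disconnected") = TRUE`.
#'
#' @param g an igraph undirected graph with at least 3 nodes.
#' @return Named numeric vector `c(C, L)`.
#' @export
graphMetrics <- function(g) {
  if (igraph::vcount(g) < 3L) stop("graph must have at least 3 nodes")
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  C <- mean(loc)
  disconnected <- !igraph::is_connected(g)
  if (disconnected) {
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  L <- igraph::mean_distance(g, directed = FALSE)
  out <- c(C = C, L = L)
  attr(out, "disconnected") <- disconnected
  out
}

#' Degree-preserving random reference graph
#'
#' Maslov-Sneppen double-edge swaps: repeatedly rewires edge pairs while
#' preserving every node's degree, avoiding self-loops and multi-edges.
#'
#' @param g an igraph undirected graph.
#' @param nSwaps number of attempted swaps (default `10 * ecount(g)`);
#'   0 returns the graph unchanged.
#' @param seed integer RNG seed.
#' @return A rewired igraph graph with the same degree sequence.
#' @export
randomReference <- function(g, nSwaps = 10L * igraph::ecount(g), seed = 1L) {
  if (nSwaps == 0L) return(g)
  if (igraph::ecount(g) < 2L) stop("need at least 2 edges to swap")
  withSeed(seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = nSwaps)))
}

#' Small-world curves and AUCs over a sparsity range
#'
#' At each sparsity: `gamma = C / mean(C_rand)`, `lambda = L / mean(L_rand)`
#' over `nRand` degree-preserving null graphs, and `sigma = gamma / lambda`.
#' AUCs are trapezoid integrals over the sparsity range.
#'
#' @param fc symmetric connectivity matrix.
#' @param sparsities ordered sparsity levels (default 0.05 to 0.50 by 0.05,
#'   the conventional window for binarized brain graphs).
#' @param nRand number of null graphs per sparsity.
#' @param seed integer RNG seed.
#' @return A [TopologyCurve-class].
#' @export
smallWorldCurve <- function(fc, sparsities = seq(0.05, 0.50, by = 0.05),
                            nRand = 20L, seed = 1L) {
  vals <- withSeed(seed, vapply(sparsities, function(s) {
    g <- binarizeAtSparsity(fc, s)
    m <- graphMetrics(g)
    nulls <- vapply(seq_len(nRand), function(b) {
      graphMetrics(randomReference(g, seed = sample.int(2^30, 1L)))
    }, numeric(2L))
    c(gamma = m[["C"]] / mean(nulls["C", ]),
      lambda = m[["L"]] / mean(nulls["L", ]))
  }, numeric(2L)))
  gamma <- vals["gamma", ]
  lambda <- vals["lambda", ]
  sigma <- gamma / lambda
  new("TopologyCurve", sparsities = sparsities, gamma = gamma,
      lambda = lambda, sigma = sigma,
      aGamma = trapezoidAUC(sparsities, gamma),
      aLambda = trapezoidAUC(sparsities, lambda),
      aSigma = trapezoidAUC(sparsities, sigma))
}

#' Correlate global gradient metrics with topology AUCs
#'
#' Pearson r and p for every (gradient metric, AUC metric) pair across
#' subjects, with BH-FDR over the whole table.
#'
#' @param gradientMetrics per-subject data.frame (e.g. from
#'   [cohortGradients()]`$metrics`) with columns `range`, `variance`,
#'   `explainedRatio`.
#' @param topologyAUCs per-subject data.frame with columns `aGamma`,
#'   `aLambda`, `aSigma` (rows aligned with `gradientMetrics`).
#' @return data.frame with `gradient_metric`, `topology_metric`, `r`, `p`,
#'   `fdr_p`.
#' @export
gradientTopologyCorr <- function(gradientMetrics, topologyAUCs) {
  gm <- c("range", "variance", "explainedRatio")
  tm <- c("aGamma", "aLambda", "aSigma")
  if (nrow(gradientMetrics) < 3L) stop("need at least 3 subjects")
  grid <- expand.grid(gradient_metric = gm, topology_metric = tm,
                      stringsAsFactors = FALSE)
  res <- t(mapply(function(a, b) {
    clinicalCorr(gradientMetrics[[a]], topologyAUCs[[b]])[c("r", "p")]
  }, grid$gradient_metric, grid$topology_metric))
  grid$r <- unname(res[, 1L])
  grid$p <- unname(res[, 2L])
  grid$fdr_p <- stats::p.adjust(grid$p, method = "BH")
  grid
}
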