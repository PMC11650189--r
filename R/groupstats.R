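# Covariate-adjusted group inference on gradient maps and global metrics.

# vectorized OLS t-statistics for one coefficient across many response columns
.glmT <- function(y, X, coef) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design matrix (collinear covariates?)")
  Q <- qr.Q(qrX)
  R <- qr.R(qrX)
  coefs <- backsolve(R, crossprod(Q, y))
  res <- y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  vcovDiag <- chol2inv(R)[coef, coef]
  se <- sqrt(sigma2 * vcovDiag)
  b <- coefs[coef, ]
  # responses fit exactly (zero residual variance) carry no information
  tss <- colSums(sweep(y, 2L, colMeans(y))^2)
  degenerate <- colSums(res^2) <= 1e-10 * pmax(tss, .Machine$double.eps)
  t <- ifelse(!degenerate & se > 0, b / se, 0)
  list(t = t, b = b, se = se, df = df)
}

# signed normal quantile of the two-sided t p-value, stable for extreme t
.tToZ <- function(t, df) {
  sign(t) * -stats::qnorm(stats::pt(-abs(t), df, log.p = TRUE), log.p = TRUE)
}

#' Covariate-adjusted group comparison of per-node maps
#'
#' Per node, ordinary least squares of the map value on
#' `[intercept, group, covariates]`; reports the group coefficient's t, its
#' two-sided p, the signed normal-quantile z, and Cohen's
#' `d = t * sqrt(1/n1 + 1/n2)` (covariate-adjusted). Nodes with zero
#' residual variance get t = 0, p = 1.
#'
#' @param y subject x node numeric matrix (rownames = subject ids matching
#'   `subjects$id`, or rows in `subjects` order).
#' @param subjects data.frame with columns `id`, `group` (values `"case"` /
#'   `"control"`), and the covariates.
#' @param covariates covariate column names adjusted for (default age, sex).
#' @param contrast label stored on the result; the t is case minus control.
#' @return A [GroupStatMap-class].
#' @export
glmCompare <- function(y, subjects, covariates = c("age", "sex"),
                       contrast = "case-control") {
  y <- as.matrix(y)
  if (!is.null(rownames(y)))
    subjects <- subjects[match(rownames(y), subjects$id), ]
  if (nrow(y) != nrow(subjects))
    stop("y rows must match the subject table")
  grp <- subjects$group
  if (min(table(grp)) < 3L) stop("each group needs at least 3 subjects")
  dat <- data.frame(.group = as.integer(grp == "case"),
                    subjects[covariates], check.names = FALSE)
  X <- stats::model.matrix(
    stats::reformulate(c(".group", covariates)), data = dat)
  fit <- .glmT(y, X, coef = 2L)
  p <- 2 * stats::pt(-abs(fit$t), fit$df)
  n1 <- sum(grp == "case")
  n2 <- sum(grp == "control")
  d <- fit$t * sqrt(1 / n1 + 1 / n2)
  ids <- colnames(y) %||% paste0("n", seq_len(ncol(y)))
  new("GroupStatMap", t = unname(fit$t), z = unname(.tToZ(fit$t, fit$df)),
      p = unname(p), d = unname(d), df = as.numeric(fit$df),
      contrast = contrast, nodeIds = ids)
}

#' Sex-by-group interaction test
#'
#' Adds the group x sex product term to the group GLM and reports its
#' per-node t and p.
#'
#' @inheritParams glmCompare
#' @return data.frame with columns `node`, `t`, `p` for the interaction term.
#' @export
interactionTest <- function(y, subjects, covariates = c("age", "sex")) {
  y <- as.matrix(y)
  if (!is.null(rownames(y)))
    subjects <- subjects[match(rownames(y), subjects$id), ]
  if (length(unique(subjects$sex)) < 2L)
    stop("sex-by-group interaction is inestimable: sex has a single level")
  dat <- data.frame(.group = as.integer(subjects$group == "case"),
                    subjects[covariates], check.names = FALSE)
  X <- stats::model.matrix(~ .group * sex + age, data = dat)
  fit <- .glmT(y, X, coef = ncol(X))  # interaction is the last column
  data.frame(node = colnames(y) %||% paste0("n", seq_len(ncol(y))),
             t = unname(fit$t), p = 2 * stats::pt(-abs(fit$t), fit$df),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR mask
#'
#' @param p numeric p-values in `[0, 1]` (non-empty).
#' @param q FDR level.
#' @return Logical mask of discoveries under BH step-up control.
#' @export
fdrBH <- function(p, q = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' Permutation cluster-extent correction
#'
#' Thresholds the per-node group comparison at `voxelP`, forms connected
#' components of same-sign supra-threshold nodes on the supplied adjacency,
#' and compares each cluster's extent against the null distribution of the
#' maximum extent obtained by permuting group labels and refitting the GLM.
#' This label-permutation max-statistic scheme is exact under group
#' exchangeability and replaces random-field cluster correction, which
#' requires volumetric smoothness estimates.
#'
#' @inheritParams glmCompare
#' @param adjacency node adjacency: an igraph object or a symmetric logical/
#'   numeric matrix covering all nodes.
#' @param voxelP per-node (cluster-forming) p threshold.
#' @param nPerm number of label permutations (>= 100 unless
#'   `strict = FALSE`).
#' @param seed integer RNG seed.
#' @param strict refuse nPerm < 100 when TRUE (default); otherwise warn.
#' @return data.frame with `cluster_id`, `sign`, `extent`, `cluster_p` and a
#'   `members` attribute (list of node index vectors); zero rows when no node
#'   survives the threshold.
#' @export
clusterCorrect <- function(y, subjects, adjacency, voxelP = 0.001,
                           nPerm = 1000L, seed = 1L,
                           covariates = c("age", "sex"), strict = TRUE) {
  if (nPerm < 100L) {
    if (strict) stop("nPerm below 100 is refused in strict mode")
    warning("nPerm below 100; cluster p-values will be coarse")
  }
  y <- as.matrix(y)
  gAdj <- if (inherits(adjacency, "igraph")) adjacency else
    igraph::graph_from_adjacency_matrix(adjacency != 0, mode = "undirected")
  if (igraph::vcount(gAdj) != ncol(y))
    stop("adjacency must cover all ", ncol(y), " nodes")
  obs <- glmCompare(y, subjects, covariates)
  clusters <- .extractClusters(obs@p, obs@t, voxelP, gAdj)
  if (!nrow(clusters$table)) {
    out <- data.frame(cluster_id = integer(), sign = character(),
                      extent = integer(), cluster_p = numeric())
    attr(out, "members") <- list()
    return(out)
  }
  if (!is.null(rownames(y)))
    subjects <- subjects[match(rownames(y), subjects$id), ]
  nullMax <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    perm <- subjects
    perm$group <- sample(perm$group)
    s <- glmCompare(y, perm, covariates)
    cl <- .extractClusters(s@p, s@t, voxelP, gAdj)
    if (nrow(cl$table)) max(cl$table$extent) else 0L
  }, 0L))
  tab <- clusters$table
  tab$cluster_p <- vapply(tab$extent,
                          function(e) (1 + sum(nullMax >= e)) / (1 + nPerm), 0)
  attr(tab, "members") <- clusters$members
  tab
}

.extractClusters <- function(p, t, voxelP, gAdj) {
  members <- list()
  rows <- list()
  cid <- 0L
  for (sgn in c(1, -1)) {
    idx <- which(p < voxelP & sign(t) == sgn)
    if (!length(idx)) next
    sub <- igraph::induced_subgraph(gAdj, idx)
    comp <- igraph::components(sub)
    for (cc in seq_len(comp$no)) {
      cid <- cid + 1L
      nodes <- idx[comp$membership == cc]
      members[[cid]] <- nodes
      rows[[cid]] <- data.frame(
        cluster_id = cid, sign = if (sgn > 0) "increase" else "decrease",
        extent = length(nodes), stringsAsFactors = FALSE)
    }
  }
  list(table = if (length(rows)) do.call(rbind, rows) else
         data.frame(cluster_id = integer(), sign = character(),
                    extent = integer()),
       members = members)
}

#' k-nearest-neighbour adjacency from spherical centroids
#'
#' Symmetrized kNN graph on parcel centroids; the spatial adjacency used by
#' cluster-extent inference on synthetic spheres.
#'
#' @param sphere data.frame with `x`, `y`, `z` columns.
#' @param k neighbours per parcel.
#' @return igraph undirected graph over the parcels.
#' @export
sphereAdjacency <- function(sphere, k = 6L) {
  xyz <- as.matrix(sphere[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(d)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(k + 1L)]
    cbind(i, nb)
  }))
  igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
}

#' Pearson correlation with a clinical variable
#'
#' Listwise-deletes missing pairs and reports Pearson r with its two-sided p.
#'
#' @param x,y per-subject numeric vectors.
#' @return Named numeric vector `c(r, p, n)`.
#' @export
clinicalCorr <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  if (sum(keep) < 3L) stop("need at least 3 paired non-missing values")
  if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x[keep], y[keep])
  c(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Paired t test with Cohen's d
#'
#' @param pre,post equal-length numeric vectors (n >= 3).
#' @return Named numeric vector `c(t, p, d)` with `d = mean(diff)/sd(diff)`.
#' @export
pairedTTest <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  if (length(pre) < 3L) stop("need at least 3 pairs")
  diffs <- pre - post
  if (stats::sd(diffs) == 0) {
    if (all(diffs == 0)) return(c(t = 0, p = 1, d = 0))
    stop("zero-variance differences")
  }
  tt <- stats::t.test(pre, post, paired = TRUE)
  c(t = unname(tt$statistic), p = tt$p.value,
    d = mean(diffs) / stats::sd(diffs))
}

#' Network composition of significant nodes
#'
#' For each effect sign, the proportion of significant nodes that belongs to
#' each network (proportions sum to 1 within a sign when any node is
#' significant).
#'
#' @param stat a [GroupStatMap-class] giving each node's effect sign.
#' @param mask logical per-node significance mask (e.g. from [fdrBH()] or a
#'   cluster result).
#' @param partition data.frame with columns `node`, `network` labeling all
#'   nodes.
#' @return data.frame with `sign`, `network`, `count`, `proportion`; the
#'   attribute `empty` is TRUE when the mask selects nothing.
#' @export
networkShare <- function(stat, mask, partition) {
  if (length(mask) != length(stat@t))
    stop("mask length must match the stat map")
  if (nrow(partition) != length(mask) || anyNA(partition$network))
    stop("partition must label every node")
  nets <- unique(partition$network)
  grid <- expand.grid(sign = c("increase", "decrease"), network = nets,
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(sg, nw) {
    s <- if (sg == "increase") 1 else -1
    sum(mask & sign(stat@t) == s & partition$network == nw)
  }, grid$sign, grid$network)
  totals <- tapply(grid$count, grid$sign, sum)
  grid$proportion <- ifelse(totals[grid$sign] > 0,
                            grid$count / totals[grid$sign], 0)
  attr(grid, "empty") <- !any(mask)
  grid
}
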