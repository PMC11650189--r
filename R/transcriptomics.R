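# PLS regression linking regional gene expression to a case-control z map,
# spin significance, and bootstrap gene-weight Z ranking.

# center (and optionally scale) columns; guard zero-SD columns
.prepX <- function(X, scale) {
  Xc <- base::scale(X, center = TRUE, scale = scale)
  if (scale && any(!is.finite(Xc)))
    stop("constant gene column(s); cannot z-score")
  Xc
}

# one NIPALS PLS component on centered data; returns weight, scores, loading
.plsComponent <- function(Xd, yd) {
  w <- drop(crossprod(Xd, yd))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("degenerate component: X'y is zero")
  w <- w / nw
  t <- drop(Xd %*% w)
  tt <- sum(t^2)
  list(w = w, t = t, p = drop(crossprod(Xd, t)) / tt, q = sum(yd * t) / tt,
       tt = tt)
}

#' Fit a PLS regression of a spatial map on gene expression
#'
#' NIPALS partial least squares with the regions x genes expression matrix as
#' predictors and the per-region map as the univariate response. Components
#' are sorted by their explained fraction of y variance (non-increasing) and
#' the first component's sign is fixed so that its region scores correlate
#' positively with y.
#'
#' @param X regions x genes numeric matrix.
#' @param y per-region response (e.g. the case-control z map).
#' @param nComponents number of components (<= regions - 2).
#' @param scale z-score the gene columns before fitting (standard for
#'   expression-atlas analyses).
#' @return A [PLSModel-class].
#' @export
plsFit <- function(X, y, nComponents = 2L, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y length must equal the region count")
  if (stats::sd(y) == 0) stop("constant response map")
  if (nComponents > n - 2L) stop("nComponents must be at most regions - 2")
  Xc <- .prepX(X, scale)
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  k <- nComponents
  W <- matrix(0, ncol(X), k)
  Tm <- matrix(0, n, k)
  ve <- numeric(k)
  Xd <- Xc
  yd <- yc
  for (a in seq_len(k)) {
    cp <- .plsComponent(Xd, yd)
    W[, a] <- cp$w
    Tm[, a] <- cp$t
    ve[a] <- cp$q^2 * cp$tt / ssy
    Xd <- Xd - tcrossprod(cp$t, cp$p)
    yd <- yd - cp$q * cp$t
  }
  ord <- order(ve, decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  Tm <- Tm[, ord, drop = FALSE]
  ve <- ve[ord]
  if (stats::cor(Tm[, 1L], yc) < 0) {
    W[, 1L] <- -W[, 1L]
    Tm[, 1L] <- -Tm[, 1L]
  }
  geneIds <- colnames(X) %||% paste0("gene", seq_len(ncol(X)))
  regionIds <- rownames(X) %||% paste0("r", seq_len(n))
  dimnames(W) <- list(geneIds, paste0("PLS", seq_len(k)))
  dimnames(Tm) <- list(regionIds, paste0("PLS", seq_len(k)))
  new("PLSModel", scores = Tm, weights = W, covarExplained = ve,
      y = as.numeric(y), geneIds = geneIds, regionIds = regionIds)
}

#' Spin significance of PLS components
#'
#' Refits the PLS on spun responses and reports, per component, the add-one
#' proportion of null explained-variance fractions at least as large as the
#' observed one. This is the spatial-autocorrelation-preserving test of
#' whether a component's explained covariance exceeds chance.
#'
#' @param model fitted [PLSModel-class].
#' @param X,y the data the model was fit to.
#' @param spins a [SpinPermutationSet-class] over the regions.
#' @param scale must match the original fit.
#' @return Numeric vector of spin p-values, one per component.
#' @export
plsSignificance <- function(model, X, y, spins, scale = TRUE) {
  A <- spinAssignments(spins)
  if (ncol(A) != length(y))
    stop("spin set parcel count must match the region count")
  k <- ncol(plsScores(model))
  obs <- covarExplained(model)
  nullVe <- vapply(seq_len(nrow(A)), function(i) {
    sort(covarExplained(plsFit(X, y[A[i, ]], nComponents = k,
                               scale = scale)),
         decreasing = TRUE)
  }, numeric(k))
  nullVe <- matrix(nullVe, nrow = k)
  vapply(seq_len(k),
         function(a) addOneP(nullVe[a, ], obs[a], side = "greater"),
         0)
}

#' Bootstrap gene-weight Z table for the first PLS component
#'
#' Resamples regions with replacement, refits the first component, aligns
#' each bootstrap weight vector's sign to the original by dot product
#' (PLS components are sign-indeterminate; without alignment the SEs are
#' inflated), and forms `Z = weight / bootstrap SE` with a two-sided normal
#' p per gene, BH-FDR across genes, and PLS1+/PLS1-/none membership by Z
#' sign and FDR significance.
#'
#' @param X regions x genes matrix.
#' @param y per-region response.
#' @param nBoot number of bootstrap resamples (>= 100).
#' @param seed integer RNG seed.
#' @param q FDR level for list membership.
#' @param scale z-score gene columns (as in [plsFit()]).
#' @return data.frame with `gene`, `weight`, `bootstrap_se`, `Z`, `p`,
#'   `fdr_p`, `list` and an attribute `nSkipped` (degenerate resamples).
#' @export
bootstrapWeights <- function(X, y, nBoot = 1000L, seed = 1L, q = 0.05,
                             scale = TRUE) {
  if (nBoot < 100L) stop("nBoot must be at least 100")
  X <- as.matrix(X)
  n <- nrow(X)
  Xc <- .prepX(X, scale)
  w0 <- .plsComponent(Xc, y - mean(y))$w
  skipped <- 0L
  wb <- withSeed(seed, {
    out <- matrix(NA_real_, ncol(X), nBoot)
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) < 3L || stats::sd(y[idx]) == 0) {
        skipped <- skipped + 1L
        next
      }
      Xb <- Xc[idx, , drop = FALSE]
      Xb <- sweep(Xb, 2L, colMeans(Xb))
      w <- .plsComponent(Xb, y[idx] - mean(y[idx]))$w
      if (sum(w * w0) < 0) w <- -w
      out[, b] <- w
    }
    out
  })
  se <- apply(wb, 1L, stats::sd, na.rm = TRUE)
  if (any(se == 0)) stop("zero bootstrap SE; increase nBoot")
  Z <- w0 / se
  p <- 2 * stats::pnorm(-abs(Z))
  fdr <- stats::p.adjust(p, method = "BH")
  membership <- ifelse(fdr <= q & Z > 0, "PLS1+",
                       ifelse(fdr <= q & Z < 0, "PLS1-", "none"))
  out <- data.frame(gene = colnames(X) %||% paste0("gene", seq_len(ncol(X))),
                    weight = w0, bootstrap_se = se, Z = Z, p = p,
                    fdr_p = fdr, list = membership, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "nSkipped") <- skipped
  out
}

#' Rank a gene-weight table by bootstrap Z
#'
#' Descending Z with a stable lexicographic tie-break on gene id.
#'
#' @param table output of [bootstrapWeights()].
#' @return The table reordered; extract `$gene` for the ranked list.
#' @export
rankGenes <- function(table) {
  if (!nrow(table)) return(table)
  out <- table[order(-table$Z, table$gene), ]
  rownames(out) <- NULL
  out
}
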