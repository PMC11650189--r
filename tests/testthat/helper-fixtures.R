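# Shared fixtures and independent oracles, all built in code.

# Dense full-spectrum embedding oracle: eigendecomposition of the
# (nonsymmetric) transition operator P itself, with the canonical
# normalization sum(dW * psi^2) = sum(dW) so components are comparable to
# diffusionEmbedding() up to sign. Independent route from the package's
# symmetric-operator implementation.
denseEmbeddingOracle <- function(A, k, alpha = 0.5) {
  A <- unname(as.matrix(A))
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  dW <- rowSums(W)
  P <- W / dW
  e <- eigen(P)
  ord <- order(Re(e$values), decreasing = TRUE)
  lam <- Re(e$values)[ord]
  V <- Re(e$vectors)[, ord, drop = FALSE]
  vapply(seq_len(k), function(j) {
    v <- V[, j + 1L]
    v <- v * sqrt(sum(dW) / sum(dW * v^2))
    v * lam[j + 1L] / (1 - lam[j + 1L])
  }, numeric(nrow(A)))
}

# max column-wise deviation up to per-column sign flips
maxDevUpToSign <- function(a, b) {
  max(vapply(seq_len(ncol(a)), function(j) {
    min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j])))
  }, 0))
}

# random dense connected affinity matrix (normalized-angle of a random FC)
randomAffinity <- function(n, seed) {
  withr::with_seed(seed, {
    ts <- matrix(rnorm(n * (n + 10)), n)
    a <- gradix::normalizedAngle(cor(t(ts)))
    diag(a) <- 0
    a
  })
}

# spatially smooth random map on a parcel sphere (Gaussian kernel over
# angular distance applied to white noise)
smoothSphereMap <- function(sphere, bandwidth = 0.7) {
  xyz <- as.matrix(sphere[, c("x", "y", "z")])
  ang <- acos(pmin(pmax(tcrossprod(xyz), -1), 1))
  K <- exp(-ang^2 / (2 * bandwidth^2))
  drop(K %*% rnorm(nrow(xyz)))
}

# minimal GradientSet around a score vector
makeGradientSet <- function(scores, ratio = 0.5) {
  new("GradientSet", components = cbind(g1 = scores),
      eigenvalues = ratio, explainedRatio = ratio,
      nodeIds = paste0("n", seq_along(scores)))
}

# small subject table + response matrix for GLM tests
makeGlmData <- function(n1 = 12, n2 = 12, nNodes = 5, seed = 1,
                        shift = 0) {
  withr::with_seed(seed, {
    n <- n1 + n2
    subjects <- data.frame(
      id = sprintf("s%02d", seq_len(n)),
      group = rep(c("case", "control"), c(n1, n2)),
      age = round(runif(n, 10, 30), 1),
      sex = sample(c("M", "F"), n, replace = TRUE),
      fd = runif(n, 0.05, 0.3),
      stringsAsFactors = FALSE)
    y <- matrix(rnorm(n * nNodes), n,
                dimnames = list(subjects$id, paste0("n", seq_len(nNodes))))
    y[subjects$group == "case", 1] <- y[subjects$group == "case", 1] + shift
    list(y = y, subjects = subjects)
  })
}
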