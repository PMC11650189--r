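# Leave-one-out SVR prediction of treatment outcomes from baseline
# gradient features, permutation validity, and network weight attribution.

# standardize columns by train-fold statistics only (no leakage)
.foldScaler <- function(train) {
  ctr <- colMeans(train)
  scl <- apply(train, 2L, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.applyScaler <- function(x, sc) {
  sweep(sweep(x, 2L, sc$center), 2L, sc$scale, `/`)
}

# linear eps-SVR fit; returns the primal weight vector and intercept too
.svrFit <- function(x, y, C, epsilon) {
  fit <- e1071::svm(x = x, y = y, type = "eps-regression",
                    kernel = "linear", cost = C, epsilon = epsilon,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  list(model = fit, weights = w, intercept = -fit$rho)
}

#' Leave-one-out SVR prediction
#'
#' Linear-kernel epsilon-SVR: per fold, the features are standardized on the
#' training subjects only and the model is fit without the held-out subject,
#' whose outcome is then predicted. Reports the Pearson correlation and MSE
#' of predicted versus observed, and the per-feature weights of a final fit
#' on all subjects (used for network attribution). The linear kernel keeps
#' the weight vector directly interpretable.
#'
#' @param features subject x feature numeric matrix (e.g. baseline
#'   principal-gradient scores).
#' @param y per-subject outcome (>= 5 subjects, non-constant).
#' @param C SVR cost.
#' @param epsilon SVR epsilon-tube width.
#' @param details also return per-fold scalers and weight vectors (used by
#'   leakage diagnostics).
#' @return An [SvrPrediction-class] (permutation p slots `NA` until
#'   [permutationValidate()] is run); with `details = TRUE`, a list with the
#'   prediction object and per-fold internals.
#' @export
svrLoocv <- function(features, y, C = 1, epsilon = 0.1, details = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 5L) stop("need at least 5 subjects")
  if (!all(is.finite(features))) stop("features must be finite")
  if (stats::sd(y) == 0) stop("constant outcome")
  pred <- numeric(n)
  folds <- if (details) vector("list", n) else NULL
  for (i in seq_len(n)) {
    tr <- features[-i, , drop = FALSE]
    sc <- .foldScaler(tr)
    fit <- .svrFit(.applyScaler(tr, sc), y[-i], C, epsilon)
    pred[i] <- stats::predict(fit$model,
                              .applyScaler(features[i, , drop = FALSE], sc))
    if (details)
      folds[[i]] <- list(scaler = sc, weights = fit$weights,
                         intercept = fit$intercept)
  }
  scAll <- .foldScaler(features)
  fitAll <- .svrFit(.applyScaler(features, scAll), y, C, epsilon)
  obj <- new("SvrPrediction", predicted = pred, observed = as.numeric(y),
             r = stats::cor(pred, y), mse = mean((pred - y)^2),
             pPermR = NA_real_, pPermMse = NA_real_,
             weights = fitAll$weights, networkShare = numeric())
  if (details) list(prediction = obj, folds = folds) else obj
}

#' Permutation validity of the LOOCV prediction
#'
#' Shuffles the outcome, reruns the full leave-one-out loop per permutation,
#' and reports add-one p-values for the correlation (greater) and the MSE
#' (less).
#'
#' @inheritParams svrLoocv
#' @param nPerm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @return Named numeric vector `c(p_perm_r, p_perm_mse)`.
#' @export
permutationValidate <- function(features, y, nPerm = 1000L, seed = 1L,
                                C = 1, epsilon = 0.1) {
  if (nPerm < 100L) stop("nPerm must be at least 100")
  obs <- svrLoocv(features, y, C, epsilon)
  nullStats <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    fit <- svrLoocv(features, sample(y), C, epsilon)
    c(fit@r, fit@mse)
  }, numeric(2L)))
  c(p_perm_r = addOneP(nullStats[1L, ], obs@r, side = "greater"),
    p_perm_mse = addOneP(nullStats[2L, ], obs@mse, side = "less"))
}

#' Network attribution of SVR feature weights
#'
#' `share_k = sum_{i in k} |w_i| / sum_i |w_i|` over the node partition;
#' shares sum to 1.
#'
#' @param weights per-node feature weights.
#' @param partition data.frame with columns `node`, `network` labeling all
#'   feature nodes.
#' @return Named numeric vector of per-network fractions.
#' @export
networkWeightShare <- function(weights, partition) {
  if (length(weights) != nrow(partition))
    stop("partition must label every feature node")
  tot <- sum(abs(weights))
  if (tot == 0) stop("all-zero weight vector")
  shares <- tapply(abs(weights), partition$network, sum) / tot
  out <- as.numeric(shares)
  names(out) <- names(shares)
  out
}
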