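# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators consume a single,
#' self-contained RNG stream and never disturb the caller's stream.
#' @noRd
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Trapezoid-rule area under a curve
#'
#' @param x ordered abscissae.
#' @param y curve values at `x`.
#' @return Scalar AUC over the range of `x`.
#' @examples
#' trapezoidAUC(c(0, 1), c(2, 2)) # constant curve: value * width
#' @export
trapezoidAUC <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L, !is.unsorted(x))
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

# standardize to zero mean, unit (sample) SD
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

# add-one permutation p-value
addOneP <- function(nullStats, obs, side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  nullStats <- nullStats[is.finite(nullStats)]
  k <- switch(side,
    greater   = sum(nullStats >= obs),
    less      = sum(nullStats <= obs),
    two.sided = sum(abs(nullStats) >= abs(obs)))
  (1 + k) / (1 + length(nullStats))
}

# symmetric-matrix sanity used by several constructors
checkSymmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop(what, " must be symmetric (tolerance ", tol, ")")
  invisible(TRUE)
}
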