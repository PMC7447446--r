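#' Estimate hidden confounding factors from an abundance matrix
#'
#' Fits a low-rank factor model with automatic-relevance (ARD) shrinkage on
#' the loading columns, via expectation-maximisation for probabilistic PCA
#' with per-factor precision updates. Known covariates are regressed out of
#' the matrix before fitting, and the model is fit on the most highly
#' expressed `nTop` features. Initialisation is from the singular value
#' decomposition, so the fit is deterministic; `seed` is accepted for
#' interface stability.
#'
#' @param matrix a log-scale [AbundanceMatrix-class] (features x lines) or
#'   a plain numeric matrix; missing values are mean-imputed per feature for
#'   the factor fit only (the data themselves are never modified).
#' @param k number of factors (>= 0; must be < number of lines).
#' @param covariates optional lines x q numeric matrix of known covariates
#'   to regress out first.
#' @param seed unused (deterministic fit); kept for interface stability.
#' @param nTop fit on the `nTop` features with highest mean abundance.
#' @param maxIter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return list of class `"latentFactorSet"` with `factors` (lines x k,
#'   zero mean, unit variance, ordered by explained variance), `loadings`
#'   (features x k), `k`, `varianceExplained`, `factorCor` (pairwise factor
#'   correlation matrix) and `maxAbsCor` (largest off-diagonal
#'   |correlation|).
#' @export
fitHiddenFactors <- function(matrix, k, covariates = NULL, seed = 1L,
                             nTop = 10000L, maxIter = 200L, tol = 1e-7) {
  v <- if (is(matrix, "AbundanceMatrix")) assayValues(matrix) else matrix
  n <- ncol(v)
  if (k >= n) stop("k must be smaller than the number of lines")
  if (k == 0)
    return(structure(list(factors = matrix(0, n, 0,
                                           dimnames = list(colnames(v), NULL)),
                          loadings = NULL, k = 0L,
                          varianceExplained = numeric(0),
                          factorCor = matrix(0, 0, 0), maxAbsCor = 0),
                     class = "latentFactorSet"))
  keep <- order(rowMeans(v, na.rm = TRUE), decreasing = TRUE)
  keep <- keep[seq_len(min(nTop, nrow(v)))]
  X <- t(v[keep, , drop = FALSE])                    # lines x features
  for (j in seq_len(ncol(X))) {
    mis <- is.na(X[, j])
    mu <- mean(X[!mis, j])
    X[mis, j] <- mu
    X[, j] <- X[, j] - mu
  }
  if (!is.null(covariates)) {
    C <- cbind(1, as.matrix(covariates))
    X <- X - C %*% solve(crossprod(C), crossprod(C, X))
  }
  p <- ncol(X)
  sv <- svd(X, nu = k, nv = k)
  W <- sv$v %*% diag(sv$d[seq_len(k)] / sqrt(n), k)  # features x k
  sigma2 <- max(mean(X^2) - sum(sv$d[seq_len(k)]^2) / (n * p), 1e-6)
  alpha <- rep(1, k)
  llOld <- -Inf
  for (it in seq_len(maxIter)) {
    ## E-step: posterior over factors given W, sigma2
    M <- crossprod(W) + sigma2 * diag(k)
    Minv <- solve(M)
    EF <- X %*% W %*% Minv                           # n x k
    EFF <- n * sigma2 * Minv + crossprod(EF)
    ## M-step with ARD precision on loading columns
    W <- crossprod(X, EF) %*% solve(EFF + sigma2 * diag(alpha, k))
    alpha <- p / pmax(colSums(W^2), 1e-12)
    resid <- sum(X^2) - 2 * sum((X %*% W) * EF) + sum(EFF * crossprod(W))
    sigma2 <- max(resid / (n * p), 1e-10)
    ll <- -0.5 * n * p * log(sigma2) - 0.5 * resid / sigma2
    if (is.finite(llOld) && abs(ll - llOld) < tol * (abs(llOld) + 1)) break
    llOld <- ll
  }
  ve <- colSums(W^2) * apply(EF, 2, var) / sum(X^2) * n
  ord <- order(ve, decreasing = TRUE)
  fac <- EF[, ord, drop = FALSE]
  ## ARD can shrink a surplus factor to (near) zero variance; such columns
  ## are kept as exact zeros rather than blown up by standardization
  live <- apply(fac, 2, sd) > 1e-8
  fac[, live] <- scale(fac[, live, drop = FALSE])
  fac[, !live] <- 0
  dimnames(fac) <- list(rownames(X), paste0("factor_", seq_len(k)))
  fc <- diag(1, k)
  if (sum(live) > 1)
    fc[live, live] <- cor(fac[, live, drop = FALSE])
  maxAbsCor <- if (k > 1) max(abs(fc[upper.tri(fc)])) else 0
  structure(list(factors = fac, loadings = W[, ord, drop = FALSE],
                 k = as.integer(k), varianceExplained = ve[ord],
                 factorCor = fc, maxAbsCor = maxAbsCor),
            class = "latentFactorSet")
}

#' @export
print.latentFactorSet <- function(x, ...) {
  cat(sprintf("latentFactorSet: %d factor(s), max |cor| = %.3f\n",
              x$k, x$maxAbsCor))
  invisible(x)
}

#' Select the number of hidden factors by the independence criterion
#'
#' Scans k upward from 1 to `kMax`, refitting the factor model at each k,
#' and returns the largest k for which all pairwise factor correlations stay
#' below `rThreshold` in absolute value; the scan stops at the first
#' violation. A single factor is vacuously independent.
#'
#' @inheritParams fitHiddenFactors
#' @param kMax largest number of factors to consider (>= 1).
#' @param rThreshold pairwise |correlation| bound (default 0.7).
#' @return the selected k (integer).
#' @export
selectFactorCount <- function(matrix, kMax, rThreshold = 0.7, seed = 1L,
                              covariates = NULL, nTop = 10000L) {
  stopifnot(kMax >= 1)
  kSel <- 1L
  for (k in seq_len(kMax)) {
    fit <- fitHiddenFactors(matrix, k, covariates = covariates, seed = seed,
                            nTop = nTop)
    if (fit$maxAbsCor >= rThreshold) break
    kSel <- as.integer(k)
  }
  kSel
}
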