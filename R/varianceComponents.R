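#' Categorical covariance matrices for random-effect factors
#'
#' For each factor f, builds the n x n matrix M with M[i, j] = 1 iff lines
#' i and j share the factor label, else 0 (block-diagonal under label
#' sorting, all-ones diagonal). Donor age is treated categorically in
#' 5-year windows anchored at 0 ([0,5), [5,10), ...).
#'
#' @param samples sample table with a `line` column and one column per
#'   requested factor (`donor`, `sex`, `age`, `medium`, `batch`,
#'   `channel`).
#' @param factors factor names to build (default: all six).
#' @return named list of 0/1 covariance matrices with line dimnames.
#' @export
buildCategoricalCovariances <- function(samples,
                                        factors = c("donor", "sex", "age",
                                                    "medium", "batch",
                                                    "channel")) {
  lines <- samples$line
  out <- list()
  for (f in factors) {
    lab <- samples[[f]]
    if (is.null(lab)) stop("factor column missing from sample table: ", f)
    if (anyNA(lab))
      stop(sprintf("missing %s label for line %s", f,
                   lines[which(is.na(lab))[1]]))
    if (f == "age") lab <- floor(as.numeric(lab) / 5) * 5
    M <- outer(lab, lab, "==") * 1
    dimnames(M) <- list(lines, lines)
    out[[f]] <- M
  }
  out
}

#' Fit a multi-component random-effects variance decomposition
#'
#' Maximizes the multivariate-normal log-likelihood of
#' y = mu + sum_k u_k + e, u_k ~ N(0, sigma_k^2 M_k), e ~ N(0, sigma_r^2 I)
#' over non-negative variances, with the mean profiled out by generalized
#' least squares. Optimization runs on the log-variance scale (so the
#' non-negativity boundary is open) with multiple random restarts.
#'
#' @param y complete numeric phenotype vector.
#' @param covariances named list of n x n categorical covariance matrices
#'   (from [buildCategoricalCovariances()]).
#' @param nRestarts number of random restarts (default 5).
#' @param tol relative convergence tolerance on the log-likelihood.
#' @return list with `variances` (named, residual last), `fractions`
#'   (summing to 1), `logLik` and `converged`.
#' @export
fitVarianceComponents <- function(y, covariances, nRestarts = 5,
                                  tol = 1e-8) {
  n <- length(y)
  stopifnot(!anyNA(y), n > 2)
  Ms <- c(covariances, list(residual = diag(n)))
  K <- length(Ms)
  ones <- rep(1, n)
  negll <- function(logs2) {
    s2 <- exp(logs2)
    Sigma <- matrix(0, n, n)
    for (k in seq_len(K)) Sigma <- Sigma + s2[k] * Ms[[k]]
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Si1 <- backsolve(ch, forwardsolve(t(ch), ones))
    Siy <- backsolve(ch, forwardsolve(t(ch), y))
    mu <- sum(Si1 * y) / sum(Si1 * ones)
    r <- y - mu
    Sir <- Siy - mu * Si1
    0.5 * (logdet + sum(r * Sir))
  }
  vy <- var(y)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    start <- if (r == 1) rep(log(vy / K), K) else
      rep(log(vy / K), K) + rnorm(K, 0, 1)
    fit <- tryCatch(optim(start, negll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = tol)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  s2 <- exp(best$par)
  names(s2) <- names(Ms)
  list(variances = s2, fractions = s2 / sum(s2), logLik = -best$value,
       converged = best$convergence == 0)
}

#' Variance decomposition across all features of a layer
#'
#' Standardizes each feature (mean 0, variance 1 over its non-missing
#' lines) and fits [fitVarianceComponents()]; intended for the paired-donor
#' line subset so the donor component is identifiable.
#'
#' @param matrix log-scale [AbundanceMatrix-class].
#' @param samples sample table (rows matching the matrix columns used).
#' @param factors factors to decompose over.
#' @param nRestarts restarts per feature.
#' @param minLines skip features observed in fewer lines.
#' @return data.frame: `feature`, `factor`, `variance`, `fraction`,
#'   `converged`.
#' @export
decomposeVarianceMatrix <- function(matrix, samples,
                                    factors = c("donor", "sex", "age",
                                                "medium", "batch",
                                                "channel"),
                                    nRestarts = 5, minLines = 20) {
  v <- assayValues(matrix)
  v <- v[, samples$line, drop = FALSE]
  covs <- buildCategoricalCovariances(samples, factors)
  rows <- list()
  for (i in seq_len(nrow(v))) {
    obs <- which(!is.na(v[i, ]))
    if (length(obs) < minLines) next
    y <- v[i, obs]
    if (sd(y) == 0) next
    y <- (y - mean(y)) / sd(y)
    fit <- fitVarianceComponents(y, lapply(covs, function(M)
      M[obs, obs, drop = FALSE]), nRestarts = nRestarts)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = rownames(v)[i], factor = names(fit$fractions),
      variance = unname(fit$variances), fraction = unname(fit$fractions),
      converged = fit$converged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress RNA out of protein abundance
#'
#' Returns the residuals of the least-squares line of protein on RNA over
#' pairwise-complete lines (missing entries stay missing). When RNA is
#' constant the mean-centered protein is returned with a warning.
#'
#' @param protein,rna named numeric vectors over the same lines.
#' @return named residual vector (same names as `protein`).
#' @export
rnaAdjustProtein <- function(protein, rna) {
  out <- rep(NA_real_, length(protein))
  names(out) <- names(protein)
  ok <- !is.na(protein) & !is.na(rna[names(protein)])
  x <- rna[names(protein)][ok]; y <- protein[ok]
  if (sd(x) == 0) {
    warning("constant RNA; returning mean-centered protein")
    out[ok] <- y - mean(y)
    return(out)
  }
  b <- cov(x, y) / var(x)
  out[ok] <- y - (mean(y) + b * (x - mean(x)))
  out
}

#' Count genes with a strong variance contribution per factor
#'
#' Counts, per factor and per decomposition set (e.g. raw versus
#' RNA-adjusted protein), the genes whose variance fraction exceeds the
#' threshold (default 20%).
#'
#' @param decompositions data.frame from [decomposeVarianceMatrix()] with
#'   an additional `set` column when several decompositions are combined.
#' @param threshold count features with fraction strictly above this.
#' @return data.frame: `set` (if present), `factor`, `nAbove`, and the
#'   per-gene fractions in attribute `fractions`.
#' @export
summarizeFractions <- function(decompositions, threshold = 0.20) {
  d <- decompositions
  if (is.null(d$set)) d$set <- "all"
  out <- do.call(rbind, lapply(split(d, list(d$set, d$factor), drop = TRUE),
                               function(x) data.frame(
    set = x$set[1], factor = x$factor[1],
    nAbove = sum(x$fraction > threshold), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "fractions") <- d[, c("set", "feature", "factor", "fraction")]
  out
}
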