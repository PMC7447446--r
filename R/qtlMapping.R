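#' Realized relationship (kinship) matrix from genotype dosages
#'
#' K = Z'Z / M where Z is the column-standardized dosage matrix (per
#' variant: mean 0, variance 1, population scaling) and M the number of
#' polymorphic variants. Monomorphic variants are excluded. Lines from the
#' same donor have identical dosage columns and hence identical kinship
#' rows; K is a Gram matrix and therefore positive semi-definite.
#'
#' @param geno a [GenotypeData-class].
#' @return lines x lines kinship matrix with attribute `nVariants`.
#' @export
computeKinship <- function(geno) {
  d <- dosages(geno)
  mu <- rowMeans(d)
  v <- rowMeans((d - mu)^2)
  poly <- v > 0
  if (!any(poly)) stop("all variants are monomorphic")
  Z <- (d[poly, , drop = FALSE] - mu[poly]) / sqrt(v[poly])
  K <- crossprod(Z) / sum(poly)
  attr(K, "nVariants") <- sum(poly)
  K
}

#' Variants in the cis window of a gene
#'
#' Returns the ids of common variants (minor allele frequency strictly
#' above `mafMin`, computed across unique donors when a donor map is given)
#' whose position lies within `window` bases of the gene boundaries
#' (1-based inclusive; strand ignored).
#'
#' @param geneCoord list or one-row data.frame with `chrom`, `start`, `end`.
#' @param geno a [GenotypeData-class].
#' @param window half-width of the cis window in bases (default 250000).
#' @param mafMin minor-allele-frequency lower bound (strict; default 0.05).
#' @param donors optional named donor map for MAF computation.
#' @return character vector of variant ids.
#' @export
defineCisWindow <- function(geneCoord, geno, window = 250000,
                            mafMin = 0.05, donors = NULL) {
  if (is.null(geneCoord$chrom) || is.na(geneCoord$chrom) ||
      is.na(geneCoord$start) || is.na(geneCoord$end))
    stop("gene has no genomic coordinates")
  vi <- variantInfo(geno)
  maf <- variantMaf(geno, donors)
  keep <- vi$chrom == geneCoord$chrom &
    vi$pos >= geneCoord$start - window &
    vi$pos <= geneCoord$end + window &
    maf > mafMin
  vi$variant[keep]
}

## Null linear mixed model y = C a + u + e, u ~ N(0, s2g K), e ~ N(0, s2e I).
## The kinship eigendecomposition rotates the model to independent errors
## with variances proportional to (S + delta), delta = s2e/s2g; delta is
## estimated by 1-D maximum likelihood with the fixed effects profiled out.
.lmmNull <- function(y, C, K = NULL, eig = NULL, fixedDelta = NULL) {
  n <- length(y)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  S <- pmax(eig$values, 0)
  Ut <- t(eig$vectors)
  ystar <- drop(Ut %*% y)
  Cstar <- Ut %*% C
  negll <- function(logDelta) {
    w <- 1 / (S + exp(logDelta))
    sw <- sqrt(w)
    ry <- qr.resid(qr(Cstar * sw), ystar * sw)
    rss <- sum(ry^2)
    n * log(rss / n) + sum(log(S + exp(logDelta)))
  }
  logDelta <- if (!is.null(fixedDelta)) log(fixedDelta) else
    optimize(negll, c(-12, 12))$minimum
  delta <- exp(logDelta)
  w <- 1 / (S + delta)
  sw <- sqrt(w)
  Cw <- Cstar * sw
  qrCw <- qr(Cw)
  yw <- ystar * sw
  ry <- qr.resid(qrCw, yw)
  list(eig = eig, S = S, Ut = Ut, delta = delta, sw = sw, qrCw = qrCw,
       ry = ry, n = n, p = ncol(C), df = n - ncol(C) - 1)
}

.assocStats <- function(RG, ssg, ry, df) {
  ssy <- sum(ry^2)
  xy <- drop(crossprod(RG, ry))
  beta <- xy / ssg
  rss <- pmax(ssy - beta * xy, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / ssg)
  ## exact t reference: permutation p-values are then uniform, which the
  ## Beta fit of the permutation minima requires
  p <- 2 * stats::pt(-abs(beta / se), df)
  data.frame(beta = beta, se = se, p = p)
}

#' Single-variant linear mixed-model association
#'
#' Fits y = C alpha + g beta + u + e with u ~ N(0, sigma_g^2 K) and
#' e ~ N(0, sigma_e^2 I). The variance ratio is estimated by 1-D likelihood
#' maximization under the null model (no g), then beta, its standard error
#' and a two-sided p-value (exact t reference with n - q - 1 degrees of
#' freedom, so that permutation p-values are uniform) are computed by
#' generalized least squares under the estimated covariance. Lines with
#' missing y, g or covariates are dropped (pairwise-complete).
#'
#' @param y named phenotype vector.
#' @param g named dosage vector (same lines).
#' @param covariates optional lines x q matrix.
#' @param K kinship matrix over at least the shared lines.
#' @param varRatio optional fixed variance ratio delta = sigma_e^2/sigma_g^2
#'   (skips the likelihood maximization).
#' @return one-row data.frame: `beta`, `se`, `p`, `n`, `delta`.
#' @export
lmmAssociation <- function(y, g, covariates = NULL, K, varRatio = NULL) {
  lines <- intersect(names(y), names(g))
  obs <- lines[!is.na(y[lines]) & !is.na(g[lines])]
  if (!is.null(covariates))
    obs <- obs[complete.cases(covariates[obs, , drop = FALSE])]
  C <- cbind(intercept = rep(1, length(obs)))
  if (!is.null(covariates)) C <- cbind(C, covariates[obs, , drop = FALSE])
  if (length(obs) < ncol(C) + 2)
    stop("fewer lines than covariates + 2")
  gv <- g[obs]
  if (sd(gv) == 0) stop("degenerate (constant) variant")
  null <- .lmmNull(y[obs], C, K = K[obs, obs])
  if (!is.null(varRatio)) null <- .lmmNull(y[obs], C, eig = null$eig,
                                           fixedDelta = varRatio)
  gw <- drop(null$Ut %*% gv) * null$sw
  rg <- qr.resid(null$qrCw, gw)
  st <- .assocStats(cbind(rg), sum(rg^2), null$ry, null$df)
  cbind(st, n = length(obs), delta = null$delta)
}

#' Cis association scan for one feature
#'
#' Tests every cis variant against the (standardized) phenotype with the
#' kinship linear mixed model, re-using the null-model variance ratio for
#' all variants. The lead variant is the smallest nominal p, ties broken by
#' larger |beta| and then smaller genomic position.
#'
#' @param y named phenotype vector (NA allowed; pairwise-complete lines
#'   used).
#' @param geno a [GenotypeData-class].
#' @param variantIds cis variant ids (e.g. from [defineCisWindow()]).
#' @param covariates optional lines x q matrix.
#' @param K kinship matrix.
#' @param eig optional precomputed `eigen(K)` (used when y is complete).
#' @param standardize standardize y to unit variance first (default TRUE).
#' @return list with `assoc` (variant, beta, se, p, pos), `lead` (one row),
#'   `skipped` (variants monomorphic on the analysis subset) and `context`
#'   (internal state consumed by [permutationBetaAdjust()]); `NULL` if no
#'   testable cis variant.
#' @export
cisScan <- function(y, geno, variantIds, covariates = NULL, K = NULL,
                    eig = NULL, standardize = TRUE) {
  if (!length(variantIds)) return(NULL)
  dos <- dosages(geno)
  obs <- names(y)[!is.na(y)]
  if (!is.null(covariates))
    obs <- obs[complete.cases(covariates[obs, , drop = FALSE])]
  yv <- y[obs]
  if (standardize) yv <- (yv - mean(yv)) / sd(yv)
  C <- cbind(intercept = rep(1, length(obs)))
  if (!is.null(covariates)) C <- cbind(C, as.matrix(covariates[obs, , drop = FALSE]))
  useEig <- !is.null(eig) && length(obs) == ncol(dos)
  null <- .lmmNull(yv, C, K = if (useEig) NULL else K[obs, obs],
                   eig = if (useEig) eig else NULL)
  G <- t(dos[variantIds, obs, drop = FALSE])          # n x m
  GW <- (null$Ut %*% G) * null$sw
  RG <- qr.resid(null$qrCw, GW)
  ssg <- colSums(RG^2)
  ok <- ssg > 1e-10
  skipped <- variantIds[!ok]
  if (!any(ok)) return(NULL)
  RG <- RG[, ok, drop = FALSE]; ssg <- ssg[ok]
  ids <- variantIds[ok]
  st <- .assocStats(RG, ssg, null$ry, null$df)
  pos <- variantInfo(geno)$pos[match(ids, variantInfo(geno)$variant)]
  assoc <- data.frame(variant = ids, beta = st$beta, se = st$se, p = st$p,
                      pos = pos, stringsAsFactors = FALSE)
  ord <- order(assoc$p, -abs(assoc$beta), assoc$pos)
  lead <- assoc[ord[1], ]
  list(assoc = assoc, lead = lead, skipped = skipped,
       context = list(RG = RG, ssg = ssg, ry = null$ry, qrCw = null$qrCw,
                      df = null$df, n = null$n, leadP = lead$p))
}

#' Permutation null with parametric Beta adjustment for the lead p-value
#'
#' The covariate-and-kinship-whitened phenotype residual vector is permuted
#' across lines `nPerm` times (and re-projected onto the covariate
#' complement); for each permutation the minimum nominal p over the cis
#' variants is recorded. A Beta(a, b) distribution is fitted to the minima
#' by maximum likelihood (moment-matching start); the adjusted p is the
#' fitted Beta CDF anchored at the permutation order statistics: within the
#' range of the minima the Beta CDF interpolates the empirical permutation
#' distribution (so adjusted p-values are exactly calibrated at the
#' permutation ranks), and below the smallest minimum it extrapolates the
#' Beta left tail, giving resolution beyond 1 / (nPerm + 1). If the Beta
#' fit degenerates, the empirical permutation p
#' (1 + #{minima <= observed}) / (nPerm + 1) is used and flagged.
#'
#' @param scan result of [cisScan()].
#' @param nPerm number of permutations (default 100).
#' @param seed integer seed for the permutations.
#' @return list with `adjustedP`, `a`, `b`, `minima`, `empiricalP` and
#'   `fallback` flag.
#' @export
permutationBetaAdjust <- function(scan, nPerm = 100, seed = 1L) {
  ctx <- scan$context
  set.seed(seed)
  n <- ctx$n
  E <- matrix(0, n, nPerm)
  for (b in seq_len(nPerm)) E[, b] <- ctx$ry[sample.int(n)]
  E <- qr.resid(ctx$qrCw, E)
  ssE <- colSums(E^2)
  A <- crossprod(ctx$RG, E)^2 / ctx$ssg                # m x B
  denom <- matrix(ssE, nrow(A), nPerm, byrow = TRUE) - A
  t2 <- A * ctx$df / pmax(denom, 1e-12)
  pmat <- 2 * stats::pt(-sqrt(t2), ctx$df)
  minima <- apply(pmat, 2, min)
  empiricalP <- (1 + sum(minima <= ctx$leadP)) / (nPerm + 1)
  fit <- .fitBetaML(minima)
  if (is.null(fit))
    return(list(adjustedP = empiricalP, a = NA, b = NA, minima = minima,
                empiricalP = empiricalP, fallback = TRUE))
  list(adjustedP = .betaAnchoredP(ctx$leadP, minima, fit$a, fit$b),
       a = fit$a, b = fit$b,
       minima = minima, empiricalP = empiricalP, fallback = FALSE)
}

## fitted-Beta CDF anchored at the permutation order statistics: piecewise
## monotone in p, equal to the empirical CDF at each minimum, Beta-shaped
## within bins and in the extrapolated tails
.betaAnchoredP <- function(p, minima, a, b) {
  x <- sort(minima)
  B <- length(x)
  i <- findInterval(p, x)
  lo <- if (i == 0) 0 else x[i]
  hi <- if (i == B) 1 else x[i + 1]
  span <- pbeta(hi, a, b) - pbeta(lo, a, b)
  frac <- if (span <= 0) 0.5 else (pbeta(p, a, b) - pbeta(lo, a, b)) / span
  (i + min(max(frac, 0), 1)) / (B + 1)
}

.fitBetaML <- function(x) {
  x <- pmin(pmax(x, 1e-300), 1 - 1e-12)
  m <- mean(x); v <- var(x)
  if (!is.finite(v) || v <= 0) return(NULL)
  common <- max(m * (1 - m) / v - 1, 1e-3)
  start <- log(c(max(m * common, 1e-3), max((1 - m) * common, 1e-3)))
  nll <- function(par) -sum(dbeta(x, exp(par[1]), exp(par[2]), log = TRUE))
  fit <- tryCatch(optim(start, nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  list(a = exp(fit$par[1]), b = exp(fit$par[2]))
}

#' Gene-level Bonferroni and Benjamini-Hochberg adjustment
#'
#' Collapses per-feature Beta-adjusted p-values to genes: the gene p is the
#' minimum over its features of min(1, adjusted p x number of features)
#' (Bonferroni for feature multiplicity); Benjamini-Hochberg q-values are
#' then computed across genes within each layer, and a gene is significant
#' iff q < `fdr`.
#'
#' @param featureTable data.frame with columns `gene`, `feature`, `layer`,
#'   `pAdjusted`, and (carried through from the lead) `variant`, `beta`.
#' @param fdr FDR threshold (default 0.10).
#' @return data.frame, one row per gene x layer: `gene`, `layer`,
#'   `leadFeature`, `leadVariant`, `beta`, `pBetaAdjusted`, `pGene`, `qBH`,
#'   `significant`.
#' @export
geneLevelAdjust <- function(featureTable, fdr = 0.10) {
  out <- do.call(rbind, lapply(split(featureTable,
                                     featureTable[c("gene", "layer")],
                                     drop = TRUE), function(d) {
    nf <- nrow(d)
    pBonf <- pmin(1, d$pAdjusted * nf)
    i <- which.min(pBonf)
    data.frame(gene = d$gene[1], layer = d$layer[1],
               leadFeature = d$feature[i], leadVariant = d$variant[i],
               beta = d$beta[i], pBetaAdjusted = d$pAdjusted[i],
               pGene = pBonf[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$qBH <- NA_real_
  for (ly in unique(out$layer)) {
    idx <- out$layer == ly
    out$qBH[idx] <- p.adjust(out$pGene[idx], method = "BH")
  }
  out$significant <- out$qBH < fdr
  out
}

#' Cis QTL mapping for a whole layer
#'
#' Runs [cisScan()] plus [permutationBetaAdjust()] for every feature of a
#' log-scale abundance layer, then [geneLevelAdjust()] across genes.
#'
#' @param matrix log-scale [AbundanceMatrix-class].
#' @param geno a [GenotypeData-class].
#' @param fmap long-format feature map (gene coordinates per feature).
#' @param covariates optional lines x q matrix (e.g. hidden factors).
#' @param K kinship matrix (default: computed from `geno`).
#' @param window,mafMin cis-window definition, see [defineCisWindow()].
#' @param nPerm permutations per feature.
#' @param fdr FDR threshold for the gene-level call.
#' @param seed integer; feature i uses seed + i.
#' @param donors optional named donor map for MAF computation.
#' @return list with `features` (per-feature lead table), `genes`
#'   (gene-level summary from [geneLevelAdjust()]) and `skipped`.
#' @export
mapCisLayer <- function(matrix, geno, fmap, covariates = NULL, K = NULL,
                        window = 250000, mafMin = 0.05, nPerm = 100,
                        fdr = 0.10, seed = 1L, donors = NULL) {
  if (is.null(K)) K <- computeKinship(geno)
  eig <- eigen(K, symmetric = TRUE)
  v <- assayValues(matrix)
  layer <- layerTag(matrix)
  info <- fmap[match(rownames(v), fmap$feature), ]
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(v))) {
    coord <- list(chrom = info$chrom[i], start = info$start[i],
                  end = info$end[i])
    if (is.null(coord$chrom) || is.na(coord$chrom)) {
      skipped <- c(skipped, rownames(v)[i]); next
    }
    cis <- defineCisWindow(coord, geno, window, mafMin, donors)
    scan <- cisScan(v[i, ], geno, cis, covariates = covariates, K = K,
                    eig = eig)
    if (is.null(scan)) { skipped <- c(skipped, rownames(v)[i]); next }
    adj <- permutationBetaAdjust(scan, nPerm = nPerm, seed = seed + i)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = rownames(v)[i], gene = info$gene[i], layer = layer,
      variant = scan$lead$variant, beta = scan$lead$beta,
      se = scan$lead$se, pNominal = scan$lead$p, pAdjusted = adj$adjustedP,
      betaA = adj$a, betaB = adj$b, fallback = adj$fallback,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(features = NULL, genes = NULL, skipped = skipped))
  features <- do.call(rbind, rows)
  genes <- geneLevelAdjust(features, fdr = fdr)
  list(features = features, genes = genes, skipped = skipped)
}

#' Trans association scan of lead cis variants against all proteins
#'
#' Tests every (lead variant, protein) pair with the same kinship linear
#' mixed model. Pairs where the protein's gene is the cis gene itself, or
#' lies within the cis window of the variant, are excluded; BH adjustment
#' is performed across all remaining tests.
#'
#' @param leads data.frame with `gene` (cis gene) and `variant` columns.
#' @param protein log-scale protein [AbundanceMatrix-class].
#' @param geno a [GenotypeData-class].
#' @param fmap long-format feature map.
#' @param covariates optional covariate matrix.
#' @param K kinship matrix.
#' @param window cis-window half-width used for the exclusion rule.
#' @param fdr FDR threshold.
#' @return list with `results` (cisGene, variant, protein, transGene, beta,
#'   se, p, q, significant) and `nTests`.
#' @export
transScan <- function(leads, protein, geno, fmap, covariates = NULL,
                      K = NULL, window = 250000, fdr = 0.10) {
  stopifnot(nrow(leads) > 0)
  if (is.null(K)) K <- computeKinship(geno)
  eig <- eigen(K, symmetric = TRUE)
  v <- assayValues(protein)
  dos <- dosages(geno)
  vi <- variantInfo(geno)
  geneOf <- setNames(fmap$gene, fmap$feature)
  gcoord <- fmap[fmap$layer == "rna_gene", ]
  rows <- list()
  for (i in seq_len(nrow(v))) {
    pg <- rownames(v)[i]
    scan <- cisScan(v[i, ], geno, leads$variant, covariates = covariates,
                    K = K, eig = eig)
    if (is.null(scan)) next
    a <- scan$assoc
    a$cisGene <- leads$gene[match(a$variant, leads$variant)]
    a$protein <- pg
    a$transGene <- unname(geneOf[pg])
    g <- gcoord[gcoord$gene == a$transGene[1], ][1, ]
    vpos <- vi[match(a$variant, vi$variant), ]
    inCis <- !is.na(g$chrom) & vpos$chrom == g$chrom &
      vpos$pos >= g$start - window & vpos$pos <= g$end + window
    a$excluded <- a$cisGene == a$transGene | inCis
    rows[[length(rows) + 1L]] <- a
  }
  all <- do.call(rbind, rows)
  res <- all[!all$excluded, , drop = FALSE]
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q < fdr
  rownames(res) <- NULL
  list(results = res[, c("cisGene", "variant", "protein", "transGene",
                         "beta", "se", "p", "q", "significant")],
       nTests = nrow(res))
}
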