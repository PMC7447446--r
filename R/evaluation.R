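#' Simulation studies of pipeline calibration and power
#'
#' These helpers run repeated synthetic cohorts through the mapping stages
#' and summarise calibration (false discovery control, p-value uniformity)
#' and power (truth recovery, classification accuracy). They are used by
#' the package's own validation suite and are exported so users can rerun
#' the same studies under modified conditions.
#'
#' @name evaluation
NULL

.nullCohortConfig <- function(nLines, nGenes, nVariants, seed)
  cohortConfig(nDonors = ceiling(nLines * 151 / 202), nLines = nLines,
               nVariants = nVariants, nGenes = nGenes,
               effectClassCounts = c(null = 0L), nComplexes = 0L,
               missingRate = 0, seed = seed)

#' False-discovery calibration on all-null cohorts
#'
#' Simulates cohorts with no planted genetic effects, maps the protein
#' layer in cis (permutation Beta adjustment, Bonferroni/BH) and reports
#' the per-cohort fraction of genes declared significant at the FDR
#' threshold together with the pooled gene-level adjusted p-values.
#'
#' @param nCohorts number of replicate cohorts.
#' @param nLines,nGenes,nVariants cohort dimensions.
#' @param nPerm,fdr mapping parameters.
#' @param seed integer seed (cohort i uses seed + i).
#' @return list with `sigFractions`, `meanSigFraction`, `mcSe` (Monte-Carlo
#'   standard error), `pooledP` (gene-level adjusted p across cohorts) and
#'   `ksP` (Kolmogorov-Smirnov uniformity p of `pooledP`).
#' @export
evaluateNullCalibration <- function(nCohorts = 20, nLines = 200,
                                    nGenes = 300, nVariants = 3000,
                                    nPerm = 100, fdr = 0.10, seed = 1L) {
  fractions <- numeric(nCohorts)
  pooled <- list()
  for (i in seq_len(nCohorts)) {
    b <- simulateCohort(.nullCohortConfig(nLines, nGenes, nVariants,
                                          seed + i))
    geno <- genotypes(b)
    res <- mapCisLayer(AbundanceMatrix(b@latent$protein, "protein", TRUE),
                       geno, featureMap(b), K = computeKinship(geno),
                       nPerm = nPerm, fdr = fdr, seed = seed + 1000L * i,
                       donors = setNames(sampleTable(b)$donor,
                                         sampleTable(b)$line))
    fractions[i] <- mean(res$genes$significant)
    pooled[[i]] <- res$genes$pGene
  }
  pooledP <- unlist(pooled)
  list(sigFractions = fractions, meanSigFraction = mean(fractions),
       mcSe = sd(fractions) / sqrt(nCohorts), pooledP = pooledP,
       ksP = suppressWarnings(stats::ks.test(pooledP, "punif")$p.value))
}

## protein-layer residual variance implied by the generator defaults
## (coupling^2 * (rna noise^2 + donor sd^2) + protein noise^2)
.proteinBaseVar <- function(cfg)
  cfg$rnaProteinCoupling^2 * (cfg$noiseSdRna^2 + cfg$donorSd^2) +
  cfg$noiseSdProtein^2

#' Effect size planting a given fraction of explained variance
#'
#' @param varExplained target fraction of phenotype variance explained by
#'   the causal variant.
#' @param baseVar residual phenotype variance (default: the generator's
#'   protein-layer base variance).
#' @return the standardized effect size beta.
#' @export
betaForVariance <- function(varExplained, baseVar = 1.65)
  sqrt(varExplained / (1 - varExplained) * baseVar)

#' Cis-QTL recovery across a grid of planted effect sizes
#'
#' For each target variance fraction, simulates cohorts with `shared`-class
#' effects of the corresponding standardized beta, maps the protein layer
#' and counts a planted gene as recovered when it is significant at the FDR
#' threshold with a lead variant in LD r^2 > `r2Min` with the true causal
#' variant.
#'
#' @param varianceGrid fractions of phenotype variance explained.
#' @param nCohorts cohorts per grid point.
#' @param nLines,plantedPerCohort,nullPerCohort cohort composition.
#' @param nPerm,fdr,r2Min mapping and recovery parameters.
#' @param seed integer seed.
#' @return data.frame per grid point: `varExplained`, `beta`, `nPlanted`,
#'   `recoveryRate`.
#' @export
evaluateCisRecovery <- function(varianceGrid = c(0.05, 0.10, 0.20),
                                nCohorts = 10, nLines = 200,
                                plantedPerCohort = 10, nullPerCohort = 50,
                                nPerm = 100, fdr = 0.10, r2Min = 0.8,
                                seed = 1L) {
  rows <- lapply(seq_along(varianceGrid), function(gi) {
    v <- varianceGrid[gi]
    hits <- 0L; total <- 0L
    for (i in seq_len(nCohorts)) {
      cfg <- cohortConfig(
        nDonors = ceiling(nLines * 151 / 202), nLines = nLines,
        nVariants = (plantedPerCohort + nullPerCohort) * 10L,
        nGenes = plantedPerCohort + nullPerCohort,
        effectClassCounts = c(shared = plantedPerCohort),
        nComplexes = 0L, missingRate = 0,
        seed = seed + 100L * gi + i)
      beta <- betaForVariance(v, .proteinBaseVar(cfg))
      cfg$effectSizeRange <- c(beta, beta)
      b <- simulateCohort(cfg)
      geno <- genotypes(b)
      res <- mapCisLayer(AbundanceMatrix(b@latent$protein, "protein", TRUE),
                         geno, featureMap(b), K = computeKinship(geno),
                         nPerm = nPerm, fdr = fdr,
                         seed = seed + 17L * i + 1000L * gi,
                         donors = setNames(sampleTable(b)$donor,
                                           sampleTable(b)$line))
      tg <- cohortTruth(b)$genes
      planted <- tg[tg$class == "shared", ]
      m <- merge(res$genes, planted, by = "gene")
      d <- dosages(geno)
      rec <- m$significant & vapply(seq_len(nrow(m)), function(j)
        ldR2(d[m$leadVariant[j], ], d[m$causal_variant[j], ]) > r2Min,
        logical(1))
      hits <- hits + sum(rec); total <- total + nrow(m)
    }
    data.frame(varExplained = v,
               beta = betaForVariance(v, 1.65),
               nPlanted = total, recoveryRate = hits / total)
  })
  do.call(rbind, rows)
}

#' Mechanism-classification accuracy on planted cohorts
#'
#' Simulates cohorts with the three RNA-informative pQTL classes planted at
#' a fixed explained-variance fraction, maps the protein layer, classifies
#' each detected planted gene and scores the assignment against the truth
#' (shared -> gene expression effect, isoform-opposite -> transcript
#' isoform specific, protein-altering -> protein-altering variant).
#'
#' @param nCohorts number of cohorts.
#' @param varExplained planted variance fraction (>= 0.15 mirrors the
#'   strong-effect regime).
#' @param perClass planted genes per class per cohort.
#' @param nLines cohort size.
#' @param nPerm,fdr,replicationP,proxyR2 stage thresholds.
#' @param seed integer seed.
#' @return list with `accuracy`, `n`, and the per-gene `table` of truth
#'   versus assigned class.
#' @export
evaluateMechanismClassification <- function(nCohorts = 5,
                                            varExplained = 0.15,
                                            perClass = 6, nLines = 200,
                                            nPerm = 100, fdr = 0.10,
                                            replicationP = 0.01,
                                            proxyR2 = 0.8, seed = 1L) {
  mapTo <- c(shared = "gene_expression_effect",
             isoform_opposite = "transcript_isoform_specific",
             protein_altering = "protein_altering_variant")
  rows <- list()
  for (i in seq_len(nCohorts)) {
    cfg <- cohortConfig(
      nDonors = ceiling(nLines * 151 / 202), nLines = nLines,
      nVariants = (3 * perClass + 12) * 10L, nGenes = 3 * perClass + 12L,
      effectClassCounts = c(shared = perClass, isoform_opposite = perClass,
                            protein_altering = perClass),
      nComplexes = 0L, missingRate = 0, seed = seed + i)
    beta <- betaForVariance(varExplained, .proteinBaseVar(cfg))
    cfg$effectSizeRange <- c(beta, beta)
    b <- simulateCohort(cfg)
    geno <- genotypes(b)
    K <- computeKinship(geno)
    fmap <- featureMap(b)
    res <- mapCisLayer(AbundanceMatrix(b@latent$protein, "protein", TRUE),
                       geno, fmap, K = K, nPerm = nPerm, fdr = fdr,
                       seed = seed + 31L * i,
                       donors = setNames(sampleTable(b)$donor,
                                         sampleTable(b)$line))
    rna <- AbundanceMatrix(b@latent$rna_gene, "rna_gene", TRUE)
    rnaTx <- AbundanceMatrix(b@latent$rna_transcript, "rna_transcript", TRUE)
    tg <- cohortTruth(b)$genes
    sig <- res$genes[res$genes$significant &
                       res$genes$gene %in%
                         tg$gene[tg$class %in% names(mapTo)], ]
    cfgP <- list(proxyR2 = proxyR2, replicationP = replicationP)
    for (j in seq_len(nrow(sig))) {
      lead <- data.frame(gene = sig$gene[j], variant = sig$leadVariant[j],
                         beta = sig$beta[j])
      geneRow <- fmap[fmap$layer == "rna_gene" &
                        fmap$gene == lead$gene, ][1, ]
      cls <- .classifyAtLead(lead, rna, rnaTx, geno, NULL, K, fmap,
                             b@variantEffects, geneRow, cfgP)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = lead$gene, truth = tg$class[tg$gene == lead$gene],
        assigned = cls$class, stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  list(accuracy = mean(d$assigned == mapTo[d$truth]), n = nrow(d),
       table = table(d$truth, d$assigned))
}

#' Trans-QTL recovery through planted protein complexes
#'
#' Simulates cohorts where each complex's limiting subunit carries a cis
#' effect of standardized size `beta`, propagated to partner subunits at
#' the generator's stoichiometric rate. The protein layer is mapped in cis;
#' significant leads seed a trans scan, and a partner counts as recovered
#' when significant at the FDR threshold with a beta of the propagated
#' sign.
#'
#' @param nSims number of simulated cohorts.
#' @param beta planted cis effect size.
#' @param nLines cohort size.
#' @param nPerm,fdr stage thresholds.
#' @param seed integer seed.
#' @return list with `recoveryRate` (per-partner), `nPartners` and
#'   `signConcordance` among recovered partners.
#' @export
evaluateTransRecovery <- function(nSims = 10, beta = 0.8, nLines = 200,
                                  nPerm = 100, fdr = 0.10, seed = 1L) {
  hits <- 0L; total <- 0L; signOk <- 0L
  for (i in seq_len(nSims)) {
    cfg <- cohortConfig(
      nDonors = ceiling(nLines * 151 / 202), nLines = nLines,
      nVariants = 400L, nGenes = 40L,
      effectClassCounts = c(shared = 6L), nComplexes = 3L,
      effectSizeRange = c(beta, beta), missingRate = 0, seed = seed + i)
    b <- simulateCohort(cfg)
    geno <- genotypes(b)
    K <- computeKinship(geno)
    prot <- AbundanceMatrix(b@latent$protein, "protein", TRUE)
    res <- mapCisLayer(prot, geno, featureMap(b), K = K, nPerm = nPerm,
                       fdr = fdr, seed = seed + 7L * i,
                       donors = setNames(sampleTable(b)$donor,
                                         sampleTable(b)$line))
    sig <- res$genes[res$genes$significant, ]
    tr <- cohortTruth(b)
    cx <- tr$complexes
    lims <- cx$gene[cx$limiting]
    sigLims <- sig[sig$gene %in% lims, ]
    if (!nrow(sigLims)) next
    trans <- transScan(data.frame(gene = sigLims$gene,
                                  variant = sigLims$leadVariant),
                       prot, geno, featureMap(b), K = K, fdr = fdr)
    for (j in seq_len(nrow(sigLims))) {
      lim <- sigLims$gene[j]
      id <- cx$complex[cx$gene == lim][1]
      partners <- setdiff(cx$gene[cx$complex == id], lim)
      betaCis <- tr$genes$beta_protein[match(lim, tr$genes$gene)]
      for (p in partners) {
        total <- total + 1L
        hit <- trans$results[trans$results$cisGene == lim &
                               trans$results$transGene == p, ]
        if (nrow(hit) && any(hit$significant)) {
          hits <- hits + 1L
          if (sign(hit$beta[which.max(hit$significant)]) == sign(betaCis))
            signOk <- signOk + 1L
        }
      }
    }
  }
  list(recoveryRate = if (total) hits / total else NA, nPartners = total,
       signConcordance = if (hits) signOk / hits else NA)
}

#' Batch-effect removal assessed by principal components
#'
#' Simulates a cohort with strong planted TMT batch shifts, runs the full
#' proteomics normalization, and reports the multiple correlation between
#' the first principal component of the protein matrix and the batch label,
#' before and after normalization.
#'
#' @param nLines,nGenes cohort dimensions.
#' @param batchSd planted per-feature batch-shift standard deviation.
#' @param seed integer seed.
#' @return list with `rBefore`, `rAfter` and the normalized bundle report.
#' @export
evaluateBatchRemoval <- function(nLines = 202, nGenes = 60, batchSd = 1.0,
                                 seed = 1L) {
  cfg <- cohortConfig(nDonors = ceiling(nLines * 151 / 202),
                      nLines = nLines, nGenes = nGenes,
                      nVariants = nGenes * 10L, batchSd = batchSd,
                      channelSd = 0.1, missingRate = 0.05, seed = seed)
  b <- simulateCohort(cfg)
  batch <- factor(sampleTable(b)$batch)
  pcBatchR <- function(m) {
    m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
    pc1 <- prcomp(t(m), scale. = FALSE)$x[, 1]
    sqrt(summary(lm(pc1 ~ batch))$r.squared)
  }
  rawProt <- log2(assayValues(cohortLayer(b, "protein")) + 1)
  norm <- processProteomics(b)
  normProt <- assayValues(norm$protein)[, colnames(rawProt), drop = FALSE]
  list(rBefore = pcBatchR(rawProt), rAfter = pcBatchR(normProt),
       report = norm$report)
}

#' XCI score accuracy and detection power
#'
#' Simulates female lines with known X-inactivation erosion, scores them
#' from binomial allele-specific counts ([computeXciStatus()]), and tests
#' detection of XCI-responsive genes ([correlateExpressionWithXci()])
#' planted at a fixed explained-variance fraction among unresponsive
#' background genes.
#'
#' @param nSims simulation replicates.
#' @param nFemales female lines per replicate.
#' @param nSnps,meanReads heterozygous chrX SNPs per line and mean read
#'   depth.
#' @param varExplained fraction of responsive-gene abundance variance
#'   explained by erosion.
#' @param nResponsive,nBackground genes per replicate.
#' @param fdr detection threshold.
#' @param seed integer seed.
#' @return list with `meanScoreError` (mean signed score - erosion error),
#'   `meanAbsScoreError`, `detectionRate` (responsive genes significant at
#'   the FDR threshold with the planted direction) and `nResponsive`.
#' @export
evaluateXciDetection <- function(nSims = 20, nFemales = 110, nSnps = 50,
                                 meanReads = 100, varExplained = 0.15,
                                 nResponsive = 5, nBackground = 45,
                                 fdr = 0.10, seed = 1L) {
  set.seed(seed)
  errs <- c(); hits <- 0L; total <- 0L
  sdE <- sqrt(0.25 / 12)              # sd of U(0, 0.5) erosion
  noiseSd <- 1
  slope <- noiseSd * sqrt(varExplained / (1 - varExplained)) / sdE
  for (s in seq_len(nSims)) {
    lines <- sprintf("f%03d", seq_len(nFemales))
    e <- runif(nFemales, 0, 0.5)
    ase <- do.call(rbind, lapply(seq_len(nFemales), function(i) {
      total <- rpois(nSnps, meanReads)
      minor <- rbinom(nSnps, total, e[i])
      flip <- runif(nSnps) < 0.5
      data.frame(line = lines[i], snp = sprintf("s%03d", seq_len(nSnps)),
                 ref_count = ifelse(flip, minor, total - minor),
                 alt_count = ifelse(flip, total - minor, minor))
    }))
    scores <- computeXciStatus(ase, minReads = 20)
    sc <- setNames(scores$score, scores$line)
    errs <- c(errs, sc[lines] - e)
    dirs <- sample(c(-1, 1), nResponsive, replace = TRUE)
    v <- rbind(
      t(vapply(seq_len(nResponsive), function(g)
        dirs[g] * slope * e + rnorm(nFemales, 0, noiseSd), numeric(nFemales))),
      matrix(rnorm(nBackground * nFemales, 0, noiseSd), nBackground))
    dimnames(v) <- list(c(sprintf("resp%02d", seq_len(nResponsive)),
                          sprintf("null%02d", seq_len(nBackground))), lines)
    res <- correlateExpressionWithXci(
      AbundanceMatrix(v, "rna_gene", TRUE), sc, fdr = fdr)
    for (g in seq_len(nResponsive)) {
      total <- total + 1L
      row <- res[res$feature == sprintf("resp%02d", g), ]
      if (nrow(row) && row$significant && row$direction == dirs[g])
        hits <- hits + 1L
    }
  }
  list(meanScoreError = mean(errs), meanAbsScoreError = mean(abs(errs)),
       detectionRate = hits / total, nResponsive = total)
}
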