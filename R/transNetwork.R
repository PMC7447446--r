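#' Peptide-to-cis-protein alignment filter for trans associations
#'
#' Guards against trans associations created by peptides mis-assigned
#' between sequence-similar proteins. Each quantifying peptide of the trans
#' protein is locally aligned to the cis protein sequence (match +1,
#' mismatch 0, gap open and extension penalties 1); the mismatch count is
#' the peptide length minus the number of identically aligned residues in
#' its best local alignment, so unaligned residues count as mismatches. The
#' trans association is discarded iff any peptide has fewer than
#' `maxMismatch` mismatches.
#'
#' @param transPeptides named character vector of peptide amino-acid
#'   sequences.
#' @param cisProteinSeq cis protein amino-acid sequence.
#' @param maxMismatch discard when a peptide's mismatch count is strictly
#'   below this (default 2).
#' @return list with `discard` (logical) and `mismatches` (named integer
#'   per peptide).
#' @export
peptideAlignmentFilter <- function(transPeptides, cisProteinSeq,
                                   maxMismatch = 2L) {
  if (!length(transPeptides) || any(nchar(transPeptides) == 0) ||
      nchar(cisProteinSeq) == 0)
    stop("empty sequence")
  letters <- Biostrings::AA_ALPHABET
  mat <- matrix(0, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(mat) <- 1
  res <- vapply(transPeptides, function(pep) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(pep),
      subject = Biostrings::AAString(cisProteinSeq),
      type = "local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 1)   # every gap position costs 1
    c(nchar(pep) - Biostrings::nmatch(aln), Biostrings::score(aln))
  }, numeric(2))
  mm <- res[1, ]
  list(discard = any(mm < maxMismatch), mismatches = mm,
       scores = res[2, ])
}

.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Protein-protein interaction enrichment of cis-trans pairs
#'
#' For each FDR threshold on the trans scan, computes the fraction of
#' significant cis-trans gene pairs present in a reference interaction list
#' (unordered pairs) and the Fisher enrichment of support among significant
#' versus non-significant tested pairs.
#'
#' @param transResults trans scan results with `cisGene`, `transGene`, `q`.
#' @param ppi data.frame of reference pairs (`gene_a`, `gene_b`).
#' @param fdrGrid FDR thresholds to evaluate (includes 0.10 by default).
#' @return data.frame per threshold: `fdr`, `nSignificant`,
#'   `fractionSupported`, `oddsRatio`, `p`; attribute `ppiEmpty` flags an
#'   empty reference.
#' @export
ppiEnrichment <- function(transResults, ppi,
                          fdrGrid = c(0.01, 0.05, 0.10, 0.20)) {
  refKeys <- if (nrow(ppi)) .pairKey(ppi$gene_a, ppi$gene_b) else character(0)
  keys <- .pairKey(transResults$cisGene, transResults$transGene)
  supported <- keys %in% refKeys
  out <- do.call(rbind, lapply(fdrGrid, function(thr) {
    sig <- transResults$q < thr
    frac <- if (any(sig)) mean(supported[sig]) else 0
    if (!length(refKeys) || !any(sig) || all(sig)) {
      or <- NA; p <- NA
    } else {
      tab <- matrix(c(sum(sig & supported), sum(sig & !supported),
                      sum(!sig & supported), sum(!sig & !supported)),
                    2, 2, byrow = TRUE)
      fe <- fisherEnrichment(tab)
      or <- fe$oddsRatio; p <- fe$p
    }
    data.frame(fdr = thr, nSignificant = sum(sig),
               fractionSupported = if (length(refKeys)) frac else 0,
               oddsRatio = or, p = p)
  }))
  attr(out, "ppiEmpty") <- !length(refKeys)
  out
}

#' Concordance of cis and trans effect sizes
#'
#' @param transAssoc data.frame with `betaCis`, `betaTrans`, and optionally
#'   `ppiSupported`.
#' @return list with `n`, `signConcordance`, `correlation` (NA with
#'   `correlationDefined = FALSE` when fewer than 3 pairs) and, when
#'   `ppiSupported` is present, the same summaries per stratum in
#'   `byPpiSupport`.
#' @export
cisTransEffectComparison <- function(transAssoc) {
  summarise <- function(d) {
    n <- nrow(d)
    if (n == 0)
      return(list(n = 0, signConcordance = NA, correlation = NA,
                  correlationDefined = FALSE))
    conc <- mean(sign(d$betaCis) == sign(d$betaTrans))
    ok <- n >= 3 && sd(d$betaCis) > 0 && sd(d$betaTrans) > 0
    list(n = n, signConcordance = conc,
         correlation = if (ok) cor(d$betaCis, d$betaTrans) else NA,
         correlationDefined = ok)
  }
  out <- summarise(transAssoc)
  if (!is.null(transAssoc$ppiSupported) && nrow(transAssoc))
    out$byPpiSupport <- lapply(split(transAssoc, transAssoc$ppiSupported),
                               summarise)
  out
}

#' Per-complex co-regulation summary
#'
#' For each protein complex reports (i) the mean pairwise co-expression
#' correlation of its quantified subunits, (ii) the member with the most
#' significant cis pQTL, (iii) the fraction of the other members associated
#' with that member's lead variant at nominal significance (p < 0.01), and
#' (iv) the donor variance fraction of the averaged complex abundance
#' profile. Complexes with fewer than two quantified members are skipped
#' with a warning.
#'
#' @param complexes data.frame with `complex` and `gene` columns.
#' @param protein log-scale protein [AbundanceMatrix-class] (rownames
#'   `pg_<gene>`).
#' @param cisGenes gene-level cis pQTL summary (`gene`, `leadVariant`,
#'   `pGene`).
#' @param geno a [GenotypeData-class].
#' @param samples sample table (for the donor covariance).
#' @param covariates,K passed to the association model.
#' @param pThreshold nominal co-association threshold (default 0.01).
#' @return data.frame per complex: `complex`, `nQuantified`, `meanPairCor`,
#'   `leadGene`, `leadVariant`, `fractionCoAssociated`, `donorFraction`.
#' @export
complexSummary <- function(complexes, protein, cisGenes, geno, samples,
                           covariates = NULL, K = NULL, pThreshold = 0.01) {
  if (is.null(K)) K <- computeKinship(geno)
  v <- assayValues(protein)
  covs <- buildCategoricalCovariances(samples, factors = "donor")
  rows <- list()
  for (cx in unique(complexes$complex)) {
    genes <- complexes$gene[complexes$complex == cx]
    pgs <- intersect(paste0("pg_", genes), rownames(v))
    if (length(pgs) < 2) {
      warning("complex ", cx, " has <2 quantified members; skipped")
      next
    }
    sub <- v[pgs, , drop = FALSE]
    cc <- cor(t(sub), use = "pairwise.complete.obs")
    meanCor <- mean(cc[upper.tri(cc)], na.rm = TRUE)
    hits <- cisGenes[cisGenes$gene %in% genes, , drop = FALSE]
    leadGene <- NA; leadVar <- NA; fracCo <- NA
    if (nrow(hits)) {
      i <- which.min(hits$pGene)
      leadGene <- hits$gene[i]; leadVar <- hits$leadVariant[i]
      others <- setdiff(pgs, paste0("pg_", leadGene))
      g <- dosages(geno)[leadVar, ]
      pvals <- vapply(others, function(pg) {
        lmmAssociation(v[pg, ], g, covariates = covariates, K = K)$p
      }, numeric(1))
      fracCo <- mean(pvals < pThreshold)
    }
    avg <- colMeans(sub, na.rm = TRUE)
    ok <- !is.na(avg)
    fit <- fitVarianceComponents((avg[ok] - mean(avg[ok])) / sd(avg[ok]),
                                 lapply(covs, function(M) M[ok, ok]))
    rows[[length(rows) + 1L]] <- data.frame(
      complex = cx, nQuantified = length(pgs), meanPairCor = meanCor,
      leadGene = leadGene, leadVariant = leadVar,
      fractionCoAssociated = fracCo,
      donorFraction = fit$fractions[["donor"]], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
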