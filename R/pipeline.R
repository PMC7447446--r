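#' Pipeline configuration with the canonical thresholds
#'
#' Collects every numeric threshold the stages use, with defaults equal to
#' the values used throughout the analysis: recurrence in >= 30 lines, cis
#' window +/- 250 kb, MAF > 5%, 100 permutations, FDR 10%, replication
#' p < 0.01, LD proxies at r^2 > 0.8, SIFT deleteriousness < 0.05, strong
#' variance contribution > 20%, XCI SNPs with >= 20 reads.
#'
#' @param cohort a [cohortConfig()] describing the (synthetic) cohort.
#' @param minLines,window,mafMin,nPerm,fdr stage thresholds.
#' @param replicationP,proxyR2,siftDeleterious,varianceThreshold,xciMinReads
#'   downstream-stage thresholds.
#' @param kProtein,kRna number of hidden factors per layer ("auto" to
#'   select by the independence criterion, or an integer).
#' @param seed integer master seed.
#' @return a validated list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(cohort = cohortConfig(), minLines = 30,
                           window = 250000, mafMin = 0.05, nPerm = 100,
                           fdr = 0.10, replicationP = 0.01, proxyR2 = 0.8,
                           siftDeleterious = 0.05, varianceThreshold = 0.20,
                           xciMinReads = 20, kProtein = 3L, kRna = 3L,
                           seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Run the full analysis pipeline on a (synthetic) cohort
#'
#' Executes the stages in dependency order: cohort simulation,
#' normalization (line filter, polymorphic-peptide filter, recurrence
#' filter, aggregation, batch scaling, quantile normalization), hidden
#' factors, cis QTL mapping on all four layers, cross-layer replication and
#' mechanism classification, trans scan with the peptide-alignment filter
#' and PPI enrichment, variance decomposition on the paired-donor subset,
#' and XCI analysis. Writes stage outputs plus a summary JSON when `outDir`
#' is given; a rerun with identical config and seed reproduces the summary
#' byte for byte.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory for TSV/JSON stage outputs.
#' @param bundle optional pre-built [CohortBundle-class] (skips simulation).
#' @return list with the per-stage results and `summary` (the summary
#'   tables written to JSON).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        bundle = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.null(bundle)) {
    config$cohort$seed <- config$seed
    bundle <- simulateCohort(config$cohort)
  }
  samples <- sampleTable(bundle)
  donors <- setNames(samples$donor, samples$line)
  geno <- genotypes(bundle)
  K <- computeKinship(geno)
  fmap <- featureMap(bundle)

  ## normalisation
  prot <- processProteomics(bundle, minLines = config$minLines)
  keepLines <- lineIds(prot$protein)
  rna <- prepareRna(cohortLayer(bundle, "rna_gene")[, keepLines])
  rnaTx <- prepareRna(cohortLayer(bundle, "rna_transcript")[, keepLines])

  ## hidden factors
  facProt <- fitHiddenFactors(prot$protein,
                              k = .resolveK(config$kProtein, prot$protein),
                              seed = config$seed)
  facRna <- fitHiddenFactors(rna, k = .resolveK(config$kRna, rna),
                             seed = config$seed)

  ## cis scans per layer
  scan <- function(m, cov) mapCisLayer(m, geno, fmap, covariates = cov,
                                       K = K, window = config$window,
                                       mafMin = config$mafMin,
                                       nPerm = config$nPerm, fdr = config$fdr,
                                       seed = config$seed, donors = donors)
  cisP <- scan(prot$protein, facProt$factors)
  cisE <- scan(rna, facRna$factors)
  cisT <- scan(rnaTx, facRna$factors)
  cisPep <- scan(prot$peptide, facProt$factors)

  ## replication + mechanism for significant pQTL genes
  sigP <- cisP$genes[cisP$genes$significant, , drop = FALSE]
  mech <- NULL
  if (nrow(sigP)) {
    mech <- do.call(rbind, lapply(seq_len(nrow(sigP)), function(i) {
      lead <- data.frame(gene = sigP$gene[i], variant = sigP$leadVariant[i],
                         beta = sigP$beta[i])
      geneRow <- fmap[fmap$layer == "rna_gene" & fmap$gene == lead$gene, ][1, ]
      .classifyAtLead(lead, rna, rnaTx, geno, facRna$factors, K, fmap,
                      bundle@variantEffects, geneRow, config)
    }))
  }

  ## trans scan
  trans <- NULL
  if (nrow(sigP)) {
    leads <- data.frame(gene = sigP$gene, variant = sigP$leadVariant,
                        stringsAsFactors = FALSE)
    trans <- transScan(leads, prot$protein, geno, fmap,
                       covariates = facProt$factors, K = K,
                       window = config$window, fdr = config$fdr)
    sig <- trans$results[trans$results$significant, , drop = FALSE]
    if (nrow(sig)) {
      keep <- vapply(seq_len(nrow(sig)), function(i) {
        peps <- bundle@peptideSeqs[
          fmap$feature[fmap$layer == "peptide" &
                         fmap$parent == sig$protein[i]]]
        cisSeq <- bundle@proteinSeqs[[paste0("pg_", sig$cisGene[i])]]
        !peptideAlignmentFilter(peps, cisSeq)$discard
      }, logical(1))
      trans$alignmentFiltered <- sig[!keep, , drop = FALSE]
      trans$significant <- sig[keep, , drop = FALSE]
    } else {
      trans$significant <- sig
      trans$alignmentFiltered <- sig
    }
    trans$ppi <- ppiEnrichment(trans$results, bundle@ppi)
  }

  ## variance components on the paired-donor subset
  paired <- samples[samples$donor %in%
                      names(which(table(samples$donor) == 2)), ]
  paired <- paired[paired$line %in% keepLines, ]
  paired <- paired[paired$donor %in%
                     names(which(table(paired$donor) == 2)), ]
  vc <- decomposeVarianceMatrix(prot$protein[, paired$line], paired,
                                nRestarts = 2)
  vcSummary <- summarizeFractions(vc, config$varianceThreshold)

  ## XCI
  xciScores <- computeXciStatus(aseCounts(bundle), config$xciMinReads,
                                samples = samples)
  scores <- setNames(xciScores$score, xciScores$line)
  scores <- scores[names(scores) %in% keepLines]
  xciRna <- correlateExpressionWithXci(rna, scores, fdr = config$fdr)
  xciProt <- correlateExpressionWithXci(prot$protein, scores,
                                        fdr = config$fdr)

  summary <- list(
    cohort = list(nLines = nrow(samples),
                  nDonors = length(unique(samples$donor)),
                  nVariants = nrow(dosages(geno))),
    normalization = prot$report,
    factors = list(kProtein = facProt$k, kRna = facRna$k),
    cis = list(pqtlGenes = sum(cisP$genes$significant),
               eqtlGenes = sum(cisE$genes$significant),
               tqtlGenes = if (!is.null(cisT$genes))
                 sum(cisT$genes$significant) else 0,
               pepqtlGenes = if (!is.null(cisPep$genes))
                 sum(cisPep$genes$significant) else 0),
    mechanism = if (!is.null(mech)) as.list(table(mech$class)) else list(),
    trans = if (!is.null(trans))
      list(nTests = trans$nTests,
           nSignificant = nrow(trans$significant),
           nAlignmentFiltered = nrow(trans$alignmentFiltered)) else list(),
    variance = list(nAboveThreshold = setNames(as.list(vcSummary$nAbove),
                                               vcSummary$factor)),
    xci = list(nScoredLines = sum(!is.na(scores)),
               rnaGenes = if (!is.null(xciRna)) sum(xciRna$significant) else 0,
               proteinGenes = if (!is.null(xciProt))
                 sum(xciProt$significant) else 0))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTsv(cisP$genes, file.path(outDir, "cis_pqtl_genes.tsv"))
    .writeTsv(cisE$genes, file.path(outDir, "cis_eqtl_genes.tsv"))
    if (!is.null(mech)) .writeTsv(mech, file.path(outDir, "mechanism.tsv"))
    if (!is.null(trans))
      .writeTsv(trans$results, file.path(outDir, "trans_results.tsv"))
    .writeTsv(vc, file.path(outDir, "variance_components.tsv"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
    jsonlite::write_json(unclass(config)[setdiff(names(config), "cohort")],
                         file.path(outDir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(bundle = bundle, normalized = prot, rna = rna,
                 factors = list(protein = facProt, rna = facRna),
                 cis = list(protein = cisP, rna_gene = cisE,
                            rna_transcript = cisT, peptide = cisPep),
                 mechanism = mech, trans = trans, variance = vc,
                 xci = list(scores = xciScores, rna = xciRna,
                            protein = xciProt),
                 summary = summary))
}

.resolveK <- function(k, matrix) {
  if (identical(k, "auto")) selectFactorCount(matrix, kMax = 10) else
    as.integer(k)
}

## classify one pQTL lead given RNA/transcript matrices: nominal LMM tests
## at the lead variant plus gene-body proxy annotation
.classifyAtLead <- function(lead, rna, rnaTx, geno, covariates, K, fmap,
                            variantEffects, geneRow, config) {
  g <- dosages(geno)[lead$variant, ]
  assocAt <- function(m, feats) {
    feats <- intersect(feats, featureIds(m))
    do.call(rbind, lapply(feats, function(f) {
      a <- tryCatch(lmmAssociation(assayValues(m)[f, ], g,
                                   covariates = covariates, K = K),
                    error = function(e) NULL)
      if (is.null(a)) return(NULL)
      data.frame(gene = lead$gene, feature = f, variant = lead$variant,
                 beta = a$beta, p = a$p, stringsAsFactors = FALSE)
    }))
  }
  eq <- assocAt(rna, lead$gene)
  tq <- assocAt(rnaTx, fmap$feature[fmap$layer == "rna_transcript" &
                                      fmap$gene == lead$gene])
  if (is.null(eq))
    eq <- data.frame(gene = character(0), feature = character(0),
                     variant = character(0), beta = numeric(0),
                     p = numeric(0))
  prox <- ldProxies(lead$variant, geno, r2Min = config$proxyR2,
                    region = list(chrom = geneRow$chrom,
                                  start = geneRow$start,
                                  end = geneRow$end))
  cats <- groupVariantEffects(
    variantEffects$term[variantEffects$variant %in% prox])
  classifyMechanism(lead, eq, tq, cats, pThreshold = config$replicationP)
}
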