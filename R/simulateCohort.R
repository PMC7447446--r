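#' Configuration for a synthetic proteogenomic cohort
#'
#' Builds and validates the parameter set for [simulateCohort()]. Defaults
#' emulate a population-scale induced pluripotent stem cell cohort: 202 lines
#' from 151 unrelated donors (a subset of donors contributing two lines),
#' common biallelic variants organised in LD blocks, TMT batches of roughly
#' ten lines sharing a reference-line replicate, four mechanistic classes of
#' planted cis effects, trans effects propagated through protein complexes,
#' peptide-level detection missingness and X-inactivation erosion in female
#' lines. Feature and variant counts default to a desk-scale genome so that
#' a full cohort simulates in seconds; they are fully configurable.
#'
#' @param nDonors number of unrelated donors.
#' @param nLines number of cell lines (>= `nDonors`); the first
#'   `nLines - nDonors` sampled donors contribute a second line.
#' @param nVariants total number of simulated variants (spread over genes).
#' @param nGenes number of genes (each with transcripts, one protein group
#'   and peptides).
#' @param mafRange range of LD-block allele frequencies, within (0, 0.5].
#' @param ldBlockSize number of variants per LD block.
#' @param ldDecay per-variant haplotype copying probability within a block;
#'   adjacent-variant genotype correlation, so r^2 decays geometrically.
#' @param nTmtBatches number of TMT batches (default: lines / 10, rounded up).
#' @param batchSd,channelSd standard deviation of per-feature per-batch and
#'   per-channel additive log-intensity shifts.
#' @param batchLoadingSd standard deviation of the shared per-batch sample
#'   loading shift applied to every feature (defaults to `batchSd`); this
#'   coherent component is what makes batch structure visible to principal
#'   components of the raw data.
#' @param missingRate independent peptide-level missingness probability.
#' @param effectClassCounts named counts of planted cis-effect classes among
#'   `shared`, `rna_only`, `isoform_opposite`, `protein_altering`, `null`.
#' @param effectSizeRange range of standardized planted effect sizes (trait
#'   shift in log units per standard-deviation of dosage).
#' @param nComplexes,complexSizeRange number and size range of protein
#'   complexes used to propagate trans effects.
#' @param transPropagation multiplier applied to the limiting subunit's cis
#'   effect when propagated to partner subunits.
#' @param complexSd standard deviation of the shared complex co-expression
#'   latent factor.
#' @param xciErosionRange range of X-inactivation erosion levels for female
#'   lines, within [0, 0.5] (0 = fully inactivated, 0.5 = fully biallelic).
#' @param nXciSnps,xciMeanReads heterozygous chrX SNPs per female line and
#'   mean read depth of the allele-specific counts.
#' @param peptidesPerProteinRange range of peptides per protein group.
#' @param noiseSdRna,noiseSdProtein residual log-scale noise s.d. for the
#'   RNA and protein layers.
#' @param donorSd s.d. of the per-gene donor random effect (log units).
#' @param rnaProteinCoupling baseline coupling of protein log abundance to
#'   the coding transcript's (pre-effect) deviation.
#' @param polymorphicPeptideRate,unmappedPeptideRate fraction of peptides
#'   overlapping a common non-synonymous variant / lacking a genomic
#'   position in the emitted peptide genomic map.
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @return a validated list of class `"cohortConfig"`.
#' @export
cohortConfig <- function(nDonors = 151L, nLines = 202L,
                         nVariants = 600L, nGenes = 60L,
                         mafRange = c(0.1, 0.5), ldBlockSize = 10L,
                         ldDecay = 0.98, nTmtBatches = NULL,
                         batchSd = 0.3, batchLoadingSd = NULL,
                         channelSd = 0.1, missingRate = 0.05,
                         effectClassCounts = c(shared = 6L, rna_only = 4L,
                                               isoform_opposite = 4L,
                                               protein_altering = 4L,
                                               null = 0L),
                         effectSizeRange = c(0.5, 1.0),
                         nComplexes = 3L, complexSizeRange = c(3L, 5L),
                         transPropagation = 0.8, complexSd = 0.3,
                         xciErosionRange = c(0, 0.5),
                         nXciSnps = 50L, xciMeanReads = 100,
                         peptidesPerProteinRange = c(3L, 30L),
                         noiseSdRna = 1, noiseSdProtein = 1,
                         donorSd = 0.4, rnaProteinCoupling = 0.7,
                         polymorphicPeptideRate = 0.02,
                         unmappedPeptideRate = 0.02,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$batchLoadingSd)) cfg$batchLoadingSd <- cfg$batchSd
  .checkConfig(cfg)
  class(cfg) <- "cohortConfig"
  cfg
}

.cfgError <- function(field, msg)
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)

.checkConfig <- function(cfg) {
  if (cfg$nLines < cfg$nDonors)
    .cfgError("nLines", "must be >= nDonors")
  if (cfg$nLines - cfg$nDonors > cfg$nDonors)
    .cfgError("nLines", "at most one repeat line per donor is supported")
  for (f in c("missingRate", "polymorphicPeptideRate", "unmappedPeptideRate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) .cfgError(f, "must lie in [0, 1]")
  if (any(cfg$mafRange <= 0) || any(cfg$mafRange > 0.5))
    .cfgError("mafRange", "must lie within (0, 0.5]")
  if (any(cfg$xciErosionRange < 0) || any(cfg$xciErosionRange > 0.5))
    .cfgError("xciErosionRange", "must lie within [0, 0.5]")
  classes <- c("shared", "rna_only", "isoform_opposite", "protein_altering",
               "null")
  if (!all(names(cfg$effectClassCounts) %in% classes))
    .cfgError("effectClassCounts",
              sprintf("classes must be among: %s", paste(classes, collapse = ", ")))
  nChrx <- .nChrxGenes(cfg$nGenes)
  if (sum(cfg$effectClassCounts) > cfg$nGenes - nChrx)
    .cfgError("effectClassCounts",
              "sum exceeds the number of autosomal genes available")
  if (cfg$nComplexes * max(cfg$complexSizeRange) > cfg$nGenes)
    .cfgError("nComplexes", "complex members exceed nGenes")
  if (floor(cfg$nVariants / cfg$nGenes) < 2)
    .cfgError("nVariants", "need at least 2 variants per gene")
  invisible(TRUE)
}

.nChrxGenes <- function(nGenes) max(2L, round(0.08 * nGenes))

## geometric-LD block genotypes: one allele-frequency per block, each
## haplotype allele copied from its neighbour with probability ldDecay
.simulateBlockDosages <- function(nVar, nDonors, maf, ldDecay, blockSize) {
  nBlocks <- ceiling(nVar / blockSize)
  h1 <- matrix(0L, nVar, nDonors)
  h2 <- matrix(0L, nVar, nDonors)
  for (b in seq_len(nBlocks)) {
    idx <- ((b - 1L) * blockSize + 1L):min(b * blockSize, nVar)
    f <- runif(1, maf[1], maf[2])
    for (hap in 1:2) {
      H <- matrix(0L, length(idx), nDonors)
      H[1, ] <- rbinom(nDonors, 1L, f)
      if (length(idx) > 1) for (j in 2:length(idx)) {
        copy <- rbinom(nDonors, 1L, ldDecay)
        H[j, ] <- ifelse(copy == 1L, H[j - 1L, ], rbinom(nDonors, 1L, f))
      }
      if (hap == 1) h1[idx, ] <- H else h2[idx, ] <- H
    }
  }
  h1 + h2
}

#' Simulate a complete synthetic cohort
#'
#' Generates genotypes (donor-shared across repeat lines), sample metadata,
#' raw abundance matrices for the four molecular layers, a feature map,
#' reference-line TMT replicates, allele-specific chrX counts, protein and
#' peptide sequences, a variant-effect annotation table, a protein-protein
#' interaction reference, and the ground-truth table of planted effects.
#'
#' The generative model works on the natural-log scale: transcript log
#' abundances carry a per-gene donor random effect and i.i.d. noise; the
#' gene-level RNA value is the abundance-weighted mean of its transcripts'
#' log values; the protein log signal couples to the coding transcript's
#' baseline deviation plus complex co-expression and protein noise; peptide
#' log intensities share their protein's signal. Cis effects of the four
#' mechanistic classes are then added by [plantCisEffects()], trans effects
#' are propagated through complexes from each limiting subunit, chrX genes
#' respond to X-inactivation erosion ([simulateXci()]), and TMT batch and
#' channel shifts plus detection missingness are applied by
#' [applyTmtStructure()] before exponentiating to raw intensities.
#'
#' @param config a [cohortConfig()] list.
#' @return a [CohortBundle-class].
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  cfg <- config
  set.seed(cfg$seed)

  ## ---- samples -----------------------------------------------------------
  donors <- sprintf("donor_%03d", seq_len(cfg$nDonors))
  nRep <- cfg$nLines - cfg$nDonors
  repDonors <- if (nRep > 0) sample(donors, nRep) else character(0)
  lineDonor <- c(donors, repDonors)
  lines <- sprintf("line_%03d", seq_len(cfg$nLines))
  sexByDonor <- setNames(sample(c("female", "male"), cfg$nDonors,
                                replace = TRUE, prob = c(0.545, 0.455)),
                         donors)
  ageByDonor <- setNames(sample(25:70, cfg$nDonors, replace = TRUE), donors)
  nB <- if (is.null(cfg$nTmtBatches)) ceiling(cfg$nLines / 10) else
    cfg$nTmtBatches
  batch <- sample(rep(seq_len(nB), length.out = cfg$nLines))
  channel <- integer(cfg$nLines)
  for (b in seq_len(nB)) {
    idx <- which(batch == b)
    channel[idx] <- seq_along(idx) + 1L   # channel 1 holds the reference
  }
  samples <- data.frame(line = lines, donor = lineDonor,
                        sex = sexByDonor[lineDonor],
                        age = ageByDonor[lineDonor],
                        medium = sample(c("E8", "mTeSR"), cfg$nLines,
                                        replace = TRUE),
                        batch = sprintf("batch_%02d", batch),
                        channel = sprintf("ch_%02d", channel),
                        stringsAsFactors = FALSE, row.names = NULL)
  refLine <- lines[1]

  ## ---- gene models -------------------------------------------------------
  nChrx <- .nChrxGenes(cfg$nGenes)
  geneIds <- sprintf("gene_%03d", seq_len(cfg$nGenes))
  isChrx <- c(rep(FALSE, cfg$nGenes - nChrx), rep(TRUE, nChrx))
  chromPool <- paste0("chr", 1:4)
  chrom <- ifelse(isChrx, "chrX",
                  chromPool[(seq_len(cfg$nGenes) - 1L) %% 4L + 1L])
  posIdx <- stats::ave(seq_len(cfg$nGenes), chrom, FUN = seq_along)
  geneStart <- posIdx * 1000000L
  geneEnd <- geneStart + 20000L

  counts <- cfg$effectClassCounts
  classes <- rep("null", cfg$nGenes)
  auto <- which(!isChrx)
  pool <- sample(auto)
  i <- 1L
  for (cl in names(counts)) {
    k <- counts[[cl]]
    if (cl == "null" || k == 0) next
    classes[pool[i:(i + k - 1L)]] <- cl
    i <- i + k
  }

  nTx <- sample(1:3, cfg$nGenes, replace = TRUE)
  nTx[classes == "isoform_opposite"] <-
    pmax(2L, nTx[classes == "isoform_opposite"])
  nPep <- sample(cfg$peptidesPerProteinRange[1]:cfg$peptidesPerProteinRange[2],
                 cfg$nGenes, replace = TRUE)

  ## ---- genotypes ---------------------------------------------------------
  mPerGene <- floor(cfg$nVariants / cfg$nGenes)
  dosList <- vector("list", cfg$nGenes)
  varMeta <- vector("list", cfg$nGenes)
  for (g in seq_len(cfg$nGenes)) {
    D <- .simulateBlockDosages(mPerGene, cfg$nDonors, cfg$mafRange,
                               cfg$ldDecay, cfg$ldBlockSize)
    ids <- sprintf("var_%03d_%03d", g, seq_len(mPerGene))
    rownames(D) <- ids
    pos <- sort(sample((geneStart[g] - 200000L):(geneEnd[g] + 200000L),
                       mPerGene))
    dosList[[g]] <- D
    varMeta[[g]] <- data.frame(variant = ids, chrom = chrom[g], pos = pos,
                               ref = "A", alt = "G", gene = geneIds[g],
                               stringsAsFactors = FALSE)
  }
  dosDonor <- do.call(rbind, dosList)
  colnames(dosDonor) <- donors
  dos <- dosDonor[, lineDonor, drop = FALSE]      # repeat lines share donor row
  colnames(dos) <- lines
  variants <- do.call(rbind, varMeta)
  geno <- GenotypeData(dos, variants[, c("variant", "chrom", "pos", "ref",
                                         "alt")])
  variantGene <- setNames(variants$gene, variants$variant)

  ## causal variant per gene: prefer a common, mid-block variant so that LD
  ## proxies exist on both sides
  donorMaf <- variantMaf(geno, setNames(samples$donor, samples$line))
  causal <- character(cfg$nGenes)
  for (g in seq_len(cfg$nGenes)) {
    ids <- rownames(dosList[[g]])
    maf <- donorMaf[ids]
    ok <- ids[maf > 0.1]
    causal[g] <- if (length(ok)) ok[ceiling(length(ok) / 2)] else
      ids[which.max(maf)]
  }
  ## protein-altering causal variants are coding, so they live inside the
  ## gene body (the proxy-annotation rule is restricted to the gene body)
  for (g in which(classes == "protein_altering")) {
    i <- match(causal[g], variants$variant)
    variants$pos[i] <- geneStart[g] + 10000L
  }
  geno <- GenotypeData(dos, variants[, c("variant", "chrom", "pos", "ref",
                                         "alt")])

  ## ---- truth tables ------------------------------------------------------
  betas <- runif(cfg$nGenes, cfg$effectSizeRange[1], cfg$effectSizeRange[2]) *
    sample(c(-1, 1), cfg$nGenes, replace = TRUE)
  truthGenes <- data.frame(gene = geneIds, class = classes,
                           causal_variant = ifelse(classes == "null", NA,
                                                   causal),
                           beta_rna_gene = 0, beta_protein = 0,
                           complex = NA_character_, chrom = chrom,
                           stringsAsFactors = FALSE)
  txRows <- list()
  featRows <- list()
  pepSeqs <- character(0); protSeqs <- character(0)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (g in seq_len(cfg$nGenes)) {
    k <- nTx[g]
    tx <- sprintf("%s_tx%d", geneIds[g], seq_len(k))
    w <- runif(k, 0.5, 1.5); w <- w / sum(w)
    codingIdx <- which.max(w)
    beta <- betas[g]; cl <- classes[g]
    txBeta <- rep(0, k)
    if (cl == "shared") {
      txBeta[codingIdx] <- beta
      truthGenes$beta_rna_gene[g] <- beta
      truthGenes$beta_protein[g] <- beta
    } else if (cl == "rna_only") {
      txBeta[] <- beta
      truthGenes$beta_rna_gene[g] <- beta
    } else if (cl == "isoform_opposite") {
      other <- setdiff(seq_len(k), codingIdx)[1]
      txBeta[codingIdx] <- beta
      txBeta[other] <- -beta * w[codingIdx] / w[other]
      truthGenes$beta_protein[g] <- beta
    } else if (cl == "protein_altering") {
      truthGenes$beta_protein[g] <- beta
    }
    txRows[[g]] <- data.frame(transcript = tx, gene = geneIds[g],
                              weight = w, coding = seq_len(k) == codingIdx,
                              beta = txBeta, stringsAsFactors = FALSE)
    pg <- sprintf("pg_%s", geneIds[g])
    peps <- sprintf("pep_%s_%02d", geneIds[g], seq_len(nPep[g]))
    seqLen <- nPep[g] * 10L + 20L
    protSeqs[pg] <- paste(sample(aa, seqLen, replace = TRUE), collapse = "")
    for (p in seq_len(nPep[g]))
      pepSeqs[peps[p]] <- substr(protSeqs[pg], (p - 1L) * 10L + 1L,
                                 (p - 1L) * 10L + 10L)
    featRows[[g]] <- rbind(
      data.frame(feature = geneIds[g], layer = "rna_gene", gene = geneIds[g],
                 parent = NA, chrom = chrom[g], start = geneStart[g],
                 end = geneEnd[g], strand = "+", coding = NA, weight = NA,
                 stringsAsFactors = FALSE),
      data.frame(feature = tx, layer = "rna_transcript", gene = geneIds[g],
                 parent = geneIds[g], chrom = chrom[g], start = geneStart[g],
                 end = geneEnd[g], strand = "+",
                 coding = seq_len(k) == codingIdx, weight = w,
                 stringsAsFactors = FALSE),
      data.frame(feature = pg, layer = "protein", gene = geneIds[g],
                 parent = geneIds[g], chrom = chrom[g], start = geneStart[g],
                 end = geneEnd[g], strand = "+", coding = NA, weight = NA,
                 stringsAsFactors = FALSE),
      data.frame(feature = peps, layer = "peptide", gene = geneIds[g],
                 parent = pg, chrom = chrom[g],
                 start = geneStart[g] + (seq_len(nPep[g]) - 1L) * 30L,
                 end = geneStart[g] + (seq_len(nPep[g]) - 1L) * 30L + 29L,
                 strand = "+", coding = NA, weight = NA,
                 stringsAsFactors = FALSE))
  }
  truthTx <- do.call(rbind, txRows)
  fmap <- do.call(rbind, featRows)
  rownames(fmap) <- NULL

  ## peptide genomic map annotations: a small fraction overlap common
  ## non-synonymous variants, a small fraction have no genomic position
  pepIdx <- which(fmap$layer == "peptide")
  fmap$ns_maf <- NA_real_
  poly <- pepIdx[runif(length(pepIdx)) < cfg$polymorphicPeptideRate]
  fmap$ns_maf[poly] <- runif(length(poly), 0.011, 0.2)
  unmapped <- setdiff(pepIdx[runif(length(pepIdx)) < cfg$unmappedPeptideRate],
                      poly)
  fmap$chrom[unmapped] <- NA

  ## ---- complexes ---------------------------------------------------------
  cisCandidates <- which(classes %in% c("shared", "protein_altering"))
  partnersPool <- which(classes == "null" & !isChrx)
  cxRows <- list()
  if (cfg$nComplexes > 0 && length(cisCandidates) >= cfg$nComplexes) {
    limiting <- sample(cisCandidates, cfg$nComplexes)
    for (cx in seq_len(cfg$nComplexes)) {
      size <- sample(cfg$complexSizeRange[1]:cfg$complexSizeRange[2], 1)
      nPartners <- min(size - 1L, length(partnersPool))
      members <- c(limiting[cx], partnersPool[seq_len(nPartners)])
      partnersPool <- partnersPool[-seq_len(nPartners)]
      id <- sprintf("complex_%02d", cx)
      cxRows[[cx]] <- data.frame(complex = id, gene = geneIds[members],
                                 limiting = geneIds[members] ==
                                   geneIds[limiting[cx]],
                                 stringsAsFactors = FALSE)
      truthGenes$complex[members] <- id
    }
  }
  truthCx <- if (length(cxRows)) do.call(rbind, cxRows) else
    data.frame(complex = character(0), gene = character(0),
               limiting = logical(0))
  ppi <- do.call(rbind, lapply(split(truthCx$gene, truthCx$complex),
                               function(gs) {
    if (length(gs) < 2) return(NULL)
    cmb <- utils::combn(gs, 2)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
               stringsAsFactors = FALSE)
  }))
  if (is.null(ppi))
    ppi <- data.frame(gene_a = character(0), gene_b = character(0))
  rownames(ppi) <- NULL

  ## ---- baseline log-scale layers ----------------------------------------
  n <- cfg$nLines
  muTx <- rnorm(nrow(truthTx), 3, 1)
  donorEff <- matrix(rnorm(cfg$nGenes * cfg$nDonors, 0, cfg$donorSd),
                     cfg$nGenes, cfg$nDonors, dimnames = list(geneIds, donors))
  donorEffLine <- donorEff[, lineDonor, drop = FALSE]
  cxLatent <- matrix(rnorm(max(1, cfg$nComplexes) * n, 0, cfg$complexSd),
                     ncol = n)

  Ttx <- matrix(0, nrow(truthTx), n,
                dimnames = list(truthTx$transcript, lines))
  for (j in seq_len(nrow(truthTx))) {
    g <- truthTx$gene[j]
    Ttx[j, ] <- muTx[j] + donorEffLine[g, ] + rnorm(n, 0, cfg$noiseSdRna)
  }
  Grna <- matrix(0, cfg$nGenes, n, dimnames = list(geneIds, lines))
  for (g in seq_len(cfg$nGenes)) {
    rows <- which(truthTx$gene == geneIds[g])
    Grna[g, ] <- colSums(Ttx[rows, , drop = FALSE] * truthTx$weight[rows])
  }
  pgIds <- sprintf("pg_%s", geneIds)
  Prot <- matrix(0, cfg$nGenes, n, dimnames = list(pgIds, lines))
  for (g in seq_len(cfg$nGenes)) {
    codingRow <- which(truthTx$gene == geneIds[g] & truthTx$coding)
    base <- cfg$rnaProteinCoupling * (Ttx[codingRow, ] - muTx[codingRow])
    if (!is.na(truthGenes$complex[g])) {
      cxId <- as.integer(sub("complex_", "", truthGenes$complex[g]))
      base <- base + cxLatent[cxId, ]
    }
    Prot[g, ] <- base + rnorm(n, 0, cfg$noiseSdProtein)
  }
  pepRows <- fmap[fmap$layer == "peptide", ]
  Pep <- matrix(0, nrow(pepRows), n, dimnames = list(pepRows$feature, lines))
  pepMu <- rnorm(nrow(pepRows), 13, 0.8)
  for (j in seq_len(nrow(pepRows)))
    Pep[j, ] <- pepMu[j] + Prot[pepRows$parent[j], ] + rnorm(n, 0, 0.2)

  layersLog <- list(rna_gene = Grna, rna_transcript = Ttx, protein = Prot,
                    peptide = Pep)

  ## ---- planted effects ---------------------------------------------------
  truth <- list(genes = truthGenes, transcripts = truthTx,
                complexes = truthCx)
  layersLog <- plantCisEffects(geno, truth, layersLog, featureMap = fmap)
  layersLog <- .plantTransEffects(geno, truth, layersLog, fmap,
                                  cfg$transPropagation)

  ## ---- X-chromosome inactivation ----------------------------------------
  xciGenes <- data.frame(gene = geneIds[isChrx],
                         slope = runif(nChrx, 0.8, 1.6) *
                           sample(c(-1, 1), nChrx, replace = TRUE),
                         stringsAsFactors = FALSE)
  xci <- simulateXci(samples, xciGenes, layersLog, fmap, cfg)
  layersLog <- xci$layers
  truth$xci <- xci$erosion
  truth$xciGenes <- xciGenes

  ## ---- TMT structure and raw layers --------------------------------------
  tmt <- applyTmtStructure(layersLog["peptide"], samples, cfg,
                           refLine = refLine)
  pepFinal <- tmt$layers$peptide

  pepAb <- AbundanceMatrix(exp(pepFinal), "peptide", logScale = FALSE)
  protAb <- aggregateProteinGroups(pepAb, fmap)
  layers <- list(
    rna_gene = AbundanceMatrix(exp(layersLog$rna_gene), "rna_gene"),
    rna_transcript = AbundanceMatrix(exp(layersLog$rna_transcript),
                                     "rna_transcript"),
    protein = protAb,
    peptide = pepAb)

  ## ---- variant-effect annotation ----------------------------------------
  terms <- rep("intron_variant", nrow(variants))
  syn <- runif(nrow(variants)) < 0.05
  terms[syn] <- "synonymous_variant"
  sift <- rep(NA_real_, nrow(variants))
  pa <- which(classes == "protein_altering")
  mis <- match(causal[pa], variants$variant)
  terms[mis] <- "missense_variant"
  sift[mis] <- runif(length(mis), 0, 0.045)
  variantEffects <- data.frame(variant = variants$variant, term = terms,
                               sift = sift, stringsAsFactors = FALSE)

  cfgList <- unclass(cfg)
  cfgList$refLine <- refLine
  cfgList$variantGene <- variantGene
  new("CohortBundle", genotypes = geno, samples = samples, layers = layers,
      latent = layersLog, featureMap = fmap, refProfile = tmt$refProfile,
      aseCounts = xci$ase, proteinSeqs = protSeqs, peptideSeqs = pepSeqs,
      variantEffects = variantEffects, ppi = ppi, truth = truth,
      config = cfgList)
}

#' Plant cis genetic effects of the four mechanistic classes
#'
#' Adds class-specific per-allele effects (scaled per standard deviation of
#' dosage) to a list of log-scale layer matrices. `shared` adds a
#' same-signed effect to the gene's RNA, its coding transcript and the
#' protein (and its peptides); `rna_only` affects all RNA features but not
#' the protein; `isoform_opposite` adds +beta to the coding transcript and
#' -beta scaled by the transcript abundance-weight ratio to another, so the
#' expected gene-level RNA effect is exactly zero while the protein (driven
#' by the coding isoform) carries the effect; `protein_altering` affects
#' only the protein and its peptides; `null` genes are untouched.
#'
#' @param geno a [GenotypeData-class].
#' @param truth list with elements `genes` (gene, class, causal_variant,
#'   beta_rna_gene, beta_protein) and `transcripts` (transcript, gene, beta).
#' @param layers named list of log-scale matrices (features x lines) for
#'   `rna_gene`, `rna_transcript`, `protein`, `peptide` (any subset).
#' @param featureMap long-format feature map linking peptides to protein
#'   groups (needed only when a peptide layer is present).
#' @return the layer list with effects added.
#' @export
plantCisEffects <- function(geno, truth, layers, featureMap = NULL) {
  tg <- truth$genes
  known <- c("shared", "rna_only", "isoform_opposite", "protein_altering",
             "null")
  bad <- setdiff(unique(tg$class), known)
  if (length(bad))
    stop("unknown effect class: ", paste(bad, collapse = ", "))
  dos <- dosages(geno)
  for (i in seq_len(nrow(tg))) {
    if (tg$class[i] == "null") next
    v <- tg$causal_variant[i]
    if (!v %in% rownames(dos))
      stop("causal variant not in genotype matrix: ", v)
    g <- dos[v, ]
    z <- (g - mean(g)) / sd(g)
    gene <- tg$gene[i]
    if (!is.null(layers$rna_gene) && gene %in% rownames(layers$rna_gene))
      layers$rna_gene[gene, ] <- layers$rna_gene[gene, ] +
        tg$beta_rna_gene[i] * z
    if (!is.null(layers$rna_transcript)) {
      tx <- truth$transcripts[truth$transcripts$gene == gene, ]
      for (j in seq_len(nrow(tx))) {
        if (tx$beta[j] == 0) next
        layers$rna_transcript[tx$transcript[j], ] <-
          layers$rna_transcript[tx$transcript[j], ] + tx$beta[j] * z
      }
    }
    if (tg$beta_protein[i] != 0) {
      pg <- paste0("pg_", gene)
      if (!is.null(layers$protein) && pg %in% rownames(layers$protein))
        layers$protein[pg, ] <- layers$protein[pg, ] + tg$beta_protein[i] * z
      if (!is.null(layers$peptide) && !is.null(featureMap)) {
        peps <- featureMap$feature[featureMap$layer == "peptide" &
                                     featureMap$parent == pg]
        peps <- intersect(peps, rownames(layers$peptide))
        if (length(peps))
          layers$peptide[peps, ] <- layers$peptide[peps, ] +
            rep(tg$beta_protein[i] * z, each = length(peps))
      }
    }
  }
  layers
}

## trans propagation: each complex's limiting subunit passes a scaled copy of
## its cis effect to the protein (and peptides) of every partner subunit
.plantTransEffects <- function(geno, truth, layers, featureMap, propagation) {
  cx <- truth$complexes
  if (!nrow(cx)) return(layers)
  dos <- dosages(geno)
  tg <- truth$genes
  for (id in unique(cx$complex)) {
    mem <- cx[cx$complex == id, ]
    lim <- mem$gene[mem$limiting][1]
    i <- match(lim, tg$gene)
    if (tg$beta_protein[i] == 0) next
    g <- dos[tg$causal_variant[i], ]
    z <- (g - mean(g)) / sd(g)
    eff <- propagation * tg$beta_protein[i] * z
    for (gene in setdiff(mem$gene, lim)) {
      pg <- paste0("pg_", gene)
      layers$protein[pg, ] <- layers$protein[pg, ] + eff
      peps <- featureMap$feature[featureMap$layer == "peptide" &
                                   featureMap$parent == pg]
      peps <- intersect(peps, rownames(layers$peptide))
      if (length(peps))
        layers$peptide[peps, ] <- layers$peptide[peps, ] +
          rep(eff, each = length(peps))
    }
  }
  layers
}

#' Simulate X-chromosome-inactivation erosion and allele-specific counts
#'
#' Each female line receives an erosion level drawn uniformly from
#' `config$xciErosionRange` (0 = one X fully silenced, 0.5 = fully
#' biallelic). Heterozygous chrX SNP read counts are drawn with the
#' minor-allele expectation equal to the erosion level; male lines
#' contribute no heterozygous chrX counts. Log abundances of the
#' XCI-responsive genes (all layers) are shifted by `slope * erosion` in
#' female lines.
#'
#' @param samples sample table with `line` and `sex` columns.
#' @param xciGenes data.frame with `gene` and `slope` (log-units per unit
#'   erosion).
#' @param layers named list of log-scale layer matrices.
#' @param featureMap long-format feature map.
#' @param config a [cohortConfig()] list.
#' @return list with `ase` (line, snp, chrom, pos, ref_count, alt_count),
#'   `layers` (adjusted), and `erosion` (line, erosion; females only).
#' @export
simulateXci <- function(samples, xciGenes, layers, featureMap, config) {
  fem <- samples$line[samples$sex == "female"]
  erosion <- runif(length(fem), config$xciErosionRange[1],
                   config$xciErosionRange[2])
  names(erosion) <- fem
  aseRows <- vector("list", length(fem))
  for (i in seq_along(fem)) {
    nSnp <- config$nXciSnps
    total <- rpois(nSnp, config$xciMeanReads)
    minor <- rbinom(nSnp, total, erosion[i])
    flip <- runif(nSnp) < 0.5          # which allele is the minor one
    aseRows[[i]] <- data.frame(
      line = fem[i], snp = sprintf("xsnp_%03d", seq_len(nSnp)),
      chrom = "chrX", pos = 100000L + seq_len(nSnp) * 1000L,
      ref_count = ifelse(flip, minor, total - minor),
      alt_count = ifelse(flip, total - minor, minor),
      stringsAsFactors = FALSE)
  }
  ase <- if (length(aseRows)) do.call(rbind, aseRows) else
    data.frame(line = character(0), snp = character(0), chrom = character(0),
               pos = integer(0), ref_count = integer(0),
               alt_count = integer(0))
  eAll <- setNames(rep(0, nrow(samples)), samples$line)
  eAll[fem] <- erosion
  for (i in seq_len(nrow(xciGenes))) {
    gene <- xciGenes$gene[i]; slope <- xciGenes$slope[i]
    shift <- slope * eAll
    if (gene %in% rownames(layers$rna_gene))
      layers$rna_gene[gene, ] <- layers$rna_gene[gene, ] + shift
    tx <- featureMap$feature[featureMap$layer == "rna_transcript" &
                               featureMap$gene == gene]
    for (t in intersect(tx, rownames(layers$rna_transcript)))
      layers$rna_transcript[t, ] <- layers$rna_transcript[t, ] + shift
    pg <- paste0("pg_", gene)
    if (pg %in% rownames(layers$protein))
      layers$protein[pg, ] <- layers$protein[pg, ] + shift
    peps <- featureMap$feature[featureMap$layer == "peptide" &
                                 featureMap$parent == pg]
    peps <- intersect(peps, rownames(layers$peptide))
    if (length(peps))
      layers$peptide[peps, ] <- layers$peptide[peps, ] +
        rep(shift, each = length(peps))
  }
  list(ase = ase, layers = layers,
       erosion = data.frame(line = fem, erosion = unname(erosion),
                            stringsAsFactors = FALSE))
}

#' Apply TMT batch/channel structure and detection missingness
#'
#' Adds per-feature per-batch and per-feature per-channel additive shifts
#' (log scale, s.d. `batchSd` / `channelSd`), plus a shared per-batch
#' sample-loading shift applied to all features (s.d. `batchLoadingSd`,
#' defaulting to `batchSd`), to each supplied layer, and masks values
#' missing independently at `missingRate`. The reference line's
#' column is never masked entirely. When `refLine` is given, a reference
#' replicate profile is also generated: the reference line re-measured in
#' every batch (with that batch's shifts plus replicate noise), as in a TMT
#' design with a shared reference channel.
#'
#' @param layers named list of log-scale matrices (features x lines).
#' @param samples sample table with `line`, `batch`, `channel` columns.
#' @param config a [cohortConfig()] list (uses `batchSd`, `channelSd`,
#'   `missingRate`).
#' @param refLine optional reference line id.
#' @return list with `layers` (shifted, masked) and `refProfile`
#'   (features x batches log-intensity matrix of the first layer;
#'   `NULL` when `refLine` is `NULL`).
#' @export
applyTmtStructure <- function(layers, samples, config, refLine = NULL) {
  batches <- sort(unique(samples$batch))
  channels <- sort(unique(samples$channel))
  lineBatch <- setNames(samples$batch, samples$line)
  lineChannel <- setNames(samples$channel, samples$line)
  loadingSd <- if (is.null(config$batchLoadingSd)) config$batchSd else
    config$batchLoadingSd
  loading <- setNames(rnorm(length(batches), 0, loadingSd), batches)
  refProfile <- NULL
  for (nm in names(layers)) {
    M <- layers[[nm]]
    bShift <- matrix(rnorm(nrow(M) * length(batches), 0, config$batchSd),
                     nrow(M), length(batches),
                     dimnames = list(rownames(M), batches))
    bShift <- sweep(bShift, 2, loading, "+")
    cShift <- matrix(rnorm(nrow(M) * length(channels), 0, config$channelSd),
                     nrow(M), length(channels),
                     dimnames = list(rownames(M), channels))
    shifted <- M + bShift[, lineBatch[colnames(M)], drop = FALSE] +
      cShift[, lineChannel[colnames(M)], drop = FALSE]
    if (!is.null(refLine) && is.null(refProfile)) {
      refProfile <- M[, rep(refLine, length(batches)), drop = FALSE] +
        bShift + rnorm(length(bShift), 0, 0.1)
      colnames(refProfile) <- batches
    }
    if (config$missingRate > 0) {
      mask <- matrix(runif(length(shifted)) < config$missingRate,
                     nrow(shifted), ncol(shifted))
      shifted[mask] <- NA
      if (!is.null(refLine) && refLine %in% colnames(shifted) &&
          all(is.na(shifted[, refLine])))
        shifted[1, refLine] <- M[1, refLine]
    }
    layers[[nm]] <- shifted
  }
  list(layers = layers, refProfile = refProfile)
}
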