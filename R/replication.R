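#' Squared genotype correlation (LD r^2) between two variants
#'
#' @param v1,v2 named dosage vectors over the same lines.
#' @return squared Pearson correlation on pairwise-complete lines.
#' @export
ldR2 <- function(v1, v2) {
  lines <- intersect(names(v1), names(v2))
  x <- v1[lines]; y <- v2[lines]
  ok <- !is.na(x) & !is.na(y)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    stop("monomorphic variant in ldR2")
  cor(x[ok], y[ok])^2
}

#' LD proxy variants of a lead variant
#'
#' Variants with r^2 strictly above `r2Min` to the lead, restricted to a
#' genomic region (the gene body for variant-effect annotation, the cis
#' window for GWAS tagging). The lead itself is always included.
#'
#' @param lead lead variant id.
#' @param geno a [GenotypeData-class].
#' @param r2Min strict r^2 threshold (default 0.8).
#' @param region optional list with `chrom`, `start`, `end` restricting the
#'   candidate variants.
#' @param candidates optional explicit candidate variant ids.
#' @return character vector of proxy variant ids (lead first).
#' @export
ldProxies <- function(lead, geno, r2Min = 0.8, region = NULL,
                      candidates = NULL) {
  dos <- dosages(geno)
  vi <- variantInfo(geno)
  if (is.null(candidates)) candidates <- vi$variant
  if (!is.null(region)) {
    sub <- vi[match(candidates, vi$variant), ]
    candidates <- candidates[sub$chrom == region$chrom &
                               sub$pos >= region$start &
                               sub$pos <= region$end]
  }
  candidates <- setdiff(candidates, lead)
  g0 <- dos[lead, ]
  keep <- vapply(candidates, function(v) {
    g <- dos[v, ]
    if (sd(g) == 0 || sd(g0) == 0) return(FALSE)
    cor(g0, g)^2 > r2Min
  }, logical(1))
  c(lead, candidates[keep])
}

#' Cross-layer replication of a QTL lead variant
#'
#' A discovery-layer QTL replicates in a target layer iff the lead variant
#' reaches nominal significance there (p < `pThreshold`) with the same
#' effect direction. For transcript or peptide target layers, replication
#' holds if any feature of the gene meets the criterion.
#'
#' @param lead one-row data.frame with `gene`, `variant`, `beta` and a
#'   `layer` tag for the discovery layer.
#' @param targetAssoc data.frame of target-layer associations at the lead
#'   variant: columns `gene`, `feature`, `variant`, `beta`, `p`.
#' @param pThreshold nominal replication threshold (default 0.01).
#' @return one-row data.frame: `gene`, `discoveryLayer`, `variant`,
#'   `targetP` (best), `signMatch`, `replicated`, `evaluable`.
#' @export
crossLayerReplication <- function(lead, targetAssoc, pThreshold = 0.01) {
  hits <- targetAssoc[targetAssoc$gene == lead$gene &
                        targetAssoc$variant == lead$variant, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(gene = lead$gene, discoveryLayer = lead$layer,
                      variant = lead$variant, targetP = NA, signMatch = NA,
                      replicated = NA, evaluable = FALSE,
                      stringsAsFactors = FALSE))
  ok <- hits$p < pThreshold & sign(hits$beta) == sign(lead$beta)
  i <- if (any(ok)) which(ok)[which.min(hits$p[ok])] else which.min(hits$p)
  data.frame(gene = lead$gene, discoveryLayer = lead$layer,
             variant = lead$variant, targetP = hits$p[i],
             signMatch = sign(hits$beta[i]) == sign(lead$beta),
             replicated = any(ok), evaluable = TRUE,
             stringsAsFactors = FALSE)
}

#' Group predicted variant-effect terms into parent categories
#'
#' `inframe_variant` collects inframe_deletion, inframe_insertion,
#' incomplete_terminal_codon_variant, stop_lost, stop_gained and
#' missense_variant; `splicing_variant` collects splice_acceptor_variant,
#' splice_donor_variant and splice_region_variant; `frameshift_variant`
#' collects feature_elongation, feature_truncation and frameshift_variant;
#' anything else maps to `other`.
#'
#' @param terms character vector of predicted-effect terms.
#' @return character vector of parent categories.
#' @export
groupVariantEffects <- function(terms) {
  inframe <- c("inframe_deletion", "inframe_insertion",
               "incomplete_terminal_codon_variant", "stop_lost",
               "stop_gained", "missense_variant")
  splicing <- c("splice_acceptor_variant", "splice_donor_variant",
                "splice_region_variant")
  frameshift <- c("feature_elongation", "feature_truncation",
                  "frameshift_variant")
  out <- rep("other", length(terms))
  out[terms %in% inframe] <- "inframe_variant"
  out[terms %in% splicing] <- "splicing_variant"
  out[terms %in% frameshift] <- "frameshift_variant"
  out
}

#' Classify the putative mechanism of a protein QTL
#'
#' Ordered rules: (1) the gene-level RNA signal replicates (nominal p below
#' the threshold, same direction) -> gene expression effect; (2) else any
#' transcript of the gene is nominally significant at the lead ->
#' transcript-isoform-specific effect; (3) else any gene-body LD proxy
#' (r^2 > 0.8) of the lead is an inframe (protein-altering) variant ->
#' protein-altering variant; (4) else unexplained. When no transcript scan
#' is available the classification degrades to three classes with a
#' warning.
#'
#' @param lead one-row data.frame with `gene`, `variant`, `beta`.
#' @param eqtlAssoc gene-RNA-layer associations at the lead variant
#'   (`gene`, `feature`, `variant`, `beta`, `p`).
#' @param tqtlAssoc transcript-layer associations at the lead variant, or
#'   `NULL` if unavailable.
#' @param proxyCategories character vector of parent categories (from
#'   [groupVariantEffects()]) of the lead's gene-body proxy variants.
#' @param pThreshold nominal threshold (default 0.01).
#' @return one-row data.frame with `gene`, `variant` and `class` in
#'   `gene_expression_effect`, `transcript_isoform_specific`,
#'   `protein_altering_variant`, `unexplained`.
#' @export
classifyMechanism <- function(lead, eqtlAssoc, tqtlAssoc, proxyCategories,
                              pThreshold = 0.01) {
  rep1 <- crossLayerReplication(
    cbind(lead, layer = "protein"), eqtlAssoc, pThreshold)
  cls <- NULL
  if (isTRUE(rep1$replicated)) cls <- "gene_expression_effect"
  if (is.null(cls)) {
    if (is.null(tqtlAssoc)) {
      warning("no transcript-level scan: classification degrades to 3 classes")
    } else {
      tx <- tqtlAssoc[tqtlAssoc$gene == lead$gene &
                        tqtlAssoc$variant == lead$variant, , drop = FALSE]
      if (nrow(tx) && any(tx$p < pThreshold))
        cls <- "transcript_isoform_specific"
    }
  }
  if (is.null(cls) && "inframe_variant" %in% proxyCategories)
    cls <- "protein_altering_variant"
  if (is.null(cls)) cls <- "unexplained"
  data.frame(gene = lead$gene, variant = lead$variant, class = cls,
             stringsAsFactors = FALSE)
}

#' Fisher's exact test with sample odds ratio
#'
#' Two-sided exact p by the minimum-likelihood convention (all tables of
#' the hypergeometric support with probability at most that of the observed
#' table), as in [stats::fisher.test()]. The odds ratio reported is the
#' sample odds ratio ad/bc, with a 0.5 continuity correction applied (and
#' flagged) only when a cell is zero. A zero margin yields p = 1 and an
#' undefined odds ratio.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `oddsRatio`, `p`, `corrected` and `orDefined`.
#' @export
fisherEnrichment <- function(table) {
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(oddsRatio = NA_real_, p = 1, corrected = FALSE,
                orDefined = FALSE))
  corrected <- any(table == 0)
  t2 <- if (corrected) table + 0.5 else table
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  p <- fisher.test(table)$p.value
  list(oddsRatio = or, p = p, corrected = corrected, orDefined = TRUE)
}

#' GWAS-catalogue tagging of a QTL via its LD proxies
#'
#' A QTL tags a GWAS signal iff at least one of its proxy variants (the
#' lead included) is annotated in the catalogue.
#'
#' @param lead lead variant id.
#' @param proxies proxy variant ids (from [ldProxies()]).
#' @param catalogue data.frame keyed by a `variant` column.
#' @return list with `tagged` and `matches` (matched catalogue rows).
#' @export
gwasTagging <- function(lead, proxies, catalogue) {
  prox <- union(lead, proxies)
  matches <- catalogue[catalogue$variant %in% prox, , drop = FALSE]
  list(tagged = nrow(matches) > 0, matches = matches)
}

.prAuc <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  prec <- tp / (tp + fp)
  rec <- tp / sum(lab)
  ## average precision: sum of precision at each recall step
  sum(prec[lab == 1]) / sum(lab)
}

#' Random-forest predictor of cross-layer QTL replication
#'
#' Trains a random-forest classifier (100 trees) on gene-level features to
#' predict whether an eQTL replicates at the protein level, over repeated
#' 80/20 train/test splits, reporting mean feature importances and the mean
#' average-precision across splits. The canonical eight features are: eQTL
#' effect size, protein coefficient of error (reference-line CV across TMT
#' batches), protein coefficient of variation, protein abundance, SNP MAF,
#' RNA abundance, number of peptides, and number of missing measurements.
#'
#' @param features genes x p numeric data.frame/matrix.
#' @param labels logical/0-1 vector of replication status per gene.
#' @param nTrees trees per forest (default 100).
#' @param nSplits number of random 80/20 splits (default 50).
#' @param testFraction held-out fraction (default 0.2).
#' @param seed integer seed.
#' @return list with `importance` (mean decrease in Gini per feature, per
#'   split in `importanceBySplit`), `meanAveragePrecision`, `prevalence`
#'   and `nSplits`.
#' @export
trainReplicationPredictor <- function(features, labels, nTrees = 100,
                                      nSplits = 50, testFraction = 0.2,
                                      seed = 1L) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (n < 50) stop("need at least 50 labeled genes")
  y <- factor(as.integer(labels), levels = c(0, 1))
  set.seed(seed)
  imp <- matrix(0, nSplits, ncol(features),
                dimnames = list(NULL, colnames(features)))
  ap <- numeric(nSplits)
  for (s in seq_len(nSplits)) {
    test <- sample.int(n, round(testFraction * n))
    fit <- randomForest::randomForest(features[-test, , drop = FALSE],
                                      y[-test], ntree = nTrees)
    imp[s, ] <- randomForest::importance(fit)[, 1]
    prob <- predict(fit, features[test, , drop = FALSE], type = "prob")[, "1"]
    ap[s] <- .prAuc(prob, y[test] == "1")
  }
  list(importance = colMeans(imp), importanceBySplit = imp,
       meanAveragePrecision = mean(ap, na.rm = TRUE),
       prevalence = mean(y == "1"), nSplits = nSplits)
}

#' Build the canonical replication-predictor feature table
#'
#' Assembles the eight per-gene features from a cohort bundle and its cis
#' scan results (see [trainReplicationPredictor()]).
#'
#' @param bundle a [CohortBundle-class].
#' @param eqtlGenes gene-level eQTL summary (needs `gene`, `beta`,
#'   `leadVariant`).
#' @param protein log-scale protein [AbundanceMatrix-class].
#' @param rna log-scale gene-RNA [AbundanceMatrix-class].
#' @return data.frame with rownames = genes and the eight feature columns.
#' @export
replicationFeatures <- function(bundle, eqtlGenes, protein, rna) {
  fmap <- featureMap(bundle)
  pgOf <- setNames(fmap$feature[fmap$layer == "protein"],
                   fmap$gene[fmap$layer == "protein"])
  pepPerGene <- table(fmap$parent[fmap$layer == "peptide"])
  ref <- bundle@refProfile
  donorMap <- setNames(sampleTable(bundle)$donor, sampleTable(bundle)$line)
  maf <- variantMaf(genotypes(bundle), donorMap)
  pv <- assayValues(protein); rv <- assayValues(rna)
  rows <- lapply(seq_len(nrow(eqtlGenes)), function(i) {
    g <- eqtlGenes$gene[i]; pg <- pgOf[[g]]
    if (is.null(pg) || !pg %in% rownames(pv) || !g %in% rownames(rv))
      return(NULL)
    peps <- fmap$feature[fmap$layer == "peptide" & fmap$parent == pg]
    refPep <- ref[intersect(peps, rownames(ref)), , drop = FALSE]
    coe <- if (nrow(refPep)) mean(apply(exp(refPep), 1,
                                        function(x) sd(x) / mean(x))) else NA
    x <- pv[pg, ]
    data.frame(gene = g,
               eqtlEffect = abs(eqtlGenes$beta[i]),
               proteinCoe = coe,
               proteinCv = sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE),
               proteinAbundance = mean(x, na.rm = TRUE),
               snpMaf = unname(maf[eqtlGenes$leadVariant[i]]),
               rnaAbundance = mean(rv[g, ], na.rm = TRUE),
               nPeptides = as.integer(pepPerGene[pg]),
               nMissing = sum(is.na(x)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$gene
  out$gene <- NULL
  out
}
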