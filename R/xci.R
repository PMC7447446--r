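#' X-chromosome-inactivation score per female line
#'
#' For each heterozygous chrX SNP the allele-specific fraction is the reads
#' of the less-expressed allele over total reads (min(ref, alt) / total, so
#' always <= 0.5 and invariant to ref/alt labelling); SNPs with fewer than
#' `minReads` total reads are excluded. The line's XCI score is the mean
#' fraction over its remaining SNPs: 0 means one X fully inactivated, 0.5
#' fully biallelic (eroded) expression.
#'
#' @param ase allele-specific count table: `line`, `snp`, `ref_count`,
#'   `alt_count`.
#' @param minReads minimum total reads per SNP (default 20).
#' @param samples optional sample table; when given, only female lines are
#'   scored.
#' @return data.frame: `line`, `score`, `nSnps` (score NA and flagged when
#'   no SNP qualifies).
#' @export
computeXciStatus <- function(ase, minReads = 20, samples = NULL) {
  if (any(ase$ref_count < 0 | ase$alt_count < 0))
    stop("negative allele counts")
  if (!is.null(samples)) {
    fem <- samples$line[samples$sex == "female"]
    ase <- ase[ase$line %in% fem, , drop = FALSE]
  }
  total <- ase$ref_count + ase$alt_count
  frac <- pmin(ase$ref_count, ase$alt_count) / total
  keep <- total >= minReads
  out <- do.call(rbind, lapply(split(seq_len(nrow(ase)), ase$line),
                               function(idx) {
    ok <- idx[keep[idx]]
    data.frame(line = ase$line[idx[1]],
               score = if (length(ok)) mean(frac[ok]) else NA_real_,
               nSnps = length(ok), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Genes whose abundance tracks XCI status
#'
#' Correlates each feature's abundance with the per-line XCI score across
#' female lines (Pearson by default, Spearman available), adjusts across
#' features by Benjamini-Hochberg, and reports the effect direction.
#'
#' @param matrix log-scale [AbundanceMatrix-class] (any layer).
#' @param scores named XCI score vector (female lines).
#' @param fdr FDR threshold (default 0.10).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param minPairs skip features with fewer complete pairs (default 10).
#' @return data.frame: `feature`, `r`, `p`, `q`, `direction`,
#'   `significant`; `NULL` with a warning when scores are constant.
#' @export
correlateExpressionWithXci <- function(matrix, scores, fdr = 0.10,
                                       method = c("pearson", "spearman"),
                                       minPairs = 10) {
  method <- match.arg(method)
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2 || sd(scores) == 0) {
    warning("XCI scores constant or insufficient; all features skipped")
    return(NULL)
  }
  v <- assayValues(matrix)[, names(scores), drop = FALSE]
  rows <- lapply(seq_len(nrow(v)), function(i) {
    ok <- !is.na(v[i, ])
    if (sum(ok) < minPairs) return(NULL)
    if (sd(v[i, ok]) == 0) return(NULL)
    ct <- stats::cor.test(v[i, ok], scores[ok], method = method,
                          exact = FALSE)
    data.frame(feature = rownames(v)[i], r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q <- p.adjust(out$p, method = "BH")
  out$direction <- sign(out$r)
  out$significant <- out$q < fdr
  rownames(out) <- NULL
  out
}

#' Enrichment of strong sex effects among chrX-encoded genes
#'
#' Builds the 2x2 table of {sex variance fraction > threshold} against
#' {gene encoded on chrX} and applies [fisherEnrichment()].
#'
#' @param decompositions data.frame from [decomposeVarianceMatrix()]
#'   (`feature`, `factor`, `fraction`).
#' @param geneChrom named chromosome vector (names = features).
#' @param threshold strong-effect fraction threshold (default 0.20).
#' @return list from [fisherEnrichment()] plus the `table`.
#' @export
chrxSexEnrichment <- function(decompositions, geneChrom, threshold = 0.20) {
  d <- decompositions[decompositions$factor == "sex", , drop = FALSE]
  strong <- d$fraction > threshold
  onX <- geneChrom[d$feature] == "chrX"
  tab <- matrix(c(sum(strong & onX), sum(strong & !onX),
                  sum(!strong & onX), sum(!strong & !onX)), 2, 2,
                byrow = TRUE,
                dimnames = list(c("strongSex", "weakSex"),
                                c("chrX", "autosome")))
  c(fisherEnrichment(tab), list(table = tab))
}
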