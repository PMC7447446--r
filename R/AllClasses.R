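#' @import methods
#' @importFrom stats median optimize optim rnorm runif rbinom rpois sd cor
#'   pnorm pbeta p.adjust complete.cases fisher.test var quantile
#'   approx predict dbeta setNames cov lm prcomp coef
#' @importFrom utils head read.delim write.table
NULL

.LAYERS <- c("rna_gene", "rna_transcript", "protein", "peptide")

#' AbundanceMatrix: one molecular layer of a cohort
#'
#' A features x lines matrix of abundances for a single molecular layer
#' (gene-level RNA, transcript-level RNA, protein group or peptide), with a
#' flag recording whether values are on a log scale. Missing measurements are
#' `NA`; they are never imputed, and downstream statistics use
#' pairwise-complete data.
#'
#' @slot values numeric matrix, features in rows, lines in columns; `NA`
#'   marks a missing measurement.
#' @slot layer one of `"rna_gene"`, `"rna_transcript"`, `"protein"`,
#'   `"peptide"`.
#' @slot logScale logical; `TRUE` when values are log-transformed.
#'
#' @aliases AbundanceMatrix
#' @exportClass AbundanceMatrix
setClass("AbundanceMatrix",
  representation(values = "matrix", layer = "character",
                 logScale = "logical"))

setValidity("AbundanceMatrix", function(object) {
  v <- object@values
  if ((nrow(v) > 0 && is.null(rownames(v))) ||
      (ncol(v) > 0 && is.null(colnames(v))))
    return("values must have feature rownames and line colnames")
  if (anyDuplicated(rownames(v))) return("duplicate feature ids")
  if (anyDuplicated(colnames(v))) return("duplicate line ids")
  if (!object@layer %in% .LAYERS)
    return(sprintf("layer must be one of: %s", paste(.LAYERS, collapse = ", ")))
  if (length(object@logScale) != 1L) return("logScale must be length 1")
  if (!object@logScale && any(v < 0, na.rm = TRUE))
    return("non-log abundances must be non-negative")
  TRUE
})

#' Construct an AbundanceMatrix
#'
#' @param values features x lines numeric matrix with dimnames.
#' @param layer molecular layer tag.
#' @param logScale whether values are log-scale.
#' @return An [AbundanceMatrix-class] object.
#' @export
AbundanceMatrix <- function(values, layer, logScale = FALSE) {
  new("AbundanceMatrix", values = as.matrix(values), layer = layer,
      logScale = logScale)
}

#' @describeIn AbundanceMatrix-class the underlying features x lines matrix
#' @param object,x an `AbundanceMatrix`
#' @export
setGeneric("assayValues", function(object) standardGeneric("assayValues"))
#' @export
setMethod("assayValues", "AbundanceMatrix", function(object) object@values)

#' @describeIn AbundanceMatrix-class the layer tag
#' @export
setGeneric("layerTag", function(object) standardGeneric("layerTag"))
#' @export
setMethod("layerTag", "AbundanceMatrix", function(object) object@layer)

#' @describeIn AbundanceMatrix-class whether values are log-scale
#' @export
setGeneric("isLogScale", function(object) standardGeneric("isLogScale"))
#' @export
setMethod("isLogScale", "AbundanceMatrix", function(object) object@logScale)

#' @describeIn AbundanceMatrix-class feature identifiers
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))
#' @export
setMethod("featureIds", "AbundanceMatrix",
          function(object) rownames(object@values))

#' @describeIn AbundanceMatrix-class line identifiers
#' @export
setGeneric("lineIds", function(object) standardGeneric("lineIds"))
#' @export
setMethod("lineIds", "AbundanceMatrix",
          function(object) colnames(object@values))

#' @export
setMethod("dim", "AbundanceMatrix", function(x) dim(x@values))

#' @export
setMethod("show", "AbundanceMatrix", function(object) {
  v <- object@values
  cat(sprintf("AbundanceMatrix [%s%s]: %d features x %d lines (%.1f%% missing)\n",
              object@layer, if (object@logScale) ", log" else "",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
})

#' @param i,j,...,drop feature/line subscripts (drop is ignored)
#' @describeIn AbundanceMatrix-class subset features (i) and/or lines (j)
#' @export
setMethod("[", "AbundanceMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  initialize(x, values = v)
})

#' GenotypeData: dosage matrix plus variant metadata
#'
#' Biallelic genotype dosages (0/1/2 copies of the alternate allele) for a
#' set of lines, with per-variant metadata (chromosome, position, alleles).
#' Lines derived from the same donor carry identical dosage columns.
#'
#' @slot dosages numeric matrix, variants in rows, lines in columns.
#' @slot variants data.frame with columns `variant`, `chrom`, `pos`,
#'   `ref`, `alt` (one row per dosage row, same order).
#'
#' @aliases GenotypeData
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(dosages = "matrix", variants = "data.frame"))

setValidity("GenotypeData", function(object) {
  d <- object@dosages
  if (is.null(rownames(d)) || is.null(colnames(d)))
    return("dosages must have variant rownames and line colnames")
  if (nrow(object@variants) != nrow(d))
    return("variants table must have one row per dosage row")
  need <- c("variant", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(object@variants)))
    return(sprintf("variants table needs columns: %s",
                   paste(need, collapse = ", ")))
  if (!identical(as.character(object@variants$variant), rownames(d)))
    return("variants$variant must match dosage rownames in order")
  if (any(d < 0 | d > 2, na.rm = TRUE))
    return("dosages must lie in [0, 2]")
  TRUE
})

#' Construct a GenotypeData object
#' @param dosages variants x lines dosage matrix (0..2).
#' @param variants data.frame of variant metadata.
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosages, variants) {
  new("GenotypeData", dosages = as.matrix(dosages), variants = variants)
}

#' @describeIn GenotypeData-class the variants x lines dosage matrix
#' @param object a `GenotypeData`
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))
#' @export
setMethod("dosages", "GenotypeData", function(object) object@dosages)

#' @describeIn GenotypeData-class the per-variant metadata table
#' @export
setGeneric("variantInfo", function(object) standardGeneric("variantInfo"))
#' @export
setMethod("variantInfo", "GenotypeData", function(object) object@variants)

#' @export
setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d variants x %d lines\n",
              nrow(object@dosages), ncol(object@dosages)))
})

#' Minor allele frequency per variant
#'
#' Allele frequencies are computed across unique donors: when a donor
#' contributed several lines only the first line is counted, so repeat lines
#' do not pseudo-replicate alleles.
#'
#' @param geno a [GenotypeData-class] object.
#' @param donors optional named character vector mapping line id to donor id.
#' @return named numeric vector of minor allele frequencies.
#' @export
variantMaf <- function(geno, donors = NULL) {
  d <- dosages(geno)
  if (!is.null(donors)) {
    keep <- !duplicated(donors[colnames(d)])
    d <- d[, keep, drop = FALSE]
  }
  af <- rowMeans(d, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' CohortBundle: a complete synthetic or assembled cohort
#'
#' The full set of inputs a proteogenomic QTL analysis consumes: genotypes,
#' a sample table, raw abundance matrices for all four molecular layers, a
#' feature map linking genes, transcripts, protein groups and peptides,
#' reference-line replicate intensities per TMT batch, allele-specific chrX
#' read counts, protein sequences, a variant-effect annotation table, a
#' protein-protein interaction reference, and (for synthetic cohorts) a
#' ground-truth table of planted effects.
#'
#' @slot genotypes a [GenotypeData-class].
#' @slot samples data.frame with columns `line`, `donor`, `sex`, `age`,
#'   `medium`, `batch`, `channel`.
#' @slot layers named list of [AbundanceMatrix-class] objects
#'   (`rna_gene`, `rna_transcript`, `protein`, `peptide`), raw scale.
#' @slot latent named list of the noise-free log-scale layer matrices used to
#'   generate the raw layers (synthetic cohorts only; empty otherwise).
#' @slot featureMap data.frame (long format): `feature`, `layer`, `gene`,
#'   `parent`, `chrom`, `start`, `end`, `strand`, `coding`, `weight`.
#' @slot refProfile features x batches matrix of the reference line's
#'   replicate peptide intensities, one column per TMT batch.
#' @slot aseCounts data.frame of allele-specific chrX counts: `line`, `snp`,
#'   `chrom`, `pos`, `ref_count`, `alt_count`.
#' @slot proteinSeqs named character vector of protein-group amino-acid
#'   sequences.
#' @slot peptideSeqs named character vector of peptide sequences.
#' @slot variantEffects data.frame: `variant`, `term`, `sift`.
#' @slot ppi data.frame of reference interaction pairs: `gene_a`, `gene_b`.
#' @slot truth list of ground-truth tables (`genes`, `transcripts`,
#'   `complexes`, `xci`, `xciGenes`); empty for real cohorts.
#' @slot config the list of simulation parameters used (if synthetic).
#'
#' @aliases CohortBundle
#' @exportClass CohortBundle
setClass("CohortBundle",
  representation(genotypes = "GenotypeData", samples = "data.frame",
                 layers = "list", latent = "list", featureMap = "data.frame",
                 refProfile = "matrix", aseCounts = "data.frame",
                 proteinSeqs = "character", peptideSeqs = "character",
                 variantEffects = "data.frame", ppi = "data.frame",
                 truth = "list", config = "list"))

setValidity("CohortBundle", function(object) {
  lines <- object@samples$line
  if (is.null(lines)) return("samples must have a 'line' column")
  if (anyDuplicated(lines)) return("duplicate line ids in sample table")
  if (!identical(colnames(dosages(object@genotypes)), lines))
    return("genotype columns must match sample table lines")
  for (nm in names(object@layers)) {
    if (!identical(lineIds(object@layers[[nm]]), lines))
      return(sprintf("layer '%s' columns must match sample table lines", nm))
  }
  TRUE
})

#' @describeIn CohortBundle-class sample metadata table
#' @param object a `CohortBundle`
#' @export
setGeneric("sampleTable", function(object) standardGeneric("sampleTable"))
#' @export
setMethod("sampleTable", "CohortBundle", function(object) object@samples)

#' @describeIn CohortBundle-class genotype data
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))
#' @export
setMethod("genotypes", "CohortBundle", function(object) object@genotypes)

#' @describeIn CohortBundle-class one abundance layer by tag
#' @param layer layer tag
#' @export
setGeneric("cohortLayer", function(object, layer) standardGeneric("cohortLayer"))
#' @export
setMethod("cohortLayer", "CohortBundle", function(object, layer) {
  stopifnot(layer %in% names(object@layers))
  object@layers[[layer]]
})

#' @describeIn CohortBundle-class the long-format feature map
#' @export
setGeneric("featureMap", function(object) standardGeneric("featureMap"))
#' @export
setMethod("featureMap", "CohortBundle", function(object) object@featureMap)

#' @describeIn CohortBundle-class ground-truth tables (synthetic cohorts)
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
#' @export
setMethod("cohortTruth", "CohortBundle", function(object) object@truth)

#' @describeIn CohortBundle-class allele-specific chrX count table
#' @export
setGeneric("aseCounts", function(object) standardGeneric("aseCounts"))
#' @export
setMethod("aseCounts", "CohortBundle", function(object) object@aseCounts)

#' @export
setMethod("show", "CohortBundle", function(object) {
  cat(sprintf("CohortBundle: %d lines (%d donors), %d variants\n",
              nrow(object@samples), length(unique(object@samples$donor)),
              nrow(dosages(object@genotypes))))
  for (nm in names(object@layers)) {
    v <- assayValues(object@layers[[nm]])
    cat(sprintf("  %-14s %6d features\n", nm, nrow(v)))
  }
  if (length(object@truth))
    cat(sprintf("  ground truth: %d genes, %d complexes\n",
                nrow(object@truth$genes),
                if (is.null(object@truth$complexes)) 0L
                else length(unique(object@truth$complexes$complex))))
})
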