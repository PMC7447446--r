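.writeTsv <- function(d, path)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

.writeMatrixTsv <- function(m, path, idCol = "feature") {
  d <- data.frame(id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- idCol
  .writeTsv(d, path)
}

#' Read an abundance matrix from TSV
#'
#' Expects the first column to hold feature ids and the remaining columns
#' one line each.
#'
#' @param path TSV path.
#' @param layer layer tag for the resulting object.
#' @param logScale whether values are log-scale.
#' @return an [AbundanceMatrix-class].
#' @export
readAbundanceTsv <- function(path, layer, logScale = FALSE) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  AbundanceMatrix(m, layer, logScale)
}

#' Read a dosage matrix TSV into GenotypeData
#'
#' Expects columns `variant`, `chrom`, `pos`, `ref`, `alt` followed by one
#' dosage column per line.
#'
#' @param path TSV path.
#' @return a [GenotypeData-class].
#' @export
readDosageTsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- d[, c("variant", "chrom", "pos", "ref", "alt")]
  m <- as.matrix(d[, setdiff(names(d), names(meta)), drop = FALSE])
  rownames(m) <- meta$variant
  GenotypeData(m, meta)
}

#' Write genotypes as a minimal VCF v4.2 (unphased GT)
#'
#' Dosages 0/1/2 are written as 0/0, 0/1 and 1/1 genotype calls.
#'
#' @param geno a [GenotypeData-class].
#' @param path output path.
#' @export
writeVcf <- function(geno, path) {
  vi <- variantInfo(geno)
  d <- dosages(geno)
  gtCode <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(d)), collapse = "\t")), con)
  body <- vapply(seq_len(nrow(d)), function(i)
    paste(c(sub("^chr", "", vi$chrom[i]), vi$pos[i], vi$variant[i],
            vi$ref[i], vi$alt[i], ".", "PASS", ".", "GT",
            gtCode[d[i, ] + 1L]), collapse = "\t"), character(1))
  writeLines(body, con)
}

#' Write a cohort bundle to a directory of plain-text files
#'
#' Emits dosage TSV and VCF, sample table, per-layer abundance TSVs,
#' feature map, allele-specific counts, reference-line replicate profile,
#' protein FASTA, peptide sequences, variant-effect and PPI tables, and the
#' ground-truth tables (TSV plus a JSON digest). Output is byte-identical
#' for identical bundles.
#'
#' @param bundle a [CohortBundle-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
writeCohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  geno <- genotypes(bundle)
  .writeTsv(cbind(variantInfo(geno), as.data.frame(dosages(geno))),
            fp("dosages.tsv"))
  writeVcf(geno, fp("genotypes.vcf"))
  .writeTsv(sampleTable(bundle), fp("samples.tsv"))
  for (nm in names(bundle@layers))
    .writeMatrixTsv(assayValues(bundle@layers[[nm]]),
                    fp(paste0("abundance_", nm, ".tsv")))
  .writeTsv(featureMap(bundle), fp("feature_map.tsv"))
  .writeTsv(aseCounts(bundle), fp("ase_counts.tsv"))
  .writeMatrixTsv(bundle@refProfile, fp("reference_profile.tsv"))
  writeLines(paste0(">", names(bundle@proteinSeqs), "\n",
                    bundle@proteinSeqs), fp("protein_sequences.fasta"))
  .writeTsv(data.frame(peptide = names(bundle@peptideSeqs),
                       sequence = bundle@peptideSeqs, row.names = NULL),
            fp("peptide_sequences.tsv"))
  .writeTsv(bundle@variantEffects, fp("variant_effects.tsv"))
  .writeTsv(bundle@ppi, fp("ppi_reference.tsv"))
  tr <- cohortTruth(bundle)
  if (length(tr)) {
    .writeTsv(tr$genes, fp("truth_genes.tsv"))
    .writeTsv(tr$transcripts, fp("truth_transcripts.tsv"))
    .writeTsv(tr$complexes, fp("truth_complexes.tsv"))
    .writeTsv(tr$xci, fp("truth_xci.tsv"))
    jsonlite::write_json(
      list(nGenes = nrow(tr$genes),
           classCounts = as.list(table(tr$genes$class)),
           nComplexes = length(unique(tr$complexes$complex))),
      fp("truth_summary.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
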