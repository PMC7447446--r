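#' Drop lines with too few identified peptides
#'
#' A line is retained iff its number of non-missing peptides is at least
#' `minFractionOfMedian` times the median peptide count across lines
#' (default 0.75, so a cohort with a median of 89,333 identified peptides
#' drops lines below 67,000).
#'
#' @param peptide an [AbundanceMatrix-class] of the peptide layer.
#' @param minFractionOfMedian fraction of the median count below which a
#'   line is dropped.
#' @return list with `retained` (line ids), `dropped` (line ids),
#'   `threshold`, and `counts` (named per-line peptide counts).
#' @export
filterLinesByPeptideCount <- function(peptide, minFractionOfMedian = 0.75) {
  stopifnot(is(peptide, "AbundanceMatrix"))
  v <- assayValues(peptide)
  if (nrow(v) == 0 || ncol(v) == 0) stop("empty peptide matrix")
  counts <- colSums(!is.na(v))
  threshold <- minFractionOfMedian * median(counts)
  keep <- counts >= threshold
  list(retained = names(counts)[keep], dropped = names(counts)[!keep],
       threshold = threshold, counts = counts)
}

#' Remove peptides overlapping common non-synonymous variants
#'
#' Peptides whose genomic location overlaps a non-synonymous variant with
#' minor allele frequency above `mafThreshold` at any of their mapped
#' locations may be mis-detected in carrier lines and can create synthetic
#' associations; they are discarded, as are peptides for which no genomic
#' position is available.
#'
#' @param peptides character vector of peptide ids to filter.
#' @param map data.frame with one row per peptide location: `peptide`,
#'   `chrom` (NA when the peptide has no genomic position) and `ns_maf`
#'   (MAF of an overlapping non-synonymous variant, NA when none).
#' @param mafThreshold drop peptides overlapping a non-synonymous variant
#'   with MAF strictly above this.
#' @return list with `retained`, `droppedPolymorphic`, `droppedUnmapped`
#'   and a `report` of counts per drop reason.
#' @export
filterPolymorphicPeptides <- function(peptides, map, mafThreshold = 0.01) {
  m <- map[map$peptide %in% peptides, , drop = FALSE]
  mapped <- unique(m$peptide[!is.na(m$chrom)])
  unmappedDrop <- setdiff(peptides, mapped)
  polyDrop <- unique(m$peptide[!is.na(m$ns_maf) & m$ns_maf > mafThreshold])
  polyDrop <- intersect(polyDrop, mapped)
  retained <- setdiff(peptides, c(unmappedDrop, polyDrop))
  list(retained = retained, droppedPolymorphic = polyDrop,
       droppedUnmapped = unmappedDrop,
       report = c(retained = length(retained),
                  polymorphic = length(polyDrop),
                  unmapped = length(unmappedDrop)))
}

#' Keep features recurrently detected across lines
#'
#' Retains features non-missing in at least `minLines` lines. When applied
#' to a protein layer with a `featureMap` and the retained peptide set, also
#' drops protein groups without at least one retained recurrent peptide.
#'
#' @param matrix an [AbundanceMatrix-class].
#' @param minLines minimum number of lines a feature must be detected in.
#' @param featureMap optional long-format feature map (protein layer only).
#' @param recurrentPeptides optional character vector of retained recurrent
#'   peptide ids (protein layer only).
#' @return the filtered [AbundanceMatrix-class].
#' @export
recurrenceFilter <- function(matrix, minLines = 30, featureMap = NULL,
                             recurrentPeptides = NULL) {
  stopifnot(is(matrix, "AbundanceMatrix"))
  v <- assayValues(matrix)
  keep <- rowSums(!is.na(v)) >= minLines
  if (layerTag(matrix) == "protein" && !is.null(featureMap) &&
      !is.null(recurrentPeptides)) {
    pep <- featureMap[featureMap$layer == "peptide", ]
    hasPep <- tapply(pep$feature %in% recurrentPeptides, pep$parent, any)
    keep <- keep & rownames(v) %in% names(hasPep)[hasPep]
  }
  matrix[keep, ]
}

#' Aggregate peptide intensities into protein-group abundances
#'
#' Protein-group abundance per line is the sum of its peptides' non-missing
#' raw intensities; the protein is missing in a line iff all of its
#' constituent peptides are missing there. Peptides not mapped to any
#' protein group are excluded with a warning.
#'
#' @param peptides an [AbundanceMatrix-class] of raw peptide intensities.
#' @param featureMap long-format feature map (peptide rows carry the
#'   protein-group id in `parent`).
#' @return a protein [AbundanceMatrix-class].
#' @export
aggregateProteinGroups <- function(peptides, featureMap) {
  stopifnot(is(peptides, "AbundanceMatrix"), !isLogScale(peptides))
  v <- assayValues(peptides)
  pep <- featureMap[featureMap$layer == "peptide", ]
  parent <- setNames(pep$parent, pep$feature)[rownames(v)]
  if (anyNA(parent)) {
    warning(sum(is.na(parent)), " peptide(s) mapped to no protein group; excluded")
    v <- v[!is.na(parent), , drop = FALSE]
    parent <- parent[!is.na(parent)]
  }
  groups <- unique(parent)
  out <- matrix(NA_real_, length(groups), ncol(v),
                dimnames = list(groups, colnames(v)))
  for (pg in groups) {
    sub <- v[parent == pg, , drop = FALSE]
    s <- colSums(sub, na.rm = TRUE)
    s[colSums(!is.na(sub)) == 0] <- NA
    out[pg, ] <- s
  }
  AbundanceMatrix(out, "protein", logScale = FALSE)
}

#' Scale intensities to equalise TMT batch medians
#'
#' For each feature and batch, intensities are multiplied by the ratio of
#' the feature's median across all lines to its median within the batch
#' (medians over non-missing values). A feature entirely missing within a
#' batch has an undefined coefficient; its values there are left unchanged
#' with a warning.
#'
#' @param matrix an [AbundanceMatrix-class] of raw intensities.
#' @param batches named character vector mapping line id to batch label.
#' @return the scaled [AbundanceMatrix-class].
#' @export
batchScale <- function(matrix, batches) {
  stopifnot(is(matrix, "AbundanceMatrix"), !isLogScale(matrix))
  v <- assayValues(matrix)
  b <- batches[colnames(v)]
  if (anyNA(b)) stop("every line needs a batch label")
  globalMed <- apply(v, 1, median, na.rm = TRUE)
  nUndef <- 0L
  for (batchId in unique(b)) {
    cols <- which(b == batchId)
    med <- apply(v[, cols, drop = FALSE], 1, median, na.rm = TRUE)
    coefs <- globalMed / med
    undef <- !is.finite(coefs)
    nUndef <- nUndef + sum(undef)
    coefs[undef] <- 1
    v[, cols] <- v[, cols, drop = FALSE] * coefs
  }
  if (nUndef > 0)
    warning(nUndef, " feature/batch combination(s) entirely missing; left unscaled")
  initialize(matrix, values = v)
}

#' Reference distribution for quantile normalization
#'
#' Selects the normalization reference line — the line with the highest
#' number of detected features, ties broken by lexicographic line id — and
#' returns its sorted intensity vector.
#'
#' @param matrix an [AbundanceMatrix-class].
#' @param refLine optionally force a specific reference line.
#' @return list with `refLine` and `sorted` (non-decreasing reference
#'   intensities).
#' @export
referenceDistribution <- function(matrix, refLine = NULL) {
  v <- assayValues(matrix)
  if (is.null(refLine)) {
    counts <- colSums(!is.na(v))
    best <- names(counts)[counts == max(counts)]
    refLine <- sort(best)[1]
  }
  r <- sort(v[!is.na(v[, refLine]), refLine])
  if (!length(r)) stop("empty reference distribution")
  list(refLine = refLine, sorted = unname(r))
}

#' Quantile-normalize each line to a reference distribution
#'
#' Within each line, the i-th ranked non-missing value is replaced by the
#' i-th ranked reference value (ranks over that line's detected features;
#' ties resolved by stable feature order). When a line has fewer detected
#' features than the reference, reference values are taken at linearly
#' interpolated quantiles. Missing values stay missing.
#'
#' @param matrix an [AbundanceMatrix-class].
#' @param ref a reference distribution from [referenceDistribution()].
#' @return the normalized [AbundanceMatrix-class].
#' @export
quantileNormalizeToReference <- function(matrix, ref) {
  r <- ref$sorted
  if (!length(r)) stop("empty reference distribution")
  v <- assayValues(matrix)
  for (l in seq_len(ncol(v))) {
    obs <- which(!is.na(v[, l]))
    m <- length(obs)
    if (m == 0) next
    rk <- rank(v[obs, l], ties.method = "first")
    target <- if (m == length(r)) r else
      approx(seq(0, 1, length.out = length(r)), r,
             xout = seq(0, 1, length.out = m))$y
    v[obs, l] <- target[rk]
  }
  initialize(matrix, values = v)
}

#' TMT ratio-compression diagnostic from variant-overlapping peptides
#'
#' A peptide overlapping a non-synonymous variant is not detected from the
#' alternate allele, so heterozygous lines should show half the intensity of
#' homozygous-reference lines. The per-peptide ratio
#' median(het)/median(hom-ref) is 0.5 without compression; values above 0.5
#' indicate ratio compression from co-isolated background signal.
#' Homozygous-alternate lines are excluded from the denominator.
#'
#' @param peptide an [AbundanceMatrix-class] of raw peptide intensities.
#' @param geno a [GenotypeData-class].
#' @param pepVariant named character vector mapping peptide id to the
#'   overlapped variant id.
#' @return list with `perPeptide` (peptide, variant, ratio, nHet, nHomRef)
#'   and `summary` (median and quartiles of the ratios).
#' @export
ratioCompressionDiagnostic <- function(peptide, geno, pepVariant) {
  v <- assayValues(peptide)
  dos <- dosages(geno)[, colnames(v), drop = FALSE]
  rows <- lapply(names(pepVariant), function(p) {
    g <- dos[pepVariant[[p]], ]
    het <- names(g)[g == 1]
    hom <- names(g)[g == 0]
    if (!length(het)) {
      warning("no heterozygous lines for peptide ", p, "; skipped")
      return(NULL)
    }
    data.frame(peptide = p, variant = pepVariant[[p]],
               ratio = median(v[p, het], na.rm = TRUE) /
                 median(v[p, hom], na.rm = TRUE),
               nHet = length(het), nHomRef = length(hom),
               stringsAsFactors = FALSE)
  })
  perPeptide <- do.call(rbind, rows)
  list(perPeptide = perPeptide,
       summary = if (is.null(perPeptide)) NULL else
         quantile(perPeptide$ratio, c(0.25, 0.5, 0.75), na.rm = TRUE))
}

#' Filter and log-transform an RNA TPM matrix
#'
#' Keeps genes with population mean TPM above `minMeanTpm` and transforms
#' values to log2(TPM + 1).
#'
#' @param matrix an [AbundanceMatrix-class] on TPM scale.
#' @param minMeanTpm keep features with mean TPM strictly above this.
#' @return a log-scale [AbundanceMatrix-class].
#' @export
prepareRna <- function(matrix, minMeanTpm = 1.0) {
  stopifnot(is(matrix, "AbundanceMatrix"), !isLogScale(matrix))
  v <- assayValues(matrix)
  if (any(v < 0, na.rm = TRUE)) stop("negative TPM values")
  keep <- rowMeans(v, na.rm = TRUE) > minMeanTpm
  initialize(matrix, values = log2(v[keep, , drop = FALSE] + 1),
             logScale = TRUE)
}

#' Full proteomics normalization pipeline
#'
#' Runs line filtering, polymorphic-peptide removal, recurrence filtering,
#' protein-group aggregation, batch median scaling and quantile
#' normalization to the reference line, then log2-transforms, mirroring the
#' order used for TMT cohort processing.
#'
#' @param bundle a [CohortBundle-class].
#' @param minFractionOfMedian,mafThreshold,minLines stage thresholds.
#' @return list with log-scale `protein` and `peptide`
#'   [AbundanceMatrix-class] objects, the `refLine` used, and a `report`
#'   list of per-stage counts.
#' @export
processProteomics <- function(bundle, minFractionOfMedian = 0.75,
                              mafThreshold = 0.01, minLines = 30) {
  pep <- cohortLayer(bundle, "peptide")
  lineFilter <- filterLinesByPeptideCount(pep, minFractionOfMedian)
  pep <- pep[, lineFilter$retained]
  fmap <- featureMap(bundle)
  pepMap <- fmap[fmap$layer == "peptide",
                 c("feature", "chrom", "start", "end", "strand", "ns_maf")]
  names(pepMap)[1] <- "peptide"
  polyFilter <- filterPolymorphicPeptides(featureIds(pep), pepMap,
                                          mafThreshold)
  pep <- pep[polyFilter$retained, ]
  pep <- recurrenceFilter(pep, minLines)
  prot <- aggregateProteinGroups(pep, fmap)
  prot <- recurrenceFilter(prot, minLines, featureMap = fmap,
                           recurrentPeptides = featureIds(pep))
  batches <- setNames(sampleTable(bundle)$batch, sampleTable(bundle)$line)
  pep <- batchScale(pep, batches)
  prot <- batchScale(prot, batches)
  refP <- referenceDistribution(pep)
  pep <- quantileNormalizeToReference(pep, refP)
  refG <- referenceDistribution(prot, refLine = refP$refLine)
  prot <- quantileNormalizeToReference(prot, refG)
  toLog <- function(a) initialize(a, values = log2(assayValues(a) + 1),
                                  logScale = TRUE)
  list(protein = toLog(prot), peptide = toLog(pep), refLine = refP$refLine,
       report = list(lineFilter = lineFilter[c("dropped", "threshold")],
                     peptideFilter = polyFilter$report,
                     nPeptides = nrow(assayValues(pep)),
                     nProteins = nrow(assayValues(prot))))
}
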