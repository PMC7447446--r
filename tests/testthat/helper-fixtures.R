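# shared fixture builders -------------------------------------------------

# tiny genotype object from a dosage matrix (variants x lines)
makeGeno <- function(d, chrom = "chr1", pos = NULL) {
  if (is.null(rownames(d))) rownames(d) <- sprintf("v%02d", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- sprintf("l%02d", seq_len(ncol(d)))
  if (is.null(pos)) pos <- seq_len(nrow(d)) * 1000L
  GenotypeData(d, data.frame(variant = rownames(d), chrom = chrom,
                             pos = pos, ref = "A", alt = "G",
                             stringsAsFactors = FALSE))
}

# small default cohort config for fast tests
smallConfig <- function(...) {
  args <- list(nDonors = 40L, nLines = 50L, nVariants = 120L, nGenes = 12L,
               effectClassCounts = c(shared = 2L, rna_only = 1L,
                                     isoform_opposite = 2L,
                                     protein_altering = 2L),
               nComplexes = 1L, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(cohortConfig, args)
}

# abundance matrix with simple dimnames
makeAb <- function(v, layer = "peptide", log = FALSE) {
  if (is.null(rownames(v))) rownames(v) <- sprintf("f%02d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("l%02d", seq_len(ncol(v)))
  AbundanceMatrix(v, layer, log)
}

# independent Smith-Waterman oracle: optimal local alignment score with
# match +1, mismatch 0, gap -1 (used against peptideAlignmentFilter)
swScoreOracle <- function(pep, prot) {
  a <- strsplit(pep, "")[[1]]; b <- strsplit(prot, "")[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m))
    S[i + 1, j + 1] <- max(S[i, j] + (a[i] == b[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1, 0)
  max(S)
}

# exhaustive gapless substring-scan oracle: the most identities any
# same-length window of the protein shares with the peptide
substringMatchesOracle <- function(pep, prot) {
  a <- strsplit(pep, "")[[1]]
  L <- length(a)
  best <- 0
  for (s in seq_len(nchar(prot) - L + 1)) {
    w <- strsplit(substr(prot, s, s + L - 1), "")[[1]]
    best <- max(best, sum(a == w))
  }
  best
}

# exhaustive two-sided Fisher p over the hypergeometric support
# (minimum-likelihood convention)
fisherEnumOracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(a)
    exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1)),
    numeric(1))
  obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
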