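test_that("line filter drops lines below the median-fraction threshold", {
  v <- matrix(1, 100, 3, dimnames = list(sprintf("p%03d", 1:100),
                                         c("a", "b", "c")))
  v[51:100, "c"] <- NA                       # counts 100 / 100 / 50
  out <- filterLinesByPeptideCount(makeAb(v), 0.75)
  expect_equal(out$threshold, 75)
  expect_equal(out$dropped, "c")
  expect_setequal(out$retained, c("a", "b"))

  allEq <- filterLinesByPeptideCount(makeAb(matrix(1, 10, 4)), 0.75)
  expect_length(allEq$dropped, 0)
  empty <- matrix(numeric(0), 2, 0,
                  dimnames = list(c("p1", "p2"), character(0)))
  expect_error(filterLinesByPeptideCount(AbundanceMatrix(empty, "peptide")),
               "empty")
})

test_that("polymorphic-peptide filter drops by overlap and unmapped status", {
  map <- data.frame(
    peptide = c("p1", "p2", "p2", "p3", "p4"),
    chrom   = c("chr1", "chr1", "chr2", "chr1", NA),
    ns_maf  = c(0.02, NA, 0.05, NA, NA))
  out <- filterPolymorphicPeptides(c("p1", "p2", "p3", "p4", "p5"), map)
  expect_setequal(out$droppedPolymorphic, c("p1", "p2"))  # p2: one of two locations
  expect_setequal(out$droppedUnmapped, c("p4", "p5"))
  expect_equal(out$retained, "p3")
  # boundary: MAF exactly at the threshold is kept (strict >)
  mapB <- data.frame(peptide = "p1", chrom = "chr1", ns_maf = 0.01)
  expect_equal(filterPolymorphicPeptides("p1", mapB)$retained, "p1")
})

test_that("recurrence filter keeps features detected in >= minLines lines", {
  v <- matrix(NA_real_, 3, 40, dimnames = list(c("a", "b", "c"),
                                               sprintf("l%02d", 1:40)))
  v["a", 1:29] <- 1; v["b", 1:30] <- 1; v["c", ] <- 1
  out <- recurrenceFilter(makeAb(v), 30)
  expect_setequal(featureIds(out), c("b", "c"))
  expect_equal(featureIds(recurrenceFilter(makeAb(v), 0)), c("a", "b", "c"))

  # protein groups need at least one retained recurrent peptide
  pv <- matrix(1, 2, 40, dimnames = list(c("pg_1", "pg_2"), colnames(v)))
  fm <- data.frame(feature = c("pepA", "pepB"), layer = "peptide",
                   parent = c("pg_1", "pg_2"))
  out <- recurrenceFilter(makeAb(pv, "protein"), 30, featureMap = fm,
                          recurrentPeptides = "pepA")
  expect_equal(featureIds(out), "pg_1")
})

test_that("protein aggregation sums detected peptides, missing iff all missing", {
  v <- matrix(c(100, 200,   # line 1
                100, NA,    # line 2
                NA, NA),    # line 3
              2, 3, dimnames = list(c("pep1", "pep2"), c("l1", "l2", "l3")))
  fm <- data.frame(feature = c("pep1", "pep2"), layer = "peptide",
                   parent = "pg_1")
  out <- assayValues(aggregateProteinGroups(makeAb(v), fm))
  expect_equal(unname(out["pg_1", ]), c(300, 100, NA))
  # unmapped peptide excluded with a warning
  fm2 <- data.frame(feature = "pep1", layer = "peptide", parent = "pg_1")
  expect_warning(aggregateProteinGroups(makeAb(v), fm2), "no protein group")
})

test_that("batch scaling matches the hand-computed median ratios", {
  v <- matrix(c(2, 4, 8, 16), 1, 4,
              dimnames = list("f1", c("a", "b", "c", "d")))
  batches <- c(a = "b1", b = "b1", c = "b2", d = "b2")
  out <- assayValues(batchScale(makeAb(v), batches))
  expect_equal(unname(out["f1", ]), c(4, 8, 4, 8))
  # single batch: identity
  one <- batchScale(makeAb(v), c(a = "b1", b = "b1", c = "b1", d = "b1"))
  expect_equal(assayValues(one), v)
  # feature entirely missing in one batch: unchanged there, warned
  v2 <- v; v2[1, c("c", "d")] <- NA
  expect_warning(out2 <- batchScale(makeAb(v2), batches), "entirely missing")
  expect_equal(unname(assayValues(out2)["f1", ]), c(2, 4, NA, NA))
})

test_that("quantile normalization maps ranks onto the reference", {
  v <- matrix(c(2, 4, 6, 5, 1, 9), 3, 2,
              dimnames = list(c("f1", "f2", "f3"), c("ref", "x")))
  ref <- referenceDistribution(makeAb(v), refLine = "ref")
  out <- assayValues(quantileNormalizeToReference(makeAb(v), ref))
  expect_equal(unname(out[, "ref"]), c(2, 4, 6))   # identity on the reference
  expect_equal(unname(out[, "x"]), c(4, 2, 6))

  # ties: stable feature order; output is a permutation of the reference
  vt <- matrix(c(1, 2, 3, 4, 7, 7, 5, 7), 4, 2,
               dimnames = list(sprintf("f%d", 1:4), c("ref", "x")))
  reft <- referenceDistribution(makeAb(vt), refLine = "ref")
  outt <- assayValues(quantileNormalizeToReference(makeAb(vt), reft))
  # brute-force oracle: i-th ranked value -> i-th reference value,
  # first-occurrence order for ties
  rk <- rank(vt[, "x"], ties.method = "first")
  expect_equal(unname(outt[, "x"]), unname(sort(vt[, "ref"])[rk]))
  expect_setequal(unname(outt[, "x"]), unname(vt[, "ref"]))

  # fewer detected features than the reference: interpolated quantiles
  vm <- vt; vm["f2", "x"] <- NA
  outm <- assayValues(quantileNormalizeToReference(makeAb(vm), reft))
  expect_true(is.na(outm["f2", "x"]))
  expect_equal(sort(unname(outm[!is.na(outm[, "x"]), "x"])),
               approx(seq(0, 1, length.out = 4), sort(vt[, "ref"]),
                      xout = seq(0, 1, length.out = 3))$y)
  expect_error(quantileNormalizeToReference(makeAb(vt),
                                            list(sorted = numeric(0))),
               "empty reference")
})

test_that("reference line selection takes the most complete line", {
  v <- matrix(1, 5, 3, dimnames = list(sprintf("f%d", 1:5),
                                       c("b", "a", "c")))
  v[1, "b"] <- NA
  expect_equal(referenceDistribution(makeAb(v))$refLine, "a")  # tie a/c -> a
})

test_that("ratio-compression diagnostic recovers the het/hom intensity ratio", {
  lines <- sprintf("l%02d", 1:30)
  g <- matrix(rep(c(0, 1, 2), each = 10), 1, 30,
              dimnames = list("v1", lines))
  geno <- makeGeno(g)
  # exact allelic halving, no noise: hom-ref 100, het 50, hom-alt 0
  v <- matrix(c(rep(100, 10), rep(50, 10), rep(0, 10)), 1, 30,
              dimnames = list("pepA", lines))
  out <- ratioCompressionDiagnostic(makeAb(v), geno, c(pepA = "v1"))
  expect_equal(out$perPeptide$ratio, 0.5)
  expect_equal(out$perPeptide$nHomRef, 10)   # hom-alt excluded

  # 50% background mixing compresses the ratio to 0.75
  vb <- v; vb[1, ] <- 0.5 * v[1, ] + 0.5 * 100
  outb <- ratioCompressionDiagnostic(makeAb(vb), geno, c(pepA = "v1"))
  expect_equal(outb$perPeptide$ratio, 0.75)

  gNoHet <- makeGeno(matrix(rep(c(0, 2), 15), 1, 30,
                            dimnames = list("v1", lines)))
  expect_warning(ratioCompressionDiagnostic(makeAb(v), gNoHet,
                                            c(pepA = "v1")),
                 "no heterozygous")
})

test_that("RNA preparation filters by mean TPM and log2-transforms", {
  v <- matrix(c(0.99, 1.01, 3, 0), 4, 1,
              dimnames = list(c("g1", "g2", "g3", "g4"), "l1"))
  # means across one line are the values themselves
  out <- prepareRna(makeAb(v, "rna_gene"))
  expect_setequal(featureIds(out), c("g2", "g3"))
  expect_equal(assayValues(out)["g3", "l1"], 2)        # log2(3 + 1)
  expect_true(isLogScale(out))
  v0 <- matrix(c(5, 0), 1, 2, dimnames = list("g1", c("l1", "l2")))
  expect_equal(assayValues(prepareRna(makeAb(v0, "rna_gene")))["g1", "l2"], 0)
  expect_error(prepareRna(makeAb(matrix(-1, 1, 1), "rna_gene")), "negative")
})

test_that("batch scale + quantile normalization equalise line distributions", {
  b <- simulateCohort(smallConfig(missingRate = 0, batchSd = 0.6))
  prot <- cohortLayer(b, "protein")
  batches <- setNames(sampleTable(b)$batch, sampleTable(b)$line)
  scaled <- batchScale(prot, batches)
  ref <- referenceDistribution(scaled)
  qn <- assayValues(quantileNormalizeToReference(scaled, ref))
  for (l in lineIds(prot))
    expect_equal(sort(unname(qn[, l])), ref$sorted)
})
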