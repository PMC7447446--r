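test_that("LD r^2 matches hand-computed Pearson values", {
  v1 <- setNames(c(0, 1, 2, 0), letters[1:4])
  expect_equal(ldR2(v1, v1), 1)
  expect_equal(ldR2(v1, setNames(c(2, 1, 0, 2), letters[1:4])), 1)
  x <- setNames(c(0, 0, 1, 2), letters[1:4])
  y <- setNames(c(0, 1, 1, 2), letters[1:4])
  expect_equal(ldR2(x, y), cor(c(0, 0, 1, 2), c(0, 1, 1, 2))^2)
  expect_equal(ldR2(x, y), 8 / 11)
  expect_error(ldR2(x, setNames(rep(1, 4), letters[1:4])), "monomorphic")
})

test_that("LD proxies use a strict r^2 threshold and match brute force", {
  set.seed(41)
  b <- simulateCohort(smallConfig(nVariants = 240L, nGenes = 8L,
                                  effectClassCounts = c(shared = 1L),
                                  nComplexes = 0L))
  geno <- genotypes(b)
  d <- dosages(geno)
  vi <- variantInfo(geno)
  block <- vi$variant[vi$chrom == vi$chrom[1]][1:30]
  lead <- block[5]
  prox <- ldProxies(lead, geno, r2Min = 0.8, candidates = block)
  # exhaustive all-pairs oracle
  oracle <- vapply(setdiff(block, lead), function(v) {
    g <- d[v, ]
    sd(g) > 0 && cor(d[lead, ], g)^2 > 0.8
  }, logical(1))
  expect_setequal(prox, c(lead, setdiff(block, lead)[oracle]))
  # exactly at the threshold: excluded (strict >)
  r2lead <- cor(d[lead, ], d[block[6], ])^2
  atBoundary <- ldProxies(lead, geno, r2Min = r2lead, candidates = block)
  expect_false(block[6] %in% atBoundary)
  # no polymorphic neighbours: proxy set is the lead alone
  mono <- rbind(d[lead, , drop = FALSE],
                matrix(1, 2, ncol(d),
                       dimnames = list(c("m1", "m2"), colnames(d))))
  expect_equal(ldProxies(lead, makeGeno(mono), candidates = c("m1", "m2")),
               lead)
})

test_that("cross-layer replication needs nominal p and a matching sign", {
  lead <- data.frame(gene = "g1", variant = "v1", beta = 0.5,
                     layer = "protein")
  target <- function(p, beta)
    data.frame(gene = "g1", feature = "g1", variant = "v1",
               beta = beta, p = p)
  expect_true(crossLayerReplication(lead, target(0.009, 0.3))$replicated)
  expect_false(crossLayerReplication(lead, target(0.009, -0.3))$replicated)
  expect_false(crossLayerReplication(lead, target(0.011, 0.3))$replicated)
  # any feature of the gene may carry the replication
  multi <- rbind(target(0.5, 0.3), target(0.004, 0.2))
  expect_true(crossLayerReplication(lead, multi)$replicated)
  none <- data.frame(gene = "g2", feature = "g2", variant = "v9",
                     beta = 1, p = 0.5)
  expect_false(crossLayerReplication(lead, none)$evaluable)
})

test_that("mechanism classification follows the ordered rules", {
  lead <- data.frame(gene = "g1", variant = "v1", beta = 0.5)
  eq <- function(p, beta = 0.4)
    data.frame(gene = "g1", feature = "g1", variant = "v1", beta = beta,
               p = p)
  tq <- data.frame(gene = "g1", feature = "g1_tx1", variant = "v1",
                   beta = -0.3, p = 0.002)
  expect_equal(classifyMechanism(lead, eq(0.001), tq, character(0))$class,
               "gene_expression_effect")
  expect_equal(classifyMechanism(lead, eq(0.5), tq, character(0))$class,
               "transcript_isoform_specific")
  tqNull <- data.frame(gene = "g1", feature = "g1_tx1", variant = "v1",
                       beta = -0.3, p = 0.4)
  expect_equal(classifyMechanism(lead, eq(0.5), tqNull,
                                 "inframe_variant")$class,
               "protein_altering_variant")
  expect_equal(classifyMechanism(lead, eq(0.5), tqNull, "other")$class,
               "unexplained")
  # RNA significant with the opposite sign does not count as replication
  expect_equal(classifyMechanism(lead, eq(0.001, beta = -0.4), tqNull,
                                 "other")$class, "unexplained")
  expect_warning(out <- classifyMechanism(lead, eq(0.5), NULL, "other"),
                 "3 classes")
  expect_equal(out$class, "unexplained")
})

test_that("variant-effect terms map to the four parent categories", {
  expect_equal(groupVariantEffects("missense_variant"), "inframe_variant")
  expect_equal(groupVariantEffects("stop_gained"), "inframe_variant")
  expect_equal(groupVariantEffects("splice_donor_variant"),
               "splicing_variant")
  expect_equal(groupVariantEffects("splice_region_variant"),
               "splicing_variant")
  expect_equal(groupVariantEffects("feature_truncation"),
               "frameshift_variant")
  expect_equal(groupVariantEffects(c("synonymous_variant", "intron_variant",
                                     "made_up_term")),
               rep("other", 3))
})

test_that("Fisher enrichment matches the enumeration oracle", {
  out <- fisherEnrichment(matrix(c(5, 5, 5, 5), 2))
  expect_equal(out$oddsRatio, 1)
  expect_equal(out$p, 1)

  tab <- matrix(c(8, 1, 2, 9), 2)    # [[8,2],[1,9]] row-wise
  out <- fisherEnrichment(tab)
  expect_equal(out$p, fisherEnumOracle(tab), tolerance = 1e-10)
  expect_equal(out$oddsRatio, 8 * 9 / (1 * 2))
  expect_false(out$corrected)

  zero <- fisherEnrichment(matrix(c(0, 10, 10, 0), 2))
  expect_true(zero$corrected)
  expect_equal(zero$oddsRatio, 0.5 * 0.5 / (10.5 * 10.5))

  margin <- fisherEnrichment(matrix(c(0, 0, 5, 5), 2, byrow = TRUE))
  expect_equal(margin$p, 1)
  expect_false(margin$orDefined)
})

test_that("GWAS tagging checks the proxy set against the catalogue", {
  cat1 <- data.frame(variant = c("rs1129187", "rs999"), trait = "AD")
  expect_true(gwasTagging("lead1", c("lead1", "rs1129187"), cat1)$tagged)
  expect_false(gwasTagging("lead1", "lead1",
                           cat1[cat1$variant == "none", ])$tagged)
  expect_true(gwasTagging("rs999", character(0), cat1)$tagged)
})

test_that("replication predictor behaves at the permutation baseline and finds planted signal", {
  set.seed(44)
  n <- 400
  feats <- data.frame(eqtlEffect = runif(n, 0, 1),
                      proteinCoe = runif(n), proteinCv = runif(n),
                      proteinAbundance = rnorm(n), snpMaf = runif(n, .05, .5),
                      rnaAbundance = rnorm(n), nPeptides = rpois(n, 10),
                      nMissing = rpois(n, 5))
  expect_equal(ncol(feats), 8)
  labels <- feats$eqtlEffect > 0.5
  planted <- trainReplicationPredictor(feats, labels, nSplits = 50, seed = 9)
  top <- apply(planted$importanceBySplit, 1, which.max)
  expect_gte(sum(top == which(colnames(feats) == "eqtlEffect")), 45)

  shuffled <- trainReplicationPredictor(feats, sample(labels), nSplits = 20,
                                        seed = 10)
  expect_lt(abs(shuffled$meanAveragePrecision - shuffled$prevalence), 0.05)
  expect_error(trainReplicationPredictor(feats[1:30, ], labels[1:30]),
               "at least 50")
})

test_that("the feature table built from a cohort has the eight features", {
  b <- simulateCohort(smallConfig(missingRate = 0.1))
  norm <- suppressWarnings(processProteomics(b, minLines = 10))
  rna <- prepareRna(cohortLayer(b, "rna_gene")[, lineIds(norm$protein)])
  eq <- data.frame(gene = cohortTruth(b)$genes$gene[1:8],
                   beta = rnorm(8),
                   leadVariant = variantInfo(genotypes(b))$variant[1:8])
  ft <- replicationFeatures(b, eq, norm$protein, rna)
  expect_equal(ncol(ft), 8)
  expect_true(all(c("eqtlEffect", "proteinCoe", "proteinCv",
                    "proteinAbundance", "snpMaf", "rnaAbundance",
                    "nPeptides", "nMissing") %in% colnames(ft)))
})
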