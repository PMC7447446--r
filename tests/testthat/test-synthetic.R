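test_that("cohort structure matches the requested donor/line design", {
  b <- simulateCohort(smallConfig())
  s <- sampleTable(b)
  expect_equal(nrow(s), 50)
  expect_equal(length(unique(s$donor)), 40)
  reps <- names(which(table(s$donor) == 2))
  expect_length(reps, 10)
  # repeat lines share the identical genotype column
  d <- dosages(genotypes(b))
  for (dn in reps) {
    ln <- s$line[s$donor == dn]
    expect_identical(unname(d[, ln[1]]), unname(d[, ln[2]]))
  }
  # every batch holds lines and one reference channel slot (channel 1 free)
  expect_true(all(table(s$batch) > 0))
  expect_false(any(s$channel == "ch_01"))
  # all matrices share the line axis
  for (ly in c("rna_gene", "rna_transcript", "protein", "peptide"))
    expect_identical(lineIds(cohortLayer(b, ly)), s$line)
})

test_that("nLines = nDonors yields no repeated donors", {
  b <- simulateCohort(smallConfig(nDonors = 30L, nLines = 30L))
  expect_equal(max(table(sampleTable(b)$donor)), 1)
})

test_that("identical config and seed reproduce the bundle byte for byte", {
  cfg <- smallConfig(seed = 99L)
  d1 <- file.path(tempdir(), "cohortA"); d2 <- file.path(tempdir(), "cohortB")
  writeCohort(simulateCohort(cfg), d1)
  writeCohort(simulateCohort(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("truth table enforces the class-specific zero-constraints", {
  tr <- cohortTruth(simulateCohort(smallConfig()))
  tg <- tr$genes
  expect_true(all(tg$beta_protein[tg$class == "rna_only"] == 0))
  expect_true(all(tg$beta_rna_gene[tg$class == "protein_altering"] == 0))
  expect_true(all(tg$beta_rna_gene[tg$class == "isoform_opposite"] == 0))
  for (g in tg$gene[tg$class == "protein_altering"])
    expect_true(all(tr$transcripts$beta[tr$transcripts$gene == g] == 0))
  for (g in tg$gene[tg$class == "isoform_opposite"]) {
    bs <- tr$transcripts$beta[tr$transcripts$gene == g & tr$transcripts$beta != 0]
    expect_gte(length(bs), 2)
    expect_lt(prod(sign(bs[1:2])), 0)
    # abundance-weighted betas cancel exactly at gene level
    tx <- tr$transcripts[tr$transcripts$gene == g, ]
    expect_equal(sum(tx$weight * tx$beta), 0, tolerance = 1e-12)
  }
  expect_true(all(tg$beta_rna_gene[tg$class == "null"] == 0))
  expect_true(all(tg$beta_protein[tg$class == "null"] == 0))
})

test_that("unknown effect class and missing causal variant raise errors", {
  b <- simulateCohort(smallConfig())
  tr <- cohortTruth(b)
  tr$genes$class[1] <- "weird"
  expect_error(plantCisEffects(genotypes(b), tr, b@latent, featureMap(b)),
               "unknown effect class")
  tr2 <- cohortTruth(b)
  tr2$genes$causal_variant[tr2$genes$class != "null"][1] <- "nope"
  expect_error(plantCisEffects(genotypes(b), tr2, b@latent, featureMap(b)),
               "not in genotype")
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohortConfig(nDonors = 10, nLines = 5), "nLines")
  expect_error(cohortConfig(mafRange = c(0, 0.5)), "mafRange")
  expect_error(cohortConfig(missingRate = 1.5), "missingRate")
  expect_error(smallConfig(nComplexes = 40L), "nComplexes")
  expect_error(smallConfig(effectClassCounts = c(shared = 50L)),
               "effectClassCounts")
})

test_that("planted shared effects are recovered by regression at large n", {
  set.seed(11)
  n <- 2000
  lines <- sprintf("l%04d", 1:n)
  g <- matrix(rbinom(n, 2, 0.3), 1, n, dimnames = list("v1", lines))
  geno <- makeGeno(g)
  z <- (g[1, ] - mean(g[1, ])) / sd(g[1, ])
  layers <- list(rna_gene = matrix(rnorm(n), 1, n,
                                   dimnames = list("gene_x", lines)),
                 protein = matrix(rnorm(n), 1, n,
                                  dimnames = list("pg_gene_x", lines)))
  truth <- list(genes = data.frame(gene = "gene_x", class = "shared",
                                   causal_variant = "v1",
                                   beta_rna_gene = 0.8, beta_protein = 0.8),
                transcripts = data.frame(transcript = character(0),
                                         gene = character(0),
                                         beta = numeric(0)))
  out <- plantCisEffects(geno, truth, layers)
  for (ly in c("rna_gene", "protein")) {
    fit <- lm(out[[ly]][1, ] ~ z)
    est <- coef(summary(fit))[2, ]
    expect_lt(abs(est[1] - 0.8), 3 * est[2])
  }
})

test_that("isoform-opposite genes carry a protein but no gene-level RNA effect", {
  set.seed(12)
  n <- 500; nSim <- 300
  lines <- sprintf("l%03d", 1:n)
  g <- matrix(rbinom(n, 2, 0.4), 1, n, dimnames = list("v1", lines))
  geno <- makeGeno(g)
  z <- (g[1, ] - mean(g[1, ])) / sd(g[1, ])
  w <- c(0.6, 0.4)
  truth <- list(
    genes = data.frame(gene = "gene_x", class = "isoform_opposite",
                       causal_variant = "v1", beta_rna_gene = 0,
                       beta_protein = 0.8),
    transcripts = data.frame(transcript = c("t1", "t2"), gene = "gene_x",
                             beta = c(0.8, -0.8 * w[1] / w[2])))
  geneHat <- protHat <- numeric(nSim)
  for (s in seq_len(nSim)) {
    tx <- rbind(t1 = rnorm(n), t2 = rnorm(n))
    colnames(tx) <- lines
    layers <- list(rna_transcript = tx,
                   rna_gene = matrix(w %*% tx, 1, n,
                                     dimnames = list("gene_x", lines)),
                   protein = matrix(rnorm(n), 1, n,
                                    dimnames = list("pg_gene_x", lines)))
    out <- plantCisEffects(geno, truth, layers)
    gLevel <- w %*% out$rna_transcript        # gene RNA from planted isoforms
    geneHat[s] <- coef(lm(gLevel[1, ] ~ z))[2]
    protHat[s] <- coef(lm(out$protein[1, ] ~ z))[2]
  }
  expect_lt(mean(abs(geneHat)), 0.05)
  expect_lt(abs(mean(protHat) - 0.8), 0.02)
})

test_that("TMT structure: identity case, batch-shift scale, missing rate", {
  s <- data.frame(line = sprintf("l%02d", 1:20),
                  batch = rep(c("b1", "b2"), each = 10),
                  channel = rep(sprintf("c%02d", 1:10), 2))
  M <- matrix(rnorm(200 * 20), 200, 20,
              dimnames = list(sprintf("f%03d", 1:200), s$line))
  cfg0 <- list(batchSd = 0, channelSd = 0, missingRate = 0)
  expect_equal(applyTmtStructure(list(peptide = M), s, cfg0)$layers$peptide, M)

  set.seed(5)
  cfgB <- list(batchSd = 0.5, batchLoadingSd = 0, channelSd = 0,
               missingRate = 0)
  out <- applyTmtStructure(list(peptide = M), s, cfgB)$layers$peptide
  shifts <- (out - M)[, c(1, 11)]   # one column per batch: the batch shifts
  expect_lt(abs(sd(shifts) - 0.5) / 0.5, 0.2)

  set.seed(6)
  cfgM <- list(batchSd = 0, channelSd = 0, missingRate = 0.2)
  out <- applyTmtStructure(list(peptide = M), s, cfgM)$layers$peptide
  nMiss <- sum(is.na(out))
  ci <- qbinom(c(0.005, 0.995), length(out), 0.2)
  expect_gte(nMiss, ci[1]); expect_lte(nMiss, ci[2])
})

test_that("XCI simulation produces the expected allele fractions", {
  s <- data.frame(line = c("f1", "f2", "m1"), sex = c("female", "female", "male"))
  fm <- data.frame(feature = character(0), layer = character(0),
                   gene = character(0), parent = character(0))
  layers <- list(rna_gene = matrix(0, 0, 3, dimnames = list(NULL, s$line)),
                 rna_transcript = matrix(0, 0, 3, dimnames = list(NULL, s$line)),
                 protein = matrix(0, 0, 3, dimnames = list(NULL, s$line)),
                 peptide = matrix(0, 0, 3, dimnames = list(NULL, s$line)))
  noGenes <- data.frame(gene = character(0), slope = numeric(0))
  cfg <- list(xciErosionRange = c(0, 0), nXciSnps = 40L, xciMeanReads = 100)
  set.seed(7)
  out <- simulateXci(s, noGenes, layers, fm, cfg)
  expect_true(all(pmin(out$ase$ref_count, out$ase$alt_count) == 0))
  expect_false("m1" %in% out$ase$line)

  cfg$xciErosionRange <- c(0.5, 0.5)
  out <- simulateXci(s, noGenes, layers, fm, cfg)
  # at full erosion the two alleles are exchangeable: alt fraction centred
  # on 0.5 (the folded minor-allele fraction is biased slightly below it)
  frac <- with(out$ase, alt_count / (ref_count + alt_count))
  expect_lt(abs(mean(frac) - 0.5), 0.02)
})

test_that("planted XCI slope yields a positive erosion-abundance correlation", {
  set.seed(8)
  nLines <- 60
  s <- data.frame(line = sprintf("f%03d", 1:nLines), sex = "female")
  fm <- data.frame(feature = "gX", layer = "rna_gene", gene = "gX",
                   parent = NA)
  cfg <- list(xciErosionRange = c(0, 0.5), nXciSnps = 10L, xciMeanReads = 50)
  hits <- replicate(100, {
    layers <- list(rna_gene = matrix(rnorm(nLines, sd = 0.3), 1, nLines,
                                     dimnames = list("gX", s$line)),
                   rna_transcript = matrix(0, 0, nLines,
                                           dimnames = list(NULL, s$line)),
                   protein = matrix(0, 0, nLines,
                                    dimnames = list(NULL, s$line)),
                   peptide = matrix(0, 0, nLines,
                                    dimnames = list(NULL, s$line)))
    out <- simulateXci(s, data.frame(gene = "gX", slope = 2), layers, fm, cfg)
    e <- setNames(out$erosion$erosion, out$erosion$line)
    cor(e, out$layers$rna_gene["gX", names(e)]) > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("kinship structure reflects donors: repeats identical, strangers near zero", {
  b <- simulateCohort(smallConfig(nVariants = 400L, nGenes = 20L,
                                  effectClassCounts = c(shared = 1L),
                                  nComplexes = 0L))
  s <- sampleTable(b)
  d <- dosages(genotypes(b))
  reps <- names(which(table(s$donor) == 2))
  cc <- cor(d)
  for (dn in reps[1:3]) {
    ln <- s$line[s$donor == dn]
    expect_equal(cc[ln[1], ln[2]], 1)
  }
  singles <- s$line[s$donor %in% names(which(table(s$donor) == 1))]
  off <- cc[singles[1:10], singles[11:20]]
  expect_lt(mean(abs(off)), 0.15)
})
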