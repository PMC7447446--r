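test_that("kinship matches the hand-computed standardized Gram matrix", {
  d <- matrix(c(0, 1, 2,
                2, 1, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("v1", "v2"), c("a", "b", "c")))
  K <- computeKinship(makeGeno(d))
  expect_equal(diag(K), c(a = 1.5, b = 0, c = 1.5))
  expect_equal(K["a", "c"], -1.5)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  # identical lines get identical rows and shared diagonal values
  d2 <- matrix(rbinom(40, 2, 0.4), 4, 10)
  d2 <- cbind(d2, d2[, 1])
  colnames(d2) <- sprintf("l%02d", 1:11)
  K2 <- computeKinship(makeGeno(d2))
  expect_equal(K2["l01", "l11"], K2["l01", "l01"])
  expect_error(computeKinship(makeGeno(matrix(1, 2, 4))), "monomorphic")
})

test_that("cis window respects the +/-250 kb boundary and the MAF filter", {
  pos <- c(750000L, 749999L, 1000000L, 1270001L, 1270000L, 1100000L)
  set.seed(31)
  d <- rbind(matrix(rbinom(5 * 40, 2, 0.3), 5, 40),
             rbinom(40, 2, 0.02))          # last variant is rare
  rownames(d) <- sprintf("v%02d", 1:6); colnames(d) <- sprintf("l%02d", 1:40)
  geno <- makeGeno(d, pos = pos)
  gene <- list(chrom = "chr1", start = 1000000L, end = 1020000L)
  ids <- defineCisWindow(gene, geno)
  expect_true("v01" %in% ids)      # exactly at start - 250000
  expect_false("v02" %in% ids)     # one base beyond
  expect_true("v05" %in% ids)      # exactly at end + 250000
  expect_false("v04" %in% ids)
  expect_false("v06" %in% ids)     # MAF below 5%
  expect_error(defineCisWindow(list(chrom = NA, start = 1, end = 2), geno),
               "no genomic coordinates")
  # MAF boundary is strict
  maf <- variantMaf(geno)
  expect_false(any(maf[ids] <= 0.05))
})

test_that("LMM equals OLS when K = I and explicit GLS under fixed variances", {
  set.seed(32)
  n <- 50
  lines <- sprintf("l%02d", 1:n)
  K <- diag(n); dimnames(K) <- list(lines, lines)
  C <- matrix(rnorm(n * 2), n, 2, dimnames = list(lines, c("c1", "c2")))
  g <- setNames(rbinom(n, 2, 0.3), lines)
  for (rep in 1:5) {
    y <- setNames(rnorm(n), lines)
    a <- lmmAssociation(y, g, C, K)
    s <- summary(lm(y ~ C + g))$coefficients["g", ]
    expect_equal(a$beta, unname(s[1]), tolerance = 1e-8)
    expect_equal(a$se, unname(s[2]), tolerance = 1e-8)
    expect_equal(a$p, unname(s[4]), tolerance = 1e-8)
  }
  # brute-force GLS oracle with Sigma = K + delta I
  Kr <- crossprod(matrix(rnorm(n * n), n)) / n
  dimnames(Kr) <- list(lines, lines)
  delta <- 0.6
  y <- setNames(rnorm(n), lines)
  a <- lmmAssociation(y, g, C, Kr, varRatio = delta)
  R <- chol(Kr + delta * diag(n))
  Xw <- backsolve(R, cbind(1, C, g), transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  fit <- lm.fit(Xw, yw)
  XtXi <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(sum(fit$residuals^2) / (n - 4) * XtXi[4, 4])
  expect_equal(a$beta, unname(fit$coefficients[4]), tolerance = 1e-6)
  expect_equal(a$se, se, tolerance = 1e-6)
})

test_that("LMM rejects degenerate inputs", {
  n <- 20; lines <- sprintf("l%02d", 1:n)
  K <- diag(n); dimnames(K) <- list(lines, lines)
  y <- setNames(rnorm(n), lines)
  expect_error(lmmAssociation(y, setNames(rep(1, n), lines), K = K),
               "degenerate")
  bigC <- matrix(rnorm(n * 19), n, 19, dimnames = list(lines, NULL))
  expect_error(lmmAssociation(y, setNames(rbinom(n, 2, .5), lines), bigC, K),
               "fewer lines")
})

test_that("nominal LMM p-values are calibrated under the null", {
  set.seed(33)
  n <- 80
  lines <- sprintf("l%02d", 1:n)
  d <- matrix(rbinom(30 * n, 2, 0.3), 30, n,
              dimnames = list(sprintf("v%02d", 1:30), lines))
  K <- computeKinship(makeGeno(d))
  g <- setNames(rbinom(n, 2, 0.4), lines)
  ps <- replicate(400, {
    y <- setNames(drop(chol(K + 0.5 * diag(n)) %*% rnorm(n)), lines)
    lmmAssociation(y, g, K = K)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cis scan lead selection follows the p / |beta| / position tie rules", {
  set.seed(34)
  n <- 100; lines <- sprintf("l%03d", 1:n)
  g <- rbinom(n, 2, 0.4)
  # v2 = half-dosage copy of v1: identical test statistic, doubled beta
  # (halving is exact in floating point, so the p-values tie exactly);
  # v3 = exact duplicate of v1 at a larger position
  d <- rbind(v1 = g, v2 = g / 2, v3 = g)
  colnames(d) <- lines
  geno <- makeGeno(d)
  K <- diag(n); dimnames(K) <- list(lines, lines)
  y <- setNames(0.3 * scale(g)[, 1] + rnorm(n), lines)
  scan <- cisScan(y, geno, c("v1", "v2"), K = K)
  expect_equal(scan$assoc$p[1], scan$assoc$p[2], tolerance = 1e-12)
  expect_equal(scan$lead$variant, "v2")   # same p, larger |beta|
  # single-variant scan: that variant is the lead
  one <- cisScan(y, geno, "v1", K = K)
  expect_equal(one$lead$variant, "v1")
  # exact duplicate: same p, same |beta| -> smaller position wins
  scan13 <- cisScan(y, geno, c("v3", "v1"), K = K)
  expect_equal(scan13$lead$variant, "v1")
})

test_that("Beta adjustment agrees with a long-permutation empirical p", {
  set.seed(35)
  n <- 120; lines <- sprintf("l%03d", 1:n)
  d <- matrix(rbinom(12 * n, 2, 0.35), 12, n,
              dimnames = list(sprintf("v%02d", 1:12), lines))
  geno <- makeGeno(d)
  K <- computeKinship(geno)
  for (i in 1:3) {
    y <- setNames(rnorm(n), lines)
    scan <- cisScan(y, geno, rownames(d), K = K)
    adj <- permutationBetaAdjust(scan, nPerm = 100, seed = 50 + i)
    long <- permutationBetaAdjust(scan, nPerm = 5000, seed = 99 + i)
    pe <- long$empiricalP
    # the 100-permutation estimate dominates the Monte-Carlo noise
    tolBand <- 3 * sqrt(pe * (1 - pe) / 100) + 1 / 101
    expect_lt(abs(adj$adjustedP - pe), tolBand)
  }
})

test_that("a uniform permutation null leaves the lead p unchanged", {
  # Beta(1,1) CDF is the identity: adjusted p equals the observed minimum
  expect_equal(pbeta(0.037, 1, 1), 0.037)
  # machinery check: minima from the fitted Beta reproduce the empirical p
  set.seed(36)
  n <- 80; lines <- sprintf("l%02d", 1:n)
  d <- matrix(rbinom(8 * n, 2, 0.4), 8, n,
              dimnames = list(sprintf("v%02d", 1:8), lines))
  geno <- makeGeno(d)
  K <- diag(n); dimnames(K) <- list(lines, lines)
  scan <- cisScan(setNames(rnorm(n), lines), geno, rownames(d), K = K)
  adj <- permutationBetaAdjust(scan, nPerm = 200, seed = 1)
  expect_false(adj$fallback)
  expect_gt(adj$a, 0); expect_gt(adj$b, 0)
  expect_lt(abs(adj$adjustedP - adj$empiricalP), 0.1)
})

test_that("gene-level adjustment applies Bonferroni then BH step-up", {
  one <- data.frame(gene = "g1", feature = "f1", layer = "protein",
                    pAdjusted = 0.02, variant = "v1", beta = 1)
  expect_equal(geneLevelAdjust(one)$pGene, 0.02)

  three <- data.frame(gene = "g1", feature = c("p1", "p2", "p3"),
                      layer = "peptide", pAdjusted = c(0.01, 0.5, 0.9),
                      variant = "v1", beta = 1)
  expect_equal(geneLevelAdjust(three)$pGene, 0.03)

  four <- data.frame(gene = paste0("g", 1:4), feature = paste0("f", 1:4),
                     layer = "protein", pAdjusted = c(0.001, 0.02, 0.03, 0.2),
                     variant = "v1", beta = 1)
  out <- geneLevelAdjust(four, fdr = 0.10)
  out <- out[order(out$pGene), ]
  expect_equal(out$qBH, c(0.004, 0.04, 0.04, 0.2))
  expect_equal(out$significant, c(TRUE, TRUE, TRUE, FALSE))
  # independent step-up oracle
  expect_equal(out$qBH, p.adjust(c(0.001, 0.02, 0.03, 0.2), "BH"))
})

test_that("trans scan excludes the cis gene and cis-window proteins", {
  b <- simulateCohort(smallConfig(seed = 77L))
  tg <- cohortTruth(b)$genes
  lim <- tg[!is.na(tg$complex) &
              tg$class %in% c("shared", "protein_altering"), ][1, ]
  prot <- makeAb(b@latent$protein, "protein", TRUE)
  leads <- data.frame(gene = lim$gene, variant = lim$causal_variant)
  out <- transScan(leads, prot, genotypes(b), featureMap(b),
                   K = computeKinship(genotypes(b)))
  expect_false(lim$gene %in% out$results$transGene)
  expect_true(all(out$results$cisGene != out$results$transGene))
  # planted complex partners show strong, sign-concordant trans effects
  partners <- cohortTruth(b)$complexes
  partners <- partners$gene[partners$complex == lim$complex &
                              partners$gene != lim$gene]
  hits <- out$results[out$results$transGene %in% partners, ]
  expect_true(all(hits$p < 0.01))
  expect_true(all(sign(hits$beta) == sign(lim$beta_protein)))
})
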