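makeQcToy <- function() {
  # 10 SNPs with engineered violations; 100 individuals
  set.seed(1)
  n <- 100
  g <- matrix(NA_real_, n, 10)
  g[, 1] <- rep(c(0, 1, 1, 2), length.out = n)         # clean, in HWE
  g[, 2] <- c(rep(1, 6), rep(0, 94))                   # MAF 0.03 -> fail MAF
  g[, 3] <- c(rep(1, 10), rep(0, 90))                  # MAF 0.05 exactly -> keep
  g[, 4] <- rep(c(0, 1, 1, 2), length.out = n)
  g[sample(n, 15), 4] <- NA                            # 15% missing -> fail
  g[, 5] <- rep(c(0, 1, 1, 2), length.out = n)
  g[sample(n, 10), 5] <- NA                            # 10% exactly -> keep
  g[, 6] <- c(rep(0, 50), rep(2, 50))                  # no hets -> fail HWE
  g[, 7] <- c(rep(0, 25), rep(1, 50), rep(2, 25))      # perfect HWE -> keep
  g[, 8] <- rep(c(0, 1, 2, 1), length.out = n)         # clean but unmapped
  g[, 9] <- rep(c(0, 1, 2, 1), length.out = n)         # clean but on X
  g[, 10] <- rep(c(0, 2, 1, 1), length.out = n)        # clean
  chrom <- c("1", "1", "1", "1", "2", "2", "2", "0", "X", "2")
  toyGenotypes(g, chrom = chrom)
}

test_that("QC filters match the hand-enumerated surviving set", {
  G <- makeQcToy()
  Gq <- qcGenotypes(G)
  expect_identical(snpInfo(Gq)$snp, c("S01", "S03", "S05", "S07", "S10"))
  rem <- qcLog(Gq)$removed
  expect_identical(rem$missingness, 1L)
  expect_identical(rem$maf, 1L)
  expect_identical(rem$hwe, 1L)
  expect_identical(rem$unmapped_x, 2L)
})

test_that("MAF and missingness thresholds are strict on the failing side", {
  G <- makeQcToy()
  Gq <- qcGenotypes(G)
  kept <- snpInfo(Gq)$snp
  expect_true("S03" %in% kept)   # MAF exactly 0.05 retained
  expect_false("S02" %in% kept)  # MAF 0.03 removed
  expect_true("S05" %in% kept)   # missingness exactly 0.10 retained
  expect_false("S04" %in% kept)  # missingness 0.15 removed
})

test_that("perfect Hardy-Weinberg proportions are retained, exact test agrees", {
  counts <- c(rep(0, 25), rep(1, 50), rep(2, 25))
  expect_gt(feednet:::.hweP(counts, "chisq"), 0.99)
  expect_gt(feednet:::.hweP(counts, "exact"), 0.5)
  # gross violation fails both
  bad <- c(rep(0, 50), rep(2, 50))
  expect_lt(feednet:::.hweP(bad, "chisq"), 1e-10)
  expect_lt(feednet:::.hweP(bad, "exact"), 1e-10)
})

test_that("QC is idempotent and imputes missing genotypes to the SNP mean", {
  G <- makeQcToy()
  Gq <- qcGenotypes(G)
  expect_false(anyNA(genotypes(Gq)))
  # S05 had 10 missing entries: imputed to the observed mean dosage
  obs <- genotypes(G)[, 5]
  expect_equal(unique(genotypes(Gq)[is.na(obs), "S05"]),
               mean(obs, na.rm = TRUE))
  Gq2 <- qcGenotypes(Gq)
  expect_identical(genotypes(Gq2), genotypes(Gq))
  expect_identical(snpInfo(Gq2)$snp, snpInfo(Gq)$snp)
})

test_that("an empty surviving SNP set is an explicit error", {
  g <- matrix(c(rep(1, 4), rep(0, 96)), 100, 2) # both MAF 0.02
  expect_error(qcGenotypes(toyGenotypes(g)), "no SNPs survive")
})

test_that("derived RFI has mean zero and the design orthogonality it promises", {
  fx <- sharedPop()
  tab <- fx$phen
  expect_lt(abs(mean(tab$RFI)), 1e-10)
  expect_equal(tab$MW, tab$BW^0.75)
  expect_equal(tab$FCR, tab$ADFI / tab$ADG)
  # residuals orthogonal to every design column (relative tolerance)
  X <- fx$fit$design
  expect_lt(max(abs(crossprod(X, tab$RFI))) / sum(abs(tab$ADFI)), 1e-8)
  # within each batch RFI is uncorrelated with the nested covariates
  for (b in levels(tab$batch)) {
    sub <- tab[tab$batch == b, ]
    expect_lt(abs(cor(sub$RFI, sub$MW)), 1e-6)
    expect_lt(abs(cor(sub$RFI, sub$ADG)), 1e-6)
    expect_lt(abs(cor(sub$RFI, sub$BF)), 1e-6)
  }
  # overall RFI-ADG correlation is zero by construction
  expect_lt(abs(cor(tab$RFI, tab$ADG)), 1e-6)
})

test_that("an exactly linear feed intake leaves zero residuals", {
  set.seed(3)
  n <- 24
  tab <- data.frame(
    batch = factor(rep(1:2, each = n / 2)),
    age_mid = round(runif(n, 121, 148)),
    ADG = runif(n, 0.7, 1.1), BF = runif(n, 18, 30), BW = runif(n, 70, 95))
  tab$BW <- tab$BW
  mw <- tab$BW^0.75
  tab$ADFI <- 0.5 + 0.2 * (tab$batch == "2") + 0.01 * tab$age_mid +
    0.02 * mw + 1.2 * tab$ADG + 0.005 * tab$BF
  der <- deriveTraits(tab)
  expect_lt(max(abs(der$table$RFI)), 1e-10)
})

test_that("RFI regression equals the normal-equations oracle on a small toy", {
  set.seed(8)
  n <- 16
  tab <- data.frame(
    batch = factor(rep(1:2, each = 8)),
    age_mid = sample(121:148, n, replace = TRUE),
    ADG = round(runif(n, 0.7, 1.1), 2), BF = sample(18:30, n, replace = TRUE),
    BW = sample(70:95, n, replace = TRUE))
  tab$ADFI <- round(runif(n, 2, 3.5), 2)
  der <- deriveTraits(tab)
  # oracle: explicit normal equations on the same parameterization
  mw <- tab$BW^0.75
  b2 <- as.numeric(tab$batch == "2")
  X <- cbind(1 - b2, b2, tab$age_mid,
             mw * (1 - b2), mw * b2,
             tab$ADG * (1 - b2), tab$ADG * b2,
             tab$BF * (1 - b2), tab$BF * b2)
  beta <- solve(t(X) %*% X, t(X) %*% tab$ADFI)
  expect_equal(der$table$RFI, drop(tab$ADFI - X %*% beta), tolerance = 1e-8)
})

test_that("trait derivation errors are informative", {
  tab <- data.frame(batch = factor(rep(1:2, each = 4)),
                    age_mid = rep(130, 8), ADG = c(rep(1, 7), 0),
                    BF = rep(20, 8), BW = rep(80, 8), ADFI = rep(2.5, 8))
  expect_error(deriveTraits(tab), "ADG must be strictly positive")
  tab$ADG[8] <- 1
  tab$batch <- factor(c(rep(1, 7), 2)) # one individual in batch 2
  expect_error(deriveTraits(tab), "at least 2 individuals")
  tab$batch <- factor(rep(1:2, each = 4)) # 4 < 5 nested coefficients
  expect_error(deriveTraits(tab), "rank")
  expect_error(deriveTraits(tab[, -1]), "must contain columns")
})

test_that("FCR and RFI rank-correlate positively on simulated data", {
  fx <- sharedPop()
  expect_gt(cor(fx$phen$FCR, fx$phen$RFI, method = "spearman"), 0.2)
})
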