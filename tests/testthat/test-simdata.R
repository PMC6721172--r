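test_that("simulated pedigree has the configured half-sib family structure", {
  fx <- sharedPop()
  ped <- fx$pop$pedigree
  off <- ped[!is.na(ped$sire), ]
  expect_length(unique(off$sire), 5)
  expect_true(all(table(off$sire) >= 1))
  # every offspring has its own dam (no full sibs)
  expect_false(anyDuplicated(off$dam) > 0)
  # founders precede their offspring in sort order
  expect_true(all(match(off$sire, ped$id) < match(off$id, ped$id)))
})

test_that("degenerate frequency range gives MAF 0.5 within sampling error", {
  cfg <- simConfig(n_individuals = 200, n_families = 4, n_snps = 300,
                   n_chromosomes = 2, maf_range = c(0.5, 0.5),
                   missing_rate = 0, seed = 9)
  pop <- simulatePopulation(cfg)
  maf <- snpInfo(pop$genotypes)$maf
  # sampling error reflects the family structure: half the alleles descend
  # from only 8 sire haplotypes, so per-SNP deviations are wide but the
  # panel mean stays near 0.5 (folded slightly below)
  expect_true(mean(maf) > 0.42)
  expect_true(all(maf > 0.2))
})

test_that("the generator is deterministic given the seed", {
  cfg <- simConfig(n_individuals = 40, n_snps = 100, n_chromosomes = 2,
                   n_genes_expressed = 30, seed = 77)
  p1 <- simulatePopulation(cfg)
  p2 <- simulatePopulation(cfg)
  expect_identical(genotypes(p1$genotypes), genotypes(p2$genotypes))
  expect_identical(p1$annotation, p2$annotation)
  ph1 <- simulatePhenotypes(p1$genotypes, p1$pedigree, cfg)
  ph2 <- simulatePhenotypes(p2$genotypes, p2$pedigree, cfg)
  expect_identical(ph1$ADFI, ph2$ADFI)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(n_families = 10, n_individuals = 5), "n_families")
  expect_error(simConfig(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simConfig(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simConfig(h2_per_trait = 1.2), "h2")
  expect_error(simConfig(pleiotropy_fraction = -0.1), "pleiotropy_fraction")
  cfg <- simConfig(n_individuals = 30, n_snps = 50)
  cfg$h2_per_trait[] <- 0 # h2 must be in (0,1) at phenotype time too
  pop <- simulatePopulation(cfg)
  expect_error(simulatePhenotypes(pop$genotypes, pop$pedigree, cfg), "h2")
})

test_that("offspring genotypes are Mendelian-consistent with their sire", {
  fx <- sharedPop()
  geno <- genotypes(fx$pop$genotypes)
  sg <- fx$pop$haplotypes$sire_genotypes
  fam <- fx$pop$haplotypes$family
  sire_of <- rownames(sg)[fam]
  ok <- TRUE
  for (i in seq_len(nrow(geno))) {
    s <- sg[sire_of[i], ]
    o <- geno[i, ]
    keep <- !is.na(o)
    # sire homozygous 0 cannot give offspring 2; homozygous 2 cannot give 0
    ok <- ok && !any(s[keep] == 0 & o[keep] == 2) &&
      !any(s[keep] == 2 & o[keep] == 0)
  }
  expect_true(ok)
})

test_that("same-sire offspring are more related than different-sire offspring", {
  fx <- sharedPop()
  K <- computeGRM(fx$Gq, allele_freq = fx$pop$haplotypes$founder_freq[
    match(snpInfo(fx$Gq)$snp, snpInfo(fx$pop$genotypes)$snp)])
  fam <- fx$pop$haplotypes$family[rownames(genotypes(fx$Gq))]
  same <- outer(fam, fam, "==") & upper.tri(K)
  diff <- (!outer(fam, fam, "==")) & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[diff]) + 0.1)
})

test_that("phenotype heritability round-trips through stored breeding values", {
  slopes <- sapply(1:12, function(s) {
    cfg <- simConfig(n_individuals = 200, n_snps = 500, n_chromosomes = 2,
                     h2_per_trait = 0.5, missing_rate = 0, seed = 100 + s)
    pop <- simulatePopulation(cfg)
    phen <- simulatePhenotypes(pop$genotypes, pop$pedigree, cfg)
    tbv <- simTruth(phen)$tbv[, "ADG"]
    # adjust the phenotype for the fixed effects before regressing
    yadj <- resid(lm(ADG ~ batch + age_mid, data = phen))
    coef(lm(tbv ~ yadj))[2]
  })
  expect_lt(abs(mean(slopes) - 0.5), 0.1)
})

test_that("true breeding values reproduce from stored per-SNP effects", {
  fx <- sharedPop()
  truth <- simTruth(simulatePhenotypes(fx$pop$genotypes, fx$pop$pedigree, fx$cfg))
  geno <- genotypes(fx$pop$genotypes)
  Z <- apply(geno, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE); x - mean(x)
  })
  expect_equal(unname(drop(Z %*% truth$effects[, "BF"])),
               unname(truth$tbv[, "BF"]), tolerance = 1e-8)
})

test_that("no genetic signal leaves only residual, batch and age variance", {
  cfg <- simConfig(n_individuals = 400, n_snps = 100, n_chromosomes = 2,
                   qtl_per_trait = 0, polygenic_fraction = 0,
                   h2_per_trait = 1e-4, seed = 31)
  pop <- simulatePopulation(cfg)
  phen <- simulatePhenotypes(pop$genotypes, pop$pedigree, cfg)
  # on the unit scale the trait is e + batch + age with var(e) ~ 1
  yadj <- resid(lm(KO ~ batch + age_mid, data = phen)) / 2.4 # KO scale sd
  expect_lt(abs(var(yadj) - 1), 0.2)
})

test_that("full pleiotropy with no background gives genetic correlation near 1", {
  cfg <- simConfig(n_individuals = 150, n_snps = 400, n_chromosomes = 2,
                   pleiotropy_fraction = 1, polygenic_fraction = 0,
                   qtl_per_trait = 50, seed = 55)
  pop <- simulatePopulation(cfg)
  truth <- simTruth(simulatePhenotypes(pop$genotypes, pop$pedigree, cfg))
  expect_gt(cor(truth$tbv[, "ADFI"], truth$tbv[, "ADG"]), 0.99)
})

test_that("expression simulation places laboratory and DE effects as configured", {
  fx <- sharedPop()
  ids <- fx$phen$id[1:60]
  groups <- setNames(rep("none", 60), ids)
  groups[1:10] <- "HFE"; groups[11:20] <- "LFE"
  se <- simulateExpression(fx$pop$genotypes, fx$pop$annotation, groups, fx$cfg)
  E <- SummarizedExperiment::assay(se, "exprs")
  lab <- SummarizedExperiment::colData(se)$lab
  # per-gene laboratory coefficients (batch/group adjusted) center on the
  # configured 0.5 shift
  grp <- factor(SummarizedExperiment::colData(se)$group)
  btc <- SummarizedExperiment::colData(se)$batch
  X <- model.matrix(~ lab + btc + grp)
  cf <- t(lm.fit(X, t(E))$coefficients)
  expect_lt(abs(mean(cf[, "lab2"]) - 0.5), 0.1)
  truth <- simTruth(se)
  de <- truth$de_genes
  grp <- SummarizedExperiment::colData(se)$group
  dde <- rowMeans(E[de, grp == "LFE"]) - rowMeans(E[de, grp == "HFE"])
  expect_gt(mean(abs(dde)), 0.5) # planted |effect| = 1 log2 unit
  expect_error(
    simulateExpression(fx$pop$genotypes, fx$pop$annotation,
                       setNames("HFE", "NOT_AN_ID"), fx$cfg),
    "unknown individuals")
})

test_that("stored cis-eQTL lie within 1 Mb of their gene", {
  fx <- sharedPop()
  ids <- fx$phen$id[1:50]
  groups <- setNames(rep("none", 50), ids)
  se <- simulateExpression(fx$pop$genotypes, fx$pop$annotation, groups, fx$cfg)
  truth <- simTruth(se)
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  info <- snpInfo(fx$pop$genotypes)
  for (i in seq_len(nrow(truth$cis))) {
    g <- rd[truth$cis$gene[i], ]
    s <- info[info$snp == truth$cis$snp[i], ]
    expect_identical(as.character(s$chrom), as.character(g$chrom))
    expect_lte(abs(s$pos - g$start), 1e6)
  }
})
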