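# Shared small simulated population, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

sharedPop <- function() {
  if (is.null(.fixture_env$pop)) {
    cfg <- simConfig(n_individuals = 150, n_families = 5, n_snps = 800,
                     n_chromosomes = 3, n_genes_expressed = 300, seed = 42)
    pop <- simulatePopulation(cfg)
    phen <- simulatePhenotypes(pop$genotypes, pop$pedigree, cfg)
    der <- deriveTraits(phen)
    Gq <- qcGenotypes(pop$genotypes)
    .fixture_env$pop <- list(cfg = cfg, pop = pop, phen = der$table,
                             fit = der$fit, Gq = Gq,
                             K = computeGRM(Gq))
  }
  .fixture_env$pop
}

# Study-sized population (n = 350, five half-sib families), built once.
sharedPop350 <- function() {
  if (is.null(.fixture_env$pop350)) {
    cfg <- simConfig(n_individuals = 350, n_families = 5, n_snps = 600,
                     n_chromosomes = 3, missing_rate = 0, seed = 600)
    pop <- simulatePopulation(cfg)
    der <- deriveTraits(simulatePhenotypes(pop$genotypes, pop$pedigree, cfg))
    .fixture_env$pop350 <- list(cfg = cfg, pop = pop, phen = der$table,
                                K = computeGRM(pop$genotypes))
  }
  .fixture_env$pop350
}

# Tiny deterministic GenotypeData for hand-checked examples.
toyGenotypes <- function(geno, chrom = NULL, pos = NULL) {
  m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- ave(seq_len(m), chrom, FUN = seq_along) * 1000
  freq <- colMeans(geno, na.rm = TRUE) / 2
  info <- data.frame(snp = sprintf("S%02d", seq_len(m)), chrom = chrom,
                     pos = pos, a1 = "A", a2 = "B",
                     maf = pmin(freq, 1 - freq), stringsAsFactors = FALSE)
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("I%02d", seq_len(nrow(geno)))
  GenotypeData(geno, info)
}

# Build a CoAssocNetwork directly from an explicit edge list.
toyNetwork <- function(nodes, from, to, weight = NULL) {
  if (is.null(weight)) weight <- rep(0.5, length(from))
  methods::new("CoAssocNetwork", nodes = nodes,
               edges = data.frame(from = from, to = to, weight = weight,
                                  stringsAsFactors = FALSE),
               aggregation = "any", nProfile = 9)
}
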