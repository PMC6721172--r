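#' Configuration for the synthetic population generator
#'
#' Defaults emulate the study design the pipeline targets: 350 barrows from
#' five paternal half-sib families distributed over four fattening batches,
#' a medium-density post-QC SNP panel (scaled down by default), nine
#' correlated production/feed-efficiency phenotypes with pleiotropic QTL and
#' a polygenic background, and a muscle expression matrix with cis/trans
#' eQTL, group-wise differential expression, batch and laboratory effects.
#'
#' @param n_individuals number of phenotyped offspring.
#' @param n_families number of paternal half-sib families (sires).
#' @param n_snps total number of SNPs across the genome.
#' @param n_chromosomes number of autosomes the SNPs are spread over.
#' @param maf_range founder allele-frequency range, within (0, 0.5].
#' @param ld_block_size gamete copying-block length in SNPs; larger blocks
#'   give longer-range linkage disequilibrium.
#' @param n_traits number of analysis traits (nine: RFI, FCR, ADFI, ADG, CW,
#'   KO, BF, LEAN, IMF; RFI and FCR are derived downstream, the other seven
#'   plus body weight are simulated directly).
#' @param qtl_per_trait number of QTL per simulated trait.
#' @param pleiotropy_fraction fraction of each grouped trait's QTL drawn from
#'   a pool shared across its trait group (effects shared with correlation 1).
#' @param h2_per_trait narrow-sense heritability per simulated trait; scalar
#'   recycled or vector of length 8 (ADFI, ADG, BW, BF, CW, KO, LEAN, IMF).
#' @param batch_count number of fattening batches (fixed effect levels).
#' @param n_genes_expressed number of annotated/expressed genes.
#' @param n_cis_eqtl,n_trans_eqtl numbers of cis and trans expression QTL.
#' @param n_de_genes number of genes differentially expressed between the
#'   low- and high-feed-efficiency groups.
#' @param de_effect DE effect size added to LFE individuals (log2 units).
#' @param lab_count number of laboratories processing expression samples.
#' @param lab_effect additive laboratory shift (log2 units) applied to every
#'   gene in non-reference laboratories.
#' @param tf_fraction fraction of genes flagged as transcription factors.
#' @param polygenic_fraction share of each trait's genetic variance assigned
#'   to the polygenic background (small effects on non-QTL SNPs).
#' @param missing_rate rate of missing genotypes introduced pre-QC.
#' @param cis_effect,trans_effect eQTL allele-substitution effects (log2 per
#'   allele).
#' @param expr_noise_sd residual SD of log2 expression.
#' @param batch_sd within-trait SD of batch effects (phenotypic SD units).
#' @param age_beta per-day age-covariate slope (phenotypic SD units).
#' @param seed global integer seed; every stage-level generator derives its
#'   sub-seed deterministically from it.
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(n_individuals = 350, n_families = 5, n_snps = 3000,
                      n_chromosomes = 6, maf_range = c(0.05, 0.5),
                      ld_block_size = 10, n_traits = 9, qtl_per_trait = 100,
                      pleiotropy_fraction = 0.4,
                      h2_per_trait = c(ADFI = 0.45, ADG = 0.40, BW = 0.40,
                                       BF = 0.50, CW = 0.40, KO = 0.30,
                                       LEAN = 0.50, IMF = 0.50),
                      batch_count = 4, n_genes_expressed = 1000,
                      n_cis_eqtl = 10, n_trans_eqtl = 5, n_de_genes = 50,
                      de_effect = 1.0, lab_count = 2, lab_effect = 0.5,
                      tf_fraction = 0.08, polygenic_fraction = 0.3,
                      missing_rate = 0.01, cis_effect = 1.0,
                      trans_effect = 0.8, expr_noise_sd = 0.5,
                      batch_sd = 0.5, age_beta = 0.02, seed = 1) {
  counts <- c(n_individuals = n_individuals, n_families = n_families,
              n_snps = n_snps, n_chromosomes = n_chromosomes,
              ld_block_size = ld_block_size, n_traits = n_traits,
              batch_count = batch_count, n_genes_expressed = n_genes_expressed,
              lab_count = lab_count)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("counts must be positive integers: ",
         paste(names(counts)[counts < 1 | counts != round(counts)],
               collapse = ", "))
  }
  if (qtl_per_trait < 0 || n_cis_eqtl < 0 || n_trans_eqtl < 0 || n_de_genes < 0) {
    stop("QTL/eQTL/DE gene counts must be non-negative")
  }
  if (n_families > n_individuals) {
    stop("invalid config: n_families (", n_families,
         ") exceeds n_individuals (", n_individuals, ")")
  }
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be within (0, 0.5] with lower <= upper")
  }
  if (length(h2_per_trait) == 1) {
    h2_per_trait <- stats::setNames(rep(h2_per_trait, 8),
      c("ADFI", "ADG", "BW", "BF", "CW", "KO", "LEAN", "IMF"))
  }
  if (length(h2_per_trait) != 8 || is.null(names(h2_per_trait))) {
    stop("h2_per_trait must be a scalar or a named vector of length 8")
  }
  checkProportion(h2_per_trait, "h2_per_trait", open0 = TRUE, open1 = TRUE)
  checkProportion(pleiotropy_fraction, "pleiotropy_fraction")
  checkProportion(tf_fraction, "tf_fraction")
  checkProportion(polygenic_fraction, "polygenic_fraction")
  checkProportion(missing_rate, "missing_rate")
  cfg <- as.list(environment())
  cfg <- cfg[setdiff(names(cfg), "counts")]
  structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$n_individuals, "offspring /", x$n_families,
      "half-sib families,", x$n_snps, "SNPs on", x$n_chromosomes,
      "chromosomes, seed", x$seed, "\n")
  invisible(x)
}
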