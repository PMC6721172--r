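#' Genotype quality control
#'
#' Filters SNPs in a fixed order: missingness, minor allele frequency,
#' Hardy-Weinberg equilibrium, then unmapped/X-chromosome markers. All
#' thresholds use strict inequalities on the failing side (a SNP with MAF of
#' exactly \code{maf_min} is retained). Remaining missing genotypes are
#' imputed to the per-SNP mean dosage, which preserves allele frequencies for
#' relationship-matrix construction. Per-filter removal counts are recorded
#' in the QC log.
#'
#' HWE is tested by the conventional 1-df chi-square on genotype counts; an
#' exact test is available via \code{hwe_test = "exact"}.
#'
#' @param G \linkS4class{GenotypeData}, pre-QC (missing values allowed).
#' @param maf_min SNPs with MAF strictly below this are removed.
#' @param miss_max SNPs with missingness strictly above this are removed.
#' @param hwe_p SNPs with an HWE test p-value strictly below this are removed.
#' @param drop_unmapped drop SNPs with chromosome \code{NA} or \code{"0"}.
#' @param drop_x drop SNPs on chromosome \code{"X"}.
#' @param hwe_test \code{"chisq"} (default) or \code{"exact"}.
#' @param impute impute remaining missing genotypes to the per-SNP mean
#'   dosage (default \code{TRUE}).
#' @return A filtered \linkS4class{GenotypeData} whose \code{qcLog} records
#'   the removal counts per filter.
#' @export
qcGenotypes <- function(G, maf_min = 0.05, miss_max = 0.10, hwe_p = 0.001,
                        drop_unmapped = TRUE, drop_x = TRUE,
                        hwe_test = c("chisq", "exact"), impute = TRUE) {
  stopifnot(methods::is(G, "GenotypeData"))
  hwe_test <- match.arg(hwe_test)
  g <- genotypes(G)
  info <- snpInfo(G)
  keep <- rep(TRUE, ncol(g))
  removed <- c(missingness = 0L, maf = 0L, hwe = 0L, unmapped_x = 0L)

  miss <- colMeans(is.na(g))
  fail <- keep & miss > miss_max
  removed["missingness"] <- sum(fail)
  keep <- keep & !fail

  freq <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  fail <- keep & maf < maf_min
  removed["maf"] <- sum(fail)
  keep <- keep & !fail

  hp <- vapply(which(keep), function(j) {
    .hweP(g[, j], hwe_test)
  }, numeric(1))
  fail_idx <- which(keep)[hp < hwe_p]
  removed["hwe"] <- length(fail_idx)
  keep[fail_idx] <- FALSE

  bad_map <- rep(FALSE, ncol(g))
  if (drop_unmapped) bad_map <- bad_map | is.na(info$chrom) | info$chrom %in% c("0", "")
  if (drop_x) bad_map <- bad_map | info$chrom %in% c("X", "x", "23")
  fail <- keep & bad_map
  removed["unmapped_x"] <- sum(fail)
  keep <- keep & !fail

  if (!any(keep)) stop("no SNPs survive quality control")

  g2 <- g[, keep, drop = FALSE]
  if (impute && anyNA(g2)) {
    mu <- colMeans(g2, na.rm = TRUE)
    idx <- which(is.na(g2), arr.ind = TRUE)
    g2[idx] <- mu[idx[, 2]]
  }
  info2 <- info[keep, , drop = FALSE]
  freq2 <- colMeans(g2) / 2
  info2$maf <- pmin(freq2, 1 - freq2)
  GenotypeData(g2, info2,
               qcLog = list(removed = as.list(removed),
                            n_input = ncol(g), n_output = sum(keep),
                            thresholds = list(maf_min = maf_min,
                                              miss_max = miss_max,
                                              hwe_p = hwe_p)))
}

# HWE p-value on one SNP's dosages (0/1/2, NA ignored).
.hweP <- function(x, test = "chisq") {
  x <- x[!is.na(x)]
  n0 <- sum(x == 0); n1 <- sum(x == 1); n2 <- sum(x == 2)
  n <- n0 + n1 + n2
  if (n == 0L) return(1)
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  if (test == "chisq") {
    exp_cnt <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((c(n0, n1, n2) - exp_cnt)^2 / exp_cnt)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    .hweExactP(n1, min(n0, n2), n)
  }
}

# Wigginton-style exact test: probability of heterozygote counts as or more
# extreme than observed, conditioning on allele counts.
.hweExactP <- function(nhet, nhom_rare, n) {
  nrare <- 2 * nhom_rare + nhet
  hets <- seq(nrare %% 2, min(nrare, 2 * n - nrare), by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (nrare - h) / 2
    hc <- n - h - hr
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hr + 1) - lgamma(hc + 1) +
      h * log(2) + lgamma(nrare + 1) + lgamma(2 * n - nrare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[hets == nhet] * (1 + 1e-12)])
}
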