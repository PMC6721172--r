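#' @import methods
NULL

#' GenotypeData: individuals x SNPs dosage matrix with per-SNP metadata
#'
#' Container for biallelic genotypes coded as the dosage of the counted (A1)
#' allele (0/1/2; \code{NA} allowed before quality control) together with
#' per-SNP metadata (chromosome, physical position, allele labels, observed
#' minor-allele frequency).
#'
#' @slot genotypes numeric matrix, individuals in rows, SNPs in columns.
#'   After QC the entries may be fractional (mean-imputed dosages).
#' @slot snpInfo data.frame with one row per SNP: \code{snp}, \code{chrom},
#'   \code{pos} (bp, 1-based), \code{a1}, \code{a2}, \code{maf}.
#' @slot qcLog list recording per-filter removal counts (empty before QC).
#'
#' @exportClass GenotypeData
setClass("GenotypeData",
  slots = c(genotypes = "matrix", snpInfo = "data.frame", qcLog = "list"))

setValidity("GenotypeData", function(object) {
  g <- object@genotypes
  info <- object@snpInfo
  msg <- character()
  if (ncol(g) != nrow(info)) {
    msg <- c(msg, "ncol(genotypes) must equal nrow(snpInfo)")
  }
  need <- c("snp", "chrom", "pos", "a1", "a2", "maf")
  if (!all(need %in% names(info))) {
    msg <- c(msg, paste("snpInfo must contain columns:",
                        paste(need, collapse = ", ")))
  } else {
    if (!identical(colnames(g), as.character(info$snp))) {
      msg <- c(msg, "colnames(genotypes) must match snpInfo$snp")
    }
    if (anyDuplicated(info$snp)) msg <- c(msg, "SNP ids must be unique")
    ok <- is.na(g) | (g >= 0 & g <= 2)
    if (!all(ok)) msg <- c(msg, "genotype dosages must lie in [0, 2] or be NA")
    # positions strictly increasing within each chromosome
    for (ch in unique(info$chrom)) {
      p <- info$pos[info$chrom == ch]
      if (length(p) > 1L && any(diff(p) <= 0)) {
        msg <- c(msg, paste0("positions not strictly increasing on chromosome ", ch))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param genotypes numeric matrix of allele dosages (individuals x SNPs).
#' @param snpInfo per-SNP metadata data.frame (see \linkS4class{GenotypeData}).
#' @param qcLog optional list of QC bookkeeping entries.
#' @return A \linkS4class{GenotypeData} object.
#' @export
GenotypeData <- function(genotypes, snpInfo, qcLog = list()) {
  genotypes <- as.matrix(genotypes)
  colnames(genotypes) <- as.character(snpInfo$snp)
  new("GenotypeData", genotypes = genotypes,
      snpInfo = as.data.frame(snpInfo), qcLog = qcLog)
}

#' AWMatrix: multi-trait association weight matrix
#'
#' Rows are retained SNPs, columns the analysed traits; each cell is the
#' signed z-score of the estimated allele-substitution effect. Row-level
#' provenance records how each SNP qualified (key-trait significance, number
#' of other significant traits, nearest gene, distance, TF flag).
#'
#' @slot zscores numeric matrix (retained SNPs x traits).
#' @slot provenance data.frame, one row per retained SNP.
#' @slot keyTrait name of the key (target) trait.
#' @slot pThreshold nominal per-trait significance threshold used.
#' @slot minOther minimum number of non-key significant traits in the
#'   multi-trait arm of the retention rule.
#' @slot maxDist maximum absolute SNP-to-gene distance (bp).
#'
#' @exportClass AWMatrix
setClass("AWMatrix",
  slots = c(zscores = "matrix", provenance = "data.frame",
            keyTrait = "character", pThreshold = "numeric",
            minOther = "numeric", maxDist = "numeric"))

setValidity("AWMatrix", function(object) {
  msg <- character()
  z <- object@zscores
  pr <- object@provenance
  if (nrow(z) != nrow(pr)) msg <- c(msg, "provenance must have one row per SNP")
  if (anyDuplicated(rownames(z))) msg <- c(msg, "AWM row names must be unique")
  if (!(object@keyTrait %in% colnames(z))) {
    msg <- c(msg, "key trait must be one of the AWM columns")
  }
  if (all(c("key_sig", "n_other_sig") %in% names(pr)) && nrow(pr) > 0) {
    ok <- pr$key_sig | pr$n_other_sig >= object@minOther
    if (!all(ok)) msg <- c(msg, "every row must pass the retention rule")
  }
  if ("distance" %in% names(pr) && nrow(pr) > 0 &&
      any(abs(pr$distance) > object@maxDist, na.rm = TRUE)) {
    msg <- c(msg, "every row must map within maxDist of its nearest gene")
  }
  if (length(msg)) msg else TRUE
})

#' CoAssocNetwork: undirected weighted SNP co-association network
#'
#' Nodes are AWM rows; an edge carries the Pearson correlation between the two
#' rows' multi-trait z-score profiles and is present only if it survived the
#' PCIT significance decision.
#'
#' @slot nodes character vector of node labels.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @slot aggregation PCIT trio-aggregation mode used (\code{"any"} or
#'   \code{"all"}).
#' @slot nProfile number of points (traits) behind each correlation.
#'
#' @exportClass CoAssocNetwork
setClass("CoAssocNetwork",
  slots = c(nodes = "character", edges = "data.frame",
            aggregation = "character", nProfile = "numeric"))

setValidity("CoAssocNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e))) {
    msg <- c(msg, "edges must have columns from, to, weight")
  } else if (nrow(e) > 0) {
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    if (!all(c(e$from, e$to) %in% object@nodes)) {
      msg <- c(msg, "edge endpoints must be network nodes")
    }
    if (any(abs(e$weight) > 1 + 1e-12)) msg <- c(msg, "|weight| must be <= 1")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edges")
  }
  if (length(msg)) msg else TRUE
})
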