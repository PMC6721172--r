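#' Read and write PLINK text genotypes (.ped/.map)
#'
#' \code{writePlink} serializes a \linkS4class{GenotypeData} to the PLINK
#' text pair; \code{readPlink} reads one back, counting the A1 allele (the
#' minor allele as observed in the file) as the dosage allele. Missing
#' genotypes are written/read as \code{0 0}.
#'
#' @param G a \linkS4class{GenotypeData}.
#' @param prefix file path prefix (\code{prefix.ped}, \code{prefix.map}).
#' @return \code{readPlink} returns a \linkS4class{GenotypeData};
#'   \code{writePlink} returns the prefix invisibly.
#' @export
writePlink <- function(G, prefix) {
  g <- genotypes(G)
  info <- snpInfo(G)
  n <- nrow(g)
  allele_str <- function(dose, a1, a2) {
    out <- character(length(dose))
    out[is.na(dose)] <- "0 0"
    out[!is.na(dose) & dose == 2] <- paste(a1, a1)
    out[!is.na(dose) & dose == 1] <- paste(a1, a2)
    out[!is.na(dose) & dose == 0] <- paste(a2, a2)
    out
  }
  cols <- vapply(seq_len(ncol(g)), function(j) {
    allele_str(round(g[, j]), info$a1[j], info$a2[j])
  }, character(n))
  ped <- cbind("FAM1", rownames(g), "0", "0", "0", "-9", cols)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map <- data.frame(info$chrom, info$snp, 0, info$pos)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname writePlink
#' @export
readPlink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"),
                           col.names = c("chrom", "snp", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  ped <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) stop(".ped column count does not match .map")
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6)])
  geno <- matrix(NA_real_, nrow(ped), m, dimnames = list(ids, map$snp))
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    x1 <- al[, 2 * j - 1]; x2 <- al[, 2 * j]
    obs <- c(x1, x2)
    tab <- sort(table(obs[obs != "0"]))
    if (length(tab) == 0) { a1[j] <- "A"; a2[j] <- "B"; next }
    a1[j] <- names(tab)[1]                      # minor = counted allele
    a2[j] <- if (length(tab) > 1) names(tab)[length(tab)] else names(tab)[1]
    miss <- x1 == "0" | x2 == "0"
    geno[!miss, j] <- (x1 == a1[j])[!miss] + (x2 == a1[j])[!miss]
  }
  freq <- colMeans(geno, na.rm = TRUE) / 2
  info <- data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
                     a1 = a1, a2 = a2, maf = pmin(freq, 1 - freq),
                     stringsAsFactors = FALSE)
  GenotypeData(geno, info)
}

#' Write an association scan as TSV
#'
#' One row per SNP with a deterministic column order (snp, chrom, pos,
#' allele, maf, effect, se, z, p, then q/bonferroni/cis_trans when present).
#'
#' @param res an \code{AssocResults} data.frame.
#' @param file output path.
#' @export
writeAssocResults <- function(res, file) {
  base <- c("snp", "chrom", "pos", "allele", "maf", "effect", "se", "z", "p")
  extra <- intersect(c("gene", "q", "bonferroni", "cis_trans"), names(res))
  utils::write.table(res[, c(base, extra)], file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a co-association network as a 3-column edge-list TSV
#'
#' @param net a \linkS4class{CoAssocNetwork}.
#' @param file output path.
#' @export
writeEdgeList <- function(net, file) {
  e <- edgeTable(net)
  names(e) <- c("node_a", "node_b", "weight")
  utils::write.table(e, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a phenotype table from TSV
#'
#' Expects one row per individual with documented column names (id, sire,
#' dam, batch, age_mid, and the trait columns); batch is converted to a
#' factor.
#'
#' @param file TSV path.
#' @return data.frame.
#' @export
readPhenotypes <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if ("batch" %in% names(tab)) tab$batch <- factor(tab$batch)
  tab
}
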