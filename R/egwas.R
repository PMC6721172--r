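#' Expression GWAS: mixed-model scans for gene-expression traits
#'
#' For each requested gene, fits the null animal model with batch and
#' laboratory fixed effects (the eGWAS model has no age covariate), scans all
#' SNPs under the fixed null-covariance approximation, and adjusts for
#' multiple testing within gene across SNPs: Benjamini-Hochberg q-values plus
#' a Bonferroni column. Each SNP is labelled \code{cis} when it lies within
#' \code{cis_window} bp of the gene position on the same chromosome, else
#' \code{trans}.
#'
#' @param expr \code{SummarizedExperiment} (genes x individuals) with colData
#'   columns \code{batch} and \code{lab}; the individuals must be a subset of
#'   the genotyped individuals.
#' @param genes character vector of gene ids to scan.
#' @param G \linkS4class{GenotypeData} post QC.
#' @param K relationship matrix over the genotyped individuals.
#' @param annotation optional gene coordinate table; defaults to
#'   \code{rowData(expr)} (needs \code{chrom} and the column named by
#'   \code{gene_pos}).
#' @param cis_window cis labelling window in bp (1 Mb).
#' @param gene_pos which gene coordinate anchors the cis window
#'   (\code{"start"} or \code{"midpoint"}).
#' @return A data.frame with one row per gene x SNP: scan columns as in
#'   \code{\link{assocScan}}, plus \code{gene}, \code{q} (BH within gene),
#'   \code{bonferroni} and \code{cis_trans}.
#' @export
egwasScan <- function(expr, genes, G, K, annotation = NULL,
                      cis_window = 1e6, gene_pos = c("start", "midpoint")) {
  gene_pos <- match.arg(gene_pos)
  E <- SummarizedExperiment::assay(expr, "exprs")
  absent <- setdiff(genes, rownames(E))
  if (length(absent)) {
    stop("genes absent from expression matrix: ",
         paste(utils::head(absent, 10), collapse = ", "))
  }
  cd <- as.data.frame(SummarizedExperiment::colData(expr))
  ids <- colnames(E)
  geno_all <- genotypes(G)
  if (!all(ids %in% rownames(geno_all))) {
    stop("expression individuals missing from genotypes: ",
         paste(utils::head(setdiff(ids, rownames(geno_all)), 5), collapse = ", "))
  }
  Gsub <- G[match(ids, rownames(geno_all)), ]
  if (is.null(rownames(K))) dimnames(K) <- list(rownames(geno_all), rownames(geno_all))
  Ksub <- K[ids, ids]
  X <- buildDesign(cd, c("batch", "lab"))

  ann <- if (is.null(annotation)) {
    as.data.frame(SummarizedExperiment::rowData(expr))
  } else annotation
  info <- snpInfo(Gsub)

  res <- lapply(genes, function(gn) {
    y <- E[gn, ]
    vc <- fitNullModel(y, X, Ksub)
    sc <- assocScan(y, X, Gsub, vc)
    sc$gene <- gn
    sc$q <- stats::p.adjust(sc$p, method = "BH")
    sc$bonferroni <- pmin(1, sc$p * sum(!is.na(sc$p)))
    ga <- ann[match(gn, ann$gene), ]
    gp <- if (gene_pos == "start") ga$start else (ga$start + ga$end) / 2
    sc$cis_trans <- ifelse(
      !is.na(sc$chrom) & sc$chrom == ga$chrom & abs(sc$pos - gp) <= cis_window,
      "cis", "trans")
    sc
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("AssocResults", "data.frame")
  out
}
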