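#' Compute a genomic relationship matrix
#'
#' Two standard estimators are provided. \code{"per-snp"} standardizes each
#' SNP by its own variance before averaging:
#' \deqn{G_{ij} = \frac{1}{m}\sum_k \frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}{2p_k(1-p_k)}}
#' \code{"overall"} divides the cross-product of centered genotypes by the
#' summed expected variance \eqn{\sum_k 2p_k(1-p_k)}. Allele frequencies are
#' taken from the analysed genotypes.
#'
#' @param G \linkS4class{GenotypeData}, post-QC (missing values imputed).
#' @param subset optional character vector of SNP ids (or column indices) to
#'   use; default all SNPs.
#' @param method \code{"per-snp"} (allele-frequency standardized) or
#'   \code{"overall"} (overall-scaled cross-product).
#' @param allele_freq optional vector of reference A1 allele frequencies
#'   (one per analysed SNP, in column order); defaults to the frequencies
#'   observed in the analysed genotypes. Supplying base-population
#'   frequencies gives relationships on the classical pedigree scale.
#' @return Symmetric n x n matrix with attributes \code{method} and
#'   \code{snps}.
#' @export
computeGRM <- function(G, subset = NULL, method = c("per-snp", "overall"),
                       allele_freq = NULL) {
  method <- match.arg(method)
  x <- if (methods::is(G, "GenotypeData")) genotypes(G) else as.matrix(G)
  if (!is.null(subset)) {
    if (is.character(subset)) {
      missing_snps <- setdiff(subset, colnames(x))
      if (length(missing_snps)) {
        stop("subset SNPs not found: ",
             paste(utils::head(missing_snps, 5), collapse = ", "))
      }
    }
    x <- x[, subset, drop = FALSE]
  }
  if (anyNA(x)) stop("genotypes contain missing values; run qcGenotypes() first")
  p <- if (is.null(allele_freq)) colMeans(x) / 2 else {
    stopifnot(length(allele_freq) == ncol(x))
    as.numeric(allele_freq)
  }
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNP(s) in subset: ",
         paste(utils::head(colnames(x)[p <= 0 | p >= 1], 5), collapse = ", "))
  }
  W <- sweep(x, 2, 2 * p)
  K <- if (method == "per-snp") {
    tcrossprod(sweep(W, 2, sqrt(2 * p * (1 - p)), "/")) / ncol(x)
  } else {
    tcrossprod(W) / sum(2 * p * (1 - p))
  }
  dimnames(K) <- list(rownames(x), rownames(x))
  attr(K, "method") <- method
  attr(K, "snps") <- colnames(x)
  K
}
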