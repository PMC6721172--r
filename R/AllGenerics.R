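#' Accessors for feednet S4 containers
#'
#' @param x a feednet S4 object.
#' @name accessors
NULL

#' @describeIn accessors genotype dosage matrix (individuals x SNPs).
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @describeIn accessors per-SNP metadata data.frame.
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @describeIn accessors QC bookkeeping list.
#' @export
setGeneric("qcLog", function(x) standardGeneric("qcLog"))

#' @describeIn accessors signed z-score matrix of an AWM.
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))

#' @describeIn accessors AWM row provenance data.frame.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @describeIn accessors network node labels.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @describeIn accessors network edge list data.frame.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @export
#' @rdname accessors
setMethod("genotypes", "GenotypeData", function(x) x@genotypes)

#' @export
#' @rdname accessors
setMethod("snpInfo", "GenotypeData", function(x) x@snpInfo)

#' @export
#' @rdname accessors
setMethod("qcLog", "GenotypeData", function(x) x@qcLog)

#' @export
#' @rdname accessors
setMethod("zscores", "AWMatrix", function(x) x@zscores)

#' @export
#' @rdname accessors
setMethod("provenance", "AWMatrix", function(x) x@provenance)

#' @export
#' @rdname accessors
setMethod("networkNodes", "CoAssocNetwork", function(x) x@nodes)

#' @export
#' @rdname accessors
setMethod("edgeTable", "CoAssocNetwork", function(x) x@edges)

setMethod("show", "GenotypeData", function(object) {
  g <- object@genotypes
  cat("GenotypeData:", nrow(g), "individuals x", ncol(g), "SNPs\n")
  cat("  chromosomes:", paste(unique(object@snpInfo$chrom), collapse = ", "), "\n")
  nmiss <- sum(is.na(g))
  cat("  missing genotypes:", nmiss,
      sprintf("(%.2f%%)\n", 100 * nmiss / length(g)))
  if (length(object@qcLog)) {
    cat("  QC applied; removed:",
        paste(names(object@qcLog$removed),
              unlist(object@qcLog$removed), collapse = ", "), "\n")
  }
})

setMethod("show", "AWMatrix", function(object) {
  cat("AWMatrix:", nrow(object@zscores), "SNPs x",
      ncol(object@zscores), "traits (key trait:", object@keyTrait, ")\n")
  cat("  retention: p <", object@pThreshold, "on key trait OR >=",
      object@minOther, "other traits; gene distance <=", object@maxDist, "bp\n")
  if (nrow(object@provenance) > 0 && "tf" %in% names(object@provenance)) {
    cat("  TF-annotated rows:", sum(object@provenance$tf, na.rm = TRUE), "\n")
  }
})

setMethod("show", "CoAssocNetwork", function(object) {
  cat("CoAssocNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "significant edges (PCIT aggregation:",
      object@aggregation, ")\n")
  if (nrow(object@edges) > 0) {
    cat(sprintf("  edge weight range: [%.3f, %.3f]\n",
                min(object@edges$weight), max(object@edges$weight)))
  }
})

#' Number of individuals / SNPs in a GenotypeData object
#'
#' @param x a \linkS4class{GenotypeData} object.
#' @return \code{dim} returns \code{c(individuals, snps)}.
#' @export
setMethod("dim", "GenotypeData", function(x) dim(x@genotypes))

#' Subset a GenotypeData object
#'
#' @param x a \linkS4class{GenotypeData} object.
#' @param i individual (row) index.
#' @param j SNP (column) index.
#' @param ... ignored.
#' @param drop ignored; always returns a GenotypeData object.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@genotypes))
  if (missing(j)) j <- seq_len(ncol(x@genotypes))
  GenotypeData(x@genotypes[i, j, drop = FALSE],
               x@snpInfo[j, , drop = FALSE], x@qcLog)
})
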