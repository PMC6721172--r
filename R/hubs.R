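#' Node degrees and transcription-factor hubs of a co-association network
#'
#' Degree is the number of significant incident edges. TF-annotated nodes are
#' extracted and ranked by degree; the network mean degree is reported as the
#' comparator for calling a TF a hub.
#'
#' @param net a \linkS4class{CoAssocNetwork}.
#' @param annotation optional SNP annotation (\code{snp}, \code{tf}) used to
#'   flag TF nodes; if the network was built from an AWM, pass its
#'   provenance. Nodes absent from the table get \code{tf = NA}.
#' @return A data.frame \code{node}, \code{degree}, \code{tf}, sorted by
#'   decreasing degree, with attributes \code{mean_degree} and
#'   \code{tf_ranking} (the TF subset).
#' @export
hubRanking <- function(net, annotation = NULL) {
  stopifnot(methods::is(net, "CoAssocNetwork"))
  nodes <- networkNodes(net)
  e <- edgeTable(net)
  deg <- table(factor(c(e$from, e$to), levels = nodes))
  out <- data.frame(node = nodes, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out$tf <- if (!is.null(annotation)) {
    as.logical(annotation$tf[match(nodes, annotation$snp)])
  } else NA
  out <- out[order(-out$degree, out$node), ]
  rownames(out) <- NULL
  attr(out, "mean_degree") <- if (length(nodes)) mean(out$degree) else NA_real_
  attr(out, "tf_ranking") <- out[!is.na(out$tf) & out$tf, , drop = FALSE]
  out
}
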