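#' Detection filtering and probe-to-gene collapse
#'
#' Drops control probes, probes detected in fewer than \code{present_min} of
#' the samples, and probes without a gene mapping; remaining probes mapping
#' to the same gene are averaged per sample to give one log2 expression value
#' per gene.
#'
#' @param exprs probe x sample numeric matrix (log2 scale).
#' @param detected logical probe x sample matrix of detection calls.
#' @param probe_map data.frame with columns \code{probe}, \code{gene}
#'   (\code{NA} for unmapped probes) and optionally \code{is_control}.
#' @param present_min minimum fraction of samples in which a probe must be
#'   detected to survive (kept when fraction detected >= \code{present_min}).
#' @param colData optional per-sample data.frame carried into the result.
#' @return A \code{SummarizedExperiment} (genes x samples) with assay
#'   \code{exprs}; \code{metadata()$filter} records per-step probe counts.
#' @export
preprocessExpression <- function(exprs, detected, probe_map,
                                 present_min = 0.25, colData = NULL) {
  exprs <- as.matrix(exprs)
  detected <- as.matrix(detected)
  stopifnot(identical(dim(exprs), dim(detected)))
  if (is.null(colnames(exprs))) {
    colnames(exprs) <- sprintf("sample%03d", seq_len(ncol(exprs)))
  }
  pm <- probe_map[match(rownames(exprs), probe_map$probe), ]

  log <- list(n_probes = nrow(exprs))
  keep <- rep(TRUE, nrow(exprs))
  if ("is_control" %in% names(pm)) {
    keep <- keep & !(pm$is_control %in% TRUE)
  }
  log$after_controls <- sum(keep)
  det_frac <- rowMeans(detected)
  keep <- keep & det_frac >= present_min
  log$after_detection <- sum(keep)
  keep <- keep & !is.na(pm$gene)
  log$after_mapping <- sum(keep)
  if (!any(keep)) stop("no genes survive expression preprocessing")

  E <- exprs[keep, , drop = FALSE]
  gene <- pm$gene[keep]
  collapsed <- rowsum(E, group = gene) / as.vector(table(gene)[sort(unique(gene))])
  collapsed <- collapsed[sort(unique(gene)), , drop = FALSE]
  log$n_genes <- nrow(collapsed)

  cd <- if (is.null(colData)) {
    S4Vectors::DataFrame(row.names = colnames(collapsed))
  } else S4Vectors::DataFrame(colData, row.names = colnames(collapsed))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = collapsed), colData = cd)
  S4Vectors::metadata(se)$filter <- log
  se
}
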