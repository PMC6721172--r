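#' Consolidate candidate genes across DE, sPLS-DA and rCCA
#'
#' Flags each gene by the analyses that reported it and keeps those hit by
#' at least \code{min_methods}. Loading concordance is the Pearson
#' correlation between the sPLS-DA first-component loadings and the rCCA
#' first-canonical-variate loadings over the genes common to both
#' selections.
#'
#' @param de \code{DEResult} from \code{\link{deTrendTest}}.
#' @param spls \code{SplsdaResult} from \code{\link{splsdaFit}}.
#' @param rcca \code{RccaResult} from \code{\link{rccaFit}}.
#' @param min_methods minimum number of methods that must report a gene.
#' @return list: \code{table} (gene x method flags with \code{n_methods} and
#'   \code{candidate}), \code{candidates} (gene ids), \code{concordance},
#'   \code{common_genes} (genes behind the concordance estimate).
#' @export
integrateCandidates <- function(de, spls, rcca, min_methods = 2) {
  de_genes <- de$gene[de$de]
  spls_genes <- spls$selected[[1]]
  rcca_genes <- rcca$selected
  universe <- sort(Reduce(union, list(de$gene, rownames(spls$loadings),
                                      rownames(rcca$trait_cor))))
  if (length(universe) == 0 ||
      length(intersect(de$gene, rownames(spls$loadings))) == 0) {
    stop("gene universes of the three analyses do not overlap")
  }
  tab <- data.frame(gene = universe,
                    de = universe %in% de_genes,
                    splsda = universe %in% spls_genes,
                    rcca = universe %in% rcca_genes,
                    stringsAsFactors = FALSE)
  tab$n_methods <- tab$de + tab$splsda + tab$rcca
  tab$candidate <- tab$n_methods >= min_methods

  common <- intersect(spls_genes, rcca_genes)
  concordance <- if (length(common) >= 3) {
    stats::cor(spls$loadings[common, 1], rcca$ycoef[common, 1])
  } else NA_real_
  list(table = tab, candidates = tab$gene[tab$candidate],
       concordance = concordance, common_genes = common)
}
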