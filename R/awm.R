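#' Build the association weight matrix (AWM) from per-trait scans
#'
#' A SNP is retained when it is nominally associated (p < \code{p_thresh})
#' with the key trait, or with at least \code{min_other} of the remaining
#' traits, and maps within \code{max_dist} bp of its nearest annotated gene.
#' Retained rows carry the signed z-scores of the allele-substitution effects
#' for all traits (significant or not).
#'
#' @param scans named list of \code{AssocResults} data.frames (one per
#'   trait), all sharing the same SNP universe and order.
#' @param key_trait name of the key (target) trait; must be in
#'   \code{names(scans)}.
#' @param p_thresh nominal per-trait significance threshold.
#' @param min_other minimum number of significant non-key traits for the
#'   multi-trait retention arm.
#' @param annotation SNP annotation data.frame (\code{snp}, \code{gene},
#'   \code{distance}, \code{tf}).
#' @param max_dist maximum absolute distance to the nearest gene (bp).
#' @return An \linkS4class{AWMatrix}.
#' @export
selectAwmSnps <- function(scans, key_trait = "RFI", p_thresh = 0.05,
                          min_other = 3, annotation, max_dist = 10000) {
  if (!key_trait %in% names(scans)) {
    stop("key trait '", key_trait, "' missing from scans")
  }
  snps <- scans[[1]]$snp
  for (s in scans) {
    if (!identical(s$snp, snps)) stop("all scans must share the same SNP universe")
  }
  P <- vapply(scans, function(s) s$p, numeric(length(snps)))
  Z <- vapply(scans, function(s) s$z, numeric(length(snps)))
  rownames(P) <- rownames(Z) <- snps

  key_sig <- !is.na(P[, key_trait]) & P[, key_trait] < p_thresh
  others <- setdiff(colnames(P), key_trait)
  n_other <- rowSums(P[, others, drop = FALSE] < p_thresh, na.rm = TRUE)

  ai <- annotation[match(snps, annotation$snp), ]
  near <- !is.na(ai$gene) & !is.na(ai$distance) & abs(ai$distance) <= max_dist
  keep <- (key_sig | n_other >= min_other) & near & !apply(is.na(Z), 1, any)

  prov <- data.frame(snp = snps, key_sig = key_sig, n_other_sig = n_other,
                     gene = ai$gene, distance = ai$distance, tf = ai$tf,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(prov) <- NULL
  methods::new("AWMatrix", zscores = Z[keep, , drop = FALSE],
               provenance = prov, keyTrait = key_trait,
               pThreshold = p_thresh, minOther = min_other, maxDist = max_dist)
}

#' Trait relationships implied by the AWM columns
#'
#' Pearson correlations between traits computed across the retained SNPs'
#' allele-substitution z-scores, and an agglomerative hierarchical clustering
#' (complete linkage on distance 1 - r).
#'
#' @param awm an \linkS4class{AWMatrix} (or plain z-score matrix) with at
#'   least 3 rows.
#' @return A list: \code{correlations} (trait x trait matrix),
#'   \code{dendrogram} (an \code{hclust} object), \code{newick} (the tree
#'   serialized as a Newick string).
#' @export
traitStructure <- function(awm) {
  Z <- if (methods::is(awm, "AWMatrix")) zscores(awm) else as.matrix(awm)
  if (nrow(Z) < 3) stop("need at least 3 AWM rows")
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant AWM column(s): ",
            paste(colnames(Z)[sds == 0], collapse = ", "),
            "; correlations set to NA")
  }
  r <- suppressWarnings(stats::cor(Z))
  rq <- r
  rq[is.na(rq)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - rq), method = "complete")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(correlations = r, dendrogram = hc, newick = nwk)
}
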