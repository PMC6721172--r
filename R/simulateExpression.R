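#' Simulate a log2-scale muscle expression matrix with eQTL and DE structure
#'
#' Expression of each gene is built as baseline + batch effect + laboratory
#' effect + cis-eQTL effect (regulatory SNP within 1 Mb of the gene on the
#' same chromosome) + trans-eQTL effects (SNP on another chromosome) + a
#' \code{de_effect} log2 shift added to \code{n_de_genes} genes in
#' low-feed-efficiency (LFE) individuals + Gaussian noise. Per-gene-per-sample
#' detection flags emulate an intensity-dependent detection call. True eQTL
#' and DE assignments are stored in \code{metadata(se)$truth}.
#'
#' @param G \linkS4class{GenotypeData} for the population.
#' @param ann SNP annotation data.frame from \code{\link{simulatePopulation}}.
#' @param groups named character vector mapping expression-profiled
#'   individual ids to \code{"HFE"}, \code{"LFE"} or \code{"none"}.
#' @param config the \code{\link{simConfig}} in force.
#' @param batch optional named factor of batch assignments for the profiled
#'   individuals; sampled if missing.
#' @return A \code{SummarizedExperiment} (genes x individuals) with assays
#'   \code{exprs} (log2 intensities) and \code{detected} (logical), colData
#'   \code{group}, \code{batch}, \code{lab}, and gene coordinates in rowData.
#' @export
simulateExpression <- function(G, ann, groups, config, batch = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(deriveSeed(config$seed, 3L))
  geno <- genotypes(G)
  ids <- names(groups)
  if (is.null(ids) || !all(ids %in% rownames(geno))) {
    missing_ids <- setdiff(ids, rownames(geno))
    stop("groups references unknown individuals: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  if (!all(groups %in% c("HFE", "LFE", "none"))) {
    stop("group labels must be 'HFE', 'LFE' or 'none'")
  }
  n <- length(ids)
  genes <- attr(ann, "genes")
  if (is.null(genes)) {
    genes <- unique(ann[!is.na(ann$gene),
                        c("gene", "gene_chrom", "gene_start", "gene_end", "tf")])
    names(genes) <- c("gene", "chrom", "start", "end", "tf")
  }
  ngene <- nrow(genes)

  dose <- geno[ids, , drop = FALSE]
  dose[is.na(dose)] <- matrix(colMeans(geno, na.rm = TRUE),
                              n, ncol(geno), byrow = TRUE)[is.na(dose)]

  baseline <- stats::rnorm(ngene, 7, 1.5)
  E <- matrix(baseline, ngene, n)
  dimnames(E) <- list(genes$gene, ids)

  if (is.null(batch)) {
    batch <- factor(sample(seq_len(config$batch_count), n, replace = TRUE))
  } else {
    batch <- factor(batch[ids])
  }
  lab <- factor(sample(seq_len(config$lab_count), n, replace = TRUE,
                       prob = seq(config$lab_count, 1)))
  batch_dev <- stats::rnorm(nlevels(batch), 0, 0.3)
  E <- E + matrix(batch_dev[as.integer(batch)], ngene, n, byrow = TRUE)
  E <- E + config$lab_effect * matrix(as.integer(lab) > 1L, ngene, n, byrow = TRUE)

  info <- snpInfo(G)
  # cis-eQTL: regulatory SNP within 1 Mb of the gene start, same chromosome
  cis <- data.frame(gene = character(0), snp = character(0), effect = numeric(0))
  if (config$n_cis_eqtl > 0) {
    cand <- sample.int(ngene)
    for (gi in cand) {
      if (nrow(cis) >= config$n_cis_eqtl) break
      near <- which(info$chrom == genes$chrom[gi] &
                    abs(info$pos - genes$start[gi]) <= 1e6 &
                    info$maf > 0.05)
      if (length(near) == 0L) next
      sk <- near[sample.int(length(near), 1L)]
      eff <- config$cis_effect * sample(c(-1, 1), 1)
      E[gi, ] <- E[gi, ] + eff * (dose[, sk] - mean(dose[, sk]))
      cis <- rbind(cis, data.frame(gene = genes$gene[gi], snp = info$snp[sk],
                                   effect = eff))
    }
  }
  trans <- data.frame(gene = character(0), snp = character(0), effect = numeric(0))
  if (config$n_trans_eqtl > 0) {
    cand <- setdiff(sample.int(ngene), match(cis$gene, genes$gene))
    for (gi in cand[seq_len(min(config$n_trans_eqtl, length(cand)))]) {
      far <- which(info$chrom != genes$chrom[gi] & info$maf > 0.05)
      if (length(far) == 0L) next
      sk <- far[sample.int(length(far), 1L)]
      eff <- config$trans_effect * sample(c(-1, 1), 1)
      E[gi, ] <- E[gi, ] + eff * (dose[, sk] - mean(dose[, sk]))
      trans <- rbind(trans, data.frame(gene = genes$gene[gi], snp = info$snp[sk],
                                       effect = eff))
    }
  }

  nde <- min(config$n_de_genes, ngene)
  de_genes <- if (nde > 0) sort(sample.int(ngene, nde)) else integer(0)
  is_lfe <- groups[ids] == "LFE"
  if (length(de_genes) > 0 && any(is_lfe) && config$de_effect != 0) {
    sgn <- sample(c(-1, 1), length(de_genes), replace = TRUE, prob = c(0.2, 0.8))
    E[de_genes, is_lfe] <- E[de_genes, is_lfe] + config$de_effect * sgn
  }

  E <- E + matrix(stats::rnorm(ngene * n, 0, config$expr_noise_sd), ngene, n)

  # intensity-dependent detection: dim genes fail the call more often
  pdet <- stats::pnorm(baseline, mean = 4.5, sd = 1)
  detected <- matrix(stats::runif(ngene * n) < pdet, ngene, n,
                     dimnames = dimnames(E))

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = E, detected = detected),
    rowData = S4Vectors::DataFrame(genes, row.names = genes$gene),
    colData = S4Vectors::DataFrame(id = ids, group = groups[ids],
                                   batch = batch, lab = lab, row.names = ids))
  S4Vectors::metadata(se)$truth <- list(
    cis = cis, trans = trans,
    de_genes = genes$gene[de_genes], de_effect = config$de_effect,
    baseline = baseline, lab_effect = config$lab_effect)
  se
}
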