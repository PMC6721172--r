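#' Simulate a half-sib population: genotypes, pedigree, gene annotation
#'
#' Founders (sires and per-offspring dams) are drawn with allele frequencies
#' uniform over \code{maf_range}; gametes are formed by copying parental
#' haplotypes in blocks of \code{ld_block_size} SNPs, which induces linkage
#' disequilibrium without a coalescent simulator; offspring genotypes are the
#' Mendelian sum of one sire and one dam gamete. Genes are placed along the
#' chromosomes, a \code{tf_fraction} of them flagged as transcription
#' factors, and every SNP is annotated with its nearest gene and signed
#' distance (0 if inside the gene body).
#'
#' @param config a \code{\link{simConfig}} object.
#' @return A list with elements
#'   \describe{
#'     \item{genotypes}{\linkS4class{GenotypeData} for the offspring, with a
#'       \code{missing_rate} fraction of entries set to \code{NA}.}
#'     \item{pedigree}{data.frame \code{id}, \code{sire}, \code{dam}
#'       (founders have \code{NA} parents, listed before their offspring).}
#'     \item{annotation}{data.frame, one row per SNP: \code{snp},
#'       \code{gene}, \code{distance} (signed bp), \code{tf},
#'       \code{gene_chrom}, \code{gene_start}, \code{gene_end}.}
#'     \item{haplotypes}{founder haplotype bookkeeping (internal).}
#'   }
#' @export
simulatePopulation <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(deriveSeed(config$seed, 1L))
  n <- config$n_individuals
  nfam <- config$n_families
  m <- config$n_snps
  nchr <- config$n_chromosomes

  # SNP map: positions strictly increasing within chromosome
  chr_sizes <- diff(round(seq(0, m, length.out = nchr + 1L)))
  chrom <- rep(as.character(seq_len(nchr)), chr_sizes)
  pos <- unlist(lapply(chr_sizes, function(k) cumsum(sample(2000:8000, k, replace = TRUE))),
                use.names = FALSE)
  snp_id <- sprintf("SNP%05d", seq_len(m))

  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  drawHap <- function() stats::rbinom(m, 1L, p)
  # gamete: per chromosome, copy parental haplotype blocks of ld_block_size
  gamete <- function(h1, h2) {
    out <- integer(m)
    start <- 1L
    for (k in chr_sizes) {
      idx <- start:(start + k - 1L)
      nb <- ceiling(k / config$ld_block_size)
      pick <- rep(sample(c(TRUE, FALSE), nb, replace = TRUE),
                  each = config$ld_block_size)[seq_len(k)]
      out[idx] <- ifelse(pick, h1[idx], h2[idx])
      start <- start + k
    }
    out
  }

  sire_id <- sprintf("SIRE%02d", seq_len(nfam))
  dam_id <- sprintf("DAM%03d", seq_len(n))
  off_id <- sprintf("ID%03d", seq_len(n))
  sire_hap <- lapply(seq_len(nfam), function(i) list(drawHap(), drawHap()))

  # family sizes: as balanced as the division allows
  fam <- sort(rep_len(seq_len(nfam), n))

  geno <- matrix(0L, n, m, dimnames = list(off_id, snp_id))
  dam_geno_sum <- numeric(m)
  for (i in seq_len(n)) {
    dh1 <- drawHap(); dh2 <- drawHap()
    dam_geno_sum <- dam_geno_sum + dh1 + dh2
    s <- sire_hap[[fam[i]]]
    geno[i, ] <- gamete(s[[1]], s[[2]]) + gamete(dh1, dh2)
  }

  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * length(geno))
    if (nmiss > 0) geno[sample(length(geno), nmiss)] <- NA
  }

  freq <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  info <- data.frame(snp = snp_id, chrom = chrom, pos = pos,
                     a1 = "A", a2 = "B", maf = maf,
                     stringsAsFactors = FALSE)

  pedigree <- data.frame(
    id = c(sire_id, dam_id, off_id),
    sire = c(rep(NA_character_, nfam + n), sire_id[fam]),
    dam = c(rep(NA_character_, nfam + n), dam_id),
    stringsAsFactors = FALSE)

  annotation <- .placeGenes(info, config)

  sire_geno <- do.call(rbind, lapply(sire_hap, function(s) s[[1]] + s[[2]]))
  dimnames(sire_geno) <- list(sire_id, snp_id)
  list(genotypes = GenotypeData(geno, info),
       pedigree = pedigree,
       annotation = annotation,
       haplotypes = list(founder_freq = p, family = stats::setNames(fam, off_id),
                         sire_genotypes = sire_geno))
}

# Place genes along chromosomes and annotate each SNP with its nearest gene.
.placeGenes <- function(info, config) {
  ngene <- config$n_genes_expressed
  chrs <- unique(info$chrom)
  per_chr <- diff(round(seq(0, ngene, length.out = length(chrs) + 1L)))
  gene_rows <- list()
  gid <- 0L
  for (ci in seq_along(chrs)) {
    snp_pos <- info$pos[info$chrom == chrs[ci]]
    L <- max(snp_pos) + 20000
    k <- per_chr[ci]
    if (k == 0L) next
    start <- sort(sample.int(L, k))
    len <- sample(5000:30000, k, replace = TRUE)
    gid_k <- gid + seq_len(k)
    gene_rows[[ci]] <- data.frame(
      gene = sprintf("GENE%04d", gid_k), chrom = chrs[ci],
      start = start, end = start + len, stringsAsFactors = FALSE)
    gid <- gid + k
  }
  genes <- do.call(rbind, gene_rows)
  genes$tf <- stats::runif(nrow(genes)) < config$tf_fraction

  ann <- data.frame(snp = info$snp, gene = NA_character_,
                    distance = NA_real_, tf = NA,
                    gene_chrom = NA_character_, gene_start = NA_real_,
                    gene_end = NA_real_, stringsAsFactors = FALSE)
  for (ch in chrs) {
    si <- which(info$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0L) next
    g <- genes[gi, ]
    g <- g[order((g$start + g$end) / 2), ]
    mid <- (g$start + g$end) / 2
    nearest <- findInterval(info$pos[si], mid) # index of last midpoint <= pos
    lo <- pmax(nearest, 1L)
    hi <- pmin(nearest + 1L, nrow(g))
    dlo <- .geneDistance(info$pos[si], g$start[lo], g$end[lo])
    dhi <- .geneDistance(info$pos[si], g$start[hi], g$end[hi])
    pick <- ifelse(abs(dhi) < abs(dlo), hi, lo)
    d <- ifelse(abs(dhi) < abs(dlo), dhi, dlo)
    ann$gene[si] <- g$gene[pick]
    ann$distance[si] <- d
    ann$tf[si] <- g$tf[pick]
    ann$gene_chrom[si] <- ch
    ann$gene_start[si] <- g$start[pick]
    ann$gene_end[si] <- g$end[pick]
  }
  attr(ann, "genes") <- genes
  ann
}

# Signed distance of a SNP to a gene body: 0 inside, negative upstream of the
# start, positive downstream of the end.
.geneDistance <- function(pos, start, end) {
  ifelse(pos < start, pos - start, ifelse(pos > end, pos - end, 0))
}
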