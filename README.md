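# feednet

Systems-genetics analysis of feed efficiency in half-sib livestock
populations: SNP co-association networks, muscle transcriptome integration,
and SNP-panel genomic prediction.

## The problem

Feed efficiency drives the economics and environmental footprint of pig
production, but its standard measure — **residual feed intake (RFI)**, the
deviation of an animal's feed intake from the intake predicted for its
maintenance, growth and backfat — is expensive to record. A practical
alternative is to find a compact panel of SNPs whose effects capture the
genetic basis of RFI and predict it early in life. Because feed efficiency
is entangled with growth, carcass and fat-deposition traits, single-trait
GWAS misses much of the signal; `feednet` implements the multi-trait,
network-based route:

1. **Phenotype derivation.** RFI is the residual of the least-squares model

   ADFI_ij = b_j + α·A_i + γ_(j)·MW_i + δ1_(j)·ADG_ij + δ2_(j)·BF_i + RFI_ij

   with batch intercepts b_j, a global age-at-midpoint covariate A_i, and
   metabolic weight (MW = body weight^0.75), growth and backfat partial
   regressions nested within batch. FCR = ADFI/ADG.
2. **Mixed-model GWAS** for nine traits under
   y_ij = b_j + β·age_i + u_i + s_ik·a_k + e_ij, with a genomic
   relationship matrix G behind the polygenic term u ~ N(0, G σ²u)
   (spectral-decomposition REML, two-step scan).
3. **Association weight matrix (AWM).** SNPs nominally associated
   (p < 0.05) with the key trait RFI, or with ≥ 3 of the other eight
   traits, and mapping within 10 kb of a gene, form a SNP × trait matrix of
   signed z-scores.
4. **PCIT network inference.** Edges between SNPs are significant
   co-associations surviving the partial-correlation-and-information-theory
   test: for every trio, first-order partials r_xy.z and a tolerance
   ε = mean of the three partial/marginal ratios decide whether an edge is
   explained away by a third SNP.
5. **Regulator search.** Among transcription-factor nodes, every trio and
   quartet is scored exhaustively for network coverage with minimum
   redundancy ("information lossless" search).
6. **Transcriptome integration.** Muscle expression of extreme-RFI groups:
   trend-moderated differential expression (|FC| > 1.5, q < 0.05), sparse
   PLS-DA (cross-validated balanced error rate), regularized CCA against
   RFI/FCR/ADG/ADFI, candidate consolidation, and an expression GWAS
   (eGWAS) labelling significant eSNPs cis (≤ 1 Mb) or trans.
7. **Genomic prediction.** Gibbs-sampled variance components and
   cross-validated GBLUP accuracy for pedigree (A), all-SNP (K) and
   selected-panel relationship matrices.

A synthetic-population generator (half-sib families, LD by haplotype-block
copying, pleiotropic QTL, batch/age/laboratory effects, cis/trans eQTL)
makes every stage testable end-to-end without external data.

## Worked example

```r
library(feednet)

cfg <- pipelineConfig(
  sim = simConfig(n_individuals = 350, n_families = 5, n_snps = 3000,
                  n_genes_expressed = 1000, seed = 1),
  n_expression = 104, egwas_max_genes = 40)
res <- runPipeline(cfg, out_dir = "run1")

mean(res$phenotypes$RFI)        # 2.3e-18  (RFI is a residual: mean 0)
mean(res$phenotypes$FCR)        # 3.18     (kg feed per kg gain)
nrow(zscores(res$awm))          # 136 retained AWM SNPs
nrow(edgeTable(res$network))    # 6430 significant PCIT edges
res$prediction$summary
#>      panel    h2  h2_sd accuracy accuracy_sd
#> 1 pedigree 0.548  0.148    0.239       0.147
#> 2 all_snps 0.452  0.104    0.250       0.175
#> 3 awm_snps 0.617  0.072    0.757       0.085
```

The prediction table is the analysis's central readout: the heritability
captured by the AWM-selected panel (0.62) exceeds the all-SNP estimate
(0.45), and its cross-validated accuracy (0.76) is far above both the
all-SNP panel (0.25) and pedigree BLUP (0.24) — the selected-panel
advantage the pipeline is designed to expose (with the optimistic bias of
full-data SNP selection discussed in the methods vignette). Stage outputs
(per-trait GWAS TSVs, the AWM, the edge list, the trait dendrogram in
Newick, DE and candidate tables, a JSON manifest) are written under
`run1/`.

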