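#' Pipeline configuration
#'
#' Collects every stage threshold with the study's settings as defaults
#' (QC: MAF < 0.05, missingness > 0.10, HWE p < 0.001; AWM: nominal p <
#' 0.05 on the key trait or >= 3 other traits, gene distance <= 10 kb; DE:
#' |FC| > 1.5 and q < 0.05; eGWAS: q <= 0.05, cis window 1 Mb; prediction:
#' 20 replicates of ~88/12 cross-validation). The Gibbs chain defaults to a
#' desk-scale 20,000/2,000/10 run; the study-scale 100,000/10,000/10 chain
#' is a configuration choice. Unknown keys are rejected.
#'
#' @param sim a \code{\link{simConfig}} for the simulate stage.
#' @param ... named overrides of the defaults listed above.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = simConfig(), ...) {
  cfg <- list(
    sim = sim,
    seed = sim$seed,
    stages = c("simulate", "qc", "traits", "gwas", "awm", "pcit",
               "regulators", "expression", "egwas", "prediction"),
    qc_maf_min = 0.05, qc_miss_max = 0.10, qc_hwe_p = 0.001,
    awm_key_trait = "RFI", awm_p_thresh = 0.05, awm_min_other = 3,
    awm_max_dist = 10000,
    pcit_aggregation = "any",
    regulator_k = 3, regulator_top_n = 10, regulator_max_tf = 25,
    n_expression = 104, n_extreme = 10,
    de_fc_thresh = 1.5, de_q_thresh = 0.05,
    splsda_ncomp = 2, splsda_keepX_grid = c(10, 25, 50), splsda_folds = 5,
    splsda_reps = 5,
    rcca_lambda1 = NULL, rcca_lambda2 = NULL,
    egwas_q_thresh = 0.05, egwas_cis_window = 1e6, egwas_max_genes = 5,
    gibbs_iters = 20000, gibbs_burnin = 2000, gibbs_thin = 10,
    cv_n_rep = 20, cv_train_frac = 0.88)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override \code{\link{pipelineConfig}} defaults; keys under
#' \code{sim:} override \code{\link{simConfig}} defaults.
#'
#' @param file YAML path.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(file) {
  raw <- yaml::read_yaml(file)
  simargs <- raw$sim %||% list()
  raw$sim <- NULL
  do.call(pipelineConfig, c(list(sim = do.call(simConfig, simargs)), raw))
}

#' Run the full integrative pipeline on a simulated population
#'
#' Executes simulate -> QC -> trait derivation -> nine mixed-model GWAS ->
#' AWM -> PCIT network -> TF regulator search -> expression analyses (DE,
#' sPLS-DA, rCCA, integration) -> eGWAS -> variance components and
#' cross-validated prediction for the pedigree, all-SNP and AWM-panel
#' relationship matrices. Stage outputs are written as plain-text files under
#' \code{out_dir} together with a JSON manifest recording seeds, stage
#' status and row counts. A stage failure halts the run and the manifest
#' marks the stages completed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param out_dir output directory (created if needed); \code{NULL} skips
#'   file output.
#' @return (invisibly) a list with all stage results and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(seed = config$seed, stages = list())
  res <- list(config = config)
  t0 <- Sys.time()
  note <- function(stage, status, n = NA) {
    manifest$stages[[stage]] <<- list(status = status, rows = n)
    if (!is.null(out_dir)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, na = "null")
    }
  }
  runStage <- function(stage, expr) {
    if (!stage %in% config$stages) { note(stage, "skipped"); return(NULL) }
    out <- tryCatch(expr, error = function(e) {
      note(stage, paste("failed:", conditionMessage(e)))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    out
  }

  # --- simulate -------------------------------------------------------
  pop <- runStage("simulate", {
    pop <- simulatePopulation(config$sim)
    phen <- simulatePhenotypes(pop$genotypes, pop$pedigree, config$sim)
    note("simulate", "ok", nrow(phen))
    c(pop, list(phenotypes = phen))
  })
  res$population <- pop

  # --- qc -------------------------------------------------------------
  Gq <- runStage("qc", {
    Gq <- qcGenotypes(pop$genotypes, maf_min = config$qc_maf_min,
                      miss_max = config$qc_miss_max, hwe_p = config$qc_hwe_p)
    note("qc", "ok", ncol(genotypes(Gq)))
    Gq
  })
  res$genotypes <- Gq

  # --- traits ---------------------------------------------------------
  der <- runStage("traits", {
    der <- deriveTraits(pop$phenotypes)
    note("traits", "ok", nrow(der$table))
    der
  })
  phen <- der$table
  res$phenotypes <- phen
  res$rfi_fit <- der$fit

  # --- gwas -----------------------------------------------------------
  traits9 <- c("RFI", "FCR", "ADFI", "ADG", "CW", "KO", "BF", "LEAN", "IMF")
  K_all <- computeGRM(Gq)
  scans <- runStage("gwas", {
    scans <- lapply(stats::setNames(traits9, traits9), function(tr) {
      gwasScan(phen, tr, Gq, K_all)
    })
    if (!is.null(out_dir)) {
      for (tr in traits9) {
        writeAssocResults(scans[[tr]],
                          file.path(out_dir, paste0("gwas_", tr, ".tsv")))
      }
    }
    note("gwas", "ok", length(traits9))
    scans
  })
  res$grm <- K_all
  res$scans <- scans

  # --- awm ------------------------------------------------------------
  ann_q <- pop$annotation[match(snpInfo(Gq)$snp, pop$annotation$snp), ]
  awm <- runStage("awm", {
    awm <- selectAwmSnps(scans, key_trait = config$awm_key_trait,
                         p_thresh = config$awm_p_thresh,
                         min_other = config$awm_min_other,
                         annotation = ann_q, max_dist = config$awm_max_dist)
    if (!is.null(out_dir)) {
      utils::write.table(cbind(provenance(awm), zscores(awm)),
                         file.path(out_dir, "awm.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    note("awm", "ok", nrow(zscores(awm)))
    awm
  })
  res$awm <- awm
  res$trait_structure <- if (!is.null(awm) && nrow(zscores(awm)) >= 3) {
    ts <- traitStructure(awm)
    if (!is.null(out_dir)) writeLines(ts$newick, file.path(out_dir, "trait_dendrogram.nwk"))
    ts
  }

  # --- pcit -----------------------------------------------------------
  net <- runStage("pcit", {
    net <- suppressWarnings(pcit(awm, aggregation = config$pcit_aggregation))
    if (!is.null(out_dir)) writeEdgeList(net, file.path(out_dir, "network_edges.tsv"))
    note("pcit", "ok", nrow(edgeTable(net)))
    net
  })
  res$network <- net
  res$hubs <- if (!is.null(net)) hubRanking(net, provenance(awm))

  # --- regulators -----------------------------------------------------
  res$regulators <- runStage("regulators", {
    hubs <- res$hubs
    tfs <- hubs$node[!is.na(hubs$tf) & hubs$tf & hubs$degree > 0]
    tfs <- utils::head(tfs, config$regulator_max_tf) # ranked by degree
    out <- if (length(tfs) >= config$regulator_k) {
      losslessSearch(net, tfs, k = config$regulator_k,
                     top_n = config$regulator_top_n)
    } else NULL
    if (!is.null(out) && !is.null(out_dir)) {
      utils::write.table(out, file.path(out_dir, "regulators.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    note("regulators", "ok", if (is.null(out)) 0L else nrow(out))
    out
  })

  # --- expression -----------------------------------------------------
  expr_res <- runStage("expression", {
    set.seed(deriveSeed(config$seed, 11L))
    n_expr <- min(config$n_expression, nrow(phen))
    expr_ids <- sort(sample(phen$id, n_expr))
    rfi <- phen$RFI[match(expr_ids, phen$id)]
    ne <- min(config$n_extreme, floor(n_expr / 2))
    groups <- rep("none", n_expr)
    groups[order(rfi)[seq_len(ne)]] <- "HFE"          # lowest RFI: efficient
    groups[order(-rfi)[seq_len(ne)]] <- "LFE"
    names(groups) <- expr_ids
    se <- simulateExpression(pop$genotypes, pop$annotation, groups, config$sim,
                             batch = stats::setNames(phen$batch, phen$id))
    extreme <- se[, se$group != "none"]
    de <- deTrendTest(extreme, fc_thresh = config$de_fc_thresh,
                      q_thresh = config$de_q_thresh)
    spls <- splsdaFit(extreme, droplevels(factor(extreme$group)),
                      ncomp = config$splsda_ncomp,
                      keepX_grid = config$splsda_keepX_grid,
                      folds = config$splsda_folds, reps = config$splsda_reps,
                      seed = config$seed)
    Xtraits <- as.matrix(phen[match(expr_ids, phen$id),
                              c("RFI", "FCR", "ADG", "ADFI")])
    rc <- rccaFit(se, Xtraits, lambda1 = config$rcca_lambda1,
                  lambda2 = config$rcca_lambda2)
    integ <- integrateCandidates(de, spls, rc)
    if (!is.null(out_dir)) {
      utils::write.table(de, file.path(out_dir, "de_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(integ$table, file.path(out_dir, "candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    note("expression", "ok", sum(de$de))
    list(se = se, de = de, splsda = spls, rcca = rc, integration = integ)
  })
  res$expression <- expr_res

  # --- egwas ----------------------------------------------------------
  res$egwas <- runStage("egwas", {
    se <- expr_res$se
    cand <- expr_res$integration$candidates
    genes <- utils::head(intersect(cand, rownames(se)), config$egwas_max_genes)
    if (length(genes) < config$egwas_max_genes) {
      # supplement with the most variable expressed genes, the standard
      # screen for expression traits likely to carry regulatory variants
      v <- apply(SummarizedExperiment::assay(se, "exprs"), 1, stats::var)
      extra <- names(sort(v, decreasing = TRUE))
      genes <- utils::head(unique(c(genes, extra)), config$egwas_max_genes)
    }
    eg <- egwasScan(se, genes, Gq, K_all,
                    cis_window = config$egwas_cis_window)
    if (!is.null(out_dir)) {
      writeAssocResults(eg, file.path(out_dir, "egwas.tsv"))
    }
    note("egwas", "ok", sum(eg$q <= config$egwas_q_thresh, na.rm = TRUE))
    eg
  })

  # --- prediction -----------------------------------------------------
  res$prediction <- runStage("prediction", {
    offspring <- phen$id
    A_full <- pedigreeA(pop$pedigree)
    A <- A_full[offspring, offspring]
    awm_snps <- provenance(awm)$snp
    panels <- list(pedigree = A, all_snps = K_all)
    if (length(awm_snps) >= 10) {
      panels$awm_snps <- computeGRM(Gq, subset = awm_snps)
    }
    X <- buildDesign(phen, c("batch", "age_mid"))
    y <- phen$RFI
    out <- lapply(stats::setNames(names(panels), names(panels)), function(nm) {
      vc <- gibbsVariance(y, X, panels[[nm]], iters = config$gibbs_iters,
                          burnin = config$gibbs_burnin,
                          thin = config$gibbs_thin,
                          seed = deriveSeed(config$seed, 13L))
      h2 <- vc$summary[vc$summary$parameter == "h2", ]
      cv <- crossValidate(y, X, panels[[nm]],
                          sigma_u2 = vc$summary$mean[1],
                          sigma_e2 = vc$summary$mean[2],
                          batch = phen$batch, n_rep = config$cv_n_rep,
                          train_frac = config$cv_train_frac,
                          seed = deriveSeed(config$seed, 17L))
      list(vc = vc, cv = cv, h2_mean = h2$mean, h2_sd = h2$sd,
           accuracy = cv$mean, accuracy_sd = cv$sd)
    })
    summ <- data.frame(
      panel = names(out),
      h2 = vapply(out, `[[`, numeric(1), "h2_mean"),
      h2_sd = vapply(out, `[[`, numeric(1), "h2_sd"),
      accuracy = vapply(out, `[[`, numeric(1), "accuracy"),
      accuracy_sd = vapply(out, `[[`, numeric(1), "accuracy_sd"),
      row.names = NULL)
    if (!is.null(out_dir)) {
      utils::write.table(summ, file.path(out_dir, "prediction_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    note("prediction", "ok", nrow(summ))
    c(out, list(summary = summ))
  })

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  note("pipeline", "ok")
  res$manifest <- manifest
  invisible(res)
}
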