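#' Simulate correlated production phenotypes on a simulated population
#'
#' Each primary trait is built as batch effect + age-covariate term + QTL
#' effects + polygenic background + residual, with the genetic part scaled so
#' the narrow-sense heritability equals the configured value. Pleiotropy is
#' induced by drawing a fraction of each grouped trait's QTL from a shared
#' pool with identical effects (production group: ADFI, ADG, BW, CW; fat
#' group: BF, IMF), which yields the correlated-trait structure the
#' downstream multi-trait analyses assume. The feed-efficiency measures RFI
#' and FCR are deliberately not simulated: they are derived downstream by
#' \code{\link{deriveTraits}} from ADFI, ADG, BF and body weight.
#'
#' True per-SNP effects and true breeding values (on the final trait scale)
#' are stored in the \code{"truth"} attribute for recovery tests, retrievable
#' with \code{\link{simTruth}}.
#'
#' @param G \linkS4class{GenotypeData} for the offspring.
#' @param ped pedigree data.frame from \code{\link{simulatePopulation}}.
#' @param config the \code{\link{simConfig}} used to simulate the population.
#' @return data.frame with one row per offspring: \code{id}, \code{sire},
#'   \code{dam}, \code{batch} (factor), \code{age_mid} (days, uniform over
#'   121-148), \code{slaughter_age}, \code{ADFI}, \code{ADG}, \code{BW},
#'   \code{BF}, \code{CW}, \code{KO}, \code{LEAN}, \code{IMF}.
#' @export
simulatePhenotypes <- function(G, ped, config) {
  stopifnot(inherits(config, "SimConfig"))
  checkProportion(config$h2_per_trait, "h2_per_trait", open0 = TRUE, open1 = TRUE)
  set.seed(deriveSeed(config$seed, 2L))
  geno <- genotypes(G)
  n <- nrow(geno)
  m <- ncol(geno)

  # centered, mean-imputed dosages for genetic values
  Z <- apply(geno, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x - mean(x)
  })

  traits <- c("ADFI", "ADG", "BW", "BF", "CW", "KO", "LEAN", "IMF")
  scales <- rbind(ADFI = c(2.81, 0.37), ADG = c(0.89, 0.11), BW = c(80, 8),
                  BF = c(24.0, 4.9), CW = c(94.8, 10.6), KO = c(74.8, 2.4),
                  LEAN = c(40.8, 4.5), IMF = c(5.23, 2.06))
  groups <- list(production = c("ADFI", "ADG", "BW", "CW"),
                 fat = c("BF", "IMF"))
  h2 <- config$h2_per_trait[traits]
  nq <- min(config$qtl_per_trait, m)
  n_shared <- round(config$pleiotropy_fraction * nq)

  # shared QTL pools per group (same SNPs, same raw effects: correlation 1)
  pool <- lapply(groups, function(g) {
    idx <- if (n_shared > 0) sample.int(m, n_shared) else integer(0)
    list(idx = idx, eff = stats::rnorm(length(idx)))
  })

  pf <- config$polygenic_fraction
  effects <- matrix(0, m, length(traits),
                    dimnames = list(colnames(geno), traits))
  tbv <- matrix(0, n, length(traits), dimnames = list(rownames(geno), traits))
  qtl_list <- vector("list", length(traits))
  names(qtl_list) <- traits

  batch <- factor(sample(seq_len(config$batch_count), n, replace = TRUE))
  batch_dev <- stats::rnorm(nlevels(batch), 0, config$batch_sd)
  age_mid <- round(stats::runif(n, 121, 148))
  slaughter_age <- round(stats::runif(n, 182, 198))

  out <- data.frame(id = rownames(geno),
                    sire = ped$sire[match(rownames(geno), ped$id)],
                    dam = ped$dam[match(rownames(geno), ped$id)],
                    batch = batch, age_mid = age_mid,
                    slaughter_age = slaughter_age,
                    stringsAsFactors = FALSE)

  for (t in traits) {
    grp <- names(groups)[vapply(groups, function(g) t %in% g, logical(1))]
    if (length(grp) == 1 && n_shared > 0) {
      sh <- pool[[grp]]
      own_n <- nq - length(sh$idx)
      own_idx <- if (own_n > 0) sample(setdiff(seq_len(m), sh$idx), own_n) else integer(0)
      qidx <- c(sh$idx, own_idx)
      qeff <- c(sh$eff, stats::rnorm(length(own_idx)))
    } else {
      qidx <- if (nq > 0) sample.int(m, nq) else integer(0)
      qeff <- stats::rnorm(length(qidx))
    }

    beta <- numeric(m)
    if (length(qidx) > 0) {
      qg <- drop(Z[, qidx, drop = FALSE] %*% qeff)
      sq <- stats::sd(qg)
      if (sq > 0) beta[qidx] <- sqrt(1 - pf) * qeff / sq
    }
    if (pf > 0) {
      others <- setdiff(seq_len(m), qidx)
      ueff <- stats::rnorm(length(others), 0, 1 / sqrt(length(others)))
      pg <- drop(Z[, others, drop = FALSE] %*% ueff)
      sp <- stats::sd(pg)
      if (sp > 0) beta[others] <- sqrt(pf) * ueff / sp
    }
    g <- drop(Z %*% beta)
    sg <- stats::sd(g)
    if (sg > 0) {
      beta <- beta * sqrt(h2[t]) / sg
      g <- g * sqrt(h2[t]) / sg
    }
    e <- stats::rnorm(n, 0, sqrt(1 - h2[t]))
    y_unit <- g + e + batch_dev[as.integer(batch)] +
      config$age_beta * (age_mid - mean(age_mid))
    out[[t]] <- scales[t, 1] + scales[t, 2] * y_unit
    effects[, t] <- beta * scales[t, 2]
    tbv[, t] <- g * scales[t, 2]
    qtl_list[[t]] <- data.frame(snp = colnames(geno)[qidx], effect = effects[qidx, t],
                                stringsAsFactors = FALSE)
  }

  attr(out, "truth") <- list(tbv = tbv, effects = effects, qtl = qtl_list,
                             h2 = h2, batch_dev = batch_dev,
                             scales = scales, age_beta = config$age_beta)
  out
}

#' Retrieve the stored simulation truth
#'
#' @param x an object produced by \code{\link{simulatePhenotypes}} or
#'   \code{\link{simulateExpression}}.
#' @return The generator's list of true effects/assignments, or \code{NULL}.
#' @export
simTruth <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    S4Vectors::metadata(x)$truth
  } else {
    attr(x, "truth")
  }
}
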