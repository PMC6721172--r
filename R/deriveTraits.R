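#' Derive the feed-efficiency phenotypes: metabolic weight, FCR and RFI
#'
#' Metabolic weight is computed as body weight to the power 0.75; the feed
#' conversion ratio as ADFI/ADG; and residual feed intake (RFI) as the
#' residual of the least-squares regression of ADFI on batch intercepts, a
#' global age-at-midpoint covariate, and metabolic weight, ADG and backfat
#' covariates each nested within batch. Being a least-squares residual, RFI
#' has mean zero and is orthogonal to every design column, so it is
#' uncorrelated with growth and backfat by construction.
#'
#' @param table phenotype data.frame with columns \code{ADFI}, \code{ADG},
#'   \code{BF}, \code{BW} (body weight, kg), \code{batch} (factor) and
#'   \code{age_mid} (days).
#' @return A list with elements
#'   \describe{
#'     \item{table}{the input with added columns \code{MW}, \code{FCR},
#'       \code{RFI}.}
#'     \item{fit}{an \code{RfiFit} list: \code{coefficients} (batch
#'       intercepts, age slope \code{alpha}, and the batch-nested partial
#'       regressions on MW, ADG and BF), \code{residuals}, \code{design}.}
#'   }
#' @export
deriveTraits <- function(table) {
  need <- c("ADFI", "ADG", "BF", "BW", "batch", "age_mid")
  if (!all(need %in% names(table))) {
    stop("phenotype table must contain columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  }
  if (any(!is.finite(table$ADG)) || any(table$ADG <= 0)) {
    stop("FCR undefined: ADG must be strictly positive for every individual")
  }
  batch <- droplevels(as.factor(table$batch))
  tab <- table
  tab$MW <- table$BW^0.75
  tab$FCR <- table$ADFI / table$ADG

  nb <- table(batch)
  if (any(nb < 2)) {
    stop("each batch needs at least 2 individuals; too small: ",
         paste(names(nb)[nb < 2], collapse = ", "))
  }

  X <- stats::model.matrix(~ 0 + batch + age_mid + batch:MW + batch:ADG + batch:BF,
                           data = transform(tab, batch = batch))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient RFI design (rank ", qrX$rank, " < ", ncol(X),
         "): some batch has fewer individuals than nested coefficients")
  }
  fit <- stats::lm.fit(X, tab$ADFI)
  tab$RFI <- unname(fit$residuals)

  cf <- fit$coefficients
  lev <- levels(batch)
  rfi_fit <- list(
    coefficients = list(
      batch_intercepts = cf[paste0("batch", lev)],
      alpha = unname(cf["age_mid"]),
      gamma_mw = cf[paste0("batch", lev, ":MW")],
      delta_adg = cf[paste0("batch", lev, ":ADG")],
      delta_bf = cf[paste0("batch", lev, ":BF")]),
    residuals = tab$RFI,
    fitted = unname(fit$fitted.values),
    design = X)
  class(rfi_fit) <- "RfiFit"
  list(table = tab, fit = rfi_fit)
}

#' @export
print.RfiFit <- function(x, ...) {
  cat("RFI regression fit:", length(x$residuals), "individuals,",
      ncol(x$design), "design columns\n")
  cat(sprintf("  residual mean %.3g, SD %.3f\n",
              mean(x$residuals), stats::sd(x$residuals)))
  cat(sprintf("  age slope alpha = %.4f kg/day per day\n", x$coefficients$alpha))
  invisible(x)
}
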