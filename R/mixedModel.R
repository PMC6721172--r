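#' Fit the null (no-SNP) animal model by spectral-decomposition REML
#'
#' The model is y = Xb + u + e with u ~ N(0, K sigma_u^2) and
#' e ~ N(0, I sigma_e^2). After rotation by the eigenvectors of K the
#' covariance is diagonal and the restricted likelihood is profiled down to a
#' one-dimensional optimization in the variance ratio
#' gamma = sigma_u^2 / sigma_e^2, solved numerically on a log grid.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (including intercept).
#' @param K relationship matrix (e.g. from \code{\link{computeGRM}}).
#' @param ridge ridge added to K's diagonal if it is not positive
#'   semi-definite; the fit is flagged when this happens.
#' @return A list of class \code{VarianceComponents}: \code{sigma_u2},
#'   \code{sigma_e2}, \code{h2}, \code{gamma}, \code{loglik},
#'   \code{boundary} and \code{non_identifiable} flags, plus the eigen
#'   rotation (\code{U}, \code{d}) and rotated data for reuse by
#'   \code{\link{assocScan}}.
#' @export
fitNullModel <- function(y, X, K, ridge = 1e-6) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2) stop("need at least ncol(X) + 2 observations")
  stopifnot(nrow(X) == n, nrow(K) == n)

  eg <- eigen(K, symmetric = TRUE)
  ridged <- FALSE
  if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
    eg <- eigen(K + ridge * diag(n), symmetric = TRUE)
    if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
      stop("K is not positive semi-definite even after ridging")
    }
    ridged <- TRUE
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  non_ident <- stats::sd(d) < 1e-10 * max(mean(d), 1e-300)
  if (non_ident) {
    warning("K is (numerically) proportional to the identity: ",
            "sigma_u2 and sigma_e2 are not separately identifiable")
  }

  remlNegLL <- function(log10g) {
    g <- 10^log10g
    w <- g * d + 1
    sw <- sqrt(w)
    Xw <- Xt / sw
    yw <- yt / sw
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    XtX <- crossprod(Xw)
    0.5 * ((n - p) * log(rss / (n - p)) + sum(log(w)) +
             determinant(XtX, logarithm = TRUE)$modulus[1])
  }

  lo <- -6; hi <- 6
  opt <- stats::optimize(remlNegLL, c(lo, hi), tol = 1e-8)
  gamma <- 10^opt$minimum
  boundary <- opt$minimum < lo + 0.05 || opt$minimum > hi - 0.05
  if (boundary && opt$minimum < lo + 0.05) gamma <- 0

  w <- gamma * d + 1
  fit <- stats::lm.fit(Xt / sqrt(w), yt / sqrt(w))
  sigma_e2 <- sum(fit$residuals^2) / (n - p)
  sigma_u2 <- gamma * sigma_e2
  out <- list(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
              h2 = sigma_u2 / (sigma_u2 + sigma_e2), gamma = gamma,
              loglik = -opt$objective, boundary = boundary,
              non_identifiable = non_ident, ridged = ridged,
              U = U, d = d, yt = yt, Xt = Xt, n = n, p = p)
  class(out) <- "VarianceComponents"
  out
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat("REML variance components (spectral):\n")
  cat(sprintf("  sigma_u2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$sigma_u2, x$sigma_e2, x$h2))
  if (x$boundary) cat("  note: variance ratio at optimizer boundary\n")
  if (x$non_identifiable) cat("  note: components not separately identifiable\n")
  invisible(x)
}

#' Single-marker mixed-model association scan
#'
#' Two-step (EMMAX-style) scan: the covariance structure
#' V = K sigma_u^2 + I sigma_e^2 is held fixed at the null-model REML fit,
#' and each SNP's allele-substitution effect is the generalized-least-squares
#' estimate under that structure, with the residual scale re-estimated per
#' marker. The candidate SNP remains in the relationship matrix (no
#' leave-one-chromosome-out). With sigma_u2 = 0 the scan reduces exactly to
#' per-SNP ordinary least squares. Wald p-values use the normal reference:
#' p = 2(1 - Phi(|z|)).
#'
#' @param y numeric response (same individuals/order as the null fit).
#' @param X fixed-effect design matrix.
#' @param G \linkS4class{GenotypeData} (or dosage matrix) to scan.
#' @param vc \code{VarianceComponents} from \code{\link{fitNullModel}} on the
#'   same y, X and relationship matrix.
#' @return data.frame of class \code{AssocResults}: \code{snp}, \code{chrom},
#'   \code{pos}, \code{allele}, \code{maf}, \code{effect}, \code{se},
#'   \code{z}, \code{p}, \code{reason} (\code{NA} rows are explained).
#' @export
assocScan <- function(y, X, G, vc) {
  stopifnot(inherits(vc, "VarianceComponents"))
  geno <- if (methods::is(G, "GenotypeData")) genotypes(G) else as.matrix(G)
  info <- if (methods::is(G, "GenotypeData")) snpInfo(G) else NULL
  n <- vc$n
  stopifnot(nrow(geno) == n)
  if (anyNA(geno)) stop("genotypes contain missing values; impute first")

  w <- vc$gamma * vc$d + 1
  sw <- sqrt(w)
  ys <- vc$yt / sw
  Xs <- vc$Xt / sw
  Ss <- crossprod(vc$U, geno) / sw

  qrX <- qr(Xs)
  yr <- qr.resid(qrX, ys)
  Sr <- qr.resid(qrX, Ss)
  gg <- colSums(Sr^2)
  gy <- drop(crossprod(Sr, yr))
  dfr <- n - vc$p - 1

  mono <- gg < 1e-10
  a <- ifelse(mono, NA_real_, gy / gg)
  rss <- pmax(sum(yr^2) - a^2 * gg, 0)
  s2 <- rss / dfr
  se <- ifelse(mono, NA_real_, sqrt(s2 / gg))
  z <- a / se
  pval <- 2 * stats::pnorm(-abs(z))

  out <- data.frame(
    snp = colnames(geno) %||% sprintf("SNP%05d", seq_len(ncol(geno))),
    chrom = if (!is.null(info)) info$chrom else NA_character_,
    pos = if (!is.null(info)) info$pos else NA_real_,
    allele = if (!is.null(info)) info$a1 else NA_character_,
    maf = if (!is.null(info)) info$maf else pmin(colMeans(geno) / 2, 1 - colMeans(geno) / 2),
    effect = a, se = se, z = z, p = pval,
    reason = ifelse(mono, "monomorphic", NA_character_),
    stringsAsFactors = FALSE)
  class(out) <- c("AssocResults", "data.frame")
  out
}

#' Convenience GWAS driver for one phenotype
#'
#' Builds the fixed-effect design (batch + age covariate, per the animal
#' model), fits the null model and runs the scan.
#'
#' @param pheno phenotype data.frame (needs \code{batch}, \code{age_mid} or
#'   the columns named in \code{covariates}).
#' @param trait name of the response column.
#' @param G \linkS4class{GenotypeData} post QC.
#' @param K relationship matrix.
#' @param covariates model terms for the fixed design.
#' @return An \code{AssocResults} data.frame with the fitted
#'   \code{VarianceComponents} attached as attribute \code{"vc"}.
#' @export
gwasScan <- function(pheno, trait, G, K, covariates = c("batch", "age_mid")) {
  if (!trait %in% names(pheno)) stop("trait '", trait, "' not in phenotype table")
  X <- buildDesign(pheno, covariates)
  vc <- fitNullModel(pheno[[trait]], X, K)
  res <- assocScan(pheno[[trait]], X, G, vc)
  attr(res, "vc") <- vc
  res
}
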