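#' Regularized canonical correlation analysis of traits and expression
#'
#' Canonical directions are obtained from the eigen-decomposition of
#' \deqn{(S_{XX} + \lambda_1 I)^{-1} S_{XY} (S_{YY} + \lambda_2 I)^{-1} S_{YX}}
#' on standardized data (so the S's are correlation matrices); canonical
#' correlations are the empirical correlations of the paired canonical
#' variates, ordered nonincreasing. In shrinkage mode the regularization
#' parameters are the analytic shrinkage intensities of the sample
#' correlation matrices (sum of estimated variances of the off-diagonal
#' correlations divided by their sum of squares), computed per side.
#'
#' Candidate genes are selected from the distribution of per-gene maximum
#' absolute trait correlations: a gene is kept when its maximum |correlation|
#' with the traits exceeds median + 2 SD of that distribution, computed by
#' default over the genes weighted on the first canonical component (those
#' whose |CC1 loading| is above the median loading magnitude), or over all
#' genes (\code{select_pop = "all"}).
#'
#' @param Y samples x genes expression matrix (or
#'   \code{SummarizedExperiment}, transposed internally).
#' @param X samples x traits matrix (e.g. RFI, FCR, ADG, ADFI).
#' @param lambda1,lambda2 ridge penalties for the trait and expression side;
#'   \code{NULL} means estimate by the shrinkage formula.
#' @param ncomp number of canonical components (at most \code{ncol(X)}).
#' @param select_pop population over which the median + 2 SD selection
#'   threshold is computed.
#' @return list of class \code{RccaResult}: \code{cancor} (canonical
#'   correlations), \code{xcoef}, \code{ycoef} (loadings), \code{variates},
#'   \code{lambda1}, \code{lambda2}, \code{trait_cor} (genes x traits
#'   correlations), \code{threshold}, \code{selected} (gene ids).
#' @export
rccaFit <- function(Y, X, lambda1 = NULL, lambda2 = NULL, ncomp = NULL,
                    select_pop = c("cc1", "all")) {
  select_pop <- match.arg(select_pop)
  if (methods::is(Y, "SummarizedExperiment")) {
    Y <- t(SummarizedExperiment::assay(Y, "exprs"))
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n != nrow(Y)) stop("X and Y must cover the same individuals")
  if (n < 3) stop("need at least 3 individuals")
  if (!is.null(lambda1) && lambda1 < 0 || !is.null(lambda2) && lambda2 < 0) {
    stop("regularization parameters must be non-negative")
  }
  Xs <- scale(X); Ys <- scale(Y)
  if (anyNA(Xs) || anyNA(Ys)) stop("constant columns cannot be standardized")
  q <- ncol(X); p <- ncol(Y)
  ncomp <- min(ncomp %||% q, q, p)

  if (is.null(lambda1)) lambda1 <- shrinkageIntensity(Xs)
  if (is.null(lambda2)) lambda2 <- shrinkageIntensity(Ys)

  Sxx <- crossprod(Xs) / (n - 1) + lambda1 * diag(q)
  Syy <- crossprod(Ys) / (n - 1) + lambda2 * diag(p)
  Sxy <- crossprod(Xs, Ys) / (n - 1)
  SyyInvSyx <- solve(Syy, t(Sxy))       # p x q
  M <- solve(Sxx, Sxy %*% SyyInvSyx)    # q x q
  eg <- eigen(M)
  ord <- order(Re(eg$values), decreasing = TRUE)[seq_len(ncomp)]
  A <- Re(eg$vectors[, ord, drop = FALSE])        # trait-side directions
  B <- SyyInvSyx %*% A                            # gene-side directions
  # normalize directions; orient each component so its dominant trait loads
  # negatively ("efficient" direction up). With unfavourable traits such as
  # RFI, genes over-expressed in inefficient animals then carry negative
  # gene-side loadings, matching the sPLS-DA sign convention.
  for (h in seq_len(ncomp)) {
    A[, h] <- A[, h] / sqrt(sum(A[, h]^2))
    nb <- sqrt(sum(B[, h]^2))
    if (nb > 0) B[, h] <- B[, h] / nb
    if (A[which.max(abs(A[, h])), h] > 0) {
      A[, h] <- -A[, h]; B[, h] <- -B[, h]
    }
  }
  Ux <- Xs %*% A
  Uy <- Ys %*% B
  # canonical correlations of the regularized problem: sqrt of the
  # eigenvalues (equal to the empirical variate correlations when both
  # lambdas are zero)
  cc <- sqrt(pmin(pmax(Re(eg$values[ord]), 0), 1))
  for (h in seq_len(ncomp)) { # align variate signs pairwise
    if (stats::cor(Ux[, h], Uy[, h]) < 0) { B[, h] <- -B[, h]; Uy[, h] <- -Uy[, h] }
  }
  ord2 <- order(cc, decreasing = TRUE)
  cc <- cc[ord2]; A <- A[, ord2, drop = FALSE]; B <- B[, ord2, drop = FALSE]
  Ux <- Ux[, ord2, drop = FALSE]; Uy <- Uy[, ord2, drop = FALSE]
  dimnames(A) <- list(colnames(X), paste0("CC", seq_len(ncomp)))
  dimnames(B) <- list(colnames(Y), paste0("CC", seq_len(ncomp)))

  trait_cor <- stats::cor(Y, X)
  maxcor <- apply(abs(trait_cor), 1, max)
  pop <- if (select_pop == "cc1") {
    abs(B[, 1]) >= stats::median(abs(B[, 1]))
  } else rep(TRUE, p)
  threshold <- stats::median(maxcor[pop]) + 2 * stats::sd(maxcor[pop])
  selected <- colnames(Y)[pop & maxcor > threshold]

  structure(list(cancor = cc, xcoef = A, ycoef = B,
                 variates = list(X = Ux, Y = Uy),
                 lambda1 = lambda1, lambda2 = lambda2,
                 trait_cor = trait_cor, maxcor = maxcor,
                 threshold = threshold, selected = selected,
                 select_pop = select_pop),
            class = "RccaResult")
}

#' Analytic shrinkage intensity toward the identity correlation target
#'
#' Ledoit-Wolf / Schafer-Strimmer estimator on standardized data: the summed
#' estimated sampling variances of the off-diagonal sample correlations
#' divided by their summed squares, clipped to [0, 1].
#'
#' @param Zs standardized samples x variables matrix.
#' @return shrinkage intensity in [0, 1].
#' @export
shrinkageIntensity <- function(Zs) {
  n <- nrow(Zs)
  Zu <- scale(Zs) * sqrt((n - 1) / n) # unit "population" scaling
  R <- crossprod(Zu) / n
  W2 <- crossprod(Zu^2) / n
  varR <- n / (n - 1)^3 * (W2 - R^2) * n # sum_k (w_kij - wbar_ij)^2 expansion
  off <- upper.tri(R)
  num <- sum(varR[off])
  den <- sum(R[off]^2)
  if (den <= 0) return(0)
  min(1, max(0, num / den))
}
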