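#' Sparse partial least squares discriminant analysis
#'
#' Sparse PLS on the centered class-indicator response: per component, the
#' X-loading is estimated by the NIPALS-style alternating scheme with
#' soft-thresholding of the loading vector so that exactly \code{keepX} genes
#' are retained, then both blocks are deflated by regression on the
#' component score. \code{keepX} per component is tuned by repeated
#' stratified M-fold cross-validation minimizing the balanced error rate
#' (BER, the mean of per-class misclassification rates) under the
#' maximum-distance prediction rule. Components are oriented so that the
#' first variate is higher in the HFE class: genes up-regulated in LFE
#' therefore carry negative first-component loadings.
#'
#' @param X samples x genes matrix (log2 expression), or a
#'   \code{SummarizedExperiment} (transposed internally).
#' @param labels factor of class labels (two classes, e.g. HFE/LFE).
#' @param ncomp number of components.
#' @param keepX integer vector (recycled) of genes to retain per component;
#'   if \code{NULL}, tuned over \code{keepX_grid}.
#' @param keepX_grid candidate keepX values for tuning.
#' @param folds number of cross-validation folds.
#' @param reps number of repeated CV partitions (the study-scale analogue
#'   uses 500; desk-scale default is lighter).
#' @param seed RNG seed for the CV partitions.
#' @return list of class \code{SplsdaResult}: \code{loadings} (genes x
#'   ncomp), \code{variates}, \code{selected} (genes per component),
#'   \code{keepX}, \code{ber} (cross-validated BER per component),
#'   \code{tuning} (BER per grid value), \code{expl_var}, plus the fitted
#'   centering/scaling needed by \code{\link{predictSplsda}}.
#' @export
splsdaFit <- function(X, labels, ncomp = 2, keepX = NULL,
                      keepX_grid = c(5, 10, 25, 50, 100, 200),
                      folds = 5, reps = 10, seed = 1) {
  if (methods::is(X, "SummarizedExperiment")) {
    X <- t(SummarizedExperiment::assay(X, "exprs"))
  }
  X <- as.matrix(X)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("splsdaFit expects exactly two classes")
  if (any(table(labels) < folds)) {
    stop("each class needs at least 'folds' samples")
  }
  p <- ncol(X)
  if (!is.null(keepX)) {
    if (any(keepX > p)) stop("keepX cannot exceed the number of genes")
    keepX <- rep_len(keepX, ncomp)
  }
  keepX_grid <- sort(unique(pmin(keepX_grid, p)))

  ber <- rep(NA_real_, ncomp)
  tuning <- NULL
  if (is.null(keepX)) {
    keepX <- integer(0)
    tuning <- vector("list", ncomp)
    for (h in seq_len(ncomp)) {
      grid_ber <- vapply(keepX_grid, function(kx) {
        .cvBer(X, labels, c(keepX, kx), folds, reps, seed)
      }, numeric(1))
      tuning[[h]] <- data.frame(comp = h, keepX = keepX_grid, ber = grid_ber)
      keepX <- c(keepX, keepX_grid[which.min(grid_ber)])
      ber[h] <- min(grid_ber)
    }
    tuning <- do.call(rbind, tuning)
  } else {
    for (h in seq_len(ncomp)) {
      ber[h] <- .cvBer(X, labels, keepX[seq_len(h)], folds, reps, seed)
    }
  }

  fit <- .splsdaCore(X, labels, ncomp, keepX)
  fit$ber <- ber
  fit$tuning <- tuning
  class(fit) <- "SplsdaResult"
  fit
}

# Core sparse PLS-DA fit on the full data.
.splsdaCore <- function(X, labels, ncomp, keepX) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[xs == 0] <- 1
  Xc <- sweep(sweep(X, 2, xm), 2, xs, "/")
  Y <- stats::model.matrix(~ 0 + labels)
  colnames(Y) <- levels(labels)
  ym <- colMeans(Y)
  Yc <- sweep(Y, 2, ym)
  ysign <- ifelse(labels == levels(labels)[1], 1, -1) # + for first class (HFE)

  U <- matrix(0, p, ncomp, dimnames = list(colnames(X), paste0("comp", seq_len(ncomp))))
  Cl <- matrix(0, p, ncomp)
  D <- matrix(0, ncol(Y), ncomp)
  Tm <- matrix(0, n, ncomp)
  total_var <- sum(Xc^2)
  expl <- numeric(ncomp)
  Xd <- Xc; Yd <- Yc
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xd, Yd)
    sv <- svd(M, nu = 1, nv = 1)
    u <- sv$u[, 1]; v <- sv$v[, 1]
    for (it in 1:100) {
      us <- .softKeep(drop(M %*% v), keepX[h])
      vn <- drop(crossprod(M, us))
      vn <- vn / sqrt(sum(vn^2))
      if (max(abs(us - u)) < 1e-10 && max(abs(vn - v)) < 1e-10) { u <- us; v <- vn; break }
      u <- us; v <- vn
    }
    u <- .softKeep(drop(M %*% v), keepX[h])
    tt <- drop(Xd %*% u)
    if (sum(tt * ysign) < 0) { u <- -u; tt <- -tt }
    t2 <- sum(tt^2)
    cl <- drop(crossprod(Xd, tt)) / t2
    dl <- drop(crossprod(Yd, tt)) / t2
    Xd <- Xd - tcrossprod(tt, cl)
    Yd <- Yd - tcrossprod(tt, dl)
    U[, h] <- u; Cl[, h] <- cl; D[, h] <- dl; Tm[, h] <- tt
    expl[h] <- t2 * sum(cl^2) / total_var
  }
  selected <- lapply(seq_len(ncomp), function(h) colnames(X)[U[, h] != 0])
  list(loadings = U, xloadings = Cl, yloadings = D, variates = Tm,
       selected = selected, keepX = keepX, ncomp = ncomp,
       expl_var = expl, xm = xm, xs = xs, ym = ym, levels = levels(labels))
}

# Soft-threshold a weight vector to its keepX largest absolute entries,
# then rescale to unit norm.
.softKeep <- function(w, keepX) {
  p <- length(w)
  lambda <- if (keepX >= p) 0 else sort(abs(w), decreasing = TRUE)[keepX + 1L]
  ws <- sign(w) * pmax(abs(w) - lambda, 0)
  nrm <- sqrt(sum(ws^2))
  if (nrm > 0) ws / nrm else ws
}

#' Predict classes from a fitted sPLS-DA model
#'
#' Applies the training centering/scaling, computes predicted indicator
#' values through the PLS regression coefficients of the first \code{comp}
#' components, and assigns each sample to the class with the largest
#' predicted value (maximum-distance rule).
#'
#' @param fit an \code{SplsdaResult} (or the core fit).
#' @param newdata samples x genes matrix with the training gene set.
#' @param comp number of components to use (default all).
#' @return factor of predicted class labels.
#' @export
predictSplsda <- function(fit, newdata, comp = fit$ncomp) {
  Xn <- sweep(sweep(as.matrix(newdata), 2, fit$xm), 2, fit$xs, "/")
  U <- fit$loadings[, seq_len(comp), drop = FALSE]
  Cl <- fit$xloadings[, seq_len(comp), drop = FALSE]
  D <- fit$yloadings[, seq_len(comp), drop = FALSE]
  Ustar <- U %*% solve(crossprod(Cl, U))
  pred <- Xn %*% Ustar %*% t(D)
  pred <- sweep(pred, 2, fit$ym, "+")
  factor(fit$levels[max.col(pred)], levels = fit$levels)
}

#' Balanced error rate
#'
#' Mean of per-class misclassification rates.
#'
#' @param truth,pred factors of true and predicted labels.
#' @return BER in [0, 1].
#' @export
balancedErrorRate <- function(truth, pred) {
  truth <- factor(truth)
  mean(vapply(levels(truth), function(l) {
    mean(pred[truth == l] != l)
  }, numeric(1)))
}

# Repeated stratified M-fold CV returning mean BER for a keepX setting.
.cvBer <- function(X, labels, keepX, folds, reps, seed) {
  set.seed(deriveSeed(seed, 7L + length(keepX)))
  errs <- numeric(0)
  for (r in seq_len(reps)) {
    fold <- integer(nrow(X))
    for (l in levels(labels)) {
      i <- which(labels == l)
      fold[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    for (f in seq_len(folds)) {
      test <- fold == f
      if (length(unique(labels[!test])) < 2 || !any(test)) next
      fit <- .splsdaCore(X[!test, , drop = FALSE], labels[!test],
                         length(keepX), keepX)
      pred <- predictSplsda(fit, X[test, , drop = FALSE], length(keepX))
      errs <- c(errs, balancedErrorRate(labels[test], pred))
    }
  }
  mean(errs)
}
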