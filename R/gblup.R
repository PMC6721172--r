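#' GBLUP prediction of held-out phenotypes
#'
#' Solves the mixed model y = Xb + u + e on the training records only
#' (generalized least squares under V = R[train, train] sigma_u^2 +
#' I sigma_e^2) and propagates breeding values to every individual in R
#' through the relationship matrix: u_hat = sigma_u^2 R[, train] V^-1
#' (y - X b_hat). A validation individual's prediction is its fixed-effect
#' part plus its propagated breeding value; individuals unrelated to the
#' training set get u_hat = 0 and are predicted by fixed effects alone.
#' Predictions are linear in y.
#'
#' @param y phenotypes for the training individuals.
#' @param X fixed-effect design for all individuals (rows align with R).
#' @param R relationship matrix over all individuals (training and
#'   validation).
#' @param train integer/logical index of training rows of R.
#' @param sigma_u2,sigma_e2 variance components (typically full-data
#'   estimates from \code{\link{gibbsVariance}} or
#'   \code{\link{fitNullModel}}).
#' @return numeric vector of predictions for all rows of R.
#' @export
gblupPredict <- function(y, X, R, train, sigma_u2, sigma_e2) {
  X <- as.matrix(X)
  n_all <- nrow(R)
  stopifnot(nrow(X) == n_all)
  tr <- if (is.logical(train)) which(train) else as.integer(train)
  if (any(tr < 1 | tr > n_all)) stop("training index outside relationship matrix")
  if (length(y) != length(tr)) stop("y must have one record per training individual")

  Xtr <- X[tr, , drop = FALSE]
  V <- sigma_u2 * R[tr, tr] + sigma_e2 * diag(length(tr))
  cV <- chol(V)
  solveV <- function(M) backsolve(cV, backsolve(cV, M, transpose = TRUE))
  ViX <- solveV(Xtr)
  Viy <- solveV(y)
  bhat <- solve(crossprod(Xtr, ViX), crossprod(Xtr, Viy))
  resid <- y - drop(Xtr %*% bhat)
  uhat <- sigma_u2 * drop(R[, tr] %*% solveV(resid))
  drop(X %*% bhat) + uhat
}

#' Cross-validated prediction accuracy
#'
#' Random training/validation replicates (default 20 replicates with
#' approximately 88/12 splits); each replicate solves GBLUP on the training
#' set with the supplied full-data variance components and records the
#' Pearson correlation between observed and predicted phenotypes in the
#' validation set. Splits in which some batch level is absent from training
#' are resampled (up to 100 attempts, logged).
#'
#' @param y phenotypes for all individuals.
#' @param X fixed-effect design for all individuals.
#' @param R relationship matrix.
#' @param sigma_u2,sigma_e2 full-data variance components.
#' @param batch optional factor used to require every level in training.
#' @param n_rep number of replicates.
#' @param train_frac fraction of records in training.
#' @param seed RNG seed for the splits.
#' @return list of class \code{PredictionResult}: \code{replicates}
#'   (data.frame \code{rep}, \code{cor}, \code{n_valid}, \code{resampled}),
#'   \code{mean}, \code{sd}, \code{splits}.
#' @export
crossValidate <- function(y, X, R, sigma_u2, sigma_e2, batch = NULL,
                          n_rep = 20, train_frac = 0.88, seed = 1) {
  n <- length(y)
  if (n < 20) stop("need at least 20 records for cross-validation")
  set.seed(as.integer(seed))
  n_train <- max(1L, min(n - 1L, round(train_frac * n)))
  reps <- data.frame(rep = seq_len(n_rep), cor = NA_real_,
                     n_valid = n - n_train, resampled = 0L)
  splits <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    for (attempt in seq_len(100)) {
      tr <- sort(sample.int(n, n_train))
      if (is.null(batch) ||
          all(levels(droplevels(factor(batch))) %in% unique(batch[tr]))) break
      if (attempt == 100) stop("could not find a split covering all batch levels")
      reps$resampled[r] <- reps$resampled[r] + 1L
    }
    va <- setdiff(seq_len(n), tr)
    pred <- gblupPredict(y[tr], X, R, tr, sigma_u2, sigma_e2)
    reps$cor[r] <- stats::cor(y[va], pred[va])
    splits[[r]] <- list(train = tr, valid = va)
  }
  structure(list(replicates = reps, mean = mean(reps$cor),
                 sd = stats::sd(reps$cor), splits = splits),
            class = "PredictionResult")
}

#' @export
print.PredictionResult <- function(x, ...) {
  cat(sprintf("Cross-validated prediction accuracy: %.3f (SD %.3f) over %d replicates\n",
              x$mean, x$sd, nrow(x$replicates)))
  invisible(x)
}
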