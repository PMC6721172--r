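# Internal helpers shared across stages.

# Derive a stage-level seed from the global seed. Keeps results < 2^31 so the
# value is always a valid R integer.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * offset) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Drop-one-level-per-factor design matrix from a data.frame of covariates.
buildDesign <- function(df, terms) {
  if (length(terms) == 0L) {
    return(matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)")))
  }
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(f, data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient (rank ", qrX$rank, " < ", ncol(X),
         " columns); check factor levels and nesting")
  }
  X
}

checkProportion <- function(x, name, open0 = FALSE, open1 = FALSE) {
  lo <- if (open0) x > 0 else x >= 0
  hi <- if (open1) x < 1 else x <= 1
  if (!all(is.finite(x)) || !all(lo & hi)) {
    stop("'", name, "' must lie in ", if (open0) "(" else "[", "0,1",
         if (open1) ")" else "]")
  }
  invisible(x)
}
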