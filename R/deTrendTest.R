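#' Trend-moderated differential expression between feed-efficiency groups
#'
#' Per-gene least-squares fit of log2 expression on group + nuisance
#' covariates (batch, laboratory). Residual variances are shrunk toward an
#' intensity-dependent prior: the prior variance is a lowess fit of the
#' (bias-corrected) log residual variance on mean log2 intensity, and the
#' prior degrees of freedom d0 are estimated by moment matching of the
#' scaled log deviates (solving trigamma(d0/2) = excess variance). The
#' moderated t statistic uses the posterior variance
#' (d0 s0^2 + d s^2) / (d0 + d) on d0 + d degrees of freedom. The group
#' contrast Delta is mean(LFE) - mean(HFE) adjusted for the nuisance terms;
#' a positive value means higher expression in the LFE (less efficient)
#' group. Reported fold change is sign(Delta) * 2^|Delta| on the linear
#' scale by default.
#'
#' @param expr \code{SummarizedExperiment} with assay \code{exprs} and
#'   colData column \code{group} (levels HFE/LFE), or a genes x samples
#'   matrix (then supply \code{group}).
#' @param group,batch,lab optional explicit per-sample covariates overriding
#'   colData.
#' @param fc_thresh fold-change threshold for the DE call.
#' @param q_thresh BH q-value threshold for the DE call.
#' @param trend use the intensity-dependent prior variance (otherwise a
#'   constant prior at the mean log variance).
#' @param d0 optional prior degrees of freedom override; \code{0} disables
#'   shrinkage entirely (ordinary t test), \code{Inf} fully shrinks to the
#'   trend.
#' @param fc_scale apply \code{fc_thresh} on the \code{"linear"} fold-change
#'   scale (default) or on the \code{"log2"} difference.
#' @return data.frame of class \code{DEResult}: \code{gene}, \code{amean},
#'   \code{delta} (log2), \code{fc} (signed linear fold change), \code{t},
#'   \code{df_total}, \code{p}, \code{q}, \code{de} flag; prior estimates in
#'   attributes \code{d0} and \code{s02}.
#' @export
deTrendTest <- function(expr, group = NULL, batch = NULL, lab = NULL,
                        fc_thresh = 1.5, q_thresh = 0.05, trend = TRUE,
                        d0 = NULL, fc_scale = c("linear", "log2")) {
  fc_scale <- match.arg(fc_scale)
  if (methods::is(expr, "SummarizedExperiment")) {
    E <- SummarizedExperiment::assay(expr, "exprs")
    cd <- as.data.frame(SummarizedExperiment::colData(expr))
    group <- group %||% cd$group
    batch <- batch %||% cd$batch
    lab <- lab %||% cd$lab
  } else {
    E <- as.matrix(expr)
  }
  if (is.null(group)) stop("a 'group' factor (HFE/LFE) is required")
  group <- factor(group, levels = c("HFE", "LFE"))
  if (any(is.na(group))) stop("group labels must be HFE or LFE")
  if (any(table(group) < 2)) stop("need at least 2 samples per group")

  covars <- data.frame(group = group)
  if (!is.null(batch)) covars$batch <- droplevels(factor(batch))
  if (!is.null(lab)) covars$lab <- droplevels(factor(lab))
  covars <- covars[, vapply(covars, function(x) nlevels(x) > 1, logical(1)),
                   drop = FALSE]
  X <- buildDesign(covars, names(covars))

  n <- ncol(E)
  dfr <- n - ncol(X)
  if (dfr < 1) stop("zero residual degrees of freedom")
  fit <- stats::lm.fit(X, t(E))
  coefs <- t(fit$coefficients)
  delta <- coefs[, "groupLFE"]
  res <- fit$residuals
  s2 <- colSums(res^2) / dfr
  xtxi <- chol2inv(chol(crossprod(X)))
  unscaled <- xtxi[which(colnames(X) == "groupLFE"),
                   which(colnames(X) == "groupLFE")]
  amean <- rowMeans(E)

  # prior variance from the mean-variance trend (bias-corrected log scale)
  loge <- log(pmax(s2, 1e-300)) - digamma(dfr / 2) + log(dfr / 2)
  e0 <- if (trend && length(unique(amean)) > 2) {
    lo <- stats::lowess(amean, loge, f = 0.5)
    stats::approx(lo$x, lo$y, xout = amean, rule = 2)$y
  } else {
    rep(mean(loge), length(loge))
  }
  zdev <- loge - e0
  evar <- max(stats::var(zdev) - trigamma(dfr / 2), 0)
  d0_hat <- if (evar > 0) 2 * .trigammaInverse(evar) else Inf
  if (!is.null(d0)) d0_hat <- d0
  s02 <- if (is.finite(d0_hat) && d0_hat > 0) {
    exp(e0 + digamma(d0_hat / 2) - log(d0_hat / 2))
  } else {
    exp(e0)
  }

  if (d0_hat == 0) {
    s2_post <- s2
    df_total <- dfr
  } else if (is.infinite(d0_hat)) {
    s2_post <- s02
    df_total <- Inf
  } else {
    s2_post <- (d0_hat * s02 + dfr * s2) / (d0_hat + dfr)
    df_total <- d0_hat + dfr
  }
  tstat <- delta / sqrt(s2_post * unscaled)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  q <- stats::p.adjust(p, method = "BH")
  fc <- sign(delta) * 2^abs(delta)
  de <- if (fc_scale == "linear") {
    abs(fc) > fc_thresh & q < q_thresh
  } else {
    abs(delta) > fc_thresh & q < q_thresh
  }

  out <- data.frame(gene = rownames(E), amean = amean, delta = delta,
                    fc = fc, t = tstat, df_total = df_total, p = p, q = q,
                    de = de, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0_hat
  attr(out, "s02") <- s02
  class(out) <- c("DEResult", "data.frame")
  out
}

# Solve trigamma(y) = x by Newton iteration on a transformed scale.
.trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}
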