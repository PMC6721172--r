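#' PCIT: partial-correlation-and-information-theory network inference
#'
#' Computes all pairwise Pearson correlations between AWM rows and decides
#' edge significance trio-locally. For every trio (x, y, z) the three
#' first-order partial correlations are computed, e.g.
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}
#' and the trio tolerance is the mean ratio
#' \eqn{\epsilon = (r_{xy.z}/r_{xy} + r_{xz.y}/r_{xz} + r_{yz.x}/r_{yz})/3}.
#' Within the trio, edge x-y is flagged non-significant when
#' \eqn{|r_{xy}| \le |\epsilon r_{xz}|} and \eqn{|r_{xy}| \le |\epsilon r_{yz}|}.
#' Under the default aggregation (\code{"any"}) an edge survives only if no
#' trio flags it; under \code{"all"} it is removed only if every valid trio
#' containing it flags it.
#'
#' Numerical guards: trios in which any of the three correlations has
#' magnitude below \code{tol} contribute nothing (their tolerance ratio is
#' undefined), and partial-correlation denominators are clamped away from
#' zero when a correlation is exactly +/-1.
#'
#' Because AWM profiles are short (one point per trait), the pairwise
#' correlations are not themselves significance-tested; PCIT's trio decision
#' replaces that test, and a warning records this when profiles have fewer
#' than 30 points.
#'
#' @param awm an \linkS4class{AWMatrix} or a plain numeric matrix whose rows
#'   are node profiles.
#' @param aggregation \code{"any"} (edge removed if any trio flags it;
#'   default) or \code{"all"} (removed only if all valid trios flag it).
#' @param tol magnitude below which a correlation is treated as zero in the
#'   tolerance denominators.
#' @return A \linkS4class{CoAssocNetwork}; surviving edges carry the raw
#'   pairwise correlation as weight.
#' @export
pcit <- function(awm, aggregation = c("any", "all"), tol = 1e-12) {
  aggregation <- match.arg(aggregation)
  Z <- if (methods::is(awm, "AWMatrix")) zscores(awm) else as.matrix(awm)
  n <- nrow(Z)
  if (n < 3) stop("PCIT needs at least 3 nodes")
  if (is.null(rownames(Z))) rownames(Z) <- sprintf("node%03d", seq_len(n))
  if (ncol(Z) < 30) {
    warning("edge weights are correlations over only ", ncol(Z),
            " profile points; their significance is not tested (the PCIT ",
            "trio decision replaces it)", call. = FALSE)
  }

  R <- stats::cor(t(Z))
  flagged <- matrix(FALSE, n, n)
  nflag <- matrix(0L, n, n)
  nvalid <- matrix(0L, n, n)
  eps0 <- 1e-12
  absR <- abs(R)
  omR2 <- pmax(1 - R^2, eps0)

  for (z in seq_len(n)) {
    cz <- R[, z]
    omc2 <- pmax(1 - cz^2, eps0)
    # r_xy.z
    A <- (R - tcrossprod(cz)) / sqrt(tcrossprod(omc2))
    # r_xz.y : numerator c[x] - R[x,y] c[y]
    cy <- matrix(cz, n, n, byrow = TRUE)
    cx <- matrix(cz, n, n)
    B <- (cx - R * cy) / sqrt(omR2 * matrix(omc2, n, n, byrow = TRUE))
    # r_yz.x
    Cm <- (cy - R * cx) / sqrt(omR2 * matrix(omc2, n, n))

    valid <- absR >= tol & abs(cx) >= tol & abs(cy) >= tol
    valid[, z] <- FALSE
    valid[z, ] <- FALSE
    diag(valid) <- FALSE

    eps <- (A / R + B / cx + Cm / cy) / 3
    kill <- valid & absR <= abs(eps * cx) & absR <= abs(eps * cy)
    flagged <- flagged | kill
    nflag <- nflag + kill
    nvalid <- nvalid + valid
  }

  removed <- if (aggregation == "any") flagged else (nvalid > 0L & nflag == nvalid)
  ut <- which(upper.tri(R) & !removed, arr.ind = TRUE)
  edges <- data.frame(from = rownames(Z)[ut[, 1]], to = rownames(Z)[ut[, 2]],
                      weight = R[ut], stringsAsFactors = FALSE)
  methods::new("CoAssocNetwork", nodes = rownames(Z), edges = edges,
               aggregation = aggregation, nProfile = ncol(Z))
}

#' First-order partial correlation
#'
#' \eqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}.
#'
#' @param rxy,rxz,ryz pairwise Pearson correlations of the trio.
#' @return The partial correlation of x and y given z.
#' @export
partialCorrelation <- function(rxy, rxz, ryz) {
  den <- sqrt(pmax(1 - rxz^2, 1e-12) * pmax(1 - ryz^2, 1e-12))
  (rxy - rxz * ryz) / den
}
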