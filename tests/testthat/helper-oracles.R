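# Independent reference implementations used as oracles. These deliberately
# use naive loops/set operations, not the package's vectorized code paths.

# Naive triple-loop PCIT on a node-profile matrix (rows = nodes).
oraclePcit <- function(Z, aggregation = c("any", "all"), tol = 1e-12) {
  aggregation <- match.arg(aggregation)
  R <- stats::cor(t(Z))
  n <- nrow(R)
  pc <- function(rxy, rxz, ryz) {
    (rxy - rxz * ryz) /
      sqrt(max(1 - rxz^2, 1e-12) * max(1 - ryz^2, 1e-12))
  }
  nflag <- nvalid <- matrix(0L, n, n)
  flagged <- matrix(FALSE, n, n)
  for (x in 1:(n - 1)) for (y in (x + 1):n) for (z in 1:n) {
    if (z == x || z == y) next
    rxy <- R[x, y]; rxz <- R[x, z]; ryz <- R[y, z]
    if (abs(rxy) < tol || abs(rxz) < tol || abs(ryz) < tol) next
    eps <- (pc(rxy, rxz, ryz) / rxy + pc(rxz, rxy, ryz) / rxz +
              pc(ryz, rxy, rxz) / ryz) / 3
    nvalid[x, y] <- nvalid[x, y] + 1L
    if (abs(rxy) <= abs(eps * rxz) && abs(rxy) <= abs(eps * ryz)) {
      flagged[x, y] <- TRUE
      nflag[x, y] <- nflag[x, y] + 1L
    }
  }
  keep <- matrix(FALSE, n, n)
  for (x in 1:(n - 1)) for (y in (x + 1):n) {
    keep[x, y] <- if (aggregation == "any") !flagged[x, y] else
      !(nvalid[x, y] > 0L && nflag[x, y] == nvalid[x, y])
  }
  idx <- which(keep, arr.ind = TRUE)
  data.frame(from = rownames(Z)[idx[, 1]], to = rownames(Z)[idx[, 2]],
             weight = R[idx], stringsAsFactors = FALSE)
}

# Naive per-SNP ordinary least squares with normal-reference Wald p-values,
# via explicit normal equations.
oracleOlsScan <- function(y, X, geno) {
  t(vapply(seq_len(ncol(geno)), function(j) {
    D <- cbind(X, snp = geno[, j])
    XtX <- t(D) %*% D
    bh <- solve(XtX, t(D) %*% y)
    res <- y - D %*% bh
    s2 <- sum(res^2) / (length(y) - ncol(D))
    se <- sqrt(s2 * solve(XtX)[ncol(D), ncol(D)])
    a <- bh[ncol(D)]
    c(effect = a, se = se, z = a / se, p = 2 * pnorm(-abs(a / se)))
  }, numeric(4)))
}

# Naive Benjamini-Hochberg adjusted p-values.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Naive set-based lossless regulator search with identical ranking rules.
oracleLossless <- function(net, tfs, k, include_self = FALSE) {
  e <- edgeTable(net)
  nb <- lapply(stats::setNames(tfs, tfs), function(tf) {
    unique(c(e$to[e$from == tf], e$from[e$to == tf]))
  })
  tfs <- sort(tfs)
  combs <- utils::combn(tfs, k, simplify = FALSE)
  rows <- lapply(combs, function(mem) {
    u <- unique(unlist(nb[mem]))
    cov <- if (include_self) length(u) else length(setdiff(u, mem))
    pairs <- utils::combn(mem, 2, simplify = FALSE)
    red <- sum(vapply(pairs, function(pr) {
      length(intersect(nb[[pr[1]]], nb[[pr[2]]]))
    }, numeric(1)))
    c(stats::setNames(as.list(mem), paste0("tf", seq_len(k))),
      list(coverage = cov, redundancy = red))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  key <- do.call(paste, c(out[paste0("tf", seq_len(k))], sep = "\r"))
  out <- out[order(-out$coverage, out$redundancy, key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Recursive kinship oracle: A(i, j) = 2 * kinship(i, j).
oracleKinshipA <- function(ped) {
  ids <- ped$id
  sire <- match(ped$sire, ids)
  dam <- match(ped$dam, ids)
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i == j) {
      s <- sire[i]; d <- dam[i]
      return(0.5 * (1 + if (!is.na(s) && !is.na(d)) phi(s, d) else 0))
    }
    # recurse on the later-listed individual (parents precede offspring)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    0.5 * (phi(if (is.na(sire[i])) NA else sire[i], j) +
             phi(if (is.na(dam[i])) NA else dam[i], j))
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:n) for (j in 1:i) A[i, j] <- A[j, i] <- 2 * phi(i, j)
  A
}

# Random AWM-like z-score matrix for PCIT stress tests.
randomAwmMatrix <- function(n_nodes, n_traits = 9) {
  Z <- matrix(stats::rnorm(n_nodes * n_traits), n_nodes,
              dimnames = list(sprintf("n%03d", seq_len(n_nodes)),
                              sprintf("t%d", seq_len(n_traits))))
  Z
}

# Random undirected network over nt TF nodes and nn target nodes.
randomNetwork <- function(nt, nn, p_edge = 0.3) {
  nodes <- c(sprintf("TF%02d", seq_len(nt)), sprintf("N%03d", seq_len(nn)))
  all_pairs <- t(utils::combn(nodes, 2))
  pick <- stats::runif(nrow(all_pairs)) < p_edge
  toyNetwork(nodes, all_pairs[pick, 1], all_pairs[pick, 2],
             stats::runif(sum(pick), -1, 1))
}
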