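#' Information-lossless search for regulator trios and quartets
#'
#' Exhaustively scores every k-combination of transcription-factor nodes by
#' the number of distinct network nodes adjacent to at least one member
#' (coverage; the members themselves excluded by default) and by the summed
#' pairwise overlap of member neighborhoods (redundancy). Combinations are
#' ranked by coverage descending, ties broken by redundancy ascending, then
#' lexicographically by member ids. Enumeration is exact, not greedy.
#'
#' @param net a \linkS4class{CoAssocNetwork}.
#' @param tf_nodes character vector of candidate regulator node ids (must be
#'   network nodes).
#' @param k combination size, 3 (trios) or 4 (quartets).
#' @param top_n number of top combinations to return.
#' @param include_self if \code{TRUE}, members adjacent to another member
#'   count toward coverage; default excludes all seed members from the count.
#' @param max_comb guard on the number of combinations enumerated.
#' @return data.frame with member columns \code{tf1..tfk}, \code{coverage},
#'   \code{redundancy}, ordered by rank; \code{top_n} rows.
#' @export
losslessSearch <- function(net, tf_nodes, k = 3, top_n = 10,
                           include_self = FALSE, max_comb = 1e7) {
  stopifnot(methods::is(net, "CoAssocNetwork"))
  if (!k %in% c(3, 4)) stop("k must be 3 (trios) or 4 (quartets)")
  nodes <- networkNodes(net)
  bad <- setdiff(tf_nodes, nodes)
  if (length(bad)) stop("tf_nodes not in network: ", paste(bad, collapse = ", "))
  tf_nodes <- sort(unique(tf_nodes))
  nt <- length(tf_nodes)
  if (nt < k) stop("need at least k TF nodes")
  ncomb <- choose(nt, k)
  if (ncomb > max_comb) {
    stop("combination count ", format(ncomb, big.mark = ","),
         " exceeds the guard (", format(max_comb, big.mark = ","),
         "); pre-filter the TF list, e.g. by degree")
  }

  e <- edgeTable(net)
  nn <- length(nodes)
  idx <- stats::setNames(seq_len(nn), nodes)
  # TF x node adjacency (logical neighborhood rows)
  L <- matrix(FALSE, nt, nn, dimnames = list(tf_nodes, nodes))
  for (tf in tf_nodes) {
    nb <- c(e$to[e$from == tf], e$from[e$to == tf])
    L[tf, idx[nb]] <- TRUE
  }
  inter <- tcrossprod(L * 1L) # pairwise neighborhood intersection sizes

  combs <- utils::combn(nt, k)
  ncb <- ncol(combs)
  coverage <- integer(ncb)
  redundancy <- integer(ncb)
  pair_idx <- utils::combn(k, 2)
  member_cols <- matrix(tf_nodes[combs], nrow = k)
  for (i in seq_len(ncb)) {
    mem <- combs[, i]
    u <- L[mem[1], ]
    for (j in 2:k) u <- u | L[mem[j], ]
    cov <- sum(u)
    if (!include_self) cov <- cov - sum(u[idx[tf_nodes[mem]]])
    coverage[i] <- cov
    redundancy[i] <- as.integer(
      sum(inter[cbind(mem[pair_idx[1, ]], mem[pair_idx[2, ]])]))
  }

  out <- as.data.frame(t(member_cols), stringsAsFactors = FALSE)
  names(out) <- paste0("tf", seq_len(k))
  out$coverage <- coverage
  out$redundancy <- redundancy
  key <- do.call(paste, c(out[paste0("tf", seq_len(k))], sep = "\r"))
  out <- out[order(-out$coverage, out$redundancy, key), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
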