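#' Pedigree-based numerator relationship matrix (tabular method)
#'
#' Builds the additive relationship matrix A over all pedigree members by
#' the recursive tabular method, assuming non-inbred unrelated founders
#' (diagonal 1). The pedigree is topologically sorted first; a cycle or an
#' unresolvable ordering is an error.
#'
#' @param ped data.frame with columns \code{id}, \code{sire}, \code{dam}
#'   (\code{NA} for unknown parents).
#' @return Symmetric matrix with pedigree ids as dimnames.
#' @export
pedigreeA <- function(ped) {
  ped <- as.data.frame(ped)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate pedigree ids")
  unknown <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(unknown)) {
    stop("parents absent from pedigree: ", paste(unknown, collapse = ", "))
  }
  # topological sort: parents before offspring
  n <- nrow(ped)
  placed <- character(0)
  remaining <- ped
  while (nrow(remaining) > 0) {
    ready <- (is.na(remaining$sire) | remaining$sire %in% placed) &
             (is.na(remaining$dam) | remaining$dam %in% placed)
    if (!any(ready)) stop("pedigree contains a cycle; cannot sort")
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  ord <- match(placed, ped$id)
  ids <- ped$id[ord]
  sire <- match(ped$sire[ord], ids)
  dam <- match(ped$dam[ord], ids)

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1) {
      prev <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[prev, s] else 0
      ad_ <- if (!is.na(d)) A[prev, d] else 0
      A[prev, i] <- A[i, prev] <- 0.5 * (as_ + ad_)
    }
  }
  A
}
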