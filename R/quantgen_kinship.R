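#' Additive relationship matrix from a pedigree
#'
#' The tabular method: founders are unrelated and non-inbred; for an
#' individual i with parents s and d, `A[i,i] = 1 + A[s,d]/2` (the diagonal
#' is one plus the inbreeding coefficient) and `A[i,j] = (A[j,s] + A[j,d])/2`
#' for any j that precedes i. Entries are twice the kinship coefficient.
#'
#' @param ped A `pedigree_table` (see [read_pedigree()]).
#' @return Symmetric positive semidefinite matrix with id dimnames,
#'   class `relationship_matrix`.
#' @export
kinship_matrix <- function(ped) {
  ord <- pedigree_order(ped)
  if (is.null(ord)) stop("kinship_matrix: pedigree contains a cycle")
  n <- length(ord)
  idx <- stats::setNames(seq_len(n), ord)
  rows <- as.data.frame(ped)[match(ord, ped$id), ]
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  sire_i <- ifelse(is.na(rows$sire), NA_integer_, idx[rows$sire])
  dam_i <- ifelse(is.na(rows$dam), NA_integer_, idx[rows$dam])
  for (i in seq_len(n)) {
    s <- sire_i[i]; d <- dam_i[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) rep(0, i - 1L) else A[j, s]
      ad_ <- if (is.na(d)) rep(0, i - 1L) else A[j, d]
      A[j, i] <- A[i, j] <- (as_ + ad_) / 2
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else A[s, d] / 2
  }
  # reorder to the pedigree's own row order
  A <- A[ped$id, ped$id]
  class(A) <- c("relationship_matrix", class(A))
  A
}

#' Memoized pairwise kinship lookup
#'
#' Returns a function `kin(i, j)` computing the kinship coefficient of two
#' pedigree members by the standard recursion (`phi(i,i) = (1 +
#' phi(sire, dam)) / 2`; for i later in the pedigree than j, `phi(i,j) =
#' (phi(sire_i, j) + phi(dam_i, j)) / 2`), with memoization. Unlike
#' [kinship_matrix()] this never materialises the full matrix, so single
#' pairs remain cheap in very large pedigrees.
#'
#' @param ped A `pedigree_table`.
#' @return Function of two ids returning their kinship coefficient.
#' @export
kinship_pairs <- function(ped) {
  ord <- pedigree_order(ped)
  if (is.null(ord)) stop("kinship_pairs: pedigree contains a cycle")
  pos_env <- list2env(as.list(stats::setNames(seq_along(ord), ord)),
                      parent = emptyenv())
  ord_rows <- match(ord, ped$id)
  sire_pos <- match(ped$sire[ord_rows], ord)
  dam_pos <- match(ped$dam[ord_rows], ord)
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (i < j) { tmp <- i; i <- j; j <- tmp }  # i is the later individual
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    s <- sire_pos[i]; d <- dam_pos[i]
    val <- if (i == j) {
      if (is.na(s) || is.na(d)) 0.5 else 0.5 * (1 + phi(s, d))
    } else if (is.na(s) && is.na(d)) {
      0
    } else {
      ((if (is.na(s)) 0 else phi(s, j)) + (if (is.na(d)) 0 else phi(d, j))) / 2
    }
    memo[[key]] <- val
    val
  }
  function(id_i, id_j) phi(pos_env[[id_i]], pos_env[[id_j]])
}
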