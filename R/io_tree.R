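#' Read an ultrametric chronogram from newick
#'
#' Reads a rooted tree whose branch lengths are in millions of years and
#' checks it: tip labels must be unique, branch lengths non-negative, and
#' root-to-tip depths equal to within a relative tolerance of 1e-6 of tree
#' depth. A tree that fails ultrametricity only is accepted with a warning
#' and carries `attr(tree, "ultrametric") = FALSE`.
#'
#' @param path Newick file with branch lengths.
#' @param tol Relative ultrametricity tolerance (default `1e-6`).
#' @return An [ape::phylo] object with an `ultrametric` attribute.
#' @export
read_chronogram <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("read_chronogram: no such file: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("read_chronogram: could not parse newick")
  validate_chronogram(tree, tol = tol)
}

#' Validate a phylo object as a chronogram
#' @param tree An [ape::phylo] object with branch lengths.
#' @param tol Relative ultrametricity tolerance.
#' @return `tree` with an `ultrametric` attribute set.
#' @export
validate_chronogram <- function(tree, tol = 1e-6) {
  if (is.null(tree$edge.length)) {
    stop("chronogram format error: tree has no branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    stop("chronogram format error: negative branch length")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("chronogram format error: duplicate tip labels")
  }
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  depth <- max(depths)
  ultra <- depth == 0 || max(depths) - min(depths) <= tol * depth
  if (!ultra) {
    warning("chronogram is not ultrametric (tip depth range ",
            signif(max(depths) - min(depths), 3), " Ma)")
  }
  attr(tree, "ultrametric") <- ultra
  tree
}

#' Graft a new tip onto a chronogram
#'
#' Inserts a new terminal taxon as sister to an existing tip, splitting the
#' sister's terminal branch at `split_age` Ma before present. Both daughter
#' branches of the new node have length `split_age`, so ultrametricity is
#' preserved. This is how taxa absent from a molecular tree are added from
#' a published divergence date (e.g. Presbytis rubicunda at 1.3 Ma from
#' P. melalophos).
#'
#' @param tree Ultrametric [ape::phylo].
#' @param new_tip Label of the tip to add (must not already exist).
#' @param sister_tip Existing tip the new taxon is sister to.
#' @param split_age Divergence age in Ma; must be positive and younger than
#'   the age of `sister_tip`'s parent node.
#' @return The enlarged chronogram.
#' @export
graft_taxon <- function(tree, new_tip, sister_tip, split_age) {
  if (new_tip %in% tree$tip.label) {
    stop("graft_taxon: tip label already present: ", new_tip)
  }
  i <- match(sister_tip, tree$tip.label)
  if (is.na(i)) stop("graft_taxon: sister tip not found: ", sister_tip)
  if (split_age <= 0) stop("graft_taxon: split_age must be positive")
  edge_i <- which(tree$edge[, 2] == i)
  parent_age <- tree$edge.length[edge_i]  # sister tip age 0 => terminal
  if (split_age >= parent_age) {
    stop("graft_taxon: split_age (", split_age,
         ") must be younger than the parent node age (", parent_age, ")")
  }
  new_clade <- list(edge = matrix(c(2L, 1L), 1, 2),
                    tip.label = new_tip,
                    edge.length = split_age,
                    Nnode = 1L)
  class(new_clade) <- "phylo"
  out <- ape::bind.tree(tree, new_clade, where = i, position = split_age)
  validate_chronogram(out)
}

#' Brownian-motion covariance matrix of a tree's tips
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j;
#' the diagonal is the root-to-tip depth. Under Brownian motion with rate
#' sigma^2 the tip values are multivariate normal with covariance
#' sigma^2 times this matrix.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @return A symmetric positive semidefinite matrix with tip-label
#'   dimnames.
#' @export
bm_covariance <- function(tree) {
  n <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  mrca_mat <- ape::mrca(tree, full = FALSE)
  V <- matrix(depths[mrca_mat], n, n,
              dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depths[seq_len(n)]
  V
}

#' Felsenstein's standardized independent contrasts
#'
#' Computes the n-1 contrasts between sister lineages, each standardized by
#' the square root of its expected Brownian variance; returns the fitted BM
#' rate as the mean squared contrast (the ML contrasts-based estimate).
#' Polytomies are resolved arbitrarily with zero-length branches first
#' (this leaves the tip covariance matrix unchanged).
#'
#' @param tree An [ape::phylo].
#' @param values Named numeric vector of tip values (names = tip labels)
#'   or unnamed in tip order.
#' @return List with `contrasts` (length n-1) and `sigma2` (mean squared
#'   contrast).
#' @export
independent_contrasts <- function(tree, values) {
  values <- .match_tip_values(tree, values)
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
  }
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  # postorder pruning: at each internal node combine the two daughters
  x <- c(values, rep(NA_real_, nn))
  v <- numeric(n + nn)             # extra variance accumulated above node
  elen <- numeric(n + nn)
  elen[tree$edge[, 2]] <- tree$edge.length
  contrasts <- numeric(0)
  reord <- ape::reorder.phylo(tree, "postorder")
  for (node in unique(reord$edge[, 1])) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    c1 <- kids[1]; c2 <- kids[2]
    v1 <- elen[c1] + v[c1]; v2 <- elen[c2] + v[c2]
    contrasts <- c(contrasts, unname(x[c1] - x[c2]) / sqrt(v1 + v2))
    x[node] <- (x[c1] / v1 + x[c2] / v2) / (1 / v1 + 1 / v2)
    v[node] <- v1 * v2 / (v1 + v2)
  }
  list(contrasts = contrasts, sigma2 = mean(contrasts^2))
}

# match a value vector to tip labels; error on missing/extra
.match_tip_values <- function(tree, values) {
  if (is.null(names(values))) {
    if (length(values) != ape::Ntip(tree)) {
      stop("values must be named by tip label or match the number of tips")
    }
    names(values) <- tree$tip.label
    return(values)
  }
  missing_tips <- setdiff(tree$tip.label, names(values))
  if (length(missing_tips) > 0L) {
    stop("missing trait values for tip(s): ",
         paste(missing_tips, collapse = ", "))
  }
  values[tree$tip.label]
}
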