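# Small in-code fixtures shared across test files.

# father, mother, two full sibs, and an inbred offspring of the sibs
inbred_pedigree <- function() {
  as_pedigree_table(data.frame(
    id = c("f", "m", "a", "b", "x"),
    sire = c(NA, NA, "f", "f", "a"),
    dam = c(NA, NA, "m", "m", "b"),
    sex = c("M", "F", "M", "F", "F"),
    stringsAsFactors = FALSE))
}

trio_pedigree <- function() {
  as_pedigree_table(data.frame(
    id = c("f", "m", "c"),
    sire = c(NA, NA, "f"),
    dam = c(NA, NA, "m"),
    sex = c("M", "F", "F"),
    stringsAsFactors = FALSE))
}

# a balanced ultrametric test tree with genus-structured tips
balanced_test_tree <- function(n_tips = 16, depth = 10) {
  tree <- ape::stree(n_tips, type = "balanced")
  tree$edge.length <- rep(1, nrow(tree$edge))
  d <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length *
    (depth / max(d[seq_len(n_tips)]))
  tree
}

# one specimen's measurement rows with chosen missingness
specimen_rows <- function(sides = c("L", "R"),
                          teeth = c("P4", "M1", "M2", "M3"),
                          md = c(P4 = 8, M1 = 10, M2 = 12, M3 = 11),
                          bl = c(P4 = 7, M1 = 8, M2 = 9, M3 = 8.5)) {
  grid <- expand.grid(side = sides, tooth = teeth,
                      stringsAsFactors = FALSE)
  data.frame(specimen_id = "s1", genus = "Papio", species = "hamadryas",
             side = grid$side, tooth = grid$tooth,
             md_length = unname(md[grid$tooth]),
             bl_breadth = unname(bl[grid$tooth]),
             stringsAsFactors = FALSE)
}

# independent full-matrix ML log-likelihood for the polygenic model:
# maximizes over beta and total variance analytically at fixed h2, using
# dense solves (no eigendecomposition) — the brute-force oracle route
dense_profile_loglik <- function(h2, y, A, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  S <- h2 * unclass(A) + (1 - h2) * diag(n)
  Si <- solve(S)
  beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
  r <- as.numeric(y - X %*% beta)
  sigma2 <- as.numeric(t(r) %*% Si %*% r) / n
  -n / 2 * log(2 * pi) - n / 2 * log(sigma2) -
    0.5 * determinant(S, logarithm = TRUE)$modulus - n / 2
}

# brute-force grid oracle for ancestral states: coordinate-wise grid
# search (coarse-to-fine) maximizing the joint BM log-likelihood, i.e.
# minimizing sum over edges of (x_child - x_parent)^2 / branch length
asr_grid_oracle <- function(tree, x, n_rounds = 40) {
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  states <- c(x, rep(mean(x), nn))
  obj <- function(s) {
    d <- s[tree$edge[, 2]] - s[tree$edge[, 1]]
    sum(d^2 / tree$edge.length)
  }
  width <- diff(range(x))
  for (round in seq_len(n_rounds)) {
    for (node in n + seq_len(nn)) {
      grid <- states[node] + seq(-width, width, length.out = 21)
      vals <- vapply(grid, function(g) {
        s <- states; s[node] <- g; obj(s)
      }, numeric(1))
      states[node] <- grid[which.min(vals)]
    }
    width <- width * 0.5
  }
  states[n + seq_len(nn)]
}

# joint-likelihood oracle for ancestral states: under BM the negative
# joint log-likelihood is sum over edges of (x_child - x_parent)^2 / len,
# minimized by a weighted graph-Laplacian solve over internal nodes
asr_laplacian_oracle <- function(tree, x) {
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  m <- n + nn
  W <- matrix(0, m, m)
  for (k in seq_len(nrow(tree$edge))) {
    i <- tree$edge[k, 1]; j <- tree$edge[k, 2]
    w <- 1 / tree$edge.length[k]
    W[i, j] <- W[i, j] + w
    W[j, i] <- W[j, i] + w
  }
  L <- diag(rowSums(W)) - W
  int <- (n + 1):m
  tip <- 1:n
  # solve L[int,int] z = -L[int,tip] x
  as.numeric(solve(L[int, int], -L[int, tip, drop = FALSE] %*% x))
}
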