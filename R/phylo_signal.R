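#' Simulate Brownian-motion trait evolution at the tips
#'
#' One multivariate-normal draw with mean `root_state` and covariance
#' `sigma2_bm * bm_covariance(tree)`.
#'
#' @param tree An [ape::phylo] with branch lengths.
#' @param sigma2_bm Brownian rate (trait variance per Ma), > 0.
#' @param root_state Trait value at the root.
#' @param n Number of independent replicate draws (default 1).
#' @return If `n = 1`, a named vector of tip values; otherwise a tips-by-n
#'   matrix.
#' @export
simulate_bm <- function(tree, sigma2_bm = 1, root_state = 0, n = 1) {
  stopifnot(sigma2_bm > 0)
  V <- bm_covariance(tree)
  L <- t(chol(V + diag(1e-12 * max(diag(V)), nrow(V))))
  z <- matrix(stats::rnorm(nrow(V) * n), nrow(V), n)
  x <- root_state + sqrt(sigma2_bm) * (L %*% z)
  rownames(x) <- tree$tip.label
  if (n == 1L) x[, 1] else x
}

# GLS phylogenetic mean and its machinery; Vi is solve(V)
.phylo_mean <- function(Vi, x) {
  ones <- rep(1, nrow(Vi))
  sum(Vi %*% x) / sum(Vi)
}

#' Blomberg's K statistic
#'
#' Ratio of the observed mean squared error of tip values about the
#' phylogenetically corrected mean (ordinary MSE0) to the GLS mean squared
#' error under the Brownian covariance (MSE), scaled by its expectation
#' under Brownian motion, `(tr(V) - n / sum(V^-1)) / (n - 1)`. K near 1 is
#' consistent with Brownian drift; K < 1 indicates less phylogenetic
#' signal than Brownian motion predicts.
#'
#' @param tree An [ape::phylo].
#' @param values Tip trait values (named by tip label, or in tip order).
#' @return The K value (scalar, >= 0).
#' @export
blomberg_k <- function(tree, values) {
  x <- .match_tip_values(tree, values)
  n <- length(x)
  if (n < 4L) stop("blomberg_k: need at least 4 tips")
  if (stats::var(x) == 0) stop("blomberg_k: trait values are constant")
  V <- bm_covariance(tree)
  Vi <- solve(V)
  a <- .phylo_mean(Vi, x)
  d <- x - a
  mse0 <- sum(d^2) / (n - 1)
  mse <- as.numeric(t(d) %*% Vi %*% d) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test of phylogenetic signal
#'
#' Computes Blomberg's K for the observed data and a permutation p-value
#' by shuffling trait values across tips. Significance is judged on the
#' variance of standardized independent contrasts: data with phylogenetic
#' signal have lower contrast variance than tip-shuffled data, so
#' `p = (1 + #permutations with contrast variance <= observed) / (1 + n_perm)`.
#'
#' @param tree An [ape::phylo].
#' @param values Tip trait values.
#' @param n_perm Number of permutations (>= 99).
#' @return An object of class `blomberg_result`: list with `K`, `p`,
#'   `n_perm`, `contrast_var_obs`.
#' @export
phylosignal_test <- function(tree, values, n_perm = 999) {
  if (n_perm < 99) stop("phylosignal_test: n_perm must be at least 99")
  x <- .match_tip_values(tree, values)
  K <- blomberg_k(tree, x)
  obs <- stats::var(independent_contrasts(tree, x)$contrasts)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    xp <- stats::setNames(sample(x), names(x))
    if (stats::var(independent_contrasts(tree, xp)$contrasts) <= obs) {
      hits <- hits + 1L
    }
  }
  out <- list(K = K, p = (1 + hits) / (1 + n_perm), n_perm = n_perm,
              contrast_var_obs = obs)
  class(out) <- "blomberg_result"
  out
}

#' @export
print.blomberg_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f  (permutation p = %.4g, %d permutations)\n",
              x$K, x$p, x$n_perm))
  invisible(x)
}

#' Phylogenetic ANOVA with a Brownian-motion simulation null
#'
#' The observed F statistic from an ordinary one-way ANOVA of tip values by
#' group is compared to a null distribution of F statistics computed from
#' `n_sim` Brownian simulations on the tree, with the Brownian rate
#' estimated from the data via independent contrasts. Per-group p-values
#' compare each group mean's deviation from the grand mean to its simulated
#' distribution (two-sided).
#'
#' @param tree An [ape::phylo]; tips are species.
#' @param groups Group (genus) label per tip, named by tip label or in tip
#'   order.
#' @param values Tip trait values.
#' @param n_sim Number of Brownian null simulations (default 1000).
#' @return An object of class `phylo_anova_result`: list with `F`,
#'   `p_phylo`, `per_group_p` (named vector), `sigma2_hat`, `n_sim`.
#' @export
phylo_anova <- function(tree, groups, values, n_sim = 1000) {
  x <- .match_tip_values(tree, values)
  if (is.null(names(groups))) {
    stopifnot(length(groups) == ape::Ntip(tree))
    names(groups) <- tree$tip.label
  }
  g <- groups[tree$tip.label]
  keep <- !is.na(x) & !is.na(g)
  dropped <- unique(g[!keep & !is.na(g)])
  dropped <- setdiff(dropped, unique(g[keep]))
  if (length(dropped) > 0L) {
    warning("phylo_anova: dropping group(s) with no values: ",
            paste(dropped, collapse = ", "))
    tree <- ape::drop.tip(tree, tree$tip.label[!keep])
    x <- x[keep]; g <- g[keep]
  }
  g <- factor(g)
  if (nlevels(g) < 2L) stop("phylo_anova: need at least 2 groups")
  F_obs <- .anova_f(x, g)
  if (stats::var(x) == 0) {
    # identical tip values: no evidence of group differences at all
    out <- list(F = 0, p_phylo = 1,
                per_group_p = stats::setNames(rep(1, nlevels(g)), levels(g)),
                sigma2_hat = 0, n_sim = n_sim)
    class(out) <- "phylo_anova_result"
    return(out)
  }
  sigma2 <- independent_contrasts(tree, x)$sigma2
  sims <- simulate_bm(tree, sigma2_bm = sigma2, root_state = 0, n = n_sim)
  F_sim <- apply(sims, 2, .anova_f, g = g)
  p_phylo <- (1 + sum(F_sim >= F_obs)) / (1 + n_sim)
  # per-group deviation of group mean from the grand mean, two-sided
  dev_obs <- abs(tapply(x, g, mean) - mean(x))
  grp_means <- rowsum(sims, g) / as.vector(table(g))
  dev_sim <- abs(sweep(grp_means, 2, colMeans(sims)))
  per_group_p <- (1 + rowSums(dev_sim >=
                                as.numeric(dev_obs[rownames(dev_sim)]))) /
    (1 + n_sim)
  names(per_group_p) <- rownames(dev_sim)
  out <- list(F = F_obs, p_phylo = p_phylo, per_group_p = per_group_p,
              sigma2_hat = sigma2, n_sim = n_sim)
  class(out) <- "phylo_anova_result"
  out
}

# one-way ANOVA F statistic (0 when all values identical)
.anova_f <- function(x, g) {
  n <- length(x); k <- nlevels(g)
  gm <- mean(x)
  means <- tapply(x, g, mean)
  cnt <- as.vector(table(g))
  ssb <- sum(cnt * (means - gm)^2)
  ssw <- sum((x - means[g])^2)
  if (ssw == 0) {
    if (ssb == 0) return(0)
    return(Inf)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' @export
print.phylo_anova_result <- function(x, ...) {
  cat(sprintf("Phylogenetic ANOVA: F = %.3f, simulation p = %.4g (%d sims)\n",
              x$F, x$p_phylo, x$n_sim))
  cat("Per-group p-values:\n")
  print(round(x$per_group_p, 4))
  invisible(x)
}
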