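test_that("Brownian tip covariance has shared-path entries", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- bm_covariance(tree)
  expect_equal(unname(V), matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3))

  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(4, 6)
  expect_equal(unname(bm_covariance(star)), 4 * diag(6))

  set.seed(2)
  rt <- ape::rcoal(20)
  expect_equal(bm_covariance(rt), ape::vcv(rt))
  ev <- eigen(bm_covariance(rt), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * max(ev))
})

test_that("taxon grafting splits the sister branch and is invertible", {
  tree <- balanced_test_tree(8, depth = 10)
  g <- graft_taxon(tree, "Presbytis_rubicunda", "t1", 1.3)
  expect_true("Presbytis_rubicunda" %in% g$tip.label)
  expect_true(attr(g, "ultrametric"))
  term <- g$edge.length[g$edge[, 2] == match("Presbytis_rubicunda",
                                             g$tip.label)]
  expect_equal(term, 1.3)
  sis <- g$edge.length[g$edge[, 2] == match("t1", g$tip.label)]
  expect_equal(sis, 1.3)

  back <- ape::drop.tip(g, "Presbytis_rubicunda")
  expect_equal(bm_covariance(back), bm_covariance(tree))

  expect_error(graft_taxon(tree, "X", "t1", 99), "younger")
  expect_error(graft_taxon(tree, "t2", "t1", 1), "already present")
})

test_that("BM simulation has the right first two moments and is seeded", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  set.seed(8)
  x <- simulate_bm(tree, sigma2_bm = 2, root_state = 5, n = 1e4)
  means <- rowMeans(x)
  # mean = root state within 3 Monte-Carlo SEs
  se <- sqrt(2 * 2 / 1e4)
  expect_true(all(abs(means - 5) < 3 * se))
  # tip variance = sigma2 * depth within 5%
  vars <- apply(x, 1, var)
  expect_true(all(abs(vars / (2 * 2) - 1) < 0.05))
  set.seed(8)
  expect_identical(simulate_bm(tree, 2, 5, n = 1e4), x)
})

test_that("independent contrasts match the analytical cherry and ape::pic", {
  cherry <- ape::read.tree(text = "((A:1.5,B:2.5):1,C:3.5);")
  ic <- independent_contrasts(cherry, c(A = 1, B = 4, C = 0))
  expect_true(any(abs(abs(ic$contrasts) - abs((1 - 4) / sqrt(1.5 + 2.5))) <
                    1e-12))
  expect_length(ic$contrasts, 2)

  set.seed(12)
  tr <- ape::rcoal(25)
  x <- stats::setNames(rnorm(25), tr$tip.label)
  mine <- sort(abs(independent_contrasts(tr, x)$contrasts))
  ref <- sort(abs(as.numeric(ape::pic(x[tr$tip.label], tr))))
  expect_equal(mine, ref)

  # contrast variance estimates the BM rate
  set.seed(13)
  tr2 <- balanced_test_tree(16, 10)
  sims <- simulate_bm(tr2, sigma2_bm = 0.5, root_state = 0, n = 400)
  s2 <- apply(sims, 2, function(v)
    independent_contrasts(tr2, stats::setNames(v, tr2$tip.label))$sigma2)
  expect_lt(abs(mean(s2) - 0.5), 0.05 * 0.5)
})

test_that("Blomberg's K matches picante and behaves under the null", {
  set.seed(21)
  tr <- ape::rcoal(15)
  x <- stats::setNames(rnorm(15, 1, 0.2), tr$tip.label)
  expect_equal(blomberg_k(tr, x),
               as.numeric(picante::Kcalc(x[tr$tip.label], tr)))

  # iid data on a star tree: both MSE ratios are ordinary, K ~ 1 on average
  star <- ape::stree(12, type = "star")
  star$edge.length <- rep(3, 12)
  set.seed(22)
  ks <- replicate(300, blomberg_k(star, stats::setNames(rnorm(12),
                                                        star$tip.label)))
  expect_lt(abs(mean(ks) - 1), 0.1)

  expect_error(blomberg_k(tr, stats::setNames(rep(1, 15), tr$tip.label)),
               "constant")
  expect_error(blomberg_k(ape::read.tree(text = "((A:1,B:1):1,C:2);"),
                          c(A = 1, B = 2, C = 3)), "4 tips")
})

test_that("phylogenetic signal permutation test detects and calibrates", {
  # maximal signal: two clades with internally identical, distinct values
  tr <- balanced_test_tree(16, 10)
  x <- stats::setNames(rep(c(0, 10), each = 8), tr$tip.label)
  set.seed(31)
  res <- phylosignal_test(tr, x, n_perm = 999)
  expect_lte(res$p, 0.01)

  expect_error(phylosignal_test(tr, x, n_perm = 10), "at least 99")

  # no signal on a star tree: p roughly uniform
  star <- ape::stree(10, type = "star")
  star$edge.length <- rep(2, 10)
  set.seed(32)
  ps <- replicate(200, {
    phylosignal_test(star, stats::setNames(rnorm(10), star$tip.label),
                     n_perm = 99)$p
  })
  expect_lt(abs(mean(ps) - 0.5), 0.08)
  expect_gt(mean(ps < 0.25), 0.15); expect_lt(mean(ps < 0.25), 0.35)
})

test_that("phylogenetic ANOVA finds real group effects, not affine artefacts", {
  tr <- balanced_test_tree(16, 10)
  groups <- stats::setNames(rep(c("g1", "g2", "g3", "g4"), each = 4),
                            tr$tip.label)
  set.seed(41)
  x <- simulate_bm(tr, sigma2_bm = 0.1, root_state = 1)
  wsd <- mean(tapply(x, groups[names(x)], sd))
  x_eff <- x + (groups[names(x)] == "g2") * 10 * wsd
  res <- phylo_anova(tr, groups, x_eff, n_sim = 999)
  expect_lte(res$p_phylo, 0.01)
  expect_lte(res$per_group_p[["g2"]], 0.05)

  # affine invariance of the p-value (identical RNG stream)
  set.seed(42)
  p1 <- phylo_anova(tr, groups, x_eff, n_sim = 199)$p_phylo
  set.seed(42)
  p2 <- phylo_anova(tr, groups, 3.2 * x_eff - 7, n_sim = 199)$p_phylo
  expect_identical(p1, p2)

  # degenerate inputs
  const <- stats::setNames(rep(1, 16), tr$tip.label)
  set.seed(43)
  res0 <- phylo_anova(tr, groups, const, n_sim = 199)
  expect_equal(res0$F, 0)
  expect_equal(res0$p_phylo, 1)
})

test_that("ML ancestral states equal GLS re-rooted means and stay in the tip hull", {
  # near-zero stem cherry: root is the simple midpoint
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(bm_root_estimate(tr, c(A = 0, B = 4)), 2)
  # asymmetric two-tip case: precision-weighted mean (0/1 + 4/3)/(1 + 1/3)
  tr2 <- ape::read.tree(text = "(A:1,B:3);")
  expect_equal(bm_root_estimate(tr2, c(A = 0, B = 4)), 1)

  # joint-likelihood oracle agreement on small trees
  set.seed(51)
  for (n in c(4, 5)) {
    tr <- ape::rcoal(n)
    x <- stats::setNames(rnorm(n), tr$tip.label)
    a <- ml_asr(tr, x)
    oracle <- asr_laplacian_oracle(tr, x[tr$tip.label])
    expect_lt(max(abs(a$nodes$estimate - oracle)), 1e-4)
  }

  # cross-check estimates against phytools on a larger tree
  set.seed(52)
  tr <- ape::rcoal(20)
  x <- stats::setNames(rnorm(20, 1, 0.3), tr$tip.label)
  a <- ml_asr(tr, x)
  fa <- phytools::fastAnc(tr, x)
  expect_lt(max(abs(a$nodes$estimate - as.numeric(fa))), 1e-8)

  # convex-hull property on random trees
  set.seed(53)
  for (rep in 1:10) {
    tr <- ape::rtree(12)
    x <- stats::setNames(rcauchy(12), tr$tip.label)  # heavy tails on purpose
    a <- ml_asr(tr, x)
    expect_true(all(a$nodes$estimate >= min(x) - 1e-10))
    expect_true(all(a$nodes$estimate <= max(x) + 1e-10))
    expect_true(all(a$nodes$ci_lo <= a$nodes$estimate))
    expect_true(all(a$nodes$ci_hi >= a$nodes$estimate))
  }

  expect_error(ml_asr(tr, x[-1]), "missing")
})

test_that("ASR nodes are addressable by MRCA tip sets", {
  tr <- balanced_test_tree(8, 10)
  set.seed(61)
  x <- stats::setNames(rnorm(8, 1, 0.1), tr$tip.label)
  a <- ml_asr(tr, x)
  row <- asr_at_mrca(a, c("t1", "t2"))
  expect_equal(row$node, ape::getMRCA(tr, c("t1", "t2")))
  root_row <- asr_at_mrca(a, tr$tip.label)
  expect_equal(root_row$node, ape::Ntip(tr) + 1L)
  expect_error(asr_at_mrca(a, c("t1", "zz")), "unknown tip")
})
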