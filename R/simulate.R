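#' Simulate a multi-generation breeding pedigree
#'
#' Non-overlapping generations: founders are unrelated; in each later
#' generation, mating pairs are drawn at random from the previous
#' generation avoiding full- and half-sibling matings (mirroring a colony
#' genetically managed to minimize inbreeding). Each generation adds
#' `mean_offspring` offspring per pedigree member accumulated so far, so
#' the expected total size is `n_founders * (1 + mean_offspring)^
#' (n_generations - 1)`. Offspring sex is drawn at a 2:1 female:male
#' ratio (the composition typical of managed breeding colonies); ages
#' decrease by generation.
#'
#' @param n_founders Number of founders.
#' @param n_generations Total generations including founders (>= 1).
#' @param mean_offspring Expected offspring per parent (rate of the
#'   branching process).
#' @return A `pedigree_table` with a `generation` column.
#' @export
simulate_pedigree <- function(n_founders = 50, n_generations = 3,
                              mean_offspring = 1.5) {
  stopifnot(n_founders >= 2, n_generations >= 1)
  id_fmt <- function(gen, i) sprintf("G%d_%03d", gen, i)
  sex <- sample(c("F", "M"), n_founders, replace = TRUE,
                prob = c(2 / 3, 1 / 3))
  # guarantee both sexes among founders
  if (length(unique(sex)) == 1L) sex[1] <- setdiff(c("F", "M"), sex[1])
  ped <- data.frame(id = id_fmt(1, seq_len(n_founders)),
                    sire = NA_character_, dam = NA_character_,
                    sex = sex, generation = 1L,
                    stringsAsFactors = FALSE)
  for (gen in seq_len(n_generations - 1L) + 1L) {
    prev <- ped[ped$generation == gen - 1L, ]
    females <- prev$id[prev$sex == "F"]
    males <- prev$id[prev$sex == "M"]
    if (length(females) == 0L || length(males) == 0L) break
    target <- round(nrow(ped) * mean_offspring)
    sire_of <- stats::setNames(ped$sire, ped$id)
    dam_of <- stats::setNames(ped$dam, ped$id)
    parents_of <- function(i) c(sire_of[[i]], dam_of[[i]])
    kids <- list()
    n_new <- 0L
    attempts <- 0L
    while (n_new < target && attempts < 50L * target) {
      attempts <- attempts + 1L
      dam <- sample(females, 1L)
      sire <- sample(males, 1L)
      # avoid full- and half-sib matings among non-founders
      pd <- parents_of(dam); ps <- parents_of(sire)
      if (any(!is.na(pd) & !is.na(ps) & pd %in% ps[!is.na(ps)])) next
      n_new <- n_new + 1L
      kids[[n_new]] <- data.frame(
        id = id_fmt(gen, n_new), sire = sire, dam = dam,
        sex = sample(c("F", "M"), 1L, prob = c(2 / 3, 1 / 3)),
        generation = gen, stringsAsFactors = FALSE)
    }
    if (n_new > 0L) ped <- rbind(ped, do.call(rbind, kids))
  }
  # ages: older generations are older, a few years of within-cohort spread
  base_age <- 8 + 6 * (max(ped$generation) - ped$generation)
  ped$age <- round(base_age + stats::runif(nrow(ped), 0, 4), 1)
  as_pedigree_table(ped)
}

#' Simulate an additive-genetic trait on a pedigree
#'
#' Generates `y = X beta + g + e` where the breeding values g have
#' covariance `h2_true * sigma_P2_true * A`. Breeding values are generated
#' by the Mendelian-sampling recursion — founders draw
#' `N(0, sigma_G2)`; an offspring draws the parental midpoint plus a
#' Mendelian deviation with variance `sigma_G2 (1/2 - (F_s + F_d)/4)` —
#' so no matrix factorization is needed and the implied covariance is
#' exactly `sigma_G2 A`. Sex and age enter as fixed effects in trait-SD
#' units.
#'
#' @param ped A `pedigree_table` (with `sex` and `age` columns).
#' @param h2_true True narrow-sense heritability in [0, 1].
#' @param sigma_P2_true True phenotypic variance (> 0).
#' @param sex_effect Additive effect of male sex, in phenotypic SD units.
#' @param age_slope Effect per year of age, in phenotypic SD units.
#' @return Named numeric vector of trait values (names = pedigree ids) with
#'   attribute `breeding_values`.
#' @export
simulate_pedigree_traits <- function(ped, h2_true = 0.5, sigma_P2_true = 1,
                                     sex_effect = 0, age_slope = 0) {
  stopifnot(h2_true >= 0, h2_true <= 1, sigma_P2_true > 0)
  sigma_G2 <- h2_true * sigma_P2_true
  sigma_E2 <- (1 - h2_true) * sigma_P2_true
  ord <- pedigree_order(ped)
  rows <- as.data.frame(ped)[match(ord, ped$id), ]
  n_all <- length(ord)
  g <- numeric(n_all)
  f_inbr <- numeric(n_all)  # inbreeding coefficients
  sire_i <- match(rows$sire, ord)
  dam_i <- match(rows$dam, ord)
  kin <- kinship_pairs(ped)  # memoized pairwise kinship, no full matrix
  for (i in seq_len(n_all)) {
    s <- sire_i[i]; d <- dam_i[i]
    if (is.na(s) || is.na(d)) {
      g[i] <- stats::rnorm(1, 0, sqrt(sigma_G2))
    } else {
      ms_var <- sigma_G2 * (0.5 - (f_inbr[s] + f_inbr[d]) / 4)
      g[i] <- (g[s] + g[d]) / 2 + stats::rnorm(1, 0, sqrt(ms_var))
      f_inbr[i] <- kin(rows$sire[i], rows$dam[i])
    }
  }
  names(g) <- ord
  g <- g[ped$id]
  sd_p <- sqrt(sigma_P2_true)
  xb <- numeric(nrow(ped))
  if (sex_effect != 0) xb <- xb + sex_effect * sd_p * (ped$sex == "M")
  if (age_slope != 0 && !is.null(ped$age)) {
    xb <- xb + age_slope * sd_p * (ped$age - mean(ped$age, na.rm = TRUE))
  }
  y <- xb + g + stats::rnorm(nrow(ped), 0, sqrt(sigma_E2))
  names(y) <- ped$id
  attr(y, "breeding_values") <- g
  y
}

#' Simulate crown measurements with known target traits
#'
#' Builds a long-format measurement table whose specimens realise given
#' MMC, PMM and IC targets. Per specimen, M1 length and breadth are drawn
#' lognormally around the size target, then M3 length = MMC x M1 length,
#' M2 length = PMM x P4 length (P4 set to a fixed fraction of M1), and
#' breadths chosen so the M3/M1 area ratio equals IC; every metric is then
#' perturbed by lognormal noise with coefficient of variation `cv`. Both
#' sides are emitted; left-side entries are removed at random with
#' probability `missing_left` to exercise the side-resolution rule.
#'
#' @param taxa Data frame with columns `genus`, `species`, `mmc`, `pmm`,
#'   `ic`, `m1_length` (mm) and `n` (specimens per taxon).
#' @param cv Lognormal noise coefficient of variation (>= 0, default 0.05).
#' @param missing_left Probability a left-side row is dropped (default 0).
#' @return A `measurement_table`.
#' @export
simulate_crown_measurements <- function(taxa, cv = 0.05, missing_left = 0) {
  stopifnot(is.data.frame(taxa))
  if (cv < 0) stop("simulate_crown_measurements: cv must be non-negative")
  sdlog <- sqrt(log(1 + cv^2))
  noisy <- function(x) x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
  rows <- list()
  spec_counter <- 0L
  for (t in seq_len(nrow(taxa))) {
    for (k in seq_len(taxa$n[t])) {
      spec_counter <- spec_counter + 1L
      sid <- sprintf("%s_%s_%03d", substr(taxa$genus[t], 1, 3),
                     substr(taxa$species[t], 1, 3), spec_counter)
      m1_len <- taxa$m1_length[t]
      m1_bl <- 0.8 * m1_len
      p4_len <- 0.7 * m1_len
      m3_len <- taxa$mmc[t] * m1_len
      m2_len <- taxa$pmm[t] * p4_len
      m2_bl <- 0.85 * m2_len
      p4_bl <- 0.9 * p4_len
      # breadth so that (m3_len * m3_bl) / (m1_len * m1_bl) = ic
      m3_bl <- taxa$ic[t] * m1_len * m1_bl / m3_len
      for (side in c("L", "R")) {
        if (side == "L" && missing_left > 0 &&
            stats::runif(1) < missing_left) next
        md <- noisy(c(p4_len, m1_len, m2_len, m3_len))
        bl <- noisy(c(p4_bl, m1_bl, m2_bl, m3_bl))
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = sid, genus = taxa$genus[t],
          species = taxa$species[t], side = side,
          tooth = c("P4", "M1", "M2", "M3"),
          md_length = md, bl_breadth = bl,
          stringsAsFactors = FALSE)
      }
    }
  }
  as_measurement_table(do.call(rbind, rows))
}

#' Simulate trait evolution on a chronogram with fossil sampling
#'
#' Runs one Brownian-motion realization recorded at every node and tip of
#' the tree, then samples noisy "fossil" observations at the requested
#' internal nodes: `fossil = true node state + N(0, obs_sd^2) -
#' trend * node_age`. `trend` is the per-Ma change of the trait toward the
#' present; a negative trend (trait decreasing through time) makes older
#' fossils carry higher values than the extant tips, the regime under which
#' ancestral state reconstruction from extant data systematically
#' under-estimates fossil values.
#'
#' @param tree Ultrametric [ape::phylo].
#' @param sigma2_bm Brownian rate.
#' @param root_state Trait value at the root.
#' @param fossil_nodes Internal node numbers to sample (default: all).
#' @param obs_sd Fossil observation noise SD (>= 0).
#' @param trend Per-Ma trait change toward the present (0 = unbiased
#'   sampling; negative = trait decreased through time).
#' @return List with `tip_values` (named), `node_states` (true values,
#'   named by node number), `fossils` (data frame: node, node_age,
#'   true_state, observed).
#' @export
simulate_clade <- function(tree, sigma2_bm = 0.01, root_state = 1,
                           fossil_nodes = NULL, obs_sd = 0, trend = 0) {
  stopifnot(obs_sd >= 0)
  n <- ape::Ntip(tree)
  root <- n + 1L
  nnode <- tree$Nnode
  depths <- ape::node.depth.edgelength(tree)
  tree_depth <- max(depths[seq_len(n)])
  x <- numeric(n + nnode)
  x[root] <- root_state
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    par <- pre$edge[k, 1]; child <- pre$edge[k, 2]
    x[child] <- x[par] + stats::rnorm(1, 0, sqrt(sigma2_bm * pre$edge.length[k]))
  }
  tip_values <- stats::setNames(x[seq_len(n)], tree$tip.label)
  node_states <- stats::setNames(x[n + seq_len(nnode)], n + seq_len(nnode))
  if (is.null(fossil_nodes)) fossil_nodes <- n + seq_len(nnode)
  node_age <- tree_depth - depths[fossil_nodes]
  fossils <- data.frame(
    node = fossil_nodes,
    node_age = node_age,
    true_state = x[fossil_nodes],
    observed = x[fossil_nodes] + stats::rnorm(length(fossil_nodes), 0, obs_sd) -
      trend * node_age)
  list(tip_values = tip_values, node_states = node_states, fossils = fossils)
}
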