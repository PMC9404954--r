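test_that("tabular relationship matrix matches hand calculations", {
  A <- kinship_matrix(trio_pedigree())
  expect_equal(A["f", "c"], 0.5)
  expect_equal(A["m", "c"], 0.5)
  expect_equal(A["f", "m"], 0)
  expect_equal(diag(unclass(A)), rep(1, 3), ignore_attr = TRUE)

  A2 <- kinship_matrix(inbred_pedigree())
  expect_equal(A2["a", "b"], 0.5)      # full sibs
  expect_equal(A2["x", "x"], 1.25)     # offspring of full-sib mating
  expect_equal(A2["a", "x"], 0.75)
  # half sibs
  half <- as_pedigree_table(data.frame(
    id = c("f", "m1", "m2", "a", "b"), sire = c(NA, NA, NA, "f", "f"),
    dam = c(NA, NA, NA, "m1", "m2"), sex = c("M", "F", "F", "M", "M")))
  expect_equal(kinship_matrix(half)["a", "b"], 0.25)
  # PSD
  expect_gte(min(eigen(unclass(A2), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-12)
})

test_that("pairwise kinship agrees with the tabular matrix", {
  set.seed(9)
  ped <- simulate_pedigree(12, 3, 1.5)
  A <- kinship_matrix(ped)
  kin <- kinship_pairs(ped)
  ids <- sample(ped$id, 6)
  for (i in ids) for (j in ids) {
    expect_equal(2 * kin(i, j), A[i, j])
  }
})

test_that("inverse normal transform uses Blom offsets and preserves ranks", {
  z <- inverse_normal(c(5, 1, 9))
  expect_equal(round(z, 2), c(0, -0.87, 0.87))
  expect_equal(z, qnorm((c(2, 1, 3) - 3 / 8) / 3.25))

  set.seed(4)
  x <- rnorm(40)
  expect_equal(rank(inverse_normal(x)), rank(x))
  # monotone relabeling changes nothing
  expect_equal(inverse_normal(exp(x)), inverse_normal(x))
  # Blom scores are symmetric: sample mean 0 for tie-free input
  expect_lt(abs(mean(inverse_normal(x))), 1e-6)
  expect_error(inverse_normal(c(1, 2)), "at least 3")
})

test_that("boundary and non-boundary LRT p-values are correct", {
  expect_equal(lrt_pvalue(0, 0, boundary = TRUE), 0.5)
  expect_equal(lrt_pvalue(2.706 / 2, 0, boundary = TRUE), 0.05,
               tolerance = 1e-3)
  expect_equal(lrt_pvalue(3.841 / 2, 0, boundary = FALSE, df = 1), 0.05,
               tolerance = 1e-3)
  expect_error(lrt_pvalue(0, 1), "optimization failure")
})

test_that("profile likelihood maximum matches the dense grid oracle", {
  set.seed(11)
  ped <- as_pedigree_table(data.frame(
    id = sprintf("i%02d", 1:10),
    sire = c(NA, NA, NA, NA, "i01", "i01", "i01", "i05", "i05", NA),
    dam = c(NA, NA, NA, NA, "i02", "i02", "i03", "i04", "i06", NA),
    sex = c("M", "F", "F", "F", "M", "F", "M", "F", "M", "M")))
  A <- kinship_matrix(ped)
  y <- stats::setNames(as.numeric(t(chol(unclass(A) * 0.6 + diag(10) * 0.4)) %*%
                                    rnorm(10)), ped$id)
  fit <- fit_variance_components(y, A)
  grid <- seq(0, 0.999, by = 0.001)
  ll_grid <- vapply(grid, dense_profile_loglik, numeric(1),
                    y = unname(y), A = A)
  expect_lt(abs(fit$loglik - max(ll_grid)), 1e-6)
  expect_lt(abs(fit$h2 - grid[which.max(ll_grid)]), 2e-3)
  # variance components always sum exactly and h2 is proper
  expect_equal(fit$sigma_G2 + fit$sigma_E2, fit$sigma_P2)
  expect_gte(fit$h2, 0); expect_lte(fit$h2, 1)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("identity relationship matrix raises the unidentifiability flag", {
  A <- diag(30)
  dimnames(A) <- list(sprintf("i%02d", 1:30), sprintf("i%02d", 1:30))
  y <- stats::setNames(rnorm(30), rownames(A))
  fit <- fit_variance_components(y, A)
  expect_true(fit$unidentifiable)
})

test_that("null p-values under h2 = 0 are uniform-conservative", {
  set.seed(20)
  ped <- simulate_pedigree(40, 3, 1.5)
  A <- kinship_matrix(ped)
  eig <- eigen(unclass(A), symmetric = TRUE)
  p <- replicate(500, {
    y <- stats::setNames(rnorm(nrow(ped)), ped$id)
    fit_variance_components(y, A, eig = eig)$p_h2
  })
  expect_gte(mean(p < 0.05), 0.02)
  expect_lte(mean(p < 0.05), 0.08)
})

test_that("covariate screening retains real effects and drops constants", {
  set.seed(31)
  ped <- simulate_pedigree(60, 3, 1.5)
  n <- nrow(ped)
  A <- kinship_matrix(ped)
  # a 2-SD sex effect is always detected at n ~ 400
  y <- simulate_pedigree_traits(ped, h2_true = 0.4, sigma_P2_true = 1,
                                sex_effect = 2)
  covars <- data.frame(sex = ped$sex, age = ped$age)
  scr <- screen_covariates(y, covars, A = A)
  expect_true("sex" %in% scr$retained)
  expect_lt(scr$p_values["sex"], 1e-6)

  # constant covariate dropped with a warning
  expect_warning(
    scr2 <- screen_covariates(y, data.frame(sex = ped$sex,
                                            cage = rep(1, n)), A = A),
    "constant covariate")
  expect_false("cage" %in% names(scr2$p_values))
})

test_that("null covariates are retained at about the screening alpha", {
  set.seed(32)
  n <- 150
  ids <- sprintf("i%03d", 1:n)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  hits <- replicate(400, {
    y <- stats::setNames(rnorm(n), ids)
    covar <- data.frame(z = rnorm(n))
    length(screen_covariates(y, covar, A = NULL, alpha = 0.05)$retained) > 0
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("covariate variance proportion is a clamped variance ratio", {
  expect_equal(covariate_variance_proportion(100, 62), 0.38)
  expect_equal(covariate_variance_proportion(100, 100), 0)
  expect_warning(p <- covariate_variance_proportion(100, 105), "clamped")
  expect_equal(p, 0)
  expect_error(covariate_variance_proportion(0, 1), "var_raw")
})

test_that("covariate-burden subset means on the printed heritability table", {
  t3 <- load_fixture("table3")
  areas <- t3$trait[t3$trait_type == "area" & t3$significant]
  gp <- t3$trait[t3$trait_type == "gp" & t3$significant]
  expect_equal(length(areas), 5)
  expect_equal(sort(gp), sort(c("R IC", "L PMM", "R PMM")))
  expect_equal(round(covariate_prop_mean(t3, areas), 2), 0.38)
  expect_equal(round(covariate_prop_mean(t3, gp), 2), 0.05)
  # identity on a one-row subset
  expect_equal(covariate_prop_mean(t3, "L MMC"), 0.082)
  expect_error(covariate_prop_mean(t3, "no such trait"), "empty subset")
})
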