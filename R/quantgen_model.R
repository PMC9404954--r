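#' Rank-based inverse normal transformation
#'
#' Blom-offset rank normalization: `z_i = qnorm((r_i - 3/8) / (n + 1/4))`
#' with mid-ranks for ties. Rank order is preserved; applied to residuals
#' before variance decomposition so the multivariate-normal likelihood is
#' well calibrated.
#'
#' @param residuals Numeric values, `n >= 3`.
#' @return Transformed values, same length and order.
#' @export
inverse_normal <- function(residuals) {
  ok <- !is.na(residuals)
  n <- sum(ok)
  if (n < 3L) stop("inverse_normal: need at least 3 non-missing values")
  out <- rep(NA_real_, length(residuals))
  r <- rank(residuals[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Likelihood-ratio test p-value with boundary correction
#'
#' `Lambda = 2 (loglik_full - loglik_null)`. For a parameter tested at the
#' boundary of its space (e.g. heritability against zero), the statistic is
#' asymptotically a 1/2:1/2 mixture of a point mass at zero and chi-square
#' with 1 df, so the p-value is half the chi-square tail probability (0.5
#' at Lambda = 0). Off-boundary tests use the plain chi-square tail with
#' `df` degrees of freedom.
#'
#' @param loglik_full,loglik_null Maximized log-likelihoods.
#' @param boundary Logical: is the null on the boundary?
#' @param df Degrees of freedom for the non-boundary case (default 1).
#' @param tol Tolerance for a slightly negative statistic (default 1e-6).
#' @return The p-value.
#' @export
lrt_pvalue <- function(loglik_full, loglik_null, boundary = TRUE, df = 1,
                       tol = 1e-6) {
  lambda <- 2 * (loglik_full - loglik_null)
  if (lambda < -tol) {
    stop("lrt_pvalue: full-model likelihood below null (optimization failure)")
  }
  lambda <- max(lambda, 0)
  if (boundary) {
    if (lambda == 0) return(0.5)
    return(0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE))
  }
  stats::pchisq(lambda, df = df, lower.tail = FALSE)
}

# core ML machinery: given eigendecomposition of A (restricted to the
# phenotyped individuals), profile log-likelihood at a fixed h2, with beta
# and total variance profiled out analytically.
.profile_loglik <- function(h2, ty, tX, d) {
  n <- length(ty)
  w <- h2 * d + (1 - h2)
  if (any(w <= 0)) return(-Inf)
  sw <- 1 / w
  XtWX <- crossprod(tX, tX * sw)
  XtWy <- crossprod(tX, ty * sw)
  beta <- solve(XtWX, XtWy)
  resid <- ty - tX %*% beta
  rss <- sum(resid^2 * sw)
  sigma_p2 <- rss / n
  -n / 2 * log(2 * pi) - n / 2 * log(sigma_p2) - sum(log(w)) / 2 - n / 2
}

#' Fit pedigree variance components by maximum likelihood
#'
#' Maximizes the multivariate-normal log-likelihood of
#' `y ~ N(X beta, sigma_G2 A + sigma_E2 I)` over (beta, sigma_G2,
#' sigma_E2), parameterized by heritability `h2 = sigma_G2 / sigma_P2` in
#' [0, 1). After a one-time eigendecomposition of A the likelihood is
#' profiled in 1-D over h2 with Brent's method; beta and the total variance
#' have closed-form profiles. The boundary-corrected likelihood-ratio test
#' against `h2 = 0` and a curvature-based standard error are reported.
#'
#' @param y Trait values, named by pedigree id (or in the order of `A`'s
#'   rows); individuals with `NA` are dropped.
#' @param A Additive relationship matrix from [kinship_matrix()].
#' @param X Fixed-effect design matrix (default intercept only). Rows must
#'   match `y`.
#' @param eig Optional pre-computed `eigen()` of `A` restricted to the
#'   phenotyped individuals (for repeated fits on one pedigree).
#' @return An object of class `variance_model`: list with `h2`, `h2_se`,
#'   `sigma_G2`, `sigma_E2`, `sigma_P2`, `loglik`, `loglik_null`, `p_h2`,
#'   `n_used`, `beta`, `boundary_flag`, `unidentifiable`.
#' @export
fit_variance_components <- function(y, A, X = NULL, eig = NULL) {
  if (!is.null(names(y)) && !is.null(rownames(A))) {
    keep <- names(y)[!is.na(y)]
    missing_ids <- setdiff(keep, rownames(A))
    if (length(missing_ids) > 0L) {
      stop("fit_variance_components: ids not in relationship matrix: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    }
    if (is.null(X)) X <- matrix(1, length(y), 1)
    X <- X[!is.na(y), , drop = FALSE]
    A <- A[keep, keep]
    y <- y[keep]
  } else {
    ok <- !is.na(y)
    if (is.null(X)) X <- matrix(1, length(y), 1)
    X <- X[ok, , drop = FALSE]
    A <- A[ok, ok]
    y <- y[ok]
  }
  n <- length(y)
  if (n < 3L) stop("fit_variance_components: too few phenotyped individuals")
  if (is.null(eig)) {
    eig <- eigen(unclass(A), symmetric = TRUE)
  }
  if (min(eig$values) < -1e-8 * max(eig$values)) {
    stop("fit_variance_components: relationship matrix not positive ",
         "semidefinite")
  }
  d <- pmax(eig$values, 0)
  ty <- as.numeric(crossprod(eig$vectors, y))
  tX <- crossprod(eig$vectors, X)
  # flat likelihood when A carries no family structure
  unident <- max(d) - min(d) < 1e-8
  ll_h2 <- function(h2) .profile_loglik(h2, ty, tX, d)
  opt <- stats::optimize(ll_h2, interval = c(0, 1 - 1e-6), maximum = TRUE,
                         tol = 1e-8)
  ll0 <- ll_h2(0)
  # boundary checks: optimize() never lands exactly on 0
  h2_hat <- opt$maximum
  loglik <- opt$objective
  if (ll0 >= loglik) {
    h2_hat <- 0
    loglik <- ll0
  }
  # recover the profiled parameters at the optimum
  w <- h2_hat * d + (1 - h2_hat)
  sw <- 1 / w
  beta <- solve(crossprod(tX, tX * sw), crossprod(tX, ty * sw))
  resid <- ty - tX %*% beta
  sigma_p2 <- sum(resid^2 * sw) / n
  # curvature-based SE from the profile likelihood
  h <- 1e-4
  h2m <- max(h2_hat - h, 0); h2p <- min(h2_hat + h, 1 - 1e-6)
  d2 <- (ll_h2(h2p) - 2 * ll_h2(h2_hat) + ll_h2(h2m)) /
    (((h2p - h2m) / 2)^2)
  h2_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  boundary_flag <- h2_hat < 0.02 || h2_hat > 0.98
  out <- list(
    h2 = h2_hat,
    h2_se = h2_se,
    h2_se_reliable = !boundary_flag && !unident && !is.na(h2_se),
    sigma_G2 = h2_hat * sigma_p2,
    sigma_E2 = (1 - h2_hat) * sigma_p2,
    sigma_P2 = sigma_p2,
    loglik = loglik,
    loglik_null = ll0,
    p_h2 = lrt_pvalue(loglik, ll0, boundary = TRUE),
    n_used = n,
    beta = as.numeric(beta),
    boundary_flag = boundary_flag,
    unidentifiable = unident
  )
  class(out) <- "variance_model"
  out
}

#' @export
print.variance_model <- function(x, ...) {
  cat(sprintf("h2 = %.3f (se %.3f)  p = %.4g  n = %d\n",
              x$h2, x$h2_se, x$p_h2, x$n_used))
  cat(sprintf("sigma_G2 = %.4g  sigma_E2 = %.4g  sigma_P2 = %.4g  logL = %.3f\n",
              x$sigma_G2, x$sigma_E2, x$sigma_P2, x$loglik))
  if (x$unidentifiable) cat("warning: no family structure (A ~ I); h2 unidentifiable\n")
  invisible(x)
}

#' Screen covariates within the variance-decomposition likelihood
#'
#' Each candidate covariate (sex, age) is tested by a non-boundary
#' chi-square(1) likelihood-ratio test comparing the polygenic model with
#' and without that covariate, the other candidates retained in both.
#' Covariates with `p < alpha` are kept and the residuals from the
#' retained-covariate mean model are returned. Constant covariates are
#' dropped with a warning. Screening is done on the raw trait scale; the
#' final residuals are what gets rank-normalized downstream.
#'
#' @param y Trait values named by pedigree id.
#' @param covars Data frame of candidate covariates (rows match `y`);
#'   factors/characters are expanded to dummies.
#' @param A Relationship matrix; pass `NULL` for an independence model
#'   (equivalent to ordinary regression screening).
#' @param alpha Retention threshold (default 0.05).
#' @return List with `retained` (character), `p_values` (named), `residuals`
#'   (named by id, from the retained mean model), `var_raw`,
#'   `var_resid_raw` (phenotypic variances before/after adjustment, for
#'   [covariate_variance_proportion()]).
#' @export
screen_covariates <- function(y, covars, A = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(covars), nrow(covars) == length(y))
  ok <- !is.na(y) & stats::complete.cases(covars)
  yy <- y[ok]
  cc <- covars[ok, , drop = FALSE]
  if (stats::var(yy) == 0) stop("screen_covariates: trait is constant")
  # expand to numeric columns, dropping constants
  cols <- list()
  for (nm in names(cc)) {
    v <- cc[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- as.numeric(factor(v)) - 1
    }
    if (length(unique(v)) < 2L) {
      warning("screen_covariates: dropping constant covariate ", nm)
      next
    }
    cols[[nm]] <- as.numeric(v)
  }
  if (is.null(A)) {
    Ak <- diag(length(yy))
    dimnames(Ak) <- list(names(yy), names(yy))
  } else {
    Ak <- A[names(yy), names(yy)]
  }
  eig <- eigen(unclass(Ak), symmetric = TRUE)
  fit_with <- function(keep_names) {
    X <- cbind(intercept = rep(1, length(yy)))
    for (nm in keep_names) X <- cbind(X, cols[[nm]])
    fit_variance_components(yy, Ak, X = X, eig = eig)
  }
  all_names <- names(cols)
  p_values <- stats::setNames(rep(NA_real_, length(all_names)), all_names)
  full <- fit_with(all_names)
  for (nm in all_names) {
    red <- fit_with(setdiff(all_names, nm))
    p_values[nm] <- lrt_pvalue(full$loglik, red$loglik, boundary = FALSE,
                               df = 1)
  }
  retained <- all_names[!is.na(p_values) & p_values < alpha]
  final <- fit_with(retained)
  X <- cbind(rep(1, length(yy)))
  for (nm in retained) X <- cbind(X, cols[[nm]])
  resid <- as.numeric(yy - X %*% stats::coef(stats::lm.fit(X, yy)))
  names(resid) <- names(yy)
  list(retained = retained,
       p_values = p_values,
       residuals = resid,
       var_raw = stats::var(yy),
       var_resid_raw = stats::var(resid))
}

#' Proportion of phenotypic variance due to covariates
#'
#' `1 - var_resid / var_raw`, clamped to [0, 1] (a warning is issued when
#' the residual variance exceeds the raw variance before clamping).
#'
#' @param var_raw Trait variance before covariate adjustment (> 0).
#' @param var_resid Residual phenotypic variance after adjustment.
#' @return Proportion in [0, 1].
#' @export
covariate_variance_proportion <- function(var_raw, var_resid) {
  if (var_raw <= 0) stop("covariate_variance_proportion: var_raw must be > 0")
  p <- 1 - var_resid / var_raw
  if (p < 0) {
    warning("covariate_variance_proportion: negative proportion clamped to 0")
    p <- 0
  }
  min(p, 1)
}

#' Heritability summary table and covariate-burden subset means
#'
#' Assembles one row per trait from fitted `variance_model`s (or a
#' pre-built table with the same columns) and computes the mean proportion
#' of variance due to covariates over a named subset of rows — the
#' comparison that contrasts the covariate burden of two-dimensional areas
#' with that of the genotype:phenotype-mapped ratio traits.
#'
#' @param models Named list of `variance_model` objects, with an optional
#'   `covariate_prop` attribute each, or a data frame with columns `trait`,
#'   `h2`, `h2_se`, `p_value`, `n`, `covariate_prop`, `significant`.
#' @return Data frame of class `heritability_table`.
#' @export
heritability_report <- function(models) {
  if (is.data.frame(models)) {
    tab <- models
  } else {
    tab <- do.call(rbind, lapply(names(models), function(nm) {
      m <- models[[nm]]
      data.frame(trait = nm, h2 = m$h2, h2_se = m$h2_se,
                 p_value = m$p_h2, n = m$n_used,
                 covariate_prop = if (is.null(m$covariate_prop)) NA_real_
                                  else m$covariate_prop,
                 stringsAsFactors = FALSE)
    }))
    tab$significant <- tab$p_value < 0.05
  }
  class(tab) <- c("heritability_table", "data.frame")
  tab
}

#' Mean covariate variance proportion over a subset of traits
#'
#' @param tab A `heritability_table` (e.g. from [heritability_report()] or
#'   `load_fixture("table3")`).
#' @param traits Character vector of trait labels selecting the subset.
#' @return Mean of `covariate_prop` over the subset.
#' @export
covariate_prop_mean <- function(tab, traits) {
  rows <- tab[tab$trait %in% traits, ]
  if (nrow(rows) == 0L) stop("covariate_prop_mean: empty subset")
  mean(rows$covariate_prop)
}
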