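test_that("with R = I and no polygenic variance the fit equals least squares", {
  set.seed(20)
  n <- 120
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- drop(X %*% c(2, 1.5, -0.8)) + rnorm(n, 0, 2)
  R <- Matrix::Diagonal(n)
  dimnames(R) <- list(paste0("i", 1:n), paste0("i", 1:n))
  fit <- fit_lmm(y, X, R, control = lmm_control(fix_sigma2_additive = 0))
  ls <- lm(y ~ x1 + x2, data = data.frame(x1 = X[, 2], x2 = X[, 3]))
  expect_equal(unname(fit$beta), unname(coef(ls)), tolerance = 1e-6)
  expect_equal(unname(fit$covariance), unname(vcov(ls)), tolerance = 1e-4)
  # REML residual variance equals the classical unbiased estimate
  expect_equal(unname(fit$vc$sigma2_resid), sum(ls$residuals^2) / (n - 3),
               tolerance = 1e-4)
})

test_that("fit matches lme4 on the full-sib compound-symmetry equivalence", {
  skip_if_not_installed("lme4")
  set.seed(21)
  nf <- 40; s <- 5; n <- nf * s
  fam <- rep(seq_len(nf), each = s)
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(nf, 0, 2)[fam] + rnorm(n, 0, 3)
  # sib-group relationship blocks: diag 1, off-diagonal 0.5
  R <- Matrix::bdiag(replicate(nf, matrix(0.5, s, s) + diag(0.5, s),
                               simplify = FALSE))
  ids <- as.character(seq_len(n)); dimnames(R) <- list(ids, ids)
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_lmm(y, X, R)
  lf <- lme4::lmer(y ~ x + (1 | fam), REML = TRUE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(fit$covariance))),
               unname(sqrt(diag(as.matrix(vcov(lf))))), tolerance = 1e-4)
  expect_equal(fit$loglik_reml, as.numeric(logLik(lf)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(0.5 * fit$vc$sigma2_additive, vc[1], tolerance = 1e-3)
})

test_that("REML optimum dominates a coarse grid (independent dense oracle)", {
  set.seed(22)
  ped <- generate_pedigree(tiny_config())
  R <- numerator_relationship_matrix(ped)
  n <- nrow(ped)
  g <- drop(crossprod(chol(as.matrix(R)), rnorm(n))) * sqrt(30)
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  y <- drop(X %*% c(5, 1)) + g + rnorm(n, 0, 8)
  fit <- fit_lmm(y, X, R)
  grid <- expand.grid(sa = c(5, 15, 30, 60, 120), se = c(16, 32, 64, 128))
  ll_grid <- mapply(function(sa, se)
    dense_reml_loglik(y, X, R, sa, rep(se, n)), grid$sa, grid$se)
  expect_gte(fit$loglik_reml, max(ll_grid) - 1e-4)
  # and the reported optimum agrees with the dense formula at the estimates
  expect_equal(fit$loglik_reml,
               dense_reml_loglik(y, X, R, fit$vc$sigma2_additive,
                                 rep(fit$vc$sigma2_resid, n)),
               tolerance = 1e-6)
})

test_that("heterogeneous residual model recovers group variances", {
  set.seed(23)
  n <- 600
  grp <- rep(c("a", "b"), each = n / 2)
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  R <- Matrix::Diagonal(n)
  dimnames(R) <- list(as.character(1:n), as.character(1:n))
  y <- drop(X %*% c(0, 1)) + rnorm(n, 0, ifelse(grp == "a", 2, 4))
  fit <- fit_lmm(y, X, R, residual_groups = grp,
                 control = lmm_control(fix_sigma2_additive = 0))
  expect_equal(unname(fit$vc$sigma2_resid["a"]), 4, tolerance = 0.35)
  expect_equal(unname(fit$vc$sigma2_resid["b"]), 16, tolerance = 0.35)
  # dense-oracle agreement in the heteroscedastic case too
  se_vec <- fit$vc$sigma2_resid[grp]
  expect_equal(fit$loglik_reml,
               dense_reml_loglik(y, X, R, 0, se_vec) , tolerance = 1e-4)
})

test_that("rank-deficient designs are rejected with the offending column", {
  set.seed(24)
  n <- 50
  X <- cbind("(Intercept)" = 1, a = rnorm(n))
  X <- cbind(X, dup = X[, "a"])
  R <- Matrix::Diagonal(n)
  expect_error(fit_lmm(rnorm(n), X, R), "dup")
})

test_that("variance-component recovery on repeated pedigree simulation", {
  set.seed(25)
  cfg <- tiny_config()
  ped <- generate_pedigree(sim_config(n_families = 5L,
    family_template = list(n_generations = 3L, gen2_children = 3L,
                           gen3_children = 4L),
    n_null_snps = 5L, n_replicates = 1L, seed = 1L))
  R <- numerator_relationship_matrix(ped)
  n <- nrow(ped)
  L <- chol(as.matrix(R) + diag(1e-10, n))
  X <- cbind("(Intercept)" = rep(1, n))
  sa <- numeric(25); se <- numeric(25)
  for (k in 1:25) {
    y <- sqrt(54) * drop(crossprod(L, rnorm(n))) + rnorm(n, 0, sqrt(127))
    f <- fit_lmm(y, X, R)
    sa[k] <- f$vc$sigma2_additive; se[k] <- f$vc$sigma2_resid
  }
  expect_equal(mean(sa), 54, tolerance = 0.35)
  expect_equal(mean(se), 127, tolerance = 0.2)
})

test_that("heterogeneity LRT: null case, type-I control and power ordering", {
  f <- fake_fit(c("(Intercept)" = 1), matrix(1))
  f$loglik_reml <- -100
  out <- residual_heterogeneity_lrt(f, f)
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)

  set.seed(26)
  n <- 150
  grp <- rep(c("m", "u"), length.out = n)
  R <- Matrix::Diagonal(n); dimnames(R) <- list(1:n, 1:n)
  X <- cbind("(Intercept)" = rep(1, n))
  pnull <- palt <- numeric(120)
  for (k in seq_len(120)) {
    y0 <- rnorm(n, 0, 3)
    hom <- fit_lmm(y0, X, R, control = lmm_control(fix_sigma2_additive = 0))
    het <- fit_lmm(y0, X, R, residual_groups = grp,
                   control = lmm_control(fix_sigma2_additive = 0))
    pnull[k] <- residual_heterogeneity_lrt(hom, het)$p
    y1 <- rnorm(n, 0, ifelse(grp == "m", 3 * sqrt(2), 3))
    hom1 <- fit_lmm(y1, X, R, control = lmm_control(fix_sigma2_additive = 0))
    het1 <- fit_lmm(y1, X, R, residual_groups = grp,
                    control = lmm_control(fix_sigma2_additive = 0))
    palt[k] <- residual_heterogeneity_lrt(hom1, het1)$p
  }
  ci <- wilson_ci(sum(pnull < 0.05), 120)
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
  expect_gt(mean(palt < 0.05), mean(pnull < 0.05))
})

test_that("LRT refuses non-nested fits", {
  f1 <- fake_fit(c("(Intercept)" = 1), matrix(1))
  f2 <- fake_fit(c("(Intercept)" = 1, x = 2), diag(2))
  f1$loglik_reml <- f2$loglik_reml <- -10
  expect_error(residual_heterogeneity_lrt(f1, f2), "nested")
})
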