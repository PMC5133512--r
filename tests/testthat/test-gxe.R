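test_that("interaction Wald statistics match closed forms", {
  # zero interaction estimate -> 1-df p = 1
  f0 <- fake_fit(c(snp = 2, snp_med = 0), diag(2))
  expect_equal(interaction_test(f0)$p_1df, 1)

  # identity covariance: X_2df = 2^2 + 1^2 = 5, chi2(2) tail = exp(-5/2)
  f1 <- fake_fit(c(snp = 2, snp_med = 1), diag(2))
  out <- interaction_test(f1)
  expect_equal(out$p_2df, exp(-5 / 2), tolerance = 1e-12)
  expect_equal(out$p_1df, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(out$beta_effect, 1)
  expect_equal(out$beta_snp_main, 2)

  # correlated covariance block: compare with an explicit 2x2 inverse
  C <- matrix(c(1.2, 0.5 * sqrt(1.2 * 0.8), 0.5 * sqrt(1.2 * 0.8), 0.8), 2)
  b <- c(snp = 1.1, snp_med = -0.7)
  f2 <- fake_fit(b, C)
  Cinv <- solve(C)
  x2 <- drop(t(b) %*% Cinv %*% b)
  expect_equal(interaction_test(f2)$p_2df,
               pchisq(x2, 2, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("non-converged or singular fits propagate as non-converged results", {
  nc <- famgxe:::lmm_nonconverged(c("snp", "snp_med"), 10L, "degenerate design")
  out <- interaction_test(nc)
  expect_false(out$converged)
  expect_equal(out$reason, "degenerate design")
  expect_true(is.na(out$beta_effect) && is.na(out$p_1df))

  sing <- fake_fit(c(snp = 1, snp_med = 1),
                   matrix(c(1, 1, 1, 1), 2))  # perfectly collinear block
  out2 <- interaction_test(sing)
  expect_false(out2$converged)
})

test_that("med-diff statistics match closed forms and are stratum-symmetric", {
  fm <- fake_fit(c("(Intercept)" = 0, snp = 4), diag(c(1, 4)))
  fu <- fake_fit(c("(Intercept)" = 0, snp = 0), diag(c(1, 1)))
  out <- med_diff_test(fm, fu, r = 0)
  expect_equal(out$beta_effect, 4)
  expect_equal(out$se_effect, sqrt(5), tolerance = 1e-12)
  expect_equal(out$p_1df, 2 * pnorm(-4 / sqrt(5)), tolerance = 1e-12)
  # z_med = 4/2 = 2, z_unmed = 0 -> X_2df = 4
  expect_equal(out$p_2df, exp(-4 / 2), tolerance = 1e-12)

  # equal estimates -> Z = 0, p = 1
  out0 <- med_diff_test(fm, fm, r = 0)
  expect_equal(out0$p_1df, 1)

  # z1 = 2, z0 = 1 -> X_2df = 5
  fa <- fake_fit(c(snp = 2), matrix(1))
  fb <- fake_fit(c(snp = 1), matrix(1))
  expect_equal(med_diff_test(fa, fb, r = 0)$p_2df, exp(-5 / 2),
               tolerance = 1e-12)

  # correlation correction: r = 0.5 shrinks the difference variance
  outr <- med_diff_test(fm, fu, r = 0.5)
  expect_equal(outr$se_effect, sqrt(4 + 1 - 2 * 0.5 * 2 * 1), tolerance = 1e-12)

  # swapping strata flips the sign but not the p-values
  sw <- med_diff_test(fu, fm, r = 0)
  expect_equal(sw$beta_effect, -out$beta_effect)
  expect_equal(sw$p_1df, out$p_1df)
  expect_equal(sw$p_2df, out$p_2df)
})

test_that("med-diff guards nonpositive difference variance and propagates
           non-convergence", {
  fa <- fake_fit(c(snp = 2), matrix(1))
  fb <- fake_fit(c(snp = 1), matrix(1))
  out <- med_diff_test(fa, fb, r = 1)  # equal SEs, r = 1 -> variance 0
  expect_false(out$converged)
  expect_match(out$reason, "variance")

  nc <- famgxe:::lmm_nonconverged("snp", 5L, "small stratified-sample size")
  out2 <- med_diff_test(fa, nc, r = 0)
  expect_false(out2$converged)
  expect_match(out2$reason, "stratified")
})

test_that("Z_1df^2 at r = 0 equals the classical slope-difference Wald form", {
  set.seed(30)
  n <- 200
  x <- rnorm(n); g <- rbinom(n, 1, 0.5)
  y <- 2 * x * g + rnorm(n)
  ls1 <- lm(y ~ x, subset = g == 1)
  ls0 <- lm(y ~ x, subset = g == 0)
  b1 <- coef(ls1)["x"]; b0 <- coef(ls0)["x"]
  v1 <- vcov(ls1)["x", "x"]; v0 <- vcov(ls0)["x", "x"]
  wald <- (b1 - b0)^2 / (v1 + v0)
  f1 <- fake_fit(c(snp = unname(b1)), matrix(v1))
  f0 <- fake_fit(c(snp = unname(b0)), matrix(v0))
  out <- med_diff_test(f1, f0, r = 0)
  z <- out$beta_effect / out$se_effect
  expect_equal(z^2, unname(wald), tolerance = 1e-12)
})

test_that("Spearman strata correlation matches hand-ranked values", {
  expect_equal(spearman_strata_correlation(1:5, 1:5)$r, 1)
  expect_equal(spearman_strata_correlation(1:5, 5:1)$r, -1)

  # ties handled by average ranks; oracle ranks written out by hand
  x <- c(10, 20, 20, 30, 40, 50)   # ranks 1, 2.5, 2.5, 4, 5, 6
  y <- c(2, 1, 3, 3, 5, 4)         # ranks 2, 1, 3.5, 3.5, 6, 5
  rx <- c(1, 2.5, 2.5, 4, 5, 6)
  ry <- c(2, 1, 3.5, 3.5, 6, 5)
  expect_equal(spearman_strata_correlation(x, y)$r, cor(rx, ry),
               tolerance = 1e-12)
  # non-converged entries (NA) are dropped from the usable intersection
  out <- spearman_strata_correlation(c(x, NA), c(y, 1))
  expect_equal(out$n_snps_used, 6L)
  expect_error(spearman_strata_correlation(c(1, NA), c(1, 2)), "fewer than 2")
})

test_that("stratified fits recover stratum-specific slopes", {
  set.seed(31)
  n <- 400
  ped <- founder_pedigree(n)
  R <- Matrix::Diagonal(n); dimnames(R) <- list(ped$id, ped$id)
  g <- rbinom(n, 2, 0.4)
  med <- rbinom(n, 1, 0.45)
  y <- 100 + 4 * g * med + 0 * g * (1 - med) + rnorm(n, 0, 3)
  ph <- data.frame(id = ped$id, sbp_t3 = y, age = rep(50, n), sex = ped$sex,
                   med = med, stringsAsFactors = FALSE)
  panel <- genotype_panel(matrix(g, n, 1, dimnames = list(ped$id, "s1")),
                          chrom = "1", pos = 100)
  ds <- make_dataset(ped, panel, ph, R)
  sf <- stratified_fits(ds, "s1", covariates = "sex")
  expect_true(sf$converged)
  expect_equal(sf$med$beta[["snp"]], 4,
               tolerance = 3 * sqrt(sf$med$covariance["snp", "snp"]) / 4)
  expect_lt(abs(sf$unmed$beta[["snp"]]),
            3 * sqrt(sf$unmed$covariance["snp", "snp"]))
  md <- med_diff_test(sf, r = 0)
  expect_true(md$converged)
  expect_lt(md$p_1df, 0.001)
})

test_that("a stratum-monomorphic SNP marks the pair non-converged", {
  set.seed(32)
  n <- 60
  ped <- founder_pedigree(n)
  R <- Matrix::Diagonal(n); dimnames(R) <- list(ped$id, ped$id)
  med <- rep(c(1L, 0L), each = n / 2)
  g <- ifelse(med == 1, 0L, rbinom(n, 1, 0.5))  # monomorphic among medicated
  ph <- data.frame(id = ped$id, sbp_t3 = rnorm(n, 120, 5), age = 50,
                   sex = ped$sex, med = med, stringsAsFactors = FALSE)
  panel <- genotype_panel(matrix(g, n, 1, dimnames = list(ped$id, "s1")),
                          chrom = "1", pos = 1)
  ds <- make_dataset(ped, panel, ph, R)
  sf <- stratified_fits(ds, "s1", covariates = "sex")
  expect_false(sf$converged)
  expect_equal(sf$reason, "small stratified-sample size")
  expect_false(med_diff_test(sf, r = 0)$converged)
})

test_that("run_scan covers both approaches on the same SNPs and is deterministic", {
  rs <- generate_replicates(tiny_config(n_null_snps = 12L, n_replicates = 1L),
                            k_pcs = 2L)
  ds <- replicate_dataset(rs, 1)
  res <- run_scan(ds, approach = "both")
  ia <- res[res$approach == "interaction_model", ]
  md <- res[res$approach == "med_diff", ]
  expect_setequal(ia$snp, md$snp)
  expect_true(all(res$p_1df[res$converged] >= 0 &
                  res$p_1df[res$converged] <= 1))
  expect_true(all(res$p_2df[res$converged] >= 0 &
                  res$p_2df[res$converged] <= 1))
  # non-converged rows are retained with a reason, never dropped
  expect_true(all(!res$converged | is.na(res$reason)))
  res2 <- run_scan(ds, approach = "both")
  expect_identical(res, res2)
  # MAC filter: every scanned SNP has MAC >= 2 in the full sample
  expect_true(all(res$mac >= 2))
})

test_that("the two 1-df tests agree in the large homoscedastic unrelated regime", {
  set.seed(33)
  n <- 1500; m <- 50
  ped <- founder_pedigree(n)
  R <- Matrix::Diagonal(n); dimnames(R) <- list(ped$id, ped$id)
  d <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(ped$id, sprintf("s%02d", 1:m)))
  panel <- genotype_panel(d, chrom = rep("1", m), pos = seq_len(m) * 1e5)
  med <- rbinom(n, 1, 0.4)
  ph <- data.frame(id = ped$id, sbp_t3 = rnorm(n, 130, 10), age = rnorm(n, 50, 10),
                   sex = ped$sex, med = med, stringsAsFactors = FALSE)
  ds <- make_dataset(ped, panel, ph, R)
  res <- run_scan(ds, approach = "both", covariates = c("age", "sex"),
                  residual_model = "homogeneous")
  ia <- res[res$approach == "interaction_model", ]
  md <- res[res$approach == "med_diff", ]
  md <- md[match(ia$snp, md$snp), ]
  ok <- ia$converged & md$converged
  expect_gt(sum(ok), 45)
  expect_gt(cor(ia$p_1df[ok], md$p_1df[ok], method = "spearman"), 0.95)
})
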