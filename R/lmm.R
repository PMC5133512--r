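#' Optimizer settings for the mixed-model REML fit
#'
#' @param max_iter maximum optimizer iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param restarts number of deterministic starting points tried until the
#'   optimizer reports convergence.
#' @param bound lower bound on each variance component (kept strictly
#'   positive so the phenotypic covariance stays invertible; an estimate at
#'   the bound still counts as converged).
#' @param fix_sigma2_additive optional fixed value for the polygenic
#'   variance (e.g. `0` reduces the model to weighted least squares).
#' @return A list of class `lmm_control`.
#' @export
lmm_control <- function(max_iter = 200L, tol = 1e-6, restarts = 3L,
                        bound = 1e-10, fix_sigma2_additive = NULL) {
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 restarts = as.integer(restarts), bound = bound,
                 fix_sigma2_additive = fix_sigma2_additive),
            class = "lmm_control")
}

# Sparse covariance V = sigma2_a * R + diag(sigma2_e[group]) and its
# Cholesky factor; `template` is reused via update() when the pattern matches.
build_V <- function(R, sigma2_a, sigma2_e, gidx) {
  V <- sigma2_a * R + Matrix::Diagonal(length(gidx), x = sigma2_e[gidx])
  methods::as(Matrix::forceSymmetric(V), "CsparseMatrix")
}

chol_V <- function(V, template = NULL) {
  if (!is.null(template)) {
    ch <- tryCatch(Matrix::update(template, V), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  Matrix::Cholesky(V, LDL = FALSE, perm = TRUE)
}

# Generalized least squares given a Cholesky factor of V; returns the
# pieces shared by the REML objective and the scan-mode per-SNP fits.
gls_core <- function(y, X, Ch) {
  ViX <- as.matrix(Matrix::solve(Ch, X))
  Viy <- as.numeric(Matrix::solve(Ch, y))
  XtViX <- crossprod(X, ViX)
  XtViy <- drop(crossprod(X, Viy))
  cXX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXX)) return(NULL)
  beta <- backsolve(cXX, backsolve(cXX, XtViy, transpose = TRUE))
  names(beta) <- colnames(X)
  yPy <- sum(y * Viy) - sum(XtViy * beta)
  list(beta = beta, cXX = cXX, yPy = yPy,
       ld_XtViX = 2 * sum(log(diag(cXX))),
       covariance = chol2inv(cXX))
}

#' Fit a polygenic linear mixed model by REML
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma2_additive * R)` and residual
#' variance constant within each level of `residual_groups` (a single level
#' gives the homogeneous model). Variance components maximize the restricted
#' likelihood (bounded quasi-Newton on the log-variance scale, deterministic
#' restarts); fixed effects are the generalized-least-squares solution at the
#' optimum with covariance `(X' V^-1 X)^-1`. Non-convergence is a
#' first-class outcome: the fit is returned with `converged = FALSE` and a
#' reason, and downstream tests propagate it rather than report numbers.
#'
#' @param y numeric outcome vector.
#' @param X design matrix with named columns, full column rank.
#' @param R sparse symmetric relationship matrix (positive semidefinite).
#' @param residual_groups optional per-observation labels for
#'   medication-specific residual variances; `NULL` fits one variance.
#' @param control an [lmm_control()].
#' @return A list of class `lmm_fit`: `beta`, `covariance`, `vc`
#'   (`sigma2_additive`, named `sigma2_resid`), `loglik_reml`, `loglik_ml`
#'   (maximum-likelihood value at the REML variance estimates), `converged`,
#'   `reason`, `n_used`, `iterations`, `vc_mode`.
#' @export
fit_lmm <- function(y, X, R, residual_groups = NULL,
                    control = lmm_control()) {
  n <- length(y)
  stopifnot(is.matrix(X), nrow(X) == n, nrow(R) == n)
  if (is.null(colnames(X)))
    stop("design error: X must have named columns", call. = FALSE)
  if (anyNA(y) || anyNA(X))
    stop("y and X must be complete", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design error: collinear columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- ncol(X)
  Rsp <- methods::as(Matrix::forceSymmetric(R), "CsparseMatrix")
  grp <- if (is.null(residual_groups)) factor(rep("resid", n))
         else factor(residual_groups)
  gidx <- as.integer(grp)
  ngrp <- nlevels(grp)
  fix_a <- control$fix_sigma2_additive
  lb <- control$bound

  s2 <- max(var(qr.resid(qrX, y)), 1e-8)
  template <- NULL
  n_eval <- 0L

  negreml <- function(theta) {
    n_eval <<- n_eval + 1L
    sa <- if (is.null(fix_a)) exp(theta[1L]) else max(fix_a, lb)
    se <- exp(theta[(if (is.null(fix_a)) 2L else 1L):length(theta)])
    V <- build_V(Rsp, sa, se, gidx)
    Ch <- chol_V(V, template)
    if (is.null(template)) template <<- Ch
    ld <- tryCatch(2 * as.numeric(Matrix::determinant(
            Ch, logarithm = TRUE, sqrt = TRUE)$modulus),
          error = function(e) NA_real_)
    if (!is.finite(ld)) return(1e10)
    g <- gls_core(y, X, Ch)
    if (is.null(g)) return(1e10)
    val <- 0.5 * (ld + g$ld_XtViX + g$yPy + (n - p) * log(2 * pi))
    if (!is.finite(val)) 1e10 else val
  }

  frac <- list(c(0.5, 0.5), c(0.9, 0.1), c(0.1, 0.9))
  best <- NULL
  converged <- FALSE
  iters <- 0L
  for (s in seq_len(max(1L, control$restarts))) {
    fr <- frac[[(s - 1L) %% length(frac) + 1L]]
    start <- log(pmax(c(if (is.null(fix_a)) fr[1L] * s2,
                        rep(fr[2L] * s2, ngrp)), lb))
    opt <- tryCatch(
      optim(start, negreml, method = "L-BFGS-B",
            lower = log(lb), upper = log(1e8),
            control = list(maxit = control$max_iter, factr = 1e8)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) {
      iters <- iters + opt$counts[1L]
      if (is.null(best) || opt$value < best$value) best <- opt
      if (opt$convergence == 0L && opt$value < 1e9) { converged <- TRUE; break }
    }
  }
  if (is.null(best))
    return(lmm_nonconverged(colnames(X), n, "optimizer failure"))

  theta <- best$par
  sa <- if (is.null(fix_a)) exp(theta[1L]) else max(fix_a, lb)
  se <- exp(theta[(if (is.null(fix_a)) 2L else 1L):length(theta)])
  names(se) <- levels(grp)
  V <- build_V(Rsp, sa, se, gidx)
  Ch <- chol_V(V, template)
  ld <- 2 * as.numeric(Matrix::determinant(Ch, logarithm = TRUE,
                                           sqrt = TRUE)$modulus)
  g <- gls_core(y, X, Ch)
  if (is.null(g))
    return(lmm_nonconverged(colnames(X), n, "singular generalized design"))
  cov <- g$covariance
  dimnames(cov) <- list(colnames(X), colnames(X))
  ll_reml <- -0.5 * (ld + g$ld_XtViX + g$yPy + (n - p) * log(2 * pi))
  ll_ml <- -0.5 * (ld + g$yPy + n * log(2 * pi))
  structure(list(beta = g$beta, covariance = cov,
                 vc = list(sigma2_additive = sa, sigma2_resid = se),
                 loglik_reml = ll_reml, loglik_ml = ll_ml,
                 converged = converged,
                 reason = if (converged) NA_character_ else
                   "optimizer did not converge",
                 n_used = n, iterations = as.integer(iters),
                 residual_groups = levels(grp), vc_mode = "exact"),
            class = "lmm_fit")
}

lmm_nonconverged <- function(xnames, n, reason) {
  structure(list(beta = NULL, covariance = NULL, vc = NULL,
                 loglik_reml = NA_real_, loglik_ml = NA_real_,
                 converged = FALSE, reason = reason, n_used = n,
                 iterations = 0L, residual_groups = NULL,
                 vc_mode = "exact"),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Polygenic LMM fit: NOT converged (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Polygenic LMM fit (%s mode), n = %d, REML loglik = %.2f\n",
              x$vc_mode, x$n_used, x$loglik_reml))
  se <- sqrt(diag(x$covariance))
  print(round(cbind(estimate = x$beta, se = se), 4))
  cat(sprintf("  sigma2_additive = %.3f; sigma2_resid: %s\n",
              x$vc$sigma2_additive,
              paste(sprintf("%s = %.3f", names(x$vc$sigma2_resid),
                            x$vc$sigma2_resid), collapse = ", ")))
  invisible(x)
}

# GLS fit with variance components (and hence V's Cholesky) held fixed --
# the fast scan mode used for per-SNP tests across many SNPs.
gls_fixed_vc <- function(y, X, Ch, vc, residual_groups = NULL) {
  # collinear designs (e.g. SNP and interaction identical because every
  # carrier is medicated) are a first-class nonconvergence outcome
  if (qr(X)$rank < ncol(X))
    return(lmm_nonconverged(colnames(X), length(y), "degenerate design"))
  g <- gls_core(y, X, Ch)
  if (is.null(g))
    return(lmm_nonconverged(colnames(X), length(y), "degenerate design"))
  cov <- g$covariance
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(beta = g$beta, covariance = cov, vc = vc,
                 loglik_reml = NA_real_, loglik_ml = NA_real_,
                 converged = TRUE, reason = NA_character_,
                 n_used = length(y), iterations = 0L,
                 residual_groups = residual_groups, vc_mode = "scan"),
            class = "lmm_fit")
}

#' Likelihood-ratio test for medication-specific residual variances
#'
#' Compares the homogeneous-residual mixed model against the model whose
#' residual variance differs by medication status (same data, same fixed
#' effects, so the REML likelihood ratio is valid). The statistic
#' `2 * (loglik_het - loglik_hom)` is clipped at zero and referred to a
#' chi-square with `df` degrees of freedom (number of extra variance
#' parameters, default 1).
#'
#' @param fit_hom,fit_het converged [fit_lmm()] results; `fit_het` must nest
#'   `fit_hom` (same rows and fixed effects, at least as many residual
#'   groups).
#' @param type which log-likelihood to use (`"reml"` default).
#' @return List with `statistic`, `df`, `p`.
#' @export
residual_heterogeneity_lrt <- function(fit_hom, fit_het, type = c("reml", "ml")) {
  type <- match.arg(type)
  if (!fit_hom$converged || !fit_het$converged)
    stop("both fits must have converged", call. = FALSE)
  if (fit_hom$n_used != fit_het$n_used ||
      !identical(names(fit_hom$beta), names(fit_het$beta)))
    stop("usage error: fits are not nested (rows or fixed effects differ)",
         call. = FALSE)
  k_hom <- length(fit_hom$vc$sigma2_resid)
  k_het <- length(fit_het$vc$sigma2_resid)
  if (k_het < k_hom)
    stop("usage error: heterogeneous fit has fewer residual groups",
         call. = FALSE)
  ll <- function(f) if (type == "reml") f$loglik_reml else f$loglik_ml
  stat <- max(0, 2 * (ll(fit_het) - ll(fit_hom)))
  df <- max(1L, k_het - k_hom)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}
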