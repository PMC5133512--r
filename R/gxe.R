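#' Build the fixed-effect design matrix for the G x E models
#'
#' Columns in order: intercept, SNP dosage (if supplied), medication
#' indicator (if requested), SNP-by-medication product, then covariates
#' (age, female indicator, PC scores found as `pc1..pck` in the phenotype
#' table).
#'
#' @param phenotypes phenotype data frame (`sbp_t3`, `age`, `sex`, `med`,
#'   optional `pc*` columns).
#' @param snp optional dosage vector aligned with `phenotypes`.
#' @param with_med include the medication main effect.
#' @param with_interaction include the SNP x medication product.
#' @param covariates subset of `c("age", "sex", "pcs")`.
#' @return Numeric design matrix with named columns.
#' @export
gxe_design <- function(phenotypes, snp = NULL, with_med = TRUE,
                       with_interaction = FALSE,
                       covariates = c("age", "sex", "pcs")) {
  n <- nrow(phenotypes)
  cols <- list("(Intercept)" = rep(1, n))
  if (!is.null(snp)) cols$snp <- as.numeric(snp)
  if (with_med) cols$med <- as.numeric(phenotypes$med)
  if (with_interaction) {
    stopifnot(!is.null(snp))
    cols$snp_med <- as.numeric(snp) * as.numeric(phenotypes$med)
  }
  if ("age" %in% covariates) cols$age <- phenotypes$age
  if ("sex" %in% covariates) cols$sexF <- as.numeric(phenotypes$sex == "female")
  if ("pcs" %in% covariates) {
    pcc <- grep("^pc[0-9]+$", names(phenotypes), value = TRUE)
    for (pc in pcc) cols[[pc]] <- phenotypes[[pc]]
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Fit the single-model interaction mixed model at one SNP
#'
#' The "interaction model": one linear mixed model with SNP, medication and
#' SNP-by-medication fixed effects plus covariates, a polygenic random
#' effect, and (by default) medication-specific residual variances.
#'
#' @param dataset a [replicate_dataset()] (or any list with `phenotypes`,
#'   `genotypes`, `R`).
#' @param snp SNP identifier in the genotype panel.
#' @param covariates see [gxe_design()].
#' @param residual_model `"heterogeneous"` (residual variance by medication
#'   status) or `"homogeneous"`.
#' @param control an [lmm_control()].
#' @return An `lmm_fit` with effects named `snp`, `med`, `snp_med`, ...
#' @export
fit_model1 <- function(dataset, snp, covariates = c("age", "sex", "pcs"),
                       residual_model = c("heterogeneous", "homogeneous"),
                       control = lmm_control()) {
  residual_model <- match.arg(residual_model)
  ph <- dataset$phenotypes
  g <- dataset$genotypes$dosages[ph$id, snp]
  X <- gxe_design(ph, snp = g, with_med = TRUE, with_interaction = TRUE,
                  covariates = covariates)
  groups <- if (residual_model == "heterogeneous") ph$med else NULL
  fit_lmm(ph$sbp_t3, X, dataset$R[ph$id, ph$id], groups, control)
}

#' Wald tests from the interaction model
#'
#' From a converged fit containing `snp` and `snp_med` effects, computes the
#' 1-df Wald statistic `b_Int^2 / Var(b_Int)` (chi-square, 1 df) and the
#' 2-df joint statistic `[b_SNP, b_Int]' C^-1 [b_SNP, b_Int]` (chi-square,
#' 2 df), where `C` is the estimated 2 x 2 covariance block of the two
#' coefficients.
#'
#' @param fit an `lmm_fit` from [fit_model1()] (or scan mode).
#' @param snp_name,int_name design-column names of the SNP main effect and
#'   the interaction term.
#' @return One-row data frame: `approach`, `beta_effect` (interaction
#'   estimate, mm Hg), `se_effect`, `beta_snp_main`, `beta_med`, `p_1df`,
#'   `p_2df`, `converged`, `reason`.
#' @export
interaction_test <- function(fit, snp_name = "snp", int_name = "snp_med") {
  empty <- data.frame(approach = "interaction_model", beta_effect = NA_real_,
                      se_effect = NA_real_, beta_snp_main = NA_real_,
                      beta_med = NA_real_, p_1df = NA_real_, p_2df = NA_real_,
                      converged = FALSE, reason = NA_character_,
                      stringsAsFactors = FALSE)
  if (!fit$converged) {
    empty$reason <- fit$reason
    return(empty)
  }
  b <- fit$beta[c(snp_name, int_name)]
  C <- fit$covariance[c(snp_name, int_name), c(snp_name, int_name)]
  if (anyNA(b) || anyNA(C)) {
    empty$reason <- "missing SNP or interaction effect"
    return(empty)
  }
  v_int <- C[2L, 2L]
  x1 <- b[[int_name]]^2 / v_int
  detC <- C[1L, 1L] * C[2L, 2L] - C[1L, 2L]^2
  if (!is.finite(detC) || detC <= 0 || v_int <= 0) {
    empty$reason <- "singular coefficient covariance"
    return(empty)
  }
  x2 <- tryCatch(drop(t(b) %*% solve(C, b)), error = function(e) NA_real_)
  if (!is.finite(x2) || x2 < 0) {
    empty$reason <- "singular coefficient covariance"
    return(empty)
  }
  data.frame(approach = "interaction_model",
             beta_effect = b[[int_name]], se_effect = sqrt(v_int),
             beta_snp_main = b[[snp_name]],
             beta_med = unname(fit$beta["med"]),
             p_1df = pchisq(x1, 1L, lower.tail = FALSE),
             p_2df = pchisq(x2, 2L, lower.tail = FALSE),
             converged = TRUE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Medication-stratified mixed-model fits at one SNP
#'
#' Fits the SNP main effect plus covariates separately among medicated and
#' unmedicated individuals, each with the relationship matrix restricted to
#' the stratum. The minor-allele-count filter is re-applied within each
#' stratum; an empty stratum or in-stratum MAC below the threshold marks the
#' pair non-converged (reason "small stratified-sample size").
#'
#' @inheritParams fit_model1
#' @param mac_threshold in-stratum minor-allele-count threshold.
#' @return List of class `stratified_fits`: `med`, `unmed` (`lmm_fit` or
#'   `NULL`), `converged`, `reason`.
#' @export
stratified_fits <- function(dataset, snp, covariates = c("age", "sex", "pcs"),
                            control = lmm_control(), mac_threshold = 2L) {
  ph <- dataset$phenotypes
  out <- list(med = NULL, unmed = NULL, converged = FALSE,
              reason = NA_character_)
  class(out) <- "stratified_fits"
  fits <- list()
  for (s in c(1L, 0L)) {
    rows <- which(ph$med == s)
    label <- if (s == 1L) "med" else "unmed"
    if (length(rows) == 0L) {
      out$reason <- "small stratified-sample size"
      return(out)
    }
    ids <- ph$id[rows]
    if (!mac_filter(dataset$genotypes, ids, mac_threshold)[[snp]]) {
      out$reason <- "small stratified-sample size"
      return(out)
    }
    phs <- ph[rows, , drop = FALSE]
    g <- dataset$genotypes$dosages[ids, snp]
    X <- gxe_design(phs, snp = g, with_med = FALSE, with_interaction = FALSE,
                    covariates = covariates)
    fit <- tryCatch(fit_lmm(phs$sbp_t3, X, dataset$R[ids, ids],
                            residual_groups = NULL, control = control),
                    error = function(e)
                      lmm_nonconverged(colnames(X), length(rows),
                                       conditionMessage(e)))
    fits[[label]] <- fit
  }
  out$med <- fits$med
  out$unmed <- fits$unmed
  out$converged <- fits$med$converged && fits$unmed$converged
  if (!out$converged)
    out$reason <- paste(stats::na.omit(c(fits$med$reason, fits$unmed$reason)),
                        collapse = "; ")
  out
}

#' Spearman correlation of SNP effects between medication strata
#'
#' Rank correlation (average ranks for ties) of the per-SNP effect estimates
#' from the two strata, over SNPs with converged estimates in both. Used to
#' correct the variance of the stratum difference in [med_diff_test()].
#'
#' @param beta_med,beta_unmed aligned numeric vectors of per-SNP estimates
#'   (NA where not converged).
#' @param scope bookkeeping label (`"per_chromosome"` default).
#' @return List of class `strata_correlation`: `r`, `n_snps_used`, `scope`.
#' @export
spearman_strata_correlation <- function(beta_med, beta_unmed,
                                        scope = c("per_chromosome",
                                                  "genome_wide")) {
  scope <- match.arg(scope)
  ok <- is.finite(beta_med) & is.finite(beta_unmed)
  if (sum(ok) < 2L)
    stop("fewer than 2 SNPs with converged estimates in both strata",
         call. = FALSE)
  r <- cor(beta_med[ok], beta_unmed[ok], method = "spearman")
  if (is.na(r)) r <- 0  # zero-variance ranks (all estimates tied)
  structure(list(r = r, n_snps_used = sum(ok), scope = scope),
            class = "strata_correlation")
}

#' Correlation-corrected difference test between medication strata
#'
#' The med-diff approach: `b_Diff = b_med - b_unmed` with
#' `SE_Diff = sqrt(SE_med^2 + SE_unmed^2 - 2 r SE_med SE_unmed)`; the 1-df
#' p-value is the two-sided standard-normal tail of `b_Diff / SE_Diff`, and
#' the 2-df joint statistic is `z_med^2 + z_unmed^2` against chi-square
#' with 2 df.
#'
#' @param fit_med,fit_unmed per-stratum `lmm_fit`s (SNP effect named
#'   `snp`), or a [stratified_fits()] object passed as `fit_med`.
#' @param r a `strata_correlation`, or a plain correlation in \[-1, 1\].
#' @return One-row data frame: `approach`, `beta_effect` (difference, mm
#'   Hg), `se_effect`, `beta_snp_med`, `beta_snp_unmed`, `p_1df`, `p_2df`,
#'   `converged`, `reason`.
#' @export
med_diff_test <- function(fit_med, fit_unmed = NULL, r = 0) {
  empty <- data.frame(approach = "med_diff", beta_effect = NA_real_,
                      se_effect = NA_real_, beta_snp_med = NA_real_,
                      beta_snp_unmed = NA_real_, p_1df = NA_real_,
                      p_2df = NA_real_, converged = FALSE,
                      reason = NA_character_, stringsAsFactors = FALSE)
  if (inherits(fit_med, "stratified_fits")) {
    pair <- fit_med
    if (!pair$converged) {
      empty$reason <- pair$reason
      return(empty)
    }
    fit_unmed <- pair$unmed
    fit_med <- pair$med
  }
  rv <- if (inherits(r, "strata_correlation")) r$r else as.numeric(r)
  stopifnot(abs(rv) <= 1)
  if (!fit_med$converged || !fit_unmed$converged) {
    empty$reason <- paste(stats::na.omit(c(fit_med$reason, fit_unmed$reason)),
                          collapse = "; ")
    return(empty)
  }
  b1 <- fit_med$beta[["snp"]]; se1 <- sqrt(fit_med$covariance["snp", "snp"])
  b0 <- fit_unmed$beta[["snp"]]; se0 <- sqrt(fit_unmed$covariance["snp", "snp"])
  v_diff <- se1^2 + se0^2 - 2 * rv * se1 * se0
  if (!is.finite(v_diff) || v_diff <= 0) {
    empty$reason <- "nonpositive variance of stratum difference"
    return(empty)
  }
  z <- (b1 - b0) / sqrt(v_diff)
  x2 <- (b1 / se1)^2 + (b0 / se0)^2
  data.frame(approach = "med_diff", beta_effect = b1 - b0,
             se_effect = sqrt(v_diff), beta_snp_med = b1,
             beta_snp_unmed = b0,
             p_1df = 2 * pnorm(-abs(z)),
             p_2df = pchisq(x2, 2L, lower.tail = FALSE),
             converged = TRUE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Per-replicate G x E scan over a SNP set
#'
#' Driver reproducing the per-SNP analyses of one phenotype replicate.
#' Applies the minor-allele-count filter, then runs the requested
#' approach(es) at every passing SNP. In `"scan"` mode the variance
#' components are estimated once from the covariates-only model (per
#' stratum for the med-diff approach) and held fixed across SNPs; `"exact"`
#' mode re-estimates them per SNP by REML. The med-diff difference test
#' uses the Spearman correlation of stratum estimates computed per
#' chromosome (or genome-wide) after all stratified fits; chromosomes with
#' fewer than two usable SNPs fall back to r = 0 with a message.
#'
#' @param dataset a [replicate_dataset()].
#' @param approach `"both"`, `"interaction_model"` or `"med_diff"`.
#' @param snp_set SNP ids to scan (default: the whole panel).
#' @param covariates see [gxe_design()].
#' @param vc_mode `"scan"` (default) or `"exact"`.
#' @param residual_model residual model for the interaction approach.
#' @param mac_threshold minor-allele-count threshold.
#' @param spearman_scope scope of the strata correlation.
#' @param control an [lmm_control()].
#' @return Data frame with one row per SNP x approach: `replicate`,
#'   `chrom`, `pos`, `snp`, `maf`, `mac`, `approach`, `beta_effect`,
#'   `se_effect`, `beta_snp_main`, `beta_med`, `beta_snp_med`,
#'   `beta_snp_unmed`, `p_1df`, `p_2df`, `converged`, `reason`,
#'   `r_spearman`, `vc_mode`.
#' @export
run_scan <- function(dataset,
                     approach = c("both", "interaction_model", "med_diff"),
                     snp_set = NULL, covariates = c("age", "sex", "pcs"),
                     vc_mode = c("scan", "exact"),
                     residual_model = c("heterogeneous", "homogeneous"),
                     mac_threshold = 2L,
                     spearman_scope = c("per_chromosome", "genome_wide"),
                     control = lmm_control()) {
  approach <- match.arg(approach)
  vc_mode <- match.arg(vc_mode)
  residual_model <- match.arg(residual_model)
  spearman_scope <- match.arg(spearman_scope)
  ph <- dataset$phenotypes
  panel <- dataset$genotypes
  meta <- panel$snp_meta
  if (is.null(snp_set)) snp_set <- meta$snp
  pass <- mac_filter(panel, ph$id, mac_threshold)[snp_set]
  snps <- snp_set[pass]
  mi <- match(snps, meta$snp)
  d <- panel$dosages[ph$id, snps, drop = FALSE]
  cnt <- colSums(round(d))
  mac <- pmin(cnt, 2 * nrow(d) - cnt)
  maf <- mac / (2 * nrow(d))
  base <- data.frame(replicate = dataset$replicate_index %||% NA_integer_,
                     chrom = meta$chrom[mi], pos = meta$pos[mi], snp = snps,
                     maf = maf, mac = as.integer(mac),
                     stringsAsFactors = FALSE, row.names = NULL)
  out <- list()

  if (approach %in% c("both", "interaction_model")) {
    rows <- interaction_scan(dataset, snps, covariates, vc_mode,
                             residual_model, control)
    rows <- cbind(base, rows, r_spearman = NA_real_, vc_mode = vc_mode,
                  stringsAsFactors = FALSE)
    out <- c(out, list(rows))
  }
  if (approach %in% c("both", "med_diff")) {
    rows <- med_diff_scan(dataset, snps, covariates, vc_mode, mac_threshold,
                          spearman_scope, control, chrom = meta$chrom[mi])
    rows <- cbind(base, rows, stringsAsFactors = FALSE)
    out <- c(out, list(rows))
  }
  res <- do.call(rbind_fill, out)
  rownames(res) <- NULL
  res
}

# interaction-model part of the scan
interaction_scan <- function(dataset, snps, covariates, vc_mode,
                             residual_model, control) {
  ph <- dataset$phenotypes
  y <- ph$sbp_t3
  Rsub <- dataset$R[ph$id, ph$id]
  groups <- if (residual_model == "heterogeneous") ph$med else NULL
  med <- as.numeric(ph$med)
  Ch <- NULL
  vc0 <- NULL
  if (vc_mode == "scan") {
    X0 <- gxe_design(ph, snp = NULL, with_med = TRUE, covariates = covariates)
    fit0 <- fit_lmm(y, X0, Rsub, groups, control)
    if (!fit0$converged)
      return(do.call(rbind, lapply(snps, function(s) {
        r <- interaction_test(lmm_nonconverged(NULL, length(y),
                                               "null model did not converge"))
        r
      })))
    gidx <- if (is.null(groups)) rep(1L, length(y)) else as.integer(factor(groups))
    V <- build_V(methods::as(Matrix::forceSymmetric(Rsub), "CsparseMatrix"),
                 fit0$vc$sigma2_additive, fit0$vc$sigma2_resid, gidx)
    Ch <- chol_V(V)
    vc0 <- fit0$vc
  }
  rows <- lapply(snps, function(s) {
    g <- dataset$genotypes$dosages[ph$id, s]
    X <- gxe_design(ph, snp = g, with_med = TRUE, with_interaction = TRUE,
                    covariates = covariates)
    fit <- if (vc_mode == "scan") {
      gls_fixed_vc(y, X, Ch, vc0, dataset$phenotypes$med)
    } else {
      tryCatch(fit_lmm(y, X, Rsub, groups, control),
               error = function(e)
                 lmm_nonconverged(colnames(X), length(y), "degenerate design"))
    }
    interaction_test(fit)
  })
  do.call(rbind, rows)
}

# med-diff part of the scan
med_diff_scan <- function(dataset, snps, covariates, vc_mode, mac_threshold,
                          spearman_scope, control, chrom) {
  ph <- dataset$phenotypes
  strata <- list(med = which(ph$med == 1L), unmed = which(ph$med == 0L))
  est <- list()
  for (label in names(strata)) {
    rows <- strata[[label]]
    nb <- length(rows)
    be <- rep(NA_real_, length(snps)); se <- rep(NA_real_, length(snps))
    reason <- rep(NA_character_, length(snps))
    if (nb < 2L) {
      reason[] <- "small stratified-sample size"
    } else {
      ids <- ph$id[rows]
      phs <- ph[rows, , drop = FALSE]
      y <- phs$sbp_t3
      Rsub <- dataset$R[ids, ids]
      passs <- mac_filter(dataset$genotypes, ids, mac_threshold)[snps]
      Ch <- NULL; vc0 <- NULL; ok0 <- TRUE
      if (vc_mode == "scan") {
        X0 <- gxe_design(phs, snp = NULL, with_med = FALSE,
                         covariates = covariates)
        fit0 <- fit_lmm(y, X0, Rsub, NULL, control)
        ok0 <- fit0$converged
        if (ok0) {
          V <- build_V(methods::as(Matrix::forceSymmetric(Rsub),
                                   "CsparseMatrix"),
                       fit0$vc$sigma2_additive, fit0$vc$sigma2_resid,
                       rep(1L, nb))
          Ch <- chol_V(V)
          vc0 <- fit0$vc
        }
      }
      for (k in seq_along(snps)) {
        if (!passs[k]) {
          reason[k] <- "small stratified-sample size"
          next
        }
        if (!ok0) {
          reason[k] <- "null model did not converge"
          next
        }
        g <- dataset$genotypes$dosages[ids, snps[k]]
        X <- gxe_design(phs, snp = g, with_med = FALSE, covariates = covariates)
        fit <- if (vc_mode == "scan") gls_fixed_vc(y, X, Ch, vc0)
               else tryCatch(fit_lmm(y, X, Rsub, NULL, control),
                             error = function(e)
                               lmm_nonconverged(colnames(X), nb,
                                                "degenerate design"))
        if (fit$converged) {
          be[k] <- fit$beta[["snp"]]
          se[k] <- sqrt(fit$covariance["snp", "snp"])
        } else reason[k] <- fit$reason
      }
    }
    est[[label]] <- list(beta = be, se = se, reason = reason)
  }

  # strata correlation per chromosome (fallback r = 0) or genome-wide
  rvec <- rep(0, length(snps))
  grp <- if (spearman_scope == "per_chromosome") chrom else rep("all", length(snps))
  for (ch in unique(grp)) {
    idx <- which(grp == ch)
    rc <- tryCatch(spearman_strata_correlation(est$med$beta[idx],
                                               est$unmed$beta[idx],
                                               scope = spearman_scope)$r,
                   error = function(e) {
                     message("strata correlation fallback to r = 0 for chromosome ",
                             ch, ": ", conditionMessage(e))
                     0
                   })
    rvec[idx] <- rc
  }

  rows <- lapply(seq_along(snps), function(k) {
    b1 <- est$med$beta[k]; b0 <- est$unmed$beta[k]
    if (is.na(b1) || is.na(b0)) {
      r <- data.frame(approach = "med_diff", beta_effect = NA_real_,
                      se_effect = NA_real_, beta_snp_med = NA_real_,
                      beta_snp_unmed = NA_real_, p_1df = NA_real_,
                      p_2df = NA_real_, converged = FALSE,
                      reason = paste(stats::na.omit(c(est$med$reason[k],
                                                      est$unmed$reason[k])),
                                     collapse = "; "),
                      stringsAsFactors = FALSE)
    } else {
      se1 <- est$med$se[k]; se0 <- est$unmed$se[k]
      v_diff <- se1^2 + se0^2 - 2 * rvec[k] * se1 * se0
      if (!is.finite(v_diff) || v_diff <= 0) {
        r <- data.frame(approach = "med_diff", beta_effect = NA_real_,
                        se_effect = NA_real_, beta_snp_med = b1,
                        beta_snp_unmed = b0, p_1df = NA_real_,
                        p_2df = NA_real_, converged = FALSE,
                        reason = "nonpositive variance of stratum difference",
                        stringsAsFactors = FALSE)
      } else {
        z <- (b1 - b0) / sqrt(v_diff)
        x2 <- (b1 / se1)^2 + (b0 / se0)^2
        r <- data.frame(approach = "med_diff", beta_effect = b1 - b0,
                        se_effect = sqrt(v_diff), beta_snp_med = b1,
                        beta_snp_unmed = b0, p_1df = 2 * pnorm(-abs(z)),
                        p_2df = pchisq(x2, 2L, lower.tail = FALSE),
                        converged = TRUE, reason = NA_character_,
                        stringsAsFactors = FALSE)
      }
    }
    r$r_spearman <- rvec[k]
    r$vc_mode <- vc_mode
    r
  })
  do.call(rbind, rows)
}

# rbind data frames with differing columns, filling with NA
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[cols]
  })
  do.call(rbind, dfs)
}
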