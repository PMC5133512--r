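#' Wilson score confidence interval for a proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return Numeric vector `c(low, high)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

clopper_pearson_ci <- function(k, n, conf = 0.95) {
  a <- 1 - conf
  c(low = if (k == 0) 0 else qbeta(a / 2, k, n - k + 1),
    high = if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k))
}

prop_summary <- function(k, n, conf, method) {
  ci <- if (n == 0) c(low = NA_real_, high = NA_real_)
        else if (method == "wilson") wilson_ci(k, n, conf)
        else clopper_pearson_ci(k, n, conf)
  data.frame(n = n, k = k, proportion = if (n == 0) NA_real_ else k / n,
             ci_low = ci[["low"]], ci_high = ci[["high"]])
}

#' True-positive proportion at a causal SNP
#'
#' Proportion of converged replicate tests with the selected p-value below
#' `alpha`, with a 95% Wilson score interval (Clopper-Pearson by flag).
#'
#' @param results scan-result rows restricted to one causal SNP and one
#'   approach (multiple replicates).
#' @param alpha significance criterion (default 0.05).
#' @param test `"1df"` or `"2df"`.
#' @param conf CI level.
#' @param ci_method `"wilson"` or `"clopper-pearson"`.
#' @return One-row data frame: `test`, `n` (converged replicates), `k`,
#'   `proportion`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' # 132 of 200 converged replicates significant -> 66.0%
tpp <- function(results, alpha = 0.05, test = c("1df", "2df"), conf = 0.95,
                ci_method = c("wilson", "clopper-pearson")) {
  test <- match.arg(test)
  ci_method <- match.arg(ci_method)
  stopifnot(nrow(results) >= 1L)
  conv <- results[results$converged, , drop = FALSE]
  if (nrow(conv) == 0L)
    stop("no converged replicates: TPP undefined", call. = FALSE)
  p <- conv[[if (test == "1df") "p_1df" else "p_2df"]]
  cbind(data.frame(test = test), prop_summary(sum(p < alpha), length(p),
                                              conf, ci_method))
}

#' False-positive proportion by MAF bin
#'
#' Pools SNP-by-replicate tests that are null by construction: every SNP
#' within `window_bp` of a causal position on the same chromosome is
#' excluded (closed window, so a causal SNP at chr7:99,457,518 with the
#' default 500 kb window excludes chr7:98,957,518-99,957,518 inclusive).
#' Remaining converged tests are binned by MAF (left-open, right-closed
#' bins) and the proportion significant at `alpha` is reported per bin with
#' a Wilson interval. `mode = "per_replicate"` instead averages the
#' per-replicate proportions within each bin (CI on the pooled counts).
#'
#' @param results scan-result rows for one approach (may span replicates).
#' @param causal_loci data frame with `chrom`, `pos` of simulated effects
#'   (possibly empty).
#' @param window_bp exclusion half-window in base pairs.
#' @param maf_bins bin edges covering (0, 0.5].
#' @param alpha significance criterion.
#' @param test `"1df"` or `"2df"`.
#' @param mode pooling mode.
#' @param conf,ci_method CI settings, see [tpp()].
#' @return Data frame per bin: `maf_bin`, `test`, `n`, `k`, `proportion`,
#'   `ci_low`, `ci_high` (rows with `n = 0` flag empty bins).
#' @export
fpp <- function(results, causal_loci = NULL, window_bp = 500000L,
                maf_bins = c(0.001, 0.01, 0.05, 0.10, 0.20, 0.50),
                alpha = 0.05, test = c("1df", "2df"),
                mode = c("pooled", "per_replicate"), conf = 0.95,
                ci_method = c("wilson", "clopper-pearson")) {
  test <- match.arg(test)
  mode <- match.arg(mode)
  ci_method <- match.arg(ci_method)
  keep <- rep(TRUE, nrow(results))
  if (!is.null(causal_loci) && nrow(causal_loci)) {
    for (i in seq_len(nrow(causal_loci))) {
      hit <- results$chrom == as.character(causal_loci$chrom[i]) &
        abs(results$pos - causal_loci$pos[i]) <= window_bp
      keep <- keep & !hit
    }
  }
  res <- results[keep & results$converged, , drop = FALSE]
  pcol <- if (test == "1df") "p_1df" else "p_2df"
  bins <- cut(res$maf, breaks = maf_bins, include.lowest = FALSE)
  out <- lapply(levels(bins), function(b) {
    sub <- res[!is.na(bins) & bins == b, , drop = FALSE]
    n <- nrow(sub)
    k <- sum(sub[[pcol]] < alpha)
    row <- cbind(data.frame(maf_bin = b, test = test),
                 prop_summary(k, n, conf, ci_method))
    if (mode == "per_replicate" && n > 0) {
      per <- tapply(sub[[pcol]] < alpha, sub$replicate, mean)
      row$proportion <- mean(per)
    }
    row
  })
  do.call(rbind, out)
}

#' Convergence bookkeeping across a scan
#'
#' Counts converged and attempted tests per approach (and optionally per
#' SNP). A med-diff test counts as converged only when both stratified
#' fits converged, which is why its totals fall below the interaction
#' model's.
#'
#' @param results scan-result rows.
#' @param by `"approach"` or `"snp"`.
#' @return Data frame of `n_tests`, `n_converged`, `prop_converged`.
#' @export
convergence_summary <- function(results, by = c("approach", "snp")) {
  by <- match.arg(by)
  if (nrow(results) == 0L)
    return(data.frame(approach = character(0), n_tests = integer(0),
                      n_converged = integer(0), prop_converged = numeric(0)))
  keys <- if (by == "approach") list(approach = results$approach)
          else list(approach = results$approach, snp = results$snp)
  agg <- aggregate(results$converged, keys,
                   FUN = function(v) c(n = length(v), k = sum(v)))
  out <- cbind(agg[setdiff(names(agg), "x")],
               n_tests = agg$x[, "n"], n_converged = agg$x[, "k"])
  out$prop_converged <- out$n_converged / out$n_tests
  out
}

#' Analytic power for interaction and joint tests
#'
#' Closed-form power under an additive SNP coding (variance `2p(1-p)`),
#' a binary exposure with prevalence `q` independent of genotype, and an
#' effective sample size `n_eff` discounting family correlation. The
#' noncentrality is `n_eff * beta^2 * 2p(1-p) * q(1-q) / sigma2_resid` for
#' the 1-df interaction test and `n_eff * beta^2 * 2p(1-p) / sigma2_resid`
#' for the 2-df joint test of a main effect; power is the upper tail of the
#' noncentral chi-square at the central `1 - alpha` quantile.
#'
#' @param maf minor allele frequency `p`.
#' @param exposure_prevalence exposure probability `q` (ignored for
#'   `df = 2`).
#' @param beta effect size, mm Hg.
#' @param sigma2_resid residual variance, mm Hg^2.
#' @param n_eff effective sample size (see [effective_sample_size()]).
#' @param alpha significance level.
#' @param df 1 (interaction) or 2 (joint main-effect test).
#' @return Power in \[0, 1\].
#' @export
#' @examples
#' analytic_power(maf = 0.027, exposure_prevalence = 0.327, beta = 9.91,
#'                sigma2_resid = 127, n_eff = 849, df = 2)
analytic_power <- function(maf, exposure_prevalence, beta, sigma2_resid,
                           n_eff, alpha = 0.05, df = 1L) {
  stopifnot(maf > 0, maf <= 0.5, sigma2_resid > 0, n_eff >= 1,
            alpha > 0, alpha < 1, df %in% c(1L, 2L))
  lambda <- n_eff * beta^2 * 2 * maf * (1 - maf) / sigma2_resid
  if (df == 1L) {
    q <- exposure_prevalence
    stopifnot(q >= 0, q <= 1)
    lambda <- lambda * q * (1 - q)
  }
  crit <- qchisq(1 - alpha, df)
  pchisq(crit, df, ncp = lambda, lower.tail = FALSE)
}

#' Effective sample size of a correlated (family) sample
#'
#' @param n_total total number of individuals.
#' @param factor information fraction retained (default 0.8).
#' @return `round(n_total * factor)` as an integer.
#' @export
#' @examples
#' effective_sample_size(1061)  # 849
effective_sample_size <- function(n_total, factor = 0.8) {
  stopifnot(n_total >= 1, factor > 0, factor <= 1)
  as.integer(round(n_total * factor))
}
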