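#' Assign medication status
#'
#' Default (`mode = "bernoulli"`): independent Bernoulli(prevalence) per
#' individual, mirroring a cross-sectional snapshot of antihypertensive use
#' at the analysed time point, with no dependence on the phenotype. An
#' optional indication mode medicates the top `prevalence` fraction of a
#' supplied latent pre-treatment blood pressure, inducing
#' treatment-by-indication confounding; it is off by default because the
#' calibration experiments do not require confounding.
#'
#' @param pedigree a `fam_pedigree`.
#' @param prevalence probability (bernoulli) or medicated fraction
#'   (indication) of medication use.
#' @param seed integer seed (ties in indication mode are broken randomly).
#' @param mode `"bernoulli"` (default) or `"indication"`.
#' @param latent latent pre-treatment trait vector aligned with the
#'   pedigree; required for indication mode (e.g. a [simulate_phenotype()]
#'   run with medication all zero).
#' @return Integer 0/1 vector named by individual id, with attribute
#'   `realized_prevalence`.
#' @export
assign_medication <- function(pedigree, prevalence, seed,
                              mode = c("bernoulli", "indication"),
                              latent = NULL) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  mode <- match.arg(mode)
  set.seed(seed)
  n <- nrow(pedigree)
  if (mode == "bernoulli") {
    med <- rbinom(n, 1L, prevalence)
  } else {
    if (is.null(latent) || length(latent) != n)
      stop("indication mode needs a latent trait vector aligned with the pedigree",
           call. = FALSE)
    k <- round(prevalence * n)
    med <- integer(n)
    med[order(latent + runif(n) * 1e-9, decreasing = TRUE)[seq_len(k)]] <- 1L
  }
  names(med) <- pedigree$id
  attr(med, "realized_prevalence") <- mean(med)
  med
}

#' Simulate an SBP-like phenotype on a pedigree
#'
#' Generates `sbp_t3 = intercept + beta_age * age + beta_sex * I(female) +
#' sum(beta_snp * G) + beta_med * med + sum(beta_int * G * med) + g + e`
#' where `g ~ N(0, sigma2_additive * R)` is the polygenic component and `e`
#' has variance `sigma2_resid_med` for medicated and `sigma2_resid_unmed`
#' for unmedicated individuals. Ages are drawn from a truncated normal
#' (inverse-CDF method); sex is taken from the pedigree. Under the default
#' carrier-nonresponse scenario (`beta_snp = 0`, `beta_med = -6.2`,
#' `beta_int = +6.2`) a medicated heterozygous carrier has expected
#' treatment benefit exactly 0.
#'
#' @param pedigree a `fam_pedigree`.
#' @param genotypes a `genotype_panel` (must contain every causal SNP).
#' @param med 0/1 medication vector aligned with the pedigree.
#' @param R relationship matrix aligned with the pedigree.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return Phenotype data frame: `id`, `sbp_t3`, `age`, `sex`, `med`.
#' @export
simulate_phenotype <- function(pedigree, genotypes, med, R, config, seed) {
  config <- validate_sim_config(config)
  n <- nrow(pedigree)
  stopifnot(length(med) == n, nrow(R) == n)
  med <- as.integer(med)  # drop names/attributes from assign_medication
  set.seed(seed)
  ad <- config$age_distribution
  lo <- pnorm(ad$min, ad$mean, ad$sd)
  hi <- pnorm(ad$max, ad$mean, ad$sd)
  age <- qnorm(runif(n, lo, hi), ad$mean, ad$sd)
  sexf <- as.numeric(pedigree$sex == "female")

  mu <- config$intercept + config$beta_age * age + config$beta_sex * sexf +
    config$beta_med * med
  for (cs in config$causal_snps) {
    if (!cs$name %in% colnames(genotypes$dosages))
      stop("causal SNP ", cs$name, " not present in the genotype panel",
           call. = FALSE)
    g <- genotypes$dosages[pedigree$id, cs$name]
    mu <- mu + cs$beta_snp * g + cs$beta_int * g * med
  }

  g_poly <- numeric(n)
  if (config$sigma2_additive > 0) {
    for (f in unique(pedigree$family)) {
      rows <- which(pedigree$family == f)
      Rf <- as.matrix(R[rows, rows, drop = FALSE])
      L <- tryCatch(chol(Rf),
                    error = function(e)
                      stop("relationship matrix block for family ", f,
                           " is not positive semidefinite: ",
                           conditionMessage(e), call. = FALSE))
      g_poly[rows] <- sqrt(config$sigma2_additive) *
        drop(crossprod(L, rnorm(length(rows))))
    }
  }
  sde <- sqrt(ifelse(med == 1, config$sigma2_resid_med,
                     config$sigma2_resid_unmed))
  e <- rnorm(n, 0, sde)
  data.frame(id = pedigree$id, sbp_t3 = mu + g_poly + e, age = age,
             sex = pedigree$sex, med = as.integer(med),
             stringsAsFactors = FALSE)
}

# deterministic per-replicate substream seed, kept below 2^31
replicate_seed <- function(seed, r, stream = 0L) {
  as.integer((as.double(seed) + 99991 * as.double(r) + 31 * stream) %%
             2147483647)
}

#' Generate a replicate family study
#'
#' Runs the full synthetic-data pipeline: one pedigree, one gene-dropped
#' genotype panel (causal SNPs first, then the null SNPs spread round-robin
#' over `null_chroms`), the numerator relationship matrix, founder principal
#' components (LD-pruned founder-polymorphic null SNPs, `k` components)
#' projected to all individuals, and `n_replicates` phenotype replicates.
#' Genotypes, pedigree and PC scores are fixed across replicates; medication
#' and phenotypes are re-simulated per replicate from a deterministic
#' function of `(seed, replicate)`.
#'
#' @param config a [sim_config()].
#' @param k_pcs number of principal components attached to the phenotype
#'   tables (0 disables PCA).
#' @param ld_r2 LD-pruning threshold for the PC SNP subset.
#' @return A list of class `replicate_set`: `pedigree`, `genotypes`, `R`,
#'   `pc_model`, `pc_scores`, `phenotypes` (list of per-replicate data
#'   frames with `pc1..pck` appended), `med` (matrix n x replicates),
#'   `truth` (data frame of generating parameters per causal SNP), `config`.
#' @export
generate_replicates <- function(config, k_pcs = 5L, ld_r2 = 0.2) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  pedigree <- generate_pedigree(config)

  if (is.null(config$maf_list)) {
    null_mafs <- runif(config$n_null_snps, config$null_maf_range[1],
                       config$null_maf_range[2])
  } else {
    null_mafs <- config$maf_list
  }
  m0 <- length(null_mafs)
  chroms <- rep(config$null_chroms, length.out = m0)
  pos <- 10000000L + 1000000L * (seq_len(m0) - 1L) %/% length(config$null_chroms)
  nm <- sprintf("null_%03d_chr%s_%d", seq_len(m0), chroms, pos)
  cs_maf <- vapply(config$causal_snps, `[[`, numeric(1), "maf")
  cs_chrom <- vapply(config$causal_snps, `[[`, character(1), "chrom")
  cs_pos <- vapply(config$causal_snps, `[[`, integer(1), "pos")
  cs_name <- vapply(config$causal_snps, `[[`, character(1), "name")
  genotypes <- drop_genotypes(pedigree,
                              maf_list = c(cs_maf, null_mafs),
                              seed = replicate_seed(config$seed, 0L, 1L),
                              chrom = c(cs_chrom, chroms),
                              pos = c(cs_pos, pos),
                              snp_names = c(cs_name, nm))
  R <- numerator_relationship_matrix(pedigree)

  pc_model <- NULL
  pc_scores <- NULL
  if (k_pcs > 0L && m0 > 0L) {
    founders <- pedigree$id[pedigree$founder]
    fd <- genotypes$dosages[founders, nm, drop = FALSE]
    poly <- nm[apply(fd, 2L, var) > 0]
    pruned <- ld_prune(genotype_panel(genotypes$dosages[, poly, drop = FALSE],
                                      chrom = genotypes$snp_meta$chrom[match(poly, genotypes$snp_meta$snp)],
                                      pos = genotypes$snp_meta$pos[match(poly, genotypes$snp_meta$snp)]),
                       r2_threshold = ld_r2, subset = founders)
    k_use <- min(k_pcs, length(pruned) - 1L, length(founders) - 1L)
    if (k_use >= 1L) {
      pc_model <- founder_pca(genotypes, founders, snp_subset = pruned,
                              k = k_use)
      pc_scores <- project_pcs(pc_model, genotypes)
    }
  }

  truth <- data.frame(snp = cs_name, chrom = cs_chrom, pos = cs_pos,
                      maf = cs_maf,
                      beta_snp = vapply(config$causal_snps, `[[`, numeric(1),
                                        "beta_snp"),
                      beta_int = vapply(config$causal_snps, `[[`, numeric(1),
                                        "beta_int"),
                      beta_med = rep(config$beta_med, length(cs_name)),
                      stringsAsFactors = FALSE)

  phenotypes <- vector("list", config$n_replicates)
  med <- matrix(0L, nrow(pedigree), config$n_replicates,
                dimnames = list(pedigree$id, NULL))
  for (r in seq_len(config$n_replicates)) {
    med_r <- assign_medication(pedigree, config$med_prevalence,
                               seed = replicate_seed(config$seed, r, 2L))
    ph <- simulate_phenotype(pedigree, genotypes, med_r, R, config,
                             seed = replicate_seed(config$seed, r, 3L))
    if (!is.null(pc_scores))
      ph <- cbind(ph, as.data.frame(pc_scores[ph$id, , drop = FALSE]))
    phenotypes[[r]] <- ph
    med[, r] <- med_r
  }
  structure(list(pedigree = pedigree, genotypes = genotypes, R = R,
                 pc_model = pc_model, pc_scores = pc_scores,
                 phenotypes = phenotypes, med = med, truth = truth,
                 config = config),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Replicate set: %d replicates, %d individuals (%d families), %d SNPs\n",
              length(x$phenotypes), nrow(x$pedigree),
              length(unique(x$pedigree$family)), ncol(x$genotypes$dosages)))
  if (nrow(x$truth))
    cat("  causal SNPs:", paste(x$truth$snp, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one replicate dataset
#'
#' @param set a `replicate_set`.
#' @param r replicate index.
#' @return A list of class `replicate_dataset` with `pedigree`, `genotypes`,
#'   `phenotypes`, `R`, `truth`, `replicate_index`.
#' @export
replicate_dataset <- function(set, r) {
  stopifnot(r >= 1L, r <= length(set$phenotypes))
  structure(list(pedigree = set$pedigree, genotypes = set$genotypes,
                 phenotypes = set$phenotypes[[r]], R = set$R,
                 truth = set$truth, replicate_index = as.integer(r)),
            class = "replicate_dataset")
}
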