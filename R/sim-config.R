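#' Describe a causal SNP for the phenotype simulator
#'
#' A causal SNP carries an additive main effect (`beta_snp`, mm Hg per minor
#' allele) and/or a SNP-by-medication interaction effect (`beta_int`, mm Hg per
#' minor allele among medicated individuals). The default carrier-nonresponse
#' configuration pairs `beta_int = +6.2` with a medication main effect of
#' `-6.2` mm Hg, so a medicated heterozygous carrier has an expected treatment
#' benefit of exactly zero.
#'
#' @param maf minor allele frequency used for gene dropping, in (0, 0.5].
#' @param beta_snp additive SNP main effect, mm Hg per minor allele.
#' @param beta_int SNP-by-medication interaction effect, mm Hg.
#' @param chrom chromosome label.
#' @param pos 1-based base-pair position.
#' @param name SNP identifier.
#' @return A list of class `causal_snp`.
#' @export
#' @examples
#' causal_snp(maf = 0.054, beta_int = 6.2)
causal_snp <- function(maf, beta_snp = 0, beta_int = 0,
                       chrom = "7", pos = 99457605L,
                       name = sprintf("snp_%s_%d", chrom, pos)) {
  stopifnot(is.numeric(maf), length(maf) == 1L, maf > 0, maf <= 0.5,
            is.numeric(beta_snp), is.numeric(beta_int), pos >= 1)
  structure(list(name = as.character(name), chrom = as.character(chrom),
                 pos = as.integer(pos), maf = maf,
                 beta_snp = beta_snp, beta_int = beta_int),
            class = "causal_snp")
}

#' Simulation configuration for family-based G x E experiments
#'
#' Assembles and validates every parameter of the synthetic cohort: pedigree
#' template, null-SNP panel, causal SNPs, medication model, covariate effects
#' and variance components. Defaults reproduce the carrier-nonresponse
#' scenario: 20 extended three-generation families totalling 1,080 individuals
#' (120 founders), a causal SNP of MAF 5.4% with interaction effect +6.2 mm Hg
#' and no main effect, medication main effect -6.2 mm Hg at prevalence 32.7%,
#' additive polygenic variance 54.3 mm Hg^2 and medication-specific residual
#' variances 118.9 / 142.7 mm Hg^2 (total phenotypic variance about 181).
#'
#' @param n_families number of disjoint extended families.
#' @param family_template list with `n_generations` (1-3), `gen2_children`
#'   (children of the founder couple, each marrying in a founder spouse) and
#'   `gen3_children` (children per second-generation couple).
#' @param n_null_snps number of non-causal SNPs in the panel.
#' @param null_maf_range range from which null-SNP MAFs are drawn uniformly;
#'   ignored when `maf_list` is supplied.
#' @param maf_list optional explicit vector of null-SNP MAFs.
#' @param null_chroms chromosome labels over which null SNPs are spread
#'   round-robin (defaults to the odd autosomes).
#' @param causal_snps list of [causal_snp()] descriptions (possibly empty).
#' @param beta_med medication main effect, mm Hg.
#' @param med_prevalence Bernoulli probability of medication use.
#' @param sigma2_additive polygenic (additive) variance, mm Hg^2.
#' @param sigma2_resid_unmed,sigma2_resid_med residual variances by medication
#'   status, mm Hg^2.
#' @param intercept,beta_age,beta_sex fixed effects: intercept (mm Hg), age
#'   slope (mm Hg/yr) and female effect (mm Hg).
#' @param age_distribution list `mean`, `sd`, `min`, `max` of the truncated
#'   normal age distribution (years).
#' @param prop_female expected cohort proportion of females.
#' @param n_replicates number of phenotype replicates.
#' @param seed integer seed from which all randomness is derived.
#' @return A validated list of class `sim_config`.
#' @seealso [scenario_carrier_nonresponse()], [scenario_main_effect()],
#'   [scenario_null()], [generate_replicates()]
#' @export
sim_config <- function(n_families = 20L,
                       family_template = list(n_generations = 3L,
                                              gen2_children = 4L,
                                              gen3_children = 11L),
                       n_null_snps = 200L,
                       null_maf_range = c(0.05, 0.5),
                       maf_list = NULL,
                       null_chroms = as.character(seq(1L, 21L, by = 2L)),
                       causal_snps = list(causal_snp(maf = 0.054,
                                                     beta_snp = 0,
                                                     beta_int = 6.2)),
                       beta_med = -6.2,
                       med_prevalence = 0.327,
                       sigma2_additive = 54.3,
                       sigma2_resid_unmed = 118.9,
                       sigma2_resid_med = 142.7,
                       intercept = 135,
                       beta_age = 0.4,
                       beta_sex = -3,
                       age_distribution = list(mean = 48.1, sd = 15,
                                               min = 18, max = 101),
                       prop_female = 0.58,
                       n_replicates = 200L,
                       seed = 20160501L) {
  cfg <- list(n_families = as.integer(n_families),
              family_template = family_template,
              n_null_snps = as.integer(n_null_snps),
              null_maf_range = as.numeric(null_maf_range),
              maf_list = maf_list,
              null_chroms = as.character(null_chroms),
              causal_snps = causal_snps,
              beta_med = beta_med,
              med_prevalence = med_prevalence,
              sigma2_additive = sigma2_additive,
              sigma2_resid_unmed = sigma2_resid_unmed,
              sigma2_resid_med = sigma2_resid_med,
              intercept = intercept,
              beta_age = beta_age,
              beta_sex = beta_sex,
              age_distribution = age_distribution,
              prop_female = prop_female,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  tpl <- cfg$family_template
  if (cfg$n_families < 1L)
    stop("configuration error: n_families must be >= 1", call. = FALSE)
  if (is.null(tpl$n_generations) || tpl$n_generations < 1L)
    stop("configuration error: family template needs >= 1 generation",
         call. = FALSE)
  if (tpl$n_generations > 3L)
    stop("configuration error: family template supports at most 3 generations",
         call. = FALSE)
  if (tpl$n_generations >= 2L && (is.null(tpl$gen2_children) || tpl$gen2_children < 1L))
    stop("configuration error: gen2_children must be >= 1", call. = FALSE)
  if (tpl$n_generations >= 3L && (is.null(tpl$gen3_children) || tpl$gen3_children < 1L))
    stop("configuration error: gen3_children must be >= 1", call. = FALSE)
  if (!is.null(cfg$maf_list)) {
    if (any(cfg$maf_list <= 0 | cfg$maf_list > 0.5))
      stop("configuration error: MAFs must lie in (0, 0.5]", call. = FALSE)
  } else {
    if (length(cfg$null_maf_range) != 2L ||
        cfg$null_maf_range[1] <= 0 || cfg$null_maf_range[2] > 0.5 ||
        diff(cfg$null_maf_range) < 0)
      stop("configuration error: null_maf_range must lie in (0, 0.5]",
           call. = FALSE)
  }
  for (cs in cfg$causal_snps)
    if (!inherits(cs, "causal_snp"))
      stop("configuration error: causal_snps must be causal_snp() objects",
           call. = FALSE)
  probs <- c(cfg$med_prevalence, cfg$prop_female)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0,1]", call. = FALSE)
  vars <- c(cfg$sigma2_additive, cfg$sigma2_resid_unmed, cfg$sigma2_resid_med)
  if (any(vars < 0))
    stop("configuration error: variances must be >= 0", call. = FALSE)
  ad <- cfg$age_distribution
  if (!(ad$min <= ad$mean && ad$mean <= ad$max) || ad$sd < 0)
    stop("configuration error: age distribution needs min <= mean <= max, sd >= 0",
         call. = FALSE)
  if (cfg$n_replicates < 1L)
    stop("configuration error: n_replicates must be >= 1", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  tpl <- x$family_template
  cat("Family G x E simulation configuration\n")
  cat(sprintf("  families: %d (template %d generations, %s gen-2, %s gen-3 children)\n",
              x$n_families, tpl$n_generations,
              tpl$gen2_children %||% "-", tpl$gen3_children %||% "-"))
  cat(sprintf("  null SNPs: %d%s; causal SNPs: %d\n", x$n_null_snps,
              if (is.null(x$maf_list))
                sprintf(" (MAF uniform %.3f-%.3f)", x$null_maf_range[1],
                        x$null_maf_range[2]) else " (explicit MAFs)",
              length(x$causal_snps)))
  for (cs in x$causal_snps)
    cat(sprintf("    %s chr%s:%d MAF %.3f beta_snp %.2f beta_int %.2f\n",
                cs$name, cs$chrom, cs$pos, cs$maf, cs$beta_snp, cs$beta_int))
  cat(sprintf("  medication: effect %.1f mm Hg, prevalence %.3f\n",
              x$beta_med, x$med_prevalence))
  cat(sprintf("  variances: additive %.1f, residual %.1f (unmed) / %.1f (med)\n",
              x$sigma2_additive, x$sigma2_resid_unmed, x$sigma2_resid_med))
  cat(sprintf("  replicates: %d, seed %d\n", x$n_replicates, x$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ready-made simulation scenarios
#'
#' Convenience wrappers around [sim_config()] for the three study conditions:
#' a carrier-nonresponse interaction scenario (a SNP whose minor-allele
#' carriers do not respond to a -6.2 mm Hg medication effect, interaction
#' +6.2 mm Hg), a strong-main-effect scenario (-9.91 mm Hg per minor allele
#' at MAF 2.7%, no interaction), and a null scenario with no genetic effects
#' for false-positive-proportion experiments.
#'
#' @param maf minor allele frequency of the causal SNP.
#' @param n_replicates number of phenotype replicates.
#' @param ... further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
scenario_carrier_nonresponse <- function(maf = 0.054, n_replicates = 200L, ...) {
  sim_config(causal_snps = list(causal_snp(maf = maf, beta_snp = 0,
                                           beta_int = 6.2, chrom = "7",
                                           pos = 99457605L,
                                           name = "gxe_causal")),
             n_replicates = n_replicates, ...)
}

#' @rdname scenario_carrier_nonresponse
#' @export
scenario_main_effect <- function(maf = 0.027, n_replicates = 100L, ...) {
  sim_config(causal_snps = list(causal_snp(maf = maf, beta_snp = -9.91,
                                           beta_int = 0, chrom = "3",
                                           pos = 48040283L,
                                           name = "main_causal")),
             n_replicates = n_replicates, ...)
}

#' @rdname scenario_carrier_nonresponse
#' @param n_null_snps number of null SNPs.
#' @param null_maf_range MAF range for the null SNPs.
#' @export
scenario_null <- function(n_null_snps = 400L, null_maf_range = c(0.01, 0.5),
                          n_replicates = 50L, ...) {
  sim_config(causal_snps = list(), n_null_snps = n_null_snps,
             null_maf_range = null_maf_range, n_replicates = n_replicates, ...)
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML file mirrors [sim_config()] field for field; `causal_snps` is a
#' sequence of mappings with keys `maf`, `beta_snp`, `beta_int`, `chrom`,
#' `pos`, `name`.
#'
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$causal_snps))
    raw$causal_snps <- lapply(raw$causal_snps, function(cs) do.call(causal_snp, cs))
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  out$causal_snps <- lapply(out$causal_snps, unclass)
  yaml::write_yaml(out, path)
  invisible(path)
}
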