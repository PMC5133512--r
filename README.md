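# famgxe

Family-based gene-medication interaction models for quantitative traits.

## The problem

A genetic variant can modify how strongly antihypertensive medication
lowers systolic blood pressure (SBP). Two complementary approaches are used
to detect such gene-by-environment (G x E) interactions:

* the **interaction model** — one linear mixed model per SNP,

  `SBP = a + b_SNP G + b_Med M + b_Int G*M + b_C X_C + g + e`,

  with a 1-df Wald test of `b_Int` and a 2-df joint Wald test of
  `(b_SNP, b_Int)`;

* the **med-diff approach** — medication-stratified mixed models combined
  via the correlation-corrected difference statistic

  `Z = (b1 - b0) / sqrt(SE1^2 + SE0^2 - 2 r SE1 SE0) ~ N(0,1)`

  (`r` = Spearman rank correlation of per-SNP estimates between strata)
  and the 2-df joint statistic `z1^2 + z0^2 ~ chi-square(2)`.

In extended pedigrees both need a polygenic random effect
`g ~ N(0, sigma_a^2 R)` with `R` the numerator relationship matrix,
ancestry principal components computed in founders and projected to
relatives, and residual variances that may differ by medication status.
`famgxe` implements both approaches plus a synthetic family-data generator
(gene dropping through three-generation pedigrees, Bernoulli medication
assignment, SBP-like phenotypes with a carrier-nonresponse interaction),
so power and false-positive calibration experiments run entirely at desk
scale. See the methods vignette (`vignettes/family-gxe-methods.Rmd`) for
the model details and default parameters.

## Worked example

Simulate one replicate of the default carrier-nonresponse scenario —
20 extended families (1,080 individuals), a causal SNP of MAF 5.4% whose
minor-allele carriers do not respond to a -6.2 mm Hg medication effect
(interaction +6.2 mm Hg) — and analyse it with both approaches:

```r
library(famgxe)
cfg <- scenario_carrier_nonresponse(n_replicates = 1, seed = 42)
rs  <- generate_replicates(cfg)
ds  <- replicate_dataset(rs, 1)

fit <- fit_model1(ds, "gxe_causal")   # SNP + med + SNP*med + age + sex + PCs
interaction_test(fit)
#>            approach beta_effect se_effect beta_snp_main  beta_med        p_1df
#> 1 interaction_model    11.19855  3.015729     -2.357843 -6.071851 0.0002045091
#>          p_2df converged reason
#> 1 0.0007965698      TRUE   <NA>

sf <- stratified_fits(ds, "gxe_causal")
med_diff_test(sf, r = 0)
#>   approach beta_effect se_effect beta_snp_med beta_snp_unmed       p_1df
#> 1 med_diff    10.12754  3.530601      8.25363       -1.87391 0.004124192
#>        p_2df converged reason
#> 1 0.01045601      TRUE   <NA>
```

In this replicate the interaction model estimates the SNP-by-medication
effect at 11.2 mm Hg (SE 3.0; single replicates scatter widely around the
simulated 6.2 — averaged over 200 replicates the estimator is unbiased),
the medication main effect at -6.1 mm Hg, and both 1-df tests reject at
p < 0.01. The med-diff approach sees the same signal as a stratum
difference of 10.1 mm Hg (medicated slope 8.3, unmedicated -1.9).

Scans and summaries:

```r
res <- run_scan(ds, approach = "both")        # every SNP, both approaches
convergence_summary(res)
fpp(res, causal_loci = rs$truth)              # FPP by MAF bin, 500 kb exclusion
analytic_power(maf = 0.027, exposure_prevalence = 0.327, beta = 9.91,
               sigma2_resid = 127, n_eff = effective_sample_size(1061),
               df = 2)                        # a priori power, 2-df joint test
```

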