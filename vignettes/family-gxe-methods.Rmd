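---
title: "Methods: family-based gene-medication interaction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based gene-medication interaction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famgxe)
```

## The scientific problem

Antihypertensive response varies widely between individuals, and part of
that variability is genetic: a variant may blunt or abolish the
blood-pressure-lowering effect of medication. Two complementary strategies
are in routine use to detect such gene-by-medication (G x E) interactions
in a quantitative trait such as systolic blood pressure (SBP):

* **Interaction model.** One model containing the SNP, the exposure, and
  their product:

  $$\mathrm{SBP} = \alpha + \beta_{SNP} G + \beta_{Med} M +
    \beta_{Int}\, G M + \beta_C X_C + g + e,$$

  with Wald tests of $\beta_{Int}$ (1 df) and of
  $(\beta_{SNP}, \beta_{Int})$ jointly (2 df) using the estimated
  $2\times 2$ coefficient covariance block
  $\begin{pmatrix}\operatorname{Var}(\beta_{SNP}) &
  \operatorname{Cov}(\beta_{SNP},\beta_{Int})\\
  \operatorname{Cov}(\beta_{SNP},\beta_{Int}) &
  \operatorname{Var}(\beta_{Int})\end{pmatrix}$.

* **Med-diff approach.** Fit the SNP main effect separately within the
  medicated and unmedicated strata, then test the difference

  $$Z_{1df} = \frac{\beta_{1} - \beta_{0}}
    {\sqrt{SE_1^2 + SE_0^2 - 2 r\, SE_1 SE_0}} \sim N(0,1),$$

  where $r$ is the Spearman rank correlation of the per-SNP estimates
  between strata (a correction for the two strata not being independent,
  e.g. because relatives span both), and jointly
  $X_{2df} = z_1^2 + z_0^2 \sim \chi^2(2)$.

In family data both approaches must absorb the phenotypic correlation
between relatives: every model carries a polygenic random effect
$g \sim N(0, \sigma_a^2 R)$ with $R$ the pedigree numerator relationship
matrix, plus age, sex and ancestry principal components as covariates, and
the residual variance is allowed to differ by medication status.

The package implements both approaches end to end, together with a
synthetic family-data generator, so that effect recovery, true-positive
proportions (TPP) and false-positive proportions (FPP) can be studied
entirely at desk scale.

## What the generator emulates

The simulator reproduces the statistical structure of a well-known
simulated family study of SBP and antihypertensive use (20 extended
Mexican American pedigrees, roughly 1,060-1,080 members, about 120
founders, 200 phenotype replicates over one fixed genotype panel):

* **Pedigrees.** `generate_pedigree()` builds three-generation extended
  families from a template: a founder couple, four second-generation
  children each marrying in a founder spouse, and eleven third-generation
  children per couple - 54 members and 6 founders per family, 1,080
  members and 120 founders in the default 20 families. Sexes of coupled
  individuals are structurally fixed; terminal children are assigned
  female with an adjusted probability so the expected cohort fraction of
  females is 0.58.
* **Genotypes.** `drop_genotypes()` draws founder dosages
  binomial(2, MAF) under Hardy-Weinberg and transmits one allele per
  parent (gene dropping). Dosages are integers; SNPs are unlinked. The
  panel is fixed across phenotype replicates.
* **Medication.** Cross-sectional Bernoulli assignment at prevalence
  0.327, redrawn per replicate, independent of the phenotype. (An
  indication mechanism - medicating the hypertensive tail - is a known
  feature of real data that this generator deliberately omits; the
  TPP/FPP logic under study does not require confounding.)
* **Phenotype.** $\mathrm{SBP} = 135 + 0.4\,\mathrm{age} - 3\,I(F) +
  \sum\beta_{SNP}G + \beta_{Med}M + \sum\beta_{Int}GM + g + e$, with
  $g \sim N(0, \sigma_a^2 R)$ simulated per family block and $e$
  heteroscedastic by medication status. Ages are truncated normal
  (mean 48.1, sd 15, range 18-101).

Three ready-made scenarios fix the study conditions:

| scenario | causal SNP | effects |
|---|---|---|
| `scenario_carrier_nonresponse()` | MAF 5.4% | $\beta_{SNP}=0$, $\beta_{Med}=-6.2$, $\beta_{Int}=+6.2$ mm Hg |
| `scenario_main_effect()` | MAF 2.7% | $\beta_{SNP}=-9.91$ mm Hg per allele, no interaction |
| `scenario_null()` | none | 400 null SNPs, MAF uniform on a configurable range |

The carrier-nonresponse parameterisation makes a medicated heterozygous
carrier's expected treatment benefit exactly zero
($-6.2 + 6.2 \times 1 = 0$); with the product coding a homozygous carrier
overshoots to $+6.2$, which at MAF 5.4% affects only a handful of
individuals.

### Default variances and why

Total phenotypic variance (net of age/sex) is set to about 181 mm Hg^2 so
that the strong main-effect SNP (MAF 2.7%, $-9.91$ mm Hg per allele)
explains $2pq\beta^2 = 5.16$ mm Hg^2, i.e. about 2.9% of variance, as in
the emulated study. Narrow-sense heritability defaults to 0.30
($\sigma_a^2 = 54.3$). The residual variances 118.9 (unmedicated) and
142.7 (medicated) implement a heteroscedasticity ratio of 1.2 - the
emulated study lets residuals differ by medication status but prints no
values, so the ratio is a package choice - and average to about 126.7 at
prevalence 0.327, giving $\sigma_a^2 + \bar\sigma_e^2 \approx 181$. The
age slope (0.4 mm Hg/yr), female effect ($-3$ mm Hg) and intercept
(135 mm Hg) are likewise package choices of realistic magnitude; all are
configurable.

## Relatedness machinery

* `numerator_relationship_matrix()` uses the recursive tabular method
  ($A_{ii} = 1 + A_{fm}/2$, $A_{ij} = (A_{fj}+A_{mj})/2$), which handles
  inbreeding without assumptions, per family block; the result is a
  sparse block-diagonal matrix with exact zeros between families.
* `founder_pca()` computes ancestry PCs in founders only (unrelated
  individuals), on an LD-pruned (`ld_prune()`, greedy in position order,
  $r^2 \le 0.2$), founder-polymorphic SNP subset, with unit-variance
  scaling by default (a toggle is provided since conventions differ);
  `project_pcs()` assigns scores to relatives by the frozen linear map,
  never re-estimating loadings with related individuals. Five PCs are
  attached to every phenotype table by default.

## Mixed-model estimation

`fit_lmm()` maximizes the restricted likelihood of
$V = \sigma_a^2 R + D$, with $D$ diagonal carrying one residual variance
per medication group (one group = homogeneous model). Because $R$ is
block-diagonal by family, $V$ is sparse; each objective evaluation is a
sparse Cholesky factorization (Matrix package) that costs roughly the sum
of cubed family sizes rather than $n^3$, which is what makes
200-replicate experiments at $n = 1080$ fast on one core.

Numerical choices:

* bounded quasi-Newton (L-BFGS-B) on the log-variance scale, up to three
  deterministic starting points (residual split 50/50, 90/10, 10/90 of
  the least-squares variance), 200 iteration cap;
* variance components bounded below at $10^{-10}$ (so $V$ stays
  invertible); an estimate at the bound still counts as converged;
* fixed effects by generalized least squares at the optimum, covariance
  $(X^\top V^{-1} X)^{-1}$; rank-deficient designs are refused with the
  offending column named;
* non-convergence is a first-class outcome: the fit carries
  `converged = FALSE` with a reason, and every downstream test emits a
  non-converged row rather than numbers, so convergence denominators are
  reproducible. A SNP monomorphic within the analyzed rows is reported as
  `"degenerate design"`; an empty or monomorphic stratum as
  `"small stratified-sample size"`.

`residual_heterogeneity_lrt()` compares homogeneous against
medication-specific residuals with the same fixed effects, so the REML
likelihood-ratio (chi-square, 1 df, clipped at zero) is valid; the ML
value at the REML variance estimates is stored alongside for reference.

### Scan mode versus exact mode

For scans over many SNPs, `run_scan()` defaults to estimating variance
components once under the covariates-only model and holding them fixed for
every SNP (per stratum for the med-diff approach); each SNP then costs one
generalized-least-squares solve. This is the standard GWAS approximation
and is what makes the 50-replicate x 400-SNP null experiments run in
minutes. `vc_mode = "exact"` re-estimates components per SNP and is the
default in the causal-SNP analyses (`fit_model1()`,
`stratified_fits()`), where per-SNP REML is affordable and the variance
structure genuinely differs under the alternative. The mode is recorded in
every output row.

### The strata correlation

The med-diff variance correction uses the Spearman rank correlation of
per-SNP stratum estimates, computed per chromosome within each replicate
over SNPs whose stratified fits both converged (a genome-wide scope is
available by flag). With desk-scale panels (tens of SNPs per chromosome)
the estimated $r$ is noisy where genome-wide data would give a tight
estimate; chromosomes with fewer than two usable SNPs fall back to
$r = 0$ with a logged message.

## Evaluation

* `tpp()`: proportion of converged replicates significant at
  $\alpha = 0.05$, Wilson score interval (Clopper-Pearson by flag).
* `fpp()`: pools SNP-by-replicate tests after excluding every SNP within
  a closed $\pm 500$ kb window of a simulated effect (so a causal SNP at
  chr7:99,457,518 excludes exactly chr7:98,957,518-99,957,518), binned by
  MAF with default edges (0.001, 0.01, 0.05, 0.10, 0.20, 0.50]; a
  per-replicate-averaged variant is provided for sensitivity.
* `analytic_power()`: noncentral chi-square power with noncentrality
  $n_{\mathrm{eff}}\,\beta^2\, 2p(1-p)\, q(1-q) / \sigma^2_e$ (1 df
  interaction) or $n_{\mathrm{eff}}\,\beta^2\, 2p(1-p) / \sigma^2_e$
  (2 df joint main-effect testing), with
  `effective_sample_size()` defaulting to 80% of the cohort to discount
  family correlation.

## Problem sizes used in the shipped experiments

The acceptance experiments run the pipeline at the emulated study's scale:
200 replicates of 1,080 individuals for interaction/medication effect
recovery (exact per-SNP REML at the causal SNP), 100 replicates for the
strong-main-effect scenario and its 2-df power, and two null experiments
of 50 replicates x 400 SNPs (MAF uniform on 1-50% for the med-diff
false-positive calibration and on 0.5-5% for the low-MAF
interaction-model check), all in scan mode. Monte-Carlo tolerances are
three standard errors of the replicate mean; false-positive calibration is
judged by whether the Wilson 95% interval covers the nominal 5%.

## Known limitations

* Genotypes are integer gene-dropped dosages without linkage
  disequilibrium or imputation error; real cohorts with imputed
  fractional dosages will show attenuated interaction estimates that the
  generator does not reproduce.
* Medication is assigned independently of blood pressure; indication
  bias, longitudinal treatment initiation and time-varying phenotypes are
  out of scope (one time point only).
* The polygenic model carries a single additive random effect; no
  dominance, shared-household, or marker-based (GRM) relatedness.
* The med-diff 2-df joint test, as published, does not correct for
  between-strata correlation; this package reproduces that behaviour
  deliberately.
* Passing the shipped calibration experiments demonstrates correctness of
  the machinery under the generator's assumptions, not performance on
  real family data.
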