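---
title: "Detecting gene-environment interaction with twin, polygenic-score and genome-wide models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-environment interaction with twin, polygenic-score and genome-wide models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxesim)
```

## The problem

Gene-environment interaction (GxE) — genetic effects whose magnitude depends
on a measured environmental moderator — is studied with three largely
separate toolkits: per-SNP moderated-regression scans in genome-wide data,
polygenic-score-by-environment (PRSxE) regressions that aggregate discovery
summary statistics into scores for an independent target sample, and twin
variance-components models in which a moderator scales the latent additive
genetic (A), shared environmental (C) and unique environmental (E) paths.
`gxesim` generates twin-family data in which all three analyses are valid
*on the same dataset*, so their behaviour — power, attenuation, robustness —
can be compared against a known truth.

## The generative model

Phenotypes follow a moderated regression,

$$Y_i = \beta_0 + \sum_j \beta_{1j}\,G_{ij} + \beta_2 m_i +
        m_i \sum_j \beta_{3j}\,G_{ij} + \varepsilon_i,
        \qquad \varepsilon_i \sim N(0, \sigma^2_\varepsilon),$$

where $G_{ij} \in \{0,1,2\}$ are allele counts and $m_i$ is the moderator.
Genotypes are built biometrically: each parent receives two
Bernoulli($p$) alleles per SNP; DZ twins each receive one randomly drawn
maternal and one paternal allele (expected co-twin genotype correlation
0.5), while MZ twins share a single transmission draw (correlation 1).
SNPs are independent — no linkage disequilibrium.

Four preset architectures (`simulate_study()`):

| study | SNPs | main effects | interaction effects |
|---|---|---|---|
| 1 | 1 | $\beta_1 = 1$ | none |
| 2 | 1 | $\beta_1 = 1$ | $\beta_3 = 1$ |
| 3 | 1000 | all $1/\sqrt{1000} = 0.0316$ | all $0.0316$ |
| 4 | 1000 | $N(0, 1/1000)$ | $N(0, 1/1000)$, independent of the main effects |

so the summed squared main and interaction effects are 1 (exactly in the
fixed regime, in expectation in the normal regime) in every moderated
preset.

Key parameter choices, each exposed in `sim_config()`:

* **Allele frequency 0.5.** A unit-effect SNP then contributes variance
  $2pq = 0.5$, which together with the residual variance of 0.5 puts
  heritability at one half — the reference point all three methods should
  recover.
* **Binary Bernoulli(0.5) moderator.** Only a two-level moderator yields
  the stratified variance-explained contrast (0.50 unexposed vs 0.80
  exposed in the single-SNP interaction preset) and the clean
  $(a + \beta_a)^2$ reading of the exposed-stratum genetic variance; a
  standard-normal moderator is available via `moderator_kind`.
* **$\beta_0 = \beta_2 = 0$.** The moderator acts purely through the
  interaction; both are configurable.
* **Residual variance 0.5**, giving unexposed-stratum phenotypic variance 1.
* **Co-twin moderators are independent.** Within-pair moderator
  correlation would induce gene-environment correlation pathways that the
  generator deliberately excludes.
* Parents receive moderator-free phenotypes; they enter only the
  single-SNP per-role regression tables.

One master seed drives a hierarchical stream (effects, moderators,
genotypes, residuals are separately re-seeded), so any stored number is
regenerable bit-for-bit, and the stored-genotype selection (`keep`) never
perturbs the stream. Genotypes are generated in 250-SNP chunks with
phenotype accumulators, keeping 100,000-family, 1000-SNP datasets inside
ordinary memory.

## The three detection routes

**Moderated scan.** `gwas_scan()` fits, per SNP,
$Y \sim 1 + G_j + m + G_j m$ (or the unmoderated
$Y \sim 1 + G_j + m$) by OLS and reports Wald $z = \hat\beta/\mathrm{se}$
with standard-normal p-values; at the sample sizes of interest
($n \ge 10^4$) the difference from the t reference is negligible. Scans
analyse DZ twin 1 only, which keeps observations independent. Monomorphic
or otherwise rank-deficient designs yield flagged missing rows rather than
errors. `count_significant()` tallies hits at the genome-wide
($5\times10^{-8}$) and Bonferroni ($0.05/n_\mathrm{snps}$) thresholds.

**PRSxE.** `build_prs()` forms three scores from discovery summary
statistics, with no clumping or thresholding (the simulated SNPs are
independent): a main-effect score
$\mathrm{PRS}_\mathrm{main} = \sum_j \hat\beta_{1j} G_{ij}$, an
interaction score
$\mathrm{PRS}_\mathrm{int} = m_i \sum_j \hat\beta_{3j} G_{ij}$ — the
moderator multiplies the weighted sum during construction, so the score
itself is the interaction variable — and a conventional single score used
with an explicit product term. `prsxe()` then fits either
$Y \sim 1 + \mathrm{PRS}_\mathrm{main} + m + \mathrm{PRS}_\mathrm{int}$
or
$Y \sim 1 + \mathrm{PRS} + m + \mathrm{PRS}\times m$ in a target sample
of MZ twin-1 individuals (5,000 by default), disjoint from the DZ
discovery sample. Scores are not standardised, so coefficients are on the
generative scale and equal 1 under perfect weights.

A design point worth spelling out: a *moderator-naive* discovery scan
does not estimate $\beta_1$ — the omitted interaction projects onto the
genotype, so its per-SNP slope converges to
$\beta_1 + \mathbb{E}[m]\,\beta_3$ (1.5 times the truth in the
equal-effects presets). A single score built from such weights smuggles
half the interaction signal into the main-effect term, and its product
term then reflects the *main-effect* architecture rather than aggregate
moderation. The study runners therefore build the conventional score from
the moderated scan's main-effect weights, which keeps the product-term
test clean; this is what makes the sign-mixed architecture (study 4)
cancel the product term toward zero while the interaction-weighted score
retains the full signal. Scores from a truly unmoderated scan remain
available (`gwas_scan(model = "standard")` + `build_prs()`), and the
absorption identity is asserted in the test suite.

**Moderated ACE twin model.** `ace_gxe()` fits, by full-information
maximum likelihood, a bivariate-normal model for twin pairs in which each
path is a linear function of the observed per-twin moderator (a
definition variable):

$$\mathrm{Var}(Y_i \mid m_i) = (a + \beta_a m_i)^2 + (c + \beta_c m_i)^2 +
  (e + \beta_e m_i)^2,$$
$$\mathrm{Cov}(Y_1, Y_2) = R\,(a + \beta_a m_1)(a + \beta_a m_2) +
  (c + \beta_c m_1)(c + \beta_c m_2),$$

with $R = 1$ for MZ and $0.5$ for DZ pairs, and a means model that
regresses each twin's phenotype on both their own and their co-twin's
moderator — the guard against gene-environment correlation leaking into
the moderation paths. Twin fits use the first 2000 pairs per zygosity by
default: registry-scale samples, far below the genome-wide analyses, which
is precisely the point of the comparison.

## Numerical choices in the twin fit

* Minimisation of $-2\ln L$ by BFGS (`maxit = 2000`, `reltol = 1e-10`)
  from data-informed starts ($a = c = e = \sqrt{\mathrm{Var}(Y)/3}$,
  moderation 0, means coefficients from an OLS pre-fit), plus three
  jittered restarts, keeping the best optimum. This makes the nesting
  property (a submodel never beats the full model) hold robustly.
* A non-positive-definite pair covariance returns a large finite penalty
  ($10^{10}$) instead of an error, so line searches recover.
* $(x, \beta_x) \to (-x, -\beta_x)$ leaves the likelihood unchanged;
  fits are canonicalised to non-negative paths at moderator 0, with the
  moderator-1 value breaking ties when a path is essentially zero.
* Standard errors come from the numerical Hessian at the optimum
  (`optimHess`); they are curvature-based, not profile-based.
* C and its moderation are estimated even though the generator has no
  shared environment; `components = "ae"` drops them.

## Monte Carlo power machinery

`power_moderated()` exploits the fact that with a binary moderator the
four-parameter interaction model is saturated: it equals two stratum-wise
simple regressions, so whole batches of replicates are fit with column
sums — no per-replicate model objects. In polygenic conditions the
non-focal SNPs all carry the same fixed weight, so their summed
contribution is `effect * (1 + m) * S` with
$S \sim \mathrm{Binomial}(2(n_\mathrm{snps}-1), p)$ — an exact one-draw
representation of the genetic background, which inflates the residual of
the focal-SNP fit exactly as a one-SNP-at-a-time scan experiences it.

`power_analytic()` is the independent cross-check. Its default method
accounts for the three design-level effects that matter at the small
sample sizes where single-SNP power crosses 80%: the Wald statistic is
noncentral-t (residual variance estimated on $n-4$ degrees of freedom),
the stratum split is binomial, and each stratum's genotype sum of squares
fluctuates around $(n_s - 1)2pq$ (Gauss-Hermite quadrature over its
normal approximation). In polygenic conditions the unmodelled background
is heteroskedastic across strata, so the pooled residual SE and the true
sampling variance of the stratum slope differ; the large-$n$ form scales
the rejection region accordingly. These refinements matter: a plain
normal approximation overstates single-SNP main-effect power by about
five percentage points near $n = 84$.

`find_n_for_power()` brackets with the analytic curve, then bisects on
integer $n$ with 2000 replicates per candidate, escalating replicates
fourfold whenever the estimate sits within two binomial standard errors
of the target. The interaction-to-main sample-size ratio under equal
effects is very close to 2 — the unexposed stratum contributes the same
information to both tests, but the interaction also needs the exposed
stratum. `power_table()` assembles the condition grid; conditions whose
searches run at $n > 10^4$ (the 100- and 1000-SNP rows) sit behind
`heavy = TRUE`.

## Orchestrated studies and problem sizes

`run_study()` executes simulate → scans → PRSxE (both discovery models)
→ twin fit with the standard analysis slices (100,000 DZ twin-1
discovery; first 5,000 MZ twin-1 targets; first 2000 + 2000 twin pairs).
Because families are exchangeable, generating 5,000 MZ families is
distributionally identical to generating 100,000 and analysing the first
5,000; the polygenic presets default to the smaller MZ set on that
ground.

`run_adhoc()` traces attenuation: across polygenicity conditions
($n_\mathrm{snps} \in \{1, 10, 100, 1000\}$, total main and interaction
variance fixed at 1, discovery $n$ = 20,000), discovery noise grows with
polygenicity and the target-sample PRS coefficients shrink accordingly —
interaction scores more than main-effect scores, since interaction
weights are noisier; the single-score product-term model attenuates its
two coefficients symmetrically because both use the same score. The twin
fit, whose information comes from 2000 + 2000 pairs regardless of
$n_\mathrm{snps}$, stays near $a = \beta_a = \sqrt{0.5} \approx 0.71$
throughout, with a slight downward tilt in $\hat\beta_a$ from estimating
C and E moderation alongside it.

The package's own verification runs at reduced but sufficient scales,
chosen once: the test suite exercises the attenuation property at 150
SNPs over discovery sizes 6000/1500/400 with 12 replicates per level,
twin parameter recovery over 30 replicates of 2000 + 2000 pairs, and the
acceptance script runs the polygenicity grid at 10 replicates per
condition (the grand mean of $\hat a$ across 40 registry-scale fits has
a standard error well under 0.01). Replicate counts and slice sizes are
arguments everywhere, so any of these can be rerun at full scale.

## What passing tests do and do not show

The generator emulates idealised data: independent biallelic SNPs at a
common allele frequency, no linkage disequilibrium, no assortative
mating, no gene-environment correlation, no selection, a single binary
moderator measured without error, Gaussian residuals, and a continuous
phenotype. Results on such data demonstrate the *statistical* behaviour
of the three methods — power asymmetries, discovery-noise attenuation,
robustness of the twin decomposition — not their performance under the
confounds of real cohorts (stratification, LD, heritable moderators,
binary outcomes). The moderated scan deliberately omits covariates;
analyses of real data would include ancestry principal components and
other standard covariates. Single-realization quantities (per-SNP
significance counts, one seed's PRS coefficients) vary across seeds and
are checked distributionally, not digit-for-digit.
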