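---
title: "Family-based association in extended pedigrees: models, simulation design and numerical choices"
author: "pedassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based association in extended pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedassoc)
```

# The two association models

## Measured genotype approach (MGA)

For a quantitative trait measured on $n$ individuals in unrelated pedigrees,
the MGA model is

$$ y = \mu + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{age}^2 +
   \beta_3\,\mathrm{bpmed} + \beta\,x + g + e, $$

where $x$ is the minor-allele count at the SNP under test,
$g \sim N(0,\, 2\Phi\sigma_g^2)$ is an additive polygenic effect with
$\Phi$ the kinship matrix, and $e \sim N(0,\, I\sigma_e^2)$. The SNP is
tested by a likelihood-ratio statistic between the unconstrained model and
the model with $\beta = 0$; under the null it is asymptotically
$\chi^2_1$. Both models are fitted by full maximum likelihood (not REML):
the two fits differ in their fixed-effect specification, and ML is what
makes their log likelihoods directly comparable. The default covariate set
is age, age², and medication use; the residualization used by the
within-family test below additionally includes sex. The two arms
deliberately follow their own conventional covariate sets; both are
configurable.

The p-value uses the plain $\chi^2_1$ upper tail. The 50:50
boundary-mixture correction applies to tests of variance components pinned
at a boundary; $\beta$ is an interior fixed-effect parameter, so no mixture
is involved here (the variance components are estimated, not tested).

## FBAT on extended pedigrees

The family-based association test conditions on parental genotypes and uses
only the randomness of Mendelian transmission. Extended pedigrees are
decomposed into parent–offspring *transmission units*: one unit per
genotyped nonfounder with both parents genotyped. Given parental
minor-allele counts $(g_f, g_m)$, each parent transmits its minor allele
with probability $g/2$, independently, so

$$ E[x \mid S] = \tfrac{g_f}{2} + \tfrac{g_m}{2}, \qquad
   \mathrm{Var}(x \mid S) = \tfrac{g_f}{2}\!\left(1-\tfrac{g_f}{2}\right)
   + \tfrac{g_m}{2}\!\left(1-\tfrac{g_m}{2}\right). $$

With $t$ the residual of the trait after ordinary least squares on age,
age², sex and medication use over all phenotyped nonfounders, the statistic
is

$$ \chi^2 = \frac{\left[\sum t\,(x - E[x\mid S])\right]^2}
  {\sum t^2\,\mathrm{Var}(x \mid S)} \;\sim\; \chi^2_1 . $$

Distinct meioses are independent given the parental genotypes, which is why
units from the same pedigree simply add in numerator and denominator. This
both-parents-genotyped decomposition is the classic trio-clustering
simplification for extended pedigrees; the general sufficient-statistic
conditioning for arbitrary missing-parent patterns (Rabinowitz–Laird) is
out of scope, and offspring with an ungenotyped parent contribute nothing.
On fully genotyped synthetic data the two approaches coincide.

A family is *informative* at a SNP if it contains at least one unit with a
heterozygous parent (positive conditional variance) and a nonzero residual.
SNPs with fewer than 10 informative families are filtered: they are neither
tested nor counted in the Bonferroni denominator, so the MGA and FBAT
denominators legitimately differ (only monomorphic SNPs are excluded for
MGA).

## Conditional-power screening (FBAT-VS)

The screening step ranks SNPs by how powerful the upcoming FBAT test is
expected to be, using only between-family information: the trait residuals
and the *expected* genotypes $E[x \mid S]$, never the realized
transmissions. Concretely:

1. Regress $t$ on an intercept plus $E[x \mid S]$; keep the slope
   $\hat\beta_s$ and ML residual variance $\hat\sigma^2_s$.
2. For each unit, tilt the Mendelian distribution exponentially toward the
   trait signal,
   $\tilde p(x) \propto p(x \mid S)\,
   \exp\{\hat\beta_s\, t\,(x - E[x \mid S]) / \hat\sigma^2_s\}$,
   and accumulate the predicted score mean
   $\tilde E[U] = \sum t\,(\tilde E[x] - E[x \mid S])$.
3. With the null variance $V_0 = \sum t^2 \mathrm{Var}(x \mid S)$, report
   $\text{power} = \Phi(-z_{\alpha/2} + \tilde E[U]/\sqrt{V_0})
   + \Phi(-z_{\alpha/2} - \tilde E[U]/\sqrt{V_0})$, and 0 when $V_0 = 0$.

The exponential tilt was chosen as the concrete rendering of
"impute, then estimate conditional power" because it has the right limits:
a zero screening slope leaves the Mendelian distribution untouched and the
power collapses to exactly $\alpha$; a diverging slope saturates the tilt
at the extreme genotype, and the power is monotone in $|\hat\beta_s|$
throughout. (Tilting with the full Gaussian likelihood
$N(t;\, \beta_s(x - E), \sigma_s^2)$ instead would re-center at large
$\beta_s$ and lose the monotonicity, so it was rejected.) The
$\hat\sigma^2_s$ in the tilt is floored at $10^{-12}$ so that perfect-fit
toy examples remain defined.

Only the top $K = 10$ ranked SNPs are tested, each at $\alpha/K = 0.005$;
ties in power are broken by input order so rankings are reproducible. The
procedure's validity rests on screen/test independence, and the test suite
asserts it directly: re-dropping all offspring genotypes given the same
parents changes every FBAT p-value while leaving the ranking bit-identical.

# Kinship

`kinshipMatrix()` implements the standard recursion over a founders-first
ordering, $\phi_{ii} = \tfrac12(1 + \phi_{f_i m_i})$ and
$\phi_{ij} = \tfrac12(\phi_{f_i j} + \phi_{m_i j})$, returning $2\Phi$. The
recursion is exact for inbred and looped pedigrees; no further adjustment
is applied or needed. Tests compare it against closed forms and against a
labelled-founder Monte-Carlo gene-dropping estimate of IBD sharing
($10^5$ drops, 3-standard-error agreement).

# Fitting: profile likelihood over heritability

Writing $h = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$ and
$\sigma^2 = \sigma_g^2 + \sigma_e^2$, the covariance is
$\sigma^2[(1-h)I + h\,2\Phi]$. Each pedigree block of $2\Phi$ is
eigendecomposed once ($2\Phi = U D U'$) and the data rotated by $U'$; for
fixed $h$ the model is weighted least squares with weights
$1/(1 - h + h d_i)$, and $\sigma^2$ profiles out in closed form. The scalar
profile likelihood is maximized over $h \in [0,1]$ with `optimize()`
(absolute tolerance $10^{-6}$), evaluating both boundaries explicitly since
boundary maxima are legitimate. A residual-variance floor of $10^{-10}$
turns exact-collinear degenerate fits into errors instead of infinite
likelihoods. Because the rotation depends only on the kinship, the
eigendecompositions and the covariate-only null fit are computed once per
scan and reused across SNPs; SNPs with missing genotypes fall back to a
complete-case refit on the reduced individual set. The likelihood-ratio
statistic is clipped at zero; a value below $-10^{-6}$ before clipping
signals an optimizer failure and is raised as an error rather than hidden.

# What the synthetic data emulates

The generator stands in for a restricted multigenerational blood-pressure
cohort and reproduces its stated structure: **20 pedigrees of 21–76
members**, three to four generations deep. Within those constraints the
mating structure is a modelling choice, stated here once: each family
starts from a founding couple; couples have $1 + \mathrm{Poisson}(2.5)$
children; non-terminal children marry in an unrelated founder spouse with
probability 0.75; a candidate family is resampled until its size lands in
range. Ages fall with generation (means 75/50/25/10 years, SD 5, floor 1),
sex is recorded from the pedigree, and medication use is Bernoulli(0.2) —
the covariates exist so both models have something real to adjust for, not
to match any particular population.

Genotypes are gene-dropped: founder alleles i.i.d. Bernoulli(MAF), each
meiosis transmitting a uniformly chosen parental allele, independently
across SNPs (linkage equilibrium). An optional block-correlation mode
exists solely to exercise the LD pruner. Traits add covariate effects, any
causal SNP effects, a per-pedigree multivariate-normal polygenic component
with covariance $2\Phi\sigma_g^2$, and i.i.d. Gaussian residuals. The null
trait is i.i.d. $N(0,1)$, independent of everything, with no polygenic
component at all — it models a phenotype with *no genetic influence*, not
merely no SNP effect.

For the large-effect benchmark variant (MAF 0.0261, additive effect
−6.2235), the per-SNP heritability identity
$h^2 = 2p(1-p)\beta^2 / (2p(1-p)\beta^2 + V_{bg})$ with $h^2 = 0.0229$
gives a background variance $V_{bg} \approx 84$. We split it as
$\sigma_g^2 = 28$, $\sigma_e^2 = 56$ — a background heritability of 1/3,
typical of blood-pressure traits; the split matters little for detecting
the SNP, whose test adjusts for the polygenic component either way.

**What passing tests do not show.** The generator produces idealized data:
fully genotyped pedigrees, no genotyping error, no ascertainment, linkage
equilibrium, Gaussian traits, and no population stratification.
Calibration and power results here therefore measure the methods under
their own assumptions; they say nothing about robustness to stratification
(where between-family methods like MGA and the screen are known to be
vulnerable and FBAT is robust by design), to informative missingness, or
to real LD.

## Problem sizes

The replicate experiments in the test suite and the acceptance script use
sizes chosen to give stable Monte-Carlo estimates at interactive cost: the
type I experiments use 100 replicates × 200 independent SNPs (20,000
tests; a binomial 99% interval around 0.05 of roughly ±0.004), and the
power experiment 200 replicates, matching the study design it emulates.
Smaller cohorts (3–12 pedigrees) are used in unit tests where only the
algebra, not the asymptotics, is at stake.

# Design decisions worth recording

- **Minor allele**: defined per SNP over the whole genotyped sample, ties
  at 0.5 broken toward the lexicographically smaller allele name. Written
  PED files use `A` for the minor allele so rereads reproduce the coding.
- **Mendelian inconsistencies** in user files are set missing with a
  warning rather than aborting — a batch scan over simulation replicates
  should never die on one bad genotype. They cannot occur in gene-dropped
  data, and the FBAT decomposition excludes impossible units defensively.
- **Missing genotypes** in MGA are handled by per-SNP complete-case
  analysis: the simplest defensible choice, and exact for the synthetic
  data which has no missingness.
- **Seeding**: every driver derives replicate $r$'s seed as
  `subSeed(seed, r)` (an affine map mod $2^{31}-1$), so a run is a pure
  function of its inputs, any replicate can be reproduced in isolation,
  and the first $k$ replicates of a longer run are unchanged — a property
  the tests assert byte-for-byte.
- **LD pruning** defaults to $r^2 < 0.2$ within a 50-SNP window. The
  synthetic SNPs are independent, so pruning is off in the power arm and
  optional in the type I arm, mirroring the asymmetry of the emulated
  study design; the thresholds only matter for user-supplied data.
- **Interfaces**: the package's functions and this vignette are the
  intended interface; `writeSyntheticStudy()` exports a complete PED/MAP +
  covariate + truth-table study for use by external tools.

# Known limitations

- The FBAT arm requires both parents genotyped per unit; cohorts with many
  ungenotyped founders lose within-family information that the full
  sufficient-statistic algorithm would retain.
- The conditional-power screen is one concrete estimator of a quantity the
  literature leaves unspecified; procedure-level properties (independence,
  null calibration, monotonicity) are guaranteed, numerical agreement with
  other implementations is not.
- Single-SNP additive models only: no dominance, no household component,
  no rare-variant aggregation, no X chromosome, no binary-trait offsets.
- Asymptotic $\chi^2_1$ p-values throughout; at very rare variants with few
  informative transmissions the FBAT statistic is discrete and the
  informative-family filter is the guard against taking its asymptotics
  seriously.
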