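# pedassoc

Quantitative-trait association testing in large multigenerational pedigrees,
with a simulation framework for comparing the two standard family-based
strategies:

- **MGA (measured genotype approach)** — a variance-components mixed model.
  The trait is `y = mu + b1*age + b2*age^2 + b3*bpmed + beta*SNP + g + e`
  with a polygenic random effect `g ~ N(0, 2*Phi*sigma_g^2)` (`Phi` the
  kinship matrix) and i.i.d. residuals `e ~ N(0, sigma_e^2)`. Each SNP is
  coded as a minor-allele count and tested as a fixed effect by a
  likelihood-ratio test: twice the log-likelihood difference between the
  unconstrained and the `beta = 0` model is asymptotically chi-squared on
  1 df.
- **FBAT (family-based association test)** — a within-family score test.
  Extended pedigrees are decomposed into parent–offspring transmission
  units; with `t` the trait residual after regression on age, age², sex and
  medication use, the statistic is `U^2 / V ~ chi2_1` where
  `U = sum t*(x - E[x|parents])` and `V = sum t^2 * Var(x|parents)`, the
  moments being the exact Mendelian conditional moments given parental
  genotypes.
- **FBAT-VS (Van Steen screening)** — SNPs are ranked by conditional power
  computed from between-family information only (trait residuals plus
  expected genotypes given the parental sufficient statistics), and only the
  top K (default 10) are FBAT-tested at `0.05/K`. Because the screen never
  looks at the realized transmissions it is statistically independent of the
  test.

The package is aimed at statistical geneticists who want to study the
operating characteristics (empirical power, type I error, multiple-testing
behaviour) of these methods on pedigree collections they can describe but
not necessarily share: a synthetic-data module generates multigenerational
pedigrees, gene-drops genotypes at chosen allele frequencies, and simulates
heritable or genetically null traits with covariates.

## Worked example

```r
library(pedassoc)

# 20 multigenerational pedigrees of 21-76 members
cohort <- generatePedigrees(pedigreeTemplate(), seed = 1)
kin    <- kinshipMatrix(cohort)
covs   <- simulateCovariates(cohort, seed = 2)

# 50 independent SNPs; one causal, explaining ~3% of trait variance
set.seed(10)
maf  <- setNames(runif(50, 0.05, 0.5), paste0("snp", 1:50))
geno <- geneDrop(cohort, maf, seed = 3)
beta <- effectFromHeritability(0.03, maf["snp7"], backgroundVar = 2)
model <- traitModel(sigmaG2 = 1, sigmaE2 = 1,
                    causalSNPs = setNames(beta, "snp7"))
pheno <- simulateTrait(cohort, geno, covs, model, kin, seed = 4)

mga <- mgaScan(pheno, geno, kin)
t   <- residualizeTrait(pheno, cohort)
fb  <- fbatScan(cohort, geno, t)
vs  <- rankAndTestTopK(screenScan(cohort, geno, t), fb)

subset(mga, p < 0.05 / sum(status == "ok"))
#>   snpID   n   betaHat      lrt            p status
#> 7  snp7 785 0.5494385 23.98844 9.691575e-07     ok
subset(vs, tested & significant)
#>   snpID conditionalPower rank tested            p significant threshold
#> 7  snp7        0.9805639    1   TRUE 0.0005329168        TRUE     0.005
```

The causal SNP is recovered by the mixed model at the Bonferroni level
(`0.05/50`), and the screen ranks it first so it is also found by the top-10
procedure at `0.05/10`; `betaHat` is in trait units per minor allele.

Replicate drivers aggregate these scans over simulation replicates:

```r
runType1Experiment(nSNPs = 200, nReplicates = 100, seed = 1)  # null trait
runPowerExperiment(causal = data.frame(snpID = "s", maf = 0.0261,
                                       beta = -6.2235),
                   model = traitModel(sigmaG2 = 28, sigmaE2 = 56),
                   nReplicates = 200, seed = 1)
```

## Layout

- `R/` — S4 containers (`Pedigree`, `Cohort`, `GenotypeMatrix`,
  `KinshipMatrix`), PED/MAP I/O, kinship recursion, the synthetic-data
  generator, and one file per method (`mga.R`, `fbat.R`, `screening.R`,
  `evaluation.R`).
- `vignettes/family-association.Rmd` — the model, the design decisions and
  the simulation conditions in detail.
- `tests/testthat/` — unit, property and acceptance suites with
  independently computed oracles (dense multivariate-normal likelihood,
  Monte-Carlo IBD gene dropping, closed-form least-squares cases).
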