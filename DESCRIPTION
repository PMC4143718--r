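Package: pedassoc
Title: Family-Based Association Testing and Power Evaluation in Extended Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative-trait association analysis in large
    multigenerational pedigrees. Implements the measured genotype approach
    (a variance-components mixed model with a polygenic random effect and a
    per-SNP fixed-effect likelihood-ratio test), the family-based association
    test (FBAT) score statistic built from parent-offspring transmission units,
    and Van Steen-type conditional-power screening with top-K testing.
    Includes pedigree/genotype/phenotype containers with PED/MAP input and
    output, recursive kinship computation, a gene-dropping simulator of
    pedigrees, genotypes and traits, and replicate drivers for empirical power
    and type I error experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
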