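test_that("generated pedigrees respect the template and are reproducible", {
  template <- pedigreeTemplate()
  coh <- generatePedigrees(template, seed = 1)
  sizes <- vapply(pedigrees(coh), function(p) nrow(members(p)), integer(1))
  expect_length(sizes, 20L)
  expect_true(all(sizes >= 21 & sizes <= 76))
  expect_identical(nrow(validatePedigree(pedigrees(coh)[[1]])), 0L)

  coh2 <- generatePedigrees(template, seed = 1)
  expect_identical(lapply(pedigrees(coh), members),
                   lapply(pedigrees(coh2), members))
  coh3 <- generatePedigrees(template, seed = 2)
  expect_false(identical(lapply(pedigrees(coh), members),
                         lapply(pedigrees(coh3), members)))

  trio <- generatePedigrees(pedigreeTemplate(nPedigrees = 1,
                                             sizeRange = c(3, 3),
                                             nGenerations = 2,
                                             meanOffspring = 0,
                                             marryInProb = 0),
                            seed = 5)
  m <- members(pedigrees(trio)[[1]])
  expect_identical(nrow(m), 3L)
  expect_identical(sum(is.na(m$father)), 2L)

  expect_error(generatePedigrees(pedigreeTemplate(nPedigrees = 1,
                                                  sizeRange = c(70, 76),
                                                  nGenerations = 2,
                                                  meanOffspring = 0,
                                                  maxTries = 10)),
               "could not generate")
})

test_that("gene dropping is Mendelian-consistent and deterministic", {
  st <- smallStudy(nPed = 3, nSNP = 10)
  cd <- genotypeCodes(st$geno)
  expect_true(all(cd %in% 0:2))
  # every transmission unit has positive Mendelian probability
  for (sid in snpIDs(st$geno)) {
    u <- expect_silent(decomposeTransmissions(st$cohort, st$geno, sid))
    nonf <- sum(!isFounder(st$cohort))
    expect_identical(nrow(u), as.integer(nonf))  # fully genotyped data
  }
  g2 <- geneDrop(st$cohort, mafs(st$geno), seed = 42 + 3)
  expect_identical(genotypeCodes(g2), cd)

  mono <- geneDrop(st$cohort, c(m1 = 0), seed = 1)
  expect_true(all(genotypeCodes(mono) == 0L))
})

test_that("gene-dropped sample MAF is unbiased for the population MAF", {
  coh <- generatePedigrees(pedigreeTemplate(), seed = 8)
  reps <- 200
  m <- numeric(reps)
  for (r in seq_len(reps))
    m[r] <- mean(genotypeCodes(geneDrop(coh, c(s = 0.3), seed = r))) / 2
  expect_lt(abs(mean(m) - 0.3), 3 * sd(m) / sqrt(reps))
})

test_that("null trait: mean/variance, independence from genotypes, determinism", {
  coh <- generatePedigrees(pedigreeTemplate(), seed = 3)
  y <- simulateNullTrait(coh, seed = 10)
  expect_identical(y, simulateNullTrait(coh, seed = 10))
  n <- length(y)
  expect_lt(abs(mean(y)), 3 / sqrt(n))
  expect_lt(abs(var(y) - 1), 4 * sqrt(2 / n))
  # correlation with SNP codes averaged over replicates ~ 0
  cors <- sapply(1:40, function(r) {
    g <- geneDrop(coh, c(s = 0.3), seed = 100 + r)
    cor(simulateNullTrait(coh, seed = 200 + r), genotypeCodes(g)[names(y), 1])
  })
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)))
})

test_that("simulated traits carry the intended variance structure", {
  coh <- generatePedigrees(pedigreeTemplate(nPedigrees = 10), seed = 4)
  kin <- kinshipMatrix(coh)
  cov <- simulateCovariates(coh, seed = 5)
  g <- geneDrop(coh, c(s = 0.3), seed = 6)
  flat <- traitModel(mu = 0, betaAge = 0, betaAge2 = 0, betaBpmed = 0,
                     sigmaG2 = 0, sigmaE2 = 1)
  # degenerate model: pure N(0,1) residual
  ph <- simulateTrait(coh, g, cov, flat, kin, seed = 7)
  n <- nrow(ph)
  expect_lt(abs(mean(ph$trait)), 3 / sqrt(n))
  expect_lt(abs(var(ph$trait) - 1), 4 * sqrt(2 / n))
  # first-degree relative phenotypic correlation ~ 0.5 * sigmaG2 / total
  her <- traitModel(mu = 0, betaAge = 0, betaAge2 = 0, betaBpmed = 0,
                    sigmaG2 = 1, sigmaE2 = 1)
  tu <- pedassoc:::transmissionIndex(coh)
  po <- sapply(1:60, function(r) {
    tr <- simulateTrait(coh, g, cov, her, kin, seed = 100 + r)
    y <- setNames(tr$trait, tr$id)
    cor(y[tu$offspring], y[tu$father])
  })
  expect_lt(abs(mean(po) - 0.25), 3 * sd(po) / sqrt(length(po)) + 0.01)
})

test_that("effect size <-> heritability algebra", {
  expect_equal(effectFromHeritability(0.5, 0.5, 1), sqrt(2))
  expect_equal(effectFromHeritability(0, 0.3, 5), 0)
  expect_error(effectFromHeritability(1, 0.3, 5))
  # the large-effect benchmark variant: MAF .0261, beta -6.2235, h2 .0229
  vsnp <- 2 * 0.0261 * (1 - 0.0261) * 6.2235^2
  expect_equal(vsnp, 1.969, tolerance = 1e-3)
  bg <- vsnp * (1 - 0.0229) / 0.0229
  expect_equal(bg, 84.0, tolerance = 2e-3)
  expect_equal(effectFromHeritability(0.0229, 0.0261, bg, sign = -1),
               -6.2235, tolerance = 1e-4)
})

test_that("a written synthetic study reads back and its truth file is coherent", {
  dir <- withr::local_tempdir()
  model <- traitModel(causalSNPs = c(s3 = 2), sigmaG2 = 1, sigmaE2 = 1)
  maf <- c(s1 = 0.2, s2 = 0.4, s3 = 0.1)
  st <- writeSyntheticStudy(dir, pedigreeTemplate(nPedigrees = 2), maf,
                            model, seed = 31)
  back <- readPedfile(file.path(dir, "study.ped"), file.path(dir, "study.map"))
  expect_identical(genotypeCodes(back$genotypes), genotypeCodes(st$genotypes))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_identical(truth$snp_id, "s3")
  expect_equal(truth$beta, 2)
  vs <- 2 * truth$maf * (1 - truth$maf) * truth$beta^2
  expect_equal(truth$h2, vs / (vs + 2))
  cov <- readCovariates(file.path(dir, "covariates.csv"))
  expect_identical(nrow(cov), nIndividuals(st$cohort))
})
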