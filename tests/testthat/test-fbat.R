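test_that("trait residualization follows least squares over nonfounders", {
  coh <- Cohort(list(Pedigree("F", id = c("f", "m", "k1", "k2", "k3"),
                              father = c(NA, NA, "f", "f", "f"),
                              mother = c(NA, NA, "m", "m", "m"),
                              sex = c("male", "female", "male", "male",
                                      "female"))))
  # perfect fit on one covariate -> all-zero residuals
  ph <- data.frame(id = c("f", "m", "k1", "k2", "k3"),
                   trait = c(9, 9, 1, 2, 3), age = c(50, 50, 1, 2, 3))
  r <- residualizeTrait(ph, coh, covariates = "age")
  expect_equal(unname(r), c(0, 0, 0), tolerance = 1e-12)
  expect_identical(names(r), c("k1", "k2", "k3"))
  # intercept-only residuals of (1, 2, 4)
  ph$trait <- c(9, 9, 1, 2, 4)
  r2 <- residualizeTrait(ph, coh, covariates = character(0))
  expect_equal(unname(r2), c(-4, -1, 5) / 3, tolerance = 1e-12)
  expect_lt(abs(sum(r2)), 1e-10)
  # founder traits never enter: wild founder values leave residuals unchanged
  ph$trait[1:2] <- c(1e6, -1e6)
  expect_equal(residualizeTrait(ph, coh, covariates = character(0)), r2)
})

test_that("conditional moments are the Punnett-square values", {
  cm <- conditionalMoments(c(1, 2, 2, 0), c(1, 0, 1, 0))
  expect_equal(cm$probs[1, ], c(`0` = .25, `1` = .5, `2` = .25))
  expect_equal(cm$mean, c(1, 1, 1.5, 0))
  expect_equal(cm$variance, c(0.5, 0, 0.25, 0))
  expect_equal(rowSums(cm$probs), rep(1, 4))
})

test_that("transmission decomposition: all-genotyped, missing parents, errors", {
  coh <- Cohort(list(threeGenPedigree()))
  ids <- members(pedigrees(coh)[[1]])$id
  codes <- matrix(c(1L, 1L, 1L, 0L, 1L, 1L, 0L), ncol = 1,
                  dimnames = list(ids, "s"))
  g <- GenotypeMatrix(codes)
  u <- decomposeTransmissions(coh, g, "s")
  expect_identical(nrow(u), 4L)              # a1, a2, c1, c2
  expect_setequal(u$offspring, c("a1", "a2", "c1", "c2"))
  # ungenotyped father removes his offspring's units only
  codes2 <- codes; codes2["a1", ] <- NA
  u2 <- decomposeTransmissions(coh, GenotypeMatrix(codes2), "s")
  expect_setequal(u2$offspring, c("a2"))     # c1, c2 lose father; a1 not offspringGeno
  # Mendelian-impossible unit excluded with a warning
  codes3 <- codes; codes3["gf", ] <- 2L; codes3["gm", ] <- 2L
  expect_warning(u3 <- decomposeTransmissions(coh, GenotypeMatrix(codes3), "s"),
                 "Mendelian")
  expect_false(any(u3$offspring %in% c("a1", "a2")))
})

test_that("FBAT statistic reproduces the hand-computed toy and edge cases", {
  units <- data.frame(ped = c("f1", "f2", "f3"),
                      offspring = c("o1", "o2", "o3"),
                      fatherGeno = c(1, 1, 1), motherGeno = c(1, 1, 1),
                      offspringGeno = c(2, 0, 1))
  t <- c(o1 = 1, o2 = -1, o3 = 2)
  res <- fbatStatistic(units, t)
  expect_equal(res$U, 2)
  expect_equal(res$V, 3)
  expect_equal(res$chi2, 4 / 3, tolerance = 1e-12)
  expect_equal(res$p, pchisq(4 / 3, 1, lower.tail = FALSE))
  expect_identical(res$nInformativeFamilies, 3L)

  # homozygous x homozygous parents carry no information
  unitsHom <- data.frame(ped = "f", offspring = c("o1", "o2"),
                         fatherGeno = c(2, 0), motherGeno = c(0, 0),
                         offspringGeno = c(1, 0))
  resHom <- fbatStatistic(unitsHom, c(o1 = 1, o2 = 2))
  expect_identical(resHom$status, "uninformative")
  expect_true(is.na(resHom$p))

  # allele relabeling x -> 2 - x flips U, keeps chi2 and p
  flip <- units
  flip$fatherGeno <- 2 - flip$fatherGeno
  flip$motherGeno <- 2 - flip$motherGeno
  flip$offspringGeno <- 2 - flip$offspringGeno
  resF <- fbatStatistic(flip, t)
  expect_equal(resF$U, -res$U)
  expect_equal(resF$chi2, res$chi2, tolerance = 1e-12)
})

test_that("U is conditionally centered with variance V under re-dropping", {
  st <- smallStudy(nPed = 4, nSNP = 1, mafRange = c(0.3, 0.3))
  units <- decomposeTransmissions(st$cohort, st$geno, snpIDs(st$geno)[1])
  t <- residualizeTrait(st$pheno, st$cohort)
  V <- fbatStatistic(units, t)$V
  R <- 1e4
  U <- vapply(seq_len(R), function(r)
    fbatStatistic(redropUnits(units, seed = r), t)$U, numeric(1))
  expect_lt(abs(mean(U)), 3 * sd(U) / sqrt(R))
  expect_lt(abs(var(U) - V) / V, 0.10)
})

test_that("chi2 is invariant to trait location shifts through the regression", {
  st <- smallStudy(nPed = 3, nSNP = 3)
  t1 <- residualizeTrait(st$pheno, st$cohort)
  sh <- st$pheno; sh$trait <- sh$trait + 100
  t2 <- residualizeTrait(sh, st$cohort)
  f1 <- fbatScan(st$cohort, st$geno, t1, minInformative = 1)
  f2 <- fbatScan(st$cohort, st$geno, t2, minInformative = 1)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-8)
})

test_that("fbatScan equals per-SNP statistics and filters sparse SNPs", {
  st <- smallStudy(nPed = 4, nSNP = 6)
  t <- residualizeTrait(st$pheno, st$cohort)
  scan <- fbatScan(st$cohort, st$geno, t, minInformative = 1)
  for (j in c(1, 3, 6)) {
    u <- decomposeTransmissions(st$cohort, st$geno, snpIDs(st$geno)[j])
    single <- fbatStatistic(u, t)
    expect_equal(scan$U[j], single$U, tolerance = 1e-10)
    expect_equal(scan$V[j], single$V, tolerance = 1e-10)
    expect_identical(scan$nInformativeFamilies[j],
                     single$nInformativeFamilies)
  }
  # with only 4 pedigrees nothing can reach 10 informative families
  scan10 <- fbatScan(st$cohort, st$geno, t, minInformative = 10)
  expect_true(all(scan10$status == "filtered"))
  expect_true(all(is.na(scan10$p)))
})
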