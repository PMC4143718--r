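## Replicate drivers: empirical power and type I error experiments,
## Bonferroni thresholds, greedy LD pruning.

#' Bonferroni-corrected significance threshold
#'
#' `alpha / nTests`. The denominator is method-specific and computed from
#' the data at hand: the number of non-monomorphic SNPs for the
#' measured-genotype scan, the number of SNPs passing the
#' informative-family filter for FBAT, and K for the top-K screen.
#'
#' @param alpha family-wise level.
#' @param nTests number of tests performed (>= 1).
#' @return the per-test threshold.
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  stopifnot(alpha > 0, alpha <= 1)
  if (length(nTests) != 1L || is.na(nTests) || nTests < 1)
    stop("nTests must be a positive count")
  alpha / nTests
}

#' Greedy LD pruning
#'
#' Left-to-right pass keeping a SNP iff its squared Pearson correlation with
#' every previously kept SNP inside a sliding window stays below
#' `r2Threshold`. Guarantees pairwise r^2 < threshold among kept SNPs within
#' the window.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param r2Threshold squared-correlation ceiling (default 0.2).
#' @param window number of previously kept SNPs compared against (default 50).
#' @return the pruned [GenotypeMatrix-class].
#' @export
ldPrune <- function(geno, r2Threshold = 0.2, window = 50) {
  cd <- geno@codes
  kept <- integer(0)
  for (j in seq_len(ncol(cd))) {
    cmp <- utils::tail(kept, window)
    ok <- TRUE
    if (length(cmp)) {
      r <- suppressWarnings(cor(cd[, j], cd[, cmp, drop = FALSE],
                                use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      ok <- all(r^2 < r2Threshold)
    }
    if (ok) kept <- c(kept, j)
  }
  GenotypeMatrix(cd[, kept, drop = FALSE], maf = geno@maf[kept])
}

#' Empirical power from per-replicate p-values
#'
#' Fraction of replicates significant at the threshold; replicates where the
#' SNP was untestable (filtered, uninformative, monomorphic: `NA` p-value)
#' count as non-significant.
#'
#' @param pvals numeric vector, one p-value (or `NA`) per replicate.
#' @param threshold significance threshold.
#' @return proportion in \[0, 1\].
#' @export
empiricalPower <- function(pvals, threshold) {
  if (!length(pvals)) stop("no replicates supplied")
  mean(!is.na(pvals) & pvals < threshold)
}

## shared study-level setup: cohort, covariates, kinship, eigen
.studySetup <- function(template, seed) {
  cohort <- generatePedigrees(template, seed = subSeed(seed, 1L))
  covariates <- simulateCovariates(cohort, seed = subSeed(seed, 2L))
  kinship <- kinshipMatrix(cohort)
  list(cohort = cohort, covariates = covariates, kinship = kinship)
}

#' Replicate-based empirical power experiment
#'
#' Emulates the power evaluation design: a fixed cohort of multigenerational
#' pedigrees with fixed covariates; per replicate, genotypes are re-dropped
#' and the trait re-simulated from the causal model, then the
#' measured-genotype scan, the FBAT scan and (optionally) the top-K screen
#' are run. Power per causal SNP is tallied at the nominal level and at the
#' method-specific Bonferroni threshold (denominators recomputed per
#' replicate from the realized monomorphic / informative-family filters; the
#' screen's denominator is K).
#'
#' @param causal data.frame with columns `snpID`, `maf`, `beta`.
#' @param template a [pedigreeTemplate()].
#' @param model base [traitModel()]; its `causalSNPs` are replaced by
#'   `causal`.
#' @param nReplicates replicate count (default 200).
#' @param nNullSNPs extra non-causal SNPs dropped alongside, MAF ~
#'   Uniform(0.05, 0.5).
#' @param alpha nominal level.
#' @param K top-K size for the screen.
#' @param seed master seed; replicate r uses [subSeed()].
#' @param includeVS run the screening arm too.
#' @param minInformative FBAT informative-family filter (default 10).
#' @return list of class `powerExperiment`: `power` (data.frame per causal
#'   SNP: MAF, beta, per-SNP heritability, and power for MGA / FBAT /
#'   FBAT-VS at nominal and Bonferroni thresholds), `pvalues` (per-replicate
#'   matrices), `nReplicates`.
#' @export
runPowerExperiment <- function(causal, template = pedigreeTemplate(),
                               model = traitModel(), nReplicates = 200,
                               nNullSNPs = 0, alpha = 0.05, K = 10,
                               seed = 1L, includeVS = TRUE,
                               minInformative = 10) {
  stopifnot(all(c("snpID", "maf", "beta") %in% names(causal)))
  setup <- .studySetup(template, seed)
  maf <- setNames(causal$maf, causal$snpID)
  if (nNullSNPs > 0) {
    set.seed(subSeed(seed, 3L))
    maf <- c(maf, setNames(runif(nNullSNPs, 0.05, 0.5),
                           paste0("null", seq_len(nNullSNPs))))
  }
  model$causalSNPs <- setNames(causal$beta, causal$snpID)
  snps <- names(maf)
  pM <- pF <- pV <- matrix(NA_real_, nReplicates, length(snps),
                           dimnames = list(NULL, snps))
  sigV <- matrix(FALSE, nReplicates, length(snps),
                 dimnames = list(NULL, snps))
  bonfM <- bonfF <- numeric(nReplicates)
  for (r in seq_len(nReplicates)) {
    s <- subSeed(seed, 10L + r)
    geno <- geneDrop(setup$cohort, maf, seed = s)
    pheno <- simulateTrait(setup$cohort, geno, setup$covariates, model,
                           setup$kinship, seed = subSeed(s, 1L))
    mga <- mgaScan(pheno, geno, setup$kinship)
    t <- residualizeTrait(pheno, setup$cohort)
    fb <- fbatScan(setup$cohort, geno, t, minInformative = minInformative)
    pM[r, ] <- mga$p
    pF[r, ] <- fb$p
    bonfM[r] <- bonferroniThreshold(alpha, max(1L, sum(mga$status == "ok")))
    bonfF[r] <- bonferroniThreshold(alpha, max(1L, sum(fb$status == "ok")))
    if (includeVS) {
      sc <- screenScan(setup$cohort, geno, t, alpha = alpha)
      vs <- rankAndTestTopK(sc, fb, K = K, alpha = alpha)
      pV[r, ] <- ifelse(vs$tested, vs$p, NA_real_)
      sigV[r, ] <- vs$significant
    }
  }
  power <- do.call(rbind, lapply(seq_along(snps), function(j) {
    sid <- snps[j]
    isCausal <- sid %in% causal$snpID
    beta <- if (isCausal) causal$beta[causal$snpID == sid] else 0
    vsnp <- 2 * maf[j] * (1 - maf[j]) * beta^2
    data.frame(
      snpID = sid, maf = unname(maf[j]), beta = beta,
      h2 = vsnp / (vsnp + model$sigmaG2 + model$sigmaE2),
      causal = isCausal,
      mgaNominal = empiricalPower(pM[, j], alpha),
      fbatNominal = empiricalPower(pF[, j], alpha),
      vsNominal = if (includeVS) empiricalPower(pV[, j], alpha) else NA_real_,
      mgaBonferroni = mean(!is.na(pM[, j]) & pM[, j] < bonfM),
      fbatBonferroni = mean(!is.na(pF[, j]) & pF[, j] < bonfF),
      vsBonferroni = if (includeVS) mean(sigV[, j]) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  structure(list(power = power,
                 pvalues = list(mga = pM, fbat = pF, vs = pV),
                 nReplicates = nReplicates, alpha = alpha, K = K),
            class = "powerExperiment")
}

#' Replicate-based type I error experiment
#'
#' Per replicate: gene-drop independent null SNPs (optionally LD-pruned),
#' simulate a trait with no genetic influence, run the measured-genotype
#' scan, the FBAT scan and (optionally) the top-K screen, and record the
#' proportion of tested SNPs with p below the nominal level. The reported
#' rate per method is the average of those per-replicate proportions; the
#' family-wise summary counts replicates with any rejection at the
#' method-specific Bonferroni threshold. Screen replicates where no SNP
#' reaches the top K contribute zero false positives.
#'
#' @param template a [pedigreeTemplate()].
#' @param nSNPs independent null SNPs per replicate.
#' @param nReplicates replicate count.
#' @param mafRange MAFs drawn Uniform(min, max) per replicate.
#' @param alpha nominal level.
#' @param K top-K size.
#' @param seed master seed.
#' @param prune apply [ldPrune()] before testing (the SNPs are simulated
#'   independent, so this is an option for user data realism, off by
#'   default).
#' @param includeVS run the screening arm too.
#' @param minInformative FBAT informative-family filter (default 10).
#' @return list of class `type1Experiment`: `rates` (data.frame per method:
#'   averaged type I proportion, family-wise false-positive replicate count
#'   after Bonferroni, tests per replicate), `perReplicate` (matrix of
#'   per-replicate proportions).
#' @export
runType1Experiment <- function(template = pedigreeTemplate(), nSNPs = 200,
                               nReplicates = 100, mafRange = c(0.05, 0.5),
                               alpha = 0.05, K = 10, seed = 1L,
                               prune = FALSE, includeVS = TRUE,
                               minInformative = 10) {
  setup <- .studySetup(template, seed)
  meth <- c("mga", "fbat", if (includeVS) "vs")
  prop <- matrix(NA_real_, nReplicates, length(meth),
                 dimnames = list(NULL, meth))
  fwe <- setNames(numeric(length(meth)), meth)
  nTested <- prop
  for (r in seq_len(nReplicates)) {
    s <- subSeed(seed, 10L + r)
    set.seed(s)
    maf <- setNames(runif(nSNPs, mafRange[1], mafRange[2]),
                    paste0("snp", seq_len(nSNPs)))
    geno <- geneDrop(setup$cohort, maf, seed = subSeed(s, 1L))
    if (prune) geno <- ldPrune(geno)
    trait <- simulateNullTrait(setup$cohort, seed = subSeed(s, 2L))
    pheno <- setup$covariates
    pheno$trait <- trait[pheno$id]
    mga <- mgaScan(pheno, geno, setup$kinship)
    t <- residualizeTrait(pheno, setup$cohort)
    fb <- fbatScan(setup$cohort, geno, t, minInformative = minInformative)
    okM <- mga$status == "ok"; okF <- fb$status == "ok"
    prop[r, "mga"] <- mean(mga$p[okM] < alpha)
    prop[r, "fbat"] <- mean(fb$p[okF] < alpha)
    nTested[r, "mga"] <- sum(okM); nTested[r, "fbat"] <- sum(okF)
    fwe["mga"] <- fwe["mga"] +
      any(mga$p[okM] < bonferroniThreshold(alpha, max(1L, sum(okM))))
    fwe["fbat"] <- fwe["fbat"] +
      any(fb$p[okF] < bonferroniThreshold(alpha, max(1L, sum(okF))))
    if (includeVS) {
      sc <- screenScan(setup$cohort, geno, t, alpha = alpha)
      vs <- rankAndTestTopK(sc, fb, K = K, alpha = alpha)
      prop[r, "vs"] <- sum(vs$tested & !is.na(vs$p) & vs$p < alpha) /
        ncol(geno@codes)
      nTested[r, "vs"] <- sum(vs$tested)
      fwe["vs"] <- fwe["vs"] + any(vs$significant)
    }
  }
  rates <- data.frame(method = meth,
                      typeI = colMeans(prop),
                      familywiseCount = unname(fwe),
                      meanTested = colMeans(nTested),
                      nReplicates = nReplicates, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(rates = rates, perReplicate = prop, alpha = alpha),
            class = "type1Experiment")
}

#' @noRd
#' @export
print.powerExperiment <- function(x, ...) {
  cat("Power experiment:", x$nReplicates, "replicates, alpha =", x$alpha,
      "\n")
  print(x$power[, c("snpID", "maf", "beta", "h2", "mgaNominal",
                    "fbatNominal", "mgaBonferroni", "fbatBonferroni",
                    "vsBonferroni")], digits = 3)
  invisible(x)
}

#' @noRd
#' @export
print.type1Experiment <- function(x, ...) {
  cat("Type I error experiment (nominal alpha =", x$alpha, ")\n")
  print(x$rates, digits = 3)
  invisible(x)
}
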