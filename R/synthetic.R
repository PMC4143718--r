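## Synthetic study generator: pedigrees, gene-dropped genotypes, covariates
## and traits with an additive polygenic component.

#' Deterministic per-replicate sub-seed
#'
#' Replicate r of a run with master seed s uses seed
#' `(s + 1000003 * r) mod (2^31 - 1)`, so any replicate can be regenerated in
#' isolation and the first k replicates of a longer run are identical to a
#' run with k replicates.
#'
#' @param seed master seed (integer).
#' @param r replicate number (0 = study-level draws).
#' @return an integer seed below 2^31.
#' @export
subSeed <- function(seed, r) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(r)) %% 2147483647)
}

#' Pedigree generator template
#'
#' Describes the multigenerational families emulated by
#' [generatePedigrees()]: a founding couple, offspring counts of
#' `1 + Poisson(meanOffspring)` per couple, and offspring of non-terminal
#' generations marrying in an unrelated founder spouse with probability
#' `marryInProb`. A candidate family is resampled until its size falls in
#' `sizeRange`.
#'
#' @param nPedigrees number of families.
#' @param sizeRange inclusive (min, max) family size.
#' @param nGenerations vector of admissible generation counts, sampled per
#'   family.
#' @param meanOffspring Poisson mean of the offspring count minus one.
#' @param marryInProb probability a non-terminal offspring founds a couple.
#' @param maxTries resampling budget per family before a configuration error.
#' @return a list of class `pedigreeTemplate`.
#' @export
pedigreeTemplate <- function(nPedigrees = 20, sizeRange = c(21, 76),
                             nGenerations = c(3, 4), meanOffspring = 2.5,
                             marryInProb = 0.75, maxTries = 1000) {
  stopifnot(nPedigrees >= 1, length(sizeRange) == 2, sizeRange[1] >= 3,
            sizeRange[1] <= sizeRange[2], all(nGenerations >= 2),
            meanOffspring >= 0, marryInProb >= 0, marryInProb <= 1)
  structure(list(nPedigrees = nPedigrees, sizeRange = sizeRange,
                 nGenerations = nGenerations, meanOffspring = meanOffspring,
                 marryInProb = marryInProb, maxTries = maxTries),
            class = "pedigreeTemplate")
}

#' Generate a cohort of multigenerational pedigrees
#'
#' @param template a [pedigreeTemplate()].
#' @param seed integer seed; the output is a deterministic function of
#'   (template, seed).
#' @return a [Cohort-class] of `nPedigrees` valid pedigrees with sizes inside
#'   `sizeRange`; individual ids are namespaced by pedigree (`P01_1`, ...).
#' @export
generatePedigrees <- function(template = pedigreeTemplate(), seed = 1L) {
  stopifnot(inherits(template, "pedigreeTemplate"))
  set.seed(subSeed(seed, 0L))
  peds <- vector("list", template$nPedigrees)
  for (i in seq_len(template$nPedigrees)) {
    pid <- sprintf("P%02d", i)
    for (try in seq_len(template$maxTries)) {
      m <- .growPedigree(template)
      if (nrow(m) >= template$sizeRange[1] && nrow(m) <= template$sizeRange[2])
        break
      m <- NULL
    }
    if (is.null(m))
      stop("could not generate a pedigree of size in [",
           template$sizeRange[1], ", ", template$sizeRange[2], "] in ",
           template$maxTries, " tries; adjust the template")
    m$id <- paste0(pid, "_", m$id)
    m$father <- ifelse(is.na(m$father), NA, paste0(pid, "_", m$father))
    m$mother <- ifelse(is.na(m$mother), NA, paste0(pid, "_", m$mother))
    peds[[i]] <- new("Pedigree", pedID = pid, members = m)
  }
  Cohort(peds)
}

## one candidate family; returns a member data.frame with local integer ids
.growPedigree <- function(template) {
  gens <- if (length(template$nGenerations) > 1)
    sample(template$nGenerations, 1) else template$nGenerations
  nextid <- 0L
  newid <- function() { nextid <<- nextid + 1L; as.character(nextid) }
  rec <- function(id, father, mother, sex)
    data.frame(id = id, father = father, mother = mother, sex = sex,
               stringsAsFactors = FALSE)
  f0 <- newid(); m0 <- newid()
  members <- rbind(rec(f0, NA, NA, "male"), rec(m0, NA, NA, "female"))
  couples <- list(c(f0, m0))
  for (g in seq_len(gens - 1L)) {
    nextCouples <- list()
    for (cp in couples) {
      k <- 1L + rpois(1L, template$meanOffspring)
      for (o in seq_len(k)) {
        oid <- newid()
        osex <- if (runif(1) < 0.5) "male" else "female"
        members <- rbind(members, rec(oid, cp[1], cp[2], osex))
        if (g < gens - 1L && runif(1) < template$marryInProb) {
          sid <- newid()
          ssex <- if (osex == "male") "female" else "male"
          members <- rbind(members, rec(sid, NA, NA, ssex))
          nextCouples[[length(nextCouples) + 1L]] <-
            if (osex == "male") c(oid, sid) else c(sid, oid)
        }
      }
    }
    couples <- nextCouples
    if (length(couples) == 0L && g < gens - 1L) break
  }
  members
}

#' Gene-drop genotypes through a cohort
#'
#' Founder alleles are drawn i.i.d. Bernoulli(MAF) and each nonfounder
#' receives one allele from each parent, chosen uniformly per meiosis, so
#' every output is Mendelian-consistent by construction. SNPs are dropped
#' independently (linkage equilibrium). With `ldBlockSize > 1`, SNPs are
#' instead generated in blocks that share founder transmissions with
#' probability `ldRho`, giving correlated columns to exercise [ldPrune()].
#'
#' @param cohort a [Cohort-class].
#' @param maf per-SNP minor allele frequencies in (0, 0.5]; names become SNP
#'   ids (default `snp1..snpK`).
#' @param seed integer seed.
#' @param ldBlockSize,ldRho optional LD-block mode (see above).
#' @return a [GenotypeMatrix-class] with the population `maf` recorded.
#' @export
geneDrop <- function(cohort, maf, seed = 1L, ldBlockSize = 1L, ldRho = 0.9) {
  stopifnot(is(cohort, "Cohort"), all(maf >= 0), all(maf <= 0.5))
  if (is.null(names(maf))) names(maf) <- paste0("snp", seq_along(maf))
  set.seed(subSeed(seed, 0L))
  ids <- individualIDs(cohort)
  nsnp <- length(maf)
  ## allele pairs per individual (rows) x SNP (cols), 0/1 = major/minor
  a1 <- matrix(0L, length(ids), nsnp, dimnames = list(ids, names(maf)))
  a2 <- a1
  pos <- setNames(seq_along(ids), ids)
  founder <- isFounder(cohort)
  nf <- sum(founder)
  fi <- which(founder)
  if (ldBlockSize <= 1L) {
    a1[fi, ] <- matrix(rbinom(nf * nsnp, 1L, rep(maf, each = nf)), nf, nsnp)
    a2[fi, ] <- matrix(rbinom(nf * nsnp, 1L, rep(maf, each = nf)), nf, nsnp)
  } else {
    blk <- (seq_len(nsnp) - 1L) %/% ldBlockSize + 1L
    for (b in unique(blk)) {
      js <- which(blk == b)
      base1 <- rbinom(nf, 1L, maf[js[1L]]); base2 <- rbinom(nf, 1L, maf[js[1L]])
      for (j in js) {
        keep1 <- runif(nf) < ldRho; keep2 <- runif(nf) < ldRho
        a1[fi, j] <- ifelse(keep1, base1, rbinom(nf, 1L, maf[j]))
        a2[fi, j] <- ifelse(keep2, base2, rbinom(nf, 1L, maf[j]))
      }
    }
  }
  for (p in cohort@pedigrees) {
    m <- p@members
    for (i in topoOrder(m)) {
      if (is.na(m$father[i])) next
      me <- pos[[m$id[i]]]
      fa <- pos[[m$father[i]]]; mo <- pos[[m$mother[i]]]
      pickF <- rbinom(nsnp, 1L, 0.5) == 1L
      pickM <- rbinom(nsnp, 1L, 0.5) == 1L
      a1[me, ] <- ifelse(pickF, a1[fa, ], a2[fa, ])
      a2[me, ] <- ifelse(pickM, a1[mo, ], a2[mo, ])
    }
  }
  GenotypeMatrix(a1 + a2, maf = maf)
}

#' Simulate covariates by generation
#'
#' Ages decrease with generation depth (means 75/50/25/10 years for depths
#' 0..3, truncated-normal noise, floor 1 year); sex is taken from the
#' pedigree (male=0, female=1); antihypertensive medication use `bpmed` is
#' Bernoulli(0.2). These distributions are a stated modelling choice — the
#' covariates only need to exist so that both association models can adjust
#' for them.
#'
#' @param cohort a [Cohort-class].
#' @param seed integer seed.
#' @param bpmedProb medication-use probability.
#' @return data.frame `id`, `ped`, `age`, `age2`, `sex`, `bpmed`.
#' @export
simulateCovariates <- function(cohort, seed = 1L, bpmedProb = 0.2) {
  set.seed(subSeed(seed, 0L))
  ids <- individualIDs(cohort)
  depth <- unlist(lapply(cohort@pedigrees,
                         function(p) generationDepth(p@members)),
                  use.names = FALSE)
  meanAge <- pmax(75 - 25 * depth, 10)
  age <- pmax(round(meanAge + rnorm(length(ids), 0, 5)), 1)
  sexnum <- ifelse(unlist(lapply(cohort@pedigrees,
                                 function(p) p@members$sex),
                          use.names = FALSE) == "female", 1L, 0L)
  data.frame(id = ids, ped = unname(pedigreeOf(cohort)), age = age,
             age2 = age^2, sex = sexnum,
             bpmed = rbinom(length(ids), 1L, bpmedProb),
             stringsAsFactors = FALSE)
}

#' Quantitative trait model
#'
#' Generative model for a blood-pressure-like trait:
#' `y = mu + b_age*age + b_age2*age^2 + b_sex*sex + b_bpmed*bpmed
#'  + sum_k beta_k x_k + g + e`, with polygenic `g ~ N(0, 2*Phi*sigmaG2)`
#' per pedigree and residual `e ~ N(0, sigmaE2)` i.i.d.
#'
#' @param mu grand mean (mm Hg for a DBP-like trait).
#' @param betaAge,betaAge2,betaSex,betaBpmed covariate effects.
#' @param causalSNPs named numeric vector: trait units per minor allele.
#' @param sigmaG2 additive polygenic variance (>= 0).
#' @param sigmaE2 residual variance (> 0).
#' @return a list of class `traitModel`.
#' @export
traitModel <- function(mu = 80, betaAge = 0.3, betaAge2 = 0.002, betaSex = 0,
                       betaBpmed = 5, causalSNPs = numeric(0),
                       sigmaG2 = 28, sigmaE2 = 56) {
  stopifnot(sigmaG2 >= 0, sigmaE2 > 0)
  structure(list(mu = mu, betaAge = betaAge, betaAge2 = betaAge2,
                 betaSex = betaSex, betaBpmed = betaBpmed,
                 causalSNPs = causalSNPs, sigmaG2 = sigmaG2,
                 sigmaE2 = sigmaE2),
            class = "traitModel")
}

#' Simulate a heritable quantitative trait
#'
#' @param cohort a [Cohort-class].
#' @param geno a [GenotypeMatrix-class] containing every causal SNP.
#' @param covariates data.frame from [simulateCovariates()] (or equivalent).
#' @param model a [traitModel()].
#' @param kinship the cohort's [KinshipMatrix-class] (2*Phi).
#' @param seed integer seed.
#' @return the covariate data.frame with a `trait` column appended.
#' @export
simulateTrait <- function(cohort, geno, covariates, model, kinship,
                          seed = 1L) {
  stopifnot(inherits(model, "traitModel"))
  set.seed(subSeed(seed, 0L))
  ids <- individualIDs(cohort)
  cv <- covariates[match(ids, covariates$id), , drop = FALSE]
  y <- model$mu + model$betaAge * cv$age + model$betaAge2 * cv$age2 +
    model$betaSex * cv$sex + model$betaBpmed * cv$bpmed
  if (length(model$causalSNPs)) {
    sn <- names(model$causalSNPs)
    if (!all(sn %in% snpIDs(geno)))
      stop("causal SNP(s) absent from genotype matrix: ",
           paste(setdiff(sn, snpIDs(geno)), collapse = ", "))
    y <- y + as.vector(geno@codes[ids, sn, drop = FALSE] %*% model$causalSNPs)
  }
  if (model$sigmaG2 > 0) {
    K <- as.matrix(kinship)[ids, ids]
    ped <- pedigreeOf(cohort)
    g <- numeric(length(ids))
    for (pid in unique(ped)) {
      ix <- which(ped == pid)
      B <- K[ix, ix, drop = FALSE] * model$sigmaG2
      e <- eigen(B, symmetric = TRUE)
      L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
      g[ix] <- as.vector(L %*% rnorm(length(ix)))
    }
    y <- y + g
  }
  y <- y + rnorm(length(ids), 0, sqrt(model$sigmaE2))
  cv$trait <- y
  cv
}

#' Simulate a trait with no genetic influence
#'
#' The null trait is i.i.d. normal, independent of all genotypes, covariates
#' and pedigree structure — the negative control for type I error
#' experiments.
#'
#' @param cohort a [Cohort-class].
#' @param seed integer seed.
#' @param mean,sd trait distribution parameters.
#' @return named numeric trait vector over all individuals.
#' @export
simulateNullTrait <- function(cohort, seed = 1L, mean = 0, sd = 1) {
  set.seed(subSeed(seed, 0L))
  ids <- individualIDs(cohort)
  setNames(rnorm(length(ids), mean, sd), ids)
}

#' SNP effect size from per-SNP heritability
#'
#' Inverts the identity `h2 = 2p(1-p)beta^2 / (2p(1-p)beta^2 + V_bg)`:
#' `beta = sqrt(h2 * V_bg / ((1 - h2) * 2p(1-p)))`.
#'
#' @param h2 per-SNP heritability in \[0, 1).
#' @param maf minor allele frequency in (0, 0.5\].
#' @param backgroundVar non-SNP trait variance (> 0).
#' @param sign +1 or -1.
#' @return the additive effect in trait units per minor allele.
#' @export
effectFromHeritability <- function(h2, maf, backgroundVar, sign = 1) {
  stopifnot(h2 >= 0, h2 < 1, maf > 0, maf <= 0.5, backgroundVar > 0)
  sign * sqrt(h2 * backgroundVar / ((1 - h2) * 2 * maf * (1 - maf)))
}

#' Write a complete synthetic study to a directory
#'
#' Produces `study.ped` / `study.map`, a covariate CSV (`covariates.csv`,
#' including the simulated trait) and a truth table (`truth.csv`: snp_id,
#' maf, beta, h2) listing the causal SNPs with their realized per-SNP
#' heritability.
#'
#' @param dir output directory (created if needed).
#' @param template a [pedigreeTemplate()].
#' @param maf per-SNP population MAFs (named).
#' @param model a [traitModel()].
#' @param seed integer seed.
#' @return invisibly, a list with the generated `cohort`, `genotypes` and
#'   `phenotypes`.
#' @export
writeSyntheticStudy <- function(dir, template = pedigreeTemplate(), maf,
                                model = traitModel(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generatePedigrees(template, seed = subSeed(seed, 1L))
  geno <- geneDrop(cohort, maf, seed = subSeed(seed, 2L))
  cov <- simulateCovariates(cohort, seed = subSeed(seed, 3L))
  kin <- kinshipMatrix(cohort)
  pheno <- simulateTrait(cohort, geno, cov, model, kin,
                         seed = subSeed(seed, 4L))
  writePedfile(cohort, geno, file.path(dir, "study.ped"),
               file.path(dir, "study.map"),
               trait = setNames(pheno$trait, pheno$id))
  write.csv(pheno, file.path(dir, "covariates.csv"), row.names = FALSE)
  cs <- model$causalSNPs
  bg <- model$sigmaG2 + model$sigmaE2
  p <- mafs(geno)[names(cs)]
  vsnp <- 2 * p * (1 - p) * cs^2
  write.csv(data.frame(snp_id = names(cs), maf = unname(p),
                       beta = unname(cs), h2 = unname(vsnp / (vsnp + bg))),
            file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(cohort = cohort, genotypes = geno, phenotypes = pheno))
}
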