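# Fixtures built in code and independent oracles used across test files.

trioPedigree <- function(pid = "F1") {
  Pedigree(pid, id = c("dad", "mom", "kid"),
           father = c(NA, NA, "dad"), mother = c(NA, NA, "mom"),
           sex = c("male", "female", "female"))
}

# grandparents -> two sibs, one marries in a spouse -> two grandchildren
threeGenPedigree <- function(pid = "G1") {
  Pedigree(pid,
           id     = c("gf", "gm", "a1", "a2", "sp", "c1", "c2"),
           father = c(NA, NA, "gf", "gf", NA, "a1", "a1"),
           mother = c(NA, NA, "gm", "gm", NA, "sp", "sp"),
           sex    = c("male", "female", "male", "female", "female",
                      "male", "female"))
}

halfSibPedigree <- function(pid = "H1") {
  Pedigree(pid, id = c("f", "m1", "m2", "k1", "k2"),
           father = c(NA, NA, NA, "f", "f"),
           mother = c(NA, NA, NA, "m1", "m2"),
           sex = c("male", "female", "female", "male", "male"))
}

# offspring of a full-sib mating: inbreeding coefficient 1/4
inbredPedigree <- function(pid = "I1") {
  Pedigree(pid, id = c("f", "m", "s1", "s2", "x"),
           father = c(NA, NA, "f", "f", "s1"),
           mother = c(NA, NA, "m", "m", "s2"),
           sex = c("male", "female", "male", "female", "female"))
}

# small ready-to-analyze study bundle (kinship, covariates, genotypes, trait)
smallStudy <- function(nPed = 4, nSNP = 25, seed = 42,
                       model = traitModel(sigmaG2 = 1, sigmaE2 = 1),
                       mafRange = c(0.1, 0.5)) {
  template <- pedigreeTemplate(nPedigrees = nPed)
  cohort <- generatePedigrees(template, seed = seed)
  kin <- kinshipMatrix(cohort)
  cov <- simulateCovariates(cohort, seed = seed + 1)
  set.seed(seed + 2)
  maf <- setNames(runif(nSNP, mafRange[1], mafRange[2]),
                  paste0("s", seq_len(nSNP)))
  geno <- geneDrop(cohort, maf, seed = seed + 3)
  pheno <- simulateTrait(cohort, geno, cov, model, kin, seed = seed + 4)
  list(cohort = cohort, kinship = kin, covariates = cov, geno = geno,
       pheno = pheno, template = template)
}

# Monte-Carlo gene-dropping estimate of 2*phi by founder-allele labelling:
# phi(i,j) is the probability that one random allele from each matches IBD.
geneDropKinship2MC <- function(ped, nDrops = 1e5, seed = 1) {
  set.seed(seed)
  m <- members(ped)
  n <- nrow(m)
  ord <- pedassoc:::topoOrder(m)
  idx <- setNames(seq_len(n), m$id)
  a1 <- matrix(0L, nDrops, n)  # allele labels, one column per individual
  a2 <- a1
  lab <- 0L
  for (i in ord) {
    if (is.na(m$father[i])) {
      a1[, i] <- lab + 1L; a2[, i] <- lab + 2L; lab <- lab + 2L
    } else {
      f <- idx[[m$father[i]]]; mo <- idx[[m$mother[i]]]
      pf <- runif(nDrops) < 0.5; pm <- runif(nDrops) < 0.5
      a1[, i] <- ifelse(pf, a1[, f], a2[, f])
      a2[, i] <- ifelse(pm, a1[, mo], a2[, mo])
    }
  }
  est <- matrix(0, n, n, dimnames = list(m$id, m$id))
  se <- est
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- if (i == j) (2 + 2 * (a1[, i] == a2[, i])) / 4
    else ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
            (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
    est[i, j] <- 2 * mean(s)
    se[i, j] <- 2 * sd(s) / sqrt(nDrops)
  }
  list(est = est, se = se)
}

# dense multivariate-normal log density, assembled without any block tricks
denseMvnLoglik <- function(y, X, beta, Sigma) {
  r <- y - as.vector(as.matrix(X) %*% beta)
  ch <- chol(Sigma)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

# fresh Mendelian draws of offspring genotypes within transmission units,
# conditional on the observed parental genotypes (the FBAT null device)
redropUnits <- function(units, seed) {
  set.seed(seed)
  pr <- conditionalMoments(units$fatherGeno, units$motherGeno)$probs
  u <- runif(nrow(units))
  units$offspringGeno <- (u > pr[, 1L]) + (u > pr[, 1L] + pr[, 2L])
  units
}

# identity-kinship object over given ids (each individual its own block)
identityKinship <- function(ids) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  new("KinshipMatrix", K, ped = ids)
}
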