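## Family-based association test: trait residualization, decomposition of
## extended pedigrees into parent-offspring transmission units, Mendelian
## conditional moments, and the score statistic U^2 / Var(U) ~ chi2_1.

#' Residualize the trait on covariates
#'
#' Ordinary least-squares residuals of the trait on an intercept plus the
#' covariates, computed over all phenotyped nonfounders pooled across
#' pedigrees (founder traits are not used by the within-family test).
#' Default covariates are age, age squared, sex and medication use.
#'
#' @param pheno data.frame with `id`, `trait` and covariate columns.
#' @param cohort the [Cohort-class] (identifies nonfounders).
#' @param covariates covariate column names.
#' @return named numeric vector of residuals, one per phenotyped nonfounder.
#' @export
residualizeTrait <- function(pheno, cohort,
                             covariates = c("age", "age2", "sex", "bpmed")) {
  fo <- isFounder(cohort)
  ph <- pheno[pheno$id %in% names(fo)[!fo] & !is.na(pheno$trait), ,
              drop = FALSE]
  miss <- setdiff(covariates, names(ph))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  X <- cbind(1, as.matrix(ph[, covariates, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) stop("residualization design is rank-deficient")
  fit <- .lm.fit(X, ph$trait)
  setNames(fit$residuals, ph$id)
}

## index of all nonfounder (offspring, father, mother) triples in a cohort
transmissionIndex <- function(cohort) {
  out <- lapply(cohort@pedigrees, function(p) {
    m <- p@members
    nf <- !is.na(m$father)
    data.frame(ped = p@pedID, offspring = m$id[nf], father = m$father[nf],
               mother = m$mother[nf], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mendelian conditional moments of an offspring genotype
#'
#' Given parental minor-allele counts, each parent transmits its minor
#' allele with probability genotype/2, independently, so the offspring count
#' is the sum of two independent Bernoulli draws. Vectorized over parents.
#'
#' @param father,mother parental genotypes in \{0,1,2\}.
#' @return list: `probs` (matrix, columns P(x=0), P(x=1), P(x=2)), `mean`,
#'   `variance`.
#' @export
conditionalMoments <- function(father, mother) {
  stopifnot(all(father %in% 0:2 | is.na(father)),
            all(mother %in% 0:2 | is.na(mother)))
  pf <- father / 2; pm <- mother / 2
  probs <- cbind(`0` = (1 - pf) * (1 - pm),
                 `1` = pf * (1 - pm) + (1 - pf) * pm,
                 `2` = pf * pm)
  list(probs = probs, mean = pf + pm,
       variance = pf * (1 - pf) + pm * (1 - pm))
}

#' Decompose a cohort into transmission units at one SNP
#'
#' Extended pedigrees are broken into parent-offspring trios: one unit per
#' genotyped nonfounder whose parents are both genotyped at the SNP. An
#' individual can appear as offspring in one unit and as a parent in others;
#' distinct meioses are independent given the parental genotypes, which is
#' what makes the units' contributions additive. Offspring with a missing
#' parental genotype contribute no unit; Mendelian-impossible units are
#' excluded with a warning.
#'
#' @param cohort a [Cohort-class].
#' @param geno a [GenotypeMatrix-class].
#' @param snpID single SNP id.
#' @return data.frame: `ped`, `offspring`, `fatherGeno`, `motherGeno`,
#'   `offspringGeno`.
#' @export
decomposeTransmissions <- function(cohort, geno, snpID) {
  stopifnot(snpID %in% snpIDs(geno))
  tu <- transmissionIndex(cohort)
  cd <- geno@codes[, snpID]
  units <- data.frame(ped = tu$ped, offspring = tu$offspring,
                      fatherGeno = unname(cd[tu$father]),
                      motherGeno = unname(cd[tu$mother]),
                      offspringGeno = unname(cd[tu$offspring]),
                      stringsAsFactors = FALSE)
  units <- units[!is.na(units$fatherGeno) & !is.na(units$motherGeno) &
                   !is.na(units$offspringGeno), , drop = FALSE]
  cm <- conditionalMoments(units$fatherGeno, units$motherGeno)
  pr <- cm$probs[cbind(seq_len(nrow(units)), units$offspringGeno + 1L)]
  if (any(pr == 0)) {
    warning(sum(pr == 0), " Mendelian-impossible transmission unit(s) ",
            "excluded at ", snpID)
    units <- units[pr > 0, , drop = FALSE]
  }
  rownames(units) <- NULL
  units
}

#' FBAT score statistic from transmission units
#'
#' `U = sum t * (x - E[x | parents])` and `V = sum t^2 * Var(x | parents)`
#' over units; `chi2 = U^2 / V` is asymptotically chi-squared on 1 df under
#' the null of no association. A family is informative if it contains at
#' least one unit with positive conditional variance (a heterozygous parent)
#' and a nonzero residual trait.
#'
#' @param units data.frame from [decomposeTransmissions()].
#' @param t named residual-trait vector ([residualizeTrait()]); units whose
#'   offspring has no residual are dropped.
#' @return list (`FbatResult`): `U`, `V`, `chi2`, `p`,
#'   `nInformativeFamilies`, `nUnits`, `status` (`"ok"`/`"uninformative"`).
#' @export
fbatStatistic <- function(units, t) {
  tv <- t[units$offspring]
  keep <- !is.na(tv)
  units <- units[keep, , drop = FALSE]
  tv <- tv[keep]
  cm <- conditionalMoments(units$fatherGeno, units$motherGeno)
  U <- sum(tv * (units$offspringGeno - cm$mean))
  V <- sum(tv^2 * cm$variance)
  nif <- length(unique(units$ped[cm$variance > 0 & tv != 0]))
  if (V <= 0)
    return(list(U = U, V = 0, chi2 = NA_real_, p = NA_real_,
                nInformativeFamilies = nif, nUnits = nrow(units),
                status = "uninformative"))
  chi2 <- U^2 / V
  list(U = U, V = V, chi2 = chi2,
       p = pchisq(chi2, df = 1, lower.tail = FALSE),
       nInformativeFamilies = nif, nUnits = nrow(units), status = "ok")
}

#' FBAT scan over all SNPs
#'
#' Computes the score statistic for every SNP (vectorized across the whole
#' genotype matrix) and applies the informative-family filter: SNPs with
#' fewer than `minInformative` informative families are flagged `"filtered"`
#' and get no p-value; they are meant to be excluded from the
#' multiple-testing denominator as well (see [bonferroniThreshold()]).
#'
#' @param cohort a [Cohort-class].
#' @param geno a [GenotypeMatrix-class].
#' @param t named residual-trait vector from [residualizeTrait()].
#' @param minInformative minimum informative families (default 10).
#' @return data.frame per SNP: `snpID`, `nUnits`, `nInformativeFamilies`,
#'   `U`, `V`, `chi2`, `p`, `status`.
#' @export
fbatScan <- function(cohort, geno, t, minInformative = 10) {
  tu <- transmissionIndex(cohort)
  tv <- t[tu$offspring]
  keep <- !is.na(tv)
  tu <- tu[keep, , drop = FALSE]; tv <- tv[keep]
  cd <- geno@codes
  GF <- cd[tu$father, , drop = FALSE]
  GM <- cd[tu$mother, , drop = FALSE]
  X  <- cd[tu$offspring, , drop = FALSE]
  E <- (GF + GM) / 2
  V1 <- GF / 2 * (1 - GF / 2) + GM / 2 * (1 - GM / 2)
  ok <- !is.na(GF) & !is.na(GM) & !is.na(X)
  ## Mendelian-impossible pairs (user data): zero out with warning
  pr <- (X == 0L) * (1 - GF / 2) * (1 - GM / 2) +
    (X == 1L) * (GF / 2 * (1 - GM / 2) + (1 - GF / 2) * GM / 2) +
    (X == 2L) * (GF / 2) * (GM / 2)
  bad <- ok & pr == 0
  if (any(bad)) {
    warning(sum(bad), " Mendelian-impossible transmission unit(s) excluded")
    ok <- ok & !bad
  }
  w <- ok * 1
  dev <- X - E; dev[!ok] <- 0
  Vc <- V1; Vc[!ok] <- 0
  U <- colSums(tv * dev)
  V <- colSums(tv^2 * Vc)
  nUnits <- colSums(w)
  inf <- (Vc > 0) & (tv != 0)
  nif <- apply(inf, 2L, function(z) length(unique(tu$ped[z])))
  chi2 <- ifelse(V > 0, U^2 / V, NA_real_)
  p <- ifelse(V > 0, pchisq(chi2, df = 1, lower.tail = FALSE), NA_real_)
  status <- ifelse(V <= 0, "uninformative",
                   ifelse(nif < minInformative, "filtered", "ok"))
  p[status != "ok"] <- NA_real_
  data.frame(snpID = colnames(cd), nUnits = nUnits,
             nInformativeFamilies = nif, U = U, V = V,
             chi2 = ifelse(status == "filtered", NA_real_, chi2), p = p,
             status = status, row.names = NULL, stringsAsFactors = FALSE)
}
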