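#' @import methods
#' @importFrom stats dnorm lm optimize pchisq pnorm qnorm rbinom rnorm rpois
#'   runif sd var coef resid cor setNames .lm.fit
#' @importFrom utils read.table write.table read.csv write.csv
NULL

SEX_LEVELS <- c("male", "female", "unknown")

#' Pedigree: one family with parent links
#'
#' A `Pedigree` holds the members of one family as a data frame with columns
#' `id`, `father`, `mother` (both `NA` for founders) and `sex`
#' (`"male"`, `"female"` or `"unknown"`). Construction checks only the shape;
#' use [validatePedigree()] for structural findings (cycles, half-specified
#' parents, unknown parent ids) and build a [Cohort-class] to enforce them.
#'
#' @slot pedID single character pedigree identifier.
#' @slot members data.frame with columns `id`, `father`, `mother`, `sex`.
#' @export
setClass("Pedigree", representation(pedID = "character", members = "data.frame"))

setValidity("Pedigree", function(object) {
  m <- object@members
  need <- c("id", "father", "mother", "sex")
  if (length(object@pedID) != 1L || is.na(object@pedID))
    return("pedID must be a single non-NA string")
  if (!all(need %in% names(m)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  if (!all(m$sex %in% SEX_LEVELS))
    return("sex must be 'male', 'female' or 'unknown'")
  if (any(is.na(m$id)) || !is.character(m$id))
    return("member ids must be non-NA character")
  TRUE
})

#' @describeIn Pedigree-class constructor from member vectors. `father`/`mother`
#'   use `NA` (or `"0"`, the PED convention) for founders.
#' @param pedID pedigree identifier.
#' @param id,father,mother,sex member columns (recycled checks apply).
#' @export
Pedigree <- function(pedID, id, father, mother, sex) {
  father <- as.character(father); mother <- as.character(mother)
  father[father %in% "0"] <- NA_character_
  mother[mother %in% "0"] <- NA_character_
  new("Pedigree", pedID = as.character(pedID),
      members = data.frame(id = as.character(id), father = father,
                           mother = mother, sex = as.character(sex),
                           stringsAsFactors = FALSE))
}

#' Cohort: a collection of pedigrees
#'
#' Families are unrelated by construction; kinship between members of
#' different pedigrees is exactly zero. Individual ids must be unique across
#' the whole cohort. The constructor validates every pedigree with
#' [validatePedigree()] and refuses invalid ones.
#'
#' @slot pedigrees list of [Pedigree-class] objects.
#' @export
setClass("Cohort", representation(pedigrees = "list"))

setValidity("Cohort", function(object) {
  if (!all(vapply(object@pedigrees, is, logical(1), "Pedigree")))
    return("pedigrees must be a list of Pedigree objects")
  pids <- vapply(object@pedigrees, function(p) p@pedID, character(1))
  if (anyDuplicated(pids)) return("duplicate pedigree ids")
  ids <- unlist(lapply(object@pedigrees, function(p) p@members$id))
  if (anyDuplicated(ids))
    return("individual ids must be unique across pedigrees")
  TRUE
})

#' @describeIn Cohort-class constructor; errors if any pedigree has validation
#'   findings.
#' @param pedigrees list of [Pedigree-class] objects.
#' @export
Cohort <- function(pedigrees) {
  obj <- new("Cohort", pedigrees = pedigrees)
  for (p in pedigrees) {
    f <- validatePedigree(p)
    if (nrow(f))
      stop("invalid pedigree '", p@pedID, "': ", f$type[1L], " (", f$id[1L], ")")
  }
  obj
}

#' GenotypeMatrix: additive minor-allele counts
#'
#' Genotypes are coded additively as the count of minor alleles (0/1/2, `NA`
#' for missing), individuals in rows, SNPs in columns. The per-SNP `maf` slot
#' records the minor allele frequency implied by the coding.
#'
#' @slot codes integer matrix in \{0,1,2,NA\} with individual rownames and SNP
#'   colnames.
#' @slot maf named numeric vector of per-SNP minor allele frequencies in
#'   \[0, 0.5\].
#' @export
setClass("GenotypeMatrix", representation(codes = "matrix", maf = "numeric"))

setValidity("GenotypeMatrix", function(object) {
  cd <- object@codes
  if (is.null(rownames(cd)) || is.null(colnames(cd)))
    return("codes must have individual rownames and SNP colnames")
  if (!all(cd %in% c(0L, 1L, 2L, NA)))
    return("codes must be 0, 1, 2 or NA")
  if (length(object@maf) != ncol(cd))
    return("maf must have one entry per SNP")
  if (any(object@maf < 0 | object@maf > 0.5, na.rm = TRUE))
    return("maf must lie in [0, 0.5]")
  TRUE
})

#' @describeIn GenotypeMatrix-class constructor. If `maf` is missing it is
#'   computed as the mean code / 2 among non-missing entries.
#' @param codes integer matrix of minor-allele counts.
#' @param maf optional per-SNP minor allele frequencies.
#' @export
GenotypeMatrix <- function(codes, maf = NULL) {
  storage.mode(codes) <- "integer"
  if (is.null(maf)) maf <- colMeans(codes, na.rm = TRUE) / 2
  names(maf) <- colnames(codes)
  new("GenotypeMatrix", codes = codes, maf = maf)
}

#' KinshipMatrix: the additive relationship matrix 2*Phi
#'
#' A symmetric numeric matrix whose (i, j) entry is twice the kinship
#' coefficient phi(i, j) — the expected additive genetic relationship. It is
#' block-diagonal across pedigrees; the `ped` slot records the pedigree of
#' each individual so downstream fits can work block-by-block.
#'
#' @slot .Data symmetric numeric matrix with matching dimnames.
#' @slot ped character vector of pedigree ids, one per individual.
#' @export
setClass("KinshipMatrix", contains = "matrix", representation(ped = "character"))

setValidity("KinshipMatrix", function(object) {
  m <- object@.Data
  if (nrow(m) != ncol(m)) return("must be square")
  if (length(object@ped) != nrow(m))
    return("ped must have one entry per individual")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10)))
    return("must be symmetric")
  TRUE
})

## ---- accessors ----

#' @export
setGeneric("pedID", function(x) standardGeneric("pedID"))
#' @describeIn Pedigree-class pedigree identifier.
#' @param x object.
#' @export
setMethod("pedID", "Pedigree", function(x) x@pedID)

#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @describeIn Pedigree-class member data frame.
#' @export
setMethod("members", "Pedigree", function(x) x@members)

#' @export
setGeneric("pedigrees", function(x) standardGeneric("pedigrees"))
#' @describeIn Cohort-class list of pedigrees.
#' @export
setMethod("pedigrees", "Cohort", function(x) x@pedigrees)

#' @export
setGeneric("individualIDs", function(x) standardGeneric("individualIDs"))
#' @describeIn Cohort-class all individual ids, pedigree by pedigree.
#' @export
setMethod("individualIDs", "Cohort",
          function(x) unlist(lapply(x@pedigrees, function(p) p@members$id),
                             use.names = FALSE))
#' @describeIn GenotypeMatrix-class individual ids (rownames).
#' @export
setMethod("individualIDs", "GenotypeMatrix", function(x) rownames(x@codes))

#' @export
setGeneric("isFounder", function(x) standardGeneric("isFounder"))
#' @describeIn Pedigree-class logical: both parents missing.
#' @export
setMethod("isFounder", "Pedigree",
          function(x) is.na(x@members$father) & is.na(x@members$mother))
#' @describeIn Cohort-class named logical over all individuals.
#' @export
setMethod("isFounder", "Cohort", function(x) {
  out <- unlist(lapply(x@pedigrees, isFounder), use.names = FALSE)
  names(out) <- individualIDs(x)
  out
})

#' @export
setGeneric("pedigreeOf", function(x) standardGeneric("pedigreeOf"))
#' @describeIn Cohort-class named character: pedigree id of each individual.
#' @export
setMethod("pedigreeOf", "Cohort", function(x) {
  out <- unlist(lapply(x@pedigrees,
                       function(p) rep(p@pedID, nrow(p@members))),
                use.names = FALSE)
  names(out) <- individualIDs(x)
  out
})

#' @export
setGeneric("genotypeCodes", function(x) standardGeneric("genotypeCodes"))
#' @describeIn GenotypeMatrix-class the integer code matrix.
#' @export
setMethod("genotypeCodes", "GenotypeMatrix", function(x) x@codes)

#' @export
setGeneric("snpIDs", function(x) standardGeneric("snpIDs"))
#' @describeIn GenotypeMatrix-class SNP ids (colnames).
#' @export
setMethod("snpIDs", "GenotypeMatrix", function(x) colnames(x@codes))

#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))
#' @describeIn GenotypeMatrix-class per-SNP minor allele frequencies.
#' @export
setMethod("mafs", "GenotypeMatrix", function(x) x@maf)

#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @describeIn Cohort-class total number of individuals.
#' @export
setMethod("nIndividuals", "Cohort",
          function(x) sum(vapply(x@pedigrees, function(p) nrow(p@members),
                                 integer(1))))

## ---- show ----

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat("Pedigree '", object@pedID, "': ", nrow(m), " members (",
      sum(is.na(m$father) & is.na(m$mother)), " founders)\n", sep = "")
})

setMethod("show", "Cohort", function(object) {
  sz <- vapply(object@pedigrees, function(p) nrow(p@members), integer(1))
  cat("Cohort: ", length(sz), " pedigrees, ", sum(sz),
      " individuals (sizes ", min(sz), "-", max(sz), ")\n", sep = "")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix: ", nrow(object@codes), " individuals x ",
      ncol(object@codes), " SNPs; MAF range [",
      sprintf("%.3f", min(object@maf)), ", ",
      sprintf("%.3f", max(object@maf)), "]; ",
      sum(is.na(object@codes)), " missing\n", sep = "")
})

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix (2*Phi): ", nrow(object), " individuals in ",
      length(unique(object@ped)), " pedigree blocks\n", sep = "")
})
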