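## Pedigree validation, topological ordering, PED/MAP input and output.

#' Validate a pedigree's structure
#'
#' Checks the structural invariants of a family: unique member ids, parents
#' either both present or both absent, referenced parents on file, and an
#' acyclic parent graph (no individual is its own ancestor). Problems are
#' returned as findings, not raised, so that batch validation of user files
#' can report everything at once.
#'
#' @param p a [Pedigree-class].
#' @return data.frame with columns `type` (one of `duplicate_id`,
#'   `half_parent`, `missing_parent`, `self_parent`, `cycle`), `id` and
#'   `message`; zero rows iff the pedigree is valid.
#' @export
validatePedigree <- function(p) {
  stopifnot(is(p, "Pedigree"))
  m <- p@members
  f <- list()
  add <- function(type, id, msg)
    f[[length(f) + 1L]] <<- data.frame(type = type, id = id, message = msg,
                                       stringsAsFactors = FALSE)
  dup <- unique(m$id[duplicated(m$id)])
  for (d in dup) add("duplicate_id", d, "individual id appears more than once")
  half <- xor(is.na(m$father), is.na(m$mother))
  for (i in which(half))
    add("half_parent", m$id[i], "exactly one parent specified")
  for (i in which(!is.na(m$father) & !(m$father %in% m$id)))
    add("missing_parent", m$id[i],
        paste0("father '", m$father[i], "' not in pedigree"))
  for (i in which(!is.na(m$mother) & !(m$mother %in% m$id)))
    add("missing_parent", m$id[i],
        paste0("mother '", m$mother[i], "' not in pedigree"))
  self <- !is.na(m$father) & m$father == m$id | !is.na(m$mother) & m$mother == m$id
  for (i in which(self)) add("self_parent", m$id[i], "individual is own parent")
  if (length(f) == 0L && is.null(topoOrder(m)))
    add("cycle", p@pedID, "pedigree contains an ancestry cycle")
  if (length(f)) do.call(rbind, f)
  else data.frame(type = character(), id = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Founders-first topological ordering
#'
#' @param m member data.frame (`id`, `father`, `mother`).
#' @return integer row order with every parent before its children, or `NULL`
#'   if the parent graph is cyclic.
#' @keywords internal
topoOrder <- function(m) {
  n <- nrow(m)
  idx <- setNames(seq_len(n), m$id)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(m$father) | placed[idx[m$father]] %in% TRUE) &
      (is.na(m$mother) | placed[idx[m$mother]] %in% TRUE)
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) NULL else ord
}

## generation depth: founders 0, child = 1 + max(parent depths)
generationDepth <- function(m) {
  ord <- topoOrder(m)
  depth <- setNames(rep(0L, nrow(m)), m$id)
  for (i in ord) {
    if (!is.na(m$father[i]))
      depth[m$id[i]] <- 1L + max(depth[m$father[i]], depth[m$mother[i]])
  }
  depth
}

#' Read a PED/MAP file pair
#'
#' Whitespace-delimited PED: family, individual, father, mother, sex
#' (1=male, 2=female, other=unknown), phenotype, then two allele columns per
#' SNP; `"0"` marks a missing parent or allele. SNP ids come from the MAP
#' file (columns: chromosome, snp id, position(s)). Genotypes are recoded to
#' minor-allele counts; the minor allele is the less frequent allele over the
#' whole genotyped sample, ties at 0.5 broken toward the lexicographically
#' smaller allele name. Offspring genotypes that are Mendelian-impossible
#' given two genotyped parents are set missing with a warning.
#'
#' @param pedPath,mapPath paths to the PED and MAP files.
#' @return list with elements `cohort` ([Cohort-class]), `genotypes`
#'   ([GenotypeMatrix-class]) and `phenotypes` (data.frame `id`, `ped`, `sex`,
#'   `trait`; trait `NA` where the PED phenotype is 0 or -9).
#' @export
readPedfile <- function(pedPath, mapPath) {
  stopifnot(file.exists(pedPath), file.exists(mapPath))
  map <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  snps <- as.character(map[[2]])
  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- 6L + 2L * length(snps)
  bad <- which(lengths(fields) != nf)
  if (length(bad))
    stop("malformed PED line ", bad[1L], ": expected ", nf, " fields, got ",
         lengths(fields)[bad[1L]])
  ped <- do.call(rbind, fields)
  fam <- ped[, 1L]; iid <- ped[, 2L]
  if (anyDuplicated(paste(fam, iid, sep = "\r")) == 0L && anyDuplicated(iid))
    stop("individual ids reused across families; ids must be unique ",
         "cohort-wide (prefix them with the family id)")
  sexmap <- c("1" = "male", "2" = "female")
  sex <- sexmap[ped[, 5L]]
  sex[is.na(sex)] <- "unknown"
  peds <- lapply(split(seq_along(iid), factor(fam, levels = unique(fam))),
                 function(rows)
                   Pedigree(fam[rows[1L]], iid[rows], ped[rows, 3L],
                            ped[rows, 4L], sex[rows]))
  cohort <- Cohort(unname(peds))

  a1 <- ped[, 6L + 2L * seq_along(snps) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_along(snps), drop = FALSE]
  codes <- matrix(NA_integer_, nrow(ped), length(snps),
                  dimnames = list(iid, snps))
  minor <- character(length(snps))
  for (j in seq_along(snps)) {
    al <- c(a1[, j], a2[, j])
    al <- al[al != "0"]
    tab <- sort(table(al))
    minor[j] <- if (length(tab) == 0L) NA_character_
      else if (length(tab) == 1L) NA_character_   # monomorphic: count 0
      else if (tab[1L] == tab[2L]) min(names(tab)) else names(tab)[1L]
    ok <- a1[, j] != "0" & a2[, j] != "0"
    cj <- rep(NA_integer_, nrow(ped))
    cj[ok] <- if (is.na(minor[j])) 0L
      else (a1[ok, j] == minor[j]) + (a2[ok, j] == minor[j])
    codes[, j] <- cj
  }
  geno <- GenotypeMatrix(codes)
  geno <- .maskMendelianErrors(cohort, geno)

  trait <- suppressWarnings(as.numeric(ped[, 6L]))
  trait[trait %in% c(0, -9)] <- NA_real_
  pheno <- data.frame(id = iid, ped = fam, sex = unname(sex), trait = trait,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, genotypes = geno, phenotypes = pheno)
}

## set child codes impossible under both genotyped parents to NA, warning once
.maskMendelianErrors <- function(cohort, geno) {
  cd <- geno@codes
  tu <- transmissionIndex(cohort)
  tu <- tu[tu$offspring %in% rownames(cd), , drop = FALSE]
  if (!nrow(tu)) return(geno)
  gf <- cd[tu$father, , drop = FALSE] / 2
  gm <- cd[tu$mother, , drop = FALSE] / 2
  x  <- cd[tu$offspring, , drop = FALSE]
  p <- (x == 0L) * (1 - gf) * (1 - gm) +
       (x == 1L) * (gf * (1 - gm) + (1 - gf) * gm) +
       (x == 2L) * gf * gm
  bad <- which(!is.na(p) & p == 0, arr.ind = TRUE)
  if (nrow(bad)) {
    warning(nrow(bad), " Mendelian-inconsistent genotype(s) set to missing")
    cd[cbind(match(tu$offspring[bad[, 1L]], rownames(cd)), bad[, 2L])] <-
      NA_integer_
    geno <- GenotypeMatrix(cd)
  }
  geno
}

#' Write a cohort and genotypes as a PED/MAP pair
#'
#' The minor allele is written as `A` and the major as `B`, so a written file
#' reads back to the identical coding (at a 0.5 tie `A` is again chosen as
#' the minor allele).
#'
#' @param cohort a [Cohort-class].
#' @param geno a [GenotypeMatrix-class] covering the cohort's individuals.
#' @param pedPath,mapPath output paths.
#' @param trait optional named trait vector written to the PED phenotype
#'   column (missing written as `-9`).
#' @param chrom chromosome label for the MAP file.
#' @return invisibly, the PED path.
#' @export
writePedfile <- function(cohort, geno, pedPath, mapPath, trait = NULL,
                         chrom = "3") {
  ids <- individualIDs(cohort)
  cd <- geno@codes[ids, , drop = FALSE]
  gstr <- matrix("0 0", nrow(cd), ncol(cd))
  gstr[cd == 0L] <- "B B"; gstr[cd == 1L] <- "A B"; gstr[cd == 2L] <- "A A"
  sexout <- c(male = "1", female = "2", unknown = "0")
  tr <- rep("-9", length(ids))
  if (!is.null(trait)) {
    tv <- trait[ids]
    tr[!is.na(tv)] <- format(tv[!is.na(tv)], digits = 10)
  }
  rows <- character(0)
  off <- 0L
  for (p in cohort@pedigrees) {
    m <- p@members
    i <- off + seq_len(nrow(m))
    rows <- c(rows, paste(p@pedID, m$id,
                          ifelse(is.na(m$father), "0", m$father),
                          ifelse(is.na(m$mother), "0", m$mother),
                          sexout[m$sex], tr[i],
                          apply(gstr[i, , drop = FALSE], 1L, paste,
                                collapse = " ")))
    off <- off + nrow(m)
  }
  writeLines(rows, pedPath)
  write.table(data.frame(chrom, colnames(cd), 0, seq_len(ncol(cd))),
              mapPath, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(pedPath)
}

#' Read a phenotype/covariate table
#'
#' CSV with a header; must contain columns `id`, `ped`, a trait column
#' (default `trait`), `age`, `sex` (0/1) and `bpmed` (0/1). An `age2` column
#' is added if absent.
#'
#' @param path CSV path.
#' @param traitCol name of the trait column.
#' @return data.frame, one row per individual.
#' @export
readCovariates <- function(path, traitCol = "trait") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "ped", traitCol, "age", "sex", "bpmed")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("covariate file lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"age2" %in% names(df)) df$age2 <- df$age^2
  df$id <- as.character(df$id)
  df
}

#' Write a kinship matrix as sparse text
#'
#' Three columns (id1, id2, 2*Phi), upper triangle including the diagonal,
#' zero entries omitted.
#'
#' @param k a [KinshipMatrix-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeKinship <- function(k, path) {
  ut <- which(upper.tri(k, diag = TRUE) & k != 0, arr.ind = TRUE)
  write.table(data.frame(id1 = rownames(k)[ut[, 1L]],
                         id2 = colnames(k)[ut[, 2L]],
                         kinship2 = k[ut]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
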