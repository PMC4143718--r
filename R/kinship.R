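## Recursive kinship computation.

#' Kinship (additive relationship) matrix of a cohort
#'
#' Computes 2*Phi, twice the kinship coefficient matrix, by the standard
#' recursion over a founders-first ordering:
#' `phi(i,i) = (1 + phi(f_i, m_i)) / 2` and
#' `phi(i,j) = (phi(f_i, j) + phi(m_i, j)) / 2` for j ordered before i, with
#' `phi = 0` between founders and between pedigrees. The recursion handles
#' inbreeding (including pedigree loops) exactly; the result is symmetric,
#' positive semidefinite and block-diagonal across pedigrees, with diagonal 1
#' for non-inbred individuals.
#'
#' @param cohort a [Cohort-class] (or a single [Pedigree-class]).
#' @return a [KinshipMatrix-class] holding 2*Phi over all individuals in
#'   cohort order.
#' @export
kinshipMatrix <- function(cohort) {
  if (is(cohort, "Pedigree")) cohort <- Cohort(list(cohort))
  stopifnot(is(cohort, "Cohort"))
  ids <- individualIDs(cohort)
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  off <- 0L
  for (p in cohort@pedigrees) {
    m <- p@members
    f <- validatePedigree(p)
    if (nrow(f)) stop("invalid pedigree '", p@pedID, "': ", f$type[1L])
    K[off + seq_len(nrow(m)), off + seq_len(nrow(m))] <- .pedKinship2(m)
    off <- off + nrow(m)
  }
  new("KinshipMatrix", K, ped = unname(pedigreeOf(cohort)))
}

## 2*Phi for one pedigree's member table
.pedKinship2 <- function(m) {
  n <- nrow(m)
  ord <- topoOrder(m)
  idx <- setNames(seq_len(n), m$id)
  phi <- matrix(0, n, n)
  done <- integer(0)
  for (i in ord) {
    fi <- m$father[i]; mi <- m$mother[i]
    if (is.na(fi)) {
      phi[i, i] <- 0.5
    } else {
      fj <- idx[[fi]]; mj <- idx[[mi]]
      phi[i, i] <- 0.5 * (1 + phi[fj, mj])
      if (length(done)) {
        v <- 0.5 * (phi[fj, done] + phi[mj, done])
        phi[i, done] <- v
        phi[done, i] <- v
      }
    }
    done <- c(done, i)
  }
  2 * phi[seq_len(n), seq_len(n), drop = FALSE]
}

## per-pedigree-block spectral decompositions of 2*Phi, reused across fits
kinshipEigen <- function(k) {
  stopifnot(is(k, "KinshipMatrix") || is.matrix(k))
  ped <- if (is(k, "KinshipMatrix")) k@ped else rep("1", nrow(k))
  m <- unclass(as.matrix(k))
  lapply(split(seq_len(nrow(m)), factor(ped, levels = unique(ped))),
         function(ix) {
           e <- eigen(m[ix, ix, drop = FALSE], symmetric = TRUE)
           list(idx = ix, U = e$vectors, d = pmax(e$values, 0))
         })
}
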