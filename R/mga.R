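## Measured genotype approach: polygenic mixed model with a per-SNP
## fixed-effect likelihood-ratio test.
##
## The covariance Sigma = 2*Phi*sigmaG2 + I*sigmaE2 is diagonalised once per
## kinship block: with 2*Phi = U diag(d) U', the rotated model has
## independent errors with variance sigma2 * ((1-h) + h*d_i), where
## h = sigmaG2 / (sigmaG2 + sigmaE2). For fixed h the GLS solution and the
## profiled total variance are closed-form; h is maximised by a bounded 1-D
## search.

VAR_FLOOR <- 1e-10

#' Log likelihood of the polygenic mixed model
#'
#' Multivariate normal log density of the trait at mean `X %*% beta` with
#' covariance `2*Phi*sigmaG2 + I*sigmaE2`, evaluated block-by-block over
#' pedigrees.
#'
#' @param y numeric trait vector.
#' @param X design matrix (including the intercept).
#' @param kinship [KinshipMatrix-class] (or plain symmetric matrix) of 2*Phi.
#' @param sigmaG2,sigmaE2 variance components (`sigmaG2 + sigmaE2 > 0`).
#' @param beta fixed-effect coefficients, one per column of X.
#' @return the log likelihood (a scalar).
#' @export
polygenicLoglik <- function(y, X, kinship, sigmaG2, sigmaE2, beta) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), ncol(X) == length(beta),
            sigmaG2 >= 0, sigmaE2 >= 0, sigmaG2 + sigmaE2 > 0)
  r <- y - as.vector(X %*% beta)
  eig <- kinshipEigen(kinship)
  ll <- 0
  for (b in eig) {
    v <- sigmaG2 * b$d + sigmaE2
    if (any(v <= 0)) stop("singular covariance block")
    rb <- crossprod(b$U, r[b$idx])
    ll <- ll - 0.5 * (length(b$idx) * log(2 * pi) + sum(log(v)) +
                        sum(rb^2 / v))
  }
  ll
}

## rotate y/X by the block eigenvectors; d is the concatenated spectrum
.rotate <- function(eig, y, X) {
  n <- length(y)
  ty <- numeric(n); tX <- matrix(0, n, ncol(X)); d <- numeric(n)
  at <- 0L
  for (b in eig) {
    k <- length(b$idx)
    rows <- at + seq_len(k)
    ty[rows] <- crossprod(b$U, y[b$idx])
    tX[rows, ] <- crossprod(b$U, X[b$idx, , drop = FALSE])
    d[rows] <- b$d
    at <- at + k
  }
  list(ty = ty, tX = tX, d = d)
}

## ML fit for fixed heritability h on rotated data; returns -loglik and fit
.profileFit <- function(h, rot, n) {
  v <- (1 - h) + h * rot$d
  w <- 1 / sqrt(v)
  fit <- .lm.fit(rot$tX * w, rot$ty * w)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + n + sum(log(v)))
  list(negll = -ll, sigma2 = sigma2, coef = fit$coefficients, h = h)
}

#' Fit the polygenic model by maximum likelihood
#'
#' Profiles the likelihood over the heritability `h = sigmaG2 / (sigmaG2 +
#' sigmaE2)` on \[0, 1\]: for fixed h the generalized-least-squares
#' coefficients and the total variance are closed-form after rotating by the
#' per-pedigree eigendecomposition of 2*Phi; h is then maximised by
#' [stats::optimize()] (absolute tolerance 1e-6), with both boundaries
#' evaluated explicitly. Boundary solutions (h = 0 or 1) are legitimate.
#'
#' @param y trait vector.
#' @param X design matrix, full column rank (an intercept column is the
#'   caller's responsibility).
#' @param kinship [KinshipMatrix-class] of 2*Phi (or a plain matrix, treated
#'   as one block).
#' @param eig optional precomputed [kinshipEigen()] result, for reuse across
#'   many fits.
#' @return list: `sigmaG2`, `sigmaE2`, `heritability`, `beta` (named by X
#'   columns), `loglik`.
#' @export
fitPolygenic <- function(y, X, kinship = NULL, eig = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  if (is.null(eig)) eig <- kinshipEigen(kinship)
  rot <- .rotate(eig, y, X)
  opt <- optimize(function(h) .profileFit(h, rot, n)$negll,
                  interval = c(0, 1), tol = 1e-6)
  cand <- list(.profileFit(0, rot, n), .profileFit(opt$minimum, rot, n),
               .profileFit(1, rot, n))
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "negll"))]]
  if (best$sigma2 < VAR_FLOOR)
    stop("degenerate fit: residual variance below the 1e-10 floor ",
         "(trait is an exact linear function of the design)")
  beta <- setNames(best$coef, colnames(X))
  list(sigmaG2 = best$h * best$sigma2, sigmaE2 = (1 - best$h) * best$sigma2,
       heritability = best$h, beta = beta, loglik = -best$negll)
}

## build the covariate design from a phenotype data.frame
.mgaDesign <- function(pheno, covariates) {
  miss <- setdiff(covariates, names(pheno))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(pheno[, covariates, drop = FALSE]))
  X
}

#' Measured-genotype test for one SNP
#'
#' Fits the polygenic mixed model with and without the SNP as an additive
#' fixed effect (both by ML, on the same complete-case individual subset)
#' and compares them by a likelihood-ratio test on 1 df: twice the
#' log-likelihood difference is asymptotically chi-squared with 1 degree of
#' freedom. Default covariates are age, age squared and medication use.
#'
#' @param pheno data.frame with `id`, `trait` and covariate columns, one row
#'   per individual.
#' @param snp named genotype vector (0/1/2/NA minor-allele counts).
#' @param kinship [KinshipMatrix-class] over (at least) the phenotyped
#'   individuals.
#' @param covariates covariate column names.
#' @param eig optional precomputed [kinshipEigen()] for the full individual
#'   set; reused when the SNP has no missing genotypes.
#' @param nullFit optional precomputed covariate-only fit for the full set.
#' @return list (`MgaResult`): `snpID`, `n`, `betaHat`, `loglikFull`,
#'   `loglikNull`, `lrt`, `p`, `status` (`"ok"` / `"monomorphic"`).
#' @export
mgaTest <- function(pheno, snp, kinship,
                    covariates = c("age", "age2", "bpmed"), eig = NULL,
                    nullFit = NULL) {
  ids <- pheno$id
  x <- snp[ids]
  keep <- !is.na(x) & !is.na(pheno$trait)
  sub <- !all(keep)
  xk <- x[keep]
  if (length(unique(xk)) < 2L)
    return(list(snpID = NA_character_, n = sum(keep), betaHat = NA_real_,
                loglikFull = NA_real_, loglikNull = NA_real_,
                lrt = NA_real_, p = NA_real_, status = "monomorphic"))
  ph <- pheno[keep, , drop = FALSE]
  X0 <- .mgaDesign(ph, covariates)
  if (sub || is.null(eig)) {
    K <- as.matrix(kinship)[ph$id, ph$id, drop = FALSE]
    ped <- if (is(kinship, "KinshipMatrix"))
      kinship@ped[match(ph$id, rownames(kinship))] else rep("1", nrow(K))
    eig <- kinshipEigen(new("KinshipMatrix", K, ped = ped))
    nullFit <- NULL
  }
  if (is.null(nullFit)) nullFit <- fitPolygenic(ph$trait, X0, eig = eig)
  full <- fitPolygenic(ph$trait, cbind(X0, snp = xk), eig = eig)
  lrt <- 2 * (full$loglik - nullFit$loglik)
  if (lrt < -1e-6)
    stop("negative likelihood ratio beyond optimizer tolerance: ", lrt)
  lrt <- max(lrt, 0)
  list(snpID = NA_character_, n = sum(keep), betaHat = unname(full$beta["snp"]),
       loglikFull = full$loglik, loglikNull = nullFit$loglik, lrt = lrt,
       p = pchisq(lrt, df = 1, lower.tail = FALSE), status = "ok")
}

#' Measured-genotype scan over all SNPs
#'
#' Applies [mgaTest()] to every SNP, computing the per-pedigree kinship
#' eigendecompositions and the covariate-only null fit once and reusing them
#' for every SNP without missing genotypes. Monomorphic SNPs are skipped
#' with a status flag; per-SNP failures never abort the scan.
#'
#' @param pheno phenotype/covariate data.frame (see [mgaTest()]).
#' @param geno a [GenotypeMatrix-class].
#' @param kinship the cohort [KinshipMatrix-class].
#' @param covariates covariate column names.
#' @return data.frame, one row per SNP in input order: `snpID`, `n`,
#'   `betaHat`, `lrt`, `p`, `status`.
#' @export
mgaScan <- function(pheno, geno, kinship,
                    covariates = c("age", "age2", "bpmed")) {
  ids <- pheno$id[!is.na(pheno$trait)]
  ph <- pheno[match(ids, pheno$id), , drop = FALSE]
  K <- as.matrix(kinship)[ids, ids, drop = FALSE]
  ped <- if (is(kinship, "KinshipMatrix"))
    kinship@ped[match(ids, rownames(kinship))] else rep("1", length(ids))
  kin <- new("KinshipMatrix", K, ped = ped)
  eig <- kinshipEigen(kin)
  X0 <- .mgaDesign(ph, covariates)
  nullFit <- fitPolygenic(ph$trait, X0, eig = eig)
  cd <- geno@codes
  out <- vector("list", ncol(cd))
  for (j in seq_len(ncol(cd))) {
    res <- tryCatch(
      mgaTest(ph, cd[, j], kin, covariates = covariates, eig = eig,
              nullFit = nullFit),
      error = function(e)
        list(snpID = NA, n = NA_integer_, betaHat = NA_real_,
             loglikFull = NA_real_, loglikNull = NA_real_, lrt = NA_real_,
             p = NA_real_, status = paste0("error: ", conditionMessage(e))))
    res$snpID <- colnames(cd)[j]
    out[[j]] <- data.frame(snpID = res$snpID, n = res$n,
                           betaHat = res$betaHat, lrt = res$lrt, p = res$p,
                           status = res$status, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write association scan results as TSV
#'
#' @param results data.frame from [mgaScan()], [fbatScan()] or
#'   [rankAndTestTopK()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeResultsTSV <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
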