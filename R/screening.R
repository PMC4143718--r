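## Van Steen-type screening: expected genotypes given parental sufficient
## statistics, a between-family screening regression, per-SNP conditional
## power via an exponential tilt of the Mendelian transmission distribution,
## and top-K testing.
##
## Everything the screen uses — parental genotypes and residual traits —
## is a function of the sufficient statistics only, never of the realized
## transmissions, so the screen is statistically independent of the FBAT
## statistic it ranks. That independence is what justifies correcting only
## for the K tested SNPs.

SIGMA2_FLOOR <- 1e-12

#' Expected offspring genotype given the sufficient statistics
#'
#' `E[x | parents]` per offspring, from [conditionalMoments()]. Uses no
#' transmission information: changing an offspring's observed genotype
#' leaves the score unchanged.
#'
#' @param units data.frame from [decomposeTransmissions()].
#' @return named numeric vector, one score per offspring.
#' @export
expectedMarkerScore <- function(units) {
  setNames(conditionalMoments(units$fatherGeno, units$motherGeno)$mean,
           units$offspring)
}

#' Between-family screening regression
#'
#' Least-squares regression of the residual trait on an intercept plus the
#' expected genotype `E[x|S]`. Its slope estimates the SNP effect from
#' between-family information only.
#'
#' @param t named residual-trait vector.
#' @param scores named expected-genotype vector ([expectedMarkerScore()]).
#' @return list: `betaScreen`, `sigma2Screen` (residual variance), `n`,
#'   `degenerate` (TRUE when the scores are constant, with `betaScreen = 0`).
#' @export
screeningRegression <- function(t, scores) {
  ids <- intersect(names(scores), names(t))
  s <- scores[ids]; tv <- t[ids]
  if (length(ids) < 3L || length(unique(s)) < 2L)
    return(list(betaScreen = 0, sigma2Screen = if (length(ids) > 1L)
      var(tv) * (length(ids) - 1L) / length(ids) else NA_real_,
      n = length(ids), degenerate = TRUE))
  fit <- .lm.fit(cbind(1, s), tv)
  list(betaScreen = unname(fit$coefficients[2L]),
       sigma2Screen = sum(fit$residuals^2) / length(ids), n = length(ids),
       degenerate = FALSE)
}

#' Conditional power of the FBAT test at one SNP
#'
#' For each transmission unit the Mendelian offspring distribution
#' `p(x | parents)` is exponentially tilted toward the trait signal,
#' `p~(x) proportional to p(x) * exp(betaScreen * t * (x - E[x]) / sigma2)`,
#' giving a predicted mean score `E~[U] = sum t * (E~[x] - E[x])`. With the
#' null transmission variance `V0 = sum t^2 * Var(x | parents)`, the power
#' of the two-sided level-`alpha` test is
#' `Phi(-z + E~[U]/sqrt(V0)) + Phi(-z - E~[U]/sqrt(V0))`, `z = z_{1-alpha/2}`.
#' `betaScreen = 0` gives power exactly `alpha`; no informative units
#' (`V0 = 0`) gives power 0 by convention. The computation depends on the
#' observed transmissions in no way.
#'
#' @param units data.frame from [decomposeTransmissions()].
#' @param t named residual-trait vector.
#' @param betaScreen,sigma2Screen from [screeningRegression()];
#'   `sigma2Screen` is floored at 1e-12.
#' @param alpha significance level of the prospective test.
#' @return power in \[0, 1\].
#' @export
conditionalPower <- function(units, t, betaScreen, sigma2Screen,
                             alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  tv <- t[units$offspring]
  keep <- !is.na(tv)
  units <- units[keep, , drop = FALSE]; tv <- tv[keep]
  if (!nrow(units)) return(0)
  cm <- conditionalMoments(units$fatherGeno, units$motherGeno)
  V0 <- sum(tv^2 * cm$variance)
  if (V0 <= 0) return(0)
  s2 <- max(sigma2Screen, SIGMA2_FLOOR)
  x <- matrix(0:2, nrow(units), 3L, byrow = TRUE)
  logw <- log(cm$probs) +
    (betaScreen * tv / s2) * (x - cm$mean)   # column-wise deviation tilt
  logw <- logw - apply(logw, 1L, max)
  w <- exp(logw) * (cm$probs > 0)
  w <- w / rowSums(w)
  tiltMean <- as.vector(w %*% (0:2))
  EU <- sum(tv * (tiltMean - cm$mean))
  z <- qnorm(1 - alpha / 2)
  shift <- EU / sqrt(V0)
  pnorm(-z + shift) + pnorm(-z - shift)
}

#' Screen every SNP: regression, conditional power
#'
#' Vectorized across the genotype matrix; numerically identical to calling
#' [screeningRegression()] and [conditionalPower()] SNP by SNP on the units
#' from [decomposeTransmissions()].
#'
#' @param cohort a [Cohort-class].
#' @param geno a [GenotypeMatrix-class].
#' @param t named residual-trait vector.
#' @param alpha prospective test level.
#' @return data.frame per SNP: `snpID`, `betaScreen`, `sigma2Screen`,
#'   `conditionalPower`, `degenerate`.
#' @export
screenScan <- function(cohort, geno, t, alpha = 0.05) {
  tu <- transmissionIndex(cohort)
  tv <- t[tu$offspring]
  keep <- !is.na(tv)
  tu <- tu[keep, , drop = FALSE]; tv <- tv[keep]
  cd <- geno@codes
  GF <- cd[tu$father, , drop = FALSE] / 2
  GM <- cd[tu$mother, , drop = FALSE] / 2
  X <- cd[tu$offspring, , drop = FALSE]
  complete <- !is.na(GF) & !is.na(GM) & !is.na(X)
  allComplete <- all(complete)
  if (!allComplete)           # rare user-data path: fall back per SNP
    return(do.call(rbind, lapply(snpIDs(geno), function(sid) {
      units <- decomposeTransmissions(cohort, geno, sid)
      reg <- screeningRegression(t, expectedMarkerScore(units))
      data.frame(snpID = sid, betaScreen = reg$betaScreen,
                 sigma2Screen = reg$sigma2Screen,
                 conditionalPower = conditionalPower(
                   units, t, reg$betaScreen, reg$sigma2Screen, alpha),
                 degenerate = reg$degenerate, stringsAsFactors = FALSE)
    })))
  E <- GF + GM
  V1 <- GF * (1 - GF) + GM * (1 - GM)
  n <- nrow(E)
  ## per-SNP OLS of t on (1, E): slope and ML residual variance
  Ebar <- colMeans(E)
  Ec <- sweep(E, 2L, Ebar)
  see <- colSums(Ec^2)
  ste <- as.vector(crossprod(Ec, tv))
  degenerate <- see == 0 | n < 3L
  beta <- ifelse(degenerate, 0, ste / see)
  tc <- tv - mean(tv)
  stt <- sum(tc^2)
  sigma2 <- ifelse(degenerate, stt / n, (stt - beta * ste) / n)
  ## exponential tilt of the transmission distribution, in log space
  P0 <- (1 - GF) * (1 - GM); P1 <- GF * (1 - GM) + (1 - GF) * GM; P2 <- GF * GM
  C <- tv * matrix(beta / pmax(sigma2, SIGMA2_FLOOR), n, ncol(E),
                   byrow = TRUE)
  l0 <- log(P0) - C * E
  l1 <- log(P1) + C * (1 - E)
  l2 <- log(P2) + C * (2 - E)
  mx <- pmax(l0, l1, l2)
  w0 <- exp(l0 - mx); w1 <- exp(l1 - mx); w2 <- exp(l2 - mx)
  tot <- w0 + w1 + w2
  tiltMean <- (w1 + 2 * w2) / tot
  EU <- colSums(tv * (tiltMean - E))
  V0 <- colSums(tv^2 * V1)
  z <- qnorm(1 - alpha / 2)
  shift <- ifelse(V0 > 0, EU / sqrt(V0), 0)
  power <- ifelse(V0 > 0, pnorm(-z + shift) + pnorm(-z - shift), 0)
  data.frame(snpID = colnames(cd), betaScreen = beta, sigma2Screen = sigma2,
             conditionalPower = power, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank by conditional power and test the top K
#'
#' SNPs are ranked by conditional power, descending, ties broken by input
#' order; only the top `K` rank-eligible SNPs (those with an FBAT p-value,
#' i.e. not filtered or uninformative) are tested, each at the
#' Bonferroni-corrected threshold `alpha / K`. A SNP outside the top K is
#' never tested, however small its FBAT p-value. With fewer than K eligible
#' SNPs, all of them are tested, still at `alpha / K`.
#'
#' @param screen data.frame from [screenScan()].
#' @param fbat data.frame from [fbatScan()] over the same SNPs.
#' @param K number of SNPs to test (default 10).
#' @param alpha family-wise level (default 0.05).
#' @return data.frame per SNP: `snpID`, `conditionalPower`, `rank`,
#'   `tested`, `p`, `significant`, `threshold`.
#' @export
rankAndTestTopK <- function(screen, fbat, K = 10, alpha = 0.05) {
  stopifnot(K >= 1, setequal(screen$snpID, fbat$snpID))
  fb <- fbat[match(screen$snpID, fbat$snpID), , drop = FALSE]
  ord <- order(-screen$conditionalPower, seq_len(nrow(screen)))
  rank <- integer(nrow(screen)); rank[ord] <- seq_len(nrow(screen))
  eligible <- !is.na(fb$p)
  topk <- ord[eligible[ord]][seq_len(min(K, sum(eligible)))]
  tested <- logical(nrow(screen)); tested[topk] <- TRUE
  thr <- alpha / K
  data.frame(snpID = screen$snpID, conditionalPower = screen$conditionalPower,
             rank = rank, tested = tested, p = ifelse(tested, fb$p, NA_real_),
             significant = tested & !is.na(fb$p) & fb$p < thr,
             threshold = thr, stringsAsFactors = FALSE)
}
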