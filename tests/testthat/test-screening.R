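test_that("expected marker scores use parents only", {
  units <- data.frame(ped = "f", offspring = c("o1", "o2", "o3"),
                      fatherGeno = c(1, 2, 2), motherGeno = c(1, 2, 1),
                      offspringGeno = c(0, 2, 1))
  s <- expectedMarkerScore(units)
  expect_equal(unname(s), c(1, 2, 1.5))
  units$offspringGeno <- c(2, 2, 2)   # changing transmissions: no effect
  expect_identical(expectedMarkerScore(units), s)
})

test_that("screening regression: exact fit, degenerate scores, null slope", {
  sc <- c(a = 1, b = 1.5, c = 2, d = 0.5)
  t <- 2 * sc
  reg <- screeningRegression(t, sc)
  expect_equal(reg$betaScreen, 2, tolerance = 1e-12)
  expect_equal(reg$sigma2Screen, 0, tolerance = 1e-12)
  expect_false(reg$degenerate)

  regD <- screeningRegression(t, c(a = 1, b = 1, c = 1, d = 1))
  expect_true(regD$degenerate)
  expect_identical(regD$betaScreen, 0)

  # under the null the slope is centered at zero over replicates
  set.seed(5)
  betas <- replicate(200, {
    s <- setNames(sample(0:2, 30, replace = TRUE) / 2 +
                    sample(0:2, 30, replace = TRUE) / 2, paste0("i", 1:30))
    screeningRegression(setNames(rnorm(30), names(s)), s)$betaScreen
  })
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(length(betas)))
})

test_that("conditional power: null tilt, V0=0, saturation limit, monotonicity", {
  units <- data.frame(ped = paste0("f", 1:3), offspring = c("o1", "o2", "o3"),
                      fatherGeno = c(1, 1, 2), motherGeno = c(1, 0, 1),
                      offspringGeno = c(1, 0, 2))
  t <- c(o1 = 0.8, o2 = -1.1, o3 = 0.4)
  expect_equal(conditionalPower(units, t, 0, 1, alpha = 0.05), 0.05,
               tolerance = 1e-12)
  noInfo <- data.frame(ped = "f", offspring = "o1", fatherGeno = 2,
                       motherGeno = 0, offspringGeno = 1)
  expect_identical(conditionalPower(noInfo, c(o1 = 1), 3, 1), 0)

  # single double-het unit, t=1: saturating tilt pushes E[x] to 2, E[U] to 1
  one <- data.frame(ped = "f", offspring = "o1", fatherGeno = 1,
                    motherGeno = 1, offspringGeno = 1)
  z <- qnorm(0.975)
  lim <- pnorm(-z + sqrt(2)) + pnorm(-z - sqrt(2))
  expect_equal(conditionalPower(one, c(o1 = 1), 1e8, 1), lim,
               tolerance = 1e-9)
  # Monte-Carlo cross-check of the tilted mean at moderate beta
  set.seed(7)
  beta <- 1.2; s2 <- 0.5
  w <- c(0.25, 0.5, 0.25) * exp(beta * 1 * ((0:2) - 1) / s2)
  mcMean <- sum((0:2) * w / sum(w))
  shift <- 1 * (mcMean - 1) / sqrt(0.5)
  expect_equal(conditionalPower(one, c(o1 = 1), beta, s2),
               pnorm(-z + shift) + pnorm(-z - shift), tolerance = 1e-12)

  pw <- vapply(c(0, 0.3, 0.8, 2, 5), function(b)
    conditionalPower(units, t, b, 1), numeric(1))
  expect_true(all(diff(pw) >= -1e-12))
  pwNeg <- vapply(c(0, -0.3, -0.8, -2, -5), function(b)
    conditionalPower(units, t, b, 1), numeric(1))
  expect_true(all(diff(pwNeg) >= -1e-12))
})

test_that("screenScan matches the per-SNP reference path exactly", {
  st <- smallStudy(nPed = 3, nSNP = 8)
  t <- residualizeTrait(st$pheno, st$cohort)
  fast <- screenScan(st$cohort, st$geno, t)
  for (j in seq_len(8)) {
    u <- decomposeTransmissions(st$cohort, st$geno, snpIDs(st$geno)[j])
    reg <- screeningRegression(t, expectedMarkerScore(u))
    expect_equal(fast$betaScreen[j], reg$betaScreen, tolerance = 1e-12)
    expect_equal(fast$conditionalPower[j],
                 conditionalPower(u, t, reg$betaScreen, reg$sigma2Screen),
                 tolerance = 1e-12)
  }
})

test_that("top-K testing: count, threshold, rank stability, no peeking past K", {
  n <- 25
  screen <- data.frame(snpID = paste0("s", 1:n),
                       conditionalPower = c(rep(0.9, 2), seq(0.8, 0, length.out = n - 2)))
  fbat <- data.frame(snpID = screen$snpID, p = rep(0.5, n),
                     status = "ok")
  fbat$p[screen$snpID == "s11"] <- 1e-10   # ranked 11th: never tested
  res <- rankAndTestTopK(screen, fbat, K = 10, alpha = 0.05)
  expect_identical(sum(res$tested), 10L)
  expect_identical(unique(res$threshold), 0.005)
  expect_identical(sort(res$rank), 1:n)
  expect_false(res$tested[res$snpID == "s11"])
  expect_false(any(res$significant))
  # ties keep input order deterministically
  expect_identical(res$rank[1:2], 1:2)
  expect_identical(rankAndTestTopK(screen, fbat, K = 10), res)

  # fewer eligible SNPs than K: all tested, threshold unchanged
  fbat2 <- fbat; fbat2$p[6:n] <- NA; fbat2$status[6:n] <- "filtered"
  res2 <- rankAndTestTopK(screen, fbat2, K = 10, alpha = 0.05)
  expect_identical(sum(res2$tested), 5L)
  expect_identical(unique(res2$threshold), 0.005)
})

test_that("screen and ranking are invariant under re-dropped transmissions", {
  st <- smallStudy(nPed = 4, nSNP = 12)
  t <- residualizeTrait(st$pheno, st$cohort)
  base <- lapply(snpIDs(st$geno), function(sid)
    decomposeTransmissions(st$cohort, st$geno, sid))
  names(base) <- snpIDs(st$geno)
  screenOf <- function(unitsList) {
    do.call(rbind, lapply(names(unitsList), function(sid) {
      reg <- screeningRegression(t, expectedMarkerScore(unitsList[[sid]]))
      data.frame(snpID = sid,
                 conditionalPower = conditionalPower(
                   unitsList[[sid]], t, reg$betaScreen, reg$sigma2Screen))
    }))
  }
  fbatOf <- function(unitsList)
    do.call(rbind, lapply(names(unitsList), function(sid) {
      r <- fbatStatistic(unitsList[[sid]], t)
      data.frame(snpID = sid, p = r$p, status = r$status)
    }))
  s0 <- screenOf(base)
  f0 <- fbatOf(base)
  r0 <- rankAndTestTopK(s0, f0, K = 5)
  changed <- 0L
  for (rep in 1:10) {
    redropped <- lapply(base, redropUnits, seed = 700 + rep)
    expect_identical(screenOf(redropped), s0)            # bit-identical screen
    r1 <- rankAndTestTopK(screenOf(redropped), fbatOf(redropped), K = 5)
    expect_identical(r1$rank, r0$rank)
    changed <- changed + !identical(fbatOf(redropped)$p, f0$p)
  }
  expect_identical(changed, 10L)   # the test statistic does move
})
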