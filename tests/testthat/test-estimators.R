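test_that("ratio estimates follow the first-order Wald construction", {
  p <- makePairs(betaExp = c(0.1, 1, -0.2), seExp = rep(0.01, 3),
                 betaOut = c(0.05, 0, 0.1), seOut = c(0.02, 0.3, 0.04))
  r <- ratioEstimates(p)
  expect_equal(r$THETA, c(0.5, 0, -0.5))
  expect_equal(r$S, c(0.2, 0.3, 0.2))
  expect_equal(r$W, r$S^-2)

  # zero exposure effect: instrument excluded with a message
  p0 <- makePairs(betaExp = c(0, 0.1), seExp = c(0.01, 0.01),
                  betaOut = c(0.05, 0.02), seOut = c(0.02, 0.02))
  expect_message(r0 <- ratioEstimates(p0), "zero exposure")
  expect_identical(nrow(r0), 1L)
})

test_that("IVW equals meta-analysis, weighted mean and zero-intercept WLS", {
  # single instrument: the ratio estimate itself
  r1 <- randomRatios(1, seed = 1)
  e1 <- mrIVW(r1)
  expect_equal(betaHat(e1), r1$THETA)
  expect_equal(stdError(e1), r1$S)

  # equal weights: the plain mean, se = s/sqrt(2)
  r2 <- data.frame(THETA = c(0.4, 0.6), S = c(0.1, 0.1), W = 100)
  e2 <- mrIVW(r2)
  expect_equal(betaHat(e2), 0.5)
  expect_equal(stdError(e2), 0.1 / sqrt(2), tolerance = 1e-12)

  # three independent routes agree to 1e-10 on random inputs
  for (seed in 1:25) {
    p <- randomPairs(sample(3:20, 1), seed = seed)
    r <- ratioEstimates(p)
    ivw <- betaHat(mrIVW(r))
    meta <- sum(r$THETA / r$S^2) / sum(1 / r$S^2)
    wls <- unname(coef(lm(BETA_OUT ~ 0 + BETA_EXP, data = p,
                          weights = p$SE_OUT^-2)))
    expect_equal(ivw, meta, tolerance = 1e-10)
    expect_equal(ivw, wls, tolerance = 1e-10)
  }
})

test_that("Cochran's Q measures weighted squared deviation from the center", {
  r <- data.frame(THETA = c(0.3, 0.3, 0.3), S = 0.1, W = 100)
  expect_equal(cochranQ(r, 0.3)$Q, 0)
  one <- data.frame(THETA = 0.5, S = 0.1, W = 100)
  q1 <- cochranQ(one, 0.5)
  expect_equal(q1$Q, 0)
  expect_identical(q1$df, 0L)
  r2 <- data.frame(THETA = c(0, 1), S = 0.1, W = 100)
  q2 <- cochranQ(r2, 0.5)
  expect_equal(q2$Q, 50)
  expect_equal(q2$perInstrumentQ, c(25, 25))
})

test_that("weighted median interpolates the weighted 50th percentile", {
  eq <- function(th) data.frame(THETA = th, S = 0.1, W = 1)
  expect_equal(betaHat(mrWeightedMedian(eq(c(0.1, 0.5, 0.9)), nBoot = 0)), 0.5)
  expect_error(mrWeightedMedian(eq(c(0.1, 0.5)), nBoot = 0), "at least 3")
  expect_equal(betaHat(mrWeightedMedian(eq(c(0, 0, 1, 1)), nBoot = 0)), 0.5)

  # equal weights reduce to the sample median (odd J) / midpoint (even J)
  set.seed(3)
  for (J in c(5, 7, 6, 8)) {
    th <- rnorm(J)
    got <- betaHat(mrWeightedMedian(eq(th), nBoot = 0))
    expect_equal(got, median(th), tolerance = 1e-12)
  }

  # random weighted inputs against the fine-grid CDF oracle
  for (seed in 1:40) {
    r <- randomRatios(sample(4:12, 1), seed = 100 + seed)
    got <- betaHat(mrWeightedMedian(r, nBoot = 0))
    expect_equal(got, wmGridOracle(r$THETA, r$W), tolerance = 1e-6)
  }

  # bootstrap SE is seeded and reproducible
  r <- randomRatios(6, seed = 5)
  a <- mrWeightedMedian(r, nBoot = 50, seed = 9)
  b <- mrWeightedMedian(r, nBoot = 50, seed = 9)
  expect_identical(stdError(a), stdError(b))
  expect_error(mrWeightedMedian(r, nBoot = 10), "seed")
})

test_that("penalization leaves concordant sets untouched and tames outliers", {
  # identical ratios: no penalty, identical to the weighted median
  same <- data.frame(THETA = rep(0.2, 5), S = 0.1, W = 100)
  expect_equal(betaHat(mrPenalizedWeightedMedian(same, nBoot = 0)),
               betaHat(mrWeightedMedian(same, nBoot = 0)))

  # infinite penalty scale reduces to the plain weighted median
  r <- randomRatios(9, seed = 31)
  expect_equal(betaHat(mrPenalizedWeightedMedian(r, nBoot = 0,
                                                 penaltyScale = Inf)),
               betaHat(mrWeightedMedian(r, nBoot = 0)))

  # one gross high-weight outlier: the penalized estimate is closer to truth
  set.seed(13)
  th <- c(rnorm(19, 0.2, 0.02), 5)
  s <- c(runif(19, 0.05, 0.2), 0.05)
  out <- data.frame(THETA = th, S = s, W = s^-2)
  pen <- betaHat(mrPenalizedWeightedMedian(out, nBoot = 0))
  unp <- betaHat(mrWeightedMedian(out, nBoot = 0))
  expect_lt(abs(pen - 0.2), abs(unp - 0.2) + 1e-12)
})

test_that("MR-Egger recovers an exact affine relation and flags degeneracy", {
  bx <- c(0.05, 0.08, 0.11, 0.14, 0.2)
  p <- makePairs(betaExp = bx, seExp = 0.01, betaOut = 0.01 + 0.3 * bx,
                 seOut = 0.02)
  e <- mrEgger(p)
  expect_equal(e@intercept, 0.01, tolerance = 1e-10)
  expect_equal(betaHat(e@slope), 0.3, tolerance = 1e-10)
  expect_lt(e@sigma, 1e-8)

  expect_error(mrEgger(makePairs(betaExp = c(0.1, 0.1, 0.1), seExp = 0.01,
                                 betaOut = c(0.1, 0.2, 0.3), seOut = 0.02)),
               "singular")
  expect_error(mrEgger(randomPairs(2, seed = 1)), "at least 3")

  # orientation: flipping the sign of both betas of any instrument is a no-op
  p2 <- randomPairs(8, seed = 17)
  flip <- c(2, 5)
  p3 <- p2
  p3$BETA_EXP[flip] <- -p3$BETA_EXP[flip]
  p3$BETA_OUT[flip] <- -p3$BETA_OUT[flip]
  e2 <- mrEgger(p2); e3 <- mrEgger(p3)
  expect_equal(e2@intercept, e3@intercept, tolerance = 1e-12)
  expect_equal(betaHat(e2@slope), betaHat(e3@slope), tolerance = 1e-12)
})

test_that("estimators are order-invariant, flip-invariant and scale-equivariant", {
  for (seed in 1:10) {
    p <- randomPairs(sample(4:15, 1), seed = 300 + seed)
    r <- ratioEstimates(p)

    perm <- sample(nrow(p))
    rp <- ratioEstimates(p[perm, ])
    expect_equal(betaHat(mrIVW(r)), betaHat(mrIVW(rp)), tolerance = 1e-12)
    expect_equal(betaHat(mrWeightedMedian(r, nBoot = 0)),
                 betaHat(mrWeightedMedian(rp, nBoot = 0)), tolerance = 1e-12)

    pf <- p
    k <- sample(nrow(p), 2)
    pf$BETA_EXP[k] <- -pf$BETA_EXP[k]
    pf$BETA_OUT[k] <- -pf$BETA_OUT[k]
    rf <- ratioEstimates(pf)
    expect_equal(betaHat(mrIVW(rf)), betaHat(mrIVW(r)), tolerance = 1e-12)
    expect_equal(betaHat(mrPenalizedWeightedMedian(rf, nBoot = 0)),
                 betaHat(mrPenalizedWeightedMedian(r, nBoot = 0)),
                 tolerance = 1e-12)

    # scaling every outcome effect and SE by c scales estimate and SE by c
    cc <- 2.7
    ps <- p
    ps$BETA_OUT <- cc * ps$BETA_OUT
    ps$SE_OUT <- cc * ps$SE_OUT
    rs <- ratioEstimates(ps)
    expect_equal(betaHat(mrIVW(rs)), cc * betaHat(mrIVW(r)), tolerance = 1e-10)
    expect_equal(stdError(mrIVW(rs)), cc * stdError(mrIVW(r)),
                 tolerance = 1e-10)
    es <- mrEgger(ps); e0 <- mrEgger(p)
    expect_equal(betaHat(es@slope), cc * betaHat(e0@slope), tolerance = 1e-9)
  }
})

test_that("the combined estimate table respects the few-instrument contract", {
  one <- InstrumentSet(randomPairs(1, seed = 2))
  res <- mrEstimateAll(one, nBoot = 0)
  expect_identical(nrow(res$estimates), 4L)
  expect_false(is.na(res$estimates$b[res$estimates$method == "ivw"]))
  expect_true(all(is.na(res$estimates$b[res$estimates$method != "ivw"])))
  expect_match(res$estimates$note[2], "not estimable")
  expect_null(res$egger)

  full <- InstrumentSet(randomPairs(10, seed = 3))
  res2 <- mrEstimateAll(full, nBoot = 25, seed = 4)
  expect_identical(res2$estimates$method,
                   c("ivw", "weighted_median", "penalized_weighted_median",
                     "egger_slope"))
  expect_true(all(is.finite(res2$estimates$b)))
  expect_equal(res2$estimates$or, exp(res2$estimates$b))
  expect_s4_class(res2$egger, "EggerResult")
})
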