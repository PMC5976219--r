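grsCohort <- function(G, counted = NULL, pheno = NULL) {
  if (is.null(counted))
    counted <- setNames(rep("A", ncol(G)), colnames(G))
  tinyCohort(G, counted, pheno)
}

test_that("risk scores follow the log-OR dosage sum", {
  G <- matrix(c(2, 1), 1, dimnames = list("i1", c("rs1", "rs2")))
  w <- data.frame(SNP = c("rs1", "rs2"), EA = "A", OR = c(1.2, 1.5),
                  EAF = NA_real_)
  s <- computeScores(grsCohort(G), w)
  expect_equal(s$SCORE, 2 * log(1.2) + 1 * log(1.5), tolerance = 1e-12)
  expect_equal(round(s$SCORE, 6), 0.770108)

  # null weights give zero scores
  w1 <- transform(w, OR = 1)
  expect_true(all(computeScores(grsCohort(G), w1)$SCORE == 0))

  # dosage columns counting the other allele are reflected as 2 - G
  sSwap <- computeScores(grsCohort(G, counted = c(rs1 = "G", rs2 = "A")), w)
  expect_equal(sSwap$SCORE, (2 - 2) * log(1.2) + 1 * log(1.5))
})

test_that("missing dosages are mean-imputed and counted", {
  G <- matrix(c(2, NA, 1, 0, 1, 2), 3,
              dimnames = list(c("i1", "i2", "i3"), c("rs1", "rs2")))
  w <- data.frame(SNP = c("rs1", "rs2"), EA = "A", OR = c(1.2, 1.5),
                  EAF = NA_real_)
  s <- computeScores(grsCohort(G), w)
  # cohort mean dosage of rs1 over observed values is 1.5
  expect_equal(s$SCORE[2], 1.5 * log(1.2) + 1 * log(1.5), tolerance = 1e-12)
  expect_identical(s$N_IMPUTED, c(0L, 1L, 0L))

  # with an EAF in the weight file, imputation uses 2 * EAF instead
  w2 <- transform(w, EAF = c(0.25, NA))
  s2 <- computeScores(grsCohort(G), w2)
  expect_equal(s2$SCORE[2], 0.5 * log(1.2) + 1 * log(1.5), tolerance = 1e-12)

  # weight variants absent from the cohort are excluded with a warning
  w3 <- rbind(w, data.frame(SNP = "rs9", EA = "A", OR = 2, EAF = NA))
  expect_warning(s3 <- computeScores(grsCohort(G), w3), "rs9")
  expect_equal(s3$SCORE[1], s$SCORE[1])
})

test_that("scores are additive over disjoint variant sets", {
  set.seed(21)
  G <- matrix(rbinom(40, 2, 0.4), 10,
              dimnames = list(paste0("i", 1:10), paste0("rs", 1:4)))
  w <- data.frame(SNP = paste0("rs", 1:4), EA = "A",
                  OR = runif(4, 0.8, 1.6), EAF = NA_real_)
  all4 <- computeScores(grsCohort(G), w)$SCORE
  a <- computeScores(grsCohort(G[, 1:2]), w[1:2, ])$SCORE
  b <- computeScores(grsCohort(G[, 3:4]), w[3:4, ])$SCORE
  expect_equal(all4, a + b, tolerance = 1e-12)
})

test_that("score regression recovers planted effects and flags bad designs", {
  set.seed(8)
  n <- 200
  G <- matrix(rbinom(n * 5, 2, 0.3), n,
              dimnames = list(paste0("i", 1:n), paste0("rs", 1:5)))
  w <- data.frame(SNP = paste0("rs", 1:5), EA = "A",
                  OR = exp(runif(5, 0.05, 0.3)), EAF = NA_real_)
  age <- rnorm(n, 60, 8); sex <- rbinom(n, 1, 0.5)
  co <- grsCohort(G, pheno = data.frame(age = age, sex = sex,
                                        row.names = rownames(G)))
  s <- computeScores(co, w)
  # noiseless: exact recovery of the planted coefficient
  co@pheno$y <- 0.5 * s$SCORE + 0.02 * age - 0.3 * sex
  # (a perfect fit makes summary.lm warn; that is the point of the check)
  r <- suppressWarnings(scoreRegression(s, co, "y", c("age", "sex")))
  expect_equal(r$beta, 0.5, tolerance = 1e-8)

  # adding a constant to a covariate leaves the score coefficient unchanged
  co2 <- co
  co2@pheno$age <- co2@pheno$age + 1000
  r2 <- suppressWarnings(scoreRegression(s, co2, "y", c("age", "sex")))
  expect_equal(r2$beta, r$beta, tolerance = 1e-8)

  # collinear covariates are an error naming the offender
  co@pheno$age2 <- co@pheno$age
  expect_error(scoreRegression(s, co, "y", c("age", "age2")), "age2")

  # confounding: a batch covariate driving both score and phenotype biases
  # the unadjusted fit but not the adjusted one
  set.seed(9)
  batch <- as.numeric(s$SCORE > median(s$SCORE))  # batch correlated with score
  co@pheno$age2 <- NULL
  co@pheno$batch <- batch
  co@pheno$y2 <- 0.5 * s$SCORE + 2 * batch + rnorm(n, sd = 0.1)
  rAdj <- scoreRegression(s, co, "y2", "batch")
  rUn <- scoreRegression(s, co, "y2", character())
  expect_lt(abs(rAdj$beta - 0.5), abs(rUn$beta - 0.5))
})

test_that("quartile assignment and contrasts behave", {
  set.seed(4)
  n <- 8
  G <- matrix(rbinom(n * 3, 2, 0.5), n,
              dimnames = list(paste0("i", 1:n), paste0("rs", 1:3)))
  w <- data.frame(SNP = paste0("rs", 1:3), EA = "A", OR = c(1.3, 1.2, 1.4),
                  EAF = NA_real_)
  co <- grsCohort(G, pheno = data.frame(row.names = rownames(G)))
  s <- computeScores(co, w)
  if (length(unique(s$SCORE)) == n)
    expect_equal(as.vector(table(s$QUARTILE)), rep(2L, 4))

  # monotone phenotype in score gives monotone contrasts
  set.seed(5)
  n <- 400
  G <- matrix(rbinom(n * 6, 2, 0.4), n,
              dimnames = list(paste0("i", 1:n), paste0("rs", 1:6)))
  w <- data.frame(SNP = paste0("rs", 1:6), EA = "A",
                  OR = exp(runif(6, 0.1, 0.4)), EAF = NA_real_)
  co <- grsCohort(G, pheno = data.frame(row.names = rownames(G)))
  s <- computeScores(co, w)
  co@pheno$y <- 2 * s$SCORE + rnorm(n, sd = 0.05)
  qc <- quartileContrasts(s, co, "y")
  expect_identical(qc$contrast, c("Q2_vs_Q1", "Q3_vs_Q1", "Q4_vs_Q1"))
  expect_true(all(diff(qc$beta) > 0))
  expect_true(all(qc$or > 1))

  # all-tied scores collapse the quartile boundaries
  co@pheno$y <- rnorm(n)
  sTied <- s
  sTied$SCORE <- 1
  sTied$QUARTILE <- 1L
  expect_error(quartileContrasts(sTied, co, "y"), "degenerate|empty")
})

test_that("first-PC phenotype matches eigendecomposition and conventions", {
  set.seed(6)
  n <- 60
  # rank-1: all 48 tracts identical
  common <- rnorm(n)
  M <- matrix(common, n, 48)
  pc <- firstPCPhenotype(M)
  z <- (common - mean(common)) / sd(common)
  expect_equal(cor(pc, z), 1.0, tolerance = 1e-12)
  expect_equal(attr(pc, "varianceExplained"), 1.0, tolerance = 1e-12)

  # random matrices against an independent svd-based oracle
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 8), 50, 8) %*% diag(runif(8, 0.5, 3))
    pc <- firstPCPhenotype(X)
    Z <- scale(X)
    sv <- svd(Z)
    ref <- sv$u[, 1]
    expect_equal(abs(cor(pc, ref)), 1.0, tolerance = 1e-8)
    expect_equal(sd(pc), 1.0, tolerance = 1e-12)
    # column scaling does not change the correlation-based result
    pcScaled <- firstPCPhenotype(X %*% diag(runif(8, 0.1, 10)))
    expect_equal(pcScaled, pc, tolerance = 1e-8, ignore_attr = TRUE)
    # row permutation permutes the scores
    perm <- sample(nrow(X))
    expect_equal(firstPCPhenotype(X[perm, ]), pc[perm], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # sign convention: negating all columns leaves the loading sum positive
  X <- matrix(rnorm(40 * 5), 40, 5) + 2 * rnorm(40)
  l1 <- attr(firstPCPhenotype(X), "loadings")
  l2 <- attr(firstPCPhenotype(-X), "loadings")
  expect_gt(sum(l1), 0)
  expect_gt(sum(l2), 0)

  # zero-variance tracts are dropped with a warning
  Xz <- cbind(X, 0)
  expect_warning(pz <- firstPCPhenotype(Xz), "zero-variance")
  expect_equal(pz, firstPCPhenotype(X), tolerance = 1e-12, ignore_attr = TRUE)
})
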