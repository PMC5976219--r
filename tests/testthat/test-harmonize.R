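oneRec <- function(ea, oa, beta = 0.05, eaf = 0.2, snp = "rs1") {
  makeStatsTable(snp, beta = beta, se = 0.01, ea = ea, oa = oa, eaf = eaf)
}

test_that("allele alignment follows the orientation truth table", {
  for (cs in orientationCases()) {
    expo <- oneRec(cs$expEA, cs$expOA, beta = 0.1, eaf = 0.2)
    outc <- oneRec(cs$outEA, cs$outOA, beta = 0.05,
                   eaf = if (cs$flip == 1) 0.2 else 0.8)
    al <- alignAlleles(expo, outc)
    expect_identical(al$status, "direct")
    expect_equal(al$BETA, cs$flip * 0.05,
                 info = paste(cs$expEA, cs$expOA, cs$label))
    expect_equal(al$EAF, 0.2, info = cs$label)
  }
})

test_that("palindromic variants are oriented by frequency or dropped", {
  # discordant frequencies imply the other strand: effect negated
  al <- alignAlleles(oneRec("A", "T", eaf = 0.10),
                     oneRec("A", "T", beta = 0.05, eaf = 0.91))
  expect_identical(al$status, "direct")
  expect_equal(al$BETA, -0.05)
  expect_equal(al$EAF, 0.09)

  # concordant frequencies keep the effect
  al <- alignAlleles(oneRec("G", "C", eaf = 0.10),
                     oneRec("G", "C", beta = 0.05, eaf = 0.12))
  expect_equal(al$BETA, 0.05)

  # frequency inside the ambiguity window: dropped
  al <- alignAlleles(oneRec("A", "T", eaf = 0.50),
                     oneRec("A", "T", eaf = 0.10))
  expect_identical(al$status, "dropped")
  expect_identical(al$reason, "palindromic_ambiguous")
  # missing frequency: dropped too
  al <- alignAlleles(oneRec("A", "T", eaf = NA),
                     oneRec("A", "T", eaf = 0.10))
  expect_identical(al$reason, "palindromic_ambiguous")
})

test_that("irreconcilable alleles are dropped and alignment is involutive", {
  al <- alignAlleles(oneRec("A", "G"), oneRec("A", "C"))
  expect_identical(al$status, "dropped")
  expect_identical(al$reason, "allele_mismatch")

  # aligning an already-aligned record is a no-op
  expo <- oneRec("A", "G", beta = 0.1, eaf = 0.2)
  outc <- oneRec("G", "A", beta = 0.05, eaf = 0.85)
  al1 <- alignAlleles(expo, outc)
  aligned <- outc
  aligned$EA <- "A"; aligned$OA <- "G"
  aligned$BETA <- al1$BETA; aligned$EAF <- al1$EAF
  al2 <- alignAlleles(expo, aligned)
  expect_equal(al2$BETA, al1$BETA)
  expect_equal(al2$EAF, al1$EAF)
})

test_that("proxy substitution obeys the strict threshold and tie-breaks", {
  outcome <- makeStats(c("p1", "p2", "p3"), beta = rep(0.05, 3),
                       se = rep(0.01, 3))
  ld <- LDTable(data.frame(A = c("rs1", "rs1", "rs2", "rs3", "rs3"),
                           B = c("p1", "p2", "p1", "p2", "p3"),
                           R2 = c(0.9, 0.75, 0.7, 0.8, 0.8),
                           DIST = c(1e4, 2e3, 1e3, 5e4, 5e3)))
  d <- substituteProxies(c("rs1", "rs2", "rs3", "rs4"), outcome, ld)
  d <- d[match(c("rs1", "rs2", "rs3", "rs4"), d$SNP), ]
  expect_identical(d$PROXY[1], "p1")      # max r2 wins
  expect_identical(d$STATUS[2], "dropped") # 0.7 is not > 0.7: strict
  expect_identical(d$REASON[2], "no_proxy")
  expect_identical(d$PROXY[3], "p3")      # tie on r2: nearer proxy
  expect_identical(d$STATUS[4], "dropped") # no LD entry at all

  # enumerated tie-break oracle: r2 desc, then distance, then lexicographic
  set.seed(42)
  for (rep in 1:20) {
    cand <- data.frame(A = "rsX", B = paste0("q", 1:4),
                       R2 = sample(c(0.8, 0.8, 0.9, 0.72)),
                       DIST = sample(c(1e3, 5e4, 2e3, 9e3)))
    want <- cand[order(-cand$R2, cand$DIST, cand$B), ][1, "B"]
    oc <- makeStats(paste0("q", 1:4), beta = rep(0.02, 4), se = rep(0.01, 4))
    got <- substituteProxies("rsX", oc, LDTable(cand))
    expect_identical(got$PROXY, want)
  }
})

test_that("greedy clumping matches the exhaustive property oracle", {
  # all pairs below threshold: everything retained
  stats <- makeStats(paste0("rs", 1:4), beta = runif(4), se = rep(0.01, 4),
                     bp = c(1e6, 1.02e6, 1.04e6, 1.06e6))
  ldNone <- LDTable(data.frame(A = "rs1", B = "rs2", R2 = 0.05, DIST = 2e4))
  expect_setequal(suppressWarnings(ldClump(stats, ldNone)),
                  paste0("rs", 1:4))

  # a correlated pair within the window collapses to the better p-value
  two <- makeStats(c("rsA", "rsB"), beta = c(0.2, 0.1), se = c(0.01, 0.01),
                   bp = c(1e6, 1.05e6), p = c(1e-12, 1e-8))
  ld2 <- LDTable(data.frame(A = "rsA", B = "rsB", R2 = 0.5, DIST = 5e4))
  expect_identical(ldClump(two, ld2), "rsA")

  # random instances against the subset oracle
  set.seed(7)
  for (i in 1:60) {
    J <- sample(4:10, 1)
    tab <- makeStatsTable(paste0("rs", 1:J), beta = rnorm(J),
                          se = runif(J, 0.01, 0.05),
                          chr = sample(c("1", "2"), J, TRUE),
                          bp = sample.int(4e5, J))
    pr <- t(combn(J, 2))
    keepPair <- runif(nrow(pr)) < 0.6
    ld <- LDTable(data.frame(
      A = tab$SNP[pr[keepPair, 1]], B = tab$SNP[pr[keepPair, 2]],
      R2 = runif(sum(keepPair)),
      DIST = abs(tab$BP[pr[keepPair, 1]] - tab$BP[pr[keepPair, 2]])))
    ret <- suppressWarnings(ldClump(tab, ld, r2Max = 0.1, windowBp = 1e5))
    expect_true(isTRUE(clumpOracleCheck(ret, tab, ld, 0.1, 1e5)))
  }
})

test_that("clumped sets stay valid when variants are removed from input", {
  set.seed(11)
  for (i in 1:15) {
    J <- 8
    tab <- makeStatsTable(paste0("rs", 1:J), beta = rnorm(J),
                          se = runif(J, 0.01, 0.05), bp = sample.int(3e5, J))
    pr <- t(combn(J, 2))
    ld <- LDTable(data.frame(A = tab$SNP[pr[, 1]], B = tab$SNP[pr[, 2]],
                             R2 = runif(nrow(pr)),
                             DIST = abs(tab$BP[pr[, 1]] - tab$BP[pr[, 2]])))
    drop <- sample(J, 1)
    sub <- tab[-drop, ]
    ret <- suppressWarnings(ldClump(sub, ld, 0.1, 1e5))
    expect_true(isTRUE(clumpOracleCheck(ret, sub, ld, 0.1, 1e5)))
  }
})

test_that("harmonization accounts for every candidate instrument", {
  expo <- makeStats(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, 0.15),
                    se = rep(0.01, 3))
  # rs1 direct; rs2 missing with proxy p2; rs3 missing without proxy
  outTab <- rbind(oneRec("A", "G", beta = 0.05, snp = "rs1"),
                  oneRec("A", "G", beta = 0.03, snp = "p2"))
  outc <- SummaryStats(outTab, trait = "out")
  ld <- LDTable(data.frame(A = "rs2", B = "p2", R2 = 0.9, DIST = 1e3))
  iset <- harmonizeInstruments(expo, outc, ld = ld)
  tab <- asTable(iset)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$STATUS, c("direct", "proxy", "dropped"))
  expect_identical(tab$PROXY[2], "p2")
  expect_equal(tab$BETA_OUT[2], 0.03)
  expect_identical(tab$REASON[3], "no_proxy")
  expect_identical(nInstruments(iset), 2L)
  st <- table(tab$STATUS)
  expect_identical(sum(st), 3L)  # selected = retained + dropped

  f <- withr::local_tempfile(fileext = ".tsv")
  writeHarmonizationReport(iset, f)
  rep <- read.delim(f)
  expect_identical(nrow(rep), 3L)
  expect_identical(rep$STATUS, c("direct", "proxy", "dropped"))
})
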