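# Builders for small in-code fixtures.

makeStatsTable <- function(snp, beta, se, chr = "1",
                           bp = seq(1e6, by = 2e5, length.out = length(snp)),
                           ea = "A", oa = "G", eaf = 0.3, p = NULL,
                           n = 10000) {
  if (is.null(p)) p <- pmin(pmax(2 * pnorm(-abs(beta / se)),
                                 .Machine$double.xmin), 1)
  data.frame(SNP = snp, CHR = chr, BP = as.integer(bp), EA = ea, OA = oa,
             EAF = eaf, BETA = beta, SE = se, P = p, N = n,
             stringsAsFactors = FALSE)
}

makeStats <- function(..., trait = "trait", binary = FALSE) {
  SummaryStats(makeStatsTable(...), trait = trait, binary = binary)
}

makePairs <- function(betaExp, seExp, betaOut, seOut,
                      snp = paste0("rs", seq_along(betaExp))) {
  data.frame(SNP = snp, BETA_EXP = betaExp, SE_EXP = seExp,
             BETA_OUT = betaOut, SE_OUT = seOut, STATUS = "direct",
             PROXY = NA_character_, PROXY_R2 = NA_real_,
             REASON = NA_character_, stringsAsFactors = FALSE)
}

randomRatios <- function(J, seed) {
  set.seed(seed)
  s <- runif(J, 0.05, 0.5)
  data.frame(SNP = paste0("rs", seq_len(J)), THETA = rnorm(J, 0.2, 0.6),
             S = s, W = s^-2, stringsAsFactors = FALSE)
}

randomPairs <- function(J, seed) {
  set.seed(seed)
  makePairs(betaExp = runif(J, 0.03, 0.2) * sample(c(-1, 1), J, TRUE),
            seExp = runif(J, 0.005, 0.02),
            betaOut = rnorm(J, 0.02, 0.05),
            seOut = runif(J, 0.005, 0.05))
}

tinyCohort <- function(G, counted, pheno = NULL) {
  if (is.null(pheno))
    pheno <- data.frame(row.names = rownames(G))
  Cohort(G, counted, pheno)
}
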