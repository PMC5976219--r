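#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a synthetic-study scenario
#'
#' Builds an [MRScenario-class] describing a synthetic two-sample MR
#' experiment with known ground truth. Defaults emulate a polygenic
#' instrument set for a common metabolic exposure: 84 instruments jointly
#' explaining 7.5% of the exposure variance (the middle of the 5-10% band
#' typical of such scores), minor-allele frequencies in \[0.1, 0.5\], a
#' shared standard-normal confounder loading on both traits, and no
#' pleiotropy.
#'
#' @param nVariants number of instruments.
#' @param nExposure,nOutcome,nCohort sample sizes for the exposure GWAS,
#'   outcome GWAS and individual-level cohort (non-overlapping samples).
#' @param mafRange allele-frequency interval.
#' @param h2Exposure exposure variance explained by the instruments.
#' @param betaCausal true causal effect of the exposure on the outcome.
#' @param pleiotropyMode `none`, `balanced` or `directional`.
#' @param pleiotropyMean,pleiotropySd mean and SD of direct effects on the
#'   invalid subset (mean forced to 0 in balanced mode).
#' @param invalidFraction fraction of instruments with direct effects.
#' @param binaryExposure,caseFraction liability-threshold binary exposure.
#' @param binaryOutcome liability-threshold binary outcome.
#' @param confounderLoading loading of the shared confounder.
#' @param ldBlocks list of `list(size=, r2=)`; `r2` is the target
#'   anchor-member dosage r-squared within the block.
#' @param seed integer seed.
#' @return An [MRScenario-class].
#' @export
mrScenario <- function(nVariants = 84L, nExposure = 50000L, nOutcome = 50000L,
                       nCohort = 4000L, mafRange = c(0.1, 0.5),
                       h2Exposure = 0.075, betaCausal = 0,
                       pleiotropyMode = "none", pleiotropyMean = 0,
                       pleiotropySd = 0, invalidFraction = 0,
                       binaryExposure = FALSE, caseFraction = 0.1,
                       binaryOutcome = FALSE, confounderLoading = 0.3,
                       ldBlocks = list(), seed = 1L) {
  if (pleiotropyMode == "balanced") pleiotropyMean <- 0
  new("MRScenario", nVariants = as.integer(nVariants),
      nExposure = as.integer(nExposure), nOutcome = as.integer(nOutcome),
      nCohort = as.integer(nCohort), mafRange = mafRange,
      h2Exposure = h2Exposure, betaCausal = betaCausal,
      pleiotropyMode = pleiotropyMode, pleiotropyMean = pleiotropyMean,
      pleiotropySd = pleiotropySd, invalidFraction = invalidFraction,
      binaryExposure = isTRUE(binaryExposure), caseFraction = caseFraction,
      binaryOutcome = isTRUE(binaryOutcome),
      confounderLoading = confounderLoading, ldBlocks = ldBlocks,
      seed = as.integer(seed))
}

#' Named scenario presets
#'
#' The standard study designs used to validate the pipeline:
#' \describe{
#'   \item{null}{no causal effect, no pleiotropy (type-I error studies;
#'     reduced samples of 10000 per GWAS).}
#'   \item{causal_valid}{causal effect 0.14 (log odds about log 1.15),
#'     84 valid instruments, h2 = 0.075, 50000 per GWAS (parameter-recovery
#'     and CI-coverage studies).}
#'   \item{balanced_pleiotropy}{no causal effect; direct effects of mean 0
#'     (SD 0.02) on half the instruments; InSIDE holds.}
#'   \item{directional_pleiotropy_inside}{no causal effect; direct effects
#'     of mean 0.05 (SD 0.01) on 90% of the instruments, drawn
#'     independently of instrument strength (InSIDE); designed a priori so
#'     the pleiotropy-intercept test has high power while the slope stays
#'     centered.}
#'   \item{median_robust}{causal effect 0.14 with strong directional
#'     pleiotropy (mean 0.1, SD 0.02) on 30% of instruments - below the
#'     half-weight validity bound of the weighted median.}
#'   \item{clump_test}{30 variants in dense LD blocks (8 blocks of 3,
#'     anchor r2 0.64) for exercising clumping and proxy search.}
#' }
#'
#' @return Named list of [MRScenario-class] objects.
#' @export
scenarioPresets <- function() {
  list(
    null = mrScenario(betaCausal = 0, nExposure = 10000L, nOutcome = 10000L,
                      seed = 101L),
    causal_valid = mrScenario(betaCausal = 0.14, seed = 102L),
    balanced_pleiotropy = mrScenario(betaCausal = 0,
                                     nExposure = 10000L, nOutcome = 10000L,
                                     pleiotropyMode = "balanced",
                                     pleiotropySd = 0.02,
                                     invalidFraction = 0.5, seed = 103L),
    directional_pleiotropy_inside = mrScenario(betaCausal = 0,
                                               pleiotropyMode = "directional",
                                               pleiotropyMean = 0.05,
                                               pleiotropySd = 0.01,
                                               invalidFraction = 0.9,
                                               seed = 104L),
    median_robust = mrScenario(betaCausal = 0.14,
                               nExposure = 10000L, nOutcome = 10000L,
                               pleiotropyMode = "directional",
                               pleiotropyMean = 0.1, pleiotropySd = 0.02,
                               invalidFraction = 0.3, seed = 105L),
    clump_test = mrScenario(nVariants = 30L, nExposure = 10000L,
                            nOutcome = 10000L,
                            ldBlocks = rep(list(list(size = 3, r2 = 0.64)), 8),
                            seed = 106L)
  )
}

#' Serialize / restore a scenario
#'
#' Scenarios round-trip losslessly through a plain named list (and hence
#' through YAML study configs).
#'
#' @param scenario an [MRScenario-class].
#' @return `scenarioToList`: a named list; `scenarioFromList`: the scenario.
#' @export
scenarioToList <- function(scenario) {
  s <- scenario
  list(nVariants = s@nVariants, nExposure = s@nExposure,
       nOutcome = s@nOutcome, nCohort = s@nCohort,
       mafRange = s@mafRange, h2Exposure = s@h2Exposure,
       betaCausal = s@betaCausal, pleiotropyMode = s@pleiotropyMode,
       pleiotropyMean = s@pleiotropyMean, pleiotropySd = s@pleiotropySd,
       invalidFraction = s@invalidFraction, binaryExposure = s@binaryExposure,
       caseFraction = s@caseFraction, binaryOutcome = s@binaryOutcome,
       confounderLoading = s@confounderLoading, ldBlocks = s@ldBlocks,
       seed = s@seed)
}

#' @rdname scenarioToList
#' @param x a named list as produced by `scenarioToList`.
#' @export
scenarioFromList <- function(x) do.call(mrScenario, x)

# Variant map: IDs, positions (blocks contiguous at 5 kb spacing, singleton
# variants 1 Mb apart), allele pair per variant (non-palindromic), and
# allele frequencies (shared within an LD block so block targets stay
# feasible).
.drawVariantMap <- function(scenario) {
  J <- scenario@nVariants
  blocks <- scenario@ldBlocks
  blockId <- integer(J)
  if (length(blocks)) {
    sizes <- vapply(blocks, function(b) as.integer(b$size), integer(1))
    blockId[seq_len(sum(sizes))] <- rep(seq_along(blocks), sizes)
  }
  f <- stats::runif(J, scenario@mafRange[1], scenario@mafRange[2])
  pos <- integer(J); chr <- integer(J)
  cur <- 0L
  for (j in seq_len(J)) {
    if (j > 1 && blockId[j] != 0L && blockId[j] == blockId[j - 1L]) {
      pos[j] <- pos[j - 1L] + 5000L       # within block: same anchor freq
      f[j] <- f[which(blockId == blockId[j])[1L]]
    } else {
      cur <- cur + 1000000L
      pos[j] <- cur
    }
    chr[j] <- 1L + (j - 1L) %% 22L
  }
  # blocks must not straddle chromosomes
  if (length(blocks)) chr[blockId != 0L] <- blockId[blockId != 0L] %% 22L + 1L
  pairPool <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  alle <- pairPool[sample.int(length(pairPool), J, replace = TRUE)]
  data.frame(SNP = paste0("rs", seq_len(J)), CHR = as.character(chr),
             BP = pos, EA = vapply(alle, `[`, character(1), 1L),
             OA = vapply(alle, `[`, character(1), 2L), MAF = f,
             BLOCK = blockId, stringsAsFactors = FALSE)
}

#' Simulate genotype dosages
#'
#' Draws diploid dosages for independent variants as Binomial(2, f_j).
#' Within an LD block each haplotype allele of a member variant copies the
#' block anchor's allele with probability q = sqrt(r2) and is drawn fresh
#' from Bernoulli(f) otherwise, which yields an anchor-member dosage
#' r-squared of r2 (and r2^2 between two non-anchor members). Copying can
#' only reach the target when frequencies match within the block; unequal
#' frequencies are an error suggesting matched frequencies.
#'
#' @param freqs named numeric vector of effect-allele frequencies.
#' @param n number of individuals.
#' @param blocks list of `list(size=, r2=)` applied to consecutive leading
#'   variants.
#' @return Integer dosage matrix (n by variants) with variant colnames.
#' @export
simulateGenotypes <- function(freqs, n, blocks = list()) {
  J <- length(freqs)
  G <- matrix(0L, n, J, dimnames = list(NULL, names(freqs)))
  inBlock <- integer(0)
  if (length(blocks)) {
    sizes <- vapply(blocks, function(b) as.integer(b$size), integer(1))
    stopifnot(sum(sizes) <= J)
    start <- cumsum(c(1L, sizes))[seq_along(sizes)]
    for (k in seq_along(blocks)) {
      idx <- seq(start[k], length.out = sizes[k])
      inBlock <- c(inBlock, idx)
      fB <- freqs[idx]
      if (max(fB) - min(fB) > 1e-12)
        stop("LD-block r2 target infeasible for unequal allele frequencies; ",
             "use matched frequencies within a block", call. = FALSE)
      q <- sqrt(blocks[[k]]$r2)
      h1 <- stats::runif(n) < fB[1L]
      h2 <- stats::runif(n) < fB[1L]
      G[, idx[1L]] <- h1 + h2
      for (j in idx[-1L]) {
        c1 <- stats::runif(n) < q
        c2 <- stats::runif(n) < q
        m1 <- ifelse(c1, h1, stats::runif(n) < fB[1L])
        m2 <- ifelse(c2, h2, stats::runif(n) < fB[1L])
        G[, j] <- m1 + m2
      }
    }
  }
  solo <- setdiff(seq_len(J), inBlock)
  if (length(solo))
    G[, solo] <- stats::rbinom(n * length(solo), 2L,
                               rep(freqs[solo], each = n))
  G
}

# Expected variance of the instrument score sum(gamma_j G_j) given the LD
# structure (dosage covariance within a block: 2 q f(1-f) anchor-member,
# 2 q^2 f(1-f) member-member).
.geneticVariance <- function(gamma, map, blocks) {
  v <- 2 * map$MAF * (1 - map$MAF)
  tot <- sum(gamma^2 * v)
  if (length(blocks)) {
    for (k in seq_along(blocks)) {
      idx <- which(map$BLOCK == k)
      q <- sqrt(blocks[[k]]$r2)
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a >= b) next
        rho <- if (a == 1L) q else q^2
        tot <- tot + 2 * gamma[idx[a]] * gamma[idx[b]] * rho * v[idx[a]]
      }
    }
  }
  tot
}

# Instrument effects: per-variant explained-variance shares Uniform(0.1,1.9)
# normalized to sum to h2 exactly, effect alleles coded exposure-increasing
# (gamma >= 0), then rescaled against the LD-aware genetic variance.
.drawEffects <- function(scenario, map) {
  J <- scenario@nVariants
  share <- stats::runif(J, 0.1, 1.9)
  share <- share / sum(share) * scenario@h2Exposure
  v <- 2 * map$MAF * (1 - map$MAF)
  gamma <- sqrt(share / v)
  gv <- .geneticVariance(gamma, map, scenario@ldBlocks)
  if (gv > 0) gamma <- gamma * sqrt(scenario@h2Exposure / gv)
  nInv <- round(scenario@invalidFraction * J)
  invalid <- sort(sample.int(J, nInv))
  alpha <- numeric(J)
  if (nInv > 0 && scenario@pleiotropyMode != "none")
    alpha[invalid] <- stats::rnorm(nInv, scenario@pleiotropyMean,
                                   scenario@pleiotropySd)
  list(gamma = gamma, alpha = alpha, invalid = invalid)
}

#' Simulate exposure and outcome traits for one sample
#'
#' Builds the causal system the two-sample design assumes: exposure
#' X = sum(gamma_j G_j) + c_U U + eps_X with the genetic part contributing
#' `h2Exposure` of the unit exposure variance and U a shared standard
#' normal confounder; outcome
#' Y = beta X + sum over invalid j of alpha_j G_j + c_U U + eps_Y.
#' Direct effects alpha are drawn independently of instrument strength, so
#' the InSIDE condition holds by construction in both pleiotropy modes.
#' Binary traits are produced by thresholding the liability at its
#' empirical (1 - case fraction) quantile.
#'
#' @param G dosage matrix from [simulateGenotypes()].
#' @param scenario an [MRScenario-class].
#' @param effects list with `gamma`, `alpha` (from the study's parameter
#'   draw; see [simulateStudy()]).
#' @return list(x, y, xLiability, yLiability).
#' @export
simulateTraits <- function(G, scenario, effects) {
  n <- nrow(G)
  cU <- scenario@confounderLoading
  varEps <- 1 - scenario@h2Exposure - cU^2
  if (varEps <= 0)
    stop("h2Exposure and confounderLoading leave no residual exposure variance",
         call. = FALSE)
  U <- stats::rnorm(n)
  gscore <- as.vector(G %*% effects$gamma)
  x <- gscore + cU * U + stats::rnorm(n, sd = sqrt(varEps))
  direct <- if (any(effects$alpha != 0))
    as.vector(G %*% effects$alpha) else 0
  y <- scenario@betaCausal * x + direct + cU * U + stats::rnorm(n)
  out <- list(xLiability = x, yLiability = y, x = x, y = y)
  if (scenario@binaryExposure)
    out$x <- as.integer(x > stats::quantile(x, 1 - scenario@caseFraction))
  if (scenario@binaryOutcome)
    out$y <- as.integer(y > stats::quantile(y, 1 - scenario@caseFraction))
  out
}

#' Per-variant summary statistics from individual-level data
#'
#' For a continuous trait, per-variant simple linear regression computed
#' in closed form (slope, residual standard error on n - 2 degrees of
#' freedom, Student-t p-value). For a binary 0/1 trait, the logistic score
#' test approximation used for case-control GWAS: beta = U / V and
#' se = V^-1/2 with U = sum(g (y - ybar)) and V = ybar (1 - ybar)
#' sum((g - gbar)^2), normal p-value. Monomorphic variants yield a flagged
#' record with `NA` effect and standard error.
#'
#' @param G dosage matrix.
#' @param trait numeric vector (0/1 when `binary`).
#' @param binary logical.
#' @param map variant map data.frame (columns SNP, CHR, BP, EA, OA).
#' @param trait_name label for the resulting [SummaryStats-class].
#' @return A [SummaryStats-class].
#' @export
deriveSummaryStats <- function(G, trait, binary = FALSE, map,
                               trait_name = "trait") {
  n <- nrow(G)
  gm <- colMeans(G)
  Sxx <- colSums(G^2) - n * gm^2
  mono <- Sxx <= 0
  if (binary) {
    ybar <- mean(trait)
    U <- as.vector(crossprod(G, trait - ybar))
    V <- ybar * (1 - ybar) * Sxx
    beta <- U / V
    se <- 1 / sqrt(V)
    p <- 2 * stats::pnorm(-abs(beta / se))
  } else {
    yc <- trait - mean(trait)
    Sxy <- as.vector(crossprod(G, yc))
    beta <- Sxy / Sxx
    rss <- sum(yc^2) - beta * Sxy
    se <- sqrt(pmax(rss, 0) / ((n - 2) * Sxx))
    p <- 2 * stats::pt(-abs(beta / se), df = n - 2)
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  beta[mono] <- NA_real_; se[mono] <- NA_real_; p[mono] <- NA_real_
  if (any(mono)) message(sum(mono), " monomorphic variant(s) flagged with NA effect")
  tab <- data.frame(SNP = map$SNP, CHR = map$CHR, BP = map$BP, EA = map$EA,
                    OA = map$OA, EAF = gm / 2, BETA = beta, SE = se, P = p,
                    N = n, stringsAsFactors = FALSE)
  SummaryStats(tab, trait = trait_name, binary = binary)
}

# Generative LD table: every within-block pair with its exact target
# r-squared (anchor-member r2, member-member r2^2) and base-pair distance.
.generativeLD <- function(map, blocks) {
  rows <- list()
  if (length(blocks)) {
    for (k in seq_along(blocks)) {
      idx <- which(map$BLOCK == k)
      q2 <- blocks[[k]]$r2
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a >= b) next
        r2 <- if (a == 1L) q2 else q2^2
        rows[[length(rows) + 1L]] <-
          data.frame(A = map$SNP[idx[a]], B = map$SNP[idx[b]], R2 = r2,
                     DIST = abs(map$BP[idx[a]] - map$BP[idx[b]]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  LDTable(if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Simulate a complete two-sample study
#'
#' Generates, under one seed, everything a study run consumes: exposure
#' and outcome GWAS summary statistics from two non-overlapping samples
#' (disjoint individual IDs by construction), the generative LD table, a
#' risk-score weight file taken from the exposure-sample estimates
#' (OR = exp(beta)), an annotation table tagging the pleiotropic
#' instruments (vocabulary: BMI, lipids, kidney_function), an
#' individual-level cohort with imaging-like phenotypes (wmh, fa, md) and
#' standard covariates, and the ground truth. To exercise harmonization,
#' a random 30% of outcome records are presented with swapped alleles
#' (effect negated, frequency reflected) - harmonization must undo this
#' exactly.
#'
#' @param scenario an [MRScenario-class].
#' @param includeCohort logical; set `FALSE` to skip the individual-level
#'   cohort arm (replicate loops that only consume summary statistics).
#' @return list with elements `map`, `exposureStats`, `outcomeStats`,
#'   `exposureIds`, `outcomeIds`, `ld`, `weights`, `annotations`, `cohort`
#'   (`NULL` when skipped), `truth` (list: betaCausal, gamma, alpha,
#'   invalid, realizedH2).
#' @export
simulateStudy <- function(scenario, includeCohort = TRUE) {
  set.seed(scenario@seed)
  map <- .drawVariantMap(scenario)
  eff <- .drawEffects(scenario, map)
  freqs <- stats::setNames(map$MAF, map$SNP)

  Gx <- simulateGenotypes(freqs, scenario@nExposure, scenario@ldBlocks)
  tx <- simulateTraits(Gx, scenario, eff)
  exposureStats <- deriveSummaryStats(Gx, tx$x, scenario@binaryExposure, map,
                                      trait_name = "exposure")
  realizedH2 <- stats::var(as.vector(Gx %*% eff$gamma)) /
    stats::var(tx$xLiability)

  Gy <- simulateGenotypes(freqs, scenario@nOutcome, scenario@ldBlocks)
  ty <- simulateTraits(Gy, scenario, eff)
  outcomeStats <- deriveSummaryStats(Gy, ty$y, scenario@binaryOutcome, map,
                                     trait_name = "outcome")
  # present some outcome records allele-swapped to exercise harmonization
  ot <- asTable(outcomeStats)
  swap <- stats::runif(nrow(ot)) < 0.3
  if (any(swap)) {
    tmp <- ot$EA[swap]; ot$EA[swap] <- ot$OA[swap]; ot$OA[swap] <- tmp
    ot$BETA[swap] <- -ot$BETA[swap]
    ot$EAF[swap] <- 1 - ot$EAF[swap]
    outcomeStats <- SummaryStats(ot, trait = "outcome",
                                 binary = scenario@binaryOutcome)
  }

  et <- asTable(exposureStats)
  weights <- data.frame(SNP = et$SNP, EA = et$EA, OR = exp(et$BETA),
                        EAF = et$EAF, stringsAsFactors = FALSE)

  vocab <- c("BMI", "lipids", "kidney_function")
  ann <- if (length(eff$invalid))
    data.frame(SNP = map$SNP[eff$invalid], TRAIT = "BMI",
               stringsAsFactors = FALSE)
  else data.frame(SNP = character(), TRAIT = character(),
                  stringsAsFactors = FALSE)
  annotations <- AnnotationTable(ann, vocabulary = vocab)

  b <- scenario@betaCausal
  cohort <- NULL
  if (includeCohort) {
  Gc <- simulateGenotypes(freqs, scenario@nCohort, scenario@ldBlocks)
  tc <- simulateTraits(Gc, scenario, eff)
  nC <- scenario@nCohort
  pheno <- data.frame(
    age = round(stats::rnorm(nC, 60, 8), 1),
    sex = stats::rbinom(nC, 1, 0.5),
    batch = stats::rbinom(nC, 1, 0.5),
    bmi = round(stats::rnorm(nC, 27, 4), 2),
    sbp = round(stats::rnorm(nC, 140, 18), 1),
    pc1 = stats::rnorm(nC), pc2 = stats::rnorm(nC))
  covEff <- with(pheno, 0.01 * age + 0.1 * sex + 0.05 * batch + 0.02 * bmi +
                   0.005 * sbp + 0.1 * pc1 - 0.1 * pc2)
  pheno$wmh <- b * tc$xLiability + covEff + stats::rnorm(nC)
  pheno$fa <- -b * tc$xLiability + covEff + stats::rnorm(nC)
  pheno$md <- b * tc$xLiability + covEff + stats::rnorm(nC)
  ids <- paste0("COH_", seq_len(nC))
  storage.mode(Gc) <- "double"
  rownames(Gc) <- ids
  rownames(pheno) <- ids
  cohort <- Cohort(Gc, stats::setNames(map$EA, map$SNP), pheno)
  }

  list(map = map, exposureStats = exposureStats, outcomeStats = outcomeStats,
       exposureIds = paste0("EXP_", seq_len(scenario@nExposure)),
       outcomeIds = paste0("OUT_", seq_len(scenario@nOutcome)),
       ld = .generativeLD(map, scenario@ldBlocks), weights = weights,
       annotations = annotations, cohort = cohort,
       truth = list(betaCausal = b, gamma = eff$gamma, alpha = eff$alpha,
                    invalid = map$SNP[eff$invalid], realizedH2 = realizedH2))
}
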