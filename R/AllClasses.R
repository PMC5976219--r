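#' @import methods
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' Canonical summary-statistic column names
#'
#' The canonical header used throughout the package for per-variant GWAS
#' association statistics: `SNP` (rsID), `CHR`, `BP` (1-based position),
#' `EA`/`OA` (effect/other allele), `EAF` (effect-allele frequency, may be
#' `NA`), `BETA` (log-OR for binary traits, trait units otherwise), `SE`,
#' `P`, `N`. Files in other dialects are mapped onto this header at read
#' time via a column map.
#'
#' @return Character vector of the ten canonical column names.
#' @export
canonicalColumns <- function() {
  c("SNP", "CHR", "BP", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
}

.validSummaryTable <- function(tab) {
  msg <- character(0)
  miss <- setdiff(canonicalColumns(), names(tab))
  if (length(miss) > 0)
    return(paste("missing canonical columns:", paste(miss, collapse = ", ")))
  if (nrow(tab) > 0) {
    if (!all(tab$EA %in% VALID_BASES) || !all(tab$OA %in% VALID_BASES))
      msg <- c(msg, "alleles must be single bases in {A,C,G,T}")
    else if (any(tab$EA == tab$OA))
      msg <- c(msg, "effect and other allele must differ")
    # monomorphic variants may carry NA BETA/SE as a flagged record
    if (any(!is.na(tab$SE) & (!is.finite(tab$SE) | tab$SE <= 0)))
      msg <- c(msg, "SE must be finite and > 0 where present")
    if (any(is.na(tab$SE) != is.na(tab$BETA)))
      msg <- c(msg, "BETA and SE must be missing together")
    eaf <- tab$EAF[!is.na(tab$EAF)]
    if (any(eaf < 0 | eaf > 1)) msg <- c(msg, "EAF must lie in [0,1]")
    p <- tab$P[!is.na(tab$P)]
    if (any(p <= 0 | p > 1)) msg <- c(msg, "P must lie in (0,1]")
    if (anyDuplicated(tab$SNP)) msg <- c(msg, "duplicated variant IDs")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

#' SummaryStats: per-variant association statistics for one trait
#'
#' Container for GWAS summary statistics of a single trait measured in a
#' single sample. One row per variant with the canonical columns of
#' [canonicalColumns()].
#'
#' @slot table data.frame with the canonical columns.
#' @slot trait character label for the trait.
#' @slot binary logical; `TRUE` when `BETA` is a log odds ratio.
#'
#' @export
setClass("SummaryStats",
  representation(table = "data.frame", trait = "character", binary = "logical"),
  prototype(
    table = data.frame(
      SNP = character(), CHR = character(), BP = integer(),
      EA = character(), OA = character(), EAF = numeric(),
      BETA = numeric(), SE = numeric(), P = numeric(), N = numeric(),
      stringsAsFactors = FALSE
    ),
    trait = "trait", binary = FALSE
  ),
  validity = function(object) {
    if (length(object@trait) != 1L) return("trait must be a single string")
    if (length(object@binary) != 1L) return("binary must be a single flag")
    .validSummaryTable(object@table)
  }
)

#' Construct a SummaryStats object
#'
#' @param table data.frame with the canonical columns ([canonicalColumns()]).
#' @param trait trait label.
#' @param binary logical, `TRUE` when effects are log odds ratios.
#' @return A [SummaryStats-class] object.
#' @export
SummaryStats <- function(table, trait = "trait", binary = FALSE) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  table$EA <- toupper(as.character(table$EA))
  table$OA <- toupper(as.character(table$OA))
  table$CHR <- as.character(table$CHR)
  table$BP <- as.integer(table$BP)
  rownames(table) <- NULL
  new("SummaryStats", table = table[, canonicalColumns()],
      trait = trait, binary = isTRUE(binary))
}

#' LDTable: pairwise linkage-disequilibrium lookup
#'
#' Stores r-squared values for variant pairs with the physical distance
#' between them. Lookup is symmetric in the pair; a pair absent from the
#' table is reported as "no data" (`NA`), which is distinct from r2 = 0,
#' and the r2 of a variant with itself is 1.
#'
#' @slot pairs data.frame with columns A, B, R2, DIST.
#' @export
setClass("LDTable",
  representation(pairs = "data.frame"),
  prototype(pairs = data.frame(A = character(), B = character(),
                               R2 = numeric(), DIST = numeric(),
                               stringsAsFactors = FALSE)),
  validity = function(object) {
    p <- object@pairs
    need <- c("A", "B", "R2", "DIST")
    if (!all(need %in% names(p))) return("pairs needs columns A, B, R2, DIST")
    if (nrow(p) > 0) {
      if (any(!is.finite(p$R2) | p$R2 < 0 | p$R2 > 1))
        return("R2 must lie in [0,1]")
      if (any(p$DIST < 0)) return("DIST must be non-negative")
    }
    TRUE
  }
)

#' Construct an LDTable
#'
#' @param pairs data.frame with columns A, B, R2 and optionally DIST
#'   (base-pair distance; defaults to `NA`).
#' @return An [LDTable-class] object.
#' @export
LDTable <- function(pairs = NULL) {
  if (is.null(pairs))
    pairs <- data.frame(A = character(), B = character(), R2 = numeric(),
                        DIST = numeric(), stringsAsFactors = FALSE)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (is.null(pairs$DIST)) pairs$DIST <- NA_real_
  pairs$A <- as.character(pairs$A)
  pairs$B <- as.character(pairs$B)
  rownames(pairs) <- NULL
  new("LDTable", pairs = pairs[, c("A", "B", "R2", "DIST")])
}

#' AnnotationTable: secondary-trait annotations per variant
#'
#' A local lookup of variant associations with secondary traits (for
#' example "lipids", "kidney_function", "BMI"), standing in for an online
#' phenome-wide lookup. Trait labels are restricted to a declared
#' controlled vocabulary.
#'
#' @slot annotations data.frame with columns SNP and TRAIT (one row per
#'   variant-trait association).
#' @slot vocabulary character vector of admissible trait labels.
#' @export
setClass("AnnotationTable",
  representation(annotations = "data.frame", vocabulary = "character"),
  prototype(annotations = data.frame(SNP = character(), TRAIT = character(),
                                     stringsAsFactors = FALSE),
            vocabulary = character()),
  validity = function(object) {
    a <- object@annotations
    if (!all(c("SNP", "TRAIT") %in% names(a)))
      return("annotations needs columns SNP, TRAIT")
    bad <- setdiff(unique(a$TRAIT), object@vocabulary)
    if (length(bad))
      return(paste("trait labels outside vocabulary:", paste(bad, collapse = ", ")))
    TRUE
  }
)

#' Construct an AnnotationTable
#'
#' @param annotations data.frame with columns SNP, TRAIT.
#' @param vocabulary admissible trait labels; defaults to the labels present.
#' @return An [AnnotationTable-class] object.
#' @export
AnnotationTable <- function(annotations = NULL, vocabulary = NULL) {
  if (is.null(annotations))
    annotations <- data.frame(SNP = character(), TRAIT = character(),
                              stringsAsFactors = FALSE)
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (is.null(vocabulary)) vocabulary <- sort(unique(annotations$TRAIT))
  rownames(annotations) <- NULL
  new("AnnotationTable", annotations = annotations[, c("SNP", "TRAIT")],
      vocabulary = as.character(vocabulary))
}

#' Cohort: individual-level dosages, phenotypes and covariates
#'
#' Holds an allele-dosage matrix (individuals by variants, dosages in
#' \[0,2\], `NA` allowed) together with the allele counted by each dosage
#' column and a phenotype/covariate table aligned on individual ID.
#'
#' @slot dosages numeric matrix, rownames = individual IDs, colnames =
#'   variant IDs.
#' @slot countedAllele named character vector: the allele whose copies each
#'   dosage column counts.
#' @slot pheno data.frame of phenotypes and covariates, rownames =
#'   individual IDs in the same order as `dosages`.
#' @export
setClass("Cohort",
  representation(dosages = "matrix", countedAllele = "character",
                 pheno = "data.frame"),
  validity = function(object) {
    d <- object@dosages
    if (!is.numeric(d)) return("dosages must be numeric")
    if (is.null(rownames(d)) || is.null(colnames(d)))
      return("dosages must have individual and variant names")
    if (anyDuplicated(rownames(d))) return("duplicated individual IDs")
    v <- d[!is.na(d)]
    if (any(v < 0 | v > 2)) return("dosages must lie in [0,2]")
    if (!identical(sort(names(object@countedAllele)), sort(colnames(d))))
      return("countedAllele must name every dosage column")
    if (!identical(rownames(object@pheno), rownames(d)))
      return("pheno rows must match dosage rows")
    TRUE
  }
)

#' Construct a Cohort
#'
#' @param dosages numeric matrix of allele dosages in \[0,2\].
#' @param countedAllele named character vector giving the counted allele per
#'   variant column.
#' @param pheno data.frame of phenotypes/covariates with rownames matching
#'   the dosage rownames.
#' @return A [Cohort-class] object.
#' @export
Cohort <- function(dosages, countedAllele, pheno) {
  pheno <- as.data.frame(pheno, stringsAsFactors = FALSE)
  pheno <- pheno[rownames(dosages), , drop = FALSE]
  new("Cohort", dosages = dosages,
      countedAllele = countedAllele[colnames(dosages)], pheno = pheno)
}

INSTRUMENT_STATUSES <- c("direct", "proxy", "dropped")

#' InstrumentSet: harmonized exposure-outcome instrument pairs
#'
#' One row per candidate instrument after harmonization: the exposure
#' association, the outcome association aligned to the exposure effect
#' allele, and a status (`direct`, `proxy` with the proxy identity and its
#' r2, or `dropped` with a reason). Dropped rows are retained so that
#' instrument accounting is exhaustive; estimators operate on the
#' non-dropped subset (see [validInstruments()]).
#'
#' @slot pairs data.frame with columns SNP, BETA_EXP, SE_EXP, BETA_OUT,
#'   SE_OUT, STATUS, PROXY, PROXY_R2, REASON.
#' @slot exposure,outcome trait labels.
#' @slot outcomeBinary logical; outcome effects are log odds ratios.
#' @export
setClass("InstrumentSet",
  representation(pairs = "data.frame", exposure = "character",
                 outcome = "character", outcomeBinary = "logical"),
  validity = function(object) {
    p <- object@pairs
    need <- c("SNP", "BETA_EXP", "SE_EXP", "BETA_OUT", "SE_OUT",
              "STATUS", "PROXY", "PROXY_R2", "REASON")
    if (!all(need %in% names(p)))
      return(paste("pairs needs columns", paste(need, collapse = ", ")))
    if (!all(p$STATUS %in% INSTRUMENT_STATUSES))
      return("STATUS must be one of direct/proxy/dropped")
    ok <- p$STATUS != "dropped"
    if (any(ok & (!is.finite(p$SE_EXP) | p$SE_EXP <= 0)) ||
        any(ok & (!is.finite(p$SE_OUT) | p$SE_OUT <= 0)))
      return("non-dropped rows must have positive standard errors")
    TRUE
  }
)

#' Construct an InstrumentSet
#'
#' @param pairs data.frame of harmonized pairs (see [InstrumentSet-class]).
#' @param exposure,outcome trait labels.
#' @param outcomeBinary logical flag for the outcome scale.
#' @return An [InstrumentSet-class] object.
#' @export
InstrumentSet <- function(pairs, exposure = "exposure", outcome = "outcome",
                          outcomeBinary = FALSE) {
  rownames(pairs) <- NULL
  new("InstrumentSet", pairs = pairs, exposure = exposure, outcome = outcome,
      outcomeBinary = isTRUE(outcomeBinary))
}

MR_METHODS <- c("ivw", "weighted_median", "penalized_weighted_median",
                "egger_slope")

#' MREstimate: a causal-effect estimate from one estimator
#'
#' Log-scale causal estimate with standard error, 95% confidence bounds and
#' two-sided p-value, plus the exponentiated (odds-ratio scale) triple for
#' reporting. For binary outcomes the log scale is log-odds; for continuous
#' outcomes it is the raw linear effect and the exponentiated triple is
#' reported alongside without asserting an odds interpretation.
#'
#' @slot method one of `ivw`, `weighted_median`, `penalized_weighted_median`,
#'   `egger_slope`.
#' @slot betaHat,se,ciLow,ciHigh,pvalue numeric scalars (log scale).
#' @slot nInstruments integer count of instruments used.
#' @export
setClass("MREstimate",
  representation(method = "character", betaHat = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pvalue = "numeric",
                 nInstruments = "integer"),
  validity = function(object) {
    if (!object@method %in% MR_METHODS)
      return(paste("method must be one of", paste(MR_METHODS, collapse = ", ")))
    b <- object@betaHat
    if (is.finite(object@ciLow) && is.finite(object@ciHigh) && is.finite(b) &&
        !(object@ciLow < b && b < object@ciHigh))
      return("confidence bounds must bracket the estimate")
    TRUE
  }
)

.MREstimate <- function(method, betaHat, se, ciLow, ciHigh, pvalue, n) {
  new("MREstimate", method = method, betaHat = betaHat, se = se,
      ciLow = ciLow, ciHigh = ciHigh, pvalue = pvalue,
      nInstruments = as.integer(n))
}

#' EggerResult: MR-Egger regression fit
#'
#' The intercept (average directional pleiotropy) with its standard error
#' and two-sided Student-t p-value on J-2 degrees of freedom, together with
#' the slope as an [MREstimate-class] (`method = "egger_slope"`).
#'
#' @slot intercept,interceptSE,interceptP numeric scalars.
#' @slot slope the slope estimate.
#' @slot sigma residual standard error of the weighted fit.
#' @export
setClass("EggerResult",
  representation(intercept = "numeric", interceptSE = "numeric",
                 interceptP = "numeric", slope = "MREstimate",
                 sigma = "numeric"))

PLEIOTROPY_MODES <- c("none", "balanced", "directional")

#' MRScenario: generative specification for a synthetic two-sample study
#'
#' Fully describes a synthetic Mendelian randomization experiment: number
#' of instruments, sample sizes for the (non-overlapping) exposure and
#' outcome GWAS samples and the individual-level cohort, allele-frequency
#' range, exposure heritability explained by the instruments, the true
#' causal effect, the pleiotropy structure, LD blocks, and the seed.
#'
#' @slot nVariants number of instruments (default 84).
#' @slot nExposure,nOutcome,nCohort sample sizes.
#' @slot mafRange minor-allele frequency interval in (0, 0.5].
#' @slot h2Exposure variance of the exposure explained jointly by the
#'   instruments (default 0.075, within the 5-10% band typical of polygenic
#'   instrument sets for common metabolic disease).
#' @slot betaCausal true causal effect of exposure on outcome.
#' @slot pleiotropyMode one of `none`, `balanced`, `directional`.
#' @slot pleiotropyMean,pleiotropySd mean and SD of direct variant-outcome
#'   effects on the invalid instrument subset.
#' @slot invalidFraction fraction of instruments with direct effects, in \[0,1).
#' @slot binaryExposure liability-threshold binary exposure flag.
#' @slot caseFraction case fraction for the binary exposure.
#' @slot binaryOutcome liability-threshold binary outcome flag.
#' @slot confounderLoading loading of the shared confounder on both traits.
#' @slot ldBlocks list of `list(size=, r2=)` LD blocks (r2 is the target
#'   anchor-member dosage r-squared within a block).
#' @slot seed integer seed; identical scenario + seed reproduces outputs
#'   byte-identically.
#' @export
setClass("MRScenario",
  representation(nVariants = "integer", nExposure = "integer",
                 nOutcome = "integer", nCohort = "integer",
                 mafRange = "numeric", h2Exposure = "numeric",
                 betaCausal = "numeric", pleiotropyMode = "character",
                 pleiotropyMean = "numeric", pleiotropySd = "numeric",
                 invalidFraction = "numeric", binaryExposure = "logical",
                 caseFraction = "numeric", binaryOutcome = "logical",
                 confounderLoading = "numeric", ldBlocks = "list",
                 seed = "integer"),
  validity = function(object) {
    if (object@nVariants < 1) return("nVariants must be >= 1")
    mr <- object@mafRange
    if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
      return("mafRange must be an interval within (0, 0.5]")
    if (object@h2Exposure < 0 || object@h2Exposure >= 1)
      return("h2Exposure must lie in [0,1)")
    if (!object@pleiotropyMode %in% PLEIOTROPY_MODES)
      return("unknown pleiotropy mode")
    if (object@invalidFraction < 0 || object@invalidFraction >= 1)
      return("invalidFraction must lie in [0,1)")
    if (object@pleiotropySd < 0) return("pleiotropySd must be >= 0")
    if (object@caseFraction <= 0 || object@caseFraction >= 1)
      return("caseFraction must lie in (0,1)")
    if (length(object@ldBlocks)) {
      sizes <- vapply(object@ldBlocks, function(b) b$size, numeric(1))
      r2s <- vapply(object@ldBlocks, function(b) b$r2, numeric(1))
      if (any(sizes < 2)) return("LD blocks must have size >= 2")
      if (sum(sizes) > object@nVariants)
        return("LD blocks exceed the number of variants")
      if (any(r2s < 0 | r2s > 1)) return("block r2 must lie in [0,1]")
    }
    TRUE
  }
)
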