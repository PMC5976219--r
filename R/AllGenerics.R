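#' @include AllClasses.R
NULL

#' Variant identifiers of an object
#' @param x an object holding per-variant data.
#' @return Character vector of variant IDs.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @describeIn variantIds variant IDs of a summary-statistic set.
#' @export
setMethod("variantIds", "SummaryStats", function(x) x@table$SNP)

#' @describeIn variantIds variant IDs (instrument candidates) of an
#'   instrument set.
#' @export
setMethod("variantIds", "InstrumentSet", function(x) x@pairs$SNP)

#' @describeIn variantIds variant columns of a cohort dosage matrix.
#' @export
setMethod("variantIds", "Cohort", function(x) colnames(x@dosages))

#' Trait label of an object
#' @param x an object carrying a trait label.
#' @return Single character string.
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @describeIn traitName trait of a summary-statistic set.
#' @export
setMethod("traitName", "SummaryStats", function(x) x@trait)

#' Underlying table of an object
#' @param x a container object.
#' @return data.frame view of the object's contents.
#' @export
setGeneric("asTable", function(x) standardGeneric("asTable"))

#' @describeIn asTable canonical-column summary-statistic table.
#' @export
setMethod("asTable", "SummaryStats", function(x) x@table)

#' @describeIn asTable LD pair table (columns A, B, R2, DIST).
#' @export
setMethod("asTable", "LDTable", function(x) x@pairs)

#' @describeIn asTable variant-trait annotation rows.
#' @export
setMethod("asTable", "AnnotationTable", function(x) x@annotations)

#' @describeIn asTable full harmonization table including dropped rows.
#' @export
setMethod("asTable", "InstrumentSet", function(x) x@pairs)

#' @describeIn asTable one-row summary of an estimate (log and exp scale).
#' @export
setMethod("asTable", "MREstimate", function(x) {
  data.frame(method = x@method, b = x@betaHat, se = x@se,
             ci_low = x@ciLow, ci_high = x@ciHigh, p = x@pvalue,
             or = exp(x@betaHat), or_ci_low = exp(x@ciLow),
             or_ci_high = exp(x@ciHigh), n_instruments = x@nInstruments,
             stringsAsFactors = FALSE)
})

#' Symmetric LD lookup
#'
#' Returns the stored r-squared for an unordered variant pair. The query is
#' symmetric; a self-pair returns 1; a pair with no entry returns `NA`
#' ("no data"), which callers must treat as distinct from r2 = 0.
#'
#' @param x an [LDTable-class].
#' @param a,b variant IDs.
#' @return Numeric r-squared, 1 for a self pair, or `NA` when unknown.
#' @export
setGeneric("ldR2", function(x, a, b) standardGeneric("ldR2"))

#' @describeIn ldR2 lookup in a pair table.
#' @export
setMethod("ldR2", "LDTable", function(x, a, b) {
  if (a == b) return(1.0)
  p <- x@pairs
  hit <- (p$A == a & p$B == b) | (p$A == b & p$B == a)
  if (!any(hit)) return(NA_real_)
  p$R2[which(hit)[1L]]
})

#' Non-dropped harmonized pairs
#'
#' @param x an [InstrumentSet-class].
#' @return data.frame of the rows with status `direct` or `proxy`.
#' @export
setGeneric("validInstruments", function(x) standardGeneric("validInstruments"))

#' @describeIn validInstruments subset of the harmonization table.
#' @export
setMethod("validInstruments", "InstrumentSet", function(x) {
  out <- x@pairs[x@pairs$STATUS != "dropped", , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' Number of instruments entering estimation
#' @param x an object with an instrument count.
#' @return Integer count.
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))

#' @describeIn nInstruments count of non-dropped pairs.
#' @export
setMethod("nInstruments", "InstrumentSet",
          function(x) sum(x@pairs$STATUS != "dropped"))

#' @describeIn nInstruments instruments used by an estimate.
#' @export
setMethod("nInstruments", "MREstimate", function(x) x@nInstruments)

#' Point estimate accessor
#' @param x an estimate object.
#' @return Numeric log-scale causal estimate.
#' @export
setGeneric("betaHat", function(x) standardGeneric("betaHat"))

#' @describeIn betaHat log-scale estimate.
#' @export
setMethod("betaHat", "MREstimate", function(x) x@betaHat)

#' Standard error accessor
#' @param x an estimate object.
#' @return Numeric standard error.
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))

#' @describeIn stdError standard error of the estimate.
#' @export
setMethod("stdError", "MREstimate", function(x) x@se)

#' Confidence interval accessor
#' @param x an estimate object.
#' @return Numeric length-2 vector (lower, upper), log scale.
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @describeIn confInt 95% bounds.
#' @export
setMethod("confInt", "MREstimate", function(x) c(x@ciLow, x@ciHigh))

#' P-value accessor
#' @param x an estimate object.
#' @return Two-sided p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @describeIn pValue two-sided p-value of the estimate.
#' @export
setMethod("pValue", "MREstimate", function(x) x@pvalue)

#' Odds-ratio-scale triple
#' @param x an estimate object.
#' @return Named numeric vector (or, ci_low, ci_high) = exp of the
#'   log-scale triple.
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @describeIn oddsRatio exponentiated estimate and bounds.
#' @export
setMethod("oddsRatio", "MREstimate", function(x) {
  c(or = exp(x@betaHat), ci_low = exp(x@ciLow), ci_high = exp(x@ciHigh))
})

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats: %s (%s), %d variants\n", object@trait,
              if (object@binary) "binary, log-OR" else "continuous",
              nrow(object@table)))
  if (nrow(object@table)) {
    print(utils::head(object@table, 4L))
    if (nrow(object@table) > 4L) cat("...\n")
  }
})

setMethod("show", "LDTable", function(object) {
  cat(sprintf("LDTable: %d variant pairs\n", nrow(object@pairs)))
})

setMethod("show", "AnnotationTable", function(object) {
  cat(sprintf("AnnotationTable: %d annotations on %d variants (vocabulary: %s)\n",
              nrow(object@annotations), length(unique(object@annotations$SNP)),
              paste(object@vocabulary, collapse = ", ")))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d individuals x %d variants; phenotypes/covariates: %s\n",
              nrow(object@dosages), ncol(object@dosages),
              paste(names(object@pheno), collapse = ", ")))
})

setMethod("show", "InstrumentSet", function(object) {
  st <- table(factor(object@pairs$STATUS, levels = INSTRUMENT_STATUSES))
  cat(sprintf("InstrumentSet: %s -> %s\n", object@exposure, object@outcome))
  cat(sprintf("  %d direct, %d proxy, %d dropped (of %d candidates)\n",
              st["direct"], st["proxy"], st["dropped"], nrow(object@pairs)))
})

setMethod("show", "MREstimate", function(object) {
  orv <- oddsRatio(object)
  cat(sprintf("MREstimate [%s], %d instruments\n", object@method,
              object@nInstruments))
  cat(sprintf("  b = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              object@betaHat, object@se, object@ciLow, object@ciHigh,
              object@pvalue))
  cat(sprintf("  exp scale: %.3f [%.3f, %.3f]\n", orv[1], orv[2], orv[3]))
})

setMethod("show", "EggerResult", function(object) {
  cat(sprintf("MR-Egger: intercept = %.4f (SE %.4f), p = %.3g\n",
              object@intercept, object@interceptSE, object@interceptP))
  cat("Slope:\n")
  show(object@slope)
})

setMethod("show", "MRScenario", function(object) {
  cat(sprintf(
    "MRScenario: %d instruments, h2 = %.3f, beta = %.3f, pleiotropy = %s\n",
    object@nVariants, object@h2Exposure, object@betaCausal,
    object@pleiotropyMode))
  cat(sprintf("  samples: exposure %d, outcome %d, cohort %d; seed %d\n",
              object@nExposure, object@nOutcome, object@nCohort, object@seed))
})
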