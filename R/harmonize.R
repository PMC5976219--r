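#' @include AllClasses.R AllGenerics.R
NULL

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.isPalindromic <- function(ea, oa) .COMPLEMENT[[ea]] == oa

#' Align an outcome record to the exposure effect allele
#'
#' Orients one variant's outcome association onto the exposure's effect
#' allele. Matching allele pairs are copied; swapped pairs negate the
#' outcome effect and reflect the frequency (eaf to 1 - eaf); strand
#' complements (A-T, C-G) are resolved by complementing and re-applying the
#' rules. Palindromic variants (A/T or G/C), whose strand cannot be
#' resolved from the allele letters, are oriented by effect-allele
#' frequency when both frequencies fall outside the ambiguity window, and
#' dropped as `palindromic_ambiguous` otherwise. Alleles irreconcilable
#' after complementing are dropped as `allele_mismatch`.
#'
#' Aligning an already-aligned pair is a no-op.
#'
#' @param exposure,outcome one-row data.frames in the canonical layout
#'   ([canonicalColumns()]) for the same variant.
#' @param eafWindow frequency interval within which a palindromic variant
#'   is considered ambiguous (default `c(0.42, 0.58)`).
#' @return A list with `status` (`"direct"` or `"dropped"`), `reason`
#'   (`NA` unless dropped), and when aligned the outcome `BETA`, `SE`,
#'   `EAF` expressed on the exposure effect allele.
#' @export
alignAlleles <- function(exposure, outcome, eafWindow = c(0.42, 0.58)) {
  stopifnot(exposure$SNP == outcome$SNP)
  eaX <- exposure$EA; oaX <- exposure$OA
  eaY <- outcome$EA;  oaY <- outcome$OA
  dropped <- function(reason)
    list(status = "dropped", reason = reason, BETA = NA_real_,
         SE = NA_real_, EAF = NA_real_)
  aligned <- function(beta, se, eaf)
    list(status = "direct", reason = NA_character_,
         BETA = beta, SE = se, EAF = eaf)

  if (.isPalindromic(eaX, oaX)) {
    # letter identity cannot distinguish strand; orient by frequency
    if (setequal(c(eaY, oaY), c(eaX, oaX))) {
      if (eaY == eaX) {
        beta <- outcome$BETA; eaf <- outcome$EAF
      } else { # swapped letters
        beta <- -outcome$BETA; eaf <- 1 - outcome$EAF
      }
      fx <- exposure$EAF
      if (is.na(fx) || is.na(eaf) ||
          (fx >= eafWindow[1] && fx <= eafWindow[2]) ||
          (eaf >= eafWindow[1] && eaf <= eafWindow[2]))
        return(dropped("palindromic_ambiguous"))
      if ((fx < 0.5) != (eaf < 0.5)) { # discordant: other strand
        beta <- -beta; eaf <- 1 - eaf
      }
      return(aligned(beta, outcome$SE, eaf))
    }
    return(dropped("allele_mismatch"))
  }

  if (eaY == eaX && oaY == oaX)
    return(aligned(outcome$BETA, outcome$SE, outcome$EAF))
  if (eaY == oaX && oaY == eaX)
    return(aligned(-outcome$BETA, outcome$SE,
                   if (is.na(outcome$EAF)) NA_real_ else 1 - outcome$EAF))
  ceaY <- .COMPLEMENT[[eaY]]; coaY <- .COMPLEMENT[[oaY]]
  if (ceaY == eaX && coaY == oaX)
    return(aligned(outcome$BETA, outcome$SE, outcome$EAF))
  if (ceaY == oaX && coaY == eaX)
    return(aligned(-outcome$BETA, outcome$SE,
                   if (is.na(outcome$EAF)) NA_real_ else 1 - outcome$EAF))
  dropped("allele_mismatch")
}

#' Choose LD proxies for instruments missing from the outcome data
#'
#' For each missing variant, selects the available outcome variant with the
#' highest r-squared strictly above `r2Min` (the conventional proxy
#' admission threshold is r2 > 0.7). Ties on r-squared are broken by the
#' smaller base-pair distance, then by lexicographic variant ID. A variant
#' with no admissible proxy is reported as dropped (`no_proxy`).
#'
#' @param missing character vector of missing instrument IDs.
#' @param outcomeStats a [SummaryStats-class] of the outcome sample.
#' @param ld an [LDTable-class].
#' @param r2Min strict lower bound for proxy admission (default 0.7).
#' @return data.frame with one row per missing variant: SNP, PROXY
#'   (`NA` when none), R2, DIST, STATUS (`proxy`/`dropped`), REASON.
#' @export
substituteProxies <- function(missing, outcomeStats, ld, r2Min = 0.7) {
  avail <- variantIds(outcomeStats)
  pairs <- asTable(ld)
  out <- lapply(missing, function(snp) {
    hit <- (pairs$A == snp & pairs$B %in% avail) |
           (pairs$B == snp & pairs$A %in% avail)
    cand <- pairs[hit, , drop = FALSE]
    if (nrow(cand)) {
      cand$OTHER <- ifelse(cand$A == snp, cand$B, cand$A)
      cand <- cand[cand$R2 > r2Min, , drop = FALSE] # strict: r2 must exceed
    }
    if (!nrow(cand))
      return(data.frame(SNP = snp, PROXY = NA_character_, R2 = NA_real_,
                        DIST = NA_real_, STATUS = "dropped",
                        REASON = "no_proxy", stringsAsFactors = FALSE))
    ord <- order(-cand$R2, cand$DIST, cand$OTHER)
    best <- cand[ord[1L], ]
    data.frame(SNP = snp, PROXY = best$OTHER, R2 = best$R2,
               DIST = best$DIST, STATUS = "proxy", REASON = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Greedy LD clumping
#'
#' Enforces instrument independence by the greedy index-variant procedure:
#' variants are ranked by ascending p-value (ties broken by ascending
#' position, then variant ID); the best remaining variant is retained and
#' every other variant on the same chromosome within `windowBp` whose
#' r-squared with it exceeds `r2Max` is removed, until no variant remains.
#' A pair with no LD entry is treated as r2 = 0 (with a warning), so
#' clumping never stalls on a sparse LD table. The window is measured as
#' the absolute distance between variant positions.
#'
#' @param records a [SummaryStats-class] (or canonical-layout data.frame)
#'   of the variants to clump.
#' @param ld an [LDTable-class].
#' @param r2Max retention threshold: a variant is removed only when its
#'   r-squared with a retained index variant strictly exceeds this value
#'   (default 0.1).
#' @param windowBp window in base pairs (default 100000).
#' @return Character vector of retained variant IDs, in retention order.
#' @export
ldClump <- function(records, ld, r2Max = 0.1, windowBp = 100000L) {
  tab <- if (is(records, "SummaryStats")) asTable(records) else records
  if (nrow(tab) == 0L) return(character(0))
  ord <- order(tab$P, tab$BP, tab$SNP)
  tab <- tab[ord, , drop = FALSE]
  remaining <- rep(TRUE, nrow(tab))
  retained <- character(0)
  unknownLD <- FALSE
  while (any(remaining)) {
    i <- which(remaining)[1L]
    retained <- c(retained, tab$SNP[i])
    remaining[i] <- FALSE
    for (j in which(remaining)) {
      if (tab$CHR[j] != tab$CHR[i]) next
      if (abs(tab$BP[j] - tab$BP[i]) > windowBp) next
      r2 <- ldR2(ld, tab$SNP[i], tab$SNP[j])
      if (is.na(r2)) { unknownLD <- TRUE; r2 <- 0 }
      if (r2 > r2Max) remaining[j] <- FALSE
    }
  }
  if (unknownLD)
    warning("LD unknown for some pairs within the clumping window; treated as r2 = 0")
  retained
}

#' Harmonize exposure instruments against an outcome sample
#'
#' Builds the instrument set entering estimation: optionally clumps the
#' exposure instruments ([ldClump()]), aligns each instrument's outcome
#' association to the exposure effect allele ([alignAlleles()]), and
#' substitutes LD proxies for instruments absent from the outcome data
#' ([substituteProxies()]). A proxy's outcome association is used as
#' recorded, on the assumption that the LD table orientation tags the
#' exposure effect allele (the synthetic generator guarantees this).
#' Every candidate appears in the result exactly once, dropped rows
#' included, so selected = retained + dropped at every stage.
#'
#' @param exposure,outcome [SummaryStats-class] objects from the two
#'   non-overlapping samples.
#' @param ld an [LDTable-class] or `NULL` (no proxies, no clumping).
#' @param proxyR2 strict proxy admission threshold (default 0.7).
#' @param clump logical; clump the exposure instruments first.
#' @param clumpR2,clumpWindowBp clumping parameters (defaults 0.1, 100 kb).
#' @param eafWindow palindrome ambiguity window.
#' @return An [InstrumentSet-class].
#' @export
harmonizeInstruments <- function(exposure, outcome, ld = NULL,
                                 proxyR2 = 0.7, clump = FALSE,
                                 clumpR2 = 0.1, clumpWindowBp = 100000L,
                                 eafWindow = c(0.42, 0.58)) {
  expTab <- asTable(exposure)
  if (clump) {
    if (is.null(ld)) stop("clumping requires an LD table", call. = FALSE)
    keep <- ldClump(exposure, ld, r2Max = clumpR2, windowBp = clumpWindowBp)
    clumpedOut <- setdiff(expTab$SNP, keep)
    expTab <- expTab[match(keep, expTab$SNP), , drop = FALSE]
  } else clumpedOut <- character(0)
  outTab <- asTable(outcome)

  rowFor <- function(snp, betaOut, seOut, status, reason,
                     proxy = NA_character_, proxyR2v = NA_real_) {
    e <- expTab[expTab$SNP == snp, ]
    data.frame(SNP = snp, BETA_EXP = e$BETA, SE_EXP = e$SE,
               BETA_OUT = betaOut, SE_OUT = seOut, STATUS = status,
               PROXY = proxy, PROXY_R2 = proxyR2v, REASON = reason,
               stringsAsFactors = FALSE)
  }

  present <- expTab$SNP[expTab$SNP %in% outTab$SNP]
  absent <- setdiff(expTab$SNP, present)
  rows <- lapply(present, function(snp) {
    al <- alignAlleles(expTab[expTab$SNP == snp, ],
                       outTab[outTab$SNP == snp, ], eafWindow = eafWindow)
    rowFor(snp, al$BETA, al$SE, al$status, al$reason)
  })
  if (length(absent)) {
    if (is.null(ld)) {
      prox <- data.frame(SNP = absent, PROXY = NA_character_, R2 = NA_real_,
                         STATUS = "dropped", REASON = "no_proxy",
                         stringsAsFactors = FALSE)
    } else prox <- substituteProxies(absent, outcome, ld, r2Min = proxyR2)
    rows <- c(rows, lapply(seq_len(nrow(prox)), function(k) {
      pr <- prox[k, ]
      if (pr$STATUS == "proxy") {
        o <- outTab[outTab$SNP == pr$PROXY, ]
        rowFor(pr$SNP, o$BETA, o$SE, "proxy", NA_character_, pr$PROXY, pr$R2)
      } else rowFor(pr$SNP, NA_real_, NA_real_, "dropped", pr$REASON)
    }))
  }
  pairs <- do.call(rbind, rows)
  pairs <- pairs[match(expTab$SNP, pairs$SNP), , drop = FALSE]
  if (length(clumpedOut)) {
    full <- asTable(exposure)
    cl <- do.call(rbind, lapply(clumpedOut, function(snp) {
      e <- full[full$SNP == snp, ]
      data.frame(SNP = snp, BETA_EXP = e$BETA, SE_EXP = e$SE,
                 BETA_OUT = NA_real_, SE_OUT = NA_real_, STATUS = "dropped",
                 PROXY = NA_character_, PROXY_R2 = NA_real_,
                 REASON = "ld_clumped", stringsAsFactors = FALSE)
    }))
    pairs <- rbind(pairs, cl)
  }
  InstrumentSet(pairs, exposure = traitName(exposure),
                outcome = traitName(outcome), outcomeBinary = outcome@binary)
}

#' Write a harmonization report
#'
#' Tab-delimited report with one row per candidate instrument: variant,
#' status, drop reason, proxy identity and proxy r-squared.
#'
#' @param x an [InstrumentSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHarmonizationReport <- function(x, path) {
  rep <- asTable(x)[, c("SNP", "STATUS", "REASON", "PROXY", "PROXY_R2")]
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
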