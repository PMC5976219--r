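#' @include AllClasses.R
NULL

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistic file and maps its header onto
#' the canonical columns ([canonicalColumns()]). Rows whose BETA or SE is
#' unparseable, or whose SE is not strictly positive, are rejected (never
#' silently dropped): the numbers of accepted and rejected rows are
#' reported via a message and attached as attributes `nAccepted` and
#' `nRejected`, and input rows = accepted + rejected always holds. Alleles
#' are upper-cased. A missing EAF is read as `NA` and the record remains
#' usable for estimation (EAF is needed only for palindrome resolution and
#' missing-dosage imputation).
#'
#' @param path file path to a tab-delimited file with a header row.
#' @param columnMap named character vector mapping canonical names to the
#'   file's column names, e.g. `c(SNP = "rsid", BETA = "b")`; canonical
#'   names absent from the map are looked up verbatim.
#' @param trait,binary trait label and binary flag stored on the result.
#' @return A [SummaryStats-class] with attributes `nAccepted`, `nRejected`.
#' @export
readSummaryStats <- function(path, columnMap = character(), trait = "trait",
                             binary = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  resolved <- vapply(canonicalColumns(), function(cn) {
    if (cn %in% names(columnMap)) columnMap[[cn]] else cn
  }, character(1))
  missing <- resolved[!resolved %in% names(raw)]
  if (length(missing))
    stop("summary-statistic file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- raw[, resolved]
  names(tab) <- canonicalColumns()
  nIn <- nrow(tab)
  if (nIn == 0L) {
    warning("summary-statistic file ", path, " has a header but no rows")
    out <- SummaryStats(tab, trait = trait, binary = binary)
    attr(out, "nAccepted") <- 0L
    attr(out, "nRejected") <- 0L
    return(out)
  }
  for (cn in c("BP", "EAF", "BETA", "SE", "P", "N"))
    tab[[cn]] <- suppressWarnings(as.numeric(tab[[cn]]))
  bad <- !is.finite(tab$BETA) | !is.finite(tab$SE) | tab$SE <= 0
  if (any(bad))
    message(sum(bad), " row(s) rejected in ", basename(path),
            " (unparseable BETA/SE or SE <= 0)")
  tab <- tab[!bad, , drop = FALSE]
  out <- SummaryStats(tab, trait = trait, binary = binary)
  attr(out, "nAccepted") <- nIn - sum(bad)
  attr(out, "nRejected") <- sum(bad)
  out
}

#' Write summary statistics
#'
#' Writes the canonical-column table as tab-delimited text. A re-read via
#' [readSummaryStats()] reproduces every field (missing EAF round-trips as
#' `NA`; numeric fields at full printed precision).
#'
#' @param x a [SummaryStats-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
  tab <- x@table
  for (cn in c("EAF", "BETA", "SE", "P", "N"))
    tab[[cn]] <- vapply(tab[[cn]], function(v)
      if (is.na(v)) "NA" else format(v, digits = 17), character(1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Tab-delimited variant pairs with an r-squared column (`A`, `B`, `R2`,
#' optional `DIST` in base pairs). Lookup on the result via [ldR2()] is
#' symmetric in the pair; unknown pairs yield `NA` ("no data"), distinct
#' from r2 = 0.
#'
#' @param path file path.
#' @return An [LDTable-class].
#' @export
readLDTable <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("A", "B", "R2") %in% names(tab)))
    stop("LD table needs columns A, B, R2", call. = FALSE)
  if (any(!is.finite(tab$R2) | tab$R2 < 0 | tab$R2 > 1))
    stop("LD table contains r2 outside [0,1]", call. = FALSE)
  LDTable(tab)
}

#' Write a pairwise LD table
#' @param x an [LDTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLDTable <- function(x, path) {
  utils::write.table(x@pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a variant annotation table
#'
#' Tab-delimited `SNP` / `TRAIT` rows recording secondary-trait
#' associations of instruments (a local stand-in for a phenome-wide
#' lookup service), restricted to a controlled vocabulary.
#'
#' @param path file path.
#' @param vocabulary admissible trait labels; defaults to those present.
#' @return An [AnnotationTable-class].
#' @export
readAnnotationTable <- function(path, vocabulary = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("SNP", "TRAIT") %in% names(tab)))
    stop("annotation table needs columns SNP, TRAIT", call. = FALSE)
  AnnotationTable(tab, vocabulary)
}

#' Write a variant annotation table
#' @param x an [AnnotationTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTable <- function(x, path) {
  utils::write.table(x@annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an individual-level cohort
#'
#' Reads a dosage file in the PLINK `.raw` text layout (one row per
#' individual; an `IID` column; one `variantID_countedAllele` column per
#' variant) and a phenotype/covariate file keyed by `IID`, and inner-joins
#' them on individual ID. The join cardinality is reported; individuals
#' present in only one file are excluded with a message.
#'
#' @param dosagePath path to the dosage file.
#' @param phenoPath path to the phenotype/covariate file.
#' @return A [Cohort-class].
#' @export
readCohort <- function(dosagePath, phenoPath) {
  dos <- utils::read.delim(dosagePath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  phe <- utils::read.delim(phenoPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"IID" %in% names(dos)) stop("dosage file lacks an IID column", call. = FALSE)
  if (!"IID" %in% names(phe)) stop("phenotype file lacks an IID column", call. = FALSE)
  if (anyDuplicated(dos$IID))
    stop("duplicated individual ID in dosage file: ",
         dos$IID[duplicated(dos$IID)][1], call. = FALSE)
  if (anyDuplicated(phe$IID))
    stop("duplicated individual ID in phenotype file: ",
         phe$IID[duplicated(phe$IID)][1], call. = FALSE)
  skip <- intersect(c("IID", "FID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(dos))
  varCols <- setdiff(names(dos), skip)
  if (!length(varCols)) stop("dosage file has no variant columns", call. = FALSE)
  if (!all(grepl("_[ACGT]$", varCols)))
    stop("dosage columns must be named variantID_countedAllele", call. = FALSE)
  ids <- intersect(dos$IID, phe$IID)
  message("cohort join: ", length(ids), " individuals in both files (",
          nrow(dos), " dosage, ", nrow(phe), " phenotype)")
  dos <- dos[match(ids, dos$IID), , drop = FALSE]
  phe <- phe[match(ids, phe$IID), setdiff(names(phe), "IID"), drop = FALSE]
  G <- as.matrix(dos[, varCols, drop = FALSE])
  mode(G) <- "numeric"
  if (any(G < 0 | G > 2, na.rm = TRUE))
    stop("dosage outside [0,2] in ", dosagePath, call. = FALSE)
  snp <- sub("_[ACGT]$", "", varCols)
  allele <- sub("^.*_", "", varCols)
  dimnames(G) <- list(ids, snp)
  rownames(phe) <- ids
  Cohort(G, stats::setNames(allele, snp), phe)
}

#' Write a cohort as dosage + phenotype text files
#'
#' @param x a [Cohort-class].
#' @param dosagePath,phenoPath output file paths.
#' @return Invisibly, `c(dosagePath, phenoPath)`.
#' @export
writeCohort <- function(x, dosagePath, phenoPath) {
  G <- x@dosages
  cols <- paste0(colnames(G), "_", x@countedAllele[colnames(G)])
  dos <- data.frame(IID = rownames(G), stats::setNames(as.data.frame(G), cols),
                    check.names = FALSE)
  utils::write.table(dos, dosagePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  phe <- data.frame(IID = rownames(G), x@pheno, check.names = FALSE)
  utils::write.table(phe, phenoPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(dosagePath, phenoPath))
}

#' Read a genetic risk score weight file
#'
#' Tab-delimited file with columns `SNP`, `EA` (effect allele) and `OR`
#' (per-allele odds ratio for the exposure, > 0), plus an optional `EAF`
#' column used for missing-dosage imputation.
#'
#' @param path file path.
#' @return data.frame with columns SNP, EA, OR and (possibly `NA`) EAF.
#' @export
readWeights <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("SNP", "EA", "OR") %in% names(tab)))
    stop("weights file needs columns SNP, EA, OR", call. = FALSE)
  if (any(!is.finite(tab$OR) | tab$OR <= 0))
    stop("weights file contains OR <= 0", call. = FALSE)
  if (is.null(tab$EAF)) tab$EAF <- NA_real_
  tab$EA <- toupper(tab$EA)
  tab[, c("SNP", "EA", "OR", "EAF")]
}
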