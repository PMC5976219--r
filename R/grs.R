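#' @include AllClasses.R AllGenerics.R
NULL

#' Compute weighted genetic risk scores
#'
#' For each individual, the score is the sum over variants of
#' log(OR_j) * G_ij, where G_ij is the dosage of the weight file's effect
#' allele. Dosage columns counting the opposite allele are realigned as
#' 2 - G. Missing dosages are mean-imputed as 2 * EAF from the weight
#' file when an EAF is available, otherwise as the cohort mean dosage;
#' imputations are counted per individual. Weight variants absent from the
#' cohort are excluded from the score (for every individual alike) with a
#' warning. Score quartiles are assigned from the empirical type-7
#' quartile boundaries with ties assigned to the lower quartile.
#'
#' @param cohort a [Cohort-class].
#' @param weights data.frame from [readWeights()] (columns SNP, EA, OR,
#'   EAF).
#' @return data.frame with columns IID, SCORE, QUARTILE, N_IMPUTED, plus
#'   attribute `nVariantsUsed`.
#' @export
computeScores <- function(cohort, weights) {
  if (any(!is.finite(weights$OR) | weights$OR <= 0))
    stop("weights must have OR > 0", call. = FALSE)
  G <- cohort@dosages
  present <- weights$SNP %in% colnames(G)
  if (any(!present))
    warning(sum(!present), " weight variant(s) absent from the cohort, ",
            "excluded from the score: ",
            paste(weights$SNP[!present], collapse = ", "))
  w <- weights[present, , drop = FALSE]
  if (nrow(w) == 0L) stop("no weight variant overlaps the cohort", call. = FALSE)
  Gs <- G[, w$SNP, drop = FALSE]
  counted <- cohort@countedAllele[w$SNP]
  swap <- counted != w$EA
  if (any(swap)) Gs[, swap] <- 2 - Gs[, swap, drop = FALSE]
  nImp <- rowSums(is.na(Gs))
  if (any(nImp > 0)) {
    fill <- ifelse(is.na(w$EAF), colMeans(Gs, na.rm = TRUE), 2 * w$EAF)
    for (j in which(colSums(is.na(Gs)) > 0))
      Gs[is.na(Gs[, j]), j] <- fill[j]
  }
  score <- as.vector(Gs %*% log(w$OR))
  qs <- stats::quantile(score, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  quartile <- 1L + (score > qs[1]) + (score > qs[2]) + (score > qs[3])
  out <- data.frame(IID = rownames(G), SCORE = score, QUARTILE = quartile,
                    N_IMPUTED = as.integer(nImp), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "nVariantsUsed") <- nrow(w)
  out
}

.designCheck <- function(fit, data) {
  aliased <- is.na(stats::coef(fit))
  if (any(aliased))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[aliased], collapse = ", "),
         call. = FALSE)
}

.grsData <- function(scores, cohort, phenotype, covariates) {
  ph <- cohort@pheno
  need <- c(phenotype, covariates)
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype/covariate column(s) not in cohort: ",
         paste(miss, collapse = ", "), call. = FALSE)
  d <- cbind(scores[match(rownames(ph), scores$IID), c("SCORE", "QUARTILE")],
             ph[, need, drop = FALSE])
  complete <- stats::complete.cases(d)
  if (any(!complete))
    message(sum(!complete), " individual(s) dropped (incomplete rows); ",
            sum(complete), " analyzed")
  d[complete, , drop = FALSE]
}

.expTriple <- function(b, se, mult = Z975) {
  c(or = exp(b), or_ci_low = exp(b - mult * se), or_ci_high = exp(b + mult * se))
}

#' Covariate-adjusted association of the risk score with a phenotype
#'
#' Ordinary least squares of a continuous phenotype on the genetic risk
#' score plus covariates (listwise deletion of incomplete rows, counts
#' reported). Returns the score coefficient with its standard error and
#' two-sided p-value, together with the exponentiated coefficient and CI,
#' reported alongside the raw linear estimate without asserting an odds
#' interpretation for continuous phenotypes. An optional log or z-score
#' transform of the phenotype is exposed because skewed imaging volumes
#' are often transformed before regression.
#'
#' @param scores data.frame from [computeScores()].
#' @param cohort a [Cohort-class].
#' @param phenotype name of a continuous phenotype column.
#' @param covariates character vector of covariate column names.
#' @param transform one of `"none"`, `"log"`, `"zscore"`.
#' @return list(beta, se, p, n, or, or_ci_low, or_ci_high).
#' @export
scoreRegression <- function(scores, cohort, phenotype, covariates = character(),
                            transform = c("none", "log", "zscore")) {
  transform <- match.arg(transform)
  d <- .grsData(scores, cohort, phenotype, covariates)
  y <- d[[phenotype]]
  y <- switch(transform, none = y, log = log(y),
              zscore = (y - mean(y)) / stats::sd(y))
  d$.y <- y
  rhs <- paste(c("SCORE", covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  .designCheck(fit, d)
  cf <- summary(fit)$coefficients["SCORE", ]
  ex <- .expTriple(cf[["Estimate"]], cf[["Std. Error"]])
  list(beta = cf[["Estimate"]], se = cf[["Std. Error"]],
       p = cf[["Pr(>|t|)"]], n = nrow(d),
       or = ex[["or"]], or_ci_low = ex[["or_ci_low"]],
       or_ci_high = ex[["or_ci_high"]])
}

#' Quartile contrasts of the risk score
#'
#' Regresses the phenotype on indicators for score quartiles 2-4 plus
#' covariates, with quartile 1 as the omitted reference, and returns the
#' three contrasts (Q2 vs Q1, Q3 vs Q1, Q4 vs Q1) with exponentiated
#' estimates and CIs. Quartiles are the assignments made by
#' [computeScores()]; a quartile emptied by ties is an error naming the
#' degenerate boundary.
#'
#' @inheritParams scoreRegression
#' @return data.frame with one row per contrast: contrast, beta, se, p,
#'   or, or_ci_low, or_ci_high, n.
#' @export
quartileContrasts <- function(scores, cohort, phenotype,
                              covariates = character()) {
  d <- .grsData(scores, cohort, phenotype, covariates)
  if (nrow(d) < 8) stop("quartile contrasts need at least 8 individuals",
                        call. = FALSE)
  counts <- table(factor(d$QUARTILE, levels = 1:4))
  if (any(counts == 0))
    stop("degenerate quartile boundaries: quartile(s) ",
         paste(names(counts)[counts == 0], collapse = ", "),
         " empty (tied scores)", call. = FALSE)
  d$QUARTILE <- factor(d$QUARTILE, levels = 1:4)
  rhs <- paste(c("QUARTILE", covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(phenotype, "~", rhs)), data = d)
  .designCheck(fit, d)
  cf <- summary(fit)$coefficients
  rows <- paste0("QUARTILE", 2:4)
  out <- do.call(rbind, lapply(seq_along(rows), function(k) {
    b <- cf[rows[k], "Estimate"]; se <- cf[rows[k], "Std. Error"]
    ex <- .expTriple(b, se)
    data.frame(contrast = paste0("Q", k + 1, "_vs_Q1"), beta = b, se = se,
               p = cf[rows[k], "Pr(>|t|)"], or = ex[["or"]],
               or_ci_low = ex[["or_ci_low"]], or_ci_high = ex[["or_ci_high"]],
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' First-principal-component phenotype from tract means
#'
#' Derives a single scalar imaging phenotype per individual as the leading
#' principal component of a matrix of per-tract diffusion means
#' (individuals by tracts): columns are standardized to mean 0 and SD 1,
#' the correlation matrix is eigendecomposed, and individuals are
#' projected onto the leading eigenvector. The loading sign is fixed so
#' the loading sum is positive, and the projection is rescaled to unit
#' variance. Zero-variance tract columns are dropped with a warning.
#'
#' @param tractMatrix numeric matrix, individuals in rows (at least 2),
#'   tracts in columns (at least 2 after dropping zero-variance columns);
#'   no missing cells.
#' @return Numeric vector of per-individual scores (unit variance), with
#'   attributes `loadings` and `varianceExplained`.
#' @export
firstPCPhenotype <- function(tractMatrix) {
  X <- as.matrix(tractMatrix)
  if (anyNA(X)) stop("tract matrix contains missing cells", call. = FALSE)
  if (nrow(X) < 2) stop("at least 2 individuals required", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance tract column(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2) stop("at least 2 informative tracts required", call. = FALSE)
  Z <- scale(X)
  eig <- eigen(stats::cor(X), symmetric = TRUE)
  v <- eig$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  proj <- as.vector(Z %*% v)
  out <- proj / stats::sd(proj)
  attr(out, "loadings") <- v
  attr(out, "varianceExplained") <- eig$values[1L] / sum(eig$values)
  out
}
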