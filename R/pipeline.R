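#' @include AllClasses.R AllGenerics.R
NULL

#' Per-test Bonferroni threshold
#'
#' Divides the family-wise alpha over the number of tests; the display
#' value is rounded to two significant figures (0.05 over 7 tests prints
#' as 0.0071).
#'
#' @param alphaFamily family-wise significance level in (0,1).
#' @param nTests number of tests (>= 1).
#' @return list(threshold, display).
#' @export
bonferroniThreshold <- function(alphaFamily = 0.05, nTests = 7L) {
  stopifnot(alphaFamily > 0, alphaFamily < 1, nTests >= 1)
  thr <- alphaFamily / nTests
  list(threshold = thr,
       display = formatC(signif(thr, 2), format = "fg"))
}

#' Assemble a study configuration
#'
#' A study configuration describes one exposure against one or more
#' outcomes: summary-statistic sources, LD and annotation tables,
#' harmonization and multiple-testing thresholds, named exclusion sets for
#' sensitivity re-runs, and estimator options. Each source is either a
#' `path` (tab-delimited file) or an in-memory object under `stats` /
#' `object`, so simulation loops can run without touching disk.
#'
#' @param exposure list(label=, path= or stats=, binary=).
#' @param outcomes list of lists like `exposure`.
#' @param ld `NULL`, a path, or an [LDTable-class].
#' @param annotations `NULL`, a path, or an [AnnotationTable-class].
#' @param thresholds overrides for list(clump_r2 = 0.1, clump_window_bp =
#'   100000, proxy_r2 = 0.7, alpha_family = 0.05, n_tests = 7).
#' @param exclusionSets named list of trait-label character vectors.
#' @param estimator overrides for list(n_boot = 1000, seed = 1,
#'   random_effects = FALSE, penalty_scale = 20).
#' @param clump logical; clump the exposure instruments before estimation.
#' @return A validated config list (class `mrStudyConfig`).
#' @export
makeStudyConfig <- function(exposure, outcomes, ld = NULL, annotations = NULL,
                            thresholds = list(), exclusionSets = list(),
                            estimator = list(), clump = FALSE) {
  thrDef <- list(clump_r2 = 0.1, clump_window_bp = 100000L, proxy_r2 = 0.7,
                 alpha_family = 0.05, n_tests = 7L)
  estDef <- list(n_boot = 1000L, seed = 1L, random_effects = FALSE,
                 penalty_scale = 20)
  thrDef[names(thresholds)] <- thresholds
  estDef[names(estimator)] <- estimator
  stopifnot(thrDef$n_tests >= 1)
  cfg <- list(exposure = exposure, outcomes = outcomes, ld = ld,
              annotations = annotations, thresholds = thrDef,
              exclusionSets = exclusionSets, estimator = estDef,
              clump = isTRUE(clump))
  class(cfg) <- "mrStudyConfig"
  cfg
}

#' Read a study configuration from YAML
#'
#' The YAML mirrors the arguments of [makeStudyConfig()]; sources are
#' given as paths. Relative paths are resolved against the config file's
#' directory.
#'
#' @param path YAML file path.
#' @return A config list as from [makeStudyConfig()].
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  abs <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  y$exposure$path <- abs(y$exposure$path)
  y$outcomes <- lapply(y$outcomes, function(o) { o$path <- abs(o$path); o })
  makeStudyConfig(exposure = y$exposure, outcomes = y$outcomes,
                  ld = abs(y$ld_path), annotations = abs(y$annotation_path),
                  thresholds = y$thresholds %||% list(),
                  exclusionSets = y$exclusion_sets %||% list(),
                  estimator = y$estimator %||% list(),
                  clump = isTRUE(y$clump))
}

.loadStats <- function(src) {
  if (!is.null(src$stats)) return(src$stats)
  readSummaryStats(src$path, trait = src$label %||% "trait",
                   binary = isTRUE(src$binary))
}

.loadLD <- function(ld) {
  if (is.null(ld)) return(NULL)
  if (is(ld, "LDTable")) return(ld)
  readLDTable(ld)
}

.loadAnnotations <- function(ann) {
  if (is.null(ann)) return(NULL)
  if (is(ann, "AnnotationTable")) return(ann)
  readAnnotationTable(ann)
}

#' Run a configured study
#'
#' The full summary-statistic arm: for every outcome, harmonizes the
#' exposure instruments against the outcome sample (clumping and proxy
#' substitution as configured), runs all four estimators plus the Egger
#' pleiotropy test, flags significance at alpha_family / n_tests (flags
#' are reported, never used to suppress rows), and keeps per-stage
#' instrument counts. An outcome whose harmonization fails entirely is
#' reported and the run continues. When `outDir` is given, writes
#' `estimates.tsv`, `egger.tsv`, `harmonization.tsv`, `forest.tsv`,
#' `counts.tsv` and `run.log`. The bundle is fully regenerable from the
#' config (all randomness flows through the configured estimator seed).
#'
#' @param config a config from [makeStudyConfig()] / [readStudyConfig()].
#' @param outDir output directory, or `NULL` to skip writing.
#' @param instrumentSubset optional character vector: restrict the
#'   exposure instruments to this set before harmonization (used by
#'   sensitivity re-runs).
#' @return list with `estimates` (one block per outcome), `egger`,
#'   `harmonization`, `counts`, `threshold`, `log`.
#' @export
runStudy <- function(config, outDir = NULL, instrumentSubset = NULL) {
  stopifnot(inherits(config, "mrStudyConfig"))
  thr <- config$thresholds
  est <- config$estimator
  exposure <- .loadStats(config$exposure)
  ld <- .loadLD(config$ld)
  bon <- bonferroniThreshold(thr$alpha_family, thr$n_tests)
  logLines <- c(sprintf("exposure: %s (%d instruments)",
                        traitName(exposure), nrow(asTable(exposure))),
                sprintf("per-test significance threshold: %s (%g/%d)",
                        bon$display, thr$alpha_family, thr$n_tests))
  if (!is.null(instrumentSubset)) {
    tab <- asTable(exposure)
    removed <- setdiff(tab$SNP, instrumentSubset)
    exposure <- SummaryStats(tab[tab$SNP %in% instrumentSubset, , drop = FALSE],
                             trait = traitName(exposure),
                             binary = exposure@binary)
    if (nrow(asTable(exposure)) == 0L)
      stop("instrument subset empties the exposure set", call. = FALSE)
    logLines <- c(logLines, sprintf("instrument subset: %d removed, %d kept",
                                    length(removed), nrow(asTable(exposure))))
  }
  estimates <- list(); eggers <- list(); harms <- list(); counts <- list()
  for (oc in config$outcomes) {
    label <- oc$label %||% "outcome"
    res <- tryCatch({
      outcome <- .loadStats(oc)
      iset <- harmonizeInstruments(exposure, outcome, ld = ld,
                                   proxyR2 = thr$proxy_r2,
                                   clump = config$clump,
                                   clumpR2 = thr$clump_r2,
                                   clumpWindowBp = thr$clump_window_bp)
      all <- mrEstimateAll(iset, nBoot = est$n_boot, seed = est$seed,
                           randomEffects = isTRUE(est$random_effects),
                           penaltyScale = est$penalty_scale)
      tabE <- cbind(outcome = label, all$estimates, stringsAsFactors = FALSE)
      tabE$significant <- !is.na(tabE$p) & tabE$p < bon$threshold
      ht <- cbind(outcome = label, asTable(iset), stringsAsFactors = FALSE)
      st <- table(factor(asTable(iset)$STATUS, levels = INSTRUMENT_STATUSES))
      cnt <- data.frame(outcome = label, selected = nrow(asTable(iset)),
                        direct = as.integer(st["direct"]),
                        proxy = as.integer(st["proxy"]),
                        dropped = as.integer(st["dropped"]),
                        used = nInstruments(iset), stringsAsFactors = FALSE)
      list(est = tabE, egger = all$egger, harm = ht, cnt = cnt,
           msg = sprintf("outcome %s: %d/%d instruments used", label,
                         nInstruments(iset), nrow(asTable(iset))))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      logLines <- c(logLines,
                    sprintf("outcome %s FAILED harmonization/estimation: %s",
                            label, conditionMessage(res)))
      next
    }
    logLines <- c(logLines, res$msg)
    estimates[[label]] <- res$est
    eggers[[label]] <- res$egger
    harms[[label]] <- res$harm
    counts[[label]] <- res$cnt
  }
  eggerTab <- do.call(rbind, lapply(names(eggers), function(l) {
    e <- eggers[[l]]
    if (is.null(e)) return(NULL)
    data.frame(outcome = l, intercept = e@intercept,
               intercept_se = e@interceptSE, intercept_p = e@interceptP,
               stringsAsFactors = FALSE)
  }))
  bundle <- list(estimates = do.call(rbind, c(estimates, make.row.names = FALSE)),
                 egger = eggerTab,
                 harmonization = do.call(rbind, c(harms, make.row.names = FALSE)),
                 counts = do.call(rbind, c(counts, make.row.names = FALSE)),
                 threshold = bon, log = logLines)
  if (!is.null(outDir)) .writeBundle(bundle, outDir)
  bundle
}

.writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) if (!is.null(x))
    utils::write.table(x, file.path(outDir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(bundle$estimates, "estimates.tsv")
  wr(bundle$egger, "egger.tsv")
  wr(bundle$harmonization, "harmonization.tsv")
  wr(bundle$counts, "counts.tsv")
  if (!is.null(bundle$estimates)) {
    forest <- bundle$estimates[, c("outcome", "method", "or", "or_ci_low",
                                   "or_ci_high")]
    names(forest) <- c("label", "method", "point", "lower", "upper")
    wr(forest, "forest.tsv")
  }
  if (!is.null(bundle$grs)) wr(bundle$grs, "grs_associations.tsv")
  writeLines(bundle$log, file.path(outDir, "run.log"))
  invisible(outDir)
}

#' Sensitivity re-run after excluding annotated instruments
#'
#' Removes every instrument whose secondary-trait annotation intersects
#' the named exclusion set, re-runs the study on the remaining
#' instruments, and reports the removed variant IDs together with the
#' change in each estimate relative to the primary run. Re-running with an
#' exclusion set that matches nothing reproduces the primary bundle.
#'
#' @param config a config from [makeStudyConfig()]; `annotations` and the
#'   named `exclusionSets` entry must be present.
#' @param exclusionSet name of an entry of `config$exclusionSets`.
#' @param primary optional primary bundle (computed if omitted).
#' @param outDir optional output directory for the re-run bundle.
#' @return list(bundle, removed, delta) where `delta` has one row per
#'   outcome/method with the primary and re-run estimates and their
#'   difference.
#' @export
sensitivityRerun <- function(config, exclusionSet, primary = NULL,
                             outDir = NULL) {
  stopifnot(inherits(config, "mrStudyConfig"))
  if (!exclusionSet %in% names(config$exclusionSets))
    stop("unknown exclusion set: ", exclusionSet, call. = FALSE)
  traits <- config$exclusionSets[[exclusionSet]]
  ann <- .loadAnnotations(config$annotations)
  if (is.null(ann)) stop("config has no annotation table", call. = FALSE)
  at <- asTable(ann)
  removed <- unique(at$SNP[at$TRAIT %in% traits])
  exposure <- .loadStats(config$exposure)
  keep <- setdiff(variantIds(exposure), removed)
  if (!length(keep))
    stop("exclusion set '", exclusionSet, "' empties the instrument set",
         call. = FALSE)
  if (is.null(primary)) primary <- runStudy(config)
  bundle <- runStudy(config, outDir = outDir, instrumentSubset = keep)
  key <- c("outcome", "method")
  m <- merge(primary$estimates[, c(key, "b")],
             bundle$estimates[, c(key, "b")],
             by = key, suffixes = c("_primary", "_rerun"))
  m$delta <- m$b_rerun - m$b_primary
  list(bundle = bundle, removed = intersect(removed, variantIds(exposure)),
       delta = m)
}

#' Run the genetic-risk-score arm
#'
#' Computes per-individual scores from a weight file, fits the
#' covariate-adjusted score regression and the quartile contrasts for each
#' requested phenotype, and (optionally) writes `grs_scores.tsv`,
#' `grs_associations.tsv` and `grs_quartiles.tsv`.
#'
#' @param cohort a [Cohort-class].
#' @param weights data.frame as from [readWeights()].
#' @param phenotypes character vector of phenotype columns.
#' @param covariates character vector of covariate columns.
#' @param outDir output directory or `NULL`.
#' @return list(scores, associations, quartiles).
#' @export
runGrsAnalysis <- function(cohort, weights,
                           phenotypes, covariates = character(),
                           outDir = NULL) {
  scores <- computeScores(cohort, weights)
  assoc <- do.call(rbind, lapply(phenotypes, function(ph) {
    r <- scoreRegression(scores, cohort, ph, covariates)
    data.frame(phenotype = ph, beta = r$beta, se = r$se, p = r$p, n = r$n,
               or = r$or, or_ci_low = r$or_ci_low, or_ci_high = r$or_ci_high,
               stringsAsFactors = FALSE)
  }))
  quart <- do.call(rbind, lapply(phenotypes, function(ph)
    cbind(phenotype = ph,
          quartileContrasts(scores, cohort, ph, covariates),
          stringsAsFactors = FALSE)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(scores, file.path(outDir, "grs_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(assoc, file.path(outDir, "grs_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(quart, file.path(outDir, "grs_quartiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(scores = scores, associations = assoc, quartiles = quart)
}
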