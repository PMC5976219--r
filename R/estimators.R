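#' @include AllClasses.R AllGenerics.R
NULL

Z975 <- 1.959964 # fixed 95% normal multiplier

.pairsOf <- function(x) {
  if (is(x, "InstrumentSet")) validInstruments(x)
  else as.data.frame(x, stringsAsFactors = FALSE)
}

#' Per-instrument ratio (Wald) estimates
#'
#' For each harmonized instrument, the ratio estimate
#' theta = beta_outcome / beta_exposure with the first-order standard
#' error s = se_outcome / |beta_exposure| (the exposure-side uncertainty
#' is ignored, as is standard with strong instruments in two-sample
#' practice) and inverse-variance weight w = s^-2. Instruments with a zero
#' exposure effect are excluded with a message.
#'
#' @param x an [InstrumentSet-class] or a data.frame with columns SNP,
#'   BETA_EXP, SE_EXP, BETA_OUT, SE_OUT.
#' @return data.frame with columns SNP, THETA, S, W.
#' @export
ratioEstimates <- function(x) {
  p <- .pairsOf(x)
  zero <- p$BETA_EXP == 0
  if (any(zero)) {
    message(sum(zero), " instrument(s) excluded: zero exposure effect (",
            paste(p$SNP[zero], collapse = ", "), ")")
    p <- p[!zero, , drop = FALSE]
  }
  s <- p$SE_OUT / abs(p$BETA_EXP)
  data.frame(SNP = p$SNP, THETA = p$BETA_OUT / p$BETA_EXP, S = s, W = s^-2,
             stringsAsFactors = FALSE, row.names = NULL)
}

.normEstimate <- function(method, b, se, n) {
  .MREstimate(method, b, se, b - Z975 * se, b + Z975 * se,
              2 * stats::pnorm(-abs(b / se)), n)
}

#' Inverse-variance weighted estimator
#'
#' The conventional MR estimate: the inverse-variance weighted mean of the
#' per-instrument ratio estimates, beta = sum(w theta) / sum(w) with
#' w = s^-2, and fixed-effect standard error (sum w)^-1/2. With
#' `randomEffects = TRUE` the standard error is scaled multiplicatively by
#' max(1, sqrt(Q / (J - 1))) for J >= 2, where Q is Cochran's statistic
#' about the estimate. Identical (to numerical precision) to the slope of
#' the zero-intercept weighted regression of outcome on exposure effects
#' with weights se_outcome^-2, and to a fixed-effect inverse-variance
#' meta-analysis of the ratios.
#'
#' @param ratios data.frame from [ratioEstimates()].
#' @param randomEffects logical; apply multiplicative random-effects
#'   scaling to the standard error.
#' @return An [MREstimate-class] with `method = "ivw"`; p-value from the
#'   normal reference, 95% CI with the 1.959964 multiplier.
#' @export
mrIVW <- function(ratios, randomEffects = FALSE) {
  J <- nrow(ratios)
  if (J < 1) stop("IVW requires at least one instrument", call. = FALSE)
  b <- sum(ratios$W * ratios$THETA) / sum(ratios$W)
  se <- sqrt(1 / sum(ratios$W))
  if (randomEffects && J >= 2) {
    Q <- cochranQ(ratios, b)$Q
    se <- se * max(1, sqrt(Q / (J - 1)))
  }
  .normEstimate("ivw", b, se, J)
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum over instruments of w (theta - center)^2, with J - 1 degrees of
#' freedom and the per-instrument contributions returned in input order.
#'
#' @param ratios data.frame from [ratioEstimates()].
#' @param center value about which heterogeneity is measured (usually the
#'   IVW estimate).
#' @return list(Q, df, perInstrumentQ).
#' @export
cochranQ <- function(ratios, center) {
  if (nrow(ratios) < 1) stop("Q requires at least one instrument", call. = FALSE)
  qi <- ratios$W * (ratios$THETA - center)^2
  list(Q = sum(qi), df = nrow(ratios) - 1L, perInstrumentQ = qi)
}

# Weighted median point estimate by cumulative-midpoint interpolation.
.weightedMedianPoint <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  wn <- w[o] / sum(w[o])
  p <- cumsum(wn) - wn / 2
  hit <- which(abs(p - 0.5) < 1e-12)
  if (length(hit)) return(th[hit[1L]])
  if (p[1L] > 0.5) return(th[1L])
  J <- length(th)
  if (p[J] < 0.5) return(th[J])
  j <- max(which(p < 0.5))
  th[j] + (th[j + 1L] - th[j]) * (0.5 - p[j]) / (p[j + 1L] - p[j])
}

.bootMedianSE <- function(theta, s, w, nBoot, seed) {
  if (nBoot < 1) return(NA_real_)
  if (is.null(seed)) stop("a seed is required for the bootstrap", call. = FALSE)
  set.seed(seed)
  J <- length(theta)
  est <- vapply(seq_len(nBoot), function(b)
    .weightedMedianPoint(stats::rnorm(J, theta, s), w), numeric(1))
  stats::sd(est)
}

.medianEstimate <- function(method, b, se, J) {
  if (is.na(se))
    return(.MREstimate(method, b, NA_real_, NA_real_, NA_real_, NA_real_, J))
  .normEstimate(method, b, se, J)
}

#' Weighted median estimator
#'
#' Orders the ratio estimates, forms normalized weights and cumulative
#' weight midpoints p_j = sum(w'_k, k <= j) - w'_j / 2, and interpolates
#' the 50th weighted percentile linearly between the bracketing order
#' statistics (if some p_j equals 0.5 exactly the corresponding theta is
#' returned). Consistent when instruments carrying at least half of the
#' weight are valid. The standard error is the standard deviation of the
#' estimate over `nBoot` parametric-bootstrap replicates theta*_j ~
#' Normal(theta_j, s_j) with the weights held fixed.
#'
#' @param ratios data.frame from [ratioEstimates()]; at least 3 instruments.
#' @param nBoot bootstrap replicates (default 1000); `nBoot = 0` skips the
#'   bootstrap and returns an estimate with `NA` uncertainty (useful in
#'   simulation loops that need only the point estimate).
#' @param seed integer seed for the bootstrap (required when `nBoot >= 1`).
#' @return An [MREstimate-class] with `method = "weighted_median"`.
#' @export
mrWeightedMedian <- function(ratios, nBoot = 1000, seed = NULL) {
  if (nrow(ratios) < 3)
    stop("the weighted median requires at least 3 instruments", call. = FALSE)
  b <- .weightedMedianPoint(ratios$THETA, ratios$W)
  se <- .bootMedianSE(ratios$THETA, ratios$S, ratios$W, nBoot, seed)
  .medianEstimate("weighted_median", b, se, nrow(ratios))
}

#' Penalized weighted median estimator
#'
#' Down-weights heterogeneity outliers before taking the weighted median:
#' with theta_WM the unpenalized weighted median, each instrument's
#' one-degree-of-freedom heterogeneity q_j = w_j (theta_j - theta_WM)^2 is
#' converted to an upper-tail chi-square(1) p-value and the weight is
#' penalized as w*_j = w_j min(1, penaltyScale p_j). The estimate is the
#' weighted median under the penalized weights; concordant instruments
#' (p_j >= 1/penaltyScale) are untouched, so with no outliers the
#' estimator reduces to the plain weighted median, as it does for
#' penaltyScale -> infinity.
#'
#' @inheritParams mrWeightedMedian
#' @param penaltyScale penalization constant (default 20).
#' @return An [MREstimate-class] with `method = "penalized_weighted_median"`.
#' @export
mrPenalizedWeightedMedian <- function(ratios, nBoot = 1000, seed = NULL,
                                      penaltyScale = 20) {
  if (nrow(ratios) < 3)
    stop("the penalized weighted median requires at least 3 instruments",
         call. = FALSE)
  bWM <- .weightedMedianPoint(ratios$THETA, ratios$W)
  q <- ratios$W * (ratios$THETA - bWM)^2
  pj <- stats::pchisq(q, df = 1, lower.tail = FALSE)
  wStar <- ratios$W * pmin(1, penaltyScale * pj)
  b <- .weightedMedianPoint(ratios$THETA, wStar)
  se <- .bootMedianSE(ratios$THETA, ratios$S, wStar, nBoot, seed)
  .medianEstimate("penalized_weighted_median", b, se, nrow(ratios))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an unconstrained intercept and weights se_outcome^-2, after
#' orienting every instrument so its exposure effect is non-negative
#' (negating both effects where needed). The intercept estimates the
#' average directional pleiotropy; the slope estimates the causal effect
#' under the InSIDE assumption. Standard errors are the unscaled WLS
#' covariance multiplied by max(1, residual standard error) — residual
#' overdispersion widens them, underdispersion is not allowed to shrink
#' them — and p-values use Student's t with J - 2 degrees of freedom. The
#' slope's 95% CI uses the same t quantile.
#'
#' @param x an [InstrumentSet-class] or data.frame of harmonized pairs
#'   (columns BETA_EXP, SE_EXP, BETA_OUT, SE_OUT); at least 3 instruments.
#' @return An [EggerResult-class].
#' @export
mrEgger <- function(x) {
  p <- .pairsOf(x)
  J <- nrow(p)
  if (J < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- ifelse(p$BETA_EXP < 0, -1, 1)
  bx <- p$BETA_EXP * flip
  by <- p$BETA_OUT * flip
  if (stats::sd(bx) < 1e-12 * max(abs(bx), 1))
    stop("MR-Egger design is singular: all exposure effects equal after orientation",
         call. = FALSE)
  w <- p$SE_OUT^-2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  seU <- sqrt(diag(sm$cov.unscaled)) # unscaled WLS covariance
  se <- seU * max(1, sigma)
  est <- stats::coef(fit)
  tq <- stats::qt(0.975, df = J - 2)
  pv <- 2 * stats::pt(-abs(est / se), df = J - 2)
  slope <- .MREstimate("egger_slope", est[[2]], se[[2]],
                       est[[2]] - tq * se[[2]], est[[2]] + tq * se[[2]],
                       pv[[2]], J)
  new("EggerResult", intercept = est[[1]], interceptSE = se[[1]],
      interceptP = pv[[1]], slope = slope, sigma = sigma)
}

#' All estimators for one harmonized instrument set
#'
#' Runs the inverse-variance weighted, weighted median, penalized weighted
#' median and MR-Egger estimators on the non-dropped pairs and assembles a
#' results table with one row per method on both the log and exponentiated
#' scales, plus Cochran's Q about the IVW estimate. With fewer than 3
#' instruments only IVW is defined; the median and Egger rows are reported
#' as not estimable.
#'
#' @param x an [InstrumentSet-class].
#' @param nBoot,seed bootstrap control for the median estimators.
#' @param randomEffects logical, passed to [mrIVW()].
#' @param penaltyScale passed to [mrPenalizedWeightedMedian()].
#' @return list with `estimates` (data.frame: method, b, se, ci_low,
#'   ci_high, p, or, or_ci_low, or_ci_high, n_instruments, note), `egger`
#'   (an [EggerResult-class] or `NULL`), and `Q` (list from [cochranQ()]).
#' @export
mrEstimateAll <- function(x, nBoot = 1000, seed = 1, randomEffects = FALSE,
                          penaltyScale = 20) {
  ratios <- ratioEstimates(x)
  J <- nrow(ratios)
  ivw <- mrIVW(ratios, randomEffects = randomEffects)
  Q <- cochranQ(ratios, betaHat(ivw))
  naRow <- function(method)
    data.frame(method = method, b = NA_real_, se = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
               or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
               n_instruments = J, note = "not estimable (fewer than 3 instruments)",
               stringsAsFactors = FALSE)
  okRow <- function(est) cbind(asTable(est), note = "", stringsAsFactors = FALSE)
  if (J >= 3) {
    wm <- mrWeightedMedian(ratios, nBoot = nBoot, seed = seed)
    pwm <- mrPenalizedWeightedMedian(ratios, nBoot = nBoot, seed = seed,
                                     penaltyScale = penaltyScale)
    egger <- mrEgger(x)
    estimates <- rbind(okRow(ivw), okRow(wm), okRow(pwm), okRow(egger@slope))
  } else {
    egger <- NULL
    estimates <- rbind(okRow(ivw), naRow("weighted_median"),
                       naRow("penalized_weighted_median"), naRow("egger_slope"))
  }
  rownames(estimates) <- NULL
  list(estimates = estimates, egger = egger, Q = Q)
}
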