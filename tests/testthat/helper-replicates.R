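# Replicate runner for simulation studies: regenerates a full synthetic
# two-sample study per replicate, runs harmonization and the estimators
# through the package's public surface, and collects per-replicate results.
# Bootstrap SEs are skipped (nBoot = 0): the replicate studies need point
# estimates and analytic IVW/Egger uncertainty only.
mrReplicates <- function(scenario, R, seedBase, egger = FALSE) {
  out <- vector("list", R)
  for (r in seq_len(R)) {
    sc <- scenario
    sc@seed <- as.integer(seedBase + r)
    st <- suppressMessages(simulateStudy(sc, includeCohort = FALSE))
    iset <- suppressMessages(
      harmonizeInstruments(st$exposureStats, st$outcomeStats, ld = st$ld))
    ratios <- suppressMessages(ratioEstimates(iset))
    ivw <- mrIVW(ratios)
    ci <- confInt(ivw)
    row <- data.frame(
      ivw = betaHat(ivw), ivw_se = stdError(ivw), ivw_p = pValue(ivw),
      ivw_lo = ci[1], ivw_hi = ci[2],
      wm = betaHat(mrWeightedMedian(ratios, nBoot = 0)),
      pwm = betaHat(mrPenalizedWeightedMedian(ratios, nBoot = 0)))
    if (egger) {
      e <- mrEgger(iset)
      J <- nInstruments(iset)
      tq <- qt(0.975, df = J - 2)
      row$egger_int <- e@intercept
      row$egger_int_p <- e@interceptP
      row$egger_int_lo <- e@intercept - tq * e@interceptSE
      row$egger_int_hi <- e@intercept + tq * e@interceptSE
      row$egger_slope <- betaHat(e@slope)
    }
    out[[r]] <- row
  }
  do.call(rbind, out)
}
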