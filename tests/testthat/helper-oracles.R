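# Independent oracles, kept deliberately separate from the package's
# implementation paths.

# Checks that a retained set is exactly the greedy clumping solution by
# its defining properties: (1) validity - no retained pair on one
# chromosome within the window has known r2 above the threshold;
# (2) maximality - every removed variant conflicts with a retained variant
# of strictly better priority; (3) retention order follows priority.
# These three properties characterize the greedy output uniquely.
clumpOracleCheck <- function(retained, tab, ld, r2Max, windowBp) {
  prio <- order(tab$P, tab$BP, tab$SNP)
  ranked <- tab$SNP[prio]
  rank <- match(tab$SNP, ranked)
  names(rank) <- tab$SNP
  conflict <- function(a, b) {
    ia <- match(a, tab$SNP); ib <- match(b, tab$SNP)
    if (tab$CHR[ia] != tab$CHR[ib]) return(FALSE)
    if (abs(tab$BP[ia] - tab$BP[ib]) > windowBp) return(FALSE)
    r2 <- ldR2(ld, a, b)
    !is.na(r2) && r2 > r2Max
  }
  for (a in retained) for (b in retained)
    if (a != b && conflict(a, b)) return("retained pair in conflict")
  for (d in setdiff(tab$SNP, retained)) {
    hit <- any(vapply(retained, function(r)
      rank[r] < rank[d] && conflict(r, d), logical(1)))
    if (!hit) return(paste("variant removed without a better-ranked cause:", d))
  }
  if (is.unsorted(rank[retained])) return("retention order violates priority")
  TRUE
}

# Fine-grid weighted-CDF oracle for the weighted median: interpolates the
# cumulative-midpoint CDF on a dense grid of candidate values and refines
# around the crossing of 0.5.
wmGridOracle <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  wn <- w[o] / sum(w[o])
  p <- cumsum(wn) - wn / 2
  if (p[1] >= 0.5) return(th[1])
  if (p[length(p)] <= 0.5) return(th[length(th)])
  searchGrid <- function(lo, hi, k = 20001L) {
    ts <- seq(lo, hi, length.out = k)
    Fv <- approx(th, p, xout = ts, ties = "ordered")$y
    ts[which.min(abs(Fv - 0.5))]
  }
  t1 <- searchGrid(min(th), max(th))
  dt <- (max(th) - min(th)) / 20000
  searchGrid(t1 - dt, t1 + dt)
}

# Truth table for two-allele orientation: expected multiplier applied to
# the outcome effect for every reconcilable configuration, built by hand
# from the strand/swap rules rather than by calling the implementation.
orientationCases <- function() {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  base <- list(c("A", "G"), c("C", "T"), c("G", "C"), c("A", "T"))
  cases <- list()
  for (al in base) {
    ea <- al[1]; oa <- al[2]
    pal <- comp[[ea]] == oa
    cases[[length(cases) + 1]] <- list(
      expEA = ea, expOA = oa, outEA = ea, outOA = oa,
      flip = 1, palindromic = pal, label = "same")
    cases[[length(cases) + 1]] <- list(
      expEA = ea, expOA = oa, outEA = oa, outOA = ea,
      flip = -1, palindromic = pal, label = "swapped")
    if (!pal) {
      cases[[length(cases) + 1]] <- list(
        expEA = ea, expOA = oa, outEA = comp[[ea]], outOA = comp[[oa]],
        flip = 1, palindromic = FALSE, label = "complement")
      cases[[length(cases) + 1]] <- list(
        expEA = ea, expOA = oa, outEA = comp[[oa]], outOA = comp[[ea]],
        flip = -1, palindromic = FALSE, label = "complement_swapped")
    }
  }
  cases
}
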