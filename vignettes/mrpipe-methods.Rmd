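---
title: "Methods: two-sample Mendelian randomization in mrpipe"
author: "mrpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The causal model

mrpipe implements the two-sample summary-statistic design used to ask
whether a cardiometabolic exposure (the motivating application is type 2
diabetes) causally affects cerebrovascular outcomes such as lacunar
stroke, intracerebral hemorrhage, white matter hyperintensity volume, and
diffusion-tensor measures of white matter microstructure. Genetic
variants robustly associated with the exposure serve as instrumental
variables: alleles are randomized at meiosis, so variant-outcome
associations are protected from the confounding and reverse causation
that afflict observational contrasts.

For instrument $j$, let $(\hat\beta_{Xj}, \sigma_{Xj})$ be its estimated
association with the exposure in one sample and
$(\hat\beta_{Yj}, \sigma_{Yj})$ its association with the outcome in a
second, non-overlapping sample. Under the instrumental-variable
assumptions each variant supplies a ratio (Wald) estimate of the causal
effect $\beta$:

$$\hat\theta_j = \frac{\hat\beta_{Yj}}{\hat\beta_{Xj}}, \qquad
  s_j = \frac{\sigma_{Yj}}{|\hat\beta_{Xj}|}, \qquad w_j = s_j^{-2}.$$

The standard error is first order: the exposure-side uncertainty
$\sigma_{Xj}$ is ignored in $s_j$, as is standard two-sample practice
with strong instruments. This choice is stated explicitly so that every
number the package produces is reproducible from the formulas here.

## Estimators

**Inverse-variance weighted (IVW).** The headline estimate is the
fixed-effect inverse-variance weighted mean
$\hat\beta = \sum_j w_j \hat\theta_j / \sum_j w_j$ with
$\mathrm{se} = (\sum_j w_j)^{-1/2}$. This is algebraically identical to
the zero-intercept weighted regression of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ with weights $\sigma_{Yj}^{-2}$, and to a fixed-effect
meta-analysis of the ratios; the test suite verifies the three routes
agree to $10^{-10}$. A multiplicative random-effects option scales the
standard error by $\max(1, \sqrt{Q/(J-1)})$, where
$Q = \sum_j w_j (\hat\theta_j - \hat\beta)^2$ is Cochran's
heterogeneity statistic.

**Weighted median.** Order the ratios
$\hat\theta_{(1)} \le \dots \le \hat\theta_{(J)}$, normalize the weights,
and form cumulative midpoints $p_j = \sum_{k \le j} w'_k - w'_j/2$. The
estimate interpolates linearly between the order statistics bracketing
$p = 0.5$ (taking $\hat\theta_{(j)}$ exactly when some $p_j = 0.5$). It
is consistent whenever instruments carrying at least half of the total
weight are valid. Its standard error is the SD of the estimate over
parametric-bootstrap replicates
$\theta^*_j \sim N(\hat\theta_j, s_j)$ with weights held fixed
(default 1000 replicates; the seed is a required input, so results are
reproducible by construction).

**Penalized weighted median.** Each instrument's one-degree-of-freedom
heterogeneity $q_j = w_j(\hat\theta_j - \hat\theta_{WM})^2$ about the
unpenalized weighted median is converted to an upper-tail
$\chi^2_1$ p-value and the weight is penalized as
$w^*_j = w_j \min(1, 20\, p_j)$. Concordant instruments
($p_j \ge 1/20$) are untouched, so the estimator reduces to the plain
weighted median when there are no outliers, and for penalty scale
$\to \infty$. The constant 20 is the conventional choice for this
construction.

**MR-Egger.** Weighted least squares of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ with an unconstrained intercept and weights
$\sigma_{Yj}^{-2}$, after orienting every instrument so its exposure
effect is non-negative. The intercept estimates average directional
pleiotropy — its deviation from zero is the pleiotropy test — and the
slope estimates $\beta$ under the InSIDE condition (instrument strength
independent of direct effects). Standard errors multiply the unscaled
WLS covariance by $\max(1, \hat\sigma)$: overdispersion from pleiotropy
widens them, but a fortuitously small residual is not allowed to shrink
them below the weighting model. Egger p-values and the slope CI use
Student's t with $J-2$ degrees of freedom; IVW and median p-values use
the normal reference, with the 95% multiplier fixed at 1.959964. These
reference-distribution choices follow the originating methods'
conventions and are stated because they are easy to get silently wrong.

For binary outcomes the estimates are log odds ratios and the
exponentiated column is an odds ratio. For continuous outcomes
(white matter hyperintensity volume, FA, MD) the package reports the raw
linear estimate and its exponential side by side, labeled, without
asserting an odds interpretation — published tables in this literature
print ORs for continuous imaging traits without stating the transform,
so both scales are kept visible. An optional log/z-score transform of
individual-level phenotypes is exposed for the same reason.

## Harmonization

Instruments are harmonized to the exposure effect allele before
estimation:

* matching allele pairs are copied; swapped pairs negate the outcome
  effect and reflect the frequency;
* strand complements (A&#8596;T, C&#8596;G) are resolved by complementing
  and re-applying the rules;
* palindromic variants (A/T, G/C) cannot be resolved from allele letters;
  they are oriented by effect-allele frequency when both frequencies lie
  outside [0.42, 0.58] — the conventional ambiguity zone, configurable —
  and otherwise dropped as ambiguous;
* instruments missing from the outcome sample receive the available
  proxy with the highest linkage $r^2$ strictly above 0.7, ties broken
  by smaller distance and then lexicographic ID;
* instrument independence is enforced by greedy clumping: rank by
  p-value (ties: position, then ID), retain the best remaining variant,
  and remove variants on the same chromosome within 100 kb whose $r^2$
  with it strictly exceeds 0.1.

Both thresholds are deliberately strict inequalities, matching how such
cutoffs are conventionally printed ($r^2 > 0.7$ admits a proxy,
$r^2 > 0.1$ removes a neighbor). The window is measured between variant
positions (the PLINK convention). A pair absent from the LD table is
"no data", which clumping treats as $r^2 = 0$ with a warning — a sparse
LD table must not stall the procedure — while proxy search treats it as
inadmissible. Dropped candidates stay in the instrument table with their
reason, so selected = retained + dropped holds at every stage.

A proxy's outcome association is used as recorded, on the assumption
that the LD table orientation tags the exposure effect allele; the
synthetic generator guarantees this, and resolving real-data proxy
phase from reference haplotypes is out of scope.

## The genetic risk score arm

The individual-level arm mirrors the confirmatory analysis style used
with biobank imaging data. Per-individual scores are
$S_i = \sum_j \ln(\mathrm{OR}_j) G_{ij}$ with dosages aligned to each
weight's effect allele (columns counting the opposite allele enter as
$2-G$). Missing dosages are mean-imputed as $2 \times$ EAF (weight file)
or the cohort mean — the standard choice that preserves the score's
expectation — and imputations are counted. Associations with continuous
imaging phenotypes use ordinary least squares with the conventional
covariate set (genotyping batch, age, sex, BMI, blood pressure, ancestry
principal components); quartile contrasts use indicator regression with
quartile 1 as reference. Quartiles come from type-7 empirical quantiles
with ties assigned to the lower quartile; the quantile rule is stated
because published reports typically do not state one. Diffusion
phenotypes can be derived as the first principal component of 48
standard-space tract means: columns are standardized, the correlation
matrix eigendecomposed, the loading sign fixed so the loading sum is
positive, and the projection rescaled to unit variance.

## The synthetic-data generator

No consortium GWAS or biobank data can ship with the package, so every
pipeline stage is validated on synthetic studies with known ground
truth. The generator draws, per study: allele frequencies
$f_j \sim U(0.1, 0.5)$; diploid genotypes $G_{ij} \sim \mathrm{Bin}(2,
f_j)$; LD blocks by haplotype copying (a member variant copies the block
anchor's allele with probability $q = \sqrt{r^2_{\mathrm{target}}}$, so
the anchor-member dosage $r^2$ hits the target and member-member pairs
sit at the square of it; copying requires matched frequencies within a
block, which the generator enforces). Traits follow

$$X = \textstyle\sum_j \gamma_j G_j + c_U U + \varepsilon_X, \qquad
  Y = \beta X + \textstyle\sum_{j \in \mathrm{invalid}} \alpha_j G_j
      + c_U U + \varepsilon_Y,$$

with $U$ a shared standard-normal confounder ($c_U = 0.3$ by default
— confounding robustness is the reason MR exists, so the generator must
include it), instrument effects scaled so the instruments jointly
explain `h2Exposure` of the unit exposure variance, and direct effects
$\alpha_j$ drawn independently of $\gamma_j$ (InSIDE holds by
construction in both pleiotropy modes). Binary traits threshold the
liability at its empirical case-fraction quantile, and their per-variant
summary statistics use the logistic score-test approximation, matching
case-control GWAS convention. Two-sample separation is by construction:
exposure, outcome and cohort samples are generated independently with
disjoint individual IDs.

Two generator design points deserve emphasis:

* **Instrument strengths are bounded away from zero.** Per-variant
  explained-variance shares are drawn $U(0.1, 1.9)$ and normalized to
  sum to the target heritability, rather than squaring Gaussian draws.
  A half-normal effect distribution puts substantial mass at zero —
  instruments that could never have reached genome-wide significance in
  the exposure scan the generator emulates — and near-zero effects make
  sign-orientation pathological: an estimated exposure effect that flips
  sign converts directional pleiotropy into balanced pleiotropy and
  biases the Egger slope.
* **Effect alleles are coded exposure-increasing** ($\gamma_j \ge 0$),
  exactly as curated instrument and weight files are published
  (risk-allele ORs above 1). Directional pleiotropy is only meaningful
  relative to this coding.

### Presets and their design rationale

Presets fix the standard validation designs; defaults are the study
conditions, not tuning knobs. The 84-instrument default with
`h2Exposure = 0.075` reflects an instrument panel jointly explaining
5–10% of exposure variance; the default causal effect 0.14 is a log
odds ratio of about 1.15, the magnitude typical of the motivating
application.

| preset | design | purpose |
|---|---|---|
| `null` | $\beta=0$, no pleiotropy, n = 10k/10k | type-I error |
| `causal_valid` | $\beta=0.14$, 84 valid instruments, n = 50k/50k | recovery, coverage |
| `balanced_pleiotropy` | $\alpha \sim N(0, 0.02)$ on half the instruments, n = 10k | Egger intercept coverage |
| `directional_pleiotropy_inside` | $\alpha \sim N(0.05, 0.01)$ on 90%, $\beta=0$, n = 50k | Egger intercept power, slope validity |
| `median_robust` | $\alpha \sim N(0.1, 0.02)$ on 30%, $\beta=0.14$, n = 10k | median vs IVW under invalid instruments |
| `clump_test` | 8 LD blocks of 3, anchor $r^2 = 0.64$ | clumping, proxy search |

The pleiotropy magnitudes were fixed by an a-priori power design before
any validation run: the directional preset sets the mean direct effect
and invalid fraction so the expected intercept is several intercept
standard errors from zero (a mixed valid/invalid set inflates the
residual variance and hence — through the $\max(1,\hat\sigma)$ scaling —
the intercept standard error, which is why the directional preset loads
pleiotropy on 90% of instruments rather than half), while the balanced
preset keeps $\tau$ comparable to the outcome-side standard errors so
the multiplicative overdispersion model remains a good approximation
and intercept coverage stays near nominal. The directional preset sets
$\beta = 0$ so that the Egger slope check isolates pleiotropy-induced
bias from finite-sample attenuation. The median-robust preset places
strong directional effects on 30% of instruments — safely below the
weighted median's half-weight validity bound while far exceeding IVW's
tolerance.

### What the generator does not emulate

Realistic human LD maps, population stratification, relatedness,
genotyping and imputation error, sample overlap between the two GWAS,
winner's curse in instrument selection, and assortative mating are all
absent. Passing the validation suite therefore demonstrates that the
estimators and plumbing are correct under the stated causal model, not
that real-data analyses are immune to those additional failure modes.

## Numerical choices and degenerate inputs

* Ties in clumping rank break by position then variant ID; proxy ties by
  distance then ID — all orderings are total, so results are
  deterministic.
* The weighted-median interpolation clamps to the extreme order
  statistic when $p=0.5$ falls outside the midpoint range (possible when
  one instrument carries over half the weight).
* MR-Egger refuses singular designs (all exposure effects equal after
  orientation) and fewer than 3 instruments; the medians refuse fewer
  than 3; IVW accepts a single instrument and then returns its ratio
  estimate unchanged.
* Instruments with an exactly zero exposure effect are excluded from
  ratio estimation with a message.
* Monomorphic variants yield flagged records with missing effect rather
  than disappearing; parsers report accepted and rejected row counts so
  rows are never silently dropped.
* An exactly collinear covariate set is an error naming the aliased
  columns; quartile contrasts report which quartile collapsed under
  ties.
* P-values are clamped to the open-closed unit interval at the smallest
  positive double to keep downstream validity checks meaningful in
  noiseless constructions.

## Validation suite problem sizes

The statistical checks in `tests/testthat/test-acceptance.R` use, as the
package's chosen validation scales: 500 replicates of `causal_valid`
(recovery and coverage), 2000 of `null` (type-I error), 150 of the
directional and 400 of the balanced pleiotropy presets, 500 of
`median_robust`, 200 random instances each for the clumping and
weighted-median oracles, and 100 random instrument sets for the IVW
route-equivalence check. `scripts/acceptance.R` recomputes the same
operating characteristics at reduced replicate counts (150/400/100/200/
150) and writes them as JSON.

## Known limitations

* **Finite-sample IVW attenuation.** With instrument effects estimated
  in a finite exposure sample, two-sample IVW is attenuated toward the
  null by approximately $h^2 / (h^2 + J/n_{\mathrm{exp}})$ — about 2%
  under the 84-instrument, $h^2 = 0.075$, $n = 50000$ design. The
  recovery study resolves this bias (it exceeds the Monte-Carlo
  uncertainty of the replicate mean at the validation scale), and the
  package makes no correction for it: the estimators are implemented as
  the field defines them. CI coverage is essentially unaffected at these
  instrument strengths.
* First-order ratio standard errors understate uncertainty when
  instruments are weak; the package does not implement second-order or
  exact ratio intervals.
* Proxy substitution assumes the LD table's allele orientation; it does
  not phase proxies from reference haplotypes.
* The estimators assume uncorrelated instruments; clumping enforces this
  only as well as the supplied LD table allows.
* MR-PRESSO-style outlier removal, mode-based estimators and
  multivariable MR are intentionally out of scope.
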