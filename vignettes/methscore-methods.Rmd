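---
title: "Polyepigenetic methylation scores: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyepigenetic methylation scores: models, simulation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscore)
```

## The score

A polyepigenetic methylation score summarizes an exposure's footprint on
the blood methylome in a single number per person. Given a weight table
$\{(i, w_i)\}$ of CpG probes with effect sizes from an external EWAS
meta-analysis, and beta values $\beta_{is} \in [0,1]$ (fraction of
methylated signal at probe $i$ in sample $s$), the raw score is the
unweighted arithmetic mean of the products,

$$ S_s = \frac{1}{|P_s|} \sum_{i \in P_s} w_i \, \beta_{is}, $$

where $P_s$ is the set of weight-table probes present and non-missing
for sample $s$. Scores are then standardized to mean 0, SD 1 within the
cohort, so all downstream effects are reported in cohort SD units. Two
consequences of this construction are worth stating explicitly:

* **Scale immateriality.** Whether betas are stored as fractions or as
  percentages only rescales every raw score by the same constant, which
  standardization removes. `meth_score()` therefore operates on
  fractions and accepts percent-scale input via
  `as_beta_matrix(x, scale = "percent")`; the two give bit-identical
  z-scores (a tested invariant).
* **Averaging convention.** The raw score is the plain mean of the
  products — there is no normalization by $\sum_i |w_i|$. Since any
  fixed rescaling of the weights is likewise absorbed by
  standardization, this choice only matters for the (rarely used) raw
  scale.

**Missingness policy.** Probes absent from the matrix or missing for a
sample are dropped from that sample's average and the denominator
shrinks accordingly; per-sample coverage (fraction of weight-table
probes used) is recorded. The default `min_coverage = 0.95` warns (and
optionally drops); coverage below 0.5 is an error, on the view that a
score computed from fewer than half of its intended probes is a
different measure. These thresholds are package policy — sensible but
not canonical, hence configurable.

## What the synthetic cohorts emulate

None of the cohort datasets this kind of score is validated on are
publicly deposited, so the package ships a seeded generator whose
defaults encode the published statistical structure of two cohorts: a
middle-aged birth cohort assayed at two waves (ages 26 and 38; 405
never-, 233 former-, 165 current-smokers at the second wave) and a
young-adult twin cohort (1116 pairs, 56% MZ). The generative direction
is *latent score first*:

1. A latent "true" score is built from the smoking phenotype: group
   offsets of 0.45 (former) and 1.65 (current) cohort-SD units, plus a
   0.07 SD/pack-year slope applied to mean-centered pack-years within
   ever-smokers. Residual variance is set to make the latent score's
   total variance exactly 1, so configured effects are genuinely in
   cohort SD units. Configurations whose structural variance already
   exceeds 1 are rejected.
2. Pack-years are drawn from the published ever-smoker distribution
   (mean 11.71, SD 8.65, clipped to [0.05, 38.75]) *identically for
   former and current smokers*. Real cohorts show correlated status and
   dose; making the two paths orthogonal is a deliberate
   simplification so that the marginal group contrasts and the
   dose-response slope are separately identifiable at their configured
   values — the recovery tests depend on it.
3. Probe-level betas are produced by a logistic squash,
   $\beta_{is} = \mathrm{logit}^{-1}(\mathrm{logit}(b_{0i}) + \lambda
   w_i T_s + \varepsilon_{is})$, with per-probe baselines $b_{0i} \sim
   U(0.1, 0.9)$, gain $\lambda = 4$, and probe noise SD 0.15. With
   synthetic weights $w_i \sim N(0, 0.05^2)$ this yields beta shifts of
   roughly 5–10 percentage points across the latent range — the
   magnitude reported for smoking-sensitive 450K probes — and keeps
   every beta strictly inside $(0,1)$. Because each probe's
   contribution $w_i \beta_{is}$ is monotone in $T_s$ regardless of the
   sign of $w_i$, the weighted-mean estimator is monotone in the
   latent score, and for realistic probe counts (hundreds and up) the
   correlation between measured and latent score exceeds 0.999.

**Two waves.** In two-wave mode, baseline current-smokers split into
quitters (fraction 0.25) and continuing smokers; the latter add
pack-years (mean 10, SD 4) and their latent score rises by 0.05 SD per
added pack-year, while quitters' scores recover by −0.25 SD. Nicotine
dependence is a thresholded liability (correlation 0.5 with cumulative
pack-years) defined for persistent smokers; patterns dependent at wave
2 only or at both waves receive a direct +0.35 SD change beyond what
their added pack-years mediate, mirroring the covariate-adjusted
contrasts the score is meant to detect.

**Twins.** The score propensity and pack-years each follow the
classical biometric ACE model (MZ pairs correlate $a^2+c^2$, DZ pairs
$a^2/2+c^2$), with defaults $a^2,c^2,e^2 = 0.709, 0.160, 0.131$ for
the score and $0.485, 0.160, 0.355$ for pack-years. The two traits are
coupled by cross-paths on the additive-genetic and unique-environment
components, solved in closed form so that the within-twin-pair
regression of score on pack-years equals 0.09 in MZ pairs and 0.18
pooled, while the score's total variance fractions stay at their
configured values. This reproduces the qualitative signature of a
partly genetically confounded, partly causal exposure effect: the
within-pair slope shrinks — but does not vanish — when only MZ pairs
are used. Pack-years in the twin cohort are a Gaussian latent on the
young-adult scale (mean 2.04, SD 1.76) and are deliberately *not*
truncated at zero, so the configured linear slopes hold exactly; the
small negative tail is the price of that exactness.

**Adversity mediation.** The confounding demonstration cohort (n =
800; 1000 probes, 100 of them smoking-sensitive) generates an
adversity count (sum of ten binary categories, mean 2), pack-years
rising 1.5 per adversity unit (residual SD 5), and betas responding to
pack-years only. These values were fixed by an a priori power
computation: they give marginal adversity-probe correlations around
0.25 at n = 800, far past the Bonferroni threshold
($0.05/1000$), so the unadjusted EWAS reliably finds hits, while
conditional independence guarantees adjusted associations are null by
construction. A `direct_adversity_slope` switch adds a true direct
epigenetic effect of adversity for studying incomplete attenuation.

## What passing tests do and do not show

The generator produces exchangeable Gaussian-latent structure with
independent probe noise. It does not emulate batch effects, cell-type
composition shifts, probe cross-reactivity, island/shore annotation
structure, age trends, or the status-dose correlation of real cohorts.
Recovery of configured effects here therefore validates the
*estimators and their inferential calibration*, not robustness to the
artefacts real methylation data carry — those require the upstream QC
and normalization this package explicitly does not do.

One measurement property of real scores *is* reproduced and worth
knowing: because betas are bounded, heavy smokers sit on flatter parts
of the logistic response, and change-score contrasts estimated through
the measured score are attenuated by a few percent relative to the
latent truth (about 3% for the quit-recovery contrast, up to ~9% for
the dependence contrasts at the default gain). The operation-level
coverage tests therefore run on record-level constructions, and the
full-pipeline tests assert pattern and near-recovery rather than exact
nominal coverage.

## Statistical analyses and their conventions

* **Contrasts, slopes, mean changes**: linear models with Wald CIs
  using normal quantiles, two-sided $\alpha = 0.05$ throughout.
  Cluster-robust (sandwich) standard errors are available everywhere a
  family/pair structure exists and are always used for the
  between/within twin decomposition.
* **AUC**: midrank Mann-Whitney ($P(\text{case} > \text{control}) +
  \tfrac12 P(\text{tie})$) with a DeLong placement-variance CI; ties
  take the midrank convention; invariant under monotone transforms.
  The test suite checks exact equality against brute-force pair
  counting and against an independent ROC implementation.
* **GEE**: Gaussian identity link with an exchangeable working
  correlation by default (the natural choice for twin pairs);
  independence is available and reproduces OLS point estimates exactly
  (a tested identity). Robust sandwich SEs are always reported. The
  estimating equations are iterated to a $10^{-10}$ coefficient
  tolerance; the working correlation is clamped to $(-0.99, 0.99)$.
* **Twin ICC**: double-entry Pearson correlation (each pair enters in
  both orders), the convention in twin methylation work; it is
  symmetric under twin order by construction. The Fisher-z CI uses the
  number of *pairs* as the effective sample size, a conservative
  choice given the duplicated entries.
* **ACE**: Falconer's closed form ($a^2 = 2(r_{MZ}-r_{DZ})$,
  $c^2 = 2r_{DZ}-r_{MZ}$, $e^2 = 1-r_{MZ}$) with truncation at zero
  and renormalization, always flagged; and a maximum-likelihood fit of
  the joint bivariate-normal pair likelihood with the phenotype
  standardized internally and means/variances fixed at 0/1 (the
  O(1/n) cost of ignoring their estimation is far below the reported
  precision). The ML parameterization is a softmax over
  $(a^2, c^2, e^2)$, which enforces non-negativity and unit sum
  without constrained optimization; CIs are profile-likelihood
  intervals found by bisection on each side, and boundary solutions
  are flagged. Asymptotic agreement with Falconer at the realized
  correlations is a tested property.
* **Between/within decomposition**: outcome regressed jointly on the
  pair mean and the within-pair deviation of the predictor. The
  deviation is orthogonal to the pair mean by construction, so for
  complete MZ pairs the within coefficient equals the through-origin
  regression of pair differences — tested as an exact identity.
* **EWAS**: per-probe OLS of beta on exposure (plus covariates)
  computed in one multi-response least-squares pass over a shared
  design; classical t p-values, or normal-based with cluster-robust
  (CR0) SEs when a cluster id is supplied. Betas are modeled
  untransformed; zero-variance probes are dropped with a log message.
  Family-wise significance is Bonferroni $\alpha/\text{(probes
  tested)}$ by default. A single-probe run equals the standalone
  `lm()` fit exactly (tested).
* **Correlation screen**: Pearson by default (Spearman optional) per
  (probe, probeset) pair within each stratum; the per-test threshold
  is the *exact* quotient $\alpha / (n_{\text{probes}} \times
  n_{\text{probesets}})$, rounded to 3 significant figures only for
  display. Joint significance requires clearing the threshold in both
  strata, and is monotone in $\alpha$ (tested).
* **cis/trans**: a pair is cis iff same chromosome and
  $|\text{probe} - \text{gene start}| \le$ 250,000 bp, boundary
  inclusive, coordinates 1-based; distances are signed with negative
  meaning upstream of the start; missing coordinates yield "unknown"
  rather than a guess.
* **Sensitivity analysis**: partial correlations by
  residual-on-residual; pairs whose probe is collinear with the
  covariate are skipped and recorded. Agreement between adjusted and
  unadjusted coefficient vectors is summarized by Spearman's rho.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the estimators at reduced
probe counts (typically 250–500 probes instead of 2623) and at the
published sample sizes; at these probe counts the measured score
correlates with the latent score above 0.999, so recovery behavior is
indistinguishable from the full panel while simulation stays light.
ML ACE recovery uses 2000 + 2000 pairs; coverage checks use 100
seeds. The parser and the screen arithmetic are exercised at the full
reference sizes (2623 weights; 2623 x 143 = 375,089 tests).

## Known limitations

* The generator's phenotype model is Gaussian-latent and linear; it
  cannot probe robustness to skewed exposures, zero-inflated
  pack-years, or nonlinear dose-response.
* `ml_ace_fit` fits the standardized ACE model only — no ADE, sex
  limitation, or covariates inside the likelihood.
* The GEE implementation covers the Gaussian identity case with
  exchangeable/independence structures, which is what family-clustered
  score analyses need; it is not a general GEE engine.
* Scores are constructed and validated for whole-blood 450K-style
  beta matrices; nothing here addresses cross-tissue transfer, probe
  QC, or normalization.

## A worked example

```{r example}
weights <- read_weight_table(
  system.file("extdata", "synthetic_weights_example.csv",
              package = "methscore"))
betas <- read_beta_matrix(
  system.file("extdata", "synthetic_betas_example.tsv",
              package = "methscore"))
scores <- meth_score(betas, weights)
scores

pheno <- read.delim(
  system.file("extdata", "synthetic_phenotype_example.tsv",
              package = "methscore"))
group_contrast(scores$z_score, pheno$smoking_status)
```
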