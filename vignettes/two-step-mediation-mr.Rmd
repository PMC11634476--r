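---
title: "Two-sample and two-step mediation Mendelian randomization with mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample and two-step mediation Mendelian randomization with mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for a modifiable exposure. In the two-sample summary-data
setting, each instrument $j$ contributes an estimated SNP–exposure effect
$\hat\gamma_j$ (standard error $\sigma_{\gamma j}$) from one GWAS and an
estimated SNP–outcome effect $\hat\Gamma_j$ ($\sigma_{\Gamma j}$) from a
second, non-overlapping GWAS. Under the instrumental-variable assumptions
(relevance, independence, and no pathway to the outcome other than the
exposure), each instrument identifies the same causal effect
$\beta = \Gamma_j / \gamma_j$.

`mrmediate` implements the standard closed-form estimators on a set of
harmonized instruments:

* **Wald ratio** (single instrument): $\hat\beta = \hat\Gamma/\hat\gamma$,
  $\mathrm{se} = \sigma_\Gamma/|\hat\gamma|$. First-order only — no
  correction for exposure-side measurement error (the "NOME"
  approximation); this is a documented limitation, mild when instruments
  are strong.
* **IVW**: weighted regression of $\hat\Gamma_j$ on $\hat\gamma_j$ through
  the origin with weights $w_j = 1/\sigma_{\Gamma j}^2$,
  $\hat\beta = \sum w_j \hat\gamma_j \hat\Gamma_j \big/ \sum w_j
  \hat\gamma_j^2$. The fixed-effect SE is
  $(\sum w_j \hat\gamma_j^2)^{-1/2}$; the default random-effects mode
  multiplies it by $\max\{1, \sqrt{Q/(J-1)}\}$, a multiplicative
  overdispersion that never shrinks below the fixed-effect SE.
* **MR-Egger**: the same weighted regression with a free intercept, after
  orienting every instrument so $\hat\gamma_j \ge 0$ (negating both
  effects where needed — the fit depends on this convention, so it is
  fixed rather than left to the caller). A non-zero intercept indicates
  directional horizontal pleiotropy; coefficient SEs carry the analogous
  $\max\{1, \sqrt{Q/(J-2)}\}$ inflation.
* **Cochran's Q**: the weighted residual sum of squares around either
  fit, referred to $\chi^2_{J-1}$ (IVW) or $\chi^2_{J-2}$ (Egger).

All confidence intervals and p-values use normal quantiles
($z_{0.975} = 1.959964$), matching conventional summary-data MR output;
with the modest instrument counts typical of drug-target MR this is
slightly anticonservative relative to a t reference, which is visible in
(and bounded by) the calibration checks below.

## Instrument selection

Instruments are selected by a strict association threshold
(`pval < p_threshold`, default $10^{-4}$ — a permissive threshold of the
kind used for eQTL-anchored drug-target instruments), pruned by greedy LD
clumping (retain the best remaining p-value, remove neighbours on the
same chromosome within 250 kb with $r^2 > 0.8$, repeat; ties broken by
variant id so the result is order-independent), and screened for weak
instruments by $F_j = (\hat\beta_j/\mathrm{se}_j)^2 > 10$. The clumping
algorithm is the PLINK-style greedy rule; the window is center-to-center
in base pairs and cross-chromosome pairs are never clumped. Variants
missing from the LD reference pass through unpruned, with a warning,
rather than being silently dropped.

## Harmonization

The outcome association is re-expressed on the exposure's effect allele.
Identical or strand-complement allele pairs are kept; swapped pairs have
the outcome beta negated and EAF complemented and are flagged. Palindromic
(A/T, C/G) variants cannot be resolved by allele matching; the default
policy drops those whose EAF is missing or within 0.08 of 0.5 in either
study (0.42–0.58) and orients the remainder by the minor/major side of
the two EAFs. This band is a convention of two-sample MR practice, chosen
once; `drop_all` and `keep` policies are available. The package performs
no liftover, reference-genome normalization, or VCF ingestion.

## MR-PRESSO

The pleiotropy residual-sum-and-outlier test is simulation-based
throughout (no analytic approximation to the null):

1. **Global test.** Observed statistic
   $\mathrm{RSS} = \sum_j w_j(\hat\Gamma_j - \hat\beta_{-j}\hat\gamma_j)^2$
   with $\hat\beta_{-j}$ the leave-one-out fixed-effect IVW slope
   (fixed-effect inside the resampling for speed and determinism). The
   null distribution is a parametric bootstrap of size $K$:
   $\gamma^*_j \sim N(\hat\gamma_j, \sigma^2_{\gamma j})$,
   $\Gamma^*_j \sim N(\hat\beta_{-j}\hat\gamma_j, \sigma^2_{\Gamma j})$,
   drawn instrument-major so a seed fully determines the result. The
   Monte-Carlo p-value $(1 + \#\{RSS^* \ge RSS\})/(K+1)$ is bounded below
   by $1/(K+1)$.
2. **Outlier test.** Each instrument's observed weighted LOO residual is
   compared with its own bootstrap residuals; instruments with
   $p_j < \alpha/J$ (Bonferroni at $\alpha = 0.05$) are outliers. Because
   of the Monte-Carlo floor, detection at $J$ instruments requires
   $K + 1 > J/\alpha$ — with the default $K = 2000$, up to $J = 100$; at
   $K = 500$ and $J = 30$ no outlier can ever be flagged. This is why
   $K$ should not be lowered when outlier localization matters.
3. **Distortion test.** The percentage difference between the raw IVW
   estimate and the outlier-corrected one, referred to a null built by
   removing random same-size subsets of the clean instruments.

## Two-step mediation

For exposure $X$, mediator $M$, outcome $Y$: step 1 estimates
$\hat\beta_1$ ($X \to M$) with $X$'s instruments; step 2 estimates
$\hat\beta_2$ ($M \to Y$) with $M$'s own instruments; the total effect
$\hat\beta_T$ ($X \to Y$) uses $X$'s instruments. Mediator instruments
that are also exposure instruments are excluded from step 2 so the
mediator stage is not contaminated by the exposure's direct pathway. The
indirect effect is the product $\hat\beta_1\hat\beta_2$ with delta-method
SE $\sqrt{\hat\beta_2^2\sigma_1^2 + \hat\beta_1^2\sigma_2^2}$ (zero
covariance — the two stages come from different samples), and the
mediation proportion is $\hat\beta_1\hat\beta_2/\hat\beta_T$.

Two delta variants are offered for the proportion SE. The default
(`denominator_mode = "fixed"`) treats $\hat\beta_T$ as known:
$\mathrm{se} = \mathrm{se}_{\mathrm{ind}}/|\hat\beta_T|$. Back-computing
from published two-step MR reports, this variant reproduces their
interval half-widths closely, while full propagation
(`"propagated"`, which adds $\sigma_T^2/\hat\beta_T^2$ under a zero
covariance assumption) yields wider intervals; both are available and the
mode is recorded in the result. Proportions outside $[0,1]$ are reported
with a warning rather than truncated; they are excluded from "mediator"
status only when direction consistency is required.

### Candidate screening

`screen_mediators()` follows the two-stage design used in
proteome/metabolome-wide mediator scans: stage A associates each
candidate with the outcome (candidate's own instruments, exposure
instruments excluded) and retains those passing `alpha_screen` after the
configured multiplicity adjustment across candidates; stage B requires an
exposure effect on the retained candidates at the raw `alpha_screen`;
qualifiers optionally must satisfy
$\operatorname{sign}(\hat\beta_1\hat\beta_2) =
\operatorname{sign}(\hat\beta_T)$. The default is no multiplicity
adjustment (raw $p < 0.05$), the common practice in such screens;
Benjamini–Hochberg and Bonferroni are available. The adjustment is applied
at stage A only, where the candidate-wise family is defined.

## The synthetic-data generator

`simulate_chain()` emulates the statistical structure of a biobank-scale
two-sample mediation study without any external data. Under
$M = \alpha X$, $Y = \delta X + \theta M$:

* exposure instruments have true effects
  $\gamma_j \sim N(0, \mathrm{gamma\_sd}^2)$ on $X$, hence
  $\alpha\gamma_j$ on $M$ and $(\delta + \alpha\theta)\gamma_j$ on $Y$;
* mediator instruments have their own effects on $M$ and act on $Y$ only
  through $\theta$;
* a `pleio_frac` subset of exposure instruments receives horizontal
  pleiotropy offsets $N(\mathrm{pleio\_mean}, \mathrm{pleio\_sd}^2)$
  (balanced when the mean is zero, directional otherwise);
* sampling noise uses the standardized-trait approximation
  $\mathrm{se} = 1/\sqrt{2f(1-f)n}$, with independent noise across the
  three GWAS (the two-sample, no-overlap assumption by construction);
* the LD matrix has blocks of adjacent variants sharing a common
  pairwise $r^2$, zero across blocks.

Defaults are fixed once to represent the kind of study the package
targets: 30 exposure and 30 mediator instruments, 200&nbsp;000 samples
per GWAS, MAF in (0.05, 0.5), `gamma_sd` = 0.05 (mean per-instrument
F well above the weak-instrument threshold at these sample sizes), and a
causal chain $\alpha = -0.207$, $\theta = 0.274$, $\delta = -0.233282$,
so the true total effect is $-0.290$ and the true mediation proportion
$\alpha\theta/(\delta + \alpha\theta) \approx 19.6\%$ — an
SGLT1-inhibition-to-frailty-like effect chain with an insulin-resistance
scale mediator. `pleio_sd` defaults to 0.005, comparable to the
per-variant outcome effects at these settings, so that enabling
pleiotropy produces realistic (not caricatured) contamination.

What the generator does **not** emulate: binary outcomes on the log-odds
scale (low-grip-strength-style binary traits are treated on the beta
scale, as summary reports commonly do), sample overlap between GWAS,
allele-frequency differences between studies, effect-size–MAF coupling,
winner's-curse selection into the instrument set, and LD-induced
correlation between the effect estimates of linked variants (LD enters
only the clumping input, not the sampling covariance). Passing recovery
and calibration tests on these simulations therefore demonstrates
internal correctness of the estimators and machinery, not robustness to
every feature of real GWAS data.

## Numerical choices and degenerate inputs

* Strict inequalities at the selection boundaries (`pval < threshold`,
  `F > f_min`), matching the usual statement "F > 10".
* Monte-Carlo p-values are never zero (floor $1/(K+1)$); analytic
  p-values are floored at the smallest positive double.
* An IVW fit on a single instrument delegates to the Wald ratio; an
  exposure effect vector of all zeros is an error, as is Egger with
  fewer than 3 instruments or MR-PRESSO with fewer than 4.
* Duplicated variant ids in an input file keep the lowest-p row
  (deterministic); unparsable or invariant-violating rows are dropped
  and counted, never silently imputed.
* The on-disk dialect writes numerics at 17 significant digits so a
  read–write round trip is bit-exact.
* LD matrices are validated for symmetry (tolerance $10^{-8}$) and unit
  diagonal on construction and on load.

## Problem sizes used in the test-suite simulations

Recovery uses 200 replicates of the default chain; calibration uses 500
replicates at $J = 20$ for Q and the test sizes and 200 replicates at
$K = 500$ for the MR-PRESSO global null; power uses 100 replicates with
2 planted 8-SE outliers among 30 instruments at $K = 2000$ (see the
Monte-Carlo floor note above). These sizes give Monte-Carlo standard
errors small enough to detect meaningful miscalibration while keeping the
whole suite desk-scale.

## Known limitations

* No exposure-side measurement-error correction in the Wald/IVW SEs.
* Normal rather than t quantiles throughout.
* The mediator screen validates on synthetic candidates; reproducing any
  particular published mediator list requires the original cohort-scale
  GWAS inputs, which are outside the package's scope.
* When outliers are weak instruments (small $|\gamma_j|$), removing them
  changes the IVW estimate little; outlier *correction* is then nearly
  neutral even though *detection* still works — a structural property of
  inverse-variance weighting worth keeping in mind when interpreting
  distortion results.
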