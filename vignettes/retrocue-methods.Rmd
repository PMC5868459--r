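---
title: "Models and methods behind the retrocue pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the retrocue pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrocue)
```

This vignette documents the statistical machinery of the package: the task
and data model, the estimators, the numerical choices, the synthetic-data
generator and what it does and does not emulate, and the design decisions
that were genuinely open.

## The task and the data model

Observers memorise four oriented bars (one per quadrant) and, after a
retention interval that may contain a retrocue toward one item, reproduce
the orientations of two of the four items in sequence on a continuous
circular scale. Each trial therefore contributes two responses, and every
response can be labelled by the *cue role* of the item it probes:

* `neutral` trials: both responses probe items that were never cued;
* `cued_first` trials: response 1 probes the cued item (`cued`),
  response 2 an uncued item (`uncued`);
* `cued_second` trials: response 1 probes an uncued item, response 2 the
  cued item.

Crossing role (cued, uncued, neutral) with response position (1, 2) yields
the six cells in which every per-subject statistic is computed; with
`n` subjects this gives the familiar F(2, 2(n−1)) degrees of freedom for
the omnibus cue effect.

Files are plain CSV (UTF-8, one header row, empty fields for missing
values), with angles in degrees and 1-based item indices; everything is
converted to radians at the module boundary because all estimators work on
the circle. Trials with a missing response are dropped only from analyses
that need that response. The participant-exclusion rule — a subject is
dropped when the Rayleigh test on their pooled signed errors has p > .01,
i.e. when their responses are statistically indistinguishable from uniform
guessing — pools both responses across all conditions by default; whether
the original criterion pooled one or both responses is not documented, so
the pool is configurable (`responses` argument of
`exclude_participants()`).

## Accuracy and circular statistics

Recall accuracy is the reciprocal of the circular standard deviation of
the signed errors, using the Mardia definition
$\mathrm{SD} = \sqrt{-2\ln \bar R}$, where $\bar R$ is the mean resultant
length — the definition standard in the precision working-memory
literature. Accuracy is reported in 1/radian. Two degenerate cases are
handled deliberately: a sample with $\bar R = 0$ (no directional
concentration whatsoever) gets accuracy 0 with a warning rather than an
error, so condition-level tables stay complete; resultants below $10^{-12}$
are treated as zero to absorb round-off in perfectly balanced samples.

The Rayleigh statistic is $z = n\bar R^2$ with the Wilkie (1983)
small-sample p-value approximation
$p = \exp\!\big(\sqrt{1 + 4n + 4(n^2 - R_n^2)} - (1 + 2n)\big)$
($R_n = n\bar R$), the same approximation used by the CircStat toolbox. It
is well calibrated at the sample sizes involved here (hundreds of
responses per subject); the test suite verifies the type-I rate on uniform
samples against the nominal level at 2000 Monte-Carlo replicates.

## The mixture model

Signed errors $e$ are modelled as a two-component circular mixture

$$p(e) = P_{\mathrm{MEM}}\, \mathrm{VM}(e;\, 0, \kappa)
       + (1 - P_{\mathrm{MEM}})\, \frac{1}{2\pi},$$

with $P_{\mathrm{MEM}}$ the probability that the probed item is recalled
at all and $\kappa$ the von Mises concentration (precision) of recalled
responses. The model deliberately has exactly two components — no swap /
non-target component — matching the reporting model of the analyses it
supports.

Fitting is by direct maximum likelihood over the box
$[0,1]\times[0,\kappa_{\max}]$ with L-BFGS-B, restarted from a coarse grid
($P_{\mathrm{MEM}} \in \{0.1, 0.3, 0.5, 0.7, 0.9\}$,
$\kappa \in \{1, 4, 16, 64\}$); with only two parameters this is cheaper
and more transparent than EM, and the multi-start makes the bimodal
corner cases (near-uniform data) reliable. The log-likelihood uses the
exponentially scaled Bessel function
($\ln I_0(\kappa) = \kappa + \ln \tilde I_0(\kappa)$) and a two-term
log-sum-exp, so it is stable up to the cap $\kappa_{\max} = 500$
(circular SD ≈ 2.6°, beyond realistic motor precision; the cap also
prevents Bessel overflow). An exhaustive lattice search
(`fit_mixture_grid()`, ties broken toward the lowest $P_{\mathrm{MEM}}$,
then the lowest $\kappa$) provides an independent cross-check: the
optimiser must land within one lattice step of a 200 × 200 grid argmax and
dominate every grid start in likelihood. Fits are computed per
subject × role × response cell with a default floor of 20 observations per
cell.

## Bias curves and the area-difference statistic

The relative orientation $\Delta$ of the *other* probed item with respect
to the current target is wrapped to $(-\pi, \pi]$ (negative = the other
item lies clockwise). The response-bias curve is estimated with 64
overlapping sliding bins: bin centres are equally spaced with a half-step
offset, so no centre sits at $0$ or $\pi$ and the positive and negative
half-domains each contain exactly 32 centres; each bin averages the signed
errors of the $\max(2, \mathrm{round}(n/4))$ trials circularly closest to
its centre (ties resolved by trial order, making the estimate
deterministic). Holding a fixed quarter of all trials per bin matches the
published binning recipe and smooths heavily — neighbouring bins share
most of their trials, so the 64 bin values are far from independent and
are only used through the summary statistic.

That statistic, the *area difference*, is the mean bin value over positive
$\Delta$ minus the mean over negative $\Delta$ — proportional, for equally
spaced centres, to the difference of the two half-domain integrals.
Positive values indicate attraction toward the other orientation, negative
values repulsion. Note one property that is easy to get wrong: jointly
negating all $\Delta$ and all errors mirrors the curve through the origin
but leaves the area difference *unchanged* (both halves swap and change
sign simultaneously); only negating the errors alone flips its sign. Group
inference is a two-sided one-sample t test of the per-subject area
differences against zero, with a JZS Bayes factor.

Response orientations are treated on the full 360° circle throughout
(responses are modelled as uniform over $2\pi$ when guessing), so relative
orientations are not folded into a 180° bar-symmetry space.

## Trade-off correlations

For each subject and condition the Pearson correlation between
$|e_1|$ and $|e_2|$ across complete trial pairs is Fisher-transformed
($r$ clipped at $\pm(1-10^{-12})$). All complete pairs enter — guess
trials are not filtered out, since guess identification would itself
depend on the fitted model. Group inference: per condition a one-sample t
test of $z$ against 0 with Bayes factor, plus a one-way repeated-measures
ANOVA for the cue-condition effect.

## Classical and Bayesian inference

`rm_anova()` handles balanced, fully crossed within-subject designs with
up to three factors, fitting via `stats::aov()` with an
`Error(subject/(A*B*C))` stratum structure so every effect is tested
against its own effect-by-subject interaction. No sphericity correction is
applied, matching the uncorrected degrees of freedom convention of the
analyses this package reproduces. Partial eta squared is
$SS_e/(SS_e+SS_{err})$. Sums of squares below
$10^{-12}\times\max(SS_{\mathrm{total}}, 1)$ are treated as zero so flat
data report $F = 0$ rather than round-off noise. The test suite checks the
full F/p/η² tables against an explicit mean-deviation sums-of-squares
decomposition written independently of `aov`.

The JZS Bayes factor for one-sample/paired t tests integrates the
Jeffreys–Zellner–Siow prior (Cauchy with scale $r = \sqrt 2/2$ on the
standardised effect, i.e. normal-on-effect given $g$ with
inverse-gamma(1/2, $r^2$/2) on $g$) by adaptive quadrature on the $g$
scale, with the integrand computed in log space relative to the null
likelihood. The quadrature tolerance ($10^{-8}$ relative) is far below the
reporting precision. The scale $\sqrt2/2$ is the default of the
BayesFactor software, which the published statistics were computed with;
the package reproduces those printed t→BF conversions to within the
rounding of the printed t statistics (a t printed to two decimals can move
the BF by more than its last printed digit, which bounds the achievable
agreement). Bayes factors for ANOVAs are deliberately not implemented:
random-effects model integration is a dependency-grade component out of
proportion to its use here, so the results bundle carries classical ANOVAs
plus t-test Bayes factors only. Between-experiment comparisons use pooled
variance (the published two-sample dfs are consistent with both pooled and
Welch forms in places; pooled is the package default and is labelled as
such).

## The synthetic-data generator

`simulate_session()` draws, per trial: four item orientations uniform on
[0°, 360°) (optionally with a minimum pairwise separation, off by default
since the original designs state none); a cued item uniform over the four
(absent on neutral trials); probe assignments uniform over the legal
choices of the condition; and two responses from the mixture model with
role- and position-specific $P_{\mathrm{MEM}}$ and $\kappa$. Three
generative extensions make the downstream analyses testable:

* **Bias**: the von Mises component of a response is centred on
  $\beta_{r,i}\sin\Delta$ — the first circular harmonic, the simplest odd
  periodic bias shape consistent with a repulsion/attraction profile
  (no parametric shape is claimed by the analyses themselves). The
  repulsion preset (`params_repulsion()`) sets $\beta = -5°$ only for
  response 1 on cued-second trials, the cell where the phenomenon was
  observed; everything is configurable per (role, index).
* **Coupling**: per trial a gain $g \sim \mathrm{Beta}(a, a)$ with
  $\mathrm{Var}(g) = \mathrm{strength}/4$ modulates precision.
  `shared_gain` multiplies both responses' $\kappa$ by $2g$ (positive
  |error| correlation); `resource_tradeoff` splits a fixed budget,
  $\kappa_1 = 2g\kappa$, $\kappa_2 = 2(1-g)\kappa$ (negative correlation,
  the zero-sum resource hypothesis); `independent` leaves both untouched.
* **Between-subject variability**: per-subject parameters are
  truncated-normal perturbations of the cohort means
  (SDs: 0.05 for $P_{\mathrm{MEM}}$, 2 for $\kappa$, 1° for $\beta$).

Cohort defaults encode a realistic effect pattern for four-item arrays —
recall rates 0.95/0.88/0.80 (cued/neutral/uncued) on the first response,
0.90/0.82/0.80 on the second, $\kappa = 12$ everywhere except 15 for
cued-first responses, no bias, no coupling — chosen once from the typical
range of continuous-report studies (recall rates 0.7–0.95 at set size
four, $\kappa$ 10–20, cue effects mainly on recall rate). Design presets
reproduce the published trial structures: E1 = 8 blocks × 60 trials
(20/20/20 per condition; 480 trials, 160 per condition), E2/E2b identical
with order cueing, E3 = two session halves (order cued / not) of
5 blocks × 60, i.e. 100 trials per condition per session, 600 in total.

Reproducibility: a master seed draws one sub-seed per subject, so cohorts
are bit-identical across runs and subjects are independent streams.

What the generator does **not** emulate: reaction times (columns are
carried but empty), sequential effects across trials (serial dependence),
swap errors to unprobed items, non-uniform guessing, oblique-orientation
anisotropies, or learning/fatigue across blocks. Passing recovery tests on
these simulations therefore validates the estimators under the stated
generative assumptions — they cannot certify that real data satisfy those
assumptions.

## Monte-Carlo validation sizes

The acceptance-level checks run, per invocation: mixture parameter
recovery on 204 datasets of 500 errors across
$P_{\mathrm{MEM}} \in \{0.3, 0.6, 0.9\} \times \kappa \in \{5, 15\}$
(median absolute $P_{\mathrm{MEM}}$ error ≤ 0.05, median relative $\kappa$
error ≤ 20%); bias-statistic calibration on 1000 null cohorts of
24 subjects × 160 trials (rejection rate within 5% ± 1.5%) plus 200
repulsion cohorts at $\beta = -5°$ (negative mean area difference in
≥ 95%); and coupling-sign recovery on 100 cohorts per regime at strength
0.5, classified by a cohort-level t test at α = .01 (≥ 95% correct per
regime). These sizes give two-sided Monte-Carlo standard errors well
inside each margin while keeping a full run in a few minutes on one CPU.

## Known limitations

* The overlapping-bin recipe is a reconstruction (nearest-quarter per
  centre with half-step offsets); other centre conventions would change
  bin values slightly but not the area statistic's behaviour.
* `rm_anova()` requires complete balanced designs and offers no sphericity
  correction or between-subject factors.
* The mixture model has no swap component; data with frequent non-target
  reports will surface as inflated guess rates.
* Accuracy's reciprocal-SD definition diverges as samples concentrate;
  cells with very few trials give noisy accuracies (the pipeline's
  per-cell floors guard the mixture fits, not the accuracy table).
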