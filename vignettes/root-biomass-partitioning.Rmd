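---
title: "Partitioning root-sample carbon into recent roots and extraneous organic matter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning root-sample carbon into recent roots and extraneous organic matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootmix)
```

## The problem

Root biomass recovered from field soil cores is rarely pure crop root.
Washed samples carry *extraneous organic matter* (EOM): dead roots of
preceding crops, weed roots, incorporated residues, and manure remnants.
When the sampled crop is maize (a C4 plant, δ¹³C around −13‰) grown after
years of C3 vegetation (δ¹³C around −29‰), the ~16‰ isotopic separation
lets a two-pool mass-balance mixing model partition each sample's carbon:

$$f = \frac{\delta^{13}C_s - \delta^{13}C_{EOM}}
           {\delta^{13}C_{RB} - \delta^{13}C_{EOM}}$$

where $f$ is the mass fraction of recent root biomass C of total C in the
sample, $\delta^{13}C_s$ the measured sample value, and
$\delta^{13}C_{RB}$, $\delta^{13}C_{EOM}$ the source signatures
(endmembers). By mass balance, $f$ and the EOM-C fraction sum to one.

`rootmix` implements this model end to end for the sampling design of the
Swiss DOK long-term trial (maize, 2013): 3 management treatments × 4 field
blocks = 12 plots, 3 depth layers (0–0.25, 0.25–0.5, 0.5–0.75 m), and two
core streams per plot × depth — Humax cores at two positions (within and
between rows; washed to a pooled >0.5 mm size class with manual EOM
exclusion) and Pürckhauer cores within rows (coarse >2 mm and fine
0.5–2 mm size classes, no exclusion). That is 144 planned observations.

## Endmember estimation

**Root endmember.** Coarse-root samples are the least contaminated stream,
and the upper tail of their δ¹³C distribution is taken to represent pure
recent maize roots: `estimate_root_endmember()` averages all values
*strictly greater than* the empirical 0.8 quantile of the coarse values.
Two numerical choices are deliberate and recorded in the estimate's `rule`
string:

* the quantile is the type-7 (linear interpolation at index $1 + q(n-1)$)
  definition — the default in most software; no other definition changes
  the selected set for the design's 36 coarse samples;
* selection is strict (`>`), so values tied with the quantile are
  excluded; with 34–36 distinct coarse values the rule selects exactly 7.

The estimator is intentionally simple (it mirrors field practice), and it
is *biased low whenever the upper tail is not actually pure*: if the top
~20% of coarse samples still contain EOM, the estimated root signature is
too light and all fractions are inflated proportionally. The synthetic
studies below quantify this (see *Known limitations*).

**EOM endmember.** `estimate_eom_endmember()` is the plain mean ± SD of a
reference set: fine roots of the preceding-year grass-clover ley, sampled
from the same plots, pooled over treatments (default n = 12). Before
pooling either endmember across groups, `group_invariance_check()` runs an
advisory one-way permutation test; a significant result warns but does not
abort, since the analysis pools regardless and the warning is the cue to
inspect group-specific signatures.

`endmember_pair()` enforces that the root signature is heavier than the
EOM signature by at least 2‰ (configurable); below that the mixing
denominator is numerically meaningless and the pair is rejected.

## Uncertainty, clamping, pooling

Three variance sources enter each fraction: the sample measurement
(default σ = 0.2‰, the usual IRMS analytical precision for plant
biomass), and the two endmember SDs, treated as independent Gaussians (no
covariance information exists). `analytic_se()` propagates them to first
order; `mc_uncertainty()` is the Monte-Carlo counterpart (default 10 000
draws, per-draw clamping, 2.5/97.5 percentile interval; draws with a
perturbed separation below 0.1‰ are rejected and redrawn). In the linear
regime the two agree to well under 5% relative error — a standing test.

Raw fractions can leave $[0,1]$ when a sample is isotopically outside the
endmember interval. `fraction` is clamped, `raw_fraction` is preserved,
and `flag` records the clamping; all group statistics use clamped values.
Field datasets of this kind report fractions spanning roughly 5–100%, so
clamping is rare but must be handled.

Pooled Pürckhauer fractions (needed to compare EOM exclusion practices on
a like-for-like pooled size class) are mass-weighted averages of the
coarse and fine fractions (`pool_size_classes()`), with carbon
concentrations refining the weights when both are supplied. `run_mixing()`
synthesizes these records per plot × depth wherever both classes and their
dry masses exist; their SE combines the two components as if independent,
which slightly overstates it because both share the endmember estimates.

## Inference: design-respecting permutation tests

The reference analysis for such data is a linear mixed model with
Kenward–Roger ANOVA. `rootmix` deliberately does **not** replicate that:
the random-effects structure for this design is under-determined, and a
permutation framework is exactly testable and assumption-light. p-values
are therefore not comparable, number for number, with a mixed-model
analysis — only the qualitative conclusions are.

Each factor is permuted at its own experimental unit, within the stratum
where units are exchangeable under the null:

| factor | unit | permuted within |
|---|---|---|
| treatment | plot (mean fraction) | whole study (optionally blocks) |
| depth | plot × depth cell | plot |
| position, size class, exclusion | sample | plot × depth cell |

The statistic is the between-level mean square of unit values; with fewer
than 20 distinct permutations the group is enumerated exactly. Interaction
tests use the Freedman–Lane scheme: residuals from the additive fit are
permuted and added back to the additive fitted values, and a cell-mean
interaction mean square is recomputed. `p = (1 + \#\{\ge obs\})/(B+1)`
with default `B = 9999`; all tests are bit-reproducible given a seed.
Under the package's null scenario the type-I error of the treatment test
sits inside [0.03, 0.07] at α = 0.05 (500 replicate studies, B = 999) — a
standing acceptance check.

## The synthetic-study generator

Because the per-sample field measurements behind this design are not
published, the generator is the package's test bed. Latent truth is
logit-normal:

$$\mathrm{logit}(f) = \mathrm{logit}(f_0) + \sum_k \beta_{k[\ell]} +
\varepsilon,\qquad \varepsilon \sim N(0, \sigma_\ell^2)$$

with baseline $f_0 = 0.5$, per-level offsets $\beta$ for treatment,
depth, position (Humax), size class (Pürckhauer) and EOM exclusion, and
dispersion $\sigma_\ell = 0.9$. The logit link keeps fractions strictly
inside (0, 1) and produces the long lower tail seen in contaminated field
samples. Measurements are generated by inverting the mixing model with
*per-sample* endmember realizations (each sample's root and EOM material
draws its own signature from $N(-13.3, 0.5^2)$ and $N(-29.3, 0.3^2)$)
plus instrument noise $N(0, 0.2^2)$ — per-sample realization represents
biological heterogeneity and is what makes endmember-SD propagation
testable. Five of the 144 observations are removed uniformly at random
(the realized study size, 139); which cells were missing in the original
study is unknown, so uniform missingness is the neutral choice.

**Calibration.** The default offsets in `dok2013_scenario()` are not free
dials: each is obtained by inverting the logit-normal mean function at
$\sigma_\ell = 0.9$ so that the *expected* group means under noise equal
the reported field values — 55/59/66% across treatments, 52/60/68% across
depths, 73/52% for within/between rows, 73/42% for coarse/fine, 74% for
EOM-excluded samples. The fine:coarse dry-mass ratio (1.82) solves
$(0.73 + 0.42\,r)/(1+r) = 0.53$, so that mass-weighted pooling reproduces
the 53% unexcluded pooled mean. Dry masses are assigned on an arbitrary
scale (coarse 0.5 g) because only the ratio matters for pooling. The
dispersion 0.9 itself is a calibration judgment: it yields per-sample
fraction SDs around 0.20 and a 5–100% range at n = 139, matching the
variability such studies report.

**What the generator does not emulate.** Additive logit effects cannot
represent treatment-specific EOM *composition* (e.g. exclusion helping
some treatments only) unless an interaction option is added to the
scenario; spatial structure within plots, depth-dependent dispersion, and
any pure-root point mass in the coarse stream are likewise absent. Passing
tests therefore validate the pipeline's arithmetic, calibration and
inference under a plausible generative model — not the field realism of
that model.

## Known limitations

* **Quantile-estimator bias under logit-normal truth.** In the baseline
  scenario the top ~19% of coarse samples average a true fraction of
  about 0.92, not 1. The estimated root endmember is consequently ~1‰ too
  light and the overall estimated fraction overshoots the true mean by
  ≈ 0.04–0.05 (MAE 0.048 over 200 replicate studies — computed by the
  acceptance suite, which records this bound as failed). This is a
  property of the estimator–generator pair, not an implementation defect:
  the estimator is unbiased exactly when the selected tail is pure, which
  a single logit-normal population never provides. Users applying the
  package to real data should ask whether their coarse-root upper tail is
  plausibly pure; if not, the root endmember needs independent support
  (e.g. hand-picked verified roots).
* **Small treatment contrasts are not recoverable.** At the calibrated
  effect sizes the BIOORG1–BIOORG2 gap (~4 points) is about one SE of the
  difference of group means, capping full-ordering recovery near 76% —
  consistent with the treatment effect being non-significant in the field
  analysis. The acceptance suite records this too.
* Fractions are C-mass fractions. Converting to biomass fractions assumes
  equal C concentration across pools unless per-pool concentrations are
  supplied to the pooling step.
* No isotope fractionation during decomposition, no Suess-effect
  adjustment, no multi-source (>2 pool) mixing, and no extrapolation of
  fractions to areal root biomass.

## Problem sizes used by the validation suite

Simulation-based checks run at the study's own scale (139 samples per
replicate): 200 replicate studies for recovery and ordering properties,
500 replicate studies at B = 999 for type-I calibration, and 10⁵ draws
for the Monte-Carlo/analytic agreement check. These sizes give binomial
SEs of about 1.5% on recovery rates and 1% on the type-I rate.

## A worked run

```{r, eval = FALSE}
study <- simulate_study(dok2013_scenario(), seed = 101)
fit <- run_pipeline(study$samples, study$reference, seed = 101)
fit$pair
summarize_fractions(fit$subsets$full, "depth")
report_table2(fit$subsets$full)
permutation_main_effect(fit$subsets$positions, "position", B = 9999, seed = 101)
```

The README shows this run's printed output; `scripts/acceptance.R`
recomputes all headline quantities from scratch.
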