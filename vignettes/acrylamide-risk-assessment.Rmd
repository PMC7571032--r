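---
title: "Deterministic dietary risk assessment for acrylamide: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic dietary risk assessment for acrylamide: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrymoe)
```

## The problem

Acrylamide forms in starchy foods baked above 120 °C, and bread is consumed
in quantities that make even moderate concentrations toxicologically
relevant. A typical assessment has three layers: an **occurrence survey**
(what concentrations are on the market, per product), a **regulatory
screening** (how those concentrations compare with EU 2017/2158 benchmark
levels), and a **deterministic exposure and risk characterisation** (what
chronic intake consumers face and what margin separates it from a
toxicological reference point). `acrymoe` implements all three plus the
analytical-method QC that underpins the occurrence data.

## Models and procedures

### Occurrence summaries

Per product we report n, mean, sample standard deviation (n − 1
denominator), median, 95th percentile and min–max. The percentile rule
defaults to linear interpolation between order statistics (type 7); on
survey-sized groups (n ≈ 18–22) the 95th percentile is sensitive to the
rule, so it is a parameter (`quantile_type`) rather than a constant. A
single observation yields sd = 0 with a warning — an error here would kill
pipelines on tiny fixtures for no analytical gain. Records below the limit
of quantification carry a `censored` flag and the LOQ as placeholder; the
substitution policy (`zero`, `half_loq`, `loq`; default LOQ 25 µg/kg) is
applied before any aggregation. No left-censored maximum-likelihood
estimators are offered: the calibrating survey had every sample above the
LOQ, and substitution is the transparent default at such low censoring
rates.

### Method QC

The calibration curve is an ordinary least-squares line of peak-area ratio
on concentration. Detection limits follow LOD = 3.3 σ/S and LOQ = 3 × LOD,
with σ read as the **residual standard deviation of the calibration fit**
(n − 2 denominator) — the common ICH interpretation of "standard deviation
of the response". Where a laboratory prefers the sd of blank or
lowest-level responses, `lod(curve, sigma = ...)` accepts it directly. All
values are kept at full precision; note that a reported LOD of 8 µg/kg and
LOQ of 25 µg/kg can only coexist through presentation rounding (3 × 8 =
24), which is why the package never rounds internally. Recovery is
100 × measured/spiked; intra-day repeatability is the mean over days of the
within-day RSD and inter-day repeatability the RSD of the daily means.

### Comparative statistics

Product means are compared by classical one-way ANOVA (`stats::aov`) with
Tukey HSD post-hoc tests (`stats::TukeyHSD`, which applies the Tukey–Kramer
correction for unequal group sizes) at a default familywise α = 0.01, the
level used for occurrence-table superscripts in this field. If the residual
variance is exactly zero while means differ, the F statistic is infinite;
the result is flagged and every contrast treated as significant rather than
erroring (detection uses a relative tolerance, residual SS ≤ 10⁻¹² of the
total SS, because exact-arithmetic inputs leave ~10⁻³¹ of floating-point
residue). If *all* observations are equal the F statistic is 0/0 and the
call errors.

The **compact letter display** is authored in the package: the
insert-and-absorb algorithm starts from one letter covering every group;
each significant pair still sharing a letter splits that letter's group set
into two copies, one without each member; letter sets contained in another
are then absorbed. This guarantees the defining invariant — two groups share
a letter **iff** their comparison is non-significant — which the test suite
verifies by brute force over *all* significance patterns with up to five
groups. Letters are assigned in input order with first-seen tie-breaking;
the display for a given matrix is deterministic.

**Spearman correlation** uses average ranks for ties and, by default, the
t approximation t = ρ√((n − 2)/(1 − ρ²)), adequate at the n ≈ 66 typical of
a pooled soft-bread correlation. An exact permutation p-value is available
for n ≤ 8, where complete enumeration (≤ 40,320 permutations) is cheap;
beyond that the approximation is the sensible tool and enumeration is
disproportionate.

The **moisture–concentration smoother** is locally weighted linear
regression (`stats::loess`, degree 1, default span 0.75) with a pointwise
95 % band of fitted ± 1.96 standard errors. It is a presentation-layer
description of the curvilinear moisture relationship (a steep rise in AA
below roughly 43 % dough moisture), not an inferential claim, and it
refuses to extrapolate outside the observed covariate range.

### Exposure and margin of exposure

The unit chain is fixed and centralised: concentration C in µg/kg (≡ ng/g),
consumption Q in g/day, body weight BW in kg, so

> DI = C × Q / BW  (ng/kg bw/day)

needs no conversion factor, and

> MOE = BMDL10 / DI

carries an explicit 10⁶ factor because BMDL10 is in mg/kg bw/day. The
scenario grid crosses consumer percentile (median vs 95th-percentile
consumer, i.e. which consumption quantile enters) with concentration
scenario (BS: median concentration; WS: 95th percentile) across age groups
— four intakes per product × group cell. Endpoints default to BMDL10 =
0.43 mg/kg bw/day (peripheral-nerve axonal degeneration, rats) with a
low-concern threshold of 125 **inclusive** ("125 or above"), and 0.17
mg/kg bw/day (Harderian-gland adenocarcinomas, mice) with a threshold of
10,000 **exclusive** ("greater than 10,000"). Threshold comparisons always
use the unrounded MOE; `di_rounded`/`moe_rounded` (half away from zero, the
convention of printed intake tables) exist for presentation only. A zero
intake makes the MOE undefined and is reported as non-computable rather
than infinite, so no sentinel propagates into reports.

## The synthetic-data generator

The study's raw samples, consumption extractions and body weights are not
published, so the generator fabricates data with the structure the analysis
assumes:

* **Concentrations** per product are drawn from a normal distribution
  truncated to the product's observed min–max range, by rejection from the
  parent normal (bounds sit within ~1.5 parent sd, so acceptance is high).
  The configured mean/sd parametrise the **parent**, not the truncated,
  distribution — the truncated mean of e.g. the bread model (57 ± 18 on
  [31, 90]) is slightly higher, and the tests compare empirical moments
  against a quadrature oracle of the truncated density, not against the
  parent parameters.
* **Recipe attributes** (moisture, sugars, salt) are uniform within each
  product's recipe range. No within-product correlation between moisture
  and concentration is modelled; the negative *pooled* correlation across
  soft-bread products emerges from between-product structure (wetter-dough
  products having lower concentrations), which is the feature the pooled
  Spearman statistic actually measures here.
* **Consumption** is either drawn (median quantity uniform on 20–120 g/day,
  a realistic span for single bread-type items in a Mediterranean diet,
  with the 95th-percentile quantity 1.5–3× the median) or supplied exactly
  via `consumption_targets`.
* The **survey-calibrated fixture** (`survey_config()`) inverts the intake
  equation against the published best-scenario intake grid:
  Q = DI_BS × BW / C_median, with nominal body weights of 55 kg
  (adolescents) and 70 kg (adults = elderly, reflecting that a single
  weight was used for both adult groups). Running the pipeline on this
  fixture reproduces the published BS intake columns exactly, making the
  printed table a regression surface. Worst-scenario cells then follow as
  BS × C_p95/C_median; they agree with the published table to within one
  intake unit (the published BS inputs are themselves rounded), except one
  published cell (wholemeal Friselle, adolescents, median consumer: 70)
  that is arithmetically inconsistent with the concentration quantile
  ratio (450/375 = 1.2 implies 60); the package reproduces the arithmetic
  and documents the discrepancy rather than special-casing it. For the same
  reason the pipeline's minimum carcinogenic MOE computed from unrounded
  intakes is one unit below the value obtained from the printed maximum
  intake.

All randomness flows from the single config seed through one RNG stream,
consumed product by product in declaration order, so output is
reproducible and independent of global RNG state.

What passing tests on generated data do **not** show: that real market
samples are truncated-normal, that recipe attributes are uniform or
independent of concentration, or that real consumption resembles the
reconstructed quantities. The fixture demonstrates the pipeline's
arithmetic on realistic magnitudes; occurrence inference on real data needs
real data.

## Problem sizes and defaults

| Parameter | Default | Why |
|---|---|---|
| samples per product | 18–22 (200 total) | the calibrating survey's sampling frame |
| censoring policy / LOQ | `half_loq`, 25 µg/kg | conventional substitution; survey LOQ |
| percentile rule | type 7 | R's default interpolation; configurable |
| post-hoc α | 0.01 | the level behind occurrence-table letters |
| LOESS span | 0.75 | standard default for ~60-point scatters |
| body weights | 55 / 70 / 70 kg | nominal Italian anthropometrics |
| BMDL10 | 0.43 / 0.17 mg/kg bw/day | neurotoxic / carcinogenic reference points |
| MOE thresholds | 125 (≥) / 10,000 (>) | stated low-concern boundaries |

Moment-recovery tests use 5,000 draws per product (sampling error ~2 % of
the sd at that size); the full suite runs in seconds on one CPU.

## Known limitations

* Deterministic point scenarios only — no Monte Carlo exposure
  distributions and no uncertainty propagation.
* No left-censored ML estimation; substitution is the only censoring
  treatment.
* The sweets category gets occurrence and screening treatment but no
  exposure assessment (reliable consumption rates for these products are
  lacking, and a biased estimate is worse than none).
* The smoother and its band are descriptive; the band is a pointwise normal
  approximation, not a simultaneous one.
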