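---
title: "Deriving and using power-law relationships between motoneuron properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and using power-law relationships between motoneuron properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnscaling)
```

## The problem and the model

Electrophysiological properties of spinal alpha-motoneurons — axonal
conduction velocity (ACV), afterhyperpolarization duration (AHP), input
resistance (R), rheobase (I_th), capacitance (C) and membrane time
constant (tau) — are strongly inter-correlated, and all of them covary
with motoneuron size. No single experiment measures them all at once:
the evidence is scattered across studies that each report one or two
property pairs on their own cohort, with their own electrodes, protocols
and units. This package implements a pipeline that merges such
heterogeneous per-study datasets into a single quantitative framework of
power laws

$$A = k \, B^{a}$$

between every pair of properties, referenced to motoneuron size
$S_{MN}$, together with the machinery to validate the laws, scale them
to absolute SI units, extend them through Rall's equivalent-cylinder
cable theory, and generate inter-consistent motoneuron profiles for
model scaling.

Power relationships (rather than linear or exponential fits) are used
throughout because Rall's cable equations are themselves power-shaped
(e.g. $\tau = R_m C_m$, $C = \tau/R \cdot L/\tanh L$), so the fitted
family composes cleanly with the theory.

## Normalization and pooled fitting

Studies differ by multiplicative offsets (cohort, preparation,
electrode). Each study's columns are therefore rescaled to percent of
that study's own maximum (`normalize_study()`), which is exactly
invariant to any positive rescaling of a column. Normalized studies
reporting the same pair are concatenated (`merge_global()`) with
per-point provenance and no reweighting; fits are ordinary least squares
of $\ln A$ on $\ln B$ (`fit_power()`), with the r-squared taken as the
squared Pearson correlation of the logs, a two-sided t-test on the
slope, and t-based 95% intervals.

Percent-of-maximum normalization is only meaningful when the studies
sampled comparable portions of the motoneuron pool. That assumption is
checked, not hoped for: `distribution_metrics()` computes the range,
mean, coefficient of variation and median-to-mean ratio of each
normalized distribution, and `homogeneity_check()` applies the
inter-study gate (sd across studies below 10 percentage points and
below 0.15 of the mean, for all four metrics) before datasets are
merged.

## The iterative size-referencing pipeline

`derive_relationships()` processes properties in the fixed order ACV,
AHP, R, I_th, C, tau. Size-referenced datasets pass through directly;
a dataset $\{A;B\}$ whose regressor is not size is converted by mapping
its $B$ values through the previously derived inverse law
$S_{MN} = f(B)$. All converted datasets of a property are merged into
its final dataset, refitted, and — if the fit passes the admission gate
$r^2 > 0.3$, $p < 0.01$ — the law is inverted for use downstream.
Finally, laws between every pair of electrophysiological properties are
obtained by composing the size laws, so the pairwise family is exactly
self-consistent (composing $A\!\to\!B$ with $B\!\to\!A$ returns the
identity to machine precision; the test suite asserts this).

Two numerical choices deserve explanation.

**Analytic inversion.** The inverse of a fitted law is computed
analytically, $B = k^{-1/a} A^{1/a}$, not by swapping axes and
refitting. An axis-swapped OLS refit has slope $r^2/a$ — shrunk towards
zero by regression to the mean — and composing through such inverses
would systematically flatten every downstream law. The refit variant
remains available (`invert_power(..., method = "refit")`) for
diagnostics.

**Re-normalization of transformed size columns.** After conversion, the
estimated size column of each contributing study is re-expressed as
percent of its own maximum — the same convention under which directly
measured sizes enter the pipeline. Without this step, subtle
asymmetries in how observed maxima are formed (a noisy dependent column
in one dataset versus a cleaner regressor column in another) leave the
transformed clouds offset from the directly measured clouds, and a
pooled fit through mutually offset parallel clouds is flattened
dramatically. The step is the identity on noiseless data, so it changes
nothing in the exact-recovery limit.

## Cross-validation

`crossvalidate()` shuffles a pooled dataset with a run-level seed,
splits it into five non-overlapping folds, refits on each 80% and scores
the held-out 20% with three metrics (`prediction_metrics()`):

* `nME` — the largest per-point relative error, in percent (values
  above 100% are possible and expected in sparse tails);
* `nRMSE` — RMSE divided by the mean observed value, in percent;
* `r2pred` — squared Pearson correlation between predictions and
  observations, compared against the full-fit `r2exp`.

Range-normalized variants of the error metrics and a
sum-of-squares-based r-squared are available behind switches; defaults
follow the definitions above because the maximum error is compared to
per-point magnitudes and the prediction r-squared is compared directly
to the experimental one. Fold assignment is a true partition, and
reruns under the same seed are bit-identical.

## Scaling to SI units and Rall extensions

Normalized laws are scaled in three steps (`scale_relationships()`):
the size fold range $q_S$ (2.4 for adult cat, from averaged per-study
max/min ratios, `empirical_fold_ratio()`) propagates through each
exponent to a theoretical fold $q_T = q_S^{|c|}$; a theoretical range
$[A_{min}, A_{max}]$ is built in closed form so that
$A_{max}/A_{min} = q_T$ exactly while the midpoint matches the
empirical average extremes (`theoretical_range()`); and the intercept
is anchored at the small-size end — $k_c = A_{min}/S_{min}^c$ for
increasing properties, $k_c = A_{max}/S_{min}^c$ for decreasing ones
(`scale_intercept()`). The same anchoring rule, applied at the
regressor's minimum, scales laws between two electrophysiological
properties.

Rall's equivalent-cylinder quantities follow from
`rall_quantities()`: $L = \pi(\tau/\tau_1 - 1)^{-1/2}$,
$C = \tau/R \cdot L/\tanh L$, $R_m = R\,S_{neuron} \tanh L / L$,
$C_m = C/S_{neuron}$, with the identities $CR = \tau L/\tanh L$ and
$R_m C_m = \tau$ holding exactly. The default $\tanh L/L = 0.6$ is the
standard literature value; 0.5 is also in published use and both are
accepted. `delta_vth()` reads the intercept of a near-Ohmic
rheobase–resistance law (exponent within 0.1 of −1) as the voltage
depolarization threshold.

The bundled `cat_framework()` stores the published 2-significant-figure
absolute constants verbatim; chained look-ups through it are therefore
accurate to roughly 10%, and the profile round-trip tests use exactly
that tolerance. A framework recomputed from corpora carries unrounded
constants.

## Profiles and pools

`build_profile()` inverts the seed property's size law, recovers
$S_{neuron}$, and evaluates every other law, producing one internally
consistent profile; the voltage threshold is attached as the product
$I_{th} R$ rather than as a constant, so the small non-Ohmic deviation
of the framework (composed exponent −1.04) stays visible.
`generate_pool()` draws sizes from a truncated lognormal with its mode
in the lower third of the log range — many small cells, few large ones —
spanning the bundled 2.4-fold range, and builds one profile per size.
Columns are monotone in size by construction: ACV, C and I_th increase,
AHP, tau and R decrease.

## The synthetic-data generator

`synthetic_spec()`/`generate_corpus()` produce study-structured corpora
with known ground truth so every stage is testable without external
data. The generator emulates:

* ground-truth power laws (defaults: the published final size
  exponents 0.7, −1.5, −2.4, 2.5, 1.0, −1.5);
* a right-skewed size distribution over a 2.4-fold range;
* per-study multiplicative scale offsets (log-uniform in [0.5, 2]),
  which normalization absorbs exactly;
* per-study sub-range sampling: a common, top-anchored window whose
  lowest 10% of the log size range is unobserved. Each study's sample
  includes its window endpoints — the sharp form of the assumption that
  studies identify the same largest motoneuron, without which
  percent-of-maximum clouds are mutually offset even without noise;
* multiplicative log-normal noise on the reported (dependent) property,
  i.e. the homoscedastic-in-log structure under which log-log OLS is the
  maximum-likelihood fit; the regressor column is a deterministic
  function of the shared latent size, which is the premise of the
  size-conversion step. The default sigma_log = 0.12 is calibrated so
  the pooled normalized ACV–size fit reproduces the published
  r-squared of about 0.58 over a 2.4-fold size range. A heteroscedastic
  variant that also perturbs regressor columns exists for robustness
  experiments.

Child seeds are stable hashes of (master seed, pair, study index), so a
corpus is extensible without reshuffling existing studies, and
everything downstream is bit-reproducible from one run-level seed.

What the generator deliberately does **not** emulate: digitization
error, age/species heterogeneity within a corpus, heteroscedasticity
(by default), and between-study disagreement about which part of the
pool was sampled beyond the common window. Passing tests on synthetic
corpora therefore certify the pipeline's algebra and its statistical
behaviour under the method's own assumptions — not the fidelity of any
particular published dataset.

## Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` run the whole workflow on a
default corpus of 51 studies (17 pairs × 3 studies × 50 points,
sigma_log 0.12, seed 1): simulation, derivation (all six exponents
recovered within their 95% intervals), fivefold cross-validation
(nRMSE 12–16% across the 17 pooled datasets), SI scaling, profile and
pool generation, external scoring and muscle-unit couplings. The test
suite uses corpora of the same order of magnitude, plus a 100-replicate
recovery experiment at sigma_log 0.3 with ten 60-point studies per
property.

## Known limitations

**Percent-of-maximum normalization under noise.** Dividing a noisy
column by its observed maximum — an extreme order statistic — shifts
each study's cloud by a random, sample-dependent amount, and those
shifts correlate with the realized sample extremes. The result is a
small systematic attenuation of every pooled log-log slope that
compounds at each transform-and-merge hop. The effect is invisible at
the noise level matching the published fits, but at sigma_log = 0.3 the
recovery experiment in the test suite shows the chained exponents'
confidence intervals no longer cover the truth at the nominal rate; at
that same noise level, the true r-squared of the conduction-velocity
fit falls below the pipeline's own 0.3 admission gate, so the
derivation cannot legally proceed past its first property. These are
properties of the published estimator itself, not of this
implementation; the corresponding acceptance test documents the failure
rather than masking it.

**Rounded bundled constants.** The bundled framework chains
2-significant-figure constants; round trips are guaranteed only to
about 10%, and several published constants (the composed
rheobase–resistance intercept among them) differ between rounding
routes by just that much.

**Scope.** Only passive, subthreshold properties are covered: no
persistent inward currents, no discharge dynamics, no dendritic
geometry, no membrane non-uniformity. Derived (inverted or composed)
laws carry no significance statistics, and nothing downstream gates on
them.
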