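---
title: "SpO2-based respiratory SOFA: models, assumptions, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SpO2-based respiratory SOFA: models, assumptions, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sofaoxi)
```

## Why estimate respiratory SOFA from SpO2

The respiratory component of the SOFA score is defined on the PaO2/FiO2
(PF) ratio, but arterial blood gases are invasive and, outside the ICU,
drawn selectively: the patients who get one are sicker than the patients
who do not. Treating missing PaO2 as normal (the conventional approach)
therefore injects the *measurement decision* into the score — a patient
scores low partly because nobody thought an ABG was needed. Pulse oximetry
is available for essentially every emergency-department patient and is
monitored continuously, so its worst value over the first day can capture
deterioration a single ABG misses. This package implements seven scoring
strategies over that trade-off (see `?sofa_methods`) and the machinery to
compare their prognostic discrimination and calibration for in-hospital
mortality.

## The conversion models

**Piecewise-linear (methods A/B).** A bedside rule: from SpO2 100% to 90%,
PaO2 falls 4 mmHg per percentage point (100 → 60 mmHg); from 90% to 80%,
1.5 mmHg per point (60 → 45 mmHg); below 80%, PaO2 is half the SpO2 value.
SpO2 exactly 80% is assigned to the middle segment (45 mmHg), making the
map continuous on [80, 100]; below 80% the rule changes form and the map
jumps from 45 to just under 40 — we keep the printed rule rather than
smoothing it.

**Hill-type inversion (methods C/D).** We use
$$\mathrm{PaO_2} = \left(\frac{27.8^{2.81}\, s}{1 - 0.99\, s}\right)^{1/2.8},
\qquad s = \mathrm{SpO_2}/100 .$$
The printed source for this equation is typographically corrupted, so the
package fixes one interpretation and isolates it in a single function
(`estimate_pao2_hill()`) so it can be swapped without touching scoring
code. This form was chosen because its half-saturation tension is
$27.8^{2.81/2.8} \approx 28$ mmHg — physiologic — and it reproduces the
classic anchor SpO2 90% → PaO2 ≈ 60 mmHg (59.79, by direct evaluation).
The 0.99 coefficient keeps the denominator positive at $s = 1$, so 100%
saturation maps to a finite ≈ 146 mmHg rather than diverging; no cap is
applied at high SpO2. Note the inner exponent 2.81 and outer 1/2.8 do not
cancel exactly; the identity value at $s/(1-0.99s)=1$ is 28.13 mmHg, not
27.8.

**SpO2 thresholds (methods E/F).** Score 0 for SpO2 > 94%, 1 for
(90, 94], 2 for (85, 90], 3 for ≤ 85%, plus one point when the patient is
on any respiratory support (supplemental oxygen or ventilation), capped at
4. Boundaries follow the printed inequalities exactly: strict lower, weak
upper.

**Conventional reference.** "Missing PaO2 as normal" is ambiguous between
imputing a normal tension and imputing a zero sub-score. The default
imputes PaO2 = 100 mmHg and scores through PF with the patient's *actual*
FiO2 — a ventilated patient without an ABG still scores points — because it
preserves the support information while taking "normal" literally. The
alternative (`conv_mode = "score_zero"`) zeroes the sub-score instead;
both are first-class code paths.

**FiO2 from the delivery device.** Room air is 0.21; nasal cannula adds
0.04 per L/min up to 6 L/min; simple masks map 5–6/7–8/9–10 L/min to
0.40/0.50/0.60 (flows outside that range are clamped to the nearest band);
reservoir masks give min(0.21 + 0.10·flow, 0.90) floored at 0.60;
high-flow and ventilator records carry their set FiO2 verbatim. This is a
standard reconstruction of an ED conversion chart, not a measured
device-specific calibration, and a local table can be supplied via
`read_fio2_lookup()`.

## Scoring conventions

"Respiratory support" — for the E/F bonus point and for the PF-score 3/4
gate — means any delivery other than room air. Non-respiratory organs use
the classic thresholds (platelets, bilirubin, MAP plus vasopressor dose
category, GCS, creatinine); renal scoring uses creatinine only, since
urine output is rarely charted reliably in this setting. Methods A/C/E
never read measured PaO2, and B/D/F reduce exactly to the conventional
measured-PaO2 branch whenever an ABG exists — both facts are enforced by
tests.

## Evaluation machinery

Discrimination is the midrank AUROC: with heavily tied integer scores the
tie-counts-half convention is not optional, so the estimator is computed
through midranks and its variance through DeLong structural components
(per-case and per-control placement values). Paired comparisons against
the conventional method use the DeLong covariance; when two methods induce
an identical ranking the difference has zero variance and the test is
reported degenerate with p = 1 rather than as 0/0. Two AUC intervals are
offered: the DeLong normal interval (default — it matches the paired-test
machinery) and a Hanley–McNeil binomial-style interval behind a flag,
since "exact binomial" interval constructions for an AUROC are not
standardized. Per-score mortality uses Clopper–Pearson beta-quantile
intervals. Calibration is plain nonstratified case resampling (default 100
replicates) with percentile intervals; the seed is a required, recorded
parameter and output is byte-reproducible. Two-sided p-values; no
multiple-testing correction across the six method-vs-conventional
comparisons.

## What the synthetic cohort emulates

A single latent severity factor $z \sim N(0,1)$ drives everything:

* **Gas exchange.** Room-air tension
  $\mathrm{PaO_2} = \mathrm{clamp}(100 - 30\,\sigma(z) - 40\,\sigma(1.5(z - 0.8)) + \varepsilon,\ 35,\ 110)$
  with $\sigma$ the logistic function and $\varepsilon \sim N(0, 6)$: a
  gentle decline for moderate illness and a steep deterioration term for
  the sick tail.
* **Oxygen therapy** is assigned by severity cutpoints (≈ 80% room air,
  12% nasal cannula, 3% simple mask, and ~5% reservoir/high-flow/
  ventilated), with flows and set FiO2 escalating in severity.
* **Two views of the supported patient.** The blood gas sees the
  *effective* tension (room-air PaO2 + 105·(FiO2 − 0.21)); the worst-in-24h
  oximetry value reflects only partial support (+30·(FiO2 − 0.21)),
  because continuous monitoring catches transient desaturation before or
  despite therapy while the one-time ABG is drawn on stable support. This
  asymmetry is what lets SpO2-based scores recover signal the conventional
  method misses; with a full boost on both, oxygen therapy cosmetically
  normalizes every sick patient's SpO2 and the threshold method E loses
  its discrimination.
* **Missingness.** PaO2 is recorded with probability
  $\sigma(-0.341 + 1.5 z)$ — sicker patients are measured more — giving
  ≈ 56% missingness overall and a measured subgroup with several-fold
  higher mortality, the pattern that makes "impute normal" look better
  than it is.
* **Outcome.** Death is Bernoulli with $\sigma(-3.869 + 1.5 z)$; the two
  intercepts were calibrated by Gaussian quadrature so the marginal rates
  hit ≈ 4.9% mortality and ≈ 44% measured. Organ labs are monotone
  log-normal/normal transforms of $z$ clamped to physiologic ranges.

SpO2 derives from tension through the forward Severinghaus curve
$S = 100\,(23400/(P^3 + 150P) + 1)^{-1}$, plus oximeter noise (default SD
1.5 percentage points) and rounding to whole percent — deliberately a
*different* curve family from the Hill inversion of methods C/D, so the
estimators face realistic model error rather than inverting their own
generator.

Randomness: every patient draws a fixed-size block from a sub-stream
seeded by (seed, patient index), so cohorts are reproducible and record
*i* is unchanged when *n* grows.

**What the generator does not emulate:** comorbidity structure, infection
foci, time-varying vitals, 28-day follow-up, and oximeter bias by skin
pigmentation or perfusion. Passing tests on this cohort show the scoring
and evaluation pipeline behaves correctly under a realistic missingness
mechanism; they do not validate any conversion against real patients.

## Numerical and design choices

* Integer scores throughout; sub-scores live in {0,…,4} and totals in
  0–24, enforced by construction and property tests.
* Degenerate inputs fail loudly: single-class outcomes are a statistical
  degeneracy error (exit code 3 at the CLI), invalid rows are reported
  with their indices (exit code 2), and a one-replicate bootstrap is
  flagged rather than silently returning zero-width intervals.
* Test problem sizes: oracle equivalence on 1,000 random tied instances
  (n ≤ 200), null size of the paired test on 2,000 replicates of n = 200,
  generator calibration at n = 15,000, self-consistency checks at
  n = 50,000 — sizes at which Monte-Carlo error is well below the asserted
  tolerances.
* The package reports; it does not decide. Nothing here adjudicates which
  conversion is clinically preferable — that depends on the real
  SpO2/PaO2 relationship in the population at hand, which a synthetic
  cohort cannot settle.
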