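---
title: "Projecting absolute breast-cancer risk in South-East Asian women"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting absolute breast-cancer risk in South-East Asian women}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searisk)
```

## The problem

A woman asking "what is my chance of developing breast cancer in the next
five years?" needs an *absolute* risk: a probability that accounts both for
her personal risk factors and for the competing possibility that she dies
of something else first. Gail-type models answer this by combining three
ingredients: a relative-risk function over categorised questionnaire
factors, population age-specific incidence deflated to a referent-profile
baseline, and population other-cause mortality. The models in this package
are the variants calibrated to the Singapore screening population — where
incidence is roughly half that of US Caucasian women and the classical
model over-predicts by two thirds — for women of Chinese, Malay and Indian
origin.

## The hazard model and its assumptions

Age is divided into fifteen intervals (0–19, then 5-year steps to an
open-ended 85+ interval). Within interval $j$ a woman with relative risk
$r$ faces a constant breast-cancer hazard $b_j r$ and an independent
other-cause mortality hazard $c_j$, with

$$b_j = B_j\,(1 - \mathrm{AR})/10^5,$$

where $B_j$ is the population incidence per 100,000 woman-years and
$\mathrm{AR}$ the attributable-risk fraction of the modelled factors. The
probability of a first breast-cancer diagnosis within $[a, a+h)$ is

$$P(a, a+h, r) \;=\; \sum_j \frac{b_j r}{b_j r + c_j}\;
\tilde S(s_j)\,\bigl(1 - e^{-\delta_j (b_j r + c_j)}\bigr),$$

where the sum runs over intervals overlapping the horizon, $s_j$ is the
start of the overlap, $\delta_j$ its length, and $\tilde S$ the joint
event-free survival accumulated from $a$ with the same piecewise hazards.
The three-way decomposition (diagnosis, other-cause death, event-free)
telescopes to exactly 1. The model assumes proportional hazards within the
two broad age classes, independence of the two causes, and that the
questionnaire factors act multiplicatively on incidence.

Three design points deserve note:

* **Partial exposures.** The textbook presentation fixes $\delta_j = 5$
  and assumes the start age sits on an interval boundary. We generalise to
  arbitrary entry ages and horizons through per-interval exposures; on
  aligned inputs the two coincide exactly (a tested property). Without
  this, any woman aged, say, 52 at entry could not be projected honestly.
* **The age-50 switch.** Both $r$ and AR are indexed by the binary
  current-age category with its cut at 50. Because 50 is an interval
  boundary, the switch happens between intervals, never inside one; a
  horizon crossing 50 uses the under-50 quantities before the boundary and
  the 50+ quantities after.
* **Survival from the start age.** $\tilde S$ is accumulated from $a$
  rather than from birth (equivalent to the ratio form
  $S(\tau_{j-1})/S(a)$); this avoids multiplying fifteen decades of
  survival and the attendant underflow.

Degenerate inputs are handled by limits rather than special cases: a zero
total hazard contributes nothing to any cause (the $0/0$ factor is taken
as 0 with $1 - e^0 = 0$), and all arithmetic is in double precision. The
last age interval is open-ended in the published tables but carries a
nominal 5-year width here, so projections are refused beyond age 90 —
consistent with the oldest published use (entry 74, horizon 5).

## Parameters

Rate tables (`builtin_rate_table`) are stored exactly as published, per
100,000 woman-years, and rescaled only at the point of use — this keeps
every stored number greppable against its source. Five tables ship:
`caucasian-1983-87`, `sg-overall`, `sg-chinese`, `sg-malay`, `sg-indian`.

Coefficient sets (`builtin_coefficients`) carry the log relative-risk
coefficients, interaction terms, admissible code ranges, and the
attributable-risk pair:

* `bcddp` — the original six-factor model with the biopsy-by-age and
  first-birth-by-family-history interactions, AR pair 0.4771/0.4736. The
  atypical-hyperplasia coefficient (0.57405) is retained but contributes
  only when the status is known; an unknown status contributes zero, which
  is how the Singapore validation handled it.
* `gail-sbsp` — the same coefficients with biopsies pooled to 0 / ≥1
  (biopsy histories could not be counted beyond "ever"), driven by
  Singapore rates.
* `s-gail-sbsp` — three factors only (menarche 0.238, first birth 0.183,
  family history 0.777), re-estimated on the Singapore nested
  case-control study.
* `e-gail-sbsp` — adds BMI (0.380, WHO-Asian cuts 23.0/27.5) and parity
  (0.203), with the Singapore AR pair 0.5356/0.5397.

The record does not state which AR pair drove the simplified model's
published projections; its near-identical total expected count to the
full Singapore model argues for the BCDDP pair, which is the default here,
and the pair is overridable (`builtin_coefficients("s-gail-sbsp",
ar = c(...))`) for sensitivity analysis.

## Category coding

Coders are total on valid input and never raise on missing values: an
unknown maps to its factor's referent bucket (code 0). The one exception
is age at first live birth, whose category structure already pools
nulliparity into the "25–29 or nulliparous" bucket (code 2); an unknown
age lands there by default, and the destination is configurable
(`code_ageflb(..., unknown_code = )`) because no published rule exists.
Category bounds are closed on the printed lower edge (BMI 23.0 → code 1,
age 50 → the older age class), and ages are whole years throughout.
Internally contradictory records — nulliparous with positive parity, or an
age at first birth alongside parity 0 — are rejected naming the conflict
rather than silently re-coded.

## Calibration and discrimination

`expected_cases` is the sum of individual predicted risks;
`eo_ratio_ci` forms $E/O$ with the log-scale interval
$(E/O)\exp(\pm 1.96\sqrt{1/O})$, undefined when $O = 0$. The constant
1.96 is fixed rather than computed from a quantile so published intervals
reproduce digit for digit.

`goodness_of_fit` refers $\sum (O-E)^2/E$ to a chi-square with $k$ degrees
of freedom, $k$ the number of categories. The usual Pearson convention
would be $k - 1$; here the expected counts come from an externally
specified model rather than from parameters fitted to the grouped data, and
$k$ (with $k = 1$ for single-group totals) is also the only choice that
reproduces the published p-values this implementation is validated
against. The deviation is deliberate and tested.

`auc` is the rank-based concordance with midranks for ties — equivalent to
the trapezoidal area under the ROC curve, and invariant under any strictly
monotone transform of the scores. That invariance is why no intermediate
logistic regression of status on risk is needed: fitted probabilities from
such a model are a monotone transform of the risks, so the concordance is
unchanged (a tested property). The variance estimator is Hanley–McNeil;
the published record does not name its estimator, and for bands of
thousands of women the choice is immaterial next to the binomial noise in
the case counts. `weighted_concordance` averages band-specific AUCs with
weights proportional to band size, renormalised over the bands that can
contribute (a band with no case, or no non-case, has no concordance and is
excluded), with variance $\sum w^2 \hat v$.

`decile_calibration` splits by predicted risk into ten near-equal buckets,
ties resolved by stable input order and any remainder distributed one
woman at a time to the lowest deciles.

## The synthetic cohort

`simulate_cohort` emulates the screening population the models were
validated on: entry ages in proportion 109 : 13,911 : 14,642 : 221 over
45–49/50–59/60–69/70–74 (uniform whole years within band), ethnic mix
24,339 : 1,619 : 1,422 Chinese/Malay/Indian, and risk factors at the
published prevalences — menarche 62.19/33.60/4.22%, BMI
36.82/43.06/20.12%, parity 65.0/23.7/11.3%, biopsy fraction 1,707/28,883,
and the first-birth-by-family-history *joint* cells as published (this is
the one joint distribution available, so it is drawn jointly; all other
factors are sampled independently because only marginals are published — a
documented fidelity gap). Nulliparity is drawn conditionally inside the
"25–29 or nulliparous" cell at rate $P(\text{parity}=0)/P(\text{cell})$,
which keeps records internally coherent while preserving both the joint
cells and the parity marginal exactly in expectation.

Outcomes are drawn from precisely the piecewise-exponential
competing-risks model the engine evaluates, by inverse transform on the
piecewise cumulative hazard. This makes the simulator a Monte-Carlo oracle
for the engine (the two are checked against each other at $n = 10^6$), and
makes simulated cohorts *self-consistent*: scoring a cohort with its own
generating model should show calibration noise only, which is exactly what
the test suite asserts (E/O intervals covering 1 in ≥95/100 seeded
replicates; decile tables within binomial bounds).

What passing these tests does **not** show: agreement with real screening
data. The simulator has no secular incidence trends, no screening
lead-time, no left truncation, and — unlike the source cohort, whose
follow-up clock started three years after a negative screen — no selection
of event-free survivors, which in reality depresses early incidence. The
published cohort-level expected counts (241.83 and kin) require the
individual-level screening records and are not reproducible from printed
material; self-consistency is the strongest desk check available, and the
weighted concordance of a 30,000-woman synthetic cohort (≈0.59 under the
simplified model) brackets the published 0.5997 without reproducing it.

## Problem sizes and randomness

All randomness flows from explicit seeds; the same seed reproduces a
cohort exactly. The test suite works at sizes chosen to keep Monte-Carlo
noise well below the tolerances asserted: $10^5$ women for prevalence
checks, $2\times10^5$–$10^6$ for hazard-model agreement (three standard
errors), 100 replicates of 30,000 for calibration coverage, and a
$10^{-4}$-year midpoint quadrature for the independent fine-grid check of
the projection sum (agreement to $10^{-8}$ over 50 random parameter
draws).

## Known limitations

Projections are refused outside ages 20–90. Relative risks treat category
codes as linear scores, exactly as the source models do — there is no
re-estimation, and coefficient uncertainty is not propagated (no
confidence intervals on individual risks). The Malay and Indian rate
tables rest on small populations and inherit their noise. None of the
shipped models has been validated for women under 45, and the simplified
model's AR ambiguity above should be borne in mind when absolute levels —
rather than rankings — matter.
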