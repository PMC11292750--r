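---
title: "Methods: computing and validating days alive and out of hospital"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: computing and validating days alive and out of hospital}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daoh90)
```

## The outcome and its day-counting conventions

Days alive and out of hospital over a horizon of $H$ days (DAOH-$H$,
$H = 90$ by default) counts, for each day in the half-open window
$[\text{index day}, \text{index day} + H)$, whether the patient was dead,
in an institution (acute hospital, inpatient rehabilitation, or
residential care), or at home, and reports the number of home days.
Each day has exactly one status, with priority
$\text{dead} > \text{in hospital} > \text{home}$, so in the standard
variant the accounting identity

$$\text{DAOH} + \text{days in hospital} + \text{days dead} = H$$

holds for every patient; the test suite asserts it on every randomized
fixture.

Administrative feeds do not state their day-counting rules, so this
package fixes them explicitly:

* **Half-open episodes** $[\text{admit}, \text{discharge})$: the
  admission day is in hospital, the discharge day is out. This makes
  length of stay equal `discharge - admit` and gives a patient with a
  typical 5-day index stay the score 85 — the upper mode seen in real
  DAOH distributions.
* **Same-day transfers merge**: a discharge and admission on the same
  day (acute ward to rehabilitation, say) form one continuous
  institutional spell. Noncontiguous stays are summed after merging.
* **The death day counts as dead**, and dead status overrides any
  concurrent admission, so an in-hospital death is never double-counted.
  This choice is arbitrary (the alternative would credit the death day to
  the hospital); it is isolated in one place and changes any patient's
  score by at most one day.
* **Pre-index history is ignored with a warning**; an episode straddling
  the index day is clipped to the window. Episodes are otherwise treated
  uniformly regardless of facility type.
* **Death-day placement in the generator is uniform** over the feasible
  window; this is arbitrary and documented as such.

The `death_zero` variant recodes every patient who died before day
$H$ to a score of 0, the post-hoc sensitivity recoding in which home days
accrued before an early out-of-hospital death are not credited. It never
exceeds the standard score and agrees with it exactly for 90-day
survivors (and for deaths whose standard score was already 0).

An independent day-by-day classifier, `daoh_oracle()`, implements the
definition literally (loop over days, classify, count) and is held apart
from the interval arithmetic of `compute_daoh()`; their exact agreement
on randomized episode sets — overlapping, abutting, pre-index, zero-length,
with deaths in and out of hospital, horizons 1–90 — is the engine's main
correctness argument.

## The synthetic registry

No patient-level registry ships with this package; instead a generative
model emulates the *structure* of an administrative stroke cohort so that
methods can be validated end-to-end against known ground truth.

Each patient receives covariates (age $\sim$ N(70, 13) bounded to
18–100; NIHSS discretized from N(14, 7.5) on 0–42; ASPECTS as
$10 - \text{Pois}(2)$ capped at 0; binary comorbidity, treatment, ICU and
sICH flags), and a latent severity

$$S = \sum_c \lambda_c \, z(\text{covariate}_c) + \varepsilon,\qquad
  \varepsilon \sim \mathrm{N}(0, \sigma^2),$$

with fixed standardization constants so loadings mean the same thing at
any cohort size. Severity then drives, monotonically and controllably:

* **index length of stay**: lognormal with log-mean
  $\mu_{LOS} + \gamma_{LOS} S$, rounded up to at least 1 day;
* **readmissions**: count $\sim$ Poisson$(\rho_0 e^{\rho_1 S})$, placed
  disjointly (rejection sampling; abutting placements allowed — the
  engine merges them) in the remaining window, with facility-specific
  stay lengths (acute $\approx$ 4 d, rehabilitation $\approx$ 25 d,
  residential $\approx$ 30 d on the log scale);
* **death within 90 days**: Bernoulli with logit
  $\alpha + \beta S$, death day uniform over the window, in or out of
  hospital;
* **mRS-90**: ordered logit on $S$ with six strictly increasing
  cutpoints; survivors are capped at 5 and the score is forced to 6
  exactly when the patient died within 90 days, so mRS 6 $\iff$ death —
  the scale's own definition.

Missingness is injected completely at random per field (the real
mechanism in administrative data is unknown), except recanalization,
which is *structurally* missing in patients without an angiogram
(IVT-only), as in real cohorts where mTICI grading requires one.

Defaults were chosen once so the marginals loosely resemble a national
reperfusion cohort — median NIHSS about 14, median ASPECTS 8, roughly
15% 90-day mortality, about half the cohort functionally independent,
and a right-skewed bimodal DAOH with modes near 0 and the high 80s — and
then frozen. Because death simultaneously forces mRS 6 and truncates
DAOH, a mortality-driven DAOH–mRS correlation exists even with all
severity links switched off; decoupling tests therefore also silence the
base death rate. What passing tests on this registry do **not** show:
fidelity to any real registry's episode-count or length-of-stay
marginals, informative missingness, mRS interrater noise, or transfer
semantics beyond same-day merging.

## The validity battery

All tests are two-sided with $\alpha = 0.05$ and no multiplicity
adjustment; records enter every analysis for which their variables are
observed (pairwise deletion), and medians of even-sized groups average
the two central order statistics.

* **Spearman correlation**: Pearson correlation of midranks. The p-value
  uses the $t$ approximation on $n-2$ degrees of freedom; for $n \le 8$
  the exact permutation distribution is enumerated instead (all $n!$
  rearrangements, valid under ties). Eight is the enumeration bound
  because $8! = 40{,}320$ statistics are instant while $10!$ is three
  orders of magnitude more work for a p-value the $t$ approximation
  already serves well.
* **Mann–Whitney**: midrank $U$; exact enumeration of all
  $\binom{n}{n_1}$ group assignments when both groups have $\le 8$
  observations (so e.g. complete separation at $3$ vs $3$ gives the
  exact two-sided $p = 2/20 = 0.1$), otherwise the normal approximation
  with tie-corrected variance and continuity correction.
* **ROC discrimination**: AUC is the tie-adjusted concordance
  probability, identically $U/(n_+ n_-)$; the identity is asserted to
  $10^{-12}$ on random data. Confidence intervals use DeLong's
  placement-value variance (analytic and deterministic; the method is
  cross-checked against an independent implementation in the test
  suite). Orientation is fixed so higher DAOH predicts the good outcome.
* **Dichotomies**: good outcome is mRS $\le k$ for
  $k \in \{0, 1, 2, 3\}$ (functional independence is $k = 2$); the DAOH
  dichotomy threshold defaults to $> 70$ days and is configurable.
* **Logistic models**: maximum likelihood by iteratively reweighted
  least squares (via `stats::glm`, log-likelihood tolerance $10^{-8}$,
  at most 100 iterations), listwise deletion within the model with
  `n_used` reported, in-sample c-statistic from the fitted
  probabilities, and complete separation surfaced as a warning rather
  than silently returning divergent coefficients. The default predictor
  set — age, sex, admission NIHSS, ASPECTS, recanalization, ICU
  admission — approximates commonly established outcome predictors and
  is fully configurable.
* **Subgroup table**: binary factors split directly; continuous factors
  at the cohort median (value $\ge$ median counts as "present").
  Differences are always present-minus-absent, so relabelling levels
  flips every sign exactly. Single-level factors yield a row with the
  difference marked unavailable. Reported p-values are unclipped.

## Pipeline and reproducibility

`run_pipeline()` chains simulate (or load) → compute → validate and
writes `daoh.csv`, `report.json`, `roc_curves.csv` and `manifest.json`;
the manifest records the seed, an MD5 hash of the canonical JSON
rendering of the configuration, input-file digests and the package
version, so identical manifests (timestamp aside) imply identical
numbers. All randomness flows through the single configuration seed.
Degenerate inputs — a constant score, an empty outcome class, everyone
dead on day 0 — surface in the report as named unavailable entries with
the reason, not as crashes.

## Problem sizes used in validation

The shipped checks use cohorts of 400–2000 synthetic patients for
structural and coupling properties, 1000 randomized single-patient
fixtures for engine/oracle equivalence, 100 random datasets for the
AUC–U identity, and 5000 rows for logistic parameter recovery; at these
sizes sampling noise is far below the asserted margins and the whole
suite runs in about a minute on one core.

## Known limitations

* DAOH weights all institutional days equally; an ICU day and a
  residential-care day both subtract one day, so intensity of care is
  not captured.
* Day-level granularity: same-day admission and discharge contributes
  zero hospital days under the half-open rule.
* The generator's parametric forms (lognormal stays, Poisson
  readmissions, proportional-odds mRS) are convenience choices with
  monotone severity links, not fits to any real registry.
* Whether real registries count the admission or discharge day as
  in-hospital varies; results at the margin (one day per transition)
  depend on the declared convention.
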