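---
title: "Non-categorical child health indicators and maternal outcomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-categorical child health indicators and maternal outcomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dyadhealth)
```

## The problem this package addresses

Caregivers of children with health problems tend to have poorer health than
caregivers of healthy children, but population-level evidence has mostly come
from surveys, which are expensive, prone to recall and single-respondent
biases, and cover specific conditions unevenly. Routinely collected
administrative health data — insurance registries, fee-for-service physician
billings, pharmacy dispensings and hospital discharge abstracts — offer an
economical, objective alternative, provided child health can be expressed
without enumerating diagnoses.

`dyadhealth` implements such a *non-categorical* design end to end. Children
aged 6–10 in a single study year are grouped by two indicators:

* **High Service Use (HSU)** — elevated use of health services, met by
  either of two criteria modelled on the first two items of the Children
  with Special Health Care Needs screener: (i) at least 274 days (nine
  months) of prescription-medication coverage within *some* 365-day window
  of a three-year observation span, or (ii) a study-year physician-visit
  count at or above the age-specific 95th percentile.
* **Diagnosis (Dx)** — any study-year diagnosis code mapping to a major
  and/or chronic Aggregated Diagnosis Group (ADG) in the sense of the Johns
  Hopkins ACG case-mix system.

The four combinations are ordered by severity — Neither < Diagnosis only <
HSU only < Both — and each mother is assigned the group of her most severe
child. Maternal health and service-use outcomes are then compared across
groupings using pooled-SD Cohen's *d* and four covariate-adjusted regression
models.

Because the source data for such studies sit in restricted provincial data
enclaves, the package ships a first-class synthetic generator emulating the
four linked streams with known ground truth, so every stage is testable and
the statistical machinery can be validated by parameter recovery.

## Indicator construction

### Medication days

A day of medicine use is any calendar day covered by at least one dispensing
interval `[fill_date, fill_date + days_supplied - 1]`. Intervals are closed,
day-granular, anchored at the fill date, and **unioned**: a day covered by
three concurrent drugs counts once, and overlapping refills are not
stacked or shifted forward (the quantity measured is days *of use*, not
pill possession). `covered_days()` merges sorted intervals; the flag
requires `max_window_coverage()` — the maximum of `covered_days` over every
365-day window whose start lies in the observation span (default
2005-01-01 to 2007-12-31, i.e. the study year ± one year). Windows may
start on *any* calendar day. Because coverage as a function of the window
start is piecewise linear, only starts aligned with merged-interval
endpoints (and the span boundaries) need inspection; a brute-force
day-enumeration oracle in the test suite confirms the sweep on over a
thousand random dispensing histories.

Numerical conventions: dispensings are clipped to the span before merging;
an empty history scores 0; a span shorter than the window is a
configuration error rather than silently returning 0.

### Visit percentile cut-offs

For each age 6–10, the cut-off is the *nearest-rank* empirical percentile:
the value at order statistic `ceiling(0.95 * n)` of the age stratum's visit
counts, with the comparison inclusive ("at or above"). On distinct counts
this flags `n - ceiling(0.95 n) + 1` children (six of a hundred; 5% in the
large-sample limit); ties can only enlarge the flagged set, which is one
reason the combined HSU prevalence exceeds the 5% nominal tail. Visit
counts for the cut-offs use study-year physician claims of service class
`visit`, excluding laboratory and x-ray claims — the same convention as the
child-outcome tables; this is configurable because source studies do not
always state it. Cut-offs are computed on the *full* child sample (before
dyad selection), matching how a registry-wide distribution would be used.

### Diagnosis flag

The licensed ACG grouper is proprietary and the specific list of twelve
major/chronic ADGs used for children is not public. The package therefore
treats the grouping as configuration: a two-column mapping from ICD-9
prefix to ADG id (`adg_map`, longest-prefix match on dot-stripped codes)
plus a set of major/chronic ADG ids. The shipped defaults
(`default_adg_map()`) are an illustrative *synthetic* mapping sized like
the real one (twelve major/chronic ids among 32) and adequate for the
synthetic code universe; real analyses must supply their own mapping.
Hospital-abstract diagnoses feed the flag alongside physician claims by
default (`include_hospital_dx`), since whether the source design included
them is unstated. Unmapped codes warn and are ignored by default
(configurable to `error`).

## Cohort construction

Children link to mothers through the shared family contract identifier.
Three rules, applied in order:

1. Children linked to more than one mother record (as can happen after
   marital separation) are excluded; the generator produces such links for
   12% of children so the exclusion is exercised.
2. Every linked child must carry a group assignment; a missing one is a
   precondition error, not a silent drop.
3. One index child per mother: the child with the most severe group. The
   tie-break among equal-severity siblings — eldest child first, then
   lexicographically smallest child id — is a package convention (source
   descriptions are silent); it makes selection deterministic and invariant
   to input row order, which the tests verify by permutation.

Maternal age is `study_year - birth_year`, the only resolution the registry
carries.

## Outcome construction

All outcomes are person-year aggregates over the event streams:

* Visit counts by service class; for mothers, claims flagged
  pregnancy-related or carrying a pregnancy/birth ICD-9 prefix (defaults:
  V22, V27, 630–679) are excluded from visit and specialist counts.
* Distinct specialists: distinct `specialty_code` values among qualifying
  visit claims.
* Prescription outcomes: fills in the year (birth-control fills excluded
  for mothers by default); medication days reuse the interval-union engine
  clipped to the year (so ≤ 365); therapeutic breadth is the number of
  distinct level-3 ATC classes, i.e. distinct 4-character prefixes;
  pain and insomnia flags are ATC-prefix matches (defaults N02/M01A and
  N05C), standing in for unpublished DIN-level lists.
* Hospitalization: length of stay is counted as *nights*
  (discharge − admit), clipped to the year's boundaries, so a stay spanning
  New Year contributes only its in-year nights; a same-day stay contributes
  zero days but still sets the any-hospitalization flag; birth-related
  stays are excluded from maternal outcomes.
* Condition flags: ICD-9 prefix lists per condition, one-year lookback
  only (the design is a single-year cross-section, which is also why
  administrative prevalences sit below "ever diagnosed" survey estimates).
  `any_chronic` is the OR over *all* configured lists, mood/anxiety
  included. The shipped lists are illustrative and user-replaceable.

## Statistical methods

**Effect sizes.** For groups $a, b$ with sizes $n_a, n_b$, means and SDs,
$$d = \frac{\bar{x}_a - \bar{x}_b}{s_p}, \qquad
s_p = \sqrt{\frac{(n_a-1)s_a^2 + (n_b-1)s_b^2}{n_a+n_b-2}},$$
categorised on $|d|$ with left-closed bins: trivial $< 0.2$, small
$[0.2, 0.5)$, medium $[0.5, 0.8)$, large $[0.8, 1.2)$, very large
$\ge 1.2$. The prose convention "0.2 to 0.5, 0.5 to 0.8" is ambiguous at
the boundaries; left-closed bins are this package's resolution. Binary
outcomes are compared as $d$ on the 0/1 indicator, with
$s = \sqrt{p(1-p)\,n/(n-1)}$ per group; Cohen's *h* would be a reasonable
alternative and the summaries needed to compute it are exposed. A zero
pooled SD yields $d = 0$ when the means agree and an explicit
undefined-effect error otherwise.

**Regressions.** Four models share one covariate set: maternal age,
lowest-income-quintile flag, premium-subsidy flag, child age, child-female
flag, and the four-level child group with Neither as reference. The visit
count uses OLS (both unadjusted and adjusted $R^2$ are reported; we treat
the unadjusted value as primary since at these sample sizes they agree to
three decimals). The three binary outcomes use maximum-likelihood logistic
regression with Wald 95% CIs (normal quantiles on the log-odds scale,
exponentiated) and the Nagelkerke pseudo-$R^2$
$$R^2_{N} = \frac{1 - \exp\{2(\ell_0 - \ell_1)/n\}}{1 - \exp\{2\ell_0/n\}},$$
which is 0 when the full model adds nothing and 1 at a perfect fit. No
multiple-testing adjustment is applied: with cohorts of this size trivially
small differences are significant, and the design is effect-size-first.
Rare outcomes in small cohorts can leave a group cell with no events; the
resulting quasi-separation is detected (divergent log-odds after an extreme
fitted-probability warning) and the model is skipped with a warning rather
than reported.

## The synthetic generator

### What it emulates

One study-year cross-section of `n_families` families: one or two mother
records per contract (two with probability 0.12, generating the excluded
multi-mother links), one to three children aged 6–10 (≥ 2 with probability
0.23), area income quintile and premium-subsidy flags as SES proxies, and
four event streams shaped like registry, claims, dispensing and discharge
data with ISO dates, ICD-9-like codes and 7-character ATC codes.

Each child draws a latent class — Neither, Diagnosis-only, HSU-only, Both —
governing its event streams:

* visit counts are negative-binomial per class and age (Neither mean ≈ 2.5,
  SD ≈ 2.3; HSU classes mean ≈ 8–11), reproducing the heavy right tails
  (SD > mean) that service-use counts show;
* children in the HSU classes receive a chronic medication spell: contiguous
  lognormal-length refills totalling 274–340 covered days inside one
  365-day window, so the medication criterion is met by construction;
  everyone may also receive short acute fills;
* children in the Dx classes carry at least one claim whose code maps to a
  major/chronic ADG; all other codes map to minor ADGs.

### Calibration

The prevalence targets (defaults 18% HSU, 12% Dx, 5% Both, hence 75%
Neither) refer to the *recovered* indicators, and the visit criterion is
relative: the empirical 95th-percentile cut-off always flags ≈ 5% of each
age stratum, sweeping in some Neither and Dx-only children with genuinely
high visit counts. `calibrate_latent_probs()` therefore solves for the
latent class probabilities by a small fixed point: given trial
probabilities it computes the expected per-age cut-off from the
negative-binomial mixture CDF, the resulting spillover tail probabilities
for the Neither and Dx-only classes, and adjusts the latent probabilities
so the *expected* recovered prevalences equal the targets. The fixed point
uses distribution functions only — no simulation — and converges in a
handful of iterations. The residual error is the integer-grid wobble of the
empirical cut-off, well inside the three-binomial-SE acceptance band at
50,000 families.

### Maternal outcomes

After the child streams are drawn, the generator classifies its own
children with the same code the pipeline uses and assigns each mother the
most severe realised group in her family — exactly the group the analysis
will assign her. Maternal outcomes are then drawn from the configured
models: a negative-binomial visit count with additive group shifts
(defaults 1.33 / 4.57 / 4.87 for Dx-only / HSU-only / Both over a Neither
mean of 6.14), and logistic models for mood/anxiety, any chronic condition
and hospitalization with configured odds ratios over Neither base rates
(13.59%, 27.42%, 2.68%). Because `any_chronic` is the OR over all condition
lists (mood included), the two binary draws are *coupled*: mood is drawn
from its logistic model and the any-chronic indicator is completed by an
extra draw with probability $(p_c - p_m)/(1 - p_m)$, so both marginals are
exactly the configured logistic models while the implication mood ⇒
any-chronic holds. Condition codes ride on visit claims; a single visit
claim is force-added only when a condition is true and the drawn visit
count is zero, biasing group visit means by ≈ 0.03 visits — an order of
magnitude below recovery tolerances. Streams that must *not* move the
outcomes (pregnancy claims, birth-control fills, birth hospitalizations,
lab/x-ray claims) are emitted too, so the exclusion logic is exercised
rather than vacuous.

Seeding: one master seed; each stream draws under its own deterministically
derived seed (`derive_seed()`), so a fixed configuration is byte-identical
across runs and a single stream can be regenerated without replaying the
others.

### What it does not emulate

No per-condition epidemiology (codes are placeholders with the right
structure, not realistic ICD-9 frequencies), no provider behaviour, costs,
coverage gaps, mortality or migration, and no multi-year trajectories.
Covariates other than the child group have no true effect on maternal
outcomes, so passing recovery tests demonstrates the estimators and
plumbing, not robustness to confounding found in real data. Linkage error,
miscoding and the under-capture of mental-health services that plague real
administrative data are likewise out of scope — conclusions about real
data quality cannot be drawn from these simulations.

## Validation problem sizes

The test suite validates calibration on one 50,000-family population
(three-binomial-SE bands on all three prevalences) and parameter recovery
and the qualitative grouping pattern on 50 seeded replicates of 3,000
families each, for both the default and the null effect configuration —
sizes chosen so that coverage statements are binomially stable while the
whole suite remains comfortably runnable on a laptop. Interval-engine
equivalence is checked against day-enumeration on 1,000 random dispensing
histories, and the regression engines against closed-form oracles (normal
equations; the 2×2 cross-product ratio; Nagelkerke endpoints).

## Known limitations

* The ADG mapping and all ICD-9/ATC code lists are illustrative defaults;
  scientific use requires the licensed grouper's output or validated lists.
* The mood/anxiety definition in real studies follows a specific published
  administrative definition; the default list here is a plausible stand-in.
* Effect sizes for proportions use the 0/1-scale *d*; magnitudes near
  category boundaries can differ under arcsine-based alternatives.
* Same-day hospital stays set the flag while contributing zero days, so
  `days_hospitalized >= any_hospitalization` can fail for those persons —
  a deliberate consequence of the nights convention.
* The single-year design cannot distinguish incidence from prevalence, and
  nothing here supports causal claims about caregiving and maternal health.
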