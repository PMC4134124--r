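---
title: "Ascertaining IBD incidence from administrative claims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ascertaining IBD incidence from administrative claims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdclaims)
```

## The problem

Inflammatory bowel disease (IBD) — Crohn's disease (CD), ulcerative colitis
(UC) and undifferentiated IBD (IBDU) — is not recorded directly in
administrative health databases. What those databases do record is every
billed physician contact and every hospital discharge abstract, each carrying
ICD diagnosis codes. `ibdclaims` turns such claim and discharge streams into
annual incidence estimates in four stages:

1. **Case ascertainment** — a validated-style scored algorithm that decides
   who is an IBD case and whether the phenotype is CD, UC or IBDU;
2. **Incident-case identification** — a pre-study washout (run-in) period
   that removes prevalent cases;
3. **Direct age standardization** of annual rates per 100,000;
4. **Poisson log-linear trend regression** with calendar year as a
   categorical factor.

Because real provincial claims databases are confidential, the package ships
a synthetic-claims generator with known ground truth, so every stage is
testable end to end.

## The case definition

Diagnosis codes are mapped by stem: ICD-9 `555.x` and ICD-10 `K50.x` are CD
codes; ICD-9 `556.x` and ICD-10 `K51.x` are UC codes. A person enters the
IBD cohort (the *gate*) with **at least one hospital discharge, or four
physician claims within a two-year period**, carrying such codes. The claim
window is implemented as a half-open 730-day interval `[t, t + 730)`
anchored at each claim date — anchoring at claims loses no window, and 730
days is used regardless of leap years so the arithmetic is exactly
reproducible.

Gated patients are then sub-classified by a cumulative score over their
IBD-coded contacts:

| contact                  | score |
|--------------------------|-------|
| physician claim, UC code | +1    |
| physician claim, CD code | −1    |
| hospital discharge, UC   | +2    |
| hospital discharge, CD   | −2    |

A cumulative score strictly greater than +2 is UC, strictly less than −2 is
CD, and anything in `[−2, +2]` is IBDU. For example, one hospitalization
with a UC discharge diagnosis plus one UC physician claim scores
`(+2) + (+1) = +3`, classifying the patient as UC. The labels partition the
integers, and swapping every UC code for a CD code negates the score and
swaps the CD/UC labels — both are verified as properties in the test suite.

**Classification window.** The source case definition does not state which
encounters feed the cumulative score. The package default scores all
IBD-coded encounters from the first contact through 730 days later — the
same two-year horizon as the gate, bounded and deterministic.
`classification_window_days = NULL` switches to all available follow-up.
Same-day encounters all count; within-day order is irrelevant because scores
are sums and the gate uses dates only.

**Washout and dating.** Any person with an IBD-coded contact during the
washout years (default 1991–1995) is excluded as prevalent. The diagnosis
date of an incident case is the *first* IBD-coded contact on or after the
study start, even when the gate is only satisfied later in the window;
incidence year is the year of that date. In the default profile the washout
span abuts the study span (1996–2009), so an incident case cannot have an
unobserved earlier contact inside the record span.

## Incidence estimation

Annual denominators are population counts of covered persons (not exact
person-days): age is calendar-year age, `year − birth_year`, consistent with
annual population tables. Crude rates are `100000 × cases / population`; a
cell with neither cases nor population carries an explicit zero rate with a
flag, and positive cases over a zero denominator is an error.

Direct standardization computes `Σ_a w_a r_a` over age bins with fixed
standard weights. The bundled standard
(`canada_2006_synthetic_standard.csv`) approximates the 2006 Canadian census
age distribution aggregated to 10-year bins; it is labelled synthetic
because it is a recorded approximation rather than an official extract, and
any standard can be supplied via `read_standard_population()`. Sexes-combined
standardized rates use pooled (both-sex) age-specific rates with the same age
weights; sex-specific standard weights are never used. Because all diseases
share the weights, the IBD standardized rate equals the sum of the CD, UC and
IBDU standardized rates — asserted as a linearity property in the tests.

## Trend model

For each disease (CD, UC, IBDU and the IBD union), sex level (women, men,
combined) and age stratum, incident counts are modelled as

`log E[count] = log(population) + α + β_year (+ γ_agegroup)`

with calendar year categorical and 1996 the reference level; the all-ages
rows add an age-group factor ("adjusted for age"). Fitting is maximum
likelihood by iteratively reweighted least squares (`stats::glm`,
`family = poisson`, convergence tolerance `1e-12`, ≤100 iterations) with
observed-information (Wald) covariance — the same plain Poisson, z-interval
behaviour as classical GENMOD-era analyses; overdispersion is deliberately
not modelled. The reported one-number summary per stratum is the final-year
contrast `100 × (exp(β_final) − 1)` with its 95% Wald interval, matching the
convention of reporting a single "% change 1996–2009" per row; contrasts for
every year level are also emitted for users who want per-year summaries.
Zero-population cells are excluded from the likelihood with a warning, and a
year level whose counts are all zero is reported non-estimable rather than
crashing. A saturated single-stratum fit reproduces empirical rate ratios to
1e-8, which is the exactness oracle for the fitter.

## The synthetic-claims generator

The generator emulates the structure of a provincial administrative
database, not any particular province's numbers:

* **Population.** `n_persons` covered persons with a configurable sex ratio
  (default 0.51 female) and age distribution over 10-year bins (default
  roughly an older eastern-Canadian structure). The sampled "age at first
  study year" extends to negative values at the youngest bin's per-year
  density, i.e. cohorts born during the study, so the `<10` denominator
  stays populated across the span. There are no deaths or migration —
  consistent with a stable, low-migration population, and immaterial to the
  pipeline being exercised.
* **Onsets.** Disease-free persons acquire CD or UC in year `y` with hazard
  `rate[d, age, sex]/100000 × trend_d^(y − 1996)`; at most one disease per
  person, onset dates uniform within the year. Defaults: a bell-shaped age
  profile peaking at 20–29 (CD steeper than UC), annual trend 0.97 for CD
  and 0.98 for UC — a declining-incidence regime. Onsets are drawn from the
  washout start onward so prevalent cases exist for the washout to remove.
* **Care contacts.** After onset, physician claims are Poisson per year
  (default mean 4) and hospitalizations Bernoulli per year (default 0.2),
  prorated in the onset year — the simplest processes matching
  "mean-per-year" parameters. Encounters carry the true disease's code,
  flipped to the other disease's code with probability `code_noise_prob`
  (default 0.05), which is what produces IBDU-like mixed coding downstream.
  These contact intensities are illustrative: no published care-contact
  intensity for IBD patients in this setting exists to calibrate against.
* **Coding systems.** A hard calendar cutover (default 2001) switches ICD-9
  to ICD-10 emission; only the code sets matter downstream, so the exact
  transition year is immaterial and configurable.
* **Records horizon.** Encounters are generated through `record_end_year`,
  default one year past the study span (so 1991–2010 for a 1996–2009
  study). Without that trailing year, onsets late in the final study year
  cannot accumulate the contacts that satisfy the gate, and final-year
  incidence is sharply under-ascertained.
* **Background noise.** All persons emit non-IBD-coded encounters (default
  1 per person-year) drawn from a small fixed list of non-target stems;
  only "target vs non-target" matters to the pipeline.
* **Determinism.** Each stage seeds its own RNG stream derived from
  `config$seed` (+0, +1, +2), so registries, onsets and encounters are
  individually and jointly reproducible.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: coding-practice drift over time,
differential access to care, comorbidity coding, migration, remission or
care-intensity decline after the initial diagnostic burst, and multi-code
discharge abstracts (readers must explode those into one row per code).
Parameter-recovery results on synthetic cohorts demonstrate the pipeline's
internal consistency, not the validity of the case definition against chart
review.

## Numerical and design choices

* Rates are carried at full precision; rendered tables round half-away-from-
  zero to one decimal (`round_half_up`), so printed percentages match report
  conventions (e.g. 22.777 → 22.8).
* Ratios of CD to UC counts within an age/sex cell are reported with an
  `undefined` flag when the UC count is zero, never an exception.
* "Four physician claims" counts encounter rows, not distinct dates: the
  case definition states no distinctness rule, and same-day duplicate claims
  are rare enough not to justify a stricter default.
* Problem sizes in the test suite were chosen to make Monte-Carlo bounds
  sharp at desk scale: ~100,000 person-years for rate-recovery checks
  (3-standard-error bands) and twenty replicates of a 200,000-person cohort
  for trend-recovery coverage.

## Known limitations

* Final-study-year estimates are mildly attenuated even with the trailing
  record year, because late-year onsets have the least record time to meet
  the gate; the same attenuation is inherent to the administrative design
  being emulated.
* A person whose onset falls at the very end of the washout period with no
  medical contact before the study start is indistinguishable from an
  incident case — the washout reduces, but cannot eliminate, prevalent-case
  contamination. The washout-soundness guarantee is therefore about coded
  contacts: no ascertained case has any IBD-coded encounter inside the
  washout span.
* Under the default generator settings the IBDU share of ascertained cases
  is far smaller than the 10–16% seen in real databases: every simulated
  patient keeps a sustained post-onset contact stream, whereas real IBDU
  labels mostly come from sparsely-seen patients whose few contacts cannot
  tip the score past ±2. Raising `code_noise_prob` (or lowering the contact
  rates) produces database-like IBDU shares when those are the object of
  study.
* Confidence intervals are plain-Poisson Wald intervals; with overdispersed
  real data they will be anti-conservative.
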