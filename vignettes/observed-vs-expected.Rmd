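---
title: "Observed-versus-expected projection of post-vaccination adverse events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observed-versus-expected projection of post-vaccination adverse events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oevax)
library(dplyr)
```

## The problem

When a vaccine is rolled out to millions of people, adverse events that
occur naturally in the background — venous thromboembolism (VT) in older
adults being the canonical example — will inevitably be observed shortly
after vaccination whether or not the vaccine causes them. An
observed-versus-expected (O/E) analysis puts a number on "inevitably": it
estimates the background incidence rate of the event from an unvaccinated
reference cohort, projects that rate onto the vaccinated population over a
fixed post-vaccination risk window, and asks whether the count of reported
events exceeds what the background alone predicts.

`oevax` implements this pipeline end to end for hospital-claims data:

1. **Case identification** — first occurrence of a hospitalization carrying
   an outcome ICD-9-CM code at any diagnosis position.
2. **Person-time** — Lexis expansion of each subject's follow-up across
   attained-age bands, censored at the first event.
3. **Rates** — stratified incidence rates with log-normal 95% confidence
   intervals.
4. **Projection** — expected events in the risk window per dose stratum.
5. **Uncertainty** — Poisson-bootstrap 95% prediction intervals.
6. **Simulation** — a synthetic-cohort generator with known hazards, so the
   whole chain is testable without restricted data.

## Case definitions and the coding-dialect rule

An outcome is defined by a code set ([`vt_code_set()`], [`itp_code_set()`]):
VT is pulmonary embolism (415.1) or deep vein thrombosis (451.11, 451.19,
451.2, 451.81, 453.8); immune thrombocytopenia (ITP) is 287.31 or the
pre-update code 287.3. A code matches at *any* diagnosis position, and only
a subject's *first* qualifying hospitalization counts — follow-up is
censored there. The ICD-9-CM 2007 update retired 287.3 for this purpose, so
that code is date-restricted: it matches only admissions before the
configured switch date (2007-01-01 by default). Codes are accepted in
dotted ("451.11") or undotted ("45111") dialects and canonicalized with
`normalize_icd9()`.

Two deliberate interpretation choices, made once and kept:

* **Independent outcomes.** A VT event censors VT follow-up only; ITP
  person-time keeps accruing (and vice versa). Nothing in the case
  definitions couples the two outcomes, and coupling them would make each
  outcome's rate depend on the other's incidence.
* **Same-day ties** break deterministically by admission date, then lowest
  diagnosis position, then code string order, so re-runs are reproducible.

## Person-time and the single time scale

All duration arithmetic uses actual day counts divided by 365.25. Attained
age is `(date − birth_date)/365.25` years, and "completed years" is the
floor of that quantity. Using one time scale for both the numerator (the
band an event's age falls in) and the denominator (the band boundaries of
the Lexis split) guarantees that an event can never be assigned to a band
whose person-time it did not accrue — calendar-birthday ages could disagree
with 365.25-day band boundaries by a day near a boundary. Over a 37-year
follow-up the 365.25-day year also avoids leap-year drift.

The Lexis split itself is continuous: each subject contributes the exact
(fractional-day) overlap of their at-risk interval with each band's age
window. The test suite checks this against a brute-force day-by-day
accumulation loop; agreement is within one day of person-time per subject
and band, which is the granularity at which whole-day admission dates make
the two computations comparable.

Subjects younger than the first band (the default scheme is 50–59, 60–69,
70–79, 80+) contribute no person-time until they age into it.

## Rate intervals

For a stratum with `d` events over `T` person-years, the rate is
`scale·d/T` and its default 95% interval is the log-normal approximation

    rate × exp(±1.959964/√d),

whose bounds are multiplicatively symmetric about the point estimate. This
is the form that reproduces the published reference table this package
ships as a fixture (15 of its 18 interval bounds to the printed 3 decimals;
the other three cells differ by one unit in the last digit, consistent with
the source computing from unrounded person-years and printing rounded
ones). An exact Poisson (Garwood) interval is available via
`ci_method = "exact"` but is not the default, precisely because the
log-normal form is what the reference analysis used. With `d = 0` the rate
is 0 and the interval is reported as undefined rather than fabricated.

ITP is rated overall only: with 2 events in ~72,000 person-years,
stratum-level estimates would be noise.

## Projection and `table_faithful`

Expected events in a risk window of `w` days for a dose stratum with `N`
first doses and background rate `r` (per `scale` person-years) are

    E = N · (r / scale) · w / 365.

The window fraction uses 365 exactly — the convention of the projection
formula — while person-time uses 365.25; the two constants serve different
conventions and are deliberately not unified. The overall row applies the
*overall* cohort rate to the total doses rather than summing stratum
expectations. On the packaged inputs the stratum sum is 78.47 while the
overall-rate convention gives 83.38: the vaccinated population is much
younger than the cohort's person-time distribution, so the overall rate
(dominated by older, higher-rate person-time) projects more events. Both
numbers are computed; the overall row follows the published convention.

`table_faithful = TRUE` rounds each stratum rate to 3 decimals before
projecting. This exists because the reference analysis demonstrably did so:
with full precision the Female 70–79 cell is 28.59, while the printed table
says 28.58, which is exactly what the printed (3-decimal) rate produces.
Reproduction mode therefore rounds; new analyses default to full precision.

## Prediction intervals, and what the bootstrap does not explain

The 95% prediction interval for a future event count resamples
`Poisson(E)` (10,000 draws by default) and takes the empirical 0.025 and
0.975 quantiles (inverse-ECDF, so they converge to the exact `qpois`
quantiles — the tests check equality at 200,000 draws). One seeded stream
drives all strata in fixed table order, so results do not depend on
parallelism. This interval conditions on the point estimate `E`: it carries
sampling variability of the future count, not uncertainty in the rate
itself.

Two published figures are *not* reproducible from this stated procedure,
and the package surfaces rather than imitates them:

* The reference table prints (79.58–86.88) around 83.38 expected events —
  non-integer bounds about five times narrower than Poisson dispersion.
  Integer Poisson resampling cannot produce them; the package reports
  (66, 102).
* The reported expected ITP count of 1.8 (95% CI 0.46–6.68): the stated
  formula gives 2.01 on the over-50 dose total and 3.07 on the all-ages
  total. The package reports its computed value.

Both discrepancies are pinned in tests that assert the mismatch, so a
future change that silently "fixed" them would fail.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` emulates a community cohort of middle-aged adults
(default 3,066 subjects, uniform ages 40–59 at entry on 1977-06-01,
administrative censoring 2014-12-31, even gender split — the reference
cohort's exact composition is not public, so these are configurable
defaults, not inferences). Within each attained-age band, outcome events
follow a time-homogeneous Poisson process at the configured hazard;
defaults are the reference analysis's own stratum rates (VT 0.3–1.7 per
1000 PY rising with age; ITP 2.77 per 100,000 PY). Every occurrence is
emitted, not just the first, to exercise the first-occurrence filter;
episodes carry the outcome code in the dialect valid at the admission date,
padded to up to three codes with distractors; background hospitalizations
(default 0.05 per PY) carry only distractor codes.

The generator does **not** model: vaccination effects on hazards,
reporting or coding errors (its codes are always correct, so identification
sensitivity/specificity on real claims is untested by construction),
competing mortality (subjects are followed to the administrative end unless
an outcome occurs), calendar trends in incidence, or within-subject event
clustering. Passing parameter-recovery tests therefore demonstrates the
*pipeline's* correctness, not robustness to real-world claims noise.

Problem sizes used by the checks: parameter recovery runs 50,000 subjects
(~1.4 million in-band person-years, every stratum within 3 standard errors
of its true hazard); the day-by-day person-time oracle runs on ≤10-subject
cohorts; bootstrap-versus-closed-form checks use 200,000 resamples; the
acceptance script's end-to-end synthetic check uses 20,000 subjects.

## Worked example

```{r, message = FALSE}
rep <- reproduce_reference_analysis(boot_settings(seed = 1))
render_report_table(rep, "VT")
glance(rep)
```

```{r, fig.width = 6, fig.height = 4}
autoplot(rep, "rates")
```

A fresh analysis on synthetic data:

```{r, message = FALSE, warning = FALSE}
cohort <- simulate_cohort(sim_config(n_subjects = 2000, seed = 7))
rep2 <- run_pipeline(
  cohort$subjects, cohort$episodes, italy_doses_2021(),
  settings = boot_settings(seed = 7)
)
tidy(rep2) %>% filter(outcome == "VT", gender == "ALL")
```

## Known limitations

* The dose table's under-50 stratum is a single aggregate; analyses needing
  a finer under-50 breakdown must supply their own dose table.
* The prediction interval ignores rate-estimation uncertainty; a
  gamma-Poisson extension would widen it, particularly for ITP with `d = 2`.
* ICD-10 mapping is out of scope; the case definitions are ICD-9-CM only.
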