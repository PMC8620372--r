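# oevax

Observed-versus-expected (O/E) pharmacovigilance for post-vaccination
adverse events, from claims-based background rates.

When a vaccine reaches millions of people, background disease does not
pause: venous thromboembolism (VT) and immune thrombocytopenia (ITP) occur
at measurable rates in older adults regardless of exposure. `oevax`
quantifies how many such events are *expected* in a fixed window after
vaccination from background rates alone, the reference point against which
reported adverse-event counts should be judged.

The pipeline:

1. **Case identification** — first hospitalization with an outcome
   ICD-9-CM code at any diagnosis position (VT: 415.1, 451.11, 451.19,
   451.2, 451.81, 453.8; ITP: 287.31, plus 287.3 for admissions before the
   2007 coding update). Both dotted and undotted code dialects are
   accepted.
2. **Person-time** — Lexis expansion: each subject's at-risk follow-up
   (entry until first event or censoring) is split across attained-age
   bands (default 50–59, 60–69, 70–79, 80+), in days/365.25.
3. **Rates** — for `d` events over `T` person-years, `rate = scale·d/T`
   with the log-normal 95% CI `rate·exp(±1.96/√d)` (per 1000 PY for VT,
   per 100,000 PY for ITP).
4. **Projection** — expected events per dose stratum,
   `E = N·(rate/scale)·w/365` for a `w`-day risk window (default 15); the
   overall row applies the overall rate to the total doses.
5. **Prediction intervals** — 95% PI from 10,000 `Poisson(E)` resamples
   (0.025/0.975 empirical quantiles).
6. **Simulation** — `simulate_cohort()` generates person-level cohorts and
   hospital episodes under known hazards so the whole chain is testable.

Results come back as tibbles; an `oe_report` object supports `tidy()`,
`glance()`, `autoplot()` and `print()`. A thin CLI over the same functions
lives at `inst/cli/oevax.R`.

## Worked example

Reproduce the packaged reference analysis — an Italian population-based
cohort (3,066 adults followed 1977–2014) projected onto the 1,767,281
over-50 first doses administered in Italy between 22 January and
12 April 2021:

```r
library(oevax)
rep <- reproduce_reference_analysis(boot_settings(seed = 1))
render_report_table(rep, "VT")
```

```
 gender age_band events person_years  rate          ci95   doses expected     pi95
      F    50-59      2         6405 0.312 (0.078-1.249)  350064     4.49    (1-9)
      F    60-69     10        13460 0.743 (0.400-1.381)  215887     6.59   (2-12)
      F    70-79     22        12802 1.718 (1.132-2.610)  404790    28.58  (18-40)
      F      80+     10         6275 1.594 (0.857-2.962)   36940     2.42    (0-6)
      M    50-59      5         6422 0.779 (0.324-1.871)  228011     7.30   (3-13)
      M    60-69     13        12393 1.049 (0.609-1.807)  148207     6.39   (2-12)
      M    70-79     15        10418 1.440 (0.868-2.388)  358223    21.20  (13-31)
      M      80+      6         4117 1.457 (0.655-3.244)   25159     1.51    (0-4)
    ALL      ALL     83        72293 1.148 (0.926-1.424) 1767281    83.38 (66-101)
```

Reading the table: the cohort's overall VT rate is 1.148 per 1000
person-years (95% CI 0.926–1.424), so among 1.77 million vaccinated
over-50s roughly 83 VT hospitalizations are expected in the 15 days after
a first dose *from background incidence alone* — between 66 and 101 in 95%
of 15-day windows. ITP, at 2.77 per 100,000 person-years, projects to
about 2 expected events. 65.4% of the 2,702,730 doses in the window went
to over-50s (`summarize_doses(italy_doses_2021())`).

A fresh analysis on your own (or simulated) data:

```r
cohort <- simulate_cohort(sim_config(n_subjects = 2000, seed = 7))
rep <- run_pipeline(cohort$subjects, cohort$episodes, italy_doses_2021(),
                    settings = boot_settings(seed = 7))
tidy(rep)        # full stratified results, full precision
autoplot(rep)    # rates with CIs by age band and gender
```

Note: the prediction intervals are those of the stated Poisson-resampling
procedure; see the methods vignette
(`vignettes/observed-vs-expected.Rmd`) for the two published figures this
procedure demonstrably cannot reproduce and how the package handles them.

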