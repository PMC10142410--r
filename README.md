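# edvest

Noninvasive estimation of left ventricular end-diastolic volume (EDV) — a
surrogate for cardiac preload — from measurements obtainable without any
arterial line or imaging-based volume tracing: cuff systolic and diastolic
blood pressure (SBP, DBP), the pre-ejection period (PEP), the ejection time
(ET), and stroke volume (SV).

EDV is the chamber volume at the end of filling and the main determinant of
preload, but no bedside monitor measures it continuously and noninvasively.
`edvest` implements an estimator built on ventricular-arterial coupling: the
ratio of end-systolic elastance (Ees, contractility) to effective arterial
elastance (Ea, arterial load). The package is aimed at anesthesiology and
hemodynamics researchers who want to run, validate, or stress-test this
estimator on their own tabular data or on simulated cohorts.

## The model

1. End-systolic arterial pressure from cuff pressures (Kappus linear form):

   `Pes = 0.205 SBP + 0.898 DBP + 0.4214`

2. Bilinear elastance approximation of systole. With `Pad` (= DBP) the
   pressure at which ejection begins and `k` the slope ratio of the ejection
   and isovolumic elastance segments, the peak isovolumic pressure is
   `Pmax = Pad [1 + (ET/PEP) k]`, and the coupling ratio is
   `Ees/Ea = (Pmax − Pes)/Pes`, giving the coupling equation

   `Ees/Ea = (Pad/Pes) (1 + k ET/PEP) − 1`.

3. The empirical slope-ratio relation `k = 0.53 (Ees/Ea)^0.51` closes the
   system; `edvest` solves the two equations simultaneously by Newton's
   method with an analytic derivative and a bracketed-bisection fallback.

4. With `Ees = Pes/(EDV − SV − V0)` and `Ea = Pes/SV`, and `V0` (the volume at
   zero end-systolic pressure) taken as 0 ml:

   `EDV = SV (1 + Ea/Ees)`.

The package also ships a forward hemodynamic simulator (the exact algebraic
inverse of the chain above) for validation cohorts, and Bland–Altman
method-agreement statistics with the percentage-error acceptability rule
(PE = 2·SD of the differences / mean of the reference method; ≤ 30% is
clinically acceptable).

## Worked example

Estimating one subject at typical young-healthy-cohort values
(SBP 117, DBP 73 mmHg, PEP 96, ET 286 ms, SV 61 ml):

```r
library(edvest)
obs <- beat_observation("cohort-means", sbp = 117, dbp = 73,
                        pep = 96, et = 286, sv = 61)
estimate_subject(obs)
#> Subject cohort-means: Pes 89.96 mmHg, Ees/Ea 1.2432, Pmax 201.80 mmHg, EDV calc 110.1 ml
```

The cuff form puts end-systolic pressure at 89.96 mmHg; the Newton solve
(5 iterations, residual at machine precision) finds a coupling ratio of 1.24,
i.e. contractility moderately exceeds arterial load; the implied hypothetical
non-ejecting peak pressure is 201.8 mmHg; and EDV follows as
61 × (1 + 1/1.2432) ≈ 110 ml.

A synthetic validation study — simulate a 48-subject cohort with realistic
measurement noise, estimate every subject, and compare estimated to true EDV:

```r
cohort <- generate_cohort(cohort_config(n = 48, seed = 7))
res <- estimate_cohort(cohort$observations)
ok <- !res$excluded
bland_altman(res$edv_ref_ml[ok], res$edv_calc_ml[ok])
#> Method agreement (n = 48)
#>   bias (reference - test): -1.83 ml (SD 9.24 ml)
#>   limits of agreement (x2.00): -20.32 to 16.65 ml
#>   percentage error: 19.6% (clinically acceptable; threshold 30%)
#>   regression: R^2 = 0.617, slope = 0.942, intercept = 7.28 ml
```

At the default noise (3 mmHg on pressures, 5 ms on timings, 4 ml on SV) the
estimator is nearly unbiased, its limits of agreement span about ±20 ml, and
the percentage error sits under the 30% acceptability line.

The same workflow is available from a shell via the thin wrapper in
`inst/cli/` (`simulate`, `estimate`, `validate` subcommands); every run logs
the seed, solver tolerance and limits-of-agreement multiplier.

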