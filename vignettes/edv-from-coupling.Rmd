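---
title: "Estimating end-diastolic volume from ventricular-arterial coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating end-diastolic volume from ventricular-arterial coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edvest)
```

## The estimation problem

Left ventricular end-diastolic volume (EDV) indexes cardiac preload, but no
bedside monitor provides it continuously and noninvasively. `edvest`
implements an estimator that needs only quantities obtainable from cuff
sphygmomanometry, an ECG/phonocardiogram-derived pre-ejection period (PEP),
a pulse-wave-derived ejection time (ET), and a stroke volume (SV) from any
source (echocardiography, arterial-pressure cardiac output, ...).

The estimator rests on the pressure–volume-loop description of a beat.
End-systolic elastance `Ees = Pes / (EDV − SV − V0)` is the contractility
index (slope of the end-systolic pressure–volume relation, with `V0` the
volume at zero end-systolic pressure); effective arterial elastance
`Ea = Pes / SV` lumps the arterial load. Their ratio, ventricular-arterial
coupling, eliminates `Pes`:

$$ \frac{E_{es}}{E_a} = \frac{SV}{EDV - SV - V_0}
   \quad\Longrightarrow\quad
   EDV = SV\left(1 + \frac{E_a}{E_{es}}\right) + V_0 . $$

So EDV follows from SV once the coupling ratio is known. The ratio itself is
obtained noninvasively from a bilinear approximation of the time-varying
ventricular elastance: systole is split into the isovolumic segment (duration
PEP) and the ejection segment (duration ET), each approximated by a line, and
`k` denotes the ratio of the two slopes. Under this geometry the hypothetical
peak pressure of a non-ejecting ventricle is
`Pmax = Pad [1 + (ET/PEP) k]` (with `Pad` the pressure at which ejection
begins, identified with cuff diastolic pressure), the coupling ratio is the
relative pressure reserve `(Pmax − Pes)/Pes`, and combining the two gives the
coupling equation

$$ x \;=\; \frac{P_{ad}}{P_{es}}\Bigl(1 + k\,\tfrac{ET}{PEP}\Bigr) - 1,
   \qquad x = E_{es}/E_a . $$

`Pes` is estimated from the cuff pressures by the published linear form
`Pes = 0.205·SBP + 0.898·DBP + 0.4214` (an empirical regression; the
intercept is used exactly as published). The system is closed by the
experimentally obtained slope-ratio relation `k = 0.53 x^{0.51}`.

Identifying `Pad` with cuff DBP is itself a modelling decision: diastolic
arterial pressure, the ventricular pressure at ejection onset, and the cuff
diastolic reading are used interchangeably in this model, and the package
follows that identification throughout (`solve_coupling` receives the DBP).

## The scalar root problem and its structure

Substituting the slope-ratio relation into the coupling equation gives a
single nonlinear equation, solved by `solve_coupling()`:

$$ f(x) = \frac{P_{ad}}{P_{es}}\Bigl(1 + 0.53\,x^{0.51}\,\tfrac{ET}{PEP}\Bigr)
          - 1 - x = 0, \qquad x > 0 . $$

Writing $A = P_{ad}/P_{es} \le 1$ and $B = A \cdot 0.53 \cdot ET/PEP$,
$f(x) = (A-1) + Bx^{0.51} - x$ is strictly concave on $x>0$ with one interior
maximum at $x_{peak} = (0.51B)^{1/0.49}$, $f(0^+) = A - 1 \le 0$, and
$f \to -\infty$. Consequently $f$ generically has **two** positive roots (or
none, when $f(x_{peak}) < 0$). The smaller root lies on the rising branch at
implausibly low coupling (typically $x < 0.1$, a severely failing ventricle
inconsistent with the other inputs); the physiological solution is the root
on the decreasing branch. Numerical choices, all made once from this
analysis:

* **Start and branch selection.** Newton starts at
  $\max(x_0, x_{peak}(1+10^{-6}))$ with default $x_0 = 1$ (mid-range
  physiological coupling, where the slope-ratio calibration gives
  $k = 0.53$). Starting at or right of the peak confines the concave Newton
  iteration to the decreasing branch, so it converges to the physiological
  root.
* **Derivative.** The closed form
  $f'(x) = A\,0.53\cdot 0.51\,x^{-0.49}\,ET/PEP - 1$ is used; no
  finite-difference step size to tune.
* **Positivity guard.** Steps are clamped to $x_{n+1} \ge x_n/10$, since the
  fractional powers are undefined at $x \le 0$.
* **Tolerance.** Absolute residual tolerance $10^{-9}$ (the equation is
  dimensionless, so this is scale-free), iteration cap 50.
* **Fallback.** If Newton leaves $(0, 100]$ or fails to converge, bisection
  runs on $(\max(10^{-6}, x_{peak}),\,100)$ — the decreasing branch — where a
  sign change exists whenever a root exists; the solution records
  `method = "bisection"`. If $f(x_{peak}) < 0$ the solver raises a
  no-solution error reporting the residual, rather than extrapolating.
* **Rejections.** `pad > pes` (inverted ejection pressure ordering) is
  rejected: it is nonphysiological cuff data, not a solvable regime.

The exponents (0.53, 0.51) come from an experimental regression in prior
pressure–volume work; they are fixed defaults but exposed in
`solver_config()` for sensitivity analyses. Refitting them is out of scope.

## Tunable parameters

| Parameter | Unit | Default | Meaning |
|---|---|---|---|
| `v0` | ml | 0 | Volume at zero end-systolic pressure. Zero is the method's key assumption, appropriate for normal ventricles; exposed in `estimate_edv()`/`estimate_subject()` for sensitivity work. |
| `tol` | — | 1e-9 | Residual tolerance of the coupling solve. |
| `x0` | — | 1 | Newton initial guess for Ees/Ea. |
| `bracket_lo`, `bracket_hi` | — | 1e-6, 100 | Fallback search bounds. |
| `k_coef`, `k_exp` | — | 0.53, 0.51 | Slope-ratio relation constants. |
| `loa_multiplier` | — | 2 | Limits-of-agreement half-width. |
| `edv_limit` | ml | 140 | Cohort exclusion cutoff (inclusive). |

Timings are stored in milliseconds throughout. Only the ratio ET/PEP enters
any equation, so the unit cancels; the CSV reader nevertheless fixes the
schema to `pep_ms`/`et_ms` and offers `timings_seconds = TRUE` to convert on
read, guarding against second-labelled sources.

## Agreement statistics

`bland_altman()` computes differences as reference − test, so a test method
that overestimates yields a negative bias; the SD of differences uses the
n−1 denominator; the limits of agreement default to bias ± **2**·SD (the
1.96 normal-quantile convention is available via `loa_multiplier`); the
percentage error is `100 · multiplier · SD / mean(reference)` — reference
mean only, not the grand mean — and is flagged clinically acceptable at 30%
or less. Regression of test on reference uses ordinary least squares and the
squared Pearson correlation; with fewer than 3 pairs or a constant reference
the regression fields are `NA` rather than fabricated.

## The forward simulator

No public dataset carries these joint measurements, so validation runs on
synthetic cohorts. A ground-truth state (Ees, Ea, EDV, V0 = 0, Pad, PEP)
determines every observable exactly by inverting the estimation chain:
`SV = EDV·r/(1+r)` with `r = Ees/Ea`; `Pes = Ea·SV`; `Pmax = Pes(1+r)`;
`k = 0.53 r^{0.51}`; `ET = PEP (Pmax/Pad − 1)/k`; and SBP back-solved from
the cuff form so that `estimate_pes(SBP, DBP = Pad)` returns `Pes` exactly.
A noise-free observation therefore satisfies every model equation
simultaneously, and the estimator must recover the ground truth to numerical
precision — the package's core parameter-recovery property (verified at
max relative EDV error below 1e-6 on a 48-subject cohort; measured around
1e-10).

`generate_cohort()` samples ground truths from configurable families. The
defaults emulate a young healthy adult cohort: coupling ratio uniform on
(0.8, 2.5); EDV normal(95, 15) truncated to (60, 139) ml; Pad normal(73, 9)
mmHg; PEP normal(96, 13) ms. These are distributions over *ground truth*, a
free choice of the simulator documented here, not a claim about any measured
cohort; they were chosen once so that the *emitted observables* land near
the intended summaries (SBP ≈ 117 ± 13, DBP ≈ 73 ± 9 mmHg, PEP ≈ 96 ± 13 ms,
ET near 286 ms, SV near 61 ml, EDV near 91–100 ml). The sampled laws alone
leave the pressure scale of `Ea` undetermined — coupling fixes only the
ratio — so an auxiliary SBP draw (normal 117 ± 13) sets it: `Pes` follows
from the cuff form and `Ea = Pes/SV`. Because the forward model back-solves
SBP through the same linear form, the noise-free round trip still closes
exactly.

Measurement noise is additive, Gaussian, independent across observables:
defaults 3 mmHg (pressures), 5 ms (timings), 4 ml (SV) — typical
cuff/Doppler repeatability magnitudes — and 0 ml on the reference EDV, i.e.
the reference method is treated as ground truth (configurable). Infeasible
ground-truth draws (back-solved SBP at or below DBP, or a peak pressure not
exceeding Pad) are resampled up to a cap, with the discarded count recorded.
All ground-truth draws are consumed from the RNG stream before any noise
draw, so cohorts sharing a seed share their subjects across noise settings —
this is what makes noise-ladder comparisons paired, and the percentage error
nondecreasing along a ladder at fixed seed.

What the simulator does **not** emulate: inter-subject correlation between
observables (draws are independent; real SBP–DBP correlation is stronger),
pathological states (`V0 > 0` is supported by the types but breaks the exact
round trip and is refused by the simulator), beat-to-beat variability,
waveform-level artifacts, and any error in the reference volume by default.
Passing tests therefore demonstrate internal consistency of the estimator
and its robustness to independent measurement noise — not clinical accuracy
on real patients, where the bilinear-elastance and `V0 = 0` assumptions and
the empirical constants themselves contribute error.

## Cohort filtering

`apply_exclusions()` flags records with missing required measurements and
records whose volume is at or above 140 ml — the normal-range motivation for
the cutoff refers to end-diastolic volume, so the default field is the
reference EDV, with the stroke-volume variant available (`field = "sv"`;
with typical SV near 61 ± 13 ml an SV cutoff at 140 ml is nearly vacuous).
The boundary is inclusive: exactly 140 ml is excluded. Nothing is dropped:
all records return with `excluded`/`exclusion_reason` set, the operation is
idempotent and order-preserving, and the flagged count is reported.

## Problem sizes and determinism

The shipped checks use a 48-subject noise-free cohort for exact recovery, a
500-subject cohort for noisy-agreement behaviour, 1000 random tuples for
solver-oracle equivalence, and a few hundred random draws per algebraic
identity — sizes at which every Monte-Carlo statement in the test suite is
stable under its fixed seed while the whole suite stays fast. All
stochastic behaviour flows through explicit seeds; an identical
configuration and seed reproduces a cohort byte for byte.

## Known limitations

* `V0 = 0` biases EDV downward in dilated ventricles; the parameter is
  exposed but the simulator's exactness guarantee holds only at zero.
* The cuff form for `Pes` and the slope-ratio relation are empirical
  regressions carried over from prior work; their error is not propagated.
* The solver deliberately refuses `Pad > Pes` and rootless inputs instead of
  returning extrapolated values; cohort pipelines record such subjects as
  excluded rather than estimated.
* Exit code 1 from the command-line `validate` subcommand signals a failed
  acceptability verdict (PE > 30%), not a crash; usage errors return 2.
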