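---
title: "Deriving volumetric response thresholds from measurement variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving volumetric response thresholds from measurement variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volresp)
library(dplyr)
```

## The problem

RECIST-style monitoring of solid tumours classifies each follow-up as
partial response (PR), stable disease (SD) or progressive disease (PD) by
thresholding the relative change of a measurement. For one-dimensional
diameters those thresholds are fixed by convention (-30 %, +20 %); for CT
tumour *volumetry* no consensus thresholds exist. `volresp` derives them
from the one quantity that is well documented for the volumetric biomarker:
the repeatability of the measurement itself, summarised by a per-measurement
coefficient of variation (CV). A change should be called significant exactly
when it exceeds what measurement noise alone can plausibly produce.

## The ratio model

Let $X_1$ and $X_2$ be the measured volumes at two timepoints, treated as
approximately bivariate normal with means $\mu_i$, standard deviations
$\sigma_i$, CVs $c_i = \sigma_i/\mu_i$ and error correlation $\rho$.
Inference about the relative change $(X_2 - X_1)/X_1$ is inference about the
ratio $W = X_2/X_1$. The Geary–Hinkley transformation

$$Z = \frac{W\mu_1 - \mu_2}{\sqrt{\sigma_2^2 - 2W\rho\sigma_1\sigma_2 + W^2\sigma_1^2}}$$

is approximately standard normal when both volumes are positive and the CVs
are moderate (the usual accuracy range is $0.005 < c_i < 0.39$;
`gh_transform()` warns outside it). Inverting $|Z| \le t$ gives closed-form
confidence limits for $\mu_2/\mu_1$ (`ratio_ci()`). With uncorrelated errors
($\rho = 0$) and a common CV $c_1 = c_2 = k$ — variance proportional to the
mean, the standard repeatability assumption for this biomarker — the limits
simplify to

$$\frac{X_2}{X_1}\cdot\frac{1 \mp t\sqrt{2k^2 - t^2k^4}}{1 - t^2k^2},$$

and the two multiplicative factors, evaluated at $X_2/X_1 = 1$, are the
decision thresholds of the no-change test:

```{r thresholds}
th <- response_thresholds(k = 0.3 / 1.96, level = 0.95)
th
tidy(th)
```

### Parameters and defaults

* `k` — per-measurement CV. Default `0.3/1.96` $\approx 0.1531$, the
  conservative 15 % repeatability of semi-automated lung-lesion volumetry
  on CT reported by the QIBA volumetry effort (the exact form keeps
  $t \cdot k = 0.3$ at the 95 % level). It is the single most influential
  input: `response_thresholds(0.05)` tightens the stable band to
  (-13 %, +15 %) and `response_thresholds(0.10)` to (-25 %, +33 %).
* `level` / `t` — confidence level of the two-sided test. At 0.95 the
  quantile is taken as 1.96 *literally*, matching how the thresholds are
  quoted in practice; other levels use `qnorm()` exactly, and `t` can be
  overridden.
* `rho` — error correlation, default 0: two CT sessions are independently
  acquired and segmented.

### Rounding and boundary conventions

The unrounded critical ratios at the defaults are 0.643288 and 1.554515.
All statistics (p-values, power, rejection regions) use these unrounded
values; the integer percent fields round half away from zero and are purely
presentational. That convention reproduces the familiar quoted pairs at
k = 0.05 (-13/+15) and k = 0.10 lower (-25), but at the default k the lower
ratio is a 35.67 % decrease and therefore prints as **-36 %**: the widely
quoted "-35 %" is obtained only by first rounding the ratio to 0.65 and is
not reachable by any consistent rounding of the exact value. We keep the
exact arithmetic and document the discrepancy rather than encode a special
case.

Observed changes exactly on a boundary are classified as stable:
rejection of "no change" requires strict exclusion of ratio 1 from the open
confidence interval. `classify_change()` defaults to the integer-percent
(clinical) boundaries; `boundaries = "ratio"` selects the statistical ones.

### P-value and power

Under the null $\mu_1 = \mu_2$ the transformation collapses to
$z_0 = (w - 1)/(k\sqrt{1 + w^2})$ (`gh_pvalue()`); under a known true ratio
$r$ it gives the probability of declaring change (`gh_power()`):

```{r power}
power_curve(ratios = c(0.5, 0.8, 1, 1.3, 1.8))
```

The rejection boundaries double as the 50 %-power points, and the power at
$r = 1$ equals the size of the test. The power at the upper boundary is
49.5 % rather than exactly 50 % — the lower-tail mass and the
$w$-dependence of the denominator shift it slightly; quoted "50 %" values
are rounded.

## Monte Carlo validation

`run_simulation_study()` rechecks the thresholds without the normal
approximation: 10,000 independent pairs per cell (configurable), true ratios
$\{1.0, 0.65, 1.55, 1.30\}$ — no change, the two derived boundaries and the
+30 % value proposed for volumetry elsewhere — under three error families
sharing mean $\mu$ and SD $k\mu$:

* **normal** — the model's own assumption; baseline draws $\le 0$
  (probability $\approx \Phi(-1/k) \approx 3\cdot10^{-11}$) are redrawn so
  the ratio exists;
* **lognormal** — moment-matched (log-scale variance $\log(1+k^2)$),
  probing the often-suggested multiplicative error;
* **uniform** — on $\mu(1 \pm \sqrt{3}k)$. The "empirical" error family
  this stands in for is not fully specified anywhere; matching the first
  two moments is the only reproducible interpretation, and its tail
  behaviour (type I error $\approx$ 3.5 %) should be read as
  qualitative only.

Rejection uses the *unrounded* critical ratios. This is a deliberate
choice: at a true ratio equal to a boundary, a band rounded to (0.65, 1.55)
puts the boundary exactly on the true ratio and forces a 50.0 % expected
rejection, while the published validation figures for that cell report
~47-48 % — consistent only with the unrounded boundaries. The band is a
parameter (`thresholds =`), so the rounded convention is one argument away.

```{r simulate}
run_simulation_study(models = "normal", ratios = c(1, 1.3),
                     n_samples = 10000, seed = 99)
```

At $n = 10^6$ the normal-model rejection rate agrees with `gh_power()` to
within Monte Carlo error at every ratio (this is the dual-route check in the
test suite: the analytic path and the simulation path are independent
implementations). All results are scale invariant in `mu1` and bit-identical
under a fixed `seed` (`withr::with_seed()` scoping, caller RNG untouched).

## Effective-diameter extrapolation

The effective diameter is the diameter of the volume-equivalent sphere,
$d = 2(3V/4\pi)^{1/3}$. Ratios map by cube root / cube
(`volume_ratio_to_diameter_ratio()` and inverse); conversions always chain
on unrounded ratios, with integer rounding applied last:

```{r diameter}
diameter_thresholds()
round(100 * (diameter_ratio_to_volume_ratio(c(0.70, 1.20)) - 1))
```

The volumetric stable band maps to roughly (-14 %, +16 %) on the diameter
scale — strictly inside RECIST's (-30 %, +20 %) — and RECIST's own pair
extrapolates to (-66 %, +73 %) in volume (exact values -65.7/+72.8; quoted
integers vary by $\pm 1$ point with the rounding convention, which is why
the tests compare at $\pm 1$).

## The multi-reader response pipeline

`assess_cohort()` consumes a tidy table (`patient_id`, `lesion_id`,
`timepoint_index` with 0 = baseline, `reader_id`, `volume_cm3`) and emits
one assessment per reader, follow-up and reference mode. The two-way
evaluation uses both the reader's **baseline** and the reader's running
**nadir** (minimum over strictly earlier timepoints, baseline included) as
reference; the nadir is per reader, so each series is self-contained, and
the known small bias of nadir referencing (the nadir is on average an
undershoot) is left uncorrected, matching standard practice.

`reader_agreement()` then asks whether the scatter of readers at one
(lesion, timepoint, reference) is no larger than the model predicts: with
$m$ the group-mean relative change and $A_L, A_U$ the critical ratios at
`(k, level)`, each reader's change must fall in
$[(1+m)A_L - 1,\; (1+m)A_U - 1]$. Groups need at least two readers; the
summary reports the within-band fraction with an exact binomial CI.

Two anchorings are available. The default includes the reader under test in
the group mean. Because each reader is then correlated with the band centre,
the observed coverage sits *above* the nominal level (with six readers and
k = 0.1531, around 97 % — the same order as reported multi-reader
validations); with `leave_one_out = TRUE` the centre is estimated from the
other readers only, and its estimation noise — which the band width ignores
— pushes coverage *below* nominal (around 94 %). Neither is exactly
calibrated at six readers; the default matches how such validations are
plotted (each reader against the group average), and the calibration test
in the suite verifies the default stays within three binomial standard
errors of the nominal level under the generator's study conditions.

## The synthetic cohort generator

`simulate_cohort()` emulates the validation setting end to end so the
pipeline is testable without patient data: 10 patients, one pulmonary
target lesion each, a baseline plus six follow-ups (70 timepoints), six
readers, baseline true volumes log-uniform on 0.195–380.976 cm³. True
trajectories follow per-patient courses (shrinking / growing / stable with
probabilities 0.4/0.4/0.2, per-step geometric mean ratios 0.75/1.35/1.0 and
log-scale jitter 0.10), chosen once as a plausible advanced-NSCLC mix that
produces responding, stable and progressive assessments in comparable
numbers under the two-way evaluation. Observed volumes multiply the truth
by i.i.d. lognormal error with CV `k` (mean 1, so observations are unbiased
on the volume scale and always positive).

What the generator does *not* emulate: scanner and protocol heterogeneity,
slice-thickness effects, segmentation-software bias, intra-reader
correlation over time, or lesion-size-dependent CV. Passing calibration
tests on this cohort therefore demonstrates internal consistency of the
model and pipeline, not field performance on real CT follow-ups.

## Problem sizes and numerical choices

The shipped tests run the Monte Carlo grid at 10,000 pairs per cell (the
validation study's own size), the analytic-vs-simulation cross-check at
$10^6$ pairs, and the calibration property over 30 generator seeds; these
sizes keep every Monte Carlo comparison at three standard errors or better
while remaining quick on one CPU. Degenerate inputs are handled explicitly:
zero CV collapses intervals to the point estimate, `t*k >= 1` and
non-positive radicands raise named errors rather than NaNs, single-reader
groups are excluded with a warning, and a missing baseline aborts with the
offending series identified.

## Command line

The same operations are scriptable via `run_cli()` /
`inst/cli/volresp`: `thresholds`, `power-curve`, `simulate`, `classify`,
`generate`, `extrapolate`, exchanging CSV tables and JSON reports (exit
codes: 0 ok, 2 validation error, 1 runtime error). All parameters are
scalar flags; no configuration files are needed.

## Known limitations

* The normal ratio model is an approximation; for CVs near the upper
  validity bound the lognormal view of the data is arguably better, though
  the simulations show the thresholds are robust across the three families.
* The integer-percent presentation of the default lower threshold (-36 %)
  differs by one point from the commonly quoted -35 % (see the rounding
  section above).
* The agreement band treats the group mean as the truth; its coverage is
  therefore nominal only asymptotically in the number of readers.
* Multi-lesion RECIST bookkeeping (target-lesion sums, new lesions,
  response confirmation) is out of scope: the unit of analysis is one
  lesion's ratio.
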