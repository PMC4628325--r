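# volresp

Decision thresholds for tumour-volume change on CT, derived from
measurement variability.

When lung lesions are followed by CT volumetry, a follow-up/baseline volume
ratio only means something once it is compared with what pure measurement
noise can produce. `volresp` models the two measurements $X_1, X_2$ as
approximately bivariate normal with constant coefficient of variation (CV)
and uses the Geary–Hinkley transformation of the ratio $W = X_2/X_1$,

$$Z = \frac{W\mu_1 - \mu_2}{\sqrt{\sigma_2^2 - 2W\rho\sigma_1\sigma_2 + W^2\sigma_1^2}} \;\approx\; \mathcal N(0, 1),$$

to turn the documented repeatability of the biomarker (CV $k$, default the
QIBA-reported $0.3/1.96 \approx 15\,\%$) into:

* closed-form confidence intervals for volume ratios (`ratio_ci()`);
* PR/SD/PD decision thresholds
  $(1 \mp t\sqrt{2k^2 - t^2k^4})/(1 - t^2k^2)$ (`response_thresholds()`),
  with p-value and power of the no-change test (`gh_pvalue()`,
  `gh_power()`, `power_curve()`);
* a Monte Carlo robustness study under normal, lognormal and uniform error
  models (`run_simulation_study()`);
* volume ↔ effective-diameter threshold extrapolation for comparison with
  RECIST (`diameter_thresholds()` and friends);
* a longitudinal multi-reader classification pipeline with baseline- and
  nadir-referenced assessments and a reader-agreement test against the
  model's predicted variability band (`assess_cohort()`,
  `reader_agreement()`);
* a synthetic multi-reader NSCLC-like cohort generator with ground truth
  (`simulate_cohort()`), so the whole pipeline is testable without patient
  data.

It is aimed at imaging scientists and biostatisticians evaluating
quantitative imaging biomarkers; everything is data-frame in, tibble out,
with `tidy()`/`glance()` methods and `autoplot()`s.

## Worked example

```r
library(volresp)
library(dplyr)

th <- response_thresholds()  # k = 0.3/1.96, 95 % level
th
#> Volumetric response thresholds (CV k = 0.1531, 95% level, t = 1.96)
#>   decrease (PR) below ratio 0.6433 (-36%)
#>   increase (PD) above ratio 1.5545 (+55%)
```

With a 15 % per-measurement CV, only a volume drop below 0.643× (a ~36 %
decrease) or growth above 1.554× (a ~55 % increase) exceeds measurement
noise at the 95 % level. (The commonly quoted −35 % corresponds to the
ratio pre-rounded to 0.65; the package reports the exact value. The upper
threshold is the familiar +55 %.) P-values and power for observed/true
ratios:

```r
gh_pvalue(c(0.52, 1.20))            # two-sided p of "no change"
#> [1] 0.005397314 0.402869394
round(100 * gh_power(c(0.5, 0.8, 1.3, 1.8)), 1)  # % probability of declaring change
#> [1] 87.5 16.2 20.7 75.0
```

A halving of volume is detected with 87.5 % power; a 20 % shrinkage mostly
goes undetected (16 %). End-to-end on a synthetic six-reader cohort:

```r
cohort <- simulate_cohort(cohort_spec(), seed = 42)
assessments <- assess_cohort(cohort$measurements)   # two-way: baseline + nadir refs
count(assessments, reference, category)
#> # A tibble: 6 × 3
#>   reference category     n
#>   <chr>     <fct>    <int>
#> 1 baseline  PR         168
#> 2 baseline  SD         119
#> 3 baseline  PD          73
#> 4 nadir     PR          45
#> 5 nadir     SD         240
#> 6 nadir     PD          75

reader_agreement(assessments)
#> Reader agreement vs predicted variability band (k = 0.1531, 95% level)
#>   700 of 720 assessments within band: 97.2% [95.7; 98.3]
```

97.2 % of the readers' assessments fall inside the variability band the
model predicts around the group-mean change — the reader scatter is fully
explained by measurement noise at CV 0.1531. Extrapolating to effective
diameters:

```r
diameter_thresholds()
#> # A tibble: 2 × 5
#>   boundary volume_ratio diameter_ratio volume_pct diameter_pct
#>   <chr>           <dbl>          <dbl>      <int>        <int>
#> 1 lower           0.643          0.863        -36          -14
#> 2 upper           1.55           1.16          55           16
```

The volumetric stable band is a (−14 %, +16 %) band on the diameter scale,
strictly narrower than RECIST's (−30 %, +20 %).

A command-line wrapper ships in `inst/cli/volresp`
(`thresholds`, `power-curve`, `simulate`, `classify`, `generate`,
`extrapolate`); see the methods vignette (`vignettes/volresp-methods.Rmd`)
for the model, assumptions, conventions and limitations.

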