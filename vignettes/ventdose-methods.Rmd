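---
title: "Methods: ventilation modelling and inhaled-dose estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ventilation modelling and inhaled-dose estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventdose)
```

## The model

`ventdose` estimates minute ventilation normalized by forced vital capacity,

$$\dot V_E / \mathrm{FVC} \;=\; \beta_0 + \beta_H\,\mathrm{HR} +
\beta_f\,f_B + b_i + \varepsilon, \qquad b_i \sim N(0, \tau^2),\;
\varepsilon \sim N(0, \sigma^2),$$

from repeated measurements on a panel of subjects. The FVC normalization is
the load-bearing assumption: minute ventilation at a given heart rate varies
several-fold across people mostly through lung size, and dividing by FVC
(measured by spirometry, or predicted from NHANES III reference equations
when spirometry is unavailable) removes enough of that variation that one
population-level equation becomes useful for subjects the model has never
seen. The subject random intercept $b_i$ absorbs what normalization does
not.

Fitting is restricted maximum likelihood under the variance-components
covariance structure (a single random intercept per subject, independent
homoscedastic residuals). Writing $\lambda = \tau^2/\sigma^2$, the marginal
covariance of subject $i$'s $n_i$ observations is
$\sigma^2 (I + \lambda J)$, whose inverse and determinant are closed-form,
so for fixed $\lambda$ the GLS fixed effects, the profiled $\hat\sigma^2$
and the restricted likelihood are all explicit. Estimation therefore
reduces to a one-dimensional search over $\lambda$: a log-scale grid on
$[10^{-10}, 10^{6}]$ followed by bounded scalar refinement, with the
boundary candidate $\lambda = 0$ compared explicitly so that
$\hat\tau^2 = 0$ is reported exactly rather than as a fuzzed small number.
All data enter through per-subject cross-products, so one likelihood
evaluation costs $O(p^2 m)$ for $p$ fixed effects and $m$ subjects — cheap
enough that the brute-force model search below refits thousands of models
in seconds. The test suite verifies the fitter against two independent
routes: a dense-grid oracle with explicit matrix inversion, and `lme4`.

Inference is t-based with residual (containment-style) degrees of freedom
$n - \mathrm{rank}(X) - (m - 1)$. With several hundred observations the
choice of degrees-of-freedom method is immaterial; exact agreement of
p-values with other software to all digits is not asserted anywhere.

AIC is $-2\ell_R + 2q$ with $q = 2$, counting only the covariance
parameters $(\tau^2, \sigma^2)$ — the convention of the mixed-model
software whose model-comparison tables this machinery mirrors. The
count-all-parameters convention is available
(`fit_lmm(..., aic_convention = "all")`). Two caveats are documented
deliberately: REML likelihoods of models with different fixed effects are
comparable only in this conventional sense, and the difference carries a
deterministic offset that depends on the scale of the added column, so no
universal "small change" threshold exists for adding a null predictor. The
tests assert instead that AIC changes agree exactly with an independent
implementation and that a pure-noise predictor never buys a material
improvement.

## Model selection and cross-validation

All $2^9 - 1 = 511$ subsets of the candidate pool {HR, f_B, ACT, warm, age,
sex, BMI, FEV$_1$/FVC, height} are enumerated in size-then-lexicographic
order and each is scored three ways: the full-data REML fit (coefficients,
p-values, AIC) and a subject-grouped five-fold cross-validation. Folds
partition *subjects*, never observations: a held-out subject contributes
nothing to training, and their prediction uses fixed effects only (their
random intercept is unknowable, and anything else would leak). The fold
assignment is a deterministic function of the subject-id set and a seed,
and disjointness of training and validation subjects is asserted on every
fold of every run. Percent errors
$100\,(\hat y - y)/y$ are pooled over all validation observations (not
averaged per fold first) and summarized as mean and SD — a signed mean, so
its expectation is a Jensen-type positive bias of order
$\mathrm{Var}(\text{held-out error})\cdot E[1/y^2]$ rather than zero.

The best model of a given size is chosen by a three-criteria rule. If one
subset minimizes both |mean percent error| and AIC it wins outright.
Otherwise the decision is arbitrated **between the two front-runners** (the
percent-error winner and the AIC winner) on the strength of their
coefficient evidence: exactly one having every $p < 0.05$ decides;
otherwise the smaller worst-case p-value decides; a residual tie falls back
to percent error. The restriction to the two front-runners is intentional.
The signed mean percent error separates models only weakly when its Jensen
bias is small, so ranking the full subset list by it rewards lucky
near-zero means from spuriously significant subject-level covariates; the
AIC front-runner, by contrast, is very stable (in replicate synthetic
cohorts it is the generative pair essentially always). The report returned
by `select_best()` names the criterion that decided.

One fold split (fixed by a seed) is reused across all 511 subsets within a
run so their scores are comparable; this is a convention, and any
percent-error figure quoted for a model is therefore averaged over many
random splits wherever it matters.

## The synthetic-data generator

The generator stands in for a study this package's methods were designed
around: a panel of 15 healthy adolescent athletes, each completing one
treadmill session — about a minute at rest, a minute walking, a 4–5 minute
ramp to a peak heart rate drawn from 160–180 beats·min⁻¹, then a 3–4 minute
cool-down — while 1-second heart rate, breathing rate and accelerometry are
recorded alongside breath-by-breath tidal volumes.

Cohort morphology: age $\sim N(17.3, 1.3)$ truncated to [15, 18], height
$\sim N(175, 10)$ cm, 40% female, BMI $\sim N(20.6, 2.9)$, race drawn from
the three NHANES III categories (0.80/0.07/0.13). Measured FVC is the
NHANES III prediction times a $N(0.92, 0.10)$ percent-predicted factor, and
FEV$_1$/FVC $\sim N(0.88, 0.051)$ — so the simulated cohort's lung function
sits at ~92% of predicted with the dispersion of a healthy adolescent
panel.

Ventilation truth: per breath, the windowed $\dot V_E/\mathrm{FVC}$ over
the seconds since the previous breath equals
$\beta_0 + \beta_H \overline{\mathrm{HR}} + \beta_f f_B + b_i +
\varepsilon$, with defaults $\beta = (-4.247, 0.0595, 0.226)$ — the
package's recommended two-predictor equation, so that recovery tests double
as plausibility checks — $\tau = 0.4$, $\sigma = 1.4$, and breathing rate
linked to heart rate by $f_B = \max(8, -7.7 + 0.31\,\mathrm{HR}) + N(0,2)$.
Tidal volume is the implied $\dot V_E / f_B$, capped at 60% of FVC; demand
beyond the cap is realized by pacing the next breaths faster, a single-pass
rendering of the tidal-volume plateau of vigorous exercise. Two details
make the generator exactly self-consistent with the preprocessing
contract: the truth is stated on the same window the individual-breath
dataset averages over (window-mean heart rate, the realized breathing rate
that paced the window), and the 1-second breathing-rate series is derived
from realized breath spacing. Consequently, with $\tau = \sigma = 0$ an
OLS refit of the individual-breath dataset returns the generative
coefficients to machine precision — the pipeline's strongest smoke test.

What the generator does **not** emulate, deliberately: residual
autocorrelation. Real breath-by-breath ventilation is strongly
autocorrelated, which is why real time-averaged datasets keep far more
dispersion (and real cross-validated percent errors are several times
larger) than independent per-breath noise allows. The generator draws
$\varepsilon$ independently per breath because that is the declared
contract and matches the analysis model's assumption; an AR(1) option
(`resid_phi`) exists for sensitivity studies, under which confidence
intervals undercover by a few percent — exactly the caveat a practitioner
should carry to real data. Passing recovery and coverage tests here
demonstrates correctness of the machinery under its own assumptions, not
robustness to the correlation structure of real physiologic series.
Activity (ACT) levels are plausible placeholders (≈0 rest, ≈0.2 walking,
0.4–0.8 running) and carry no quantitative guarantees.

Field sessions alternate 5-minute rest/activity bouts (heart rate ≈75/≈150
with 30-s transitions) and draw the pollutant concentration as a
stationary AR(1) series with the requested mean, SD a quarter of the mean,
lag-1 correlation 0.8, floored at zero, on a 1-minute grid.

All randomness flows from one seed through deterministic per-stage,
per-subject substreams, so every object in a run is reproducible from the
master seed alone.

## Preprocessing choices

Breath volumes attach to the 1-second row containing the exhalation start
(floor of the event time); two breaths flooring to the same second sum, so
attached volume is conserved exactly. Fixed averaging windows (60/30/15 s)
align to session start; the individual-breath time base emits one record
per breath covering the seconds since the previous one. Per window,
$\dot V_E = \bar V_T \cdot \bar f_B$ — the mean volumetric flow during the
window, the formula this method defines — with total-volume/duration
available behind `ve_mode = "volume_per_time"` for sensitivity checks. The
two differ when $f_B$ varies within a window (a Jensen gap worth ~0.01 on
the intercept of a 30-s refit of noise-free data, and nothing on the
slopes). Windows with physiologic data but no breath are dropped with a
message, since ventilation is undefined there. The warm indicator smooths
heart rate with a centered 15-s rolling mean and splits the session at the
last attainment of the smoothed maximum: 0 up to and including the peak,
1 after, so constant or monotone series are all 0.

## Dose integration

Ventilation for a field record is $\mathrm{FVC}\cdot(\beta_0 + \beta_H
\mathrm{HR} + \beta_f f_B)$, floored at zero — the equations are never
calibrated at very low heart rate, and a negative extrapolated ventilation
is unphysical, so the floor is this package's extrapolation policy.
Integration is rectangle-rule on the 1-minute concentration grid: each
second's prediction belongs to the minute containing it, partial leading
and trailing minutes are weighted by coverage, per-interval volume is
$\dot V_E \Delta t/1000$ m³, exposure is $c\,\Delta t$, dose is $c$ ×
volume, and totals are sums (the unit chain L·min⁻¹ → m³ → µg·m⁻³ → µg).
No interpolation happens across intervals, gaps in coverage are an error
rather than a silent zero, and the rest counterfactual re-integrates the
same concentration series under a constant baseline ventilation.

## Problem sizes and numerical conventions

The shipped tests run the generator at the study's own scale — 15 subjects,
~10-minute sessions, ~300 thirty-second records — with 100 replicate
cohorts for coverage checks, 50 for selection checks, and 20 random fold
splits wherever a percent error is averaged; the full 511-subset
enumeration is exercised end-to-end in the pipeline run, while replicate
selection studies score the two-predictor stratum that the choice under
test depends on. λ is searched on a quarter-decade log grid before
refinement; REML local optimality is probed against random λ draws in the
property tests; rank-deficient designs, single-subject data, subjects with
fewer than two observations, unknown race categories, negative
concentrations and coverage gaps are all explicit errors naming the
offending input.

## Known limitations

The NHANES III equations cover three race/ethnicity categories; anything
else requires an explicit user-supplied mapping (`race_map`) — the package
refuses to guess. The mixed model is a random intercept only: no random
slopes, no non-identity links, no Kenward–Roger or Satterthwaite
corrections. The generator's independence of residuals, its ACT placeholder
and its fixed breathing-rate link are idealizations; conclusions about real
sessions should lean on the documented caveats above. The recommended
coefficients shipped as `ventilation_model("model1")`/`"model2"` presets
derive from healthy adolescents and a treadmill protocol; applying them to
children, older adults, or subjects with airway obstruction is
extrapolation.
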