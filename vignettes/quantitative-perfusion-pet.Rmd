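---
title: "Quantitative myocardial perfusion PET with mbfpet: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative myocardial perfusion PET with mbfpet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbfpet)
```

## The measurement problem

Dynamic cardiac PET measures myocardial blood flow (MBF, mL of blood per
gram of tissue per minute) by following a bolus of a perfusion tracer
through the heart. The scanner records, frame by frame, the activity
concentration in the left-ventricular (LV) blood pool — the arterial input
function $C_A(t)$ — in the right-ventricular (RV) blood pool $C_{RV}(t)$,
and in the myocardial wall, $C_{PET}(t)$. Tracer-kinetic compartment
modelling turns these time–activity curves into absolute flow. `mbfpet`
implements that computation chain end to end: forward models, weighted
fitting, basis-function parametric mapping, a retention estimator,
17-segment scoring and threshold interpretation, protocol/dosimetry
arithmetic, and a synthetic study generator that makes every stage testable
against known ground truth.

## Kinetic models

**One-tissue compartment model.** Tracer enters tissue at rate $K_1$
(mL/g/min) and clears at rate $k_2$ (1/min):
$$C_T(t) = K_1\, C_A(t) \otimes e^{-k_2 t}.$$
A myocardial region additionally contains blood signal and spill-over from
both ventricular cavities, so the measured signal is
$$C_{PET}(t) = (1 - V_{LV} - V_{RV})\, C_T(t) + V_{LV} C_A(t) + V_{RV} C_{RV}(t),$$
with $V_{LV}, V_{RV}$ the fractional blood contributions. The
$(1 - V_{LV} - V_{RV})$ pre-factor is a convention that some
implementations omit; `pet_signal_1tc(..., prefactor = FALSE)` reproduces
the variant without it, and every fit records which convention was used.
We close the parameter domain at $V_{LV} + V_{RV} \le 1$: the equality
point is the degenerate pure-blood voxel, which must be representable both
to express the identity $C_{PET} = C_A$ and so that fits of blood-pool
curves can converge to it.

**Water model.** $^{15}$O-water is freely diffusible: $K_1 =$ MBF, and
clearance is tied to flow through the tissue partition coefficient
$p = 0.91$ g/mL, $k_2 = \mathrm{MBF}/0.91$. The model is re-parameterised
as
$$C_{PET}(t) = \mathrm{PTF} \cdot \mathrm{MBF}\cdot C_A(t) \otimes
e^{-\frac{\mathrm{MBF}}{0.91}t} + V_{LV} C_A(t) + V_{RV} C_{RV}(t),$$
where the perfusable tissue fraction PTF (g/mL) is the amplitude term
acting as an intrinsic partial-volume correction. Whether PTF absorbs the
$(1-V_{LV}-V_{RV})$ factor is convention-dependent; the default here is
that it does (no explicit pre-factor), with
`ptf_absorbs_blood_fraction = FALSE` exposing the other convention for
cross-checks. Derived quantities: transmural MBF
$= \mathrm{MBF}\cdot\mathrm{PTF}/(1 + V_{LV} + V_{RV})$, and the
perfusable tissue index PTI $= \mathrm{PTF}/\mathrm{ATF}$, a viability
marker.

**Irreversible two-tissue model.** For $^{13}$N-ammonia a trapping rate
$k_3$ (metabolic incorporation into the glutamine pool) feeds an
irreversible second compartment. The total tissue activity has the closed
form
$$C_T(t) = K_1\left[\tfrac{k_2}{k_2+k_3} C_A \otimes e^{-(k_2+k_3)t} +
\tfrac{k_3}{k_2+k_3} \textstyle\int_0^t C_A\right],$$
which nests the one-tissue model at $k_3 = 0$ and pure trapping
($C_T = K_1 \int C_A$) at $k_2 = 0$.

**Extraction correction.** For extracted tracers $K_1 = E(\mathrm{MBF})
\cdot \mathrm{MBF}$ with a flow-dependent first-pass extraction fraction.
`mbfpet` uses the generalized Renkin–Crone form
$E(\mathrm{MBF}) = 1 - a\,e^{-b/\mathrm{MBF}}$ with coefficients held in a
JSON configuration file, because the guideline literature presents the
relation only graphically; the shipped defaults ($a=0.77$, $b=0.63$ for
rubidium; $a=0.607$, $b=1.25$ for ammonia) come from the cited primary
validation studies and can be replaced wholesale via
`extraction_model()`. Inversion (`k1_to_mbf()`) is by bisection to 1e-6 on
the configured validity range; a $K_1$ above the maximum attainable value
on that range raises an unidentifiable-flow error rather than
extrapolating.

**Retention estimator.** The simplified estimator divides late tissue
uptake by the cumulative arterial integral,
$K_i = C_{PET}(T)/\int_0^{T} C_A$, trapezoidally on the frame grid. $K_i$
underestimates MBF more than $K_1$ does; the blood-correction convention
inside this estimator is not standardized, so both the naive and the
$V_{LV}$-corrected variants are exposed
(`retention_ki(..., blood_correction = list(V_LV = ...))`).

## Numerical core

Input functions are represented as piecewise-linear curves, zero before
$t = 0$. For that representation the convolution with an exponential
kernel has an exact per-segment recursion
($I_{j+1} = I_j e^{-k\,\Delta t} + C_{j+1} g_1 - b\, g_2$, with series
fallbacks for $k\,\Delta t < 10^{-5}$ to avoid cancellation), so the
forward models carry no quadrature error; the test suite checks them
against 1-ms trapezoidal quadrature and a stiff ODE integration to
better than 0.1%.

Frame values are frame-averaged concentrations, not midpoint samples,
matching how dynamic PET frames are formed. Frame averages of the smooth
convolution term use Simpson's rule with 8 subdivisions per frame; the
piecewise-linear blood terms are averaged exactly (their kinks would
degrade a fixed-order rule). Time is seconds at every interface and
minutes for rate constants internally, converted in exactly one place.

## Estimation

`fit_1tc()` / `fit_2tc_irr()` perform bounded Levenberg–Marquardt least
squares with weights proportional to frame duration times physical decay
survival (the inverse-variance shape of counting statistics on
decay-corrected frames, deliberately excluding the value dependence), a
fixed multi-start grid over $k_2 \in \{0.2, 0.6, 1.5, 3\}$ min$^{-1}$ to
guard the $K_1/k_2$ trade-off, and box constraints $K_1 \in [0,6]$,
$k_2, k_3 \in [0,8]$, $V \in [0,1]$ (all configurable via
`fit_options()`). Non-convergence flags the result instead of throwing.
The two-tissue fit defaults to the first 4 minutes of data, ahead of late
tracer metabolism; the full window is available. Standard errors use a
model-based sandwich form: frame variance is taken proportional to
(value)/(duration × decay survival) with a single scale estimated from the
residuals, because a classical $\sigma^2 (J^TWJ)^{-1}$ under-reports when
the weights intentionally ignore the value dependence. Monte-Carlo checks
in the test suite hold the reported SEs within 30% of the empirical
spread at 5% frame noise.

`fit_water_basis()` exploits that for fixed MBF the water model is linear
in $(\mathrm{PTF}\cdot\mathrm{MBF}, V_{LV}, V_{RV})$: each candidate on a
basis grid (default 30 log-spaced flows covering 0.2–6 mL/g/min) is solved
by weighted non-negative least squares (exact active-set enumeration for
the 3-column problem), and the minimizing grid point is refined between
its neighbours by parabolic interpolation on log-MBF followed by a bounded
Brent polish — off-grid flows are recovered to well under 1%. Ties resolve
to the smallest MBF for stability at flat optima. `fit_parametric_map()`
applies the same solver voxel-wise with the basis precomputed once;
voxels below the activity mask threshold carry `NA` sentinels.

## The synthetic study generator

The generator defines the study conditions for all tests. The arterial
input is a gamma-variate first pass (default: 8 s arrival delay, 60 kBq/mL
peak, shape 3, scale 4.5 s — a tight automated-injector bolus) plus a
recirculation tail formed by convolving the first pass with an exponential
dispersion kernel (fraction 0.15, time constant 40 s). The RV curve leads
the arterial curve by a 4 s transit delay and is scaled by 1.15, as the
right heart sees the bolus earlier and less dispersed. Seventeen segmental
curves are produced from per-segment ground-truth parameters on any
framing scheme (the registry ships the published re-binning schemes keyed
by first author and tracer).

Noise is zero-mean Gaussian on the decay-corrected frame values with
variance proportional to value/(frame duration × decay survival) — the
standard behaviour of reconstructed, decay-corrected PET frames — and the
level parameter is calibrated so that `noise_level` equals the coefficient
of variation at the peak myocardial frame (0.05 is a typical clinical
study). Default ground truth in the pipeline configuration: resting MBF
0.9 mL/g/min with stress 3× rest, PTF 0.7 g/mL, $V_{LV} = 0.25$,
$V_{RV} = 0.1$; extracted-tracer simulations tie $k_2 = K_1/0.8$ through
an apparent distribution volume of 0.8 mL/g. These are mid-normal values
for rest/hyperaemia studies. Patient motion is emulated as the documented
late-phase hump — affected frames become $(1-f)\cdot$tissue
$+ f\cdot$blood mixtures, with the affected range and fraction recorded in
metadata; the magnitude of real "myocardial creep" is not quantified in
the guideline literature, so the defaults are arbitrary and exposed.
Shortened-protocol contamination adds the physically decayed
mono-exponential continuation of the rest curves' late phase to the stress
study, and `correct_residual()` inverts it by the same extrapolation rule.

What the generator does *not* emulate — reconstruction artefacts,
attenuation/scatter residuals, detector saturation, spatially correlated
noise, partial-volume geometry — bounds what passing tests mean: they
validate the computation chain on data that satisfy the models'
assumptions, not robustness to scanner physics.

Simulation sizes used throughout the tests (17-segment studies on the
published 4–10 min schemes, 200-replicate Monte-Carlo runs, 6×6 voxel
phantom maps) were chosen to give ~3% Monte-Carlo precision on variance
ratios and sub-percent precision on bias estimates.

## Scoring, interpretation and reporting

Semi-quantitative reading scores each of the 17 AHA segments 0 (normal) to
4 (absent perfusion); SSS/SRS are the stress/rest sums, SDS their
difference, and percent scores divide by the maximum 68. Classification
bands: SSS 0–3 normal, 4–7 mildly abnormal, 8+ moderate-to-severe — the
published bands skip SSS = 8 ("4–7" then "> 8"), an ambiguity we resolve
to moderate/severe; the stricter conventions (any SSS > 0; SSS% > 1%) are
selectable. Water studies omit scoring altogether, since a freely
diffusible tracer yields no uptake images.

The water abnormality rule — at least two *adjacent* segments with
hyperaemic MBF ≤ 2.30 mL/min/g (inclusive boundary) — needs a segment
adjacency graph that the 17-segment model itself does not define. The
shipped graph connects ring neighbours (basal 1–6, mid 7–12, apical 13–16,
each cyclic), radial basal–mid pairs (i, i+6), mid–apical neighbours
(13: 7, 8, 12; 14: 8, 9; 15: 9, 10, 11; 16: 11, 12) and the apex (17) to
all apical segments; tests verify the rule against a brute-force scan over
all pairs. Territory aggregation uses the standard LAD/RCA/LCX assignment
and is configurable to a patient's own coronary distribution. Global MFR
is reported both as mean-of-segment-ratios and ratio-of-global-means, as
the literature does not choose between them. Resting MBF can be normalized
to a reference rate–pressure product (default 10,000 — a convention, not a
guideline-fixed number). The LVEF-reserve rule classifies a stress–rest
change above +5 percentage units as making severe CAD unlikely and below
−5 as making it likely, flagging any negative reserve. Structured reports
(JSON + Markdown) follow the standard reporting scheme and omit the score
sections for water.

## Known limitations

* The 2TC fit inherits the usual identifiability weakness of $k_3$ at
  short acquisition windows; the default 4-min window trades late-phase
  information for robustness to metabolism.
* The retention estimator's conversion to MBF reuses the $K_1$ extraction
  curve, which overstates flow slightly since $K_i < K_1$; it is intended
  as the simplified comparator, not the primary estimator.
* The residual-activity correction assumes a mono-exponential late phase;
  multi-compartment washout would leave a small structured residual.
* Voxel-wise mapping is provided for phantom-scale arrays; it is not
  optimized for full clinical volumes.
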