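# mbfpet — quantitative myocardial blood flow from dynamic cardiac PET

`mbfpet` implements the computation chain behind quantitative myocardial
perfusion PET: from dynamic time–activity curves to absolute myocardial
blood flow (MBF), myocardial flow reserve (MFR), 17-segment scoring and a
structured clinical-style report. It is aimed at physicists and
methodologists who want a transparent, fully testable reference
implementation of the standard kinetic models — every stage is exercised
end-to-end on synthetic rest/stress studies with known ground truth, so no
patient data are needed to validate the chain.

## The models

The myocardial PET signal is modelled as tissue uptake plus ventricular
blood signal and spill-over:

* **One-tissue compartment model** (rubidium-82, early-window ammonia):

  C_PET(t) = (1 − V_LV − V_RV) · K1 · C_A(t) ⊗ e^(−k2 t) + V_LV·C_A(t) + V_RV·C_RV(t)

  with uptake K1 (mL/g/min), clearance k2 (1/min) and blood fractions
  V_LV, V_RV. Flow follows from K1 through a configurable Renkin–Crone
  extraction model E(MBF) = 1 − a·e^(−b/MBF).

* **Water model** (oxygen-15 water, K1 = MBF, k2 = MBF/0.91):

  C_PET(t) = PTF · MBF · C_A(t) ⊗ e^(−(MBF/0.91) t) + V_LV·C_A(t) + V_RV·C_RV(t)

  where the perfusable tissue fraction PTF is an intrinsic partial-volume
  correction. A basis-function implementation solves the linear
  sub-problem per candidate MBF, enabling fast voxel-wise parametric maps.

* **Irreversible two-tissue model** (ammonia with metabolic trapping k3),
  solved in closed form, plus the simplified **retention estimator**
  Ki = C_PET(T) / ∫₀ᵀ C_A.

Around the estimators: frame re-binning schemes from the published
literature, decay correction, flow-dependent extraction inversion,
AHA 17-segment maps with SSS/SRS/SDS scoring and threshold rules (water:
two adjacent segments at ≤ 2.30 mL/min/g), LVEF-reserve classification,
rate–pressure-product normalization, dosimetry and protocol-timing
arithmetic, and a synthetic rest/stress study generator with a
gamma-variate bolus and counting-statistics frame noise.

## Worked example

Simulate a rest/stress water study (resting MBF 0.9 mL/g/min, stress
3× rest, 5% frame noise), quantify all 17 segments with the
basis-function water fit, and report:

```r
library(mbfpet)
cfg <- run_config(tracer = "water", seed = 42, noise_level = 0.05)
cmd_simulate(cfg, "study")
cmd_quantify(cfg, "study", "res")
cmd_report("res", "rep")
res <- jsonlite::read_json("res/results.json", simplifyVector = TRUE)
mean(unlist(res$rest$mbf))        # 0.901  (truth 0.9 mL/g/min)
mean(unlist(res$stress$mbf))      # 2.674  (truth 2.7 mL/g/min)
res$mfr$global_mean_of_ratios     # 2.975  (truth 3)
unlist(res$territory$stress)      # LAD 2.672, RCA 2.766, LCX 2.585, global 2.674
res$interpretation$abnormal       # FALSE: no two adjacent segments <= 2.30
```

A single-curve fit shows the estimator interface; at 5% peak noise the
estimates carry calibrated standard errors:

```r
st <- simulate_study("water", framing_scheme("clinical-water")$schedule,
                     water_params(2.5, 0.7, 0.25, 0.1),
                     noise_level = 0.05, seed = 42)
fit_water_basis(st$curves$seg01, st$input_fine$C_A, st$input_fine$C_RV,
                tracer = st$tracer)
#> <fit_result> model water_basis, wrss 6.546, converged
#>    MBF    PTF   V_LV   V_RV
#> 2.4565 0.7375 0.2590 0.0940
```

Protocol arithmetic is one-liners: `effective_dose(c(400, 400), "water")`
gives `0.8` mSv and `min_interval("ammonia") / 60` gives `49.8` minutes
(five half-lives of the 9.96-min tracer).

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/cli/`:

```sh
Rscript inst/cli/mbfpet all --tracer water --seed 42 --noise 0.05 --out run/
```

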