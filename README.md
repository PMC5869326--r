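# tackit

Tracer kinetic analysis of dynamic [¹⁸F]FDG PET time-activity curves
(TACs), built around three estimators of the net influx constant
**Ki** (mL·min⁻¹·mL⁻¹) and their head-to-head comparison on a
21-patient lung cancer cohort whose per-patient fitted parameters are
packaged as a machine-readable table.

## What it computes

For a blood input function A_p(t) and a tissue curve A_T(t):

* **Patlak graphical analysis** — ordinary least squares of
  A_T(t)/A_p(t) against the stretched time ∫₀ᵗA_p dτ / A_p(t); the
  slope is Ki, the intercept the free-tracer fraction V_b. Exact only
  when trapping is irreversible (release rate k_b = 0).
* **Three-parameter kinetic model (3P)** — the input function is fitted
  as A_p(t) = A₀·[8.20 e^(−9.3363 t) + 1.17 e^(−α₂t) + e^(−α₃t)]
  (decay-uncorrected), which makes the reversible-trapping tissue curve
  closed-form:

      A_T(t) = Ki·A₀·Σᵢ cᵢ (e^(−αᵢt) − e^(−βt)) / (β − αᵢ) + V_b·A_p(t),
      β = λ + k_b,  λ = ln2 / 109.77 min⁻¹

  so (Ki, k_b, V_b) are fitted directly to the measured TAC by bounded
  nonlinear least squares.
* **Five-parameter two-tissue model (5P)** — K₁, k₂, k₃, k₄, V_b with
  the macroparameters Ki = K₁k₃/(k₂+k₃) and k_b = k₂k₄/(k₂+k₃).
* **Comparison statistics** — Bland–Altman ratio/difference agreement
  (mean, t-based 95% CI of the mean, 1.96·SD limits of agreement),
  Pearson correlations and OLS lines, driven by the packaged table.
* **Synthetic data** — forward simulation of IF/tissue TAC pairs with
  seeded multiplicative Gaussian noise, for validation and
  parameter-recovery tests.

## Worked example

Simulate patient 9 of the cohort at 5% multiplicative noise, refit both
models, then reproduce the cohort statistics from the packaged table:

```r
library(tackit)
pc <- physical_constants()                 # 18F half-life 109.77 min
d  <- table1_fixture()                     # 21 patients x 14 parameters
r9 <- d[d$patient_id == 9, ]

m9   <- if_model(r9$A0, r9$alpha2, r9$alpha3)
case <- synthetic_case(m9,
          truth_3p = c(r9$kma3p_Ki, r9$kma3p_kb, r9$kma3p_Vb),
          noise = noise_model("multiplicative-gaussian", 0.05, 42))
tacs <- generate_case(case, pc)

fit_3p(tacs$tissue_tac, m9, pc)
#> <kma3p_fit> Ki=0.0408 mL/min/mL, k_b=0.0012 /min, V_b=0.106 (R=0.951)
patlak_analysis(tacs$tissue_tac, m9, pc)$Ki
#> [1] 0.0389

run_reproduction(list(seed = 1L))
#> == cohort reproduction report ==
#> patients: 21 (8 with k_b > 0)
#> 3P/Patlak Ki ratio: 1.060 +/- 0.039 (CI), LoA 0.170
#>   k_b = 0 subset:   1.014 +/- 0.030 (CI), LoA 0.098
#> Ki ratio vs k_b: slope 43.679, intercept 1.022, R 0.801
#> 5P/Patlak ratio 1.057, 3P/5P ratio 1.017, |kb diff| 0.00041
#> synthetic refit: max rel. Ki error 2.97e-14, trend rho 0.88
```

Reading: the generating truth for patient 9 was Ki = 0.0446 with
k_b = 0.0018; at 5% noise the 3P refit lands at 0.0408 while Patlak,
which forces k_b = 0, lands lower at 0.0389 — the systematic Patlak
underestimation that grows with k_b (cohort-wide regression slope ~44
per unit k_b, R = 0.801). The trapped-tracer curve of the cohort-mean
fit peaks at ~87 min versus ~83 min for the total TAC
(`peak_times_3p()`), late of the usual static-imaging window.

A command-line front end is installed as `exec/tackit`
(`tackit reproduce --out report.json`, `tackit simulate --patient 9 ...`,
`tackit fit-3p tissue.csv --if-model model.json`, ...); see
`?tackit_cli`.

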