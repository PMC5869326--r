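---
title: "Kinetic analysis of dynamic FDG-PET time-activity curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of dynamic FDG-PET time-activity curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tackit)
```

## The problem

Dynamic [18F]FDG PET of a tumour yields two sampled curves: the blood
input function $A_p(t)$ (tracer concentration in blood, kBq/mL) and the
tissue time-activity curve $A_T(t)$. The clinically interesting quantity
is the net influx constant $K_i$ (mL min$^{-1}$ mL$^{-1}$), the
steady-state rate at which tracer is phosphorylated and trapped. The
textbook estimator is Patlak's graphical analysis, which is exact only
if trapping is irreversible. Many tissues release a little trapped
tracer back to blood; `tackit` implements three estimators that differ
in how they treat that release, plus the agreement statistics used to
compare them on a 21-patient lung cancer cohort whose per-patient fitted
parameters ship with the package (`table1_fixture()`).

## Models

**Input function.** $A_p(t)$ is modelled as a tri-exponential decay on
the decay-uncorrected scale,
$$A_p(t) = A_0\,[\,8.20\,e^{-9.3363\,t} + 1.17\,e^{-\alpha_2 t} + e^{-\alpha_3 t}\,],$$
with the amplitude ratios and the fast constant frozen at Hunter's
whole-blood population values and only $(A_0,\alpha_2,\alpha_3)$ fitted
per patient (`fit_if()`). The justification for freezing the fast term
is quantitative: at the cohort-mean slow constants it carries only about
1.1% of the total area under the curve (`if_auc_fractions()`), while the
slowest term carries ~89%.

**Patlak.** With irreversible trapping, plotting $A_T(t)/A_p(t)$ against
the "stretched time" $\int_0^t A_p\,d\tau / A_p(t)$ gives a line with
slope $K_i$ and intercept $V_b$, the free-tracer (blood + interstitial)
fraction (`stretched_time_transform()`, `patlak_fit()`). Validity
requires $t > t^*$, after the reversible pools equilibrate with plasma;
the default late acquisition window (11 × 5-min frames, mid-times
7.5-57.5 min) satisfies this.

**Three-parameter model (3P).** Allowing a slow release rate $k_b$
(min$^{-1}$) from the trapped pool and exploiting the exponential-sum
input function gives a closed-form tissue curve on the uncorrected
scale, with $\beta = \lambda + k_b$ ($\lambda = \ln 2 / 109.77$
min$^{-1}$, the 18F decay constant):
$$A_T(t) = K_i A_0 \sum_{i=1}^{3} c_i\,
  \frac{e^{-\alpha_i t} - e^{-\beta t}}{\beta - \alpha_i}
  + V_b A_p(t).$$
`fit_3p()` estimates $(K_i, k_b, V_b)$ by bounded nonlinear least
squares directly on the measured tissue TAC — no data transform, so the
trapped and free components are available analytically
(`decompose_3p()`) and the curve can be extrapolated beyond the
acquisition to locate its peak (`peak_times_3p()`).

**Five-parameter model (5P).** The standard two-tissue compartment model
($K_1, k_2, k_3, k_4$, plus $V_b$) is solved analytically by convolving
its bi-exponential impulse response with the tri-exponential input
(`tissue_model_5p()`, `fit_5p()`). Its macroparameters are
$K_i = K_1 k_3/(k_2+k_3)$ and $k_b = k_2 k_4/(k_2+k_3)$
(`ki_from_micro()`, `kb_from_micro()`). Because these combine three
independently estimated microparameters, their uncertainty is larger
than the directly fitted 3P values — which is the cohort's central
observation: the Patlak underestimation of $K_i$ grows with $k_b$
(visible as the regression of the 3P/Patlak $K_i$ ratio on $k_b$,
slope ≈ 44, R ≈ 0.80) yet is invisible in the noisier 5P comparison.

## Decay-state conventions

Activities carry an explicit `decay_corrected` flag at every boundary;
operations convert rather than assume:

* `fit_if()`, `fit_3p()`, `fit_5p()` work on *uncorrected* data — the
  canonical model forms above absorb $\lambda$ into their exponents.
* Patlak works on *corrected* data, since Patlak theory has no decay
  term. Correcting a tri-exponential model just shifts every time
  constant by $-\lambda$, so the same machinery serves both scales.

## Numerical choices

* **Optimiser.** The reference analysis used Levenberg-Marquardt. Plain
  LM cannot hold $k_b \ge 0$, and 13 of the 21 cohort fits sit exactly
  on that bound, so we use a projected LM step (damped normal equations
  with the candidate clipped to the box and accepted only on SSQ
  descent) followed by an L-BFGS-B polish. Same model, different
  mechanism; noise-free self-generated data are recovered to machine
  precision (asserted at 1e-6 / 1e-4 relative in the tests).
* **Bounds.** IF: $\alpha_2 \in [0.02, 2]$, $\alpha_3 \in [0.001, 0.1]$
  — prevents the two slow exponentials from swapping roles. 3P:
  $K_i \in (0,1]$, $k_b \in [0, 0.1]$, $V_b \in [0,1)$. 5P:
  $K_1 \in (0,2]$, $k_{2,3} \in [0,2]$, $k_4 \in [0,0.5]$, with three
  deterministic multistarts (cohort-typical values ±2-fold) because the
  5P objective is multimodal. A fixed start set was preferred over
  randomised multistart: it makes refits bit-reproducible with no RNG
  coupling.
* **Starting values** (nothing published): IF from the cohort-mean
  magnitudes ($\alpha_2 = 0.15$, $\alpha_3 = 0.015$, $A_0$ from the last
  sample); 3P from a Patlak fit of the same data (slope → $K_i$,
  intercept clipped to $[0, 0.5]$ → $V_b$, $k_b = 0.001$).
* **Removable singularity.** $\beta$ can collide with $\alpha_3$ (both
  ~0.01 min$^{-1}$); within $10^{-9}$ min$^{-1}$ the exponential
  difference quotient is replaced by its limit $c_i t e^{-\beta t}$.
  The closed form is verified against adaptive quadrature of the
  defining convolution to 1e-8 relative, including at the collision.
* **Patlak integral.** The running integral $\int_0^t A_p$ uses the
  fitted analytic IF, because the 0-5-min segment is unobserved; a
  trapezoid mode (analytic fill-in before the first frame) exists for
  sensitivity checks. Residuals are unweighted everywhere: frame
  durations are recorded but no weighting rule was published.
* **Peak search**: 0.1-min grid over (0, 600] min plus golden-section
  refinement; the curves are flat near their maxima, so peak times are
  meaningful to ~±1 min at best.

## The synthetic-data generator

`generate_case()` emulates the stated acquisition: the 11 × 5-min late
scheme (or a dense bolus scheme — 12 × 5 s, 6 × 10 s, 8 × 30 s, then
5-min frames — for 5P fits, since the real short-frame protocol is
unpublished), a tri-exponential IF sampled at frame mid-times, tissue
from the 3P or 5P forward model, and optional multiplicative Gaussian
noise (default coefficient 0.05) applied independently to IF and tissue.
Multiplicative Gaussian was chosen over Poisson because TACs are
calibrated concentrations, not counts; the true noise magnitude of
5-hottest-voxel VOI curves is unknowable from the published material,
so no acceptance-level claim depends on the noise level. What a green
synthetic test establishes is therefore *self-consistency* (generator →
fitter round trips, Patlak bias trends), not fidelity to scanner noise,
partial-volume effects, respiratory motion, or IF calibration error —
none of which are modelled.

The per-patient parameter table itself is transcribed, checksummed and
re-summarised against its printed mean/SD rows; cohort statistics are
computed directly from it ("fixture branch" of `run_reproduction()`),
never from synthetic refits, so printed-number reproduction cannot
silently depend on the generator.

## Known limitations and open readings

* The published methods fit "Ki, k_b, and F"; F is never defined and is
  read here as $V_b$ (the only remaining unknown of the model).
* The sign convention of the printed 3P-minus-5P $k_b$ difference
  (+0.00041 min$^{-1}$) is opposite to what the table arithmetic gives
  (−0.00041); the package reports the signed value and asserts the
  magnitude.
* The blood term is additive ($+V_b A_p$), consistent with the model
  equations here; software using a $(1-V_b)$-weighted convention will
  disagree slightly in $V_b$ (the cohort's 3P and 5P $V_b$ were
  uncorrelated anyway, R = 0.12).
* Whether the original Patlak implementation used corrected or
  uncorrected curves, and analytic or trapezoidal integrals, is
  unstated; both choices are exposed as options with the defaults
  motivated above.

## A worked example

```{r example}
pc <- physical_constants()
d <- table1_fixture()
r9 <- d[d$patient_id == 9, ]

# forward-simulate patient 9, noise-free, and refit
m9 <- if_model(r9$A0, r9$alpha2, r9$alpha3)
case <- synthetic_case(m9, truth_3p = c(r9$kma3p_Ki, r9$kma3p_kb,
                                        r9$kma3p_Vb))
tacs <- generate_case(case, pc)
fit_3p(tacs$tissue_tac, m9, pc)
patlak_analysis(tacs$tissue_tac, m9, pc)$Ki

# cohort statistics straight from the packaged table
print(run_reproduction(list(seed = 1L)))
```
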