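---
title: "Tracer-based tolerance-test analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer-based tolerance-test analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracegtt)
```

# The measurement and the model

An oral glucose or mixed-meal tolerance test with a co-administered
[U-¹³C₆]-glucose tracer produces, per animal, three sparse time series:
blood glucose at 0, 5, 10, 20, 30, 45, 60, 90 and 120 min; a GC-MS
mass-isotopologue distribution (MID) of the glucose pentaacetate
derivative at the same times; and blood-spot insulin at 0, 10, 30, 60,
90 and 120 min. The bolus is 1 g/kg body weight, 5% w/w tracer.

The kinetic skeleton is a two-compartment model. Glucose leaves the
gastrointestinal compartment at the apparent absorption rate
$k_a = k_1 + k_L$, of which the fraction $F = k_1/(k_1+k_L)$
(bioavailability) reaches plasma; plasma glucose is cleared at the
fractional rate $k_2$. The tracer pool receives no endogenous input, so
its plasma concentration is the pure absorption-clearance response

$$c(t) = A\,\frac{k_a}{k_a-k_2}\left(e^{-k_2 t}-e^{-k_a t}\right),
\qquad A = \frac{F\,D_{tracer}}{V},$$

with the analytic limit $A\,k_a\,t\,e^{-k_a t}$ at $k_a = k_2$. The
unlabelled pool additionally receives endogenous glucose production
(EGP) from the liver:

$$\frac{dQ_u}{dt} = F k_a D_u e^{-k_a t} + EGP(t) - k_2 Q_u(t).$$

All concentrations are pool-concentration units (mM; mM/min for EGP).
Multiplying EGP by $V \times 1000/180.16$ converts to µmol/min.

## Assumptions

* Tracer and tracee are kinetically identical and share one bolus, so
  the unlabelled oral input uses the same $(k_a, F)$ as the tracer.
* The animal is in fasting steady state at $t=0$:
  $EGP(0) = k_2\,Q_u(0)$.
* A single, constant distribution volume $V$ applies over the test.
* Insulin acts implicitly: its effects are already contained in the
  measured curves; the model does not couple insulin to $k_2$ or EGP
  mechanistically.

# Parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| pool volume $V$ | mL | 0.2 × BW(g) | glucose distribution volume ≈ 0.2 mL/g in mice; only $D/V$ enters any observable, so $V$ is a stated convention, not a fitted quantity |
| tracer share | – | 0.05 | 5% w/w of the bolus |
| EGP windows | min | steady 90–120, overall 5–120 | last 30 min; full period excluding the unresolvable first 5 min |
| blood-spot factor | – | 1.28 | spot-to-plasma volume correction for filter-paper samples |
| insulin unit conversion | µU/ng | 23.1 | ELISA convention for HOMA-IR / Matsuda; configurable |
| mass window | – | m0–m6 | the fully labelled tracer appears at m+6, so the window must reach m6; an m0–m4 window remains selectable |
| ion formula | – | C₁₆H₂₆NO₁₁ | glucose pentaacetate ammonium adduct, nominal m/z 408 for m0 |

Because only the lumped amplitude $F D/V$ is identifiable from the
tracer curve, $F$ is derived by fixing $V$. A fitted $F > 1$ is
reported with a warning rather than clipped: it is the visible symptom
of a misspecified volume for that animal.

# The synthetic cohort

`sample_cohort()` draws per-animal ground truth; `simulate_test()`
forward-simulates the measurement design. All compartment equations are
linear with exponential forcings, so the simulator evaluates exact
closed-form solutions; numerical integration appears only as an
independent oracle in the test suite (`deSolve`), which also verifies
tracer mass conservation (GI + plasma + cleared + lost = dose to 1e-8).

Ground-truth EGP follows a double-exponential suppression dip
$EGP(t) = EGP_{basal}\,[1 - d\,(e^{-t/\tau_1}-e^{-t/\tau_2})/s_{max}]$,
chosen because reconstructed EGP in these experiments drops after the
bolus to a minimum and then recovers to a new stationary level. With
OGTT time constants (τ₁ = 40, τ₂ = 10 min) the minimum falls near 18
min; the mixed meal is emulated purely by slower absorption (k_a × 0.6)
and later suppression (τ₁ = 90, τ₂ = 30 min, minimum near 49 min) — no
macronutrient model is attempted.

Default population values (CV of the lognormal inter-animal jitter in
parentheses): k_a 0.045/min (12%), F 0.8 (logit jitter), k₂ 0.02/min
(10%), fasting glucose 8 mM (8%), suppression depth 0.5 (15%), insulin
C 1.8/1.5 ng/mL M/F (20%), k_e 0.012/min (10%), k_a(ins) ≈ 4 k_e,
baseline 0.4 ng/mL (20%). Each dam contributes one male and one female
pup sharing a litter multiplier (5% CV) on fasting glucose and insulin
amplitude, so the dam is a meaningful experimental unit. The fasting
steady-state invariant $EGP_{basal} = k_2 \cdot G_{fast}$ holds for
every animal; consequently a configured "lower basal EGP" group effect
is realized through lower fasting glucose at fixed clearance.

Group effects are multiplicative shifts. The defaults emulate the
offspring phenotype of gestational diabetes exposure qualitatively:
k_a × 1.25 and insulin C × 0.70 in both sexes, plus basal EGP × 0.80
and baseline insulin × 0.85 in females; the high-fat group carries only
k_a × 1.05.

Measurement noise is multiplicative lognormal (mean-preserving) with
defaults CV 3% (glucose), 2% (enrichment), 10% (insulin) — typical
assay precision. The enrichment CV applies to the enrichment reading
itself: the true label fraction is perturbed before the
natural-abundance convolution, so the emitted MID channels carry
perfectly correlated noise. What the generator deliberately does *not*
emulate: drift or autocorrelated assay error, missing samples,
chromatographic interference in the MID, circadian or stress effects,
and any β-cell secretion mechanism. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated error
model, not robustness to every failure mode of real data.

# Numerical choices

**MID correction.** The correction matrix column $j$ is the theoretical
spectrum of a species with $j$ labelled carbons — natural abundance on
all remaining atoms, computed by truncated polynomial convolution of
IUPAC isotope abundances and validated in the tests against brute-force
enumeration over all isotope combinations of a small ion. Correction
solves the least-squares system by QR, refuses matrices with condition
number above 1e8, keeps negative solution components visible by default
(non-negative least squares is an opt-in), and renormalizes to the
simplex. Enrichment is read as the m6 fraction; `one_minus_m0` is
available where "labelled fraction" is preferred.

**Tracer fit.** `ka` is parameterized as `k2 + δ` with `δ > 0`, making
rate label-switching impossible by construction. Residuals are weighted
relatively (1/y², floored at 5% of the curve maximum so the t = 0 point
cannot dominate): the assays are multiplicative-error instruments, and
relative weighting is the variance-matched objective. Measured on
100-replicate recovery studies at glucose CV 3% + enrichment CV 2%,
it lowers the median |relative error| of k_a from 6–11% (animal-
dependent) to 5–9%. Plain unweighted fitting remains available
(`weighting = "none"`).

**Insulin fit.** The fasting baseline is the measured t = 0 value; the
biexponential increment is fitted above it with `ka_ins = ke + δ`. The
likelihood surface has a ridge along $k_a \to k_e$ with $C(k_a-k_e)$
fixed (the gamma-shape limit), so the fit multi-starts over six rate
combinations and keeps the best converged optimum. On this design (6
samples, 10% CV) the amplitude $C$ itself is weakly identified — its
median |relative error| over 100 replicates is ≈ 30–40% and no
objective reweighting repairs that; the identifiable functional is the
fitted AUC, whose time-average recovers with median error ≈ 7%. All
downstream consumers (IS-P, IS-L) therefore use `average_insulin()`,
never $C$ directly. This is a stated limitation, not a defect of the
optimizer: at 2% CV, $C$ recovers with median error ≈ 7%.

**EGP reconstruction.** Differentiating a 9-point interpolant of
$Q_u$ directly propagates the sharp absorption transient into the
spline derivative; pointwise errors against ground truth reach ~28%.
The package instead evaluates the algebraically identical split
$EGP = dE/dt + k_2 E$ with $E = Q_u - A(t)$, where $A(t)$ is the
closed-form absorption response known from the tracer fit. $E$ is
smooth (fasting level plus the gentle suppression response), and an
end-matched cubic spline through its nine values yields pointwise EGP
errors below ~3% on [5, 120] min in noiseless simulations. The direct
formula is available via `split_absorption = FALSE`.
`smooth_unlabeled()` defaults to the shape-preserving monotone Hermite
scheme for the measured pool itself (no overshoot on noisy data); its
derivative is first-order accurate near extrema — about 15% sup-norm on
this grid versus 10% for the C2 natural spline — which is why the
default EGP path does not rely on it. Negative reconstructed EGP values
are retained and summarized as `negative_fraction`; clipping would bias
the overall mean upward silently.

**Indices.** IS-L needs reference means $\bar{EGP}, \bar{INS}$; the
package uses arithmetic means over the analyzed cohort, grouped per sex
(each dataset holds one protocol), on the 5–120 min window, with
`egp_overall` as the EGP input — the window on which both quantities
are defined for every animal. HOMA-IR and Matsuda use the
literature-standard formulas (the source analysis cites but does not
print them), each isolated in one small function with explicit unit
conversions (18.016 mg/dL per mM; 23.1 µU/mL per ng/mL).

**Statistics.** Same-sex siblings are averaged per dam before any test,
so n is the number of litters. One-way ANOVA with Tukey HSD runs per
sex; the sex × group analysis uses type-II sums of squares
(`car::Anova`), appropriate for the unbalanced layouts litter attrition
produces (type II equals type I on balanced data, which the tests
verify). Mixed-effects repeated-measures modelling of whole time
courses is out of scope; curves are compared through AUC summaries
(e.g. 0–30 min trapezoids on raw points).

# Problem sizes in the tests

The suite validates with cohorts of 12–24 virtual mice, 100-replicate
Monte-Carlo recovery studies, and a packaged 12-animal OGTT fixture
(`inst/extdata/ogtt12_synthetic`, generated by `write_dataset()` with
seed 4711 and labelled synthetic); these sizes make every property
cheap to re-run while leaving the Monte-Carlo medians stable to well
under the margins being asserted.

# Known limitations

* $F$ is only as good as the assumed distribution volume; per-animal
  volume error lands in $F$ (and is flagged when $F > 1$) but cancels
  from $k_a$, $k_2$ and the EGP shape.
* The insulin amplitude $C$ is weakly identified at the 6-point, 10%-CV
  design (see above); report averaged insulin, not $C$.
* The MMTT is emulated only through slower absorption and delayed
  suppression; protein/fat handling, incretin effects and gastric
  emptying dynamics are not modelled.
* EGP in the first ~5 min is dominated by the interpolation boundary
  and the bolus transient and is excluded from the overall mean.
* The one-compartment clearance term makes $k_2$ an *apparent*,
  insulin-agnostic clearance ("glucose effectiveness"); dynamic
  insulin action on clearance is not separated.
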