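---
title: "Methods: dissolution similarity and pharmacokinetic bioequivalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissolution similarity and pharmacokinetic bioequivalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkbioeq)
```

pkbioeq implements the complete analysis chain used to decide whether
generic immediate-release tablet brands can substitute a branded reference:
in-vitro dissolution-profile comparison, noncompartmental analysis (NCA) of
single-dose plasma profiles, compartmental model fitting, and brand-level
bioavailability statistics. Every stage can be exercised on simulated
studies with known ground truth, which is how the package validates itself.

## Dissolution similarity

Two release curves sampled on a common grid are compared with the
model-independent factors

$$f_1 = 100\,\frac{\sum_t |R_t - T_t|}{\sum_t R_t}, \qquad
  f_2 = 50\,\log_{10}\!\Big(\big[1 + \tfrac1n \sum_t (R_t-T_t)^2\big]^{-1/2}
  \cdot 100\Big),$$

where $R_t$ and $T_t$ are percent of label dissolved by the reference and
test product. $f_1$ is the average absolute difference relative to the
cumulative reference release, in percent; the factor of 100 puts it on the
percent scale on which the conventional 0--15 acceptance band and published
values are quoted. $f_2$ maps a mean squared difference of zero to 100 and a
constant 10-point difference to just below 50, hence the familiar
$f_2 \ge 50$ similarity threshold. A verdict of "similar" requires both
$0 \le f_1 \le 15$ and $50 \le f_2 \le 100$.

Two deliberate choices:

* **Plateau truncation is optional and off by default.** Regulatory practice
  often retains at most one point where both products exceed 85% dissolved,
  because the plateau carries no discriminating information and inflates
  $f_2$. `truncate_after_85 = TRUE` enables exactly that rule.
* **Mismatched time grids are an error**, never silently interpolated. Only
  `classify_release()` interpolates, linearly and explicitly, to evaluate
  the 15- and 30-minute rules (very rapid: >85% at 15 min; rapid: ≥85% at
  30 min; compliant: ≥80% at 30 min).

The dissolution simulator draws from the cumulative Weibull model
$f(t) = f_{max}\,(1 - e^{-(t/t_d)^b})$ (with $t_d$ the 63.2% time in
minutes and $b$ the shape), plus optional additive Gaussian noise, clipped
to [0, 110]% — a standard flexible description of immediate-release curves.

## Noncompartmental analysis

`nca_profile()` computes, per profile: observed $T_{max}$/$C_{max}$
(earliest time on ties), linear trapezoidal $AUC_{last}$ and $AUMC_{last}$,
$MRT_{last} = AUMC_{last}/AUC_{last}$, the terminal slope $\lambda_z$, and
the derived quantities
$AUC_\infty = AUC_{last} + C_{last}/\lambda_z$,
$Cl/F = D/AUC_\infty$, $V_z/F = D/(\lambda_z\,AUC_\infty)$.

Numerical and procedural choices:

* **Linear trapezoid by default.** The lin-up/log-down rule (exact on
  exponential decay segments) is available as `method = "linear-log"` but
  the plain linear rule is the default, being the simplest defensible
  reading of "trapezoidal method" and the easier rule to audit.
* **Terminal slope selection.** Log-linear least squares on every candidate
  window of ≥3 points strictly after $C_{max}$, keeping the window with the
  best adjusted $R^2$. A nonpositive slope or fewer than 3 usable points
  yields a flagged not-estimable result and disables extrapolation rather
  than producing a nonsense tail.
* **Censored samples are dropped, not zeroed**; the pre-dose sample is an
  exact zero and is retained. Profiles that start after dosing are
  integrated from an implicit (0, 0) anchor, since a single extravascular
  dose implies $C(0)=0$; this makes $AUC_{last}$ invariant to whether the
  pre-dose row is recorded explicitly.
* **Two half-life conventions, never mixed.** The moment-based identities
  $K_{el} = 1/MRT$ and $t_{1/2} = 0.693\,MRT$ are reported as `kel_eq2` /
  `hl_eq2`, separately from the regression-based `lambda_z` /
  `hl_lambda_z`. They coincide only for a one-compartment iv bolus, so both
  are exposed and clearly labelled. The steady-state projection
  `css_24h` $= AUC_\infty/24$ uses a fixed 24-hour dosing interval.
* **Aggregation.** `nca_summary()` reports the mean of per-subject
  half-lives and, separately, the half-life of the mean rate constant
  (`hl_of_mean_lambda_z`); the two differ whenever $\lambda_z$ varies
  between subjects, and published tables rarely state which was used.

## Compartmental modelling

The central model is the two-compartment open model with first-order
absorption. With micro constants $k_{10}, k_{12}, k_{21}$ the hybrid rates
$\alpha > \beta$ are the roots of
$s^2 - (k_{10}+k_{12}+k_{21})s + k_{10}k_{21} = 0$, and the oral curve is
the triexponential

$$C(t) = \frac{k_a D}{V_1}\left[
  \frac{(k_{21}-\alpha)e^{-\alpha t}}{(k_a-\alpha)(\beta-\alpha)} +
  \frac{(k_{21}-\beta)e^{-\beta t}}{(k_a-\beta)(\alpha-\beta)} +
  \frac{(k_{21}-k_a)e^{-k_a t}}{(\alpha-k_a)(\beta-k_a)}\right].$$

A pure biexponential (`iv_biexponential`) cannot produce the nonzero
$T_{max}$ seen after oral dosing — its maximum is at $t=0$ — so the oral
variant is the default, with the iv form retained for bolus data and for
macro-constant work. One-compartment analogues exist for model selection.

* **Initialization by curve stripping.** The terminal window (chosen as in
  NCA) gives $B, \beta$; the positive residuals of earlier post-peak points
  give $A, \alpha$; $k_a$ starts at $2/T_{max}$ (nudged away from $\alpha$
  when they collide). Monoexponential-looking data trigger a flagged
  one-compartment fallback with $\alpha = 5\beta$.
* **Log-parameterized Levenberg–Marquardt.** All rate constants and volumes
  are optimized on the log scale, which enforces positivity without
  constraints; the biexponential is parameterized as $\beta$ plus a
  positive gap so $\alpha > \beta$ by construction. Convergence tolerance
  is $10^{-10}$ on the relative SSE change, at most 500 iterations;
  non-convergence returns the flagged initialization rather than garbage.
  Because optimization starts at the stripping initialization and
  Levenberg–Marquardt never increases the objective, the fitted SSE is
  never worse than the stripping SSE.
* **Degenerate absorption.** $k_a = \alpha$ or $k_a = \beta$ makes the
  triexponential form singular; the public curve function rejects it, and
  the optimizer core nudges $k_a$ by one part in $10^7$ so transient
  excursions cannot produce NaNs.
* **Weighting.** Uniform weights are the default; $1/C$ and $1/C^2$ are
  available. When fitting data whose residual error is proportional — as
  in this package's simulator, and as typical of chromatographic assays —
  $1/C^2$ is the variance-matched choice and is what the package's own
  recovery benchmarks use; it visibly improves both parameter recovery and
  model discrimination at this design's ten sampling points.
* **Model selection.** Candidates are ranked by AICc computed from the
  (weighted) SSE with $k$ equal to the number of fitted mean parameters,
  the small-sample form appropriate for $n \approx 10$ observations. The
  pre-dose zero is a real observation of the design and is included in
  $n$. Ties in SSE resolve to the simpler model through the penalty.
* **Micro/macro identities.** `derive_microconstants()` implements
  $k_{21} = (A\beta + B\alpha)/(A+B)$, $k_{10} = \alpha\beta/k_{21}$,
  $k_{12} = \alpha+\beta-k_{21}-k_{10}$; parameter sets implying
  $k_{12} < 0$ beyond rounding are rejected as inconsistent. The round trip
  micro → macro → micro is exact to machine precision and is
  property-tested to $10^{-9}$ over 1000 random draws.

## Brand comparison

Relative bioavailability follows
$F_r = 100 \cdot (AUC_T \cdot D_R)/(AUC_R \cdot D_T)$, by default on
$AUC_\infty$. Two aggregation conventions are reported, because published
summary tables are rarely explicit: the ratio of brand-mean AUCs (default)
and the mean of subject-wise ratios formed by index pairing (defined only
for equal group sizes; in a parallel design the pairing is arbitrary, which
is why it is not the default). A test brand is classed *interchangeable*
when its ratio-of-means $F_r \ge 90\%$ — a pragmatic screening criterion,
deliberately weaker than formal average bioequivalence (90% CI of the
log-AUC ratio within 80–125%), which this package does not perform.

Parameters are compared across brands by one-way ANOVA and Tukey's HSD
(studentized-range) test at $\alpha = 0.05$, via `stats::aov()` and
`stats::TukeyHSD()`. The degenerate all-groups-constant case (e.g. every
animal sharing the same $T_{max}$) is handled explicitly in the limit:
$F = 0, p = 1$ when means agree, $p \to 0$ when they differ with zero
within-group variance.

## The study simulator

`rabbit_cipro_truth()` encodes the packaged study conditions: a single
500 mg oral dose in six rabbits per brand, sampled pre-dose and at 0.25,
0.5, 1, 1.5, 2, 4, 8, 12, 24 hr, assay LOQ 0.05 mg/L. The kinetic preset —
$k_a = 3.0$, $V_1/F = 25.5$ L, $k_{10} = 0.35$, $k_{12} = 0.79$,
$k_{21} = 0.82$ (all rates 1/hr) — gives $\alpha = 1.80$, $\beta = 0.159$,
a terminal half-life of 4.3 hr, $T_{max} \approx 0.58$ hr,
$C_{max} \approx 11.3$ mg/L, $Cl/F \approx 8.9$ L/hr and a pronounced
distribution phase (fast-phase intercept share ≈ 0.6), matching the ranges
reported for ciprofloxacin in rabbits and the strongly biphasic disposition
such data show. The 24-hr concentration (≈0.18 mg/L) sits comfortably above
the LOQ, so censoring is rare under the defaults but fully exercised by
raising `loq`.

Variability is log-normal between subjects on $k_a$, $V_1/F$ and $k_{10}$
only (CV 10% by default), keeping $k_{12}/k_{21}$ shared so that
parameter-recovery benchmarks stay well conditioned; residual error is
proportional (CV 5%), applied as $C\,e^\varepsilon$ so values stay
positive. The printed SDs of published summary tables of this design are
on the order of 1% — consistent with standard errors of triplicate assay
replicates, not biological spread — so the 10% between-subject CV is chosen
as the realistic magnitude for small-animal PK rather than transcribed from
a table. Simulation is bit-reproducible for a fixed seed without disturbing
the caller's RNG stream.

What the simulator does *not* emulate: absorption-phase misspecification
(true absorption is exactly first order), correlated parameter variability,
time-varying clearance, enterohepatic recirculation, assay heteroscedasticity
beyond the proportional model, and dropout. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated generative
model, not robustness to every feature of real rabbit data.

## Validation scale and known limitations

The test suite validates each stage at sizes chosen to make the statistical
checks sharp yet quick: brute-force oracles on 3–10-point profiles,
parameter recovery over 20 simulated subjects at 5% residual CV, the
micro/macro round trip over 1000 random parameter sets, and a null
calibration of 200 replicate six-brand studies confirming that the Tukey
family-wise error stays at its nominal 5% and that mean relative
bioavailability is 100% within simulation error.

Limitations worth knowing: the AICc comparison at ten points per subject
has limited power against near-monoexponential kinetics (fast distribution
masked by slow absorption), which is a property of the design, not of the
implementation; $F_r$ conventions differ and the package reports both
rather than adjudicating; and no formal average-bioequivalence interval is
computed. Urinary NCA, steady-state designs, partial AUCs, and population
(mixed-effects) modelling are out of scope.
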