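---
title: "Methods: calibration, validation statistics and NCA in quantpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibration, validation statistics and NCA in quantpk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantpk)
```

`quantpk` covers three layers of a quantitative LC-MS/MS bioanalysis: the
calibration model and its inversion, the regulatory validation statistics,
and non-compartmental pharmacokinetics with dose-normalized oral
bioavailability. This vignette explains the models, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## The calibration model

Over a wide dynamic range (here 3.910–1000 ng/ml, a 256-fold span),
electrospray MRM response is close to, but not exactly, proportional to
concentration: detector saturation and ionization competition bend the
response slightly. The Wagner model captures this with a quadratic in
log-log space,

$$\ln y = a(\ln x)^2 + b\ln x + c,$$

where $x$ is concentration (ng/ml) and $y$ the response — the analyte/IS
peak-area ratio by default (`response_basis = "area_ratio"`), or the raw
analyte area. A pure power law is the special case $a = 0$
(`model_kind = "linear_loglog"`), and an untransformed straight line is
available as `"linear"` for narrow ranges.

Assumptions built into this choice:

* **Multiplicative errors.** Peak-area noise is roughly proportional to the
  signal, so unweighted least squares in $\ln$–$\ln$ space is already
  variance-stabilized. For that reason the default is *unweighted* OLS; the
  familiar $1/x$ and $1/x^2$ weights are available through the `weights`
  argument for laboratories whose SOPs require them.
* **Monotonicity.** The curve must be strictly increasing over
  $[\mathrm{LLOQ}, \mathrm{ULOQ}]$, i.e. $2a\ln x + b > 0$ there. Because
  that derivative is linear in $\ln x$, checking both endpoints suffices.
  A fit violating it is *rejected with an error*, never silently inverted:
  a non-monotone calibration has no unambiguous back-calculation.

### Inversion (back-calculation)

Given a response $y$, back-calculation solves
$a u^2 + b u + (c - \ln y) = 0$ for $u = \ln x$. A quadratic has two roots;
the root on the increasing branch ($2au + b > 0$) is always
$u = (-b + \sqrt{b^2 - 4a(c - \ln y)})/(2a)$, regardless of the sign of
$a$, and it is unique for any accepted fit. Numerical choices:

* When $|a| < 10^{-12}$ (`a_tol`) the quadratic formula suffers
  catastrophic cancellation, so the linear log-log solution
  $u = (\ln y - c)/b$ is used instead. The threshold sits far below any
  curvature a real assay produces and keeps the $a \to 0$ limit continuous
  (the test suite checks the two paths agree).
* A negative discriminant means the response lies above the curve's
  attainable maximum (possible when $a < 0$); that is an error — the
  response is unreachable, not censorable.
* Back-calculated concentrations outside $[\mathrm{LLOQ}, \mathrm{ULOQ}]$
  are *flagged*, not rejected (`quality = TRUE` returns the flag). Dilution
  QCs legitimately read above the ULOQ before the `dilution_factor`
  (applied after inversion, on the measured value) corrects them.
* The fit's $r^2$ is the coefficient of determination *in the fitting
  (log-log) space*, since that is where least squares ran. Whether a
  published curve $r^2$ was computed in transformed or raw space is usually
  unstated; the transformed-space definition is the one consistent with the
  estimator, so it is the one reported.

## Validation statistics

All accuracy/precision summaries reduce to `level_stats()`: mean, %Nom
$= 100\,\bar{x}/\text{nominal}$, %CV $= 100\,s/\bar{x}$ with the $n-1$
denominator (the convention of bioanalytical reports; exposed, not
hard-coded, for audit), and %Bias $=$ %Nom $- 100$. Identities the suite
enforces as properties: %Nom − %Bias = 100 always; every statistic is
permutation-invariant; recovery, IS-MF, stability ratios and %CV are
invariant to rescaling all areas by a common factor; and every pass/fail
flag can be reproduced by re-evaluating its stated inequality on the
reported numbers — no hidden state.

Acceptance limits default to the FDA/EMA convention: ±15% (bias and CV)
with ±20% at the LLOQ, 15% on matrix-factor variability, ±15% for stability
and cross-matrix accuracy. All of them live in `run_config()`, never in
code. Two judgement calls deserve note:

* **Batch acceptance** rules (e.g. 4-6-15) vary between laboratories; the
  pooled per-level flag reported here is deliberately simple (|%Bias| and
  %CV within the limit) and is a *flag*, not a gate.
* **Cross-matrix validation** reports a per-level breach (|%Bias| > 15%)
  without raising an error, because guidance explicitly allows wider limits
  "if justified" — the judgement belongs to the analyst. The overall `pass`
  flag still turns false so the breach cannot pass unnoticed.
* **Stock-solution stability** compares raw peak areas of stored versus
  freshly prepared stocks (after their stated dilution), not
  concentrations — stocks are solvent solutions with no calibration matrix.

## Non-compartmental analysis

Internal units are minutes, µmol/l and µmol/kg (`µmol/l = (ng/ml)/MW`,
`µmol/kg = 1000·(mg/kg)/MW`); reported units follow PK convention (Cmax in
µM, Tmax and t½ in hours, AUC in min·µmol/l, CL in ml/min/kg, volumes in
l/kg).

**Terminal slope.** `fit_lambda_z()` regresses $\ln C$ on $t$ over a
terminal window. In automatic mode every window of ≥ 3 positive points
starting strictly after Tmax and ending at the last positive observation is
fitted, the adjusted $r^2$ is maximized, and ties (within $10^{-10}$) go to
the *longer* window — on noise-free exponential data every window is
perfect, and the longest uses the most information. An explicit time window
can be forced when matching a historical analysis.

**BLQ rules.** Values below the LLOQ before Tmax are kept as 0 (the drug
genuinely is not there yet); BLQ values after Tmax — embedded or trailing —
are excluded, so censored tails can never flatten the slope. NCA results
are therefore invariant to appending BLQ samples after the last positive
observation (tested as a property).

**AUC.** Linear trapezoid is the default; `linear_up_log_down` integrates
declining segments under a local mono-exponential assumption, which is
exact on exponential decay. On a sparse late schedule (the 8-point design
used here, with a 12 h gap before the last sample) the linear rule
overestimates the tail of a steep decay by several percent, while the
log-down rule is exact — so the parameter-recovery tests at the sparse
schedule use `linear_up_log_down`, and dense-grid tests show the linear
rule converging. For real, noisy data the linear rule remains the
conservative default.

**IV back-extrapolation.** An IV bolus profile whose first sample is drawn
after $t = 0$ misses the initial area; standard practice is to
back-extrapolate $C(0)$ log-linearly from the first two positive points and
include $(0, C_0)$ in the integration (`iv_c0 = TRUE`). Without it, a
5-minute first sample on a 2–3 h half-life drug biases CL upward by ~2.5%.
Oral profiles instead get the point $(0, 0)$ — nothing has been absorbed at
the instant of dosing.

**Extrapolation and disposition.**
$AUC_\infty = AUC_\mathrm{last} + C_\mathrm{last}/\lambda_z$,
$AUMC_\infty = AUMC_\mathrm{last} + C_\mathrm{last}t_\mathrm{last}/\lambda_z
+ C_\mathrm{last}/\lambda_z^2$, MRT $= AUMC_\infty/AUC_\infty$. For IV arms
CL $=$ dose$/AUC_\infty$, $V_z = CL/\lambda_z$, $V_{ss} = CL\cdot$MRT. For
oral arms these are returned as `NA` with a reason code rather than the
misleading CL/F. The "Vd" printed in PK summary tables is interpreted as
$V_z$; the identity $V_z = CL \cdot t_{1/2}/\ln 2$ holds exactly under that
reading and is verified by the acceptance tests. Oral half-lives are
reported from the oral profile's own λz, which under slow absorption may
reflect absorption rather than elimination (flip-flop kinetics) — reported
as-is, documented, not "corrected".

**Bioavailability.** $F = 100\,(AUC_{po}/D_{po})/(AUC_{iv}/D_{iv})$,
computed from the dose-matched arm pairs (high with high, low with low) on
the *mean-profile* NCA, matching how group-mean PK tables are built. The
ratio is invariant under any consistent change of AUC or dose units applied
to both routes (tested).

## The synthetic-data generator

The generator exists so that every estimator can be tested against a known
truth without instrument data.

* `make_batch()` draws the standard validation batch — nine standards
  (3.910–1000 ng/ml) in duplicate, seven QC levels (3.909–800.0 ng/ml) in
  six-fold, a 1600 ng/ml dilution QC, six blanks, two double blanks, three
  SPVS — with analyte areas
  `recovery × lot effect × exp(a(ln x)² + b ln x + c) × lognormal noise`.
  Default noise (5% analyte, 3% IS) sits in the middle of the precision
  range a validated method typically shows (single digits, larger at the
  LLOQ); the default generating curve gives areas of realistic MRM
  magnitude (≈10⁴ at 10 ng/ml). One correlated lot-effect pair is drawn per
  batch, so a single batch is internally consistent and the zero-noise
  closure (back-calculated = nominal, exactly) holds regardless of the lot
  draw.
* `make_matrix_effect_set()` draws per-lot lognormal suppression factors
  for analyte and IS with configurable correlation (default 0.8).
  IS-normalization cancels only the correlated part — with correlation 1
  the IS-MF is identically 1 however strong the suppression, which is the
  cancellation property the IS is chosen for, and what makes the test
  non-trivial.
* `simulate_profile()`/`simulate_study()` use one-compartment closed forms:
  IV bolus $C(t) = (D/V)e^{-k_e t}$, first-order oral
  $C(t) = \frac{F D k_a}{V(k_a - k_e)}(e^{-k_e t} - e^{-k_a t})$, with
  multiplicative lognormal residuals and censoring below the LLOQ. Default
  truths ($k_e$ ≈ 0.004/min, $V$ ≈ 9 l/kg, $F$ ≈ 0.25, MW ≈ 505 g/mol,
  doses 40/20 mg/kg PO and 5/2.5 mg/kg IV, n = 5, 15% residual CV) are
  chosen as plausible magnitudes for a moderately cleared, highly
  distributed small molecule in mice — they are simulation settings, not
  claims about any real compound. Sampling schedules mimic the snapshot-PK
  design: first sample 5 min (IV) or 10 min (PO), then 0.5–24 h; no t = 0
  sample is drawn.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: chromatographic integration errors,
retention-time drift and carry-over; heteroscedasticity beyond the
lognormal model (real LLOQ-level noise is often worse than proportional);
between-animal parameter variability (residual noise is the only
stochastic term in the PK arms); multi-compartment disposition, transit
absorption, enterohepatic recirculation; and blood-to-plasma partitioning.

All generators restore the caller's RNG state and are byte-deterministic
under a fixed seed; identical seeds give identical data sets.

## Test design and problem sizes

Expected values in the tests come from three sources: hand-derivable cases
(rectangle AUCs, identity curves, constant vectors), independent oracles
computed alongside the test (normal equations solved directly for $r^2$,
bisection inversion of the forward curve, exhaustive window search for λz,
concatenate-and-recompute pooling, closed-form integrals), and published
summary statistics recomputed from their printed inputs. Monte-Carlo checks
run at desk scale: the noisy-study envelope was pre-computed from 400
simulated studies at the generating conditions (F = 30%, 15% CV, n = 5) and
frozen as the 0.1–99.9% quantile band widened outward to the next half
percent; the %CV concentration check uses one 800-replicate level. Dense
grids use 1-minute (IV recovery) to 2-minute (study closure) steps out to
2880 min. The full suite runs in well under a minute on one CPU.

## Known limitations

* The calibration module fits one curve per batch; pooled-across-batch
  fitting and weighting schemes beyond $1/x$, $1/x^2$ are out of scope.
* No 4PL/5PL response models, carry-over quantification beyond
  blank-response flagging, or incurred-sample reanalysis.
* NCA covers bolus IV and first-order oral arms; no infusions, no
  compartmental fitting, no population methods.
* The command-line wrapper is a thin convenience over the package
  functions; the functions themselves (and `run_validation()`/`run_nca()`)
  are the supported interface.
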