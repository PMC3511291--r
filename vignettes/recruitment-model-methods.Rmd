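---
title: "Methods: the minimal recruitment model, its simulator, and the fitting pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the minimal recruitment model, its simulator, and the fitting pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungrecruit)
```

## The model

The package analyses step-wise PEEP recruitment manoeuvres with a minimal
recruitment model. The lung is treated as a large collection of units that
are either open or collapsed. A collapsed unit opens when airway pressure
exceeds its threshold opening pressure (TOP) and then contributes a fixed
unit volume; an open unit collapses again when pressure falls below its
threshold closing pressure (TCP). Across units the thresholds are taken to
be normally distributed, so the recruited volume at pressure $P$ is

$$V(P) = \tfrac12\left(1 + \operatorname{erf}\frac{P - \mu}{\sqrt{2}\,\sigma}\right)\cdot TLC,$$

the normal CDF of the threshold distribution scaled by the recruitable
capacity $TLC$. Three parameters per curve: $\mu$ (the pressure of the
maximum rate of recruitment or derecruitment), $\sigma$ (the spread of the
threshold distribution, read as lung heterogeneity), and $TLC$ (the
asymptotic recruitable volume). Inflation limbs estimate the TOP
distribution, deflation limbs the TCP distribution. The model is evaluated
through the `pnorm`/`qnorm`/`dnorm` identities
($\tfrac12(1+\operatorname{erf}(z/\sqrt2)) = \Phi(z)$), so forward
evaluation, inversion and the threshold density are exact and mutually
consistent.

The model deliberately omits alveolar over-distension, gas exchange, and
gravitationally superimposed pressure; it is a monitoring model for the
recruitment state, not a full mechanics model.

## What the simulator emulates

`simulate_rm()` generates synthetic ventilator waveforms from an explicit
unit population so every downstream stage can be tested against known
truth. It emulates:

- **volume control**: each inspiration delivers $V_t$ = weight $\times$
  12 ml/kg at constant (square) flow; the inspiratory flow profile and
  I:E ratio (1:2) are conventions, not facts of the reference protocol,
  which does not state them;
- **the step-wise manoeuvre**: PEEP 5, 10, 15, 20 cmH2O, 12 breaths per
  level (within the protocol's 10-15), 15 breaths/min, 50 Hz sampling;
- **hysteretic recruitment**: at each sample the alveolar pressure is the
  smallest pressure at which the unit population holds the delivered
  volume; units keep their open/closed state between samples. Airway
  pressure adds a resistive component $R\cdot\dot V$ ($R$ = 0.02
  cmH2O·s/ml);
- **passive expiration**: single-exponential flow decay toward the volume
  held by units whose TCP is below the current PEEP, cut off when flow
  falls under 1% of its peak. The time constant is $R$ times a compliance
  proxy ($V_t$ over driving pressure), floored at 0.3 s so the deflation
  transition is resolved at 50 Hz — without the floor the pure
  recruitment mechanics empty in a few samples, which no real expiratory
  circuit does;
- **trapped volume**: after a PEEP increase, units with TCP between the
  old and new PEEP stay open at end-expiration, so the end-expiratory
  volume rises. The ground-truth gain per step is recorded on the
  returned object for test use;
- **measurement noise**: multiplicative Gaussian noise (2% relative SD by
  default) on the pressure and flow channels; the volume channel is the
  trapezoidal integral of the recorded flow, as a ventilator would
  compute it;
- **auto-PEEP** as an optional additive end-expiratory pressure offset.

It does not emulate viscoelastic tissue behaviour (the hysteretic state
machine needs about two breaths to settle, which is what the
representative-breath convention relies on), spontaneous effort,
superimposed pressure layers, or any gas-exchange physiology. Passing
tests on this generator therefore demonstrates the pipeline's
correctness on data that satisfy the model's own assumptions; they do not
demonstrate that real lungs satisfy them.

### Scenario calibration

The shipped scenarios fix the study conditions once: a 24-kg subject
(median body mass of the reference cohort), healthy TOP $\sim N(42, 19)$
cmH2O (the scale of baseline-PEEP fits in healthy lungs), and an injured
("ARDS") variant with TOP $\sim N(57, 24)$ — a +15 cmH2O shift and
+5 cmH2O widening, i.e. more collapse and more heterogeneity.

Two generator parameters are not stated anywhere and were set by
feasibility and identifiability arguments rather than taken from tables:

- **TCP $\sim N(18, 12)$ cmH2O.** Under fixed-unit-volume mechanics the
  volume exhaled each breath is exactly the volume of units that close,
  so ventilation at PEEP 20 is only sustainable if a tidal volume's worth
  of open units has TCP above 20; at the same time the stacked PV curves
  of a recruitment manoeuvre show trapped volume at *every* PEEP
  increment, which requires closing mass inside every 5-cmH2O step. A
  wide TCP distribution satisfies both. Note the per-PEEP *fitted* TCP
  values of a deflation limb are truncation-shaped estimates (they track
  PEEP), not the generating distribution, so these generator values are
  not comparable 1:1 with fitted tables.
- **Recruitable capacity 1000 ml** ($10^5$ units × 0.010 ml, 42 ml/kg).
  The manoeuvre's plateau pressures must span the TOP mean for the
  per-PEEP fits to be identifiable; much larger capacities leave every
  window on the lower tail of the recruitment curve, where the
  three-parameter fit is a ridge. The stable fits of real manoeuvres
  imply windows that explore the curve.

Seeds are explicit everywhere: the population and the noise stream use
separate seeds derived from one argument, and identical seeds give
bit-identical records.

## Waveform processing

`segment_breaths()` delimits breaths at inspiratory flow onsets (rising
through 5% of peak absolute flow, re-armed below 1%, so noise cannot
re-trigger). Integration windows start one sample before each onset so
that consecutive windows tile the record exactly; inspired and expired
volumes are trapezoidal integrals of the positive and negative flow.

The **representative breath** at each PEEP level is the pointwise mean of
the last two breaths after resampling both limbs to 200 phase points
(robust to noise; `"last"` takes the final breath instead). Two breaths
suffice because the simulator — like a stabilised lung — is periodic by
then.

The **trapped volume** of a PEEP increment is the summed inspired-minus-
expired volume over the breaths of the incoming level; at steady state the
per-breath terms telescope to the full end-expiratory gain, so the window
choice is uncritical. Small negative estimates are clamped to zero with a
warning, since end-expiratory volume cannot fall at a PEEP increase under
this protocol.

**Volume-axis referencing.** Curves stack by offsetting each level's
volume axis with the running sum of preceding trapped volumes. The
simulator starts from the relaxed, fully collapsed state, so by default
the net gain of the first level (the baseline wash-in) is included as the
`0->PEEP1` increment and the stacked curves sit on the absolute recruited
volume; on records that begin at a ventilatory steady state this term is
near zero and the familiar "first level has offset zero" convention is
recovered (`include_washin = FALSE` enforces it exactly). With hysteretic
retention the higher-PEEP curves exceed the static recruitment curve by
precisely the retained open volume — that surplus is not an artefact, it
is the mechanism by which the fitted mean TOP falls as PEEP rises.

An optional quasi-static correction removes the resistive pressure
component ($p_{aw} - R\dot V$) when a resistance estimate is configured.
The default fits raw recorded pressure; the scenario analyses enable the
correction with the known simulated resistance because at simulated peak
expiratory flows the resistive term otherwise dominates the deflation
limb.

## Fitting

`fit_limb()` estimates $(\mu, \sigma, TLC)$ by bounded
Levenberg-Marquardt least squares (tolerances $10^{-10}$ on the cost and
$10^{-8}$ on parameters), with $\sigma > 0$ and $TLC \ge \max v_i$.
Initialisation: $\mu$ at the pressure of the steepest finite-difference
slope, $\sigma$ = span/4, $TLC = 1.05\max v_i$. A deterministic
multi-start grid (means up to two spans above the window, a range of
spreads, capacity chosen so the model passes through the top of the
curve) guards against local minima on tail-only windows; the lowest-cost
solution is returned, so results are bit-reproducible — there is no
stochastic restart.

**Objective.** The default minimises *relative* residuals (weights
$1/\max(v_i, 0.01\max v)$): the measurement model is multiplicative
noise, so residual spread scales with volume and relative weighting is
the matching least-squares criterion. It also keeps the low-volume tail,
which carries most of the information about the distribution location,
from being ignored. `weighting = "none"` gives plain least squares; the
two coincide on noise-free data. With plain least squares the relative
error of the fitted tail is essentially unconstrained, which inflates the
percentage fitting error even when the parameters are accurate.

**Identifiability.** Curves whose pressure span is below one fitted
$\sigma$ are flagged `poorly_identified` but retained, mirroring how
badly-windowed baseline-PEEP fits are reported rather than discarded.
`fit_manoeuvre(tlc_max = "auto")` additionally caps the fitted capacity
at 1.2 times the largest volume observed anywhere in the manoeuvre: a
capacity far beyond anything the data demonstrate is unsupported, and
without the cap tail-only windows drift up a $(\mu,\sigma,TLC)$ ridge.
$TLC$ remains a free parameter per limb and PEEP — the only
self-contained choice, since no independent capacity measurement (e.g.
nitrogen-washout FRC) is available in this setting; there is no joint
fitting across PEEP levels.

Fit quality is reported as the mean absolute percentage error (MAPE),
$\frac{100}{n}\sum |V_{model}(p_i) - v_i|/v_i$, excluding points below 1%
of the curve's maximum volume to avoid division blow-up. The per-point
denominator is the literal reading of "percentage error"; normalising by
the tidal span instead is a coarser but more tolerant alternative that
this package does not use.

## Reporting and disease-state grouping

`summarize_fits()` reports median, nearest-rank quartiles (for $n=9$ the
3rd and 7th order statistics — the convention that reproduces the bundled
reference summaries from their per-subject values) and the arithmetic
mean; rounding to one decimal happens only at render time. Four cells of
the bundled healthy reference table recompute 0.1 away from their
originally reported summaries because the per-subject source values are
themselves rounded to one decimal; these are documented and asserted at
their recomputed values.

`wilcoxon_rank_sum()` is a two-sided rank-sum test with mid-ranks for
ties, exact by enumeration of all $\binom{N}{n_x}$ assignments for pooled
sizes up to 12, and a tie-corrected, continuity-corrected normal
approximation beyond. It is written here because an exact p-value in the
presence of ties requires the enumeration route; the standard
implementation serves as the cross-check oracle in the tests.

DSG places a subject on the (mean TOP, SD) plane at the baseline-PEEP
inflation fit — which PEEP level feeds the plane is not standardised, and
baseline is the level at which subjects are compared before and after
injury. Panels: B = low SD & low TOP (healthiest), A = high SD & low
TOP, D = low SD & high TOP, C = high SD & high TOP. Panel thresholds are
mandatory configuration with no claimed defaults (they are patient- and
population-specific); ties go to the lower category with a note.
Trajectories are labelled `improving`/`worsening`/`mixed`/`unchanged`
from the signs of the consecutive changes in mean TOP and SD.

## Numerical choices and degenerate inputs

- Unit-state bookkeeping is driven by the trapezoidally integrated flow
  channel, so the recorded waveforms, the committed unit states, and the
  ground-truth trapped volumes are mutually consistent to within one unit
  volume per breath.
- A population whose TOP (and therefore TCP) lies entirely below the
  lowest PEEP cannot be ventilated under these mechanics — everything is
  open, nothing can close, so expiration is impossible; the simulator
  raises an infeasible-ventilation error rather than fabricating a
  steady state. Likewise a tidal volume at or above total capacity is
  rejected up front.
- Curve construction collapses duplicate pressures by averaging and
  clamps end-expiratory samples a few ml below the breath-onset
  reference to the curve floor.
- Fits on curves with fewer than 3 points, or with constant volume
  ($\sigma$ unbounded), are rejected with specific errors;
  `fit_manoeuvre()` converts per-curve failures into annotated rows and
  continues.

## Problem sizes

The test suite runs the full pipeline on $10^5$-unit populations for the
acceptance-level checks and $2\times10^4$-unit populations elsewhere;
Monte-Carlo oracle checks use $10^6$ draws; parameter recovery uses 20
seeded truths with 50-point curves. The whole suite completes in well
under a minute on a single core.

## Known limitations

- The generator satisfies the model's assumptions by construction;
  agreement between fitted and generating parameters on synthetic data
  says nothing about viscoelastic, elastic-distension or superimposed-
  pressure effects in real lungs.
- Fitted deflation parameters are strongly shaped by truncation at PEEP;
  they should be read as per-PEEP effective quantities.
- Baseline-PEEP inflation fits ride on an unmeasurable pre-manoeuvre
  volume and are the least reliable — consistent with the largest
  reported fitting errors occurring at the lowest PEEP and with the
  auto-PEEP distortion discussed for low-PEEP fits.
- The deflation limb fitted here is the within-breath expiratory limb;
  fitting the post-manoeuvre step-wise PEEP decrease is a documented
  alternative left as future work.
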