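---
title: "Error-field training: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-field training: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(errorfields)
```

This vignette is the package's own account of the science it implements: the
models, their assumptions, every tunable parameter that matters, and the
design decisions that were genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The task and its reference

The simulated task is planar goal-directed reaching under an *angle-angle*
visuomotor transformation: the cursor displays shoulder rotation against
elbow flexion rather than hand position, so the mover must re-learn the map
from motor commands to cursor motion. The ideal movement is a straight-line
reach between targets 15 cm apart on the display, traversed with the
minimum-jerk profile

$$x_{MJ}(t) = x_0 + (x_T - x_0)\left(10 s^3 - 15 s^4 + 6 s^5\right),
\qquad s = t / t_d,$$

with ideal duration $t_d = 1.5$ s. Beyond $t_d$ the reference is clamped at
the target — the quintic is never extrapolated, which would otherwise blow up
cubically. Cursor error $\varepsilon(t)$ is the measured position minus this
reference, resolved into an *extent* component (along the start-to-target
unit vector, positive toward or past the target) and a *perpendicular*
component (positive on the counter-clockwise side). The sign convention is a
package choice, pinned so tests can assert on it; the decomposition is an
isometry regardless.

The angle-to-screen calibration is a per-axis affine map (default 10 cm per
radian, zero offset). Its scale is a free parameter of the task display; all
errors, statistics and torques live in the screen (cm) plane, so nothing
downstream depends on the calibration beyond it being invertible.

## The Gaussian error field

A subject's error statistics are characterized from the transformed trials of
the intermittent-exposure phase, separately for each of the three movement
directions and each error component:

1. samples are assigned to a common grid of 50 uniform time bins over
   $[0, t_d]$ by nearest sample time per trial;
2. the across-trial mean and standard deviation are computed at each bin;
3. degree-7 polynomials are least-squares fitted to the mean and SD curves.

The likelihood of an error $\varepsilon$ at time $t$ is then the scalar
Gaussian density per component,

$$p(\varepsilon) = \frac{1}{\sigma_{d,t,i}\sqrt{2\pi}}
  \exp\!\left(-\frac{(\varepsilon - \mu_{d,t,i})^2}{2\sigma_{d,t,i}^2}\right).$$

Numerical choices:

* **Time is rescaled to $[0,1]$ before fitting.** A raw degree-7 monomial
  basis on $t \in [0, 1.5]$ seconds is ill-conditioned; rescaling keeps the
  normal-equations condition number manageable. Coefficients are stored
  against the rescaled time.
* **50 bins** comfortably over-determine an 8-coefficient fit while keeping
  the nearest-sample assignment cheap.
* **SD floor, default 0.05 cm.** The density divides by $\sigma$; fitted SD
  polynomials are left unconstrained (they may dip negative between bins) and
  the floor is applied at evaluation. Without it a near-deterministic error
  component would produce unbounded densities that only the torque cap could
  absorb.
* Evaluation outside $[0, t_d]$ clamps $t$ to the domain.

At least two trials per direction are required; fewer is an error naming the
direction, because an SD cannot be formed.

## Controllers, λ calibration, and the safety envelope

Three controller modes share one safety envelope:

| mode | torque per component | meaning |
|------|----------------------|---------|
| `ef` | $\tau_i = \lambda\, p(\varepsilon_i)\, \varepsilon_i$ | error field: likely errors amplified |
| `ea` | $\tau_i = \lambda\, \varepsilon_i$ | classic error augmentation |
| `null` | $0$ | control |

Torque is emitted only during the first 1.5 s of movement (so the mover can
still settle on the target), and the torque *vector magnitude* is capped at
15 Nm with direction preserved — the cap is read as a safety limit on total
torque, not per component.

The scale factor λ is calibrated per subject and mode: per-trial peak torques
are estimated on the characterization trials at $\lambda = 1$ without the
cap, and λ is set to $15 / Q_{0.8}$, the level divided by the 80th percentile
of those peaks (linear interpolation between order statistics, R's default
quantile). This is the reading of "80% of estimated peak torques reach
15 Nm" that yields a single λ: after calibration exactly 80% of estimated
peaks lie at or below the cap, so roughly the largest fifth of trials would
saturate it. λ is pooled across directions (one value per subject) and held
constant through training. Calibration is homogeneous of degree −1 in the
error scale, which the tests exercise directly.

## The synthetic learner

The package needs a closed loop that can be run and tested without human
data, so it ships a minimal trial-by-trial adaptation model — the standard
linear state-space form used throughout the motor-adaptation literature,
chosen because it is the simplest learner that produces the exponential
error decay the analysis machinery fits.

The learner holds an internal affine compensation $(L, l)$ for the
visuomotor distortion (default distortion: a 25° rotation in the angle-angle
plane). On a transformed trial it aims at
$(I + L)\,r(t) + l$ for reference point $r(t)$ (relative to the reach
start), the distortion maps the aim to the cursor, correlated motor noise is
added, and — when forces are on — the controller torque computed from the
*current* experienced error displaces the cursor through a scalar admittance
(cm/Nm), acting with a one-sample delay (the causal discrete-time loop).
After each transformed trial,

$$L \leftarrow \rho L - \eta\, \frac{\sum_t e(t)\, r(t)^\top}{\sum_t \lVert r(t)\rVert^2},
\qquad l \leftarrow \rho l - \eta\, \bar e,$$

with retention $\rho$ and learning rate $\eta$. The update uses only the
recorded cursor and reference — never the true transformation — so each trial
informs the map only along its own movement direction, and cycling the three
directions (0°, 120°, 240° headings) identifies the full map. Torque enters
learning exactly one way: by changing the experienced error. That is the
simplest mechanism by which haptic augmentation can alter adaptation.

Assumptions and deliberate simplifications:

* adaptation happens only on transformed trials (the veridical baseline
  context is treated as already learned; washout dynamics are out of scope);
* no muscle-level or impedance/co-contraction modelling — the visuomotor
  task is a remapping task in which stiffening cannot help;
* motor noise is a smoothed (moving-average) Gaussian process per component,
  emulating within-trial correlated noise rather than white sample noise;
* movement duration is simulated as $t_d$ plus Gaussian jitter (SD 0.08 s)
  and graded against a ±0.15 s "proper timing" band — the feedback bands are
  a package choice, configurable, since only their existence is documented
  for the original task.

**Stability.** The admittance feedback loop has gain roughly
$\lambda \times \text{admittance}$ (times the density for EF); with the
default priors (admittance 0.05–0.15 cm/Nm, calibrated λ of a few Nm/cm) it
is well below 1. A diverging configuration (error past $10^3$ cm) raises an
error naming the cause rather than returning garbage.

## Protocol and cohort defaults

The three-phase protocol runs 30 baseline trials, 50 intermittent-exposure
trials, and 70 training trials. The intermittent transformation dose is
exact — `round(n × 1/5)` trials — and is stratified as evenly as possible
across the three directions so that characterization always has at least two
trials per direction; only the overall one-in-five rate is a protocol datum,
the stratification is a package guarantee. Cohorts default to 7 subjects per
group in three groups (EF, EA, control), drawing per-subject learning rate
(0.10–0.25), retention (0.98–0.999), motor noise SD (0.3–0.8 cm), admittance
(0.05–0.15 cm/Nm) and a small random initial map from uniform priors — a
plausible healthy-adult spread producing heterogeneous but universally
learnable subjects. All randomness flows from a single seed per run;
cohort-level seeds derive from one base seed, so every dataset is exactly
reproducible.

## Learning-curve analysis

The per-trial outcome is the time-averaged error magnitude over the
movement. The learning curve is fitted as $S + R\,e^{-t/\tau}$ with $S, R
\ge 0$ by non-negative least squares: τ is searched on a 200-point
log-spaced grid over $[0.5, 500]$ trials; at each τ the 2-parameter
non-negative solve is exact (KKT candidate enumeration); the best grid point
is then locally refined with a bounded 1-D optimization. The explicit
bounded grid makes the known failure mode of exponential fits — absurdly
slow time constants on flat, noisy series — inspectable: a series with no
decaying structure comes back with $R = 0$ and τ pinned at the grid edge
rather than a spurious interior optimum. The refinement only ever lowers the
residual, so the grid-only result remains a valid lower bound for
brute-force comparisons.

Cross-validation mirrors the study design: one fit pooling all subjects in a
group plus one leave-one-subject-out fit per subject ($n + 1$ fits for $n$
subjects); each fit is repeated 50 times on random 80% subsets and scored by
NRMSE on the held-out 20%, keeping the best repeat. NRMSE is defined here as
test RMSE divided by the range of the training series — the most common
normalization, pinned because the name alone does not determine one.

Secondary measures: *change in error* (mean of the first five training-trial
errors minus the mean of the last five — invariant to everything between);
the *distribution shift* $\Delta\varepsilon$, the per-time-bin late-minus-
early mean error normalized by the early-training SD and averaged in
magnitude over the movement, with early/late defined as the first/last 10
training trials (a package choice, configurable); and the group pipeline
Shapiro-Wilk → Kruskal-Wallis → Dunn's rank test with Šidák correction.
Dunn's z uses the standard tie-corrected pooled-rank formula; for two groups
it squares to the Kruskal-Wallis statistic, which the tests verify.

## What passing tests do and do not show

The synthetic cohort exhibits: direction-dependent systematic errors,
between-subject heterogeneity, exponential-looking error decay in every
group, torque envelopes respected end-to-end, and exact reproducibility from
seeds. It does **not** emulate: non-Gaussian or multimodal error
distributions, impedance control, fatigue or attention effects, or any
mechanism that makes likelihood-weighted augmentation *differentially* more
effective than plain augmentation — in this learner both act only through
the magnitude of experienced error. Passing tests therefore validate the
machinery (characterization, calibration, control, fitting, statistics), not
the clinical claim that EF training outperforms EA or control in humans;
group-level orderings observed in simulation should not be read as evidence
about real subjects.

Problem sizes used by the test suite and acceptance script — 70-trial
training phases, 7 subjects per group, ten cohort seeds for the closed-loop
checks, a 100-trial calibration set, $10^5$-sample torque stress sweeps —
are the package's chosen desk-scale study conditions; statistics at this
scale are for verifying the pipeline, not for estimating effect sizes.

## Known limitations

* The error model is symmetric and unimodal by construction; errors that are
  systematically skewed within a direction are summarized by a Gaussian.
* Characterization happens once, before training; the field is not
  re-estimated as errors shrink, so late-training errors live in the tails
  of a stale field (EF torques fade accordingly).
* Torques live in the extent/perpendicular plane of the display; mapping to
  physical joint torques through the manipulator Jacobian is out of scope.
* The external-data loader is layout-driven: it makes no assumption about
  any particular deposit's column structure and requires a descriptor.
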