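---
title: "From OSN transduction to run-to-turn decisions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From OSN transduction to run-to-turn decisions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvataxis)
```

This vignette documents the scientific models implemented in `larvataxis`,
the assumptions behind them, the synthetic-data generators that stand in
for experimental recordings, and the numerical choices that a user fitting
or simulating these models should know about.

## The transduction model

A *Drosophila* larva with a single functional Or42a olfactory sensory
neuron (OSN) performs robust chemotaxis, which makes that one neuron's
input–output function the natural unit of analysis. The package models the
transduction cascade phenomenologically with three variables: the stimulus
intensity $x$ (odor concentration in µM, or light intensity in W/m²
driving ChR2 as an odor surrogate), an intermediate variable $u$
(plausibly calcium-bound calmodulin; its units are undefined, see
*Identifiability*), and the firing rate $y$ in Hz:

$$
\frac{du}{dt} = \alpha_1 x + \alpha_3 y - \alpha_2 u, \qquad
\frac{dy}{dt} = \frac{\beta_1 x}{\beta_2 + x + \beta_3 u}
  - \beta_4\frac{y^n}{y^n + \theta^n} - \beta_5 y .
$$

The $\alpha_1 x$ production term makes $u$ an *incoherent feed-forward*
(IFF) branch: the stimulus excites $y$ directly through the saturating
drive and inhibits it with a delay through $u$ in the denominator. The
$\alpha_3 y$ term is *integral feedback* (IFB): the output builds up its
own inhibitor. `transduction_params()` exposes three fitted presets —
light-driven pure IFF, odor-driven pure IFF, and the odor-driven composite
IFF+IFB — and the `variant` field drops the unused branch. The decay of
$y$ combines a first-order term $\beta_5 y$ and a constitutive offset
$\beta_4$ gated by a steep Hill function (exponent $n = 2$, threshold
$\theta$) so that the offset disappears at very low rates and the origin
remains a fixed point. Membrane potential is deliberately not modelled;
excitation and inhibition act directly on the rate.

Two slow corrections, both applied by default and both bypassable with
`corrections_enabled = FALSE`, reconcile short-ramp and long-recording
behavior: $\beta_4$ grows by 2.3% with half-effect at 30 s,
$\beta_4(t) = (1 + 0.023\,t^4/(t^4+30^4))\beta_4$, and the Hill threshold
relaxes as $\theta' = \theta\,(30/t)^2$ for $t > 30$ s. We implement the
$\beta_4$ correction as a *small* multiplicative drift anchored at
$\beta_4$ for $t \to 0$: this is the only reading under which the offset
term is active during ramps, which the closed-form analysis below (and its
excellent agreement with the full ODE) requires.

### Integration

`integrate_transduction()` offers two integrators. The reference is
`deSolve`'s `lsoda` (rtol $10^{-6}$, atol $10^{-8}$) with the stimulus
interpolated linearly between samples. For parameter fitting and
closed-loop simulation a fixed-grid classical Runge–Kutta scheme steps
once per stimulus sample; because the Hill gate makes the $y$-equation
locally stiff near $y \approx \theta$ (Jacobian up to
$0.65\,\beta_4/\theta \approx 2600\ \mathrm{s^{-1}}$ for the light
parameters), the scheme substeps adaptively from a local stiffness
estimate, capped at 60 substeps per frame. The two integrators agree to
better than $10^{-2}$ Hz on the ramp suite (tested), and the solutions
preserve nonnegativity of $u$ and $y$.

Initial conditions default to the fixed point at the stimulus baseline
(recordings and simulations begin under sustained baseline stimulation);
`init = "zero"` reproduces the assumption used in deriving the
quasi-steady-state solution. `steady_state()` solves the fixed point with
the slow corrections evaluated at a fixed reference time (default 24 s,
the end of the dose–response measurement window) because the $\beta_4$
drift never plateaus exactly.

## The quasi-steady-state solution and transient normalization

For the pure IFF motif, $u$ ($\tau \approx 1/\alpha_2 \approx 1$ s) and
$y$ ($\tau \approx 1/\beta_5 \approx 0.1$ s) are fast relative to the
ramps ($\tau_x \approx 10$ s; `stimulus_timescale()` computes this
diagnostic). Setting $dy/dt \approx 0$ and linearizing the Hill gate to 1
gives

$$
y_\mathrm{QSSA}(t)
 = \delta_1\,\frac{x}{\delta_2 + x - \delta_3 S(x,t)} - \delta_4,
\qquad
S(x,t) = \int_0^t e^{-\alpha_2 (t-t')}\,\frac{dx}{dt'}\,dt',
$$

with $\delta_1 = \beta_1\alpha_2 / (\beta_5(\alpha_2+\alpha_1\beta_3))$,
$\delta_2 = \beta_2\alpha_2/(\alpha_2+\alpha_1\beta_3)$,
$\delta_3 = \alpha_1\beta_3/(\alpha_2+\alpha_1\beta_3) < 1$ and
$\delta_4 = \beta_4/\beta_5$. The denominator is a hyperbolic
dose–response whose half-saturation point is *transiently renormalized* by
an exponentially weighted memory of the stimulus derivative — the OSN
fires more for a given intensity while the stimulus accelerates and is
suppressed, down to complete inhibition, while it decelerates. For the
light parameters:

```{r}
unlist(qssa_constants(transduction_params("light_iff"))[1:4])
```

`scaling_term()` evaluates $S$ by the exact exponential-kernel recursion
for piecewise-linear stimuli (one-pole filter, $O(N)$, exact on ramps).

On the light-ramp suite the closed form tracks the full ODE within 15% of
the peak rate throughout its validity region for the smooth-onset shapes.
The idealized ramps contain slope *discontinuities*, and for roughly
$2/\beta_5 \approx 0.15$ s after a corner the premise $dy/dt \approx 0$
is violated — the closed form overshoots transiently, up to 20% of peak
at the onset corner of the steepest-onset shapes (the 48 W/m²/s linear
ramp and the asymptotic surrogate). Physical stimulation hardware delivers
rounded onsets, for which this transient shrinks; the package keeps the
idealized corners and documents the bound honestly rather than smoothing
the inputs.

The Hill-gate linearization holds above
$\tilde y = \theta\sqrt{(1-\varepsilon)/\varepsilon}$
(`validity_threshold()`; 1.3 Hz for $\theta = 0.3$ Hz,
$\varepsilon = 0.05$), and `qssa_rate()` returns a validity mask combining
this threshold with positivity of the rescaled denominator. The slow
corrections are ignored in the QSSA (the derivation uses the uncorrected
constants); this is a documented, sub-percent source of mismatch against
the corrected ODE at ramp timescales.

## The linear-filter baseline

`estimate_filter()` implements frequency-domain reverse correlation
(cross-spectrum over regularized power spectrum, mean-subtracted 5-s
windows with 50% overlap, spectral regularization
$10^{-6}\max|F(x)|^2$), and `predict_linear()` convolves and rescales to
a target mean. Driven by a de Bruijn intensity sequence
(`make_msequence()`, all 625 ordered 4-tuples of 5 levels, 33-ms steps)
the estimated filter is biphasic, but its predictions on graded ramps are
reliably worse than the transduction ODE — the package reproduces this
insufficiency of linear identification as a property test on synthetic
data.

## Fitting the ODE to PSTHs

`fit_transduction()` maximizes a Gaussian log-likelihood of the PSTH mean
given the model, with a per-entry multiplicative scale factor (bounded
[0.5, 2]) absorbing across-preparation variability. Two estimator details
proved essential for unbiased fits on trial-limited PSTHs and are easy to
get wrong:

* the residual sigma must be the standard error of the PSTH *mean* — the
  across-trial standard deviation divided by $\sqrt{n_\mathrm{trials}}$ —
  with the noisy per-bin variance smoothed over ~0.5 s and floored at
  0.5 Hz. Weighting by the raw per-bin trial standard deviation makes
  near-silent bins dominate the fit by orders of magnitude and biases the
  weighted scale estimate far below 1 (verified on synthetic data);
* the nuisance scale is profiled out by *unweighted* regression through
  the origin: inverse-variance weights are proportional to 1/rate for
  Poisson spiking and therefore correlated with the observations, which
  biases a weighted scale estimate downward, while the unweighted
  estimator is unbiased. Optimization is Nelder–Mead simplex over
unconstrained transforms of the parameters (positivity by construction),
followed by a finite-difference BFGS refinement, with seeded multi-start
and perturb–restart cycles. For the pure IFF model $\alpha_1$ is fixed at
0.1: the units of $u$ are arbitrary, so one parameter of the $u$-equation
must be pinned.

### Identifiability and gauge fixing

Two structural facts shape the optimizer design, and both are easy to miss:

* **An exact scale gauge.** Scaling $(\beta_1, \beta_4, \theta)$ by any
  $c$ scales the entire solution $y(t)$ by $c$, which the free per-entry
  scale factors absorb exactly — the likelihood is perfectly flat along
  this one-parameter family. The fitted parameter set is therefore
  *defined* in the gauge where the per-entry scales have unit geometric
  mean, enforced by a quadratic penalty on the mean log-scale.
* **A soft $(\delta_1, \delta_4)$ ridge.** With $\delta_2 \approx 1$ far
  below the stimulus range, the data constrain $\delta_1 - \delta_4$
  sharply but the individual constants only through the curvature of the
  dose–response and the sub-baseline inhibition transients. The IFF search
  therefore runs in QSSA coordinates
  $(\delta_1-\delta_4,\ \delta_2,\ \delta_3,\ \delta_4,\ \alpha_2,\
  \beta_5,\ \theta)$, where the sharp and soft directions are
  axis-aligned, and is initialized by a closed-form QSSA pre-fit (no ODE
  integrations) followed by an ODE stage over the coordinates the QSSA
  cannot see ($\beta_5$, $\theta$, $\delta_4$).

With this design, a noiseless self-fit on three ramps recovers all four
$\delta$ constants, $\alpha_2$ and $\theta$ essentially exactly. Under
realistic noise one more ingredient is required: with 10-trial Poisson
PSTHs of graded ramps *alone* — even all ten — the likelihood retains a
near-null direction along which several parameters co-vary (verified:
the objective changes by only a few units across 25–60% excursions of
$\delta_1$ and $\delta_4$), and the constants are unidentifiable.
Anchoring the dataset with steady-state dose–response steps — the
independent 20–24-s window measurements that also constrained the
original fit — collapses that direction; with five ramps plus four 24-s
steps, all four $\delta$ constants are recovered within 8% at 10 trials
across seeds (tested at 15%). Goodness of fit is reported per entry as
Pearson's $\rho$ and CV(RMSE) = RMSE / mean(observed), the two metrics
used throughout.

## The turn GLM and likelihood analysis

The behavioral observable is the probability $\lambda(t)$ that a run
surviving at $t$ terminates in a turn within a 1-s window. The test model
is a logit-link GLM on the model-predicted firing rate,
$\mathrm{logit}\,\lambda = \gamma_0 + \gamma_1 y(t)$ with
$\gamma_0 = -0.3534$, $\gamma_1 = -0.1523\ \mathrm{Hz^{-1}}$; controls
replace $y$ with the raw stimulus (optionally plus its single-frame
33-ms derivative), and a rectified-linear variant omits the logit.

`estimate_turn_probability()` is the nonparametric counterpart: the
fraction of surviving runs ending within the sliding centered 1-s window,
$(N b_i - N e_i)/N b_i$, with estimates flagged unreliable once fewer than
10% of runs survive. `fit_turn_glm()` regresses
$\mathrm{logit}\,\hat\lambda$ on the input by OLS over reliable time
points, clipping $\hat\lambda$ to $[1/(2N), 1 - 1/(2N)]$ (the empirical
estimator can hit 0 or 1); count-weighted regression is available as an
option but off by default. Turn-probability error bars come from 100
half-sized resamples without replacement.

Run likelihoods follow the 1-s binning anchored at the run end: a run of
duration $T$ is evaluated at $t_k = (T \bmod 1) + k$ for
$k = 0,\dots,\lfloor T\rfloor - 1$ (five evaluations for a 5.6-s run),
survival factors $(1-\lambda)$ at all but the last point, and $\lambda$ or
$(1-\lambda)$ last depending on whether the run ended in a turn or was
censored. `bootstrap_compare()` resamples runs with replacement (default
10,000), reports the distribution of
$(\log L_\mathrm{test} - \log L_\mathrm{control})/\log L_\mathrm{test}$,
and counts the resamples in which the control's raw log-likelihood beats
the test model's (a zero count is reported as $< 1/n$). Note the sign
convention: because log-likelihoods are negative, the relative statistic
is *negative* when the test model wins. Uncoupled controls are built by
`control_inputs()`: the time-reversed stimulus (preserving its statistics)
and the per-trajectory constant mean activity.

## Behavioral classification

`classify_states()` is a two-state machine on three kinematic features
(`kinematic_features()`): the head angle between the tail→midpoint body
axis and midpoint→head neck axis, the tail velocity, and its projection on
the unit body axis. A run is interrupted when the head angle exceeds
$\tau_1 = 18°$ (head cast) or the projection falls below
$\tau_2 = 0.0065$ (stop/backward motion, in mm per frame at 30 Hz — the
calibration under which the published threshold magnitude is meaningful);
it resumes only below $\tau_3 = 13°$ with forward motion, giving
hysteresis. Positions are pre-smoothed with a Savitzky–Golay filter
(default 15 frames, order 3; the window and order are our defaults — real
tracker data carry stepper-motor jitter, simulated data do not).
`detect_turns_geometric()` is the offline alternative: the midpoint path
resampled at 5-mm arc length, bends above 20° merged into single turn
events. `runs_from_states()` converts either output into a
`run_ensemble`, flagging trajectory-end censoring.

## The synthetic larva

`simulate_larva()` closes the loop: per 33-ms frame it samples the
landscape at the head (bilinear interpolation on a 1-mm grid, as in the
tracker), advances the transduction ODE one step, maps the rate through
the GLM, and converts the 1-s window probability to a per-frame hazard
$p_f = 1 - (1-\lambda)^{dt}$ — the unique thinning consistent with the
1-s definition of $\lambda$. A triggered turn holds the body stationary
for 1.5 s while the heading rotates to a new direction; the magnitude of
the heading change is uniform in [30°, 120°].

The turn *direction* deserves a note. With a fully random direction the
simulated population does not accumulate at the gradient peak: the inward
drift from run-length modulation alone (klinokinesis) is cancelled by the
outward entropic drift of a 2-D random walk. Real larvae orient their
turns by lateral head casts, and gradient ascent is described as runs plus
*directed* turns; the simulator therefore samples the intensity a body
length ahead along both candidate headings and commits to the brighter
side with probability `turn_bias` (default 0.75, matching the fraction of
correctly oriented first head sweeps reported for real larvae;
`turn_bias = 0.5` gives fully undirected turns). With the default, 25
agents released at 9.6 mm reach a median final distance of ~5.6 mm from
the peak.

### Landscapes

`make_landscape()` builds the radial intensity fields on a 1×1 mm grid.
For the volcano/well/mesa/linear-hat family the annulus between the foot
(16 mm) and the rim (8 mm) is constructed so that inward motion at 1 mm/s
reproduces the 8-s exponential ramp from 15 to 207 W/m²; inside the rim
the profiles diverge — mirrored exponential fall (volcano), abrupt drop to
baseline (well, the family's only discontinuity), sustained maximum
(mesa), or a gentle linear rise to an apex at the center (linear hat;
apex 1.15 × the rim intensity by default — the paper-relevant feature is
the sharp *deceleration* of the stimulus at the rim, not the apex value).
The exponential gradient is parameterized separately as
$I(r) = I_\min + (I_\max-I_\min)e^{-r/\ell}$ with $\ell = 4$ mm: the
literal 8-s-ramp transect would imply $\ell = 1$ mm and be imperceptible
at the 9.6-mm release distance; 4 mm keeps the transect exponential (4-s
time constant at 1 mm/s) while matching the broad published gradient
geometry. Rim crossings are referenced to the head position, which defines
the closed-loop stimulus.

`synthetic_psth()` emulates repeated recordings as inhomogeneous Poisson
trials (thinning) summarized by the standard 50-ms sliding-window PSTH,
and `make_turn_ensemble()` emulates the open-loop paradigm: every run
replays a ramp from run onset (the protocol resets to baseline outside
runs), with per-frame hazard termination and censoring at trace end. Turn
probability estimation for GLM training uses the unfiltered ensemble; the
1-s minimum-duration filter applies to likelihood analyses, matching the
published run counts.

## What the synthetic data do and do not show

The generators reproduce the statistical structure the analysis assumes:
Poisson trial noise around ODE rates, hazard-driven run terminations,
closed-loop stimulus histories over known landscapes, and exact
reproducibility under a seed. They do not emulate peristalsis, head-cast
kinematics within turns, weathervaning, tracker jitter, realistic odor
plumes (the PDE-reconstructed gradients are replaced by analytic radial
surrogates), or across-animal parameter variability. Passing tests
therefore validate the estimators and the internal consistency of the
model chain — e.g. that GLM parameters are recoverable from 600 runs per
ramp within 10% — not the biological accuracy of any parameter value.
Quantities tied to real-larva kinematics (the published post-rim latencies
of 0.93–6.7 s, median run durations) are matched in *ordering* but not in
absolute value: in particular the GLM's basal rate caps the simulated
turn release after a well crossing at a slower pace than real larvae
exhibit.

## Problem sizes used by the test suite

The shipped tests run the analyses at reduced but statistically adequate
scales, chosen once: ramp suites at 30 Hz (fits at 20 Hz), 600 simulated
runs per ramp for GLM recovery, three-ramp fit datasets with 10 Poisson
trials, 200 rim-entering runs per landscape for the duration orderings,
and 25 closed-loop trajectories of 3 minutes for accumulation and
turn-triggered averages. These match the published orders of magnitude
(490–970 runs per open-loop condition, 25 trajectories, minimum 3-minute
sessions) where feasible and are stated here as the package's own
reproducibility conditions.
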