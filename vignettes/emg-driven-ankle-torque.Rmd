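---
title: "EMG-driven ankle torque: model, calibration and synthetic validation"
author: "emgtorque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMG-driven ankle torque: model, calibration and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgtorque)
```

## The problem

Measuring ankle torque directly during rehabilitation lags the movement;
surface EMG (sEMG) leads it. `emgtorque` turns four channels of processed
sEMG envelopes (tibialis anterior, soleus, medial and lateral
gastrocnemius) plus the joint angle into the net torque about one ankle
axis, using a Hill-type muscle-tendon model, and calibrates the model's 16
subject-specific parameters against a measured torque recording with a
genetic algorithm. The intended consumer is a rehabilitation-robotics or
biomechanics workflow that needs subject-adapted torque prediction from
wearable-grade signals.

## Model chain

**Activation dynamics.** Normalized EMG $e(t) \in [0,1]$ (envelope divided
by the MVC maximum) passes through a delayed second-order recursion

$$u(t) = \alpha\, e(t - d) - \beta_1 u(t-1) - \beta_2 u(t-2),$$

with electromechanical delay $d$ (default 40 ms, realized as a
round-half-up integer number of samples) and defaults $\alpha = 0.9486$,
$\beta_1 = -0.052$, $\beta_2 = 0.000627$. The characteristic roots are
real and below 0.06 in magnitude, and the DC gain
$\alpha/(1+\beta_1+\beta_2)$ is within $3\times 10^{-5}$ of 1, so the
stage is essentially a delayed copy with a two-sample transient. Neural
activation then becomes muscle activation through the exponential shaping

$$a = \frac{e^{Au} - 1}{e^{A} - 1}, \qquad A \in (-3, 0),$$

strictly increasing and concave for the default $A = -1.5$. We clip $u$
defensively to $[0,1]$ before the shaping (counting clip events); whether
clipping precedes the shaping is an interpretation, since with near-unity
DC gain and inputs in $[0,1]$ the recursion barely leaves the band.

**Hill-type muscle-tendon unit.** Each muscle is a contractile element in
parallel with an elastic element, in series with a tendon, at pennation
angle $\varphi$:

* active force-length: $f_A(l) = q_0 + q_1 l + q_2 l^2$ on
  $l \in [0.5, 1.5]$ (zero outside), $q = (-2.06, 6.16, -3.13)$;
* passive force-length: $f_P(l) = e^{10l - 15}$;
* force-velocity: concentric $0.3(v+1)/(0.3-v)$ for normalized velocity
  $v < 0$, eccentric $(2.34v + 0.039)/(1.3v + 0.039)$ for $v \ge 0$ —
  equal to 1 at $v = 0$, zero at $v = -1$, asymptote $2.34/1.3 = 1.8$;
* tendon: strain $\varepsilon = (l_t - l_{st})/l_{st}$; force
  $F_0^m \cdot 1480.3\,\varepsilon^2$ in the toe region
  $0 < \varepsilon < 0.0127$ and $F_0^m(37.5\,\varepsilon - 0.24)$
  beyond, zero when slack. The two branches meet with a small documented
  gap ($\approx 0.0025\,F_0^m$) at the knee;
* pennation: $\varphi = \arcsin(l_0^m \sin\varphi_0 / l_m)$
  (constant-thickness model);
* activation-scaled optimal length:
  $l_0^m(a) = l_0^m(\lambda(1-a) + 1)$, $\lambda = 0.15$. The normalized
  length fed to $f_A$ and $f_P$ uses this scaled optimum by default
  (`model_constants(scale_l0m = FALSE)` restores plain $l_0^m$
  normalization for comparison).

At each instant the tendon force (from the current fiber and MTU lengths)
is balanced against the fiber force to recover the force-velocity scale

$$f_v = \frac{F_t - f_P(l)\,F_0^m \cos\varphi}
             {f_A(l)\,a\,F_0^m \cos\varphi},$$

which the closed-form inverse of the force-velocity curve maps to a fiber
velocity $v_m = v_0^m \cdot v$. Fiber length is integrated by classic
4th-order Runge-Kutta at the sampling interval, interpolating inputs at
half-steps.

**Geometry and torque.** Musculotendon length is a cubic in the joint
angle, $l_{mt}(\theta) = \mu_0 + \mu_1\theta + \mu_2\theta^2 +
\mu_3\theta^3$, and the moment arm is its exact derivative. Joint torque
is $M(\theta, t) = \sum_i r_i(\theta) F_{t,i}(t)$. We adopt the
convention that positive torque means dorsiflexion / inversion / internal
rotation, with $\theta = 0$ the neutral anatomical position, and absorb
each muscle's sign into its polynomial coefficients (the moment arm is
implemented literally as $\partial l_{mt}/\partial\theta$, so an agonist's
MTU "lengthens" along its positive direction; within a fixed-sign
convention this is self-consistent, and the calibration and torque
summation only ever see the product $r_i F_i$).

## Parameters that matter

| Parameter | Units | Default | Role |
|---|---|---|---|
| $F_0^m$ | N | 1270 / 2830 / 1115 / 490 (ta, sol, gm, gl) | force scale; calibrated, bounds ±50% |
| $l_0^m$ | m | 0.031 / 0.030 / 0.045 / 0.064 | optimal fiber length; calibrated, ±50% |
| $l_{st}$ | m | 0.310 / 0.268 / 0.408 / 0.385 | tendon slack length; calibrated, ±15% |
| $\varphi_0$ | deg | 12 / 25 / 17 / 8 | pennation at $l_0^m$; calibrated, ±50% |
| $v_0^m$ | m/s | $10\,l_0^m$ | max shortening velocity; fixed by convention, recomputed from the calibrated $l_0^m$ |
| $d_e$ | ms | 40 | electromechanical delay |
| $A$ | — | −1.5 | activation shaping |
| $\lambda$ | — | 0.15 | activation-dependent optimum shift |

Tendon slack length is by far the most geometry-critical parameter: a few
millimetres decide whether the tendon is slack or carrying force, which is
why its calibration interval is the narrow one.

The moment-arm polynomials are **package defaults, not measured values**
(`default_ankle_geometry()`); published values for these four muscles on a
seated bench are not available, so we ship physiologically plausible arms
(tibialis anterior sagittal arm 0.018 m at neutral, plantarflexors 0.012
to 0.014 m, smaller arms for the coronal and horizontal axes) with every
muscle's neutral MTU length set to $l_{st} + l_0^m\cos\varphi_0$ of the
anatomical set, i.e. every tendon exactly slack at neutral. Arm magnitudes
are deliberately bounded so that $|\mu_1| \times$ ROM stays well inside
each muscle's fiber-length budget (about $0.7\,l_0^m$ of shortening and
$0.45\,l_0^m$ of stretch, with margin for calibration candidates with
smaller $l_0^m$); larger arms combined with the small printed optimal
fiber lengths would drive fibers out of the valid range of the
force-length curves within the stated ranges of motion. All geometry is
overridable via `geometry_poly()` or a text config.

## Numerical choices

* **Degenerate force balance.** When activation or $f_A$ is near zero the
  force-balance denominator vanishes; we floor it at $10^{-6} F_0^m$ and
  clamp $f_v$, never raising mid-integration. Clamp counts are reported
  (`n_clamp` attributes and evaluation reports) as the model's
  numerical-health signal.
* **Velocity cap.** $f_v$ is clamped into $[0,\, f(v{=}1)]$ with
  $f(1) = 2.379/1.339 \approx 1.777$, bounding fiber speed at $v_0^m$ in
  both directions. Clamping instead at just below the 1.8 asymptote looks
  harmless but maps to absurd lengthening velocities (the inverse blows up
  at the asymptote) and destroys the integration; the force-velocity curve
  is within 1.3% of its asymptote at $v = 1$, so the cap costs essentially
  nothing.
* **Fiber-length guard.** Integration aborts (with the offending step
  named) if $l_m$ leaves $(0.25, 2.5)\,l_0^m$; during calibration the
  abort becomes a large finite penalty ($10^{12}$) so the GA can continue.
* **Initial fiber length** defaults to $l_0^m$; the first few tens of
  milliseconds are a settling transient toward the slack-equilibrium
  operating point (prediction quality at movement onset is limited by this
  assignment; `lm0` is exposed per muscle).
* **Angles** are radians internally, degrees at every I/O boundary.

## Calibration

The 16-parameter vector is quantized linearly into 16 bits per parameter
over its bounds (all-zero = lower bound, all-one = upper). Each
generation: fitness $1/(1 + \text{objective})$ — positive and
order-preserving for a minimization target, roulette selection,
single-point crossover with probability 0.6, positional mutation with
probability 0.1 (per individual, one random bit; a per-bit mode is
available), and elitist carryover of the single best individual, which
makes the best-so-far trace nonincreasing and the reported optimum
well-defined. The objective pools all calibration trials across DOFs into
one sum of squared torque residuals, matching a single optimized
16-parameter set. Defaults are population 100 and 150 generations; the
packaged acceptance workflow runs a reduced scale (population 40,
generations 60) that calibrates the default scenario in seconds to
minutes on one core.

## What the synthetic generator emulates — and what it does not

`generate_trial()` emulates a seated rehabilitation-bench protocol: a
half-sine angle sweep from neutral to the movement's range of motion (30°
dorsiflexion, 45° plantarflexion, 15° inversion, 35° internal and 25°
external rotation) and back; smooth agonist-weighted EMG envelope bells
plus truncated Gaussian noise (SD 0.02) and a small resting tone (0.02);
and torque from the forward model at known true parameters plus Gaussian
noise with SD 5% of the trial's peak torque. Envelope peaks are submaximal
(agonist ≈ 0.2, synergists ≈ 0.05–0.13), chosen so peak torques land at
the tens-of-N·m scale of damped bench movements; the agonist weighting per
movement follows the known contribution pattern (tibialis anterior
dominates dorsiflexion, the triceps surae dominates plantarflexion and
inversion, soleus is nearly silent in internal rotation, the medial
gastrocnemius in external rotation).

The default ground truth (`ankle_muscle_defaults("subject")`) perturbs the
anatomical set by fixed factors within the calibration bounds — strongly
in force and pennation (±25–35%), mildly in lengths — and coherently
within synergist groups (a stronger dorsiflexor, uniformly weaker
plantarflexors), so that parameter deviations do not cancel in the summed
torque and calibration has something real to recover. The shipped
`"calibrated"` reference set is not used as simulation truth: its
medial-gastrocnemius tendon slack length lies below the calibration
bounds and outside the default geometry's operating range.

What passing on synthetic data does **not** show: real sEMG
nonstationarity (electrode shift, sweat, crosstalk between the
gastrocnemius heads), real moment-arm curves, co-contraction patterns
beyond the baseline tone, trial-to-trial kinematic variability (the sweep
is identical across repetitions), or soft-tissue artifacts in the measured
torque. Results on the synthetic scenario bound what the code computes,
not how well the model fits human ankles.

## Scenario, split and problem sizes

The default scenario (`ankle_scenario()`) runs each of the five movements
three times — the bench protocol's repetition count — at 1 kHz for 5 s
(5001 samples per trial; 1 kHz keeps the 40 ms delay an exact 40-sample
shift and the integration chatter of near-slack fibers negligible). The
first two repetitions of each movement calibrate, the third is held out,
mirroring a train/held-out subject split at trial level. The
test-suite recovery check uses a smaller three-movement, 3 s variant; the
single-parameter oracle test uses 2 s trials at 500 Hz. These sizes are
the package's validation design, chosen to exercise every code path at
dense sampling while keeping a full run in minutes on one core.

## Known limitations

* One DOF at a time; no coupled 3-D geometry, no muscle wrapping.
* No fatigue, history dependence, or raw-EMG synthesis; envelope
  preprocessing (`emg_envelope()`) is a convenience extension with
  standard 20–450 Hz band-pass / 6 Hz low-pass defaults, not a validated
  pipeline.
* The GA at reduced scale underconverges on the pooled five-movement
  objective (rotation movements contribute little identifiable signal);
  held-out RMSE lands well under the headline bound but above the noise
  floor. Full-scale settings (population 100, 150 generations) close part
  of that gap at proportional cost.
* RMSE units are N·m throughout; contribution fractions are reported as
  signed N·m series because antagonist contributions change sign within a
  movement.
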