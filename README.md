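# emgtorque

EMG-driven computation of ankle joint torque with a Hill-type
muscle–tendon model, and genetic-algorithm calibration of its
physiological parameters.

## What it does

Rehabilitation devices need the torque a patient's ankle produces, but
measuring torque directly lags the movement, while surface EMG (sEMG)
leads it. `emgtorque` computes the net torque about one ankle axis
(dorsi/plantarflexion, inversion/eversion, or internal/external rotation)
from four channels of MVC-normalized sEMG envelopes — tibialis anterior,
soleus, medial and lateral gastrocnemius — plus the joint angle:

1. **Activation dynamics** — a delayed second-order recursion
   `u(t) = α·e(t−d) − β₁u(t−1) − β₂u(t−2)` (electromechanical delay
   d = 40 ms) followed by exponential shaping
   `a = (e^{Au} − 1)/(e^A − 1)`, A ∈ (−3, 0).
2. **Hill-type muscle–tendon mechanics** per muscle — active and passive
   force–length curves, a hyperbolic force–velocity curve with closed-form
   inverse, a quadratic-toe/linear tendon force–strain curve, a
   constant-thickness pennation model, and 4th-order Runge–Kutta
   integration of fiber length.
3. **Joint geometry** — musculotendon length as a cubic polynomial of the
   joint angle; the moment arm is its exact derivative; torque is
   `M(θ,t) = Σᵢ rᵢ(θ)·Fᵢ(t)`.

The 16 subject-specific parameters (maximum isometric force, optimal
fiber length, tendon slack length and pennation angle, for each of the
four muscles) are calibrated against measured torque by a binary-coded
genetic algorithm (roulette selection, single-point crossover 0.6,
positional mutation 0.1, elitism) within per-class bounds (±50%, ±15% for
tendon slack length).

Because no subject recordings ship with the package, a synthetic-trial
generator emulates the bench protocol — the five standard movements (30°
dorsiflexion, 45° plantarflexion, 15° inversion, 35° internal and 25°
external rotation), three repetitions each, MVC-normalized envelope bells
per muscle, torque from the forward model at known ground-truth parameters
plus 5%-of-peak Gaussian noise — so the entire pipeline is testable and
reproducible end to end.

## Worked example

```r
library(emgtorque)

# a synthetic dorsiflexion trial from known ground truth
tr <- generate_trial(trial_spec("dorsiflexion", seed = 42))
tr
#> <trial> dorsiflexion (sagittal): 5001 samples @ 1000 Hz,
#>   theta in [0.0, 30.0] deg, torque in [-2.26, 10.43] N m

# predict torque with the anatomical (uncalibrated) parameter set
p <- predict_torque(tr, ankle_muscle_defaults("anatomical"))
rmse(p, tr$torque)
#> [1] 2.529918

# calibrate on the train repetitions of the full five-movement scenario
sc <- ankle_scenario(seed = 1)
res <- run_ga(sc$trials[sc$role == "train"],
              ga = ga_config(population = 40, generations = 60, seed = 2))
ev <- evaluate_trials(sc$trials[sc$role == "test"], res$params)
ev
#> <evaluation_report>
#>           movement        dof      rmse peak_torque n_clamp
#>       dorsiflexion   sagittal 1.4104231   10.670155    2838
#>     plantarflexion   sagittal 0.9663712   10.232623    1954
#>          inversion    coronal 0.8128603    9.498847    2039
#>  internal_rotation horizontal 0.5024859    3.631095    2562
#>  external_rotation horizontal 0.5656821    1.922834    2428
#> RMSE across trials: 0.852 +/- 0.364 N m
```

The calibrated model's held-out error (0.85 N·m mean) sits between the
injected noise floor (≈ 0.3 N·m) and the uncalibrated anatomical
parameters (≈ 1.28 N·m). `n_clamp` counts force-balance clamp events, the
model's numerical-health signal; `muscle_contributions()` breaks torque
into signed per-muscle series (tibialis anterior dominates dorsiflexion
by construction of the scenario).

## Command line

A thin CLI over the same functions:

```sh
Rscript inst/cli/emg2torque.R simulate  --out trials/ --seed 1
Rscript inst/cli/emg2torque.R calibrate --manifest trials/manifest.txt --out fit/ --seed 1 \
    --population 40 --generations 60
Rscript inst/cli/emg2torque.R predict   --trial trials/trial_01_dorsiflexion.csv \
    --params fit/calibrated_params.txt --out pred.csv
Rscript inst/cli/emg2torque.R evaluate  --manifest trials/manifest.txt \
    --params fit/calibrated_params.txt --out report/
```

All tabular outputs are CSV; every run writes a JSON run record with
seeds, configuration and input hashes.

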