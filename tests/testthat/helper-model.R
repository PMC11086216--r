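# shared fixtures: all built in code at test time

ta_anat <- function() ankle_muscle_defaults("anatomical")$ta

# fiber length at which the fiber is in equilibrium (vm = 0) for constant
# activation and MTU length; located by root-finding, independent of the
# integrator
equilibrium_lm <- function(a, lmt, mp, const = model_constants()) {
  f <- function(lm) as.numeric(fiber_velocity(lm, a, lmt, mp, const))
  lo <- 0.3 * mp$l0m
  hi <- 2.2 * mp$l0m
  uniroot(f, c(lo, hi), tol = 1e-13)$root
}

# small, fast synthetic trial for pipeline tests
quick_trial <- function(movement = "dorsiflexion", seed = 1, duration = 2,
                        fs = 500, torque_noise = 0, emg_noise = 0, ...) {
  generate_trial(trial_spec(movement, duration = duration,
                            sample_rate = fs, torque_noise_sd = torque_noise,
                            emg_noise_sd = emg_noise, seed = seed), ...)
}

# forward-Euler integration of the fiber ODE at a refined step, linearly
# interpolating the activation and MTU-length inputs; brute-force oracle
# for the RK4 integrator
euler_fiber <- function(a, lmt, mp, const = model_constants(), dt,
                        lm0 = mp$l0m, refine = 100) {
  n <- length(a)
  h <- dt / refine
  lm <- lm0
  t_in <- (seq_len(n) - 1) * dt
  for (k in seq_len((n - 1) * refine)) {
    tk <- (k - 1) * h
    ak <- approx(t_in, a, xout = tk)$y
    lk <- approx(t_in, lmt, xout = tk)$y
    lm <- lm + h * as.numeric(fiber_velocity(lm, ak, lk, mp, const))
  }
  lm
}
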