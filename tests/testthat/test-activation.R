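test_that("normalize_emg divides by the MVC maximum and clips", {
  t <- seq(0, 1, by = 0.01)
  flat <- signal_series(t, rep(2.5, length(t)))
  expect_equal(normalize_emg(flat, 2.5)$values, rep(1, length(t)))
  zero <- signal_series(t, rep(0, length(t)))
  expect_equal(normalize_emg(zero, 2.5)$values, rep(0, length(t)))

  # one overshooting sample clips to exactly 1; others scale elementwise
  v <- rep(0.5, length(t)); v[7] <- 1.2 * 2.5
  s <- normalize_emg(signal_series(t, v), 2.5)
  expect_equal(s$values[7], 1.0)
  expect_equal(s$values[-7], v[-7] / 2.5)
  expect_equal(s$t, t)

  expect_error(normalize_emg(flat, 0), "positive")
  expect_error(normalize_emg(flat, -1), "positive")
  expect_error(normalize_emg(signal_series(t, c(-0.1, rep(0.2, length(t) - 1))), 1),
               "nonnegative")
})

test_that("neural activation recursion: zero input, steady state, delay", {
  p <- activation_params() # de = 40 ms, fs = 1000 Hz
  t <- seq(0, 0.499, by = 1e-3)

  expect_equal(neural_activation(signal_series(t, rep(0, 500)), p)$values,
               rep(0, 500))

  # sustained step: steady state equals the closed-form DC gain
  # alpha/(1 + beta1 + beta2) (value computed independently)
  u <- neural_activation(signal_series(t, rep(1, 500)), p, clip = FALSE)
  expect_equal(u$values[500], 0.99997153781201674, tolerance = 1e-12)

  # unit impulse at sample k first appears at sample k + 40 (40 ms at 1 kHz)
  e <- rep(0, 500); k <- 100; e[k] <- 1
  u <- neural_activation(signal_series(t, e), p)
  expect_equal(which(u$values != 0)[1], k + 40)
  expect_equal(u$values[k + 40], p$alpha)
})

test_that("recursion is stable and linear, with geometrically decaying impulse response", {
  p <- activation_params()
  r <- Mod(polyroot(c(p$beta2, p$beta1, 1)))
  expect_true(all(r < 0.06)) # real roots, both well inside the unit circle

  # unstable coefficient pair is rejected at construction
  expect_error(activation_params(beta1 = -2.5, beta2 = 1.4), "unstable")

  t <- seq(0, 0.299, by = 1e-3)
  e1 <- runif(300)
  s <- function(v) signal_series(t, v)
  u1 <- neural_activation(s(e1), p, clip = FALSE)$values
  for (cc in c(0.3, 0.7, 1)) {
    uc <- neural_activation(s(cc * e1), p, clip = FALSE)$values
    expect_equal(uc, cc * u1, tolerance = 1e-12)
  }

  # impulse response bounded by C * rho^n for rho the largest root magnitude
  e <- rep(0, 300); e[1] <- 1
  h <- neural_activation(s(e), p, clip = FALSE)$values
  rho <- max(r)
  n <- seq_along(h)
  expect_true(all(abs(h[45:300]) <= 10 * p$alpha * rho^(n[45:300] - 41) + 1e-300))
})

test_that("muscle activation shaping: endpoints, frozen midpoint, monotonicity", {
  expect_equal(muscle_activation(0, A = -1.5), 0)
  expect_equal(muscle_activation(1, A = -1.5), 1)
  # (e^-0.75 - 1)/(e^-1.5 - 1), evaluated independently to 17 digits
  expect_equal(muscle_activation(0.5, A = -1.5), 0.67917869917539297,
               tolerance = 1e-14)

  u <- seq(0, 1, by = 0.01)
  for (A in c(-2.9, -1.5, -0.5, -0.01)) {
    a <- muscle_activation(u, A = A)
    expect_true(all(diff(a) > 0), label = paste("strictly increasing at A =", A))
    expect_true(all(a >= 0 & a <= 1))
  }
  expect_error(muscle_activation(0.5, A = 0), "(-3, 0)", fixed = TRUE)
  expect_error(muscle_activation(0.5, A = -3), "(-3, 0)", fixed = TRUE)
  expect_error(muscle_activation(0.5, A = 1), "(-3, 0)", fixed = TRUE)
})

test_that("activations stay in [0, 1] for arbitrary EMG in [0, 1]", {
  p <- activation_params()
  t <- seq(0, 0.499, by = 1e-3)
  set.seed(42)
  for (i in 1:20) {
    e <- signal_series(t, runif(500))
    u_raw <- neural_activation(e, p, clip = FALSE)$values
    u <- neural_activation(e, p)
    a <- muscle_activation(u, p$A)
    # near-unity DC gain: even the unclipped recursion stays in band
    expect_true(all(u_raw > -1e-12 & u_raw < 1 + 1e-3))
    expect_true(all(u$values >= 0 & u$values <= 1))
    expect_true(all(a$values >= 0 & a$values <= 1))
  }
})

test_that("signal series enforce a uniform time base and CSV round-trip", {
  expect_error(signal_series(c(0, 0.1, 0.3), c(1, 2, 3)), "uniform")
  expect_error(signal_series(c(0, 0.1, 0.1), c(1, 2, 3)), "increasing")
  s <- signal_series(seq(0, 1, by = 0.05), runif(21))
  f <- tempfile(fileext = ".csv")
  write_signal_csv(s, f)
  s2 <- read_signal_csv(f)
  expect_equal(s2$values, s$values)
  expect_equal(s2$fs, s$fs, tolerance = 1e-9)
  unlink(f)
})
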