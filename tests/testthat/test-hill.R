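test_that("active force-length: branch values and brute-force agreement", {
  expect_equal(active_force_length(0.4), 0)
  expect_equal(active_force_length(1.0), 0.97)   # q0 + q1 + q2 by hand
  expect_equal(active_force_length(0.5), 0.2375) # endpoints of the window,
  expect_equal(active_force_length(1.5), 0.1375) # evaluated independently

  co <- model_constants()
  l <- seq(0, 2, length.out = 121)
  brute <- vapply(l, function(x) {
    if (x < 0.5 || x > 1.5) return(0)
    max(co$q0 + co$q1 * x + co$q2 * x^2, 0)
  }, 1.0)
  expect_equal(active_force_length(l, co), brute)
})

test_that("passive force-length: exponent cancellation and monotonicity", {
  expect_equal(passive_force_length(1.5), 1.0)
  expect_equal(passive_force_length(1.0), 0.006737946999085467,
               tolerance = 1e-14) # e^-5, independent evaluation
  l <- seq(0.2, 2, length.out = 120)
  f <- passive_force_length(l)
  expect_true(all(f > 0))
  expect_true(all(diff(f) > 0))
  expect_equal(f, exp(10 * l - 15))
})

test_that("force-velocity: branch anchors, continuity, asymptote, clamping", {
  expect_equal(force_velocity(0), 1)
  expect_equal(force_velocity(-1), 0)
  # both branch formulas give 1 at v = 0
  expect_equal(0.3 * (0 + 1) / (0.3 - 0), 1)
  expect_equal((2.34 * 0 + 0.039) / (1.3 * 0 + 0.039), 1)
  # eccentric asymptote 2.34/1.3
  expect_equal(force_velocity(1e9), 2.34 / 1.3, tolerance = 1e-6)
  expect_lt(max(force_velocity(seq(-1, 50, by = 0.01))), 1.8)
  # continuity at the branch point
  expect_equal(force_velocity(-1e-12), force_velocity(1e-12),
               tolerance = 1e-9)
  expect_warning(out <- force_velocity(-1.5), "clamped")
  expect_equal(out, 0)
})

test_that("invert_force_velocity is the exact closed-form inverse", {
  expect_equal(invert_force_velocity(1), 0)
  expect_equal(invert_force_velocity(0), -1)
  set.seed(7)
  x <- runif(100, -1 + 1e-9, 5)
  expect_equal(invert_force_velocity(force_velocity(x)), x,
               tolerance = 1e-10)
})

test_that("tendon curve: slack, toe region, knee gap below 0.005*F0m", {
  mp <- muscle_params(1000, 0.03, 0.25, 10, name = "test")
  expect_equal(tendon_force(mp$lst, mp), 0)
  expect_equal(tendon_force(0.9 * mp$lst, mp), 0)
  # eps = 0.01 in the toe region: F0m * 1480.3 * 1e-4
  expect_equal(tendon_force(mp$lst * 1.01, mp), 1000 * 1480.3 * 1e-4,
               tolerance = 1e-9)
  # documented branch mismatch at the knee, evaluated independently:
  # 1480.3*0.0127^2 = 0.238757587, 37.5*0.0127 - 0.24 = 0.23625
  co <- model_constants()
  gap <- co$k_quad * co$eps_knee^2 - (co$k_lin * co$eps_knee - co$c_lin)
  expect_equal(gap, 0.002507587, tolerance = 1e-9)
  expect_lt(abs(gap), 0.005)

  # nondecreasing over a dense sweep through both branches
  lt <- seq(0.2, 0.35, length.out = 500)
  expect_true(all(diff(tendon_force(lt, mp)) >= 0))
  expect_true(all(tendon_force(lt, mp) >= 0))
})

test_that("pennation angle: identity case, frozen value, monotone decrease", {
  mp <- ta_anat() # phi0 = 12 degrees
  expect_equal(pennation_angle(mp$l0m, mp), 12 * pi / 180)
  # asin(sin 12deg / 2), evaluated independently
  expect_equal(pennation_angle(2 * mp$l0m, mp), 0.10414400051050507,
               tolerance = 1e-14)
  expect_lt(pennation_angle(1.5 * mp$l0m, mp), pennation_angle(mp$l0m, mp))
  expect_warning(phi <- pennation_angle(mp$l0m * sin(mp$phi0_rad) / 2, mp),
                 "clamped")
  expect_equal(phi, pi / 2)
})

test_that("tendon length: arithmetic, slack composition, infeasibility error", {
  expect_equal(tendon_length(0.35, 0.04, 0), 0.31)
  expect_equal(tendon_length(0.35, 0.04, pi / 2), 0.35)
  mp <- ta_anat()
  phi <- pennation_angle(mp$l0m, mp)
  lt <- tendon_length(mp$lst + mp$l0m * cos(phi), mp$l0m, phi)
  expect_equal(lt, mp$lst, tolerance = 1e-12)
  expect_equal(tendon_force(lt, mp), 0) # exactly slack => zero force
  expect_error(tendon_length(0.01, 0.04, 0, muscle = "ta"), "ta")
})

test_that("effective optimal length follows activation", {
  mp <- ta_anat()
  expect_equal(effective_optimal_length(1, mp), mp$l0m)
  expect_equal(effective_optimal_length(0, mp), 1.15 * mp$l0m)
  expect_equal(effective_optimal_length(0.5, mp), 1.075 * mp$l0m)
})

test_that("fiber velocity: isometric equilibrium, clamp path, fv round-trip", {
  mp <- ta_anat()
  lmt <- mp$lst + mp$l0m * cos(mp$phi0_rad) + 0.004
  lm_eq <- equilibrium_lm(0.4, lmt, mp)
  expect_equal(as.numeric(fiber_velocity(lm_eq, 0.4, lmt, mp)), 0,
               tolerance = 1e-10)
  expect_equal(attr(fiber_velocity(lm_eq, 0.4, lmt, mp), "fv"), 1,
               tolerance = 1e-6)

  # tendon force below passive alone: fv clamps to 0 -> maximal shortening
  v <- fiber_velocity(1.49 * mp$l0m, 0.01, mp$lst + 1.49 * mp$l0m, mp,
                      model_constants(scale_l0m = FALSE))
  expect_equal(as.numeric(v), -mp$v0m)
  expect_equal(attr(v, "fv"), 0)

  # when no clamp fires, force_velocity(vm/v0m) reproduces the fv used
  for (dlmt in c(0.002, 0.0035, 0.005)) {
    v <- fiber_velocity(mp$l0m, 0.5, mp$lst + mp$l0m * cos(mp$phi0_rad) + dlmt, mp)
    expect_equal(force_velocity(as.numeric(v) / mp$v0m), attr(v, "fv"),
                 tolerance = 1e-8)
  }
})

test_that("RK4 integration: fixed point, step-halving, Euler oracle, engines agree", {
  mp <- ta_anat()
  co <- model_constants()
  lmt0 <- mp$lst + mp$l0m * cos(mp$phi0_rad) + 0.003
  lm_eq <- equilibrium_lm(0.35, lmt0, mp, co)

  # constant equilibrium input: relative drift < 1e-9 over 1000 steps
  n <- 1001
  st <- integrate_fiber_length(rep(0.35, n), rep(lmt0, n), mp, co,
                               dt = 1e-3, lm0 = lm_eq)
  expect_lt(abs(st$lm[n] - lm_eq) / lm_eq, 1e-9)

  # smooth driven input for the order checks (no clamps along the path)
  tt <- seq(0, 0.5, by = 1e-3)
  a_fun <- function(t) 0.35 + 0.1 * sin(2 * pi * t)
  lmt_fun <- function(t) lmt0 + 0.001 * sin(pi * t)
  st1 <- integrate_fiber_length(a_fun(tt), lmt_fun(tt), mp, co,
                                dt = 1e-3, lm0 = lm_eq)
  expect_identical(attr(st1, "n_clamp_fv"), 0L)
  tt2 <- seq(0, 0.5, by = 5e-4)
  st2 <- integrate_fiber_length(a_fun(tt2), lmt_fun(tt2), mp, co,
                                dt = 5e-4, lm0 = lm_eq)
  expect_lt(abs(st2$lm[nrow(st2)] - st1$lm[nrow(st1)]) / lm_eq, 1e-6)

  # brute-force fine-step Euler agrees with RK4 to < 1e-4 relative
  lm_euler <- euler_fiber(a_fun(tt), lmt_fun(tt), mp, co, dt = 1e-3,
                          lm0 = lm_eq, refine = 100)
  expect_lt(abs(lm_euler - st1$lm[nrow(st1)]) / lm_eq, 1e-4)

  # the compiled engine and the R reference engine are the same algorithm
  st_r <- integrate_fiber_length(a_fun(tt), lmt_fun(tt), mp, co,
                                 dt = 1e-3, lm0 = lm_eq, engine = "r")
  expect_equal(st_r$lm, st1$lm, tolerance = 1e-12)
  expect_equal(st_r$Ft, st1$Ft, tolerance = 1e-12)

  # slack tendon + near-zero drive: the fiber shortens through the lower
  # bound and the integration aborts, naming the offending step
  expect_error(
    integrate_fiber_length(rep(0.01, 200), rep(mp$lst, 200), mp, co,
                           dt = 1e-2, lm0 = 0.26 * mp$l0m),
    "left \\(0.25, 2.5\\)\\*l0m at step")
})

test_that("tendon equilibrium identity and F0m homogeneity hold along trajectories", {
  mp <- ta_anat()
  co <- model_constants()
  lmt0 <- mp$lst + mp$l0m * cos(mp$phi0_rad) + 0.003
  lm_eq <- equilibrium_lm(0.35, lmt0, mp, co)
  tt <- seq(0, 0.5, by = 1e-3)
  a <- 0.35 + 0.1 * sin(2 * pi * tt)
  lmt <- lmt0 + 0.001 * sin(pi * tt)
  st <- integrate_fiber_length(a, lmt, mp, co, dt = 1e-3, lm0 = lm_eq)
  # Ft = (FAm + FPm) cos(phi) wherever no clamp fired (none here)
  expect_lt(max(abs(st$Ft - (st$FAm + st$FPm) * cos(st$phi))), 1e-6 * mp$F0m)

  # doubling F0m doubles every force and leaves the kinematics unchanged
  mp2 <- muscle_params(2 * mp$F0m, mp$l0m, mp$lst, mp$phi0, mp$v0m, "ta2")
  st2 <- integrate_fiber_length(a, lmt, mp2, co, dt = 1e-3, lm0 = lm_eq)
  expect_equal(st2$lm, st$lm, tolerance = 1e-12)
  expect_equal(st2$Ft, 2 * st$Ft, tolerance = 1e-9)
  expect_equal(st2$FAm, 2 * st$FAm, tolerance = 1e-9)
  expect_equal(st2$FPm, 2 * st$FPm, tolerance = 1e-9)
})

test_that("muscle parameter validation and config round-trip", {
  expect_error(muscle_params(-1, 0.03, 0.25, 10), "positive")
  expect_error(muscle_params(1000, 0.03, 0.25, 50), "45")
  p <- ankle_muscle_defaults("anatomical")
  f <- tempfile(fileext = ".txt")
  write_muscle_config(p, f)
  p2 <- read_muscle_config(f)
  expect_equal(names(p2), names(p))
  for (m in names(p)) {
    expect_equal(p2[[m]]$F0m, p[[m]]$F0m)
    expect_equal(p2[[m]]$lst, p[[m]]$lst)
    expect_equal(p2[[m]]$phi0, p[[m]]$phi0)
  }
  unlink(f)
})
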