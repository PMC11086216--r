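#' Normalized active force-length curve
#'
#' Quadratic on normalized fiber length `l` in \[0.5, 1.5\], zero outside:
#' `fA(l) = q0 + q1*l + q2*l^2`. With the default coefficients the peak is
#' close to 1 near `l = 1`.
#'
#' @param l_norm normalized fiber length(s), >= 0.
#' @param c a [model_constants()] object.
#' @return Dimensionless force scale(s), >= 0. Vectorized.
#' @export
active_force_length <- function(l_norm, c = model_constants()) {
  stopifnot(all(l_norm >= 0))
  f <- ifelse(l_norm >= 0.5 & l_norm <= 1.5,
              c$q0 + c$q1 * l_norm + c$q2 * l_norm^2, 0)
  pmax(f, 0)
}

#' Normalized passive force-length curve
#'
#' Exponential resistance to stretch: `fP(l) = exp(10*(l - 1))/exp(5)`,
#' i.e. `exp(10*l - 15)`. Strictly positive and strictly increasing;
#' reaches 1 at `l = 1.5`.
#'
#' @inheritParams active_force_length
#' @return Dimensionless force scale(s), > 0. Vectorized.
#' @export
passive_force_length <- function(l_norm) {
  stopifnot(all(l_norm >= 0))
  exp(10 * l_norm - 15)
}

#' Normalized force-velocity curve
#'
#' Hyperbolic force-velocity relation on normalized fiber velocity
#' `v_norm = vm/v0m` (negative = shortening):
#' concentric branch (`v_norm < 0`) `0.3*(v_norm + 1)/(0.3 - v_norm)`,
#' eccentric branch (`v_norm >= 0`)
#' `(2.34*v_norm + 0.039)/(1.3*v_norm + 0.039)`. Both branches equal 1 at
#' `v_norm = 0`; the curve is 0 at maximal shortening `v_norm = -1` and
#' approaches the eccentric asymptote 2.34/1.3 = 1.8 for fast lengthening.
#' Inputs below -1 are clamped to -1 with a warning.
#'
#' @param v_norm normalized fiber velocity(ies).
#' @return Dimensionless force scale(s) in \[0, 1.8). Vectorized.
#' @export
force_velocity <- function(v_norm) {
  if (any(v_norm < -1)) {
    warning("v_norm below -1 clamped to -1", call. = FALSE)
    v_norm <- pmax(v_norm, -1)
  }
  ifelse(v_norm < 0,
         0.3 * (v_norm + 1) / (0.3 - v_norm),
         (2.34 * v_norm + 0.039) / (1.3 * v_norm + 0.039))
}

#' Closed-form inverse of the force-velocity curve
#'
#' Each branch of [force_velocity()] is a Mobius function, so the inverse is
#' closed-form: `v_norm = 0.3*(fv - 1)/(fv + 0.3)` for `fv < 1` and
#' `0.039*(fv - 1)/(2.34 - 1.3*fv)` for `fv >= 1`. Inputs are clamped into
#' the invertible range \[0, 1.8 - 1e-6\].
#'
#' @param fv dimensionless force-velocity value(s).
#' @return Normalized velocity(ies) with
#'   `force_velocity(invert_force_velocity(fv)) == fv` to ~1e-10. Vectorized.
#' @export
invert_force_velocity <- function(fv) {
  fv_max <- 2.34 / 1.3
  fv <- pmin(pmax(fv, 0), fv_max - 1e-6)
  ifelse(fv < 1,
         0.3 * (fv - 1) / (fv + 0.3),
         0.039 * (fv - 1) / (2.34 - 1.3 * fv))
}

#' Tendon force from tendon length
#'
#' Piecewise force-strain curve on tendon strain
#' `eps = (lt - lst)/lst`: zero for `eps <= 0` (slack tendon), a quadratic
#' toe region `F0m*k_quad*eps^2` for `0 < eps < eps_knee`, and a linear
#' region `F0m*(k_lin*eps - c_lin)` beyond. Nonnegative and nondecreasing
#' in `lt`; the two branches meet at the knee with a small documented gap
#' (below 0.005*F0m with the default constants).
#'
#' @param lt tendon length(s) (m), >= 0.
#' @param mp a [muscle_params()] object (uses `F0m`, `lst`).
#' @param c a [model_constants()] object.
#' @return Tendon force(s) in N. Vectorized over `lt`.
#' @export
tendon_force <- function(lt, mp, c = model_constants()) {
  stopifnot(inherits(mp, "muscle_params"), all(lt >= 0))
  eps <- (lt - mp$lst) / mp$lst
  ifelse(eps <= 0, 0,
         ifelse(eps < c$eps_knee,
                mp$F0m * c$k_quad * eps^2,
                mp$F0m * (c$k_lin * eps - c$c_lin)))
}

#' Pennation angle from fiber length
#'
#' Constant-thickness pennation model:
#' `phi = asin(l0m*sin(phi0)/lm)`, decreasing in `lm`. Arguments above 1
#' (fiber shorter than the fixed muscle height allows) are clamped, giving
#' `phi = pi/2`, with a warning.
#'
#' @param lm fiber length(s) (m), > 0.
#' @param mp a [muscle_params()] object.
#' @return Pennation angle(s) in radians. Vectorized over `lm`.
#' @export
pennation_angle <- function(lm, mp) {
  stopifnot(inherits(mp, "muscle_params"), all(lm > 0))
  s <- mp$l0m * sin(mp$phi0_rad) / lm
  if (any(s > 1)) {
    warning("fiber shorter than pennation geometry allows; angle clamped to pi/2",
            call. = FALSE)
    s <- pmin(s, 1)
  }
  asin(pmax(s, 0))
}

#' Tendon length from MTU and fiber geometry
#'
#' `lt = lmt - lm*cos(phi)`: the musculotendon length minus the fiber
#' projected onto the tendon line of action.
#'
#' @param lmt musculotendon unit length(s) (m), > 0.
#' @param lm fiber length(s) (m), > 0.
#' @param phi pennation angle(s) (rad).
#' @param muscle,step labels used in the error message when the geometry is
#'   infeasible (negative tendon length).
#' @return Tendon length(s) in m, >= 0.
#' @export
tendon_length <- function(lmt, lm, phi, muscle = "muscle", step = NA) {
  stopifnot(all(lmt > 0), all(lm > 0))
  lt <- lmt - lm * cos(phi)
  if (any(lt < 0))
    stop("infeasible geometry for ", muscle,
         if (!is.na(step)) paste0(" at step ", which(lt < 0)[1]) else "",
         ": tendon length would be negative", call. = FALSE)
  lt
}

#' Activation-dependent optimal fiber length
#'
#' `l0m(a) = l0m*(lambda*(1 - a) + 1)`: the optimal length widens by the
#' fraction `lambda` as activation falls to zero, and equals the nominal
#' `l0m` at full activation.
#'
#' @param a activation(s) in \[0, 1\].
#' @param mp a [muscle_params()] object.
#' @param c a [model_constants()] object.
#' @return Effective optimal fiber length(s) in m. Vectorized over `a`.
#' @export
effective_optimal_length <- function(a, mp, c = model_constants()) {
  stopifnot(all(a >= 0), all(a <= 1))
  mp$l0m * (c$lambda_pct * (1 - a) + 1)
}

# scalar fiber-state evaluation shared by fiber_velocity() and the R
# integration engine; mirrors eval_fiber() in src/forward.cpp
eval_fiber_r <- function(lm, a, lmt, mp, c) {
  s <- min(max(mp$l0m * sin(mp$phi0_rad) / lm, 0), 1)
  phi <- asin(s)
  cphi <- cos(phi)
  lt <- lmt - lm * cphi
  eps <- (lt - mp$lst) / mp$lst
  Ft <- if (eps <= 0) 0
        else if (eps < c$eps_knee) mp$F0m * c$k_quad * eps^2
        else mp$F0m * (c$k_lin * eps - c$c_lin)
  l0_eff <- if (c$scale_l0m) mp$l0m * (c$lambda_pct * (1 - a) + 1) else mp$l0m
  l <- lm / l0_eff
  fA <- if (l < 0.5 || l > 1.5) 0 else max(c$q0 + c$q1 * l + c$q2 * l^2, 0)
  fP <- exp(10 * l - 15)
  den <- fA * a * mp$F0m * cphi
  den_min <- 1e-6 * mp$F0m
  clamp_den <- den < den_min
  den <- max(den, den_min)
  fv <- (Ft - fP * mp$F0m * cphi) / den
  # cap at the fv of lengthening velocity v0m so |vm| <= v0m either way
  fv_cap <- (2.34 + 0.039) / (1.3 + 0.039)
  clamp_fv <- fv < 0 || fv > fv_cap
  fv <- min(max(fv, 0), fv_cap)
  vm <- mp$v0m * (if (fv < 1) 0.3 * (fv - 1) / (fv + 0.3)
                  else 0.039 * (fv - 1) / (2.34 - 1.3 * fv))
  list(vm = vm, fv = fv, fA = fA, fP = fP, phi = phi, Ft = Ft,
       clamp_fv = clamp_fv, clamp_den = clamp_den)
}

#' Instantaneous fiber velocity
#'
#' Solves the Hill force balance for fiber velocity at one instant: the
#' force-velocity scale is recovered as
#' `fv = (Ft - fP(l)*F0m*cos(phi)) / (fA(l)*a*F0m*cos(phi))`, clamped into
#' the invertible range \[0, 1.8), and mapped through
#' [invert_force_velocity()] to `vm = v0m * v_norm`. Normalized length uses
#' the activation-scaled optimal length when `c$scale_l0m` is TRUE.
#' Degenerate denominators (`a` or `fA` near zero) are floored at
#' `1e-6*F0m` and the resulting `fv` clamped, so the computation never
#' blows up mid-integration.
#'
#' @param lm current fiber length (m).
#' @param a current activation in \[0, 1\].
#' @param lmt current musculotendon length (m).
#' @param mp a [muscle_params()] object.
#' @param c a [model_constants()] object.
#' @return Scalar fiber velocity in m/s (negative = shortening), with
#'   attribute `fv` (the clamped force-velocity scale used).
#' @export
fiber_velocity <- function(lm, a, lmt, mp, c = model_constants()) {
  stopifnot(inherits(mp, "muscle_params"), lm > 0, a >= 0, a <= 1)
  st <- eval_fiber_r(lm, a, lmt, mp, c)
  structure(st$vm, fv = st$fv)
}

#' Integrate fiber length through a trial
#'
#' Classic 4th-order Runge-Kutta integration of `dlm/dt = vm`, with `vm`
#' from [fiber_velocity()] at each stage and the activation and MTU-length
#' inputs interpolated linearly at half steps. Emits the full fiber state
#' per timestep: fiber length, velocity, pennation angle, active / passive
#' / total fiber force and tendon force.
#'
#' @param a numeric vector of activations in \[0, 1\] (one per timestep).
#' @param lmt numeric vector of musculotendon lengths (m), same length.
#' @param mp a [muscle_params()] object.
#' @param c a [model_constants()] object.
#' @param dt timestep (s).
#' @param lm0 initial fiber length (m); default `mp$l0m`.
#' @param engine `"cpp"` (compiled fast path, default) or `"r"` (reference
#'   implementation; identical formulas, used for cross-checking).
#' @return A data.frame of class `fiber_state` with columns `t`, `lm`,
#'   `vm`, `phi`, `FAm`, `FPm`, `Fm`, `Ft`, and attributes `n_clamp_fv`,
#'   `n_clamp_den` (clamp-event counts).
#'   If the fiber leaves `(0.25*l0m, 2.5*l0m)` the integration aborts with
#'   an error naming the first bad step.
#' @export
integrate_fiber_length <- function(a, lmt, mp, c = model_constants(),
                                   dt = 1e-3, lm0 = mp$l0m,
                                   engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(mp, "muscle_params"), length(a) == length(lmt),
            dt > 0, lm0 > 0)
  assert_unit_range(a, "activation")
  n <- length(a)
  if (engine == "cpp") {
    res <- .forward_fiber_cpp(a, lmt, dt, mp$F0m, mp$l0m, mp$lst,
                              mp$phi0_rad, mp$v0m, lm0, c$lambda_pct,
                              c$q0, c$q1, c$q2, c$eps_knee, c$k_quad,
                              c$k_lin, c$c_lin, c$scale_l0m)
  } else {
    res <- forward_fiber_r(a, lmt, dt, mp, c, lm0)
  }
  if (res$abort_step > 0)
    stop("fiber length for ", mp$name, " left (0.25, 2.5)*l0m at step ",
         res$abort_step, " (t = ", signif((res$abort_step - 1) * dt, 6),
         " s)", call. = FALSE)
  out <- data.frame(t = (seq_len(n) - 1) * dt, lm = res$lm, vm = res$vm,
                    phi = res$phi, FAm = res$FAm, FPm = res$FPm,
                    Fm = res$Fm, Ft = res$Ft)
  attr(out, "n_clamp_fv") <- res$n_clamp_fv
  attr(out, "n_clamp_den") <- res$n_clamp_den
  class(out) <- c("fiber_state", "data.frame")
  out
}

# pure-R RK4 engine; same stage scheme as the compiled path
forward_fiber_r <- function(a, lmt, dt, mp, c, lm0) {
  n <- length(a)
  lm_out <- vm_out <- phi_out <- FAm <- FPm <- Fm <- Ft <- numeric(n)
  n_clamp_fv <- n_clamp_den <- 0L
  abort_step <- 0L
  lm <- lm0
  lo <- 0.25 * mp$l0m; hi <- 2.5 * mp$l0m
  for (i in seq_len(n)) {
    if (lm <= lo || lm >= hi) { abort_step <- i; break }
    st <- eval_fiber_r(lm, a[i], lmt[i], mp, c)
    n_clamp_fv <- n_clamp_fv + st$clamp_fv
    n_clamp_den <- n_clamp_den + st$clamp_den
    lm_out[i] <- lm; vm_out[i] <- st$vm; phi_out[i] <- st$phi
    FAm[i] <- st$fA * st$fv * a[i] * mp$F0m
    FPm[i] <- st$fP * mp$F0m
    Fm[i] <- FAm[i] + FPm[i]
    Ft[i] <- st$Ft
    if (i == n) break
    a_half <- 0.5 * (a[i] + a[i + 1])
    lmt_half <- 0.5 * (lmt[i] + lmt[i + 1])
    k1 <- st$vm
    k2 <- eval_fiber_r(lm + 0.5 * dt * k1, a_half, lmt_half, mp, c)$vm
    k3 <- eval_fiber_r(lm + 0.5 * dt * k2, a_half, lmt_half, mp, c)$vm
    k4 <- eval_fiber_r(lm + dt * k3, a[i + 1], lmt[i + 1], mp, c)$vm
    lm <- lm + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(lm = lm_out, vm = vm_out, phi = phi_out, FAm = FAm, FPm = FPm,
       Fm = Fm, Ft = Ft, abort_step = abort_step,
       n_clamp_fv = n_clamp_fv, n_clamp_den = n_clamp_den)
}

#' Write a fiber-state series to CSV
#'
#' Columns `t, lm, vm, phi_deg, FAm, FPm, Ft` (angles in degrees at the
#' I/O boundary).
#'
#' @param state a `fiber_state` from [integrate_fiber_length()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fiber_state_csv <- function(state, path) {
  stopifnot(inherits(state, "fiber_state"))
  df <- data.frame(t = state$t, lm = state$lm, vm = state$vm,
                   phi_deg = state$phi * 180 / pi,
                   FAm = state$FAm, FPm = state$FPm, Ft = state$Ft)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
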