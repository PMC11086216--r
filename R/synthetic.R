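#' Specification of one synthetic ankle-movement trial
#'
#' Describes a single movement trial for the synthetic generator: which
#' movement, its range of motion, duration, sampling rate, noise levels and
#' RNG seed. The five standard movements and their default ranges of motion
#' are dorsiflexion 30, plantarflexion 45, inversion 15, internal rotation
#' 35 and external rotation 25 degrees; plantarflexion and external
#' rotation sweep the negative direction of their DOF axis.
#'
#' @param movement one of `"dorsiflexion"`, `"plantarflexion"`,
#'   `"inversion"`, `"internal_rotation"`, `"external_rotation"`.
#' @param rom_deg signed range of motion in degrees; default is the
#'   movement's standard value.
#' @param duration trial duration in s (default 5).
#' @param sample_rate sampling rate in Hz (default 1000).
#' @param torque_noise_sd additive Gaussian torque noise SD, as a fraction
#'   of the trial's peak absolute torque (default 0.05).
#' @param emg_noise_sd additive truncated-Gaussian EMG noise SD, absolute
#'   (default 0.02).
#' @param emg_baseline resting muscle tone added to every EMG channel
#'   (default 0.02); keeps activations away from the degenerate zero-drive
#'   regime of the fiber-velocity solution.
#' @param seed RNG seed for this trial.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(movement, rom_deg = NULL, duration = 5,
                       sample_rate = 1000, torque_noise_sd = 0.05,
                       emg_noise_sd = 0.02, emg_baseline = 0.02,
                       seed = 1) {
  movement <- match.arg(movement, MOVEMENTS$movement)
  row <- MOVEMENTS[MOVEMENTS$movement == movement, ]
  if (is.null(rom_deg)) rom_deg <- row$rom_deg
  if (rom_deg == 0) stop("rom_deg must be nonzero", call. = FALSE)
  stopifnot(duration > 0, sample_rate > 0, torque_noise_sd >= 0,
            emg_noise_sd >= 0, emg_baseline >= 0)
  structure(list(movement = movement, dof = row$dof, rom_deg = rom_deg,
                 duration = duration, sample_rate = sample_rate,
                 torque_noise_sd = torque_noise_sd,
                 emg_noise_sd = emg_noise_sd, emg_baseline = emg_baseline,
                 seed = as.integer(seed)),
            class = "trial_spec")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf(
    "<trial_spec> %s (%s), ROM %g deg, %g s @ %g Hz, noise (torque %g, emg %g), seed %d\n",
    x$movement, x$dof, x$rom_deg, x$duration, x$sample_rate,
    x$torque_noise_sd, x$emg_noise_sd, x$seed))
  invisible(x)
}

# default agonist weighting of the EMG envelopes per movement: peak
# envelope value per muscle, qualitatively matching the known muscle
# contributions (tibialis anterior dominates dorsiflexion, triceps surae
# dominates plantarflexion and inversion, soleus nearly silent in internal
# rotation, medial gastrocnemius nearly silent in external rotation); the
# submaximal magnitudes emulate damped rehabilitation-bench movements
default_emg_weights <- function() {
  w <- rbind(
    dorsiflexion      = c(ta = 0.22, sol = 0.02, gm = 0.05, gl = 0.05),
    plantarflexion    = c(ta = 0.04, sol = 0.12, gm = 0.13, gl = 0.11),
    inversion         = c(ta = 0.06, sol = 0.11, gm = 0.11, gl = 0.09),
    internal_rotation = c(ta = 0.08, sol = 0.02, gm = 0.11, gl = 0.08),
    external_rotation = c(ta = 0.08, sol = 0.06, gm = 0.02, gl = 0.11))
  w
}

#' Generate one synthetic trial
#'
#' Builds a complete trial from known ground truth: the joint angle is a
#' half-sine sweep from neutral to the range of motion and back; the EMG
#' envelopes are smooth agonist-weighted bell curves plus truncated
#' Gaussian noise, clipped to \[0, 1\]; the torque is the forward model
#' evaluated at the true parameters plus Gaussian noise scaled to the peak
#' torque. Deterministic given `spec$seed`.
#'
#' @param spec a [trial_spec()].
#' @param true_params named list of four [muscle_params()]; default the
#'   `"subject"` set of [ankle_muscle_defaults()], so synthetic subjects
#'   differ from the anatomical initial guess the way a real subject would.
#' @param geoms named list of [geometry_poly()]; default
#'   [default_ankle_geometry()] for the spec's DOF.
#' @param act an [activation_params()]; default at the spec's sample rate.
#' @param const a [model_constants()].
#' @param emg_weights named numeric vector of per-muscle envelope peaks;
#'   default the movement's row of the package weight table.
#' @return An object of class `trial`: list with `t`, `fs`, `movement`,
#'   `dof`, `theta` (rad), `emg` (n x 4 matrix in \[0, 1\]), `torque`
#'   (N m), and `provenance` (spec, true parameters, seed, noiseless
#'   torque).
#' @export
generate_trial <- function(spec, true_params = ankle_muscle_defaults("subject"),
                           geoms = default_ankle_geometry(spec$dof),
                           act = activation_params(sample_rate = spec$sample_rate),
                           const = model_constants(),
                           emg_weights = default_emg_weights()[spec$movement, ]) {
  stopifnot(inherits(spec, "trial_spec"))
  set.seed(spec$seed)
  n <- round(spec$duration * spec$sample_rate) + 1
  t <- (seq_len(n) - 1) / spec$sample_rate
  theta <- spec$rom_deg * pi / 180 * sin(pi * t / spec$duration)
  bell <- sin(pi * t / spec$duration)^2
  emg <- sapply(MUSCLES, function(m) {
    e <- spec$emg_baseline + emg_weights[[m]] * bell +
      rnorm(n, 0, spec$emg_noise_sd)
    pmin(pmax(e, 0), 1)
  })
  trial <- structure(list(t = t, fs = spec$sample_rate,
                          movement = spec$movement, dof = spec$dof,
                          theta = theta, emg = emg, torque = numeric(n),
                          provenance = list(spec = spec, seed = spec$seed)),
                     class = "trial")
  clean <- tryCatch(
    predict_torque(trial, true_params, geoms = geoms, act = act,
                   const = const),
    error = function(e) stop("forward model failed for spec [", spec$movement,
                             ", seed ", spec$seed, "]: ", conditionMessage(e),
                             call. = FALSE))
  noise_sd <- spec$torque_noise_sd * max(abs(clean))
  trial$torque <- as.numeric(clean) + rnorm(n, 0, noise_sd)
  trial$provenance$true_params <- true_params
  trial$provenance$torque_clean <- as.numeric(clean)
  trial$provenance$torque_noise_sd_abs <- noise_sd
  trial
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf(
    "<trial> %s (%s): %d samples @ %g Hz, theta in [%.1f, %.1f] deg, torque in [%.2f, %.2f] N m\n",
    x$movement, x$dof, length(x$t), x$fs, min(x$theta) * 180 / pi,
    max(x$theta) * 180 / pi, min(x$torque), max(x$torque)))
  invisible(x)
}

#' Generate the default five-movement scenario
#'
#' Emulates the full measurement protocol: each of the five standard
#' movements repeated `n_reps` times (three in the protocol), each
#' repetition with its own noise realization. Repetitions `1..n_reps-1` are
#' marked for calibration and the last repetition of each movement is held
#' out for evaluation.
#'
#' @param seed master seed; per-trial seeds are derived from it (and kept
#'   well below 2^31).
#' @param n_reps repetitions per movement (default 3).
#' @param duration,sample_rate,torque_noise_sd,emg_noise_sd passed to
#'   [trial_spec()].
#' @param movements character vector of movements (default all five).
#' @param ... passed to [generate_trial()] (e.g. `true_params`).
#' @return A list with elements `trials` (list of [generate_trial()]
#'   outputs), `role` (character, `"train"` / `"test"` per trial) and
#'   `seed`.
#' @export
ankle_scenario <- function(seed = 1, n_reps = 3, duration = 5,
                           sample_rate = 1000, torque_noise_sd = 0.05,
                           emg_noise_sd = 0.02,
                           movements = MOVEMENTS$movement, ...) {
  stopifnot(n_reps >= 2)
  trials <- list()
  role <- character(0)
  k <- 0
  for (mv in movements) {
    for (rep in seq_len(n_reps)) {
      k <- k + 1
      sp <- trial_spec(mv, duration = duration, sample_rate = sample_rate,
                       torque_noise_sd = torque_noise_sd,
                       emg_noise_sd = emg_noise_sd,
                       seed = (seed %% 20000L) * 1000L + k)
      trials[[k]] <- generate_trial(sp, ...)
      role[k] <- if (rep < n_reps) "train" else "test"
    }
  }
  list(trials = trials, role = role, seed = seed)
}

#' Write / read a trial as CSV
#'
#' Plain CSV with columns `t, theta_deg, emg_ta, emg_sol, emg_gm, emg_gl,
#' torque_Nm`, preceded by `#`-prefixed header lines recording the
#' movement, DOF, sampling rate and seed. Round-trips all series exactly
#' (values are written with full precision).
#'
#' @param trial a `trial`.
#' @param path file path.
#' @return `read_trial` returns a `trial`; `write_trial` returns `path`
#'   invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# movement: %s", trial$movement),
               sprintf("# dof: %s", trial$dof),
               sprintf("# fs: %.10g", trial$fs),
               sprintf("# seed: %s",
                       if (is.null(trial$provenance$seed)) "NA"
                       else trial$provenance$seed)), con)
  df <- data.frame(t = trial$t, theta_deg = trial$theta * 180 / pi,
                   emg_ta = trial$emg[, "ta"], emg_sol = trial$emg[, "sol"],
                   emg_gm = trial$emg[, "gm"], emg_gl = trial$emg[, "gl"],
                   torque_Nm = trial$torque)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(df, 1, function(r)
    paste(sprintf("%.15g", r), collapse = ",")), con)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*$", "", kv))
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 3) stop("truncated trial file: ", path, call. = FALSE)
  cols <- strsplit(body[1], ",")[[1]]
  need <- c("t", "theta_deg", "emg_ta", "emg_sol", "emg_gm", "emg_gl",
            "torque_Nm")
  if (!identical(cols, need))
    stop("unexpected columns in ", path, " (line 1 of data)", call. = FALSE)
  rows <- strsplit(body[-1], ",")
  bad <- which(lengths(rows) != length(need))
  if (length(bad))
    stop("malformed CSV in ", path, ": line ",
         length(meta_lines) + 1 + bad[1], " has ", lengths(rows)[bad[1]],
         " fields, expected ", length(need), call. = FALSE)
  m <- matrix(as.numeric(unlist(rows)), ncol = length(need), byrow = TRUE)
  if (anyNA(m))
    stop("non-numeric values in ", path, call. = FALSE)
  colnames(m) <- need
  t <- m[, "t"]
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("non-uniform time column in ", path, call. = FALSE)
  emg <- m[, c("emg_ta", "emg_sol", "emg_gm", "emg_gl")]
  colnames(emg) <- MUSCLES
  assert_unit_range(emg, "EMG envelopes")
  structure(list(t = t, fs = 1 / dt[1],
                 movement = meta$movement %||% "unknown",
                 dof = meta$dof %||% "sagittal",
                 theta = m[, "theta_deg"] * pi / 180, emg = emg,
                 torque = m[, "torque_Nm"],
                 provenance = list(seed = suppressWarnings(
                   as.integer(meta$seed %||% NA)))),
            class = "trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
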