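#' Predict joint torque for a trial
#'
#' Deterministic composition of the three model stages: EMG envelopes to
#' muscle activations (delayed recursion + exponential shaping), Hill-type
#' fiber-state integration per muscle, and moment-arm-weighted torque
#' summation.
#'
#' @param trial a `trial` (from [generate_trial()] or [read_trial()]).
#' @param params named list of four [muscle_params()].
#' @param geoms named list of [geometry_poly()] for the trial's DOF;
#'   default [default_ankle_geometry()].
#' @param act an [activation_params()]; default at the trial's sampling
#'   rate.
#' @param const a [model_constants()].
#' @param lm0 optional named numeric of initial fiber lengths (m); default
#'   each muscle's `l0m`.
#' @param detail return the full per-muscle breakdown instead of just the
#'   torque series (default FALSE).
#' @return If `detail = FALSE`, a numeric torque series (N m) with
#'   attribute `n_clamp` (total clamp events). Otherwise a list with
#'   `torque`, per-muscle `contributions` (n x 4 matrix of r_i*F_i),
#'   `activation` (n x 4), `fibers` (list of fiber states) and `n_clamp`.
#' @export
predict_torque <- function(trial, params, geoms = default_ankle_geometry(trial$dof),
                           act = activation_params(sample_rate = trial$fs),
                           const = model_constants(), lm0 = NULL,
                           detail = FALSE) {
  stopifnot(inherits(trial, "trial"))
  if (!all(MUSCLES %in% names(params)))
    stop("params must cover muscles: ", paste(MUSCLES, collapse = ", "),
         call. = FALSE)
  if (!all(MUSCLES %in% names(geoms)))
    stop("missing geometry for muscle(s): ",
         paste(setdiff(MUSCLES, names(geoms)), collapse = ", "),
         call. = FALSE)
  dt <- 1 / trial$fs
  n <- length(trial$t)
  acts <- sapply(MUSCLES, function(m) {
    e <- signal_series(trial$t, trial$emg[, m])
    emg_to_activation(e, act)$values
  })
  contrib <- matrix(0, n, length(MUSCLES),
                    dimnames = list(NULL, MUSCLES))
  fibers <- list()
  n_clamp <- 0L
  for (m in MUSCLES) {
    lmt <- mtu_length(trial$theta, geoms[[m]], warn = FALSE)
    st <- tryCatch(
      integrate_fiber_length(acts[, m], lmt, params[[m]], const, dt = dt,
                             lm0 = if (is.null(lm0)) params[[m]]$l0m
                                   else lm0[[m]]),
      error = function(e) stop("hill_mtu stage failed for ", m, ": ",
                               conditionMessage(e), call. = FALSE))
    fibers[[m]] <- st
    n_clamp <- n_clamp + attr(st, "n_clamp_fv") + attr(st, "n_clamp_den")
    contrib[, m] <- moment_arm(trial$theta, geoms[[m]]) * st$Ft
  }
  torque <- rowSums(contrib)
  if (!detail) {
    attr(torque, "n_clamp") <- n_clamp
    return(torque)
  }
  list(torque = torque, contributions = contrib, activation = acts,
       fibers = fibers, n_clamp = n_clamp)
}

#' Root-mean-square error between two torque series
#'
#' `sqrt(mean((predicted - measured)^2))`.
#'
#' @param predicted,measured numeric series of equal length on the same
#'   time base.
#' @return RMSE in the series' units (N m for torque).
#' @export
rmse <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("series lengths differ (", length(predicted), " vs ",
         length(measured), ")", call. = FALSE)
  sqrt(mean((as.numeric(predicted) - as.numeric(measured))^2))
}

#' Per-muscle torque contributions and activation summary
#'
#' Runs one forward prediction and reports each muscle's moment-arm-weighted
#' tendon-force series (signed N m; the four series sum exactly to the
#' predicted joint torque) together with its mean activation.
#'
#' @inheritParams predict_torque
#' @return A list with `contributions` (n x 4 signed torque matrix, N m),
#'   `total` (their row sum), `mean_activation` (named numeric),
#'   `mean_abs_contribution` (named numeric, N m), and `n_clamp` (clamp
#'   events during the forward run).
#' @export
muscle_contributions <- function(trial, params,
                                 geoms = default_ankle_geometry(trial$dof),
                                 act = activation_params(sample_rate = trial$fs),
                                 const = model_constants(), lm0 = NULL) {
  det <- predict_torque(trial, params, geoms, act, const, lm0,
                        detail = TRUE)
  list(contributions = det$contributions,
       total = det$torque,
       mean_activation = colMeans(det$activation),
       mean_abs_contribution = colMeans(abs(det$contributions)),
       n_clamp = det$n_clamp)
}

#' Evaluate a parameter set on a set of trials
#'
#' Computes per-trial torque RMSE, per-muscle mean activation and mean
#' absolute torque contribution, and the global mean and SD of RMSE across
#' trials. Clamp events (the model's numerical-health signal) are counted
#' per trial.
#'
#' @param trials list of `trial` objects.
#' @param params named list of four [muscle_params()].
#' @param geoms_by_dof named list of geometry sets keyed by DOF; default
#'   the package defaults for all three DOFs.
#' @param act_fn function(fs) returning [activation_params()]; default the
#'   package defaults at each trial's sampling rate.
#' @param const a [model_constants()].
#' @return An object of class `evaluation_report`: list with `per_trial`
#'   (data.frame: movement, dof, rmse, peak_torque, n_clamp),
#'   `mean_activation` and `mean_abs_contribution` (trial x muscle
#'   matrices), `rmse_mean`, `rmse_sd`.
#' @export
evaluate_trials <- function(trials, params,
                            geoms_by_dof = default_geometry_set(),
                            act_fn = function(fs) activation_params(sample_rate = fs),
                            const = model_constants()) {
  stopifnot(length(trials) >= 1)
  per <- data.frame(movement = character(0), dof = character(0),
                    rmse = numeric(0), peak_torque = numeric(0),
                    n_clamp = integer(0))
  act_mat <- contrib_mat <- NULL
  for (tr in trials) {
    mc <- muscle_contributions(tr, params, geoms = geoms_by_dof[[tr$dof]],
                               act = act_fn(tr$fs), const = const)
    per <- rbind(per, data.frame(
      movement = tr$movement, dof = tr$dof,
      rmse = rmse(mc$total, tr$torque),
      peak_torque = max(abs(tr$torque)),
      n_clamp = mc$n_clamp))
    act_mat <- rbind(act_mat, mc$mean_activation)
    contrib_mat <- rbind(contrib_mat, mc$mean_abs_contribution)
  }
  rownames(act_mat) <- rownames(contrib_mat) <- per$movement
  structure(list(per_trial = per, mean_activation = act_mat,
                 mean_abs_contribution = contrib_mat,
                 rmse_mean = mean(per$rmse), rmse_sd = sd(per$rmse)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$per_trial, row.names = FALSE)
  cat(sprintf("RMSE across trials: %.3f +/- %.3f N m\n",
              x$rmse_mean, if (is.na(x$rmse_sd)) 0 else x$rmse_sd))
  invisible(x)
}

#' Default geometry sets for the three ankle DOFs
#'
#' @return Named list `sagittal` / `coronal` / `horizontal`, each a named
#'   list of four [geometry_poly()].
#' @export
default_geometry_set <- function() {
  out <- lapply(DOFS, default_ankle_geometry)
  names(out) <- DOFS
  out
}

#' Write a machine-readable run record
#'
#' Records what produced a set of outputs: package version, timestamp,
#' seeds, configuration values and input-file hashes. JSON, one file per
#' run.
#'
#' @param path output file.
#' @param seed seed(s) used.
#' @param config named list of configuration values (must be
#'   JSON-serializable).
#' @param inputs character vector of input file paths to hash (md5).
#' @return `path`, invisibly.
#' @export
write_run_record <- function(path, seed, config = list(),
                             inputs = character(0)) {
  rec <- list(package = "emgtorque",
              version = as.character(packageVersion("emgtorque")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config,
              input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
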