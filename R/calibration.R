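#' Calibration bounds for the 16 physiological parameters
#'
#' The calibrated set is (`F0m`, `l0m`, `lst`, `phi0`) for each of the four
#' muscles. Bounds are centered on an initial parameter set with a
#' per-class fractional half-width: +/-50% for maximum force, optimal fiber
#' length and pennation angle, +/-15% for tendon slack length.
#'
#' @param initial named list of four [muscle_params()] (default the
#'   anatomical set of [ankle_muscle_defaults()]).
#' @param frac named numeric of fractional half-widths per parameter class
#'   (defaults `F0m = 0.5, l0m = 0.5, lst = 0.15, phi0 = 0.5`).
#' @return An object of class `parameter_bounds`: a data.frame with one row
#'   per parameter (`param`, `muscle`, `field`, `initial`, `lower`,
#'   `upper`).
#' @examples
#' b <- parameter_bounds()
#' b[b$param == "ta.F0m", ] # 1270 N, bounds [635, 1905]
#' @export
parameter_bounds <- function(initial = ankle_muscle_defaults("anatomical"),
                             frac = c(F0m = 0.5, l0m = 0.5, lst = 0.15,
                                      phi0 = 0.5)) {
  fields <- c("F0m", "l0m", "lst", "phi0")
  stopifnot(all(fields %in% names(frac)), all(frac > 0), all(frac < 1))
  rows <- do.call(rbind, lapply(MUSCLES, function(m) {
    p <- initial[[m]]
    data.frame(param = paste(m, fields, sep = "."), muscle = m,
               field = fields,
               initial = c(p$F0m, p$l0m, p$lst, p$phi0),
               stringsAsFactors = FALSE)
  }))
  rows$lower <- rows$initial * (1 - frac[rows$field])
  rows$upper <- rows$initial * (1 + frac[rows$field])
  stopifnot(all(rows$lower < rows$initial), all(rows$initial < rows$upper))
  structure(rows, class = c("parameter_bounds", "data.frame"))
}

#' Convert between muscle-parameter lists and 16-vectors
#'
#' The calibration code works on a flat named 16-vector ordered
#' `ta.F0m, ta.l0m, ta.lst, ta.phi0, sol.F0m, ...`. `v0m` is recomputed as
#' `10*l0m` so velocity scaling follows the calibrated optimal length.
#'
#' @param params named list of four [muscle_params()].
#' @return `param_vector` returns a named numeric 16-vector;
#'   `params_from_vector` returns a named list of `muscle_params`.
#' @export
param_vector <- function(params) {
  v <- unlist(lapply(MUSCLES, function(m) {
    p <- params[[m]]
    c(p$F0m, p$l0m, p$lst, p$phi0)
  }))
  names(v) <- as.character(t(outer(MUSCLES, c("F0m", "l0m", "lst", "phi0"),
                                   paste, sep = ".")))
  v
}

#' @rdname param_vector
#' @param v named numeric 16-vector.
#' @export
params_from_vector <- function(v) {
  stopifnot(length(v) == 16)
  out <- lapply(seq_along(MUSCLES), function(i) {
    x <- v[(i - 1) * 4 + 1:4]
    muscle_params(x[1], x[2], x[3], x[4], name = MUSCLES[i])
  })
  names(out) <- MUSCLES
  out
}

#' Genetic-algorithm configuration
#'
#' Binary-coded GA with roulette selection, single-point crossover and
#' positional (bit-flip) mutation, plus elitist carryover of the single
#' best individual.
#'
#' @param population population size (default 100).
#' @param generations maximum generations (default 150).
#' @param crossover_prob single-point crossover probability (default 0.6).
#' @param mutation_prob mutation probability (default 0.1). In
#'   `mutation_mode = "individual"` (default) this is the probability that
#'   an individual has one random bit flipped; in `"per_bit"` every bit
#'   flips independently with this probability.
#' @param bits_per_param bits of the linear quantization per parameter
#'   (default 16, minimum 8).
#' @param mutation_mode `"individual"` or `"per_bit"`.
#' @param seed RNG seed (mandatory field of every calibration result).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 100, generations = 150,
                      crossover_prob = 0.6, mutation_prob = 0.1,
                      bits_per_param = 16,
                      mutation_mode = c("individual", "per_bit"),
                      seed = 1) {
  stopifnot(population >= 4, generations >= 1, bits_per_param >= 8,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 bits_per_param = as.integer(bits_per_param),
                 mutation_mode = match.arg(mutation_mode),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Encode / decode parameters as a bitstring
#'
#' Linear quantization of each parameter into `bits` bits over its
#' `[lower, upper]` interval: the all-zero codeword is the lower bound, the
#' all-one codeword the upper bound, and decode(encode(p)) differs from `p`
#' by at most one quantization step `(upper - lower)/(2^bits - 1)` per
#' parameter. Out-of-bound values are clamped before encoding.
#'
#' @param p named numeric 16-vector (see [param_vector()]).
#' @param bounds a [parameter_bounds()].
#' @param bits bits per parameter.
#' @return `encode_params` returns an integer 0/1 vector of length
#'   `16*bits` (least significant bit first within each parameter);
#'   `decode_params` returns a named numeric 16-vector.
#' @export
encode_params <- function(p, bounds, bits = 16) {
  stopifnot(length(p) == nrow(bounds))
  p <- pmin(pmax(p, bounds$lower), bounds$upper)
  steps <- 2^bits - 1
  q <- round((p - bounds$lower) / (bounds$upper - bounds$lower) * steps)
  unname(unlist(lapply(q, function(x) as.integer(intToBits(x)[1:bits]))))
}

#' @rdname encode_params
#' @param bitstring integer 0/1 vector of length `16*bits`.
#' @export
decode_params <- function(bitstring, bounds, bits = 16) {
  stopifnot(length(bitstring) == nrow(bounds) * bits)
  steps <- 2^bits - 1
  m <- matrix(bitstring, nrow = bits)
  q <- as.numeric(2^(0:(bits - 1)) %*% m)
  v <- bounds$lower + q / steps * (bounds$upper - bounds$lower)
  names(v) <- bounds$param
  v
}

# precompute everything about a trial that the 16 parameters do not touch:
# activations, MTU lengths and moment arms per muscle, measured torque
prepare_trial_context <- function(trial, geoms, act, const) {
  a <- sapply(MUSCLES, function(m)
    emg_to_activation(signal_series(trial$t, trial$emg[, m]), act)$values)
  lmt <- sapply(MUSCLES, function(m)
    mtu_length(trial$theta, geoms[[m]], warn = FALSE))
  r <- sapply(MUSCLES, function(m) moment_arm(trial$theta, geoms[[m]]))
  list(a = a, lmt = lmt, r = r, torque = trial$torque, dt = 1 / trial$fs)
}

# squared-error objective on prepared contexts; forward-model aborts give a
# large finite penalty so the GA can continue
objective_from_contexts <- function(v, ctxs, const, penalty = 1e12) {
  total <- 0
  for (ctx in ctxs) {
    pred <- numeric(length(ctx$torque))
    for (i in seq_along(MUSCLES)) {
      x <- v[(i - 1) * 4 + 1:4]
      res <- .forward_fiber_cpp(ctx$a[, i], ctx$lmt[, i], ctx$dt,
                                x[1], x[2], x[3], x[4] * pi / 180,
                                10 * x[2], x[2], const$lambda_pct,
                                const$q0, const$q1, const$q2,
                                const$eps_knee, const$k_quad, const$k_lin,
                                const$c_lin, const$scale_l0m)
      if (res$abort_step > 0) return(penalty)
      pred <- pred + ctx$r[, i] * res$Ft
    }
    total <- total + sum((ctx$torque - pred)^2)
  }
  total
}

#' Torque-matching objective for a parameter set
#'
#' Runs the full forward model (activation -> Hill muscle-tendon mechanics
#' -> geometry) on every trial and returns the sum over trials and sampling
#' points of the squared difference between measured and predicted torque.
#' A forward-model abort (fiber length out of range) yields a large finite
#' penalty (1e12) instead of an error, so an optimizer can continue.
#'
#' @param params named list of four [muscle_params()] or a named numeric
#'   16-vector (see [param_vector()]).
#' @param trials list of `trial` objects.
#' @param geoms_by_dof named list of geometry sets keyed by DOF.
#' @param act_fn function(fs) returning [activation_params()].
#' @param const a [model_constants()].
#' @return Nonnegative scalar (N^2 m^2 summed over samples).
#' @export
calibration_objective <- function(params, trials,
                                  geoms_by_dof = default_geometry_set(),
                                  act_fn = function(fs) activation_params(sample_rate = fs),
                                  const = model_constants()) {
  v <- if (is.list(params)) param_vector(params) else params
  stopifnot(length(v) == 16)
  ctxs <- lapply(trials, function(tr)
    prepare_trial_context(tr, geoms_by_dof[[tr$dof]], act_fn(tr$fs), const))
  objective_from_contexts(v, ctxs, const)
}

#' Calibrate the 16 parameters with a genetic algorithm
#'
#' Binary-coded GA minimizing [calibration_objective()] within
#' [parameter_bounds()]: a seeded random population within bounds; each
#' generation computes fitness `1/(1 + objective)` for roulette selection,
#' applies single-point crossover and positional mutation, and carries the
#' best-ever individual over unchanged (elitism), so the best-so-far
#' objective trace is nonincreasing. Aborts with a diagnostic if every
#' individual is penalized (infeasible forward model) for 5 consecutive
#' generations.
#'
#' @param trials list of `trial` objects (the calibration set).
#' @param bounds a [parameter_bounds()].
#' @param ga a [ga_config()].
#' @param geoms_by_dof named list of geometry sets keyed by DOF.
#' @param act_fn function(fs) returning [activation_params()].
#' @param const a [model_constants()].
#' @param verbose print progress every 10 generations.
#' @return An object of class `calibration_result`: list with
#'   `best_params` (named 16-vector), `params` (list of
#'   [muscle_params()]), `objective` (best objective value),
#'   `objective_trace` (best-so-far per generation, nonincreasing),
#'   `rmse_per_trial` (torque RMSE on each calibration trial at the
#'   optimum), `seed`, and `ga` (the configuration).
#' @export
run_ga <- function(trials, bounds = parameter_bounds(), ga = ga_config(),
                   geoms_by_dof = default_geometry_set(),
                   act_fn = function(fs) activation_params(sample_rate = fs),
                   const = model_constants(), verbose = FALSE) {
  stopifnot(length(trials) >= 1, inherits(ga, "ga_config"))
  set.seed(ga$seed)
  ctxs <- lapply(trials, function(tr)
    prepare_trial_context(tr, geoms_by_dof[[tr$dof]], act_fn(tr$fs), const))
  bits <- ga$bits_per_param
  nbits <- nrow(bounds) * bits
  pop <- matrix(sample(0:1, ga$population * nbits, replace = TRUE),
                nrow = ga$population)
  penalty <- 1e12
  eval_pop <- function(pop) {
    apply(pop, 1, function(bs)
      objective_from_contexts(decode_params(bs, bounds, bits), ctxs, const,
                              penalty))
  }
  obj <- eval_pop(pop)
  best_i <- which.min(obj)
  best_bits <- pop[best_i, ]
  best_obj <- obj[best_i]
  trace <- numeric(ga$generations)
  n_all_penalized <- 0
  for (gen in seq_len(ga$generations)) {
    if (all(obj >= penalty)) {
      n_all_penalized <- n_all_penalized + 1
      if (n_all_penalized >= 5)
        stop("calibration aborted: entire population infeasible for 5 ",
             "consecutive generations", call. = FALSE)
    } else n_all_penalized <- 0
    fitness <- 1 / (1 + obj)
    idx <- sample.int(ga$population, ga$population, replace = TRUE,
                      prob = fitness / sum(fitness))
    newpop <- pop[idx, , drop = FALSE]
    # single-point crossover on consecutive pairs
    for (i in seq(1, ga$population - 1, by = 2)) {
      if (runif(1) < ga$crossover_prob) {
        cut <- sample.int(nbits - 1, 1)
        tail1 <- newpop[i, (cut + 1):nbits]
        newpop[i, (cut + 1):nbits] <- newpop[i + 1, (cut + 1):nbits]
        newpop[i + 1, (cut + 1):nbits] <- tail1
      }
    }
    # positional mutation
    if (ga$mutation_mode == "individual") {
      for (i in seq_len(ga$population)) {
        if (runif(1) < ga$mutation_prob) {
          j <- sample.int(nbits, 1)
          newpop[i, j] <- 1L - newpop[i, j]
        }
      }
    } else {
      flip <- matrix(runif(ga$population * nbits) < ga$mutation_prob,
                     nrow = ga$population)
      newpop[flip] <- 1L - newpop[flip]
    }
    # elitism: the best-ever individual survives unchanged
    newpop[1, ] <- best_bits
    pop <- newpop
    obj <- eval_pop(pop)
    gi <- which.min(obj)
    if (obj[gi] < best_obj) {
      best_obj <- obj[gi]
      best_bits <- pop[gi, ]
    }
    trace[gen] <- best_obj
    if (verbose && gen %% 10 == 0)
      message("generation ", gen, ": best objective ", signif(best_obj, 6))
  }
  best_v <- decode_params(best_bits, bounds, bits)
  best_params <- params_from_vector(best_v)
  rmse_per_trial <- vapply(trials, function(tr) {
    rmse(predict_torque(tr, best_params,
                        geoms = geoms_by_dof[[tr$dof]],
                        act = act_fn(tr$fs), const = const),
         tr$torque)
  }, 1.0)
  structure(list(best_params = best_v, params = best_params,
                 objective = best_obj, objective_trace = trace,
                 rmse_per_trial = rmse_per_trial, seed = ga$seed, ga = ga,
                 bounds = bounds),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> objective %.6g after %d generations (seed %d)\n",
    x$objective, length(x$objective_trace), x$seed))
  cat("  RMSE on calibration trials:",
      paste(sprintf("%.3f", x$rmse_per_trial), collapse = ", "), "N m\n")
  m <- matrix(x$best_params, nrow = 4,
              dimnames = list(c("F0m", "l0m", "lst", "phi0"), MUSCLES))
  print(round(m, 4))
  invisible(x)
}

#' Write a calibration result as structured text + trace CSV
#'
#' Writes the optimized parameter set as a muscle config (see
#' [write_muscle_config()]) and the objective trace as a two-column CSV
#' `generation, best_objective`.
#'
#' @param result a `calibration_result`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_calibration_result <- function(result, dir) {
  stopifnot(inherits(result, "calibration_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_muscle_config(result$params, file.path(dir, "calibrated_params.txt"))
  write.csv(data.frame(generation = seq_along(result$objective_trace),
                       best_objective = result$objective_trace),
            file.path(dir, "objective_trace.csv"), row.names = FALSE)
  writeLines(c(sprintf("objective: %.10g", result$objective),
               sprintf("seed: %d", result$seed),
               sprintf("rmse_per_trial: %s",
                       paste(sprintf("%.6g", result$rmse_per_trial),
                             collapse = " "))),
            file.path(dir, "summary.txt"))
  invisible(dir)
}
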