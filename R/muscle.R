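#' Per-muscle physiological parameters
#'
#' The constants of one muscle-tendon unit in the Hill model. Four of them
#' (`F0m`, `l0m`, `lst`, `phi0`) form the calibrated set; `v0m` is fixed
#' relative to `l0m` by convention because contraction speed has little
#' effect on the computed torque.
#'
#' @param F0m maximum isometric fiber force (N).
#' @param l0m optimal fiber length (m).
#' @param lst tendon slack (relaxation) length (m).
#' @param phi0 pennation angle at optimal fiber length (degrees, in
#'   \[0, 45\]).
#' @param v0m maximum contraction velocity (m/s); default `10 * l0m` per
#'   second, the standard musculoskeletal convention.
#' @param name muscle label.
#' @return An object of class `muscle_params`.
#' @examples
#' muscle_params(1270, 0.031, 0.31, 12, name = "ta")
#' @export
muscle_params <- function(F0m, l0m, lst, phi0, v0m = 10 * l0m,
                          name = "muscle") {
  if (F0m <= 0 || l0m <= 0 || lst <= 0 || v0m <= 0)
    stop("F0m, l0m, lst, v0m must all be strictly positive", call. = FALSE)
  if (phi0 < 0 || phi0 > 45)
    stop("phi0 must lie in [0, 45] degrees", call. = FALSE)
  structure(list(F0m = F0m, l0m = l0m, lst = lst, phi0 = phi0,
                 phi0_rad = phi0 * pi / 180, v0m = v0m, name = name),
            class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf(
    "<muscle_params> %s: F0m=%g N, l0m=%g m, lst=%g m, phi0=%g deg, v0m=%g m/s\n",
    x$name, x$F0m, x$l0m, x$lst, x$phi0, x$v0m))
  invisible(x)
}

#' Default ankle muscle parameter sets
#'
#' Per-muscle parameters for the four lower-leg muscles driving the ankle:
#' tibialis anterior (`ta`), soleus (`sol`), medial (`gm`) and lateral
#' (`gl`) gastrocnemius.
#'
#' Three sets are shipped. `"anatomical"`: the literature-derived initial
#' values used as the calibration starting point and bound centers.
#' `"subject"`: the anatomical values perturbed by fixed factors within the
#' calibration bounds; this is the default ground truth of the
#' synthetic-trial generator, emulating a subject whose physiology differs
#' from the anatomical guess (force and pennation substantially, fiber and
#' tendon lengths mildly -- tendon slack length is the geometry-critical
#' parameter, so real-scale deviations there would leave the default
#' moment-arm polynomials' operating range). `"calibrated"`: a
#' GA-optimized reference set; note its medial-gastrocnemius tendon slack
#' length lies below the default calibration bounds and outside the
#' operating range of the default geometry, so it is shipped for reference
#' rather than as a simulation truth.
#'
#' @param set `"anatomical"`, `"subject"` or `"calibrated"`.
#' @return Named list of four [muscle_params()] (names `ta`, `sol`, `gm`,
#'   `gl`).
#' @examples
#' ankle_muscle_defaults()$ta
#' @export
ankle_muscle_defaults <- function(set = c("anatomical", "subject",
                                          "calibrated")) {
  set <- match.arg(set)
  tab <- if (set == "anatomical") {
    list(ta  = c(1270, 0.031, 0.310, 12),
         sol = c(2830, 0.030, 0.268, 25),
         gm  = c(1115, 0.045, 0.408, 17),
         gl  = c(490,  0.064, 0.385, 8))
  } else if (set == "subject") {
    # perturbations are coherent within synergist groups (stronger
    # dorsiflexor, uniformly weaker plantarflexors) so that individual
    # parameter deviations do not cancel in the summed joint torque
    list(ta  = c(1270 * 1.35, 0.031 * 0.92, 0.310 * 1.015, 12 * 1.20),
         sol = c(2830 * 0.70, 0.030 * 1.08, 0.268 * 0.990, 25 * 0.80),
         gm  = c(1115 * 0.75, 0.045 * 0.95, 0.408 * 1.010, 17 * 1.25),
         gl  = c(490  * 0.70, 0.064 * 1.06, 0.385 * 0.995, 8  * 0.75))
  } else {
    list(ta  = c(1247.985, 0.027, 0.314, 12.010),
         sol = c(4070.933, 0.032, 0.309, 25.702),
         gm  = c(1422.002, 0.050, 0.326, 14.302),
         gl  = c(632.503,  0.059, 0.422, 7.307))
  }
  out <- lapply(names(tab), function(m) {
    v <- tab[[m]]
    muscle_params(v[1], v[2], v[3], v[4], name = m)
  })
  names(out) <- names(tab)
  out
}

#' Shared Hill-model constants
#'
#' Curve constants shared by all muscles: the activation-dependent change of
#' optimal fiber length, the active force-length quadratic, and the tendon
#' force-strain curve (quadratic toe region up to the strain breakpoint,
#' linear beyond).
#'
#' @param lambda_pct fractional widening of the optimal fiber length at zero
#'   activation (default 0.15).
#' @param q0,q1,q2 active force-length quadratic coefficients (defaults
#'   -2.06, 6.16, -3.13; near-unity peak close to normalized length 1).
#' @param eps_knee tendon-strain breakpoint between toe and linear regions
#'   (default 0.0127).
#' @param k_quad toe-region quadratic stiffness (default 1480.3).
#' @param k_lin,c_lin linear-region slope and offset (defaults 37.5, 0.24).
#' @param scale_l0m normalize fiber length by the activation-scaled optimal
#'   length (default TRUE); set FALSE to normalize by the plain `l0m`.
#' @return An object of class `model_constants`.
#' @export
model_constants <- function(lambda_pct = 0.15, q0 = -2.06, q1 = 6.16,
                            q2 = -3.13, eps_knee = 0.0127, k_quad = 1480.3,
                            k_lin = 37.5, c_lin = 0.24, scale_l0m = TRUE) {
  l <- seq(0.5, 1.5, by = 0.01)
  if (any(q0 + q1 * l + q2 * l^2 < 0))
    stop("active force-length quadratic must be nonnegative on [0.5, 1.5]",
         call. = FALSE)
  if (eps_knee <= 0 || k_quad <= 0 || k_lin <= 0)
    stop("tendon curve constants must be positive", call. = FALSE)
  structure(list(lambda_pct = lambda_pct, q0 = q0, q1 = q1, q2 = q2,
                 eps_knee = eps_knee, k_quad = k_quad, k_lin = k_lin,
                 c_lin = c_lin, scale_l0m = scale_l0m),
            class = "model_constants")
}

#' @export
print.model_constants <- function(x, ...) {
  cat(sprintf(
    "<model_constants> lambda=%g, q=(%g, %g, %g), tendon knee=%g (%g eps^2 | %g eps - %g)\n",
    x$lambda_pct, x$q0, x$q1, x$q2, x$eps_knee, x$k_quad, x$k_lin, x$c_lin))
  invisible(x)
}

#' Read / write muscle parameter sets as structured text
#'
#' One block per muscle in a plain `key: value` format, e.g.
#' \preformatted{[ta]
#' F0m: 1270
#' l0m: 0.031
#' lst: 0.31
#' phi0_deg: 12
#' v0m: 0.31}
#'
#' @param params named list of [muscle_params()].
#' @param path file path.
#' @return `read_muscle_config` returns a named list of `muscle_params`;
#'   `write_muscle_config` returns `path` invisibly.
#' @export
write_muscle_config <- function(params, path) {
  lines <- unlist(lapply(params, function(p) {
    c(sprintf("[%s]", p$name),
      sprintf("F0m: %.10g", p$F0m),
      sprintf("l0m: %.10g", p$l0m),
      sprintf("lst: %.10g", p$lst),
      sprintf("phi0_deg: %.10g", p$phi0),
      sprintf("v0m: %.10g", p$v0m),
      "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_muscle_config
#' @export
read_muscle_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^\\[.+\\]$", lines)
  if (!length(heads)) stop("no [muscle] blocks in ", path, call. = FALSE)
  out <- list()
  bounds <- c(heads, length(lines) + 1)
  for (i in seq_along(heads)) {
    name <- gsub("^\\[|\\]$", "", lines[heads[i]])
    block <- lines[(heads[i] + 1):(bounds[i + 1] - 1)]
    kv <- strsplit(block, ":")
    keys <- trimws(vapply(kv, `[`, "", 1))
    vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
    names(vals) <- keys
    out[[name]] <- muscle_params(vals[["F0m"]], vals[["l0m"]], vals[["lst"]],
                                 vals[["phi0_deg"]],
                                 v0m = if ("v0m" %in% keys) vals[["v0m"]]
                                       else 10 * vals[["l0m"]],
                                 name = name)
  }
  out
}
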