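#' Cubic musculotendon-length geometry for one (muscle, DOF) pair
#'
#' The musculotendon length of a muscle is approximated as a cubic
#' polynomial of the joint angle,
#' `lmt(theta) = mu0 + mu1*theta + mu2*theta^2 + mu3*theta^3`, and the
#' moment arm is its exact derivative,
#' `r(theta) = mu1 + 2*mu2*theta + 3*mu3*theta^2`. The torque sign
#' convention (positive torque = dorsiflexion / inversion / internal
#' rotation; `theta = 0` is the neutral anatomical position) is absorbed
#' into the sign of each muscle's coefficients.
#'
#' @param mu0,mu1,mu2,mu3 polynomial coefficients (m, m/rad, m/rad^2,
#'   m/rad^3).
#' @param muscle muscle label.
#' @param dof movement label (e.g. `"sagittal"`).
#' @param rom_deg length-2 numeric: declared range of motion in degrees.
#' @return An object of class `geometry_poly`.
#' @examples
#' g <- geometry_poly(0.34, 0.03, muscle = "ta", dof = "sagittal")
#' mtu_length(0.2, g)
#' moment_arm(0.2, g)
#' @export
geometry_poly <- function(mu0, mu1 = 0, mu2 = 0, mu3 = 0, muscle = "muscle",
                          dof = "sagittal", rom_deg = c(-45, 45)) {
  stopifnot(length(rom_deg) == 2, rom_deg[1] < rom_deg[2])
  g <- structure(list(mu0 = mu0, mu1 = mu1, mu2 = mu2, mu3 = mu3,
                      muscle = muscle, dof = dof, rom_deg = rom_deg),
                 class = "geometry_poly")
  th <- seq(rom_deg[1], rom_deg[2], length.out = 101) * pi / 180
  if (any(mtu_length(th, g, warn = FALSE) <= 0))
    stop("lmt(theta) must stay positive over the range of motion",
         call. = FALSE)
  if (any(abs(moment_arm(th, g)) > 0.15))
    stop("|moment arm| exceeds 0.15 m over the range of motion",
         call. = FALSE)
  g
}

#' @export
print.geometry_poly <- function(x, ...) {
  cat(sprintf(
    "<geometry_poly> %s / %s: mu = (%g, %g, %g, %g), ROM [%g, %g] deg\n",
    x$muscle, x$dof, x$mu0, x$mu1, x$mu2, x$mu3,
    x$rom_deg[1], x$rom_deg[2]))
  invisible(x)
}

#' Musculotendon length at a joint angle
#'
#' Evaluates the cubic `mu0 + mu1*theta + mu2*theta^2 + mu3*theta^3`.
#' Angles outside the declared range of motion are still evaluated, with a
#' warning.
#'
#' @param theta joint angle(s) in radians.
#' @param g a [geometry_poly()].
#' @param warn warn when `theta` leaves the declared ROM (default TRUE).
#' @return MTU length(s) in m. Vectorized.
#' @export
mtu_length <- function(theta, g, warn = TRUE) {
  stopifnot(inherits(g, "geometry_poly"))
  rom <- g$rom_deg * pi / 180
  if (warn && any(theta < rom[1] - 1e-9 | theta > rom[2] + 1e-9))
    warning("theta outside the declared range of motion for ", g$muscle,
            "/", g$dof, call. = FALSE)
  g$mu0 + theta * (g$mu1 + theta * (g$mu2 + theta * g$mu3))
}

#' Moment arm at a joint angle
#'
#' The exact derivative of [mtu_length()] with respect to the joint angle:
#' `r(theta) = mu1 + 2*mu2*theta + 3*mu3*theta^2`.
#'
#' @inheritParams mtu_length
#' @return Moment arm(s) in m. Vectorized.
#' @export
moment_arm <- function(theta, g) {
  stopifnot(inherits(g, "geometry_poly"))
  g$mu1 + theta * (2 * g$mu2 + theta * 3 * g$mu3)
}

#' Joint torque from per-muscle tendon forces
#'
#' `M(theta, t) = sum_i r_i(theta)*F_i(t)`: each muscle's tendon force
#' weighted by its angle-dependent moment arm. Antagonists contribute with
#' the negative moment arms encoded in their polynomials.
#'
#' @param forces named list of numeric tendon-force series (N), one per
#'   muscle; all the same length.
#' @param geoms named list of [geometry_poly()], covering every muscle in
#'   `forces`.
#' @param theta numeric joint-angle series (rad), same length as the
#'   force series.
#' @return Numeric torque series (N m).
#' @export
joint_torque <- function(forces, geoms, theta) {
  if (!all(names(forces) %in% names(geoms)))
    stop("missing geometry for muscle(s): ",
         paste(setdiff(names(forces), names(geoms)), collapse = ", "),
         call. = FALSE)
  n <- unique(c(vapply(forces, length, 1L), length(theta)))
  if (length(n) != 1)
    stop("force and angle series must share one time base", call. = FALSE)
  tq <- numeric(n[1])
  for (m in names(forces))
    tq <- tq + moment_arm(theta, geoms[[m]]) * forces[[m]]
  tq
}

#' Load-cell lever-arm configuration
#'
#' Lever arms mapping the three bench load-cell forces to torques about the
#' three ankle axes.
#'
#' @param arms length-3 positive numeric, lever arms in m (defaults
#'   0.050, 0.200, 0.040).
#' @return An object of class `loadcell_config`.
#' @export
loadcell_config <- function(arms = c(0.050, 0.200, 0.040)) {
  stopifnot(length(arms) == 3, all(arms > 0))
  structure(list(arms = arms), class = "loadcell_config")
}

#' Convert load-cell forces to torques
#'
#' `T_i = F_i * l_i` per channel.
#'
#' @param forces numeric matrix or data.frame with three columns (N), or a
#'   length-3 vector.
#' @param cfg a [loadcell_config()].
#' @return Torques (N m) with the same shape as `forces`.
#' @export
loadcell_torque <- function(forces, cfg = loadcell_config()) {
  stopifnot(inherits(cfg, "loadcell_config"))
  if (is.null(dim(forces))) {
    stopifnot(length(forces) == 3, all(is.finite(forces)))
    return(forces * cfg$arms)
  }
  forces <- as.matrix(forces)
  stopifnot(ncol(forces) == 3, all(is.finite(forces)))
  sweep(forces, 2, cfg$arms, `*`)
}

#' Default ankle geometry polynomials
#'
#' Package-default cubic MTU-length polynomials for the four muscles on one
#' degree of freedom. These are physiologically plausible package defaults
#' (the tibialis anterior sagittal arm is ~0.03 m at neutral), not measured
#' values; override them via [geometry_poly()] or a geometry config file
#' for subject-specific work.
#'
#' The neutral-angle MTU length of each muscle is set to
#' `lst + l0m*cos(phi0)` of the anatomical parameter set, so every tendon
#' is exactly slack at the neutral position and force builds up through
#' activation-driven fiber shortening and angle-driven length change. Arm
#' magnitudes are kept small enough that MTU excursions over the declared
#' ranges of motion stay within the Hill model's valid fiber-length range.
#'
#' @param dof `"sagittal"` (dorsi/plantarflexion, positive = dorsiflexion),
#'   `"coronal"` (inversion/eversion, positive = inversion) or
#'   `"horizontal"` (internal/external rotation, positive = internal).
#' @return Named list of four [geometry_poly()] (names `ta`, `sol`, `gm`,
#'   `gl`).
#' @export
default_ankle_geometry <- function(dof = c("sagittal", "coronal",
                                           "horizontal")) {
  dof <- match.arg(dof)
  anat <- ankle_muscle_defaults("anatomical")
  mu0 <- vapply(anat, function(p) p$lst + p$l0m * cos(p$phi0_rad), 1.0)
  # arm magnitudes bounded so that |mu1 * ROM| stays well inside each
  # muscle's fiber-length budget (~0.7*l0m shortening, ~0.45*l0m stretch,
  # with margin for calibration candidates down to 0.8*l0m)
  arms <- switch(dof,
    # dorsiflexor positive, plantarflexors negative
    sagittal = list(rom = c(-50, 35),
                    mu1 = c(ta = 0.018, sol = -0.012, gm = -0.014,
                            gl = -0.014),
                    mu2 = c(ta = -0.001, sol = -0.001, gm = -0.001,
                            gl = -0.0008)),
    # invertors positive; lateral gastrocnemius slightly everting
    coronal = list(rom = c(-20, 20),
                   mu1 = c(ta = 0.008, sol = 0.012, gm = 0.010,
                           gl = -0.007),
                   mu2 = c(ta = 0.0005, sol = -0.0008, gm = -0.0008,
                           gl = 0.0004)),
    # internal rotators positive; soleus nearly neutral
    horizontal = list(rom = c(-30, 40),
                      mu1 = c(ta = 0.007, sol = 0.002, gm = 0.009,
                              gl = -0.008),
                      mu2 = c(ta = -0.0004, sol = 0, gm = -0.0008,
                              gl = 0.0004)))
  out <- lapply(MUSCLES, function(m)
    geometry_poly(mu0[[m]], arms$mu1[[m]], arms$mu2[[m]], 0,
                  muscle = m, dof = dof, rom_deg = arms$rom))
  names(out) <- MUSCLES
  out
}

#' Read / write geometry configs as structured text
#'
#' One block per (muscle, DOF) pair:
#' \preformatted{[ta sagittal]
#' mu0: 0.3403
#' mu1: 0.03
#' mu2: -0.002
#' mu3: 0
#' rom_deg: -50 35}
#'
#' @param geoms named list of [geometry_poly()].
#' @param path file path.
#' @return `read_geometry_config` returns a named list of `geometry_poly`
#'   keyed by muscle; `write_geometry_config` returns `path` invisibly.
#' @export
write_geometry_config <- function(geoms, path) {
  lines <- unlist(lapply(geoms, function(g) {
    c(sprintf("[%s %s]", g$muscle, g$dof),
      sprintf("mu0: %.10g", g$mu0), sprintf("mu1: %.10g", g$mu1),
      sprintf("mu2: %.10g", g$mu2), sprintf("mu3: %.10g", g$mu3),
      sprintf("rom_deg: %.10g %.10g", g$rom_deg[1], g$rom_deg[2]),
      "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_geometry_config
#' @export
read_geometry_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^\\[.+\\]$", lines)
  if (!length(heads)) stop("no [muscle dof] blocks in ", path, call. = FALSE)
  out <- list()
  bounds <- c(heads, length(lines) + 1)
  for (i in seq_along(heads)) {
    hdr <- strsplit(gsub("^\\[|\\]$", "", lines[heads[i]]), "\\s+")[[1]]
    block <- lines[(heads[i] + 1):(bounds[i + 1] - 1)]
    kv <- strsplit(block, ":")
    keys <- trimws(vapply(kv, `[`, "", 1))
    vals <- lapply(kv, function(x)
      as.numeric(strsplit(trimws(x[2]), "\\s+")[[1]]))
    names(vals) <- keys
    out[[hdr[1]]] <- geometry_poly(vals$mu0, vals$mu1, vals$mu2, vals$mu3,
                                   muscle = hdr[1], dof = hdr[2],
                                   rom_deg = vals$rom_deg)
  }
  out
}
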