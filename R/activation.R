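#' Activation-dynamics parameters
#'
#' Parameters of the EMG-to-activation model shared across muscles: an
#' electromechanical delay, a second-order recursion turning normalized EMG
#' `e(t)` into neural activation `u(t)`, and an exponential shaping factor
#' turning `u(t)` into muscle activation `a(t)`.
#'
#' The recursion is `u(t) = alpha*e(t - d) - beta1*u(t-1) - beta2*u(t-2)`
#' with the delay `d` realized as an integer number of samples. Stability
#' requires the roots of `z^2 + beta1*z + beta2` to lie inside the unit
#' circle; with the defaults the roots are real and below 0.06 in magnitude,
#' and the DC gain `alpha/(1 + beta1 + beta2)` is within 3e-5 of unity, so
#' the recursion is essentially a delayed copy with a two-sample smoothing
#' transient.
#'
#' @param de electromechanical delay in ms (default 40; physiological range
#'   roughly 10-100 ms).
#' @param alpha recursion gain (default 0.9486).
#' @param beta1,beta2 recursion coefficients (defaults -0.052, 0.000627).
#' @param A nonlinear shape factor, strictly in (-3, 0) (default -1.5;
#'   `A = 0` is a singular point of the shaping formula).
#' @param sample_rate sampling rate in Hz (default 1000).
#' @return An object of class `activation_params`.
#' @examples
#' p <- activation_params()
#' p$de # 40 ms
#' @export
activation_params <- function(de = 40, alpha = 0.9486, beta1 = -0.052,
                              beta2 = 0.000627, A = -1.5,
                              sample_rate = 1000) {
  if (de < 0) stop("electromechanical delay must be >= 0", call. = FALSE)
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  if (!(A > -3 && A < 0))
    stop("shape factor A must lie strictly in (-3, 0)", call. = FALSE)
  r <- recursion_roots(beta1, beta2)
  if (max(Mod(r)) >= 1)
    stop("unstable recursion: roots of z^2 + beta1*z + beta2 must have ",
         "magnitude < 1 (got ", paste(signif(Mod(r), 4), collapse = ", "),
         ")", call. = FALSE)
  structure(list(de = de, alpha = alpha, beta1 = beta1, beta2 = beta2,
                 A = A, sample_rate = sample_rate),
            class = "activation_params")
}

#' @export
print.activation_params <- function(x, ...) {
  cat(sprintf(
    "<activation_params> de=%g ms, alpha=%g, beta1=%g, beta2=%g, A=%g, fs=%g Hz\n",
    x$de, x$alpha, x$beta1, x$beta2, x$A, x$sample_rate))
  cat(sprintf("  DC gain alpha/(1+beta1+beta2) = %.6f, delay = %d samples\n",
              dc_gain(x), delay_samples(x)))
  invisible(x)
}

# roots of the characteristic polynomial z^2 + beta1 z + beta2
recursion_roots <- function(beta1, beta2) {
  polyroot(c(beta2, beta1, 1))
}

# steady-state gain of the recursion for a sustained unit input
dc_gain <- function(p) p$alpha / (1 + p$beta1 + p$beta2)

# delay in whole samples, round-half-up
delay_samples <- function(p) {
  floor(p$de * p$sample_rate / 1000 + 0.5)
}

#' Normalize an EMG envelope by its MVC maximum
#'
#' Divides a processed (rectified, low-pass filtered) EMG envelope by the
#' maximum of the muscle's maximum-voluntary-contraction recording, then
#' clips to \[0, 1\].
#'
#' @param raw_envelope a [signal_series()] with nonnegative values.
#' @param mvc_max positive scalar: the MVC envelope maximum for this muscle.
#' @return A `signal_series` with values in \[0, 1\] on the same time base.
#' @export
normalize_emg <- function(raw_envelope, mvc_max) {
  stopifnot(inherits(raw_envelope, "signal_series"))
  if (!is.numeric(mvc_max) || length(mvc_max) != 1 || mvc_max <= 0)
    stop("mvc_max must be a positive scalar", call. = FALSE)
  if (min(raw_envelope$values) < 0)
    stop("EMG envelope values must be nonnegative", call. = FALSE)
  v <- pmin(raw_envelope$values / mvc_max, 1)
  signal_series(raw_envelope$t, v)
}

#' Neural activation from normalized EMG
#'
#' Applies the delayed second-order recursion
#' `u(t) = alpha*e(t - d) - beta1*u(t-1) - beta2*u(t-2)` with zero initial
#' history; samples of `e` before the start of the recording are taken as
#' zero. The output is clipped to \[0, 1\] (the number of clipped samples is
#' attached as attribute `n_clipped`).
#'
#' @param e a [signal_series()] of normalized EMG in \[0, 1\].
#' @param p an [activation_params()] object; its `sample_rate` is replaced
#'   by the series' own rate for the delay computation.
#' @param clip clip the output to \[0, 1\] (default TRUE). Disable to study
#'   the raw linear recursion (e.g. linearity and impulse-response tests).
#' @return A `signal_series` of neural activation `u(t)`.
#' @export
neural_activation <- function(e, p = activation_params(), clip = TRUE) {
  stopifnot(inherits(e, "signal_series"), inherits(p, "activation_params"))
  assert_unit_range(e$values, "normalized EMG")
  fs <- e$fs
  d <- floor(p$de * fs / 1000 + 0.5)
  n <- length(e)
  if (d >= n)
    stop("delay (", d, " samples) must be shorter than the series (", n,
         ")", call. = FALSE)
  e_del <- c(rep(0, d), e$values[seq_len(n - d)])
  # u(t) = x(t) + (-beta1) u(t-1) + (-beta2) u(t-2): recursive linear filter
  u <- as.numeric(stats::filter(p$alpha * e_del,
                                filter = c(-p$beta1, -p$beta2),
                                method = "recursive"))
  n_clipped <- 0L
  if (clip) {
    n_clipped <- sum(u < 0 | u > 1)
    u <- pmin(pmax(u, 0), 1)
  }
  out <- signal_series(e$t, u)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Muscle activation from neural activation
#'
#' Applies the exponential shaping `a = (exp(A*u) - 1)/(exp(A) - 1)`,
#' elementwise. For `A` in (-3, 0) this maps \[0, 1\] onto \[0, 1\],
#' strictly increasing and concave (activation rises faster than neural
#' drive at low effort).
#'
#' @param u a [signal_series()] of neural activation in \[0, 1\], or a bare
#'   numeric vector.
#' @param A nonlinear shape factor in (-3, 0) (default -1.5).
#' @return Same type as `u`, with activation values in \[0, 1\].
#' @export
muscle_activation <- function(u, A = -1.5) {
  if (!(is.numeric(A) && length(A) == 1 && A > -3 && A < 0))
    stop("shape factor A must lie strictly in (-3, 0)", call. = FALSE)
  if (inherits(u, "signal_series")) {
    assert_unit_range(u$values, "neural activation")
    return(signal_series(u$t, expm1(A * u$values) / expm1(A)))
  }
  assert_unit_range(u, "neural activation")
  expm1(A * u) / expm1(A)
}

#' Full EMG-to-activation chain
#'
#' Convenience composition of [neural_activation()] and
#' [muscle_activation()].
#'
#' @inheritParams neural_activation
#' @return A `signal_series` of muscle activation `a(t)` in \[0, 1\].
#' @export
emg_to_activation <- function(e, p = activation_params()) {
  muscle_activation(neural_activation(e, p), p$A)
}

#' Raw EMG to envelope (optional preprocessing helper)
#'
#' Standard envelope extraction for raw surface EMG: band-pass, full-wave
#' rectification, then low-pass. This is an extension beyond the core
#' model, which accepts already-processed envelopes; it requires the
#' `signal` package.
#'
#' @param raw a [signal_series()] of raw EMG (arbitrary units).
#' @param band band-pass corner frequencies in Hz (default `c(20, 450)`;
#'   the upper corner is reduced to 0.45*fs when fs is too low).
#' @param lowpass envelope low-pass corner in Hz (default 6).
#' @param order Butterworth order (default 4).
#' @return A `signal_series` envelope (nonnegative, same time base).
#' @export
emg_envelope <- function(raw, band = c(20, 450), lowpass = 6, order = 4) {
  if (!requireNamespace("signal", quietly = TRUE))
    stop("emg_envelope needs the 'signal' package", call. = FALSE)
  stopifnot(inherits(raw, "signal_series"))
  fs <- raw$fs
  hi <- min(band[2], 0.45 * fs)
  if (band[1] >= hi)
    stop("band-pass corners infeasible at fs = ", fs, " Hz", call. = FALSE)
  bp <- signal::butter(order, c(band[1], hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, raw$values)
  x <- abs(x)
  lp <- signal::butter(order, lowpass / (fs / 2), type = "low")
  env <- pmax(signal::filtfilt(lp, x), 0)
  signal_series(raw$t, env)
}
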