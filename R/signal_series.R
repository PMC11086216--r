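#' Uniformly sampled signal series
#'
#' A light container for one uniformly sampled, dimensionless time series
#' (an EMG envelope, a neural or muscle activation). The time base must be
#' uniform to within a relative tolerance of 1e-9; the sampling rate is
#' derived from it and stored.
#'
#' @param t numeric vector of time stamps in seconds, uniformly spaced,
#'   strictly increasing.
#' @param values numeric vector, same length as `t`.
#' @return An object of class `signal_series`: a list with elements `t`,
#'   `values` and `fs` (sampling rate in Hz).
#' @examples
#' s <- signal_series(seq(0, 1, by = 0.01), sin(seq(0, 1, by = 0.01)))
#' s$fs
#' @export
signal_series <- function(t, values) {
  t <- as.numeric(t)
  values <- as.numeric(values)
  if (length(t) != length(values))
    stop("t and values must have the same length", call. = FALSE)
  if (length(t) < 2)
    stop("a signal series needs at least two samples", call. = FALSE)
  if (anyNA(t) || anyNA(values))
    stop("NA in signal series", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0))
    stop("time stamps must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt[1]), 1e-300))
    stop("time base is not uniform (relative tolerance 1e-9)", call. = FALSE)
  structure(list(t = t, values = values, fs = 1 / dt[1]),
            class = "signal_series")
}

#' @export
print.signal_series <- function(x, ...) {
  cat(sprintf("<signal_series> %d samples @ %.6g Hz, t in [%.4g, %.4g]\n",
              length(x$t), x$fs, x$t[1], x$t[length(x$t)]))
  cat(sprintf("  values in [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.signal_series <- function(x) length(x$values)

#' @export
as.data.frame.signal_series <- function(x, ...) {
  data.frame(t = x$t, value = x$values)
}

#' Read / write a signal series as two-column CSV
#'
#' Round-trips a [signal_series()] through a plain `t,value` CSV file.
#'
#' @param x a `signal_series`.
#' @param path file path.
#' @return `read_signal_csv` returns a `signal_series`; `write_signal_csv`
#'   returns `path` invisibly.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "signal_series"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("t", "value") %in% names(df)))
    stop("expected columns 't' and 'value' in ", path, call. = FALSE)
  signal_series(df$t, df$value)
}

# internal: check values lie in [0, 1] up to roundoff
assert_unit_range <- function(v, what) {
  if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}
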