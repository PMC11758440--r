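#' Uniformly sampled time series
#'
#' The universal carrier for all signals in the package: iEEG voltage
#' traces (mV), instantaneous power (mV^2) and fMRI region-of-interest
#' time courses (arbitrary signal units).  A `zte_ts` is a numeric
#' vector of samples together with the time of the first sample and the
#' sampling rate; sample `i` (1-based) sits at time `t0 + (i - 1) / fs`.
#'
#' @param values numeric vector of samples; must be finite and non-empty.
#' @param fs sampling rate in samples per second (> 0).
#' @param t0 time of the first sample in seconds. Default 0.
#' @param unit free-text unit label carried along for display ("mV",
#'   "mV^2", "a.u.").
#'
#' @return An object of class `zte_ts`.
#' @examples
#' x <- zte_ts(sin(2 * pi * 7 * seq(0, 1, by = 1e-3)), fs = 1000)
#' ts_times(x)[1:5]
#' @export
zte_ts <- function(values, fs, t0 = 0, unit = "a.u.") {
  if (!is.numeric(values) || length(values) < 1L)
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs),
         t0 = as.numeric(t0), unit = unit),
    class = "zte_ts"
  )
}

#' @export
print.zte_ts <- function(x, ...) {
  cat(sprintf("<zte_ts> %d samples @ %g Hz, t0 = %g s, span %.6g s [%s]\n",
              length(x$values), x$fs, x$t0,
              length(x$values) / x$fs, x$unit))
  invisible(x)
}

#' @export
length.zte_ts <- function(x) length(x$values)

#' Sample times of a time series
#'
#' @param x a [zte_ts()].
#' @return Numeric vector of sample times in seconds.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "zte_ts"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' Write / read a time series as two-column delimited text
#'
#' The on-disk exchange format is plain tab-separated text with a header
#' line `time_s<TAB>value`; the sampling rate is recovered from the
#' median spacing of the time column on read.
#'
#' @param x a [zte_ts()].
#' @param path file path.
#' @return `write_ts` returns `path` invisibly; `read_ts` returns a
#'   [zte_ts()].
#' @export
write_ts <- function(x, path) {
  stopifnot(inherits(x, "zte_ts"))
  df <- data.frame(time_s = ts_times(x), value = x$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_ts
#' @param unit unit label to attach on read.
#' @export
read_ts <- function(path, unit = "a.u.") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (ncol(df) < 2L) stop("expected two columns (time_s, value)", call. = FALSE)
  dt <- stats::median(diff(df[[1]]))
  zte_ts(df[[2]], fs = 1 / dt, t0 = df[[1]][1], unit = unit)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's
# global RNG state.  All stochastic generators in the package route
# their randomness through this helper so that identical seeds give
# bit-identical output.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Integer number of samples spanned by a duration, insisting that the
# duration is commensurate with the sampling grid.  The default
# tolerance absorbs floating error from rates recovered off disk; the
# artifact-template path relaxes it to half a sample.
samples_for <- function(duration_s, fs, what = "duration", tol = 0.01) {
  n <- duration_s * fs
  if (abs(n - round(n)) > tol + 1e-12)
    stop(sprintf("%s (%g s) is not commensurate with fs = %g", what,
                 duration_s, fs), call. = FALSE)
  as.integer(round(n))
}
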