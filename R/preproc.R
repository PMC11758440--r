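#' Epoch set: stimulus-locked fixed-length windows
#'
#' A matrix of equal-length epochs cut around stimulus onsets, together
#' with the window start relative to onset, the sampling rate, and
#' per-epoch labels (stimulation frequency, experiment, subject, ...).
#'
#' @param epochs numeric matrix, one row per epoch.
#' @param rel_t0 time of the first column relative to stimulus onset
#'   (s); negative when the window includes pre-stimulus baseline.
#' @param fs sampling rate (samples/s).
#' @param labels data.frame with one row per epoch, or `NULL`.
#' @return A `zte_epochs` object.
#' @export
zte_epochs <- function(epochs, rel_t0, fs, labels = NULL) {
  if (!is.matrix(epochs)) epochs <- matrix(epochs, nrow = 1)
  if (!is.null(labels) && nrow(labels) != nrow(epochs))
    stop("`labels` must have one row per epoch", call. = FALSE)
  structure(list(epochs = epochs, rel_t0 = rel_t0, fs = fs,
                 labels = labels),
            class = "zte_epochs")
}

#' @export
print.zte_epochs <- function(x, ...) {
  cat(sprintf(
    "<zte_epochs> %d epochs x %d samples @ %g Hz, window [%g, %g) s\n",
    nrow(x$epochs), ncol(x$epochs), x$fs, x$rel_t0,
    x$rel_t0 + ncol(x$epochs) / x$fs))
  invisible(x)
}

#' Relative sample times of an epoch set
#' @param ep a [zte_epochs()].
#' @return Numeric vector of times relative to stimulus onset (s).
#' @export
epoch_times <- function(ep) {
  stopifnot(inherits(ep, "zte_epochs"))
  ep$rel_t0 + (seq_len(ncol(ep$epochs)) - 1) / ep$fs
}

# Zero-phase IIR filtering with odd-reflection padding at both ends.
# Forward-backward application squares the magnitude response and
# cancels the phase; the reflection padding suppresses the start-up
# transients that plain forward-backward filtering leaves on signals
# with non-zero edges.
filtfilt_reflect <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(as.numeric(signal::filtfilt(filt = b, a = a, x = x)))
  pre <- 2 * x[1] - x[(pad + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(filt = b, a = a, x = c(pre, x, post))
  y[(pad + 1L):(pad + n)]
}

# RBJ biquad notch coefficients at centre frequency f0 with quality Q.
notch_coef <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + al, -2 * cos(w0), 1 - al)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filtering of iEEG
#'
#' The standard conditioning chain for the electrophysiology signal:
#' a Butterworth band-pass (realised as a high-pass/low-pass cascade of
#' order `order` each) followed by narrow IIR notches at the power-line
#' frequency and its harmonics.  Every stage is applied
#' forward-backward with reflection padding, so the output is
#' zero-phase and evoked-component timing is preserved.
#'
#' @param sig a [zte_ts()] voltage trace.
#' @param band band-pass edges in Hz. Default `c(4, 190)`.
#' @param notches notch centre frequencies in Hz. Default
#'   `c(50, 100, 150)`.
#' @param order Butterworth order per cascade section. Default 4.
#' @param notch_q notch quality factor. Default 30.
#' @return A filtered [zte_ts()].
#' @export
bandpass_notch <- function(sig, band = c(4, 190),
                           notches = c(50, 100, 150), order = 4,
                           notch_q = 30) {
  stopifnot(inherits(sig, "zte_ts"))
  fs <- sig$fs
  if (fs <= 2 * max(band))
    stop(sprintf("fs = %g too low for band up to %g Hz", fs, max(band)),
         call. = FALSE)
  x <- sig$values
  pad <- as.integer(min(length(x) - 1L, ceiling(3 * fs / band[1])))
  hp <- signal::butter(order, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(order, band[2] / (fs / 2), type = "low")
  x <- filtfilt_reflect(hp$b, hp$a, x, pad)
  x <- filtfilt_reflect(lp$b, lp$a, x, pad)
  for (f0 in notches) {
    if (f0 >= fs / 2) next
    nc <- notch_coef(f0, fs, notch_q)
    x <- filtfilt_reflect(nc$b, nc$a, x, pad)
  }
  zte_ts(x, fs = fs, t0 = sig$t0, unit = sig$unit)
}

#' Build an MRI gradient-artifact template from baseline volumes
#'
#' Averages the signal segments locked to the first `n_volumes` volume
#' triggers (all during the stimulus-free baseline), yielding a
#' one-volume-period template of the gradient artifact.  Averaging over
#' `n` volumes attenuates uncorrelated signal by `1/sqrt(n)` while the
#' volume-locked artifact survives unchanged.
#'
#' @param sig a [zte_ts()] iEEG recording.
#' @param volume_triggers volume trigger times (s).
#' @param n_volumes number of baseline volumes to average (default 90).
#' @param period_s volume period (s); `period_s * fs` must be within
#'   half a sample of an integer.
#' @return Numeric template of length `round(period_s * fs)`.
#' @export
build_artifact_template <- function(sig, volume_triggers, n_volumes = 90,
                                    period_s = 2) {
  stopifnot(inherits(sig, "zte_ts"))
  fs <- sig$fs
  m <- samples_for(period_s, fs, "volume period", tol = 0.5)
  n <- length(sig$values)
  starts <- round((volume_triggers - sig$t0) * fs) + 1L
  ok <- starts >= 1L & (starts + m - 1L) <= n
  starts <- starts[ok]
  if (length(starts) < n_volumes)
    stop(sprintf(
      "insufficient baseline: %d full-window triggers available, %d required",
      length(starts), n_volumes), call. = FALSE)
  starts <- starts[seq_len(n_volumes)]
  acc <- numeric(m)
  for (s in starts) acc <- acc + sig$values[s:(s + m - 1L)]
  acc / n_volumes
}

#' Subtract a gradient-artifact template at every volume trigger
#'
#' The template is subtracted from the recording at each volume trigger
#' whose full window fits inside the recording; trailing partial
#' windows are skipped with a warning, and samples outside any trigger
#' window are left unchanged.
#'
#' @param sig a [zte_ts()] iEEG recording.
#' @param template numeric artifact template (from
#'   [build_artifact_template()]).
#' @param volume_triggers volume trigger times (s); trigger spacing must
#'   be at least the template length (windows must not overlap).
#' @return A [zte_ts()] with the artifact removed.
#' @export
subtract_artifact_template <- function(sig, template, volume_triggers) {
  stopifnot(inherits(sig, "zte_ts"))
  fs <- sig$fs
  m <- length(template)
  starts <- sort(round((volume_triggers - sig$t0) * fs)) + 1L
  if (length(starts) > 1L && any(diff(starts) < m))
    stop("volume trigger windows overlap the template length",
         call. = FALSE)
  n <- length(sig$values)
  out <- sig$values
  skipped <- 0L
  for (s in starts) {
    if (s < 1L) { skipped <- skipped + 1L; next }
    e <- s + m - 1L
    if (e > n) { skipped <- skipped + 1L; next }
    out[s:e] <- out[s:e] - template
  }
  if (skipped > 0L)
    warning(sprintf("%d trigger window(s) outside the recording skipped",
                    skipped), call. = FALSE)
  zte_ts(out, fs = fs, t0 = sig$t0, unit = sig$unit)
}

#' Select the stimulus-sensitive electrode
#'
#' Given several candidate (already filtered) recordings, computes for
#' each the mean power during stimulation relative to the mean power
#' over the whole recording, and returns the 1-based index of the
#' candidate with the highest ratio; ties go to the lowest index.
#'
#' @param sigs list of [zte_ts()] candidates on a common time base.
#' @param stim_intervals list of `c(start, end)` stimulation intervals
#'   (s), or a two-column matrix.
#' @return Integer index of the selected electrode.
#' @export
select_electrode <- function(sigs, stim_intervals) {
  if (length(sigs) < 1L) stop("need at least one candidate", call. = FALSE)
  if (is.matrix(stim_intervals))
    stim_intervals <- split(stim_intervals, seq_len(nrow(stim_intervals)))
  if (length(stim_intervals) < 1L)
    stop("`stim_intervals` must be non-empty", call. = FALSE)
  ratio <- vapply(sigs, function(s) {
    stopifnot(inherits(s, "zte_ts"))
    t <- ts_times(s)
    in_stim <- rep(FALSE, length(t))
    for (iv in stim_intervals)
      in_stim <- in_stim | (t >= iv[1] & t < iv[2])
    if (!any(in_stim))
      stop("no samples inside the stimulation intervals", call. = FALSE)
    p <- s$values^2
    mean(p[in_stim]) / mean(p)
  }, numeric(1))
  which.max(ratio)   # which.max returns the first (lowest-index) maximum
}

#' Instantaneous power of a voltage trace
#'
#' Element-wise square of the signal; the broadband power carrier used
#' throughout the coupling analysis.
#'
#' @param sig a [zte_ts()] in mV.
#' @return A non-negative [zte_ts()] in mV^2.
#' @export
instantaneous_power <- function(sig) {
  stopifnot(inherits(sig, "zte_ts"))
  zte_ts(sig$values^2, fs = sig$fs, t0 = sig$t0, unit = "mV^2")
}

#' Cut stimulus-locked epochs from a recording
#'
#' One fixed-length epoch per onset.  The epoch grid is the recording's
#' own sampling grid: the first sample of each epoch is the first grid
#' point at or after `onset + rel_start` (half-open windows), so no
#' resampling occurs and the sample nearest the onset maps to relative
#' time 0.
#'
#' @param sig a [zte_ts()].
#' @param onsets stimulus onset times (s).
#' @param rel_start window start relative to onset (s, usually
#'   negative).
#' @param duration window length (s).
#' @param labels optional data.frame of per-onset labels.
#' @return A [zte_epochs()].
#' @export
extract_epochs <- function(sig, onsets, rel_start, duration,
                           labels = NULL) {
  stopifnot(inherits(sig, "zte_ts"))
  fs <- sig$fs
  n <- length(sig$values)
  len <- samples_for(duration, fs, "epoch duration")
  i0 <- ceiling((onsets + rel_start - sig$t0) * fs - 1e-9) + 1L
  bad <- i0 < 1L | (i0 + len - 1L) > n
  if (any(bad))
    stop(sprintf(
      "epoch window outside the recording for onset(s): %s",
      paste(format(onsets[bad]), collapse = ", ")), call. = FALSE)
  ep <- matrix(NA_real_, nrow = length(onsets), ncol = len)
  for (i in seq_along(onsets))
    ep[i, ] <- sig$values[i0[i]:(i0[i] + len - 1L)]
  zte_epochs(ep, rel_t0 = rel_start, fs = fs, labels = labels)
}

#' Baseline-correct an epoch set
#'
#' Subtracts from each epoch the mean of its samples in the baseline
#' window (relative times in `[baseline[1], baseline[2])`), so that the
#' per-epoch baseline mean is exactly zero afterwards.
#'
#' @param ep a [zte_epochs()].
#' @param baseline `c(start, end)` relative to stimulus onset (s).
#' @return A baseline-corrected [zte_epochs()].
#' @export
baseline_correct <- function(ep, baseline) {
  stopifnot(inherits(ep, "zte_epochs"))
  t <- epoch_times(ep)
  sel <- t >= baseline[1] - 1e-9 & t < baseline[2] - 1e-9
  if (!any(sel))
    stop("baseline window contains no samples of the epoch", call. = FALSE)
  mu <- rowMeans(ep$epochs[, sel, drop = FALSE])
  zte_epochs(ep$epochs - mu, rel_t0 = ep$rel_t0, fs = ep$fs,
             labels = ep$labels)
}
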