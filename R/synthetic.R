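#' Stimulus schedule objects
#'
#' A schedule describes one experiment: an ordered set of stimulation
#' events (onset, pulse-train frequency, pulse count, block duration),
#' an initial stimulus-free baseline, the total recording duration, and
#' the volume trigger times of the concurrently running MRI acquisition.
#'
#' @param events data.frame with columns `onset_s`, `frequency_hz`,
#'   `n_pulses`, `duration_s`, one row per stimulation event, sorted by
#'   onset.
#' @param baseline_s stimulus-free baseline before the first event (s).
#' @param total_duration_s total recording duration (s).
#' @param volume_tr_s volume repetition time of the MRI acquisition (s).
#' @return A `zte_schedule` object.
#' @export
zte_schedule <- function(events, baseline_s, total_duration_s,
                         volume_tr_s = 2) {
  need <- c("onset_s", "frequency_hz", "n_pulses", "duration_s")
  if (!all(need %in% names(events)))
    stop("`events` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(events) > 0) {
    if (is.unsorted(events$onset_s, strictly = FALSE))
      stop("events must be sorted by onset", call. = FALSE)
    if (any(events$onset_s < baseline_s - 1e-9))
      stop("event onsets must not precede the baseline period",
           call. = FALSE)
    ends <- events$onset_s + events$duration_s
    if (nrow(events) > 1 &&
        any(events$onset_s[-1] < ends[-nrow(events)] - 1e-9))
      stop("stimulation events overlap", call. = FALSE)
    if (total_duration_s < max(ends) - 1e-9)
      stop("total duration shorter than the last event", call. = FALSE)
  }
  triggers <- seq(0, total_duration_s - volume_tr_s, by = volume_tr_s)
  structure(
    list(events = events, baseline_s = baseline_s,
         total_duration_s = total_duration_s,
         volume_tr_s = volume_tr_s,
         volume_trigger_times_s = triggers),
    class = "zte_schedule"
  )
}

#' @export
print.zte_schedule <- function(x, ...) {
  cat(sprintf(
    "<zte_schedule> %d events, baseline %g s, total %g s (%g min), %d volume triggers (TR %g s)\n",
    nrow(x$events), x$baseline_s, x$total_duration_s,
    x$total_duration_s / 60, length(x$volume_trigger_times_s),
    x$volume_tr_s))
  invisible(x)
}

#' Event-related stimulation schedule with jittered onsets (Group 1 design)
#'
#' Builds the short-train, event-related paradigm used for impulse
#' response estimation: `n_events` repetitions of a brief pulse train
#' (default 1 s at 7 Hz) separated by long rests, one train per
#' `cycle_s` cycle.  Successive onsets are offset from the nominal cycle
#' grid by a deterministic jitter drawn without replacement from the
#' grid `0, jitter_grid_s, 2 * jitter_grid_s, ...` in a seed-determined
#' order, so that the stimulus phase relative to the volume acquisition
#' tiles the sub-volume interval and repeated events can later be pooled
#' into fine peristimulus time bins.
#'
#' @param n_events number of stimulation events (>= 1).
#' @param train_hz pulse rate within a train (events/s).
#' @param train_s train duration (s); must be < `cycle_s`.
#' @param cycle_s cycle length: train plus rest (s).
#' @param jitter_grid_s jitter grid step (s); 0 disables jitter.
#' @param seed integer seed controlling the order in which jitter
#'   offsets are assigned to events.
#' @param volume_tr_s MRI volume repetition time (s).
#' @return A [zte_schedule()].
#' @examples
#' sch <- make_group1_schedule(20, seed = 1)
#' sch$total_duration_s / 60  # 16 minutes
#' @export
make_group1_schedule <- function(n_events = 20, train_hz = 7,
                                 train_s = 1, cycle_s = 48,
                                 jitter_grid_s = 0.1, seed = 1,
                                 volume_tr_s = 2) {
  if (n_events < 1) stop("`n_events` must be >= 1", call. = FALSE)
  if (train_s <= 0 || cycle_s <= 0 || train_hz <= 0)
    stop("durations and rates must be positive", call. = FALSE)
  if (train_s >= cycle_s) stop("`train_s` must be < `cycle_s`", call. = FALSE)
  if (jitter_grid_s < 0) stop("`jitter_grid_s` must be >= 0", call. = FALSE)
  jit_max <- (n_events - 1) * jitter_grid_s
  if (train_s + jit_max >= cycle_s)
    stop("jitter grid too wide: events would overlap", call. = FALSE)
  offsets <- (seq_len(n_events) - 1) * jitter_grid_s
  perm <- with_seed(seed, sample.int(n_events))
  onsets <- (seq_len(n_events) - 1) * cycle_s + offsets[perm]
  events <- data.frame(
    onset_s = onsets,
    frequency_hz = train_hz,
    n_pulses = as.integer(round(train_hz * train_s)),
    duration_s = train_s
  )
  zte_schedule(events, baseline_s = 0,
               total_duration_s = n_events * cycle_s,
               volume_tr_s = volume_tr_s)
}

#' Block-design stimulation schedule over randomised frequencies (Group 2)
#'
#' Builds the long-block paradigm used for the coupling analysis: after
#' a stimulus-free baseline, `blocks_per_freq` blocks of continuous
#' stimulation are delivered at each frequency, with the block order
#' randomised by `seed`, and a fixed rest after every block.
#'
#' @param frequencies_hz distinct stimulation frequencies (pulses/s).
#' @param blocks_per_freq blocks per frequency (>= 1).
#' @param block_s stimulation block duration (s).
#' @param break_s rest after each block (s).
#' @param baseline_s initial stimulus-free baseline (s).
#' @param seed integer seed for the block-order randomisation.
#' @param volume_tr_s MRI volume repetition time (s).
#' @return A [zte_schedule()].
#' @examples
#' sch <- make_group2_schedule(seed = 1)
#' sch$total_duration_s / 60  # 31 minutes
#' @export
make_group2_schedule <- function(frequencies_hz = c(1, 3, 5, 7, 9, 13, 17),
                                 blocks_per_freq = 4, block_s = 16,
                                 break_s = 44, baseline_s = 180,
                                 seed = 1, volume_tr_s = 2) {
  if (length(frequencies_hz) < 1 || any(frequencies_hz <= 0))
    stop("`frequencies_hz` must be non-empty and positive", call. = FALSE)
  if (anyDuplicated(frequencies_hz))
    stop("`frequencies_hz` must be distinct", call. = FALSE)
  if (blocks_per_freq < 1) stop("`blocks_per_freq` must be >= 1", call. = FALSE)
  if (block_s <= 0 || break_s < 0 || baseline_s < 0)
    stop("durations must be non-negative (block > 0)", call. = FALSE)
  freqs <- rep(frequencies_hz, each = blocks_per_freq)
  freqs <- freqs[with_seed(seed, sample.int(length(freqs)))]
  n <- length(freqs)
  onsets <- baseline_s + (seq_len(n) - 1) * (block_s + break_s)
  events <- data.frame(
    onset_s = onsets,
    frequency_hz = freqs,
    n_pulses = as.integer(round(freqs * block_s)),
    duration_s = block_s
  )
  zte_schedule(events, baseline_s = baseline_s,
               total_duration_s = baseline_s + n * (block_s + break_s),
               volume_tr_s = volume_tr_s)
}

#' Parameters of the simulated evoked iEEG waveform
#'
#' The response to a single stimulus pulse is modelled as a triphasic
#' waveform: an initial positive lobe, a larger negative lobe, and a
#' final slower positive lobe, each realised as a Gaussian bump with its
#' own amplitude, latency and width.  Within a pulse train the k-th
#' response is scaled by the adaptation factor
#' `a(k) = a_inf + (1 - a_inf) * exp(-(k - 1) / kappa(f))`, with the
#' rate constant `kappa` (in pulses) decreasing with stimulation
#' frequency so that high-frequency trains adapt faster, as observed in
#' somatosensory cortex.
#'
#' @param a_pos1,a_neg,a_pos2 lobe amplitudes (mV); `a_neg < 0` and
#'   `|a_neg| > a_pos1`.
#' @param l1,l2,l3 lobe latencies from pulse onset (s); `l1 < l2 < l3`.
#' @param w1,w2,w3 lobe widths (Gaussian sigma, s); `w3 > w1`.
#' @param a_inf adaptation floor in (0, 1]; 1 disables adaptation.
#' @param kappa adaptation rate constant: a function of frequency (Hz)
#'   returning pulses, or a single number used at all frequencies.  The
#'   default `20 / sqrt(f)` decreases with frequency and corresponds to
#'   adaptation time constants `kappa / f` of roughly 20 s at 1 Hz down
#'   to 0.3 s at 17 Hz.
#' @return A `zte_waveform` parameter object.
#' @export
waveform_params <- function(a_pos1 = 0.2, a_neg = -0.5, a_pos2 = 0.1,
                            l1 = 0.012, l2 = 0.028, l3 = 0.070,
                            w1 = 0.004, w2 = 0.007, w3 = 0.016,
                            a_inf = 0.4, kappa = function(f) 20 / sqrt(f)) {
  if (a_pos1 <= 0 || a_pos2 <= 0 || a_neg >= 0)
    stop("need a_pos1 > 0, a_pos2 > 0, a_neg < 0", call. = FALSE)
  if (abs(a_neg) <= a_pos1)
    stop("the negative lobe must exceed the first positive lobe",
         call. = FALSE)
  if (!(l1 < l2 && l2 < l3)) stop("latencies must satisfy l1 < l2 < l3",
                                  call. = FALSE)
  if (any(c(w1, w2, w3) <= 0) || w3 <= w1)
    stop("widths must be positive with w3 > w1", call. = FALSE)
  if (a_inf <= 0 || a_inf > 1) stop("`a_inf` must be in (0, 1]",
                                    call. = FALSE)
  if (is.numeric(kappa) && length(kappa) == 1) {
    k0 <- kappa
    kappa <- function(f) rep(k0, length(f))
  }
  if (!is.function(kappa)) stop("`kappa` must be a function or a number",
                                call. = FALSE)
  structure(list(a_pos1 = a_pos1, a_neg = a_neg, a_pos2 = a_pos2,
                 l1 = l1, l2 = l2, l3 = l3, w1 = w1, w2 = w2, w3 = w3,
                 a_inf = a_inf, kappa = kappa),
            class = "zte_waveform")
}

#' Evaluate the triphasic single-pulse waveform
#'
#' @param t times from pulse onset (s).
#' @param wf a [waveform_params()] object.
#' @return Waveform values (mV) at `t`.
#' @export
triphasic_waveform <- function(t, wf) {
  stopifnot(inherits(wf, "zte_waveform"))
  wf$a_pos1 * exp(-((t - wf$l1)^2) / (2 * wf$w1^2)) +
    wf$a_neg  * exp(-((t - wf$l2)^2) / (2 * wf$w2^2)) +
    wf$a_pos2 * exp(-((t - wf$l3)^2) / (2 * wf$w3^2))
}

#' Simulate the clean evoked iEEG trace for a schedule
#'
#' Sums one adaptation-scaled triphasic waveform per stimulus pulse on a
#' uniform sampling grid covering the whole schedule.  The trace is
#' exactly zero outside evoked responses.
#'
#' @param schedule a [zte_schedule()].
#' @param wf a [waveform_params()] object.
#' @param fs sampling rate (samples/s); must resolve the fastest lobe of
#'   the waveform.
#' @return A [zte_ts()] in mV starting at t = 0.
#' @export
simulate_evoked_ieeg <- function(schedule, wf, fs = 5000) {
  stopifnot(inherits(schedule, "zte_schedule"), inherits(wf, "zte_waveform"))
  f_content <- 3 / (2 * pi * min(wf$w1, wf$w2, wf$w3))
  if (fs < 2 * f_content)
    stop(sprintf(
      "fs = %g too low for waveform content (~%.0f Hz); need >= %.0f",
      fs, f_content, 2 * f_content), call. = FALSE)
  n <- as.integer(round(schedule$total_duration_s * fs))
  out <- numeric(n)
  span_s <- wf$l3 + 4 * wf$w3
  tmpl_t <- seq(0, span_s, by = 1 / fs)
  tmpl <- triphasic_waveform(tmpl_t, wf)
  m <- length(tmpl)
  ev <- schedule$events
  for (i in seq_len(nrow(ev))) {
    f <- ev$frequency_hz[i]
    np <- ev$n_pulses[i]
    kap <- wf$kappa(f)
    k <- seq_len(np)
    amp <- wf$a_inf + (1 - wf$a_inf) * exp(-(k - 1) / kap)
    pulse_t <- ev$onset_s[i] + (k - 1) / f
    idx0 <- round(pulse_t * fs)      # 0-based sample of pulse onset
    for (j in k) {
      lo <- idx0[j] + 1L
      hi <- min(lo + m - 1L, n)
      if (lo > n) next
      out[lo:hi] <- out[lo:hi] + amp[j] * tmpl[seq_len(hi - lo + 1L)]
    }
  }
  zte_ts(out, fs = fs, t0 = 0, unit = "mV")
}

#' Noise and artifact parameters for simulated recordings
#'
#' Describes the contamination added on top of clean signals: broadband
#' Gaussian noise, power-line sinusoids at 50 Hz and harmonics, an MRI
#' gradient-artifact template repeated at every volume trigger (for the
#' iEEG side), and Gaussian noise plus a slow sinusoidal drift (for the
#' fMRI side).
#'
#' @param broadband_sd standard deviation of broadband iEEG noise (mV).
#' @param line_freqs_hz power-line frequencies (Hz).
#' @param line_amps_mv sinusoid amplitudes, one per line frequency (mV).
#' @param artifact_template gradient-artifact template (mV), one volume
#'   period long at the recording rate; `NULL` for none.
#' @param fmri_noise_sd fMRI noise standard deviation (signal units).
#' @param drift_amplitude amplitude of the slow fMRI drift (signal units).
#' @param drift_period_s drift period (s); the default 300 s lies well
#'   above the 100-s high-pass cutoff used in preprocessing, so the
#'   detrending stage is exercised.
#' @param seed integer seed; all noise draws are reproducible from it.
#' @return A `zte_noise` parameter object.
#' @export
noise_params <- function(broadband_sd = 0.02,
                         line_freqs_hz = c(50, 100, 150),
                         line_amps_mv = c(0.05, 0.02, 0.01),
                         artifact_template = NULL,
                         fmri_noise_sd = 0.05,
                         drift_amplitude = 0.2,
                         drift_period_s = 300,
                         seed = 1) {
  if (broadband_sd < 0 || fmri_noise_sd < 0 || drift_amplitude < 0)
    stop("standard deviations and amplitudes must be >= 0", call. = FALSE)
  if (length(line_amps_mv) != length(line_freqs_hz))
    stop("one line amplitude per line frequency", call. = FALSE)
  if (any(line_amps_mv < 0)) stop("line amplitudes must be >= 0",
                                  call. = FALSE)
  structure(list(broadband_sd = broadband_sd,
                 line_freqs_hz = line_freqs_hz,
                 line_amps_mv = line_amps_mv,
                 artifact_template = artifact_template,
                 fmri_noise_sd = fmri_noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 seed = as.integer(seed)),
            class = "zte_noise")
}

#' Zero-contamination noise parameters
#'
#' Convenience constructor for noiseless simulations (identity checks,
#' deterministic pipelines).
#' @param seed integer seed (unused draws, kept for manifest symmetry).
#' @return A `zte_noise` object with all amplitudes zero.
#' @export
noise_params_zero <- function(seed = 1) {
  noise_params(broadband_sd = 0, line_amps_mv = c(0, 0, 0),
               artifact_template = NULL, fmri_noise_sd = 0,
               drift_amplitude = 0, seed = seed)
}

#' Simulate a contaminated iEEG recording
#'
#' Adds broadband Gaussian noise, power-line sinusoids (with
#' seed-determined phases) and the MRI gradient-artifact template
#' (inserted at every volume trigger whose full window fits the
#' recording) to a clean evoked trace.
#'
#' @param clean a [zte_ts()] clean evoked trace (from
#'   [simulate_evoked_ieeg()]).
#' @param schedule the [zte_schedule()] providing volume trigger times.
#' @param noise a [noise_params()] object.
#' @return A [zte_ts()] of the same length as `clean`.
#' @export
simulate_ieeg_recording <- function(clean, schedule, noise) {
  stopifnot(inherits(clean, "zte_ts"), inherits(schedule, "zte_schedule"),
            inherits(noise, "zte_noise"))
  fs <- clean$fs
  n <- length(clean$values)
  tmpl <- noise$artifact_template
  if (!is.null(tmpl)) {
    want <- round(schedule$volume_tr_s * fs)
    if (length(tmpl) != want)
      stop(sprintf(
        "artifact template length %d does not match volume period (%d samples)",
        length(tmpl), want), call. = FALSE)
  }
  out <- clean$values
  with_seed(noise$seed, {
    if (noise$broadband_sd > 0)
      out <- out + stats::rnorm(n, sd = noise$broadband_sd)
    if (any(noise$line_amps_mv > 0)) {
      t <- ts_times(clean)
      phases <- stats::runif(length(noise$line_freqs_hz), 0, 2 * pi)
      for (i in seq_along(noise$line_freqs_hz))
        if (noise$line_amps_mv[i] > 0)
          out <- out + noise$line_amps_mv[i] *
            sin(2 * pi * noise$line_freqs_hz[i] * t + phases[i])
    }
  })
  if (!is.null(tmpl)) {
    m <- length(tmpl)
    for (tr in schedule$volume_trigger_times_s) {
      lo <- round((tr - clean$t0) * fs) + 1L
      hi <- lo + m - 1L
      if (lo < 1L || hi > n) next
      out[lo:hi] <- out[lo:hi] + tmpl
    }
  }
  zte_ts(out, fs = fs, t0 = clean$t0, unit = clean$unit)
}

#' Simulate an fMRI time course from neuronal power
#'
#' The forward model of the package: the fMRI signal is the neuronal
#' power convolved with the hemodynamic impulse response function,
#' scaled by a gain, bin-averaged down to the acquisition resolution,
#' and contaminated by a slow sinusoidal drift plus Gaussian noise.
#'
#' @param neural_power a non-negative [zte_ts()] (mV^2).
#' @param irf an [irf_params()] object.
#' @param gain scalar gain (fMRI units per convolved-power unit).
#' @param dt_out output sampling interval (s); must be an integer
#'   multiple of the power series' sample interval.
#' @param noise a [noise_params()] object; only the fMRI fields are used.
#' @param kernel_span_s IRF kernel span passed to
#'   [convolve_power_with_irf()].
#' @return A [zte_ts()] at `1 / dt_out` Hz.
#' @export
simulate_fmri_timecourse <- function(neural_power, irf, gain, dt_out,
                                     noise = noise_params_zero(),
                                     kernel_span_s = 60) {
  stopifnot(inherits(neural_power, "zte_ts"), inherits(noise, "zte_noise"))
  if (any(neural_power$values < -1e-12))
    stop("`neural_power` must be non-negative", call. = FALSE)
  conv <- convolve_power_with_irf(neural_power, irf,
                                  kernel_span_s = kernel_span_s)
  conv$values <- gain * conv$values
  out <- downsample_bins(conv, dt_out)
  t <- ts_times(out)
  with_seed(noise$seed + 1L, {
    if (noise$drift_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      out$values <- out$values + noise$drift_amplitude *
        sin(2 * pi * t / noise$drift_period_s + phase)
    }
    if (noise$fmri_noise_sd > 0)
      out$values <- out$values +
        stats::rnorm(length(out$values), sd = noise$fmri_noise_sd)
  })
  out$unit <- "a.u."
  out
}

#' Write a small 4-D NIfTI phantom carrying a planted ROI time course
#'
#' Builds a `dim x dim x dim x T` volume series in which the voxels of a
#' central cubic ROI carry `timecourse` exactly and all other voxels are
#' constant background, and writes both the series and the binary ROI
#' mask as NIfTI.  Used to exercise ROI time-course extraction.
#'
#' @param timecourse a [zte_ts()]; one volume per sample.
#' @param path output path for the 4-D series (".nii" / ".nii.gz").
#' @param mask_path output path for the 3-D ROI mask.
#' @param dim edge length of the cubic volume (voxels).
#' @param roi_halfwidth half-width of the cubic ROI (voxels).
#' @param background constant background value.
#' @return Invisibly, a list with the two paths.
#' @export
write_nifti_phantom <- function(timecourse, path, mask_path, dim = 8,
                                roi_halfwidth = 1, background = 100) {
  stopifnot(inherits(timecourse, "zte_ts"))
  nt <- length(timecourse$values)
  arr <- array(background, c(dim, dim, dim, nt))
  c0 <- ceiling(dim / 2)
  rng <- max(1, c0 - roi_halfwidth):min(dim, c0 + roi_halfwidth)
  for (ti in seq_len(nt))
    arr[rng, rng, rng, ti] <- timecourse$values[ti]
  mask <- array(0L, c(dim, dim, dim))
  mask[rng, rng, rng] <- 1L
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, 1 / timecourse$fs)
  RNifti::writeNifti(img, path)
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path)
  invisible(list(series = path, mask = mask_path))
}
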