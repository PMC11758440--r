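#' Default pipeline configuration
#'
#' Returns the full nested parameter list driving the simulation and
#' analysis pipeline, with every analysis parameter at its standard
#' value: 4-190 Hz band-pass with 50/100/150 Hz notches, 90 baseline
#' volumes for the artifact template, 14-s/70-s epochs with 3-s/28-s
#' pre-stimulus baselines, 100-ms/2-s bins, 22-s and 4-s response
#' windows, and the exhaustive IRF search grid (shape and rate 0.1 to
#' 15 in steps of 0.1; onset 0 to 1 s in steps of 0.1 s).  The
#' generator truth IRF defaults to shape 2.9, rate 1.2 /s, onset 0.5 s.
#'
#' @param group experimental design: 1 (event-related, IRF derivation)
#'   or 2 (block design, coupling analysis).
#' @param seed integer seed for all randomness of a run.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(group = 1, seed = 1) {
  stopifnot(group %in% c(1, 2))
  cfg <- list(
    group = group,
    seed = as.integer(seed),
    subject = "s01",
    experiment = sprintf("g%d_s01_e01", group),
    modality = "electrical",
    ieeg = list(
      fs = 5000, band = c(4, 190), notches = c(50, 100, 150),
      filter_order = 4, notch_q = 30,
      n_electrodes = if (group == 2) 2L else 1L,
      second_electrode_gain = 0.3,
      n_template_volumes = 90
    ),
    waveform = list(
      a_pos1 = 0.2, a_neg = -0.5, a_pos2 = 0.1,
      l1 = 0.012, l2 = 0.028, l3 = 0.070,
      w1 = 0.004, w2 = 0.007, w3 = 0.016,
      a_inf = 0.4, kappa_scale = 20
    ),
    noise = list(
      broadband_sd = 0.02,
      line_freqs_hz = c(50, 100, 150),
      line_amps_mv = c(0.05, 0.02, 0.01),
      artifact_amplitude = 0.3,
      fmri_noise_sd = 0.025,
      drift_amplitude = 0.2,
      drift_period_s = 300
    ),
    irf = list(alpha = 2.9, beta = 1.2, tau = 0.5),
    grid = list(alpha = (1:150) / 10, beta = (1:150) / 10,
                tau = (0:10) / 10),
    fmri = list(
      gain = 50,
      conv_fs = if (group == 1) 100 else 10,
      dt_out = if (group == 1) 0.1 else 2,
      gain_freq_slope = if (group == 1) 0 else 0.04,
      duration_gain_drift = if (group == 1) 0 else 0.8,
      gain_drift_period_s = 600,
      highpass_cutoff_s = 100
    ),
    windows = if (group == 1) {
      list(rel_start = -3, duration = 14, baseline = c(-3, 0),
           bin_s = 0.1)
    } else {
      list(rel_start = -28, duration = 70, baseline = c(-28, 0),
           bin_s = 2, response_window = c(0, 22),
           early_window = c(0, 4), low_freqs = c(1, 3, 5, 7))
    },
    schedule = if (group == 1) {
      list(n_events = 20, train_hz = 7, train_s = 1, cycle_s = 48,
           jitter_grid_s = 0.1, volume_tr_s = 2)
    } else {
      list(frequencies_hz = c(1, 3, 5, 7, 9, 13, 17),
           blocks_per_freq = 4, block_s = 16, break_s = 44,
           baseline_s = 180, volume_tr_s = 2)
    }
  )
  cfg
}

#' Read / write a pipeline configuration as YAML or JSON
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param cfg a configuration list (for writing).
#' @return `read_pipeline_config` returns the configuration list merged
#'   over the defaults for its group.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path,
                                                      simplifyVector = TRUE)
          else stop("config must be .yaml/.yml/.json", call. = FALSE)
  group <- if (!is.null(user$group)) user$group else 1
  seed <- if (!is.null(user$seed)) user$seed else 1
  modifyList(default_pipeline_config(group, seed), user)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

wf_from_config <- function(cfg) {
  w <- cfg$waveform
  ks <- w$kappa_scale
  waveform_params(a_pos1 = w$a_pos1, a_neg = w$a_neg, a_pos2 = w$a_pos2,
                  l1 = w$l1, l2 = w$l2, l3 = w$l3,
                  w1 = w$w1, w2 = w$w2, w3 = w$w3,
                  a_inf = w$a_inf, kappa = function(f) ks / sqrt(f))
}

schedule_from_config <- function(cfg) {
  s <- cfg$schedule
  if (cfg$group == 1) {
    make_group1_schedule(n_events = s$n_events, train_hz = s$train_hz,
                         train_s = s$train_s, cycle_s = s$cycle_s,
                         jitter_grid_s = s$jitter_grid_s,
                         seed = cfg$seed, volume_tr_s = s$volume_tr_s)
  } else {
    make_group2_schedule(frequencies_hz = s$frequencies_hz,
                         blocks_per_freq = s$blocks_per_freq,
                         block_s = s$block_s, break_s = s$break_s,
                         baseline_s = s$baseline_s, seed = cfg$seed,
                         volume_tr_s = s$volume_tr_s)
  }
}

#' Deterministic MRI gradient-artifact template
#'
#' A volume-locked artifact burst used by the simulator: two decaying
#' oscillations at the start of each volume period, identical at every
#' trigger (the assumption under which template subtraction is exact).
#'
#' @param fs sampling rate (samples/s).
#' @param tr_s volume period (s).
#' @param amplitude peak amplitude (mV).
#' @return Numeric template of length `round(tr_s * fs)`.
#' @export
default_artifact_template <- function(fs, tr_s = 2, amplitude = 0.3) {
  m <- round(tr_s * fs)
  t <- (seq_len(m) - 1) / fs
  env <- exp(-t / (0.05 * tr_s))
  amplitude * env * (sin(2 * pi * 131 * t) +
                       0.5 * sin(2 * pi * 67 * t + 1))
}

noise_from_config <- function(cfg, fs, electrode = 1L) {
  nz <- cfg$noise
  tmpl <- if (nz$artifact_amplitude > 0)
    default_artifact_template(fs, cfg$schedule$volume_tr_s,
                              nz$artifact_amplitude)
  else NULL
  noise_params(broadband_sd = nz$broadband_sd,
               line_freqs_hz = nz$line_freqs_hz,
               line_amps_mv = nz$line_amps_mv,
               artifact_template = tmpl,
               fmri_noise_sd = nz$fmri_noise_sd,
               drift_amplitude = nz$drift_amplitude,
               drift_period_s = nz$drift_period_s,
               seed = cfg$seed * 101L + electrode)
}

#' Simulate a complete experiment
#'
#' Generates one synthetic experiment under the configured design:
#' stimulus schedule, clean evoked iEEG, contaminated iEEG recordings
#' (one per electrode; additional electrodes carry an attenuated evoked
#' response), and the fMRI time course obtained by convolving the
#' clean neuronal power with the ground-truth IRF, applying the
#' configured gain structure, bin-averaging to the acquisition
#' resolution and adding drift plus noise.  For the block design, the
#' per-frequency gain profile and the post-4-s gain drift plant the
#' stimulation-dependent nonlinearities that the coupling analysis is
#' designed to expose.
#'
#' @param config a [default_pipeline_config()] list.
#' @param out_dir optional directory; when given, the dataset is also
#'   written to disk ([write_dataset()]).
#' @return A `zte_dataset` list with `schedule`, `clean` (list of
#'   [zte_ts()]), `recordings` (list of [zte_ts()]), `fmri`
#'   ([zte_ts()]), and metadata.
#' @export
run_simulate <- function(config = default_pipeline_config(),
                         out_dir = NULL) {
  cfg <- config
  fs <- cfg$ieeg$fs
  sched <- schedule_from_config(cfg)
  wf <- wf_from_config(cfg)
  clean1 <- simulate_evoked_ieeg(sched, wf, fs = fs)
  ne <- cfg$ieeg$n_electrodes
  clean <- vector("list", ne)
  clean[[1]] <- clean1
  if (ne > 1L)
    for (e in 2:ne) {
      c2 <- clean1
      c2$values <- cfg$ieeg$second_electrode_gain * c2$values
      clean[[e]] <- c2
    }
  recordings <- lapply(seq_len(ne), function(e)
    simulate_ieeg_recording(clean[[e]], sched,
                            noise_from_config(cfg, fs, electrode = e)))

  # fMRI forward model from the clean neuronal power of electrode 1
  power <- instantaneous_power(clean1)
  pw_ds <- downsample_bins(power, 1 / cfg$fmri$conv_fs)
  irf_truth <- irf_params(cfg$irf$alpha, cfg$irf$beta, cfg$irf$tau)
  conv <- convolve_power_with_irf(pw_ds, irf_truth, kernel_span_s = 60)
  conv$values <- cfg$fmri$gain * conv$values
  # planted stimulation-dependent gain structure (block design)
  tt <- ts_times(conv)
  mod <- rep(1, length(tt))
  if (cfg$group == 2) {
    for (i in seq_len(nrow(sched$events))) {
      ev <- sched$events[i, ]
      resp <- tt >= ev$onset_s & tt < ev$onset_s + ev$duration_s + 6
      late <- tt >= ev$onset_s + 4 & tt < ev$onset_s + ev$duration_s + 6
      mod[resp] <- mod[resp] *
        (1 + cfg$fmri$gain_freq_slope * (ev$frequency_hz - 7))
      # sustained-response residual: after the first 4 s of a block the
      # neurovascular gain carries a slow session-scale drift, so the
      # late response is partly decoupled from the neuronal drive while
      # the first 4 s remain faithfully coupled
      mod[late] <- mod[late] *
        (1 + cfg$fmri$duration_gain_drift *
           sin(2 * pi * ev$onset_s / cfg$fmri$gain_drift_period_s))
    }
  }
  conv$values <- conv$values * mod
  fmri <- downsample_bins(conv, cfg$fmri$dt_out)
  tt_out <- ts_times(fmri)
  nz <- cfg$noise
  with_seed(cfg$seed * 101L + 99L, {
    if (nz$drift_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      fmri$values <- fmri$values + nz$drift_amplitude *
        sin(2 * pi * tt_out / nz$drift_period_s + phase)
    }
    if (nz$fmri_noise_sd > 0)
      fmri$values <- fmri$values +
        stats::rnorm(length(fmri$values), sd = nz$fmri_noise_sd)
  })
  ds <- structure(
    list(config = cfg, schedule = sched, clean = clean,
         recordings = recordings, fmri = fmri,
         subject = cfg$subject, experiment = cfg$experiment,
         modality = cfg$modality, irf_truth = irf_truth),
    class = "zte_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' @export
print.zte_dataset <- function(x, ...) {
  cat(sprintf(
    "<zte_dataset> group %d, %s, subject %s, %d electrode(s), %g s @ %g Hz iEEG, fMRI dt %g s\n",
    x$config$group, x$modality, x$subject, length(x$recordings),
    x$schedule$total_duration_s, x$config$ieeg$fs,
    1 / x$fmri$fs))
  invisible(x)
}

#' Write / read a simulated dataset as plain-text files
#'
#' Writes `schedule.json`, one `ieeg_el<k>.tsv` per electrode, and
#' `fmri.tsv`, plus a `manifest.json` recording the configuration,
#' seed, package version and file checksums, so any report can be
#' regenerated from the manifest alone.
#'
#' @param ds a `zte_dataset` from [run_simulate()].
#' @param dir output directory (created if missing).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset`
#'   returns a `zte_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "zte_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(...) file.path(dir, ...)
  sched <- ds$schedule
  jsonlite::write_json(
    list(events = sched$events, baseline_s = sched$baseline_s,
         total_duration_s = sched$total_duration_s,
         volume_tr_s = sched$volume_tr_s),
    w("schedule.json"), auto_unbox = TRUE, digits = NA)
  files <- "schedule.json"
  for (e in seq_along(ds$recordings)) {
    f <- sprintf("ieeg_el%d.tsv", e)
    write_ts(ds$recordings[[e]], w(f))
    files <- c(files, f)
  }
  write_ts(ds$fmri, w("fmri.tsv"))
  files <- c(files, "fmri.tsv")
  cks <- tools::md5sum(file.path(dir, files))
  names(cks) <- files
  jsonlite::write_json(
    list(package = "ztefmri",
         version = as.character(utils::packageVersion("ztefmri")),
         seed = ds$config$seed, subject = ds$subject,
         experiment = ds$experiment, modality = ds$modality,
         config = ds$config, md5 = as.list(cks)),
    w("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- modifyList(default_pipeline_config(man$config$group,
                                            man$config$seed),
                    man$config)
  sj <- jsonlite::read_json(file.path(dir, "schedule.json"),
                            simplifyVector = TRUE)
  sched <- zte_schedule(as.data.frame(sj$events), sj$baseline_s,
                        sj$total_duration_s, sj$volume_tr_s)
  ie_files <- sort(list.files(dir, pattern = "^ieeg_el[0-9]+\\.tsv$"))
  recordings <- lapply(ie_files,
                       function(f) read_ts(file.path(dir, f), unit = "mV"))
  fmri <- read_ts(file.path(dir, "fmri.tsv"))
  structure(
    list(config = cfg, schedule = sched, clean = NULL,
         recordings = recordings, fmri = fmri,
         subject = man$subject, experiment = man$experiment,
         modality = man$modality,
         irf_truth = irf_params(cfg$irf$alpha, cfg$irf$beta,
                                cfg$irf$tau)),
    class = "zte_dataset")
}

# onsets whose full epoch window fits inside the recording; events cut
# off at the edges (e.g. a first stimulus closer to the recording start
# than the pre-stimulus baseline) are dropped with a warning
onsets_in_bounds <- function(sig, onsets, rel_start, duration) {
  lo <- sig$t0
  hi <- sig$t0 + length(sig$values) / sig$fs
  ok <- (onsets + rel_start >= lo - 1e-9) &
    (onsets + rel_start + duration <= hi + 1e-9)
  if (any(!ok))
    warning(sprintf("%d event(s) with epoch windows outside the recording dropped",
                    sum(!ok)), call. = FALSE)
  onsets[ok]
}

# mean baseline-corrected epoch of a zte_ts as another zte_ts on the
# epoch-relative grid
mean_epoch_ts <- function(sig, onsets, rel_start, duration) {
  ep <- extract_epochs(sig, onsets, rel_start, duration)
  mean_ep <- zte_ts(colMeans(ep$epochs), fs = sig$fs, t0 = rel_start,
                    unit = sig$unit)
  mean_ep
}

baseline_correct_ts <- function(sig, baseline) {
  t <- ts_times(sig)
  sel <- t >= baseline[1] - 1e-9 & t < baseline[2] - 1e-9
  sig$values <- sig$values - mean(sig$values[sel])
  sig
}

#' Derive the IRF from an event-related experiment
#'
#' The end-to-end IRF estimation path: condition the iEEG (band-pass +
#' notch; electrode selection when several electrodes are present),
#' average the stimulus-locked voltage epochs, square the mean response
#' into power, baseline-correct, and fit the gamma IRF by exhaustive
#' grid search of the convolution against the mean baseline-corrected
#' fMRI epoch; finally characterise the winning IRF (OT, TTP, FWHM).
#'
#' @param ds a group-1 `zte_dataset` (from [run_simulate()] or
#'   [read_dataset()]).
#' @param grid an [irf_grid()]; default taken from the dataset
#'   configuration.
#' @param out_path optional path for a JSON report.
#' @return A list with `fit` (`zte_irf_fit`), `characterization`
#'   (`zte_irf_char`), `power_epoch`, `fmri_epoch` and `electrode`.
#' @export
run_derive_irf <- function(ds, grid = NULL, out_path = NULL) {
  stopifnot(inherits(ds, "zte_dataset"))
  cfg <- ds$config
  if (cfg$group != 1)
    stop("IRF derivation expects a group-1 (event-related) dataset",
         call. = FALSE)
  if (is.null(grid))
    grid <- irf_grid(cfg$grid$alpha, cfg$grid$beta, cfg$grid$tau)
  wdw <- cfg$windows
  filtered <- lapply(ds$recordings, bandpass_notch,
                     band = cfg$ieeg$band, notches = cfg$ieeg$notches,
                     order = cfg$ieeg$filter_order,
                     notch_q = cfg$ieeg$notch_q)
  ev <- ds$schedule$events
  stim_iv <- lapply(seq_len(nrow(ev)), function(i)
    c(ev$onset_s[i], ev$onset_s[i] + ev$duration_s[i]))
  el <- if (length(filtered) > 1L) select_electrode(filtered, stim_iv)
        else 1L
  onsets <- suppressWarnings(
    onsets_in_bounds(filtered[[el]], ev$onset_s, wdw$rel_start,
                     wdw$duration))
  # mean voltage epoch -> squared -> baseline-corrected
  mean_v <- mean_epoch_ts(filtered[[el]], onsets, wdw$rel_start,
                          wdw$duration)
  mean_pw <- instantaneous_power(mean_v)
  mean_pw <- baseline_correct_ts(mean_pw, wdw$baseline)
  pw_fit <- downsample_bins(mean_pw, 1 / cfg$fmri$conv_fs)
  # mean baseline-corrected fMRI epoch
  mean_fmri <- mean_epoch_ts(ds$fmri, onsets, wdw$rel_start,
                             wdw$duration)
  mean_fmri <- baseline_correct_ts(mean_fmri, wdw$baseline)
  fit <- fit_irf_grid(pw_fit, mean_fmri, grid, bin_s = wdw$bin_s)
  ch <- characterize_irf(function(t) gamma_irf(fit$best, t))
  report <- list(fit = fit, characterization = ch,
                 power_epoch = mean_pw, fmri_epoch = mean_fmri,
                 electrode = el)
  if (!is.null(out_path)) {
    jsonlite::write_json(
      list(best = fit$best[c("alpha", "beta", "tau")],
           scale = fit$scale, ssr = fit$ssr, r2 = fit$r2,
           onset_time_s = ch$onset_time_s,
           time_to_peak_s = ch$time_to_peak_s, fwhm_s = ch$fwhm_s,
           electrode = el, seed = cfg$seed),
      out_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# per-dataset block-level epochs for the coupling analysis:
# fMRI (detrended, 2-s bins) and IRF-convolved neuronal power (2-s
# bins), both baseline-corrected, plus block labels
prepare_coupling_epochs <- function(ds, irf) {
  cfg <- ds$config
  wdw <- cfg$windows
  sched <- ds$schedule
  ev <- sched$events
  fs <- ds$recordings[[1]]$fs
  # artifact template subtraction before any filtering
  recs <- ds$recordings
  if (cfg$noise$artifact_amplitude > 0) {
    recs <- lapply(recs, function(r) {
      tmpl <- build_artifact_template(
        r, sched$volume_trigger_times_s,
        n_volumes = cfg$ieeg$n_template_volumes,
        period_s = sched$volume_tr_s)
      subtract_artifact_template(r, tmpl, sched$volume_trigger_times_s)
    })
  }
  filtered <- lapply(recs, bandpass_notch, band = cfg$ieeg$band,
                     notches = cfg$ieeg$notches,
                     order = cfg$ieeg$filter_order,
                     notch_q = cfg$ieeg$notch_q)
  stim_iv <- lapply(seq_len(nrow(ev)), function(i)
    c(ev$onset_s[i], ev$onset_s[i] + ev$duration_s[i]))
  el <- if (length(filtered) > 1L) select_electrode(filtered, stim_iv)
        else 1L
  sig <- filtered[[el]]
  # per-block: epoch voltage, square, baseline-correct, convolve, bin
  conv_dt <- 1 / cfg$fmri$conv_fs
  n_bins <- samples_for(wdw$duration, 1 / wdw$bin_s, "epoch")
  neural <- matrix(NA_real_, nrow(ev), n_bins)
  vep <- extract_epochs(sig, ev$onset_s, wdw$rel_start, wdw$duration)
  for (i in seq_len(nrow(ev))) {
    pw <- zte_ts(vep$epochs[i, ]^2, fs = fs, t0 = wdw$rel_start,
                 unit = "mV^2")
    pw <- baseline_correct_ts(pw, wdw$baseline)
    pw <- downsample_bins(pw, conv_dt)
    cv <- convolve_power_with_irf(pw, irf, kernel_span_s = 60)
    neural[i, ] <- downsample_bins(cv, wdw$bin_s)$values
  }
  # fMRI: high-pass detrend, epoch, baseline-correct
  fmri_hp <- highpass_100s(ds$fmri, cfg$fmri$highpass_cutoff_s)
  fep <- extract_epochs(fmri_hp, ev$onset_s, wdw$rel_start,
                        wdw$duration)
  fep <- baseline_correct(fep, wdw$baseline)
  labels <- data.frame(subject = ds$subject, experiment = ds$experiment,
                       modality = ds$modality,
                       frequency_hz = ev$frequency_hz,
                       trial = seq_len(nrow(ev)))
  list(fmri = zte_epochs(fep$epochs, wdw$rel_start, 1 / wdw$bin_s,
                         labels),
       neural = zte_epochs(neural, wdw$rel_start, 1 / wdw$bin_s,
                           labels),
       electrode = el)
}

#' Coupling analysis across experiments
#'
#' The end-to-end block-design path.  For every experiment: gradient
#' artifact template subtraction (90 baseline volumes), band-pass and
#' notch filtering, electrode selection, per-block squaring, baseline
#' correction, IRF convolution and 2-s binning on the iEEG side; 100-s
#' high-pass detrending, epoching and baseline correction on the fMRI
#' side.  Response sizes are computed over the full 22-s and the early
#' 4-s windows, z-scored within experiment, averaged per subject and
#' frequency, and regressed (fMRI on neuronal, with intercept) for the
#' four window-by-frequency-subset combinations; per-frequency mean
#' time courses get no-intercept fits and fixed-reference-scaling
#' residuals.
#'
#' @param datasets list of group-2 `zte_dataset` objects.
#' @param irf the [irf_params()] to convolve with (from
#'   [run_derive_irf()]).
#' @param out_path optional path for a JSON report.
#' @return A list with `records` (both windows), `aggregated`,
#'   `fits` (named: `full_all`, `early_all`, `full_low`, `early_low`),
#'   `freq_fits`, `fixed_scaling`, `mean_fmri`, `mean_neural`.
#' @export
run_correlate <- function(datasets, irf, out_path = NULL) {
  if (inherits(datasets, "zte_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L, inherits(irf, "zte_irf"))
  cfg <- datasets[[1]]$config
  if (cfg$group != 2)
    stop("coupling analysis expects group-2 (block design) datasets; run the IRF derivation first for group 1",
         call. = FALSE)
  wdw <- cfg$windows
  prep <- lapply(datasets, prepare_coupling_epochs, irf = irf)
  lab <- do.call(rbind, lapply(prep, function(p) p$fmri$labels))
  fmat <- do.call(rbind, lapply(prep, function(p) p$fmri$epochs))
  nmat <- do.call(rbind, lapply(prep, function(p) p$neural$epochs))
  fs_ep <- 1 / wdw$bin_s

  rec_for <- function(window) {
    r <- lab
    r$fmri_size <- apply(fmat, 1, response_size, fs = fs_ep,
                         window = window, rel_t0 = wdw$rel_start)
    r$neural_size <- apply(nmat, 1, response_size, fs = fs_ep,
                           window = window, rel_t0 = wdw$rel_start)
    standardize_within_experiment(r)
  }
  rec_full <- rec_for(wdw$response_window)
  rec_early <- rec_for(wdw$early_window)
  agg_full <- aggregate_subject_frequency(rec_full)
  agg_early <- aggregate_subject_frequency(rec_early)
  low <- wdw$low_freqs
  fits <- list(
    full_all = linear_fit(agg_full$neural_size, agg_full$fmri_size),
    early_all = linear_fit(agg_early$neural_size, agg_early$fmri_size),
    full_low = with(agg_full[agg_full$frequency_hz %in% low, ],
                    linear_fit(neural_size, fmri_size)),
    early_low = with(agg_early[agg_early$frequency_hz %in% low, ],
                     linear_fit(neural_size, fmri_size))
  )
  # mean-of-means time courses per frequency
  freqs <- sort(unique(lab$frequency_hz))
  mm <- function(mat, f) {
    sel <- lab$frequency_hz == f
    by_subj <- split(seq_len(nrow(mat))[sel], lab$subject[sel])
    gm <- mean_of_means(lapply(by_subj,
                               function(i) mat[i, , drop = FALSE]))
    zte_ts(gm, fs = fs_ep, t0 = wdw$rel_start)
  }
  mean_fmri <- lapply(freqs, function(f) mm(fmat, f))
  mean_neural <- lapply(freqs, function(f) mm(nmat, f))
  names(mean_fmri) <- names(mean_neural) <- as.character(freqs)
  freq_fits <- frequency_wise_timecourse_fit(mean_fmri, mean_neural)
  ref_f <- if (7 %in% freqs) 7 else freqs[which.min(abs(freqs - 7))]
  fixed <- fixed_scaling_residuals(mean_fmri, mean_neural,
                                   ref_frequency = ref_f,
                                   ref_window = wdw$early_window)
  report <- list(records = list(full = rec_full, early = rec_early),
              aggregated = list(full = agg_full, early = agg_early),
              fits = fits, freq_fits = freq_fits,
              fixed_scaling = fixed,
                 mean_fmri = mean_fmri, mean_neural = mean_neural)
  if (!is.null(out_path)) {
    jsonlite::write_json(
      list(fits = lapply(fits, function(f)
             f[c("beta1", "beta0", "r2", "mse", "n")]),
           freq_fits = freq_fits,
           fixed_scaling_beta1 = fixed$beta1,
           n_experiments = length(datasets),
           n_blocks = nrow(lab)),
      out_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
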