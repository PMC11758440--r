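# Shared fixtures: reduced-scale configurations that keep the test run
# fast while preserving the structure of the two experimental designs.
# iEEG is simulated at 1 kHz (well above twice the 190-Hz band edge and
# the ~120-Hz waveform content); grids are coarsened where exhaustive
# search is not itself under test.

zero_noise_cfg <- function(cfg) {
  cfg$noise <- list(broadband_sd = 0,
                    line_freqs_hz = c(50, 100, 150),
                    line_amps_mv = c(0, 0, 0),
                    artifact_amplitude = 0,
                    fmri_noise_sd = 0, drift_amplitude = 0,
                    drift_period_s = 300)
  cfg
}

g1_cfg <- function(seed = 3, fs = 1000, noise_free = TRUE,
                   coarse_grid = TRUE) {
  cfg <- default_pipeline_config(1, seed = seed)
  cfg$ieeg$fs <- fs
  if (noise_free) cfg <- zero_noise_cfg(cfg)
  if (coarse_grid)
    cfg$grid <- list(alpha = seq(1, 5, by = 0.1),
                     beta = seq(0.5, 2, by = 0.1),
                     tau = (0:10) / 10)
  cfg
}

g2_cfg <- function(seed = 11, fs = 1000, subject = "s01",
                   experiment = "e01", blocks_per_freq = 2,
                   n_electrodes = 1L, noise_free = FALSE) {
  cfg <- default_pipeline_config(2, seed = seed)
  cfg$ieeg$fs <- fs
  cfg$ieeg$n_electrodes <- n_electrodes
  cfg$schedule$blocks_per_freq <- blocks_per_freq
  cfg$subject <- subject
  cfg$experiment <- experiment
  if (noise_free) cfg <- zero_noise_cfg(cfg)
  cfg
}

# a short flat-spectrum test signal
white_ts <- function(n, fs, seed = 1, sd = 1) {
  set.seed(seed)
  zte_ts(rnorm(n, sd = sd), fs = fs)
}

paper_irf <- function() irf_params(2.9, 1.2, 0.5)

# independent brute-force oracle for the grid fit: naive loop over the
# grid through the public convolve + downsample operations
brute_force_fit <- function(pw, fmri, grid, bin_s) {
  best <- NULL
  for (a in grid$alpha) for (b in grid$beta) for (tau in grid$tau) {
    p <- irf_params(a, b, tau)
    cv <- convolve_power_with_irf(pw, p,
                                  kernel_span_s = length(pw$values) / pw$fs,
                                  tail_tol = Inf)
    z <- downsample_bins(cv, bin_s)$values[seq_along(fmri$values)]
    zz <- sum(z^2)
    s <- if (zz > 0) sum(z * fmri$values) / zz else 0
    ssr <- sum((fmri$values - s * z)^2)
    if (is.null(best) || ssr < best$ssr - 1e-12)
      best <- list(alpha = a, beta = b, tau = tau, ssr = ssr,
                   scale = s)
  }
  best
}
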