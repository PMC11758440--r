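test_that("event-related schedule reproduces the 16-min design", {
  sch <- make_group1_schedule(20, train_hz = 7, train_s = 1,
                              cycle_s = 48, jitter_grid_s = 0.1,
                              seed = 1)
  expect_equal(nrow(sch$events), 20L)
  expect_true(all(sch$events$n_pulses == 7L))
  expect_equal(sch$total_duration_s, 960)      # 16 min
  expect_equal(sch$total_duration_s / 60, 16)
  # volume triggers strictly increasing on the TR grid
  expect_true(all(diff(sch$volume_trigger_times_s) > 0))
})

test_that("single-event schedule puts the train at time zero", {
  sch <- make_group1_schedule(1, 7, 1, 48, jitter_grid_s = 0,
                              seed = 5)
  expect_equal(sch$events$onset_s, 0)
  expect_equal(sch$events$n_pulses, 7L)
})

test_that("jitter grid tiles the sub-volume interval with distinct phases", {
  # a 20-point grid in steps of 0.1/20 s makes all onset phases
  # modulo 0.1 s distinct
  step <- 0.1 / 20
  sch <- make_group1_schedule(20, 7, 1, 48, jitter_grid_s = step,
                              seed = 2)
  phases <- round(sch$events$onset_s %% 0.1, 9)
  expect_equal(length(unique(phases)), 20L)
  # and the default 0.1-s grid tiles the 2-s volume period
  sch2 <- make_group1_schedule(20, 7, 1, 48, jitter_grid_s = 0.1,
                               seed = 2)
  phases2 <- sort(round(sch2$events$onset_s %% 2, 9))
  expect_equal(phases2, seq(0, 1.9, by = 0.1))
})

test_that("invalid event-related designs are rejected", {
  expect_error(make_group1_schedule(0), ">= 1")
  expect_error(make_group1_schedule(5, train_s = 50, cycle_s = 48),
               "cycle_s")
  expect_error(make_group1_schedule(20, jitter_grid_s = 3), "overlap")
})

test_that("block schedule reproduces the 31-min design", {
  sch <- make_group2_schedule(seed = 1)
  expect_equal(nrow(sch$events), 28L)                     # 7 x 4 blocks
  expect_equal(sch$total_duration_s, 1860)                # 31 min
  expect_equal(sch$total_duration_s / 60, 31)
  expect_equal(length(sch$volume_trigger_times_s), 930L)  # 2-s volumes
  # pulse counts follow round(f * 16 s)
  expect_equal(sort(unique(sch$events$n_pulses)),
               as.integer(round(sort(c(1, 3, 5, 7, 9, 13, 17)) * 16)))
  # exact schedule arithmetic
  expect_equal(sch$baseline_s + nrow(sch$events) * (16 + 44),
               sch$total_duration_s)
})

test_that("block order is randomised but the design multiset is fixed", {
  a <- make_group2_schedule(seed = 1)
  b <- make_group2_schedule(seed = 2)
  expect_equal(sort(a$events$frequency_hz), sort(b$events$frequency_hz))
  expect_false(identical(a$events$frequency_hz, b$events$frequency_hz))
  expect_error(make_group2_schedule(frequencies_hz = c(5, 5)),
               "distinct")
})

test_that("single-block schedule matches round(f * duration) pulses", {
  sch <- make_group2_schedule(frequencies_hz = 5, blocks_per_freq = 1,
                              block_s = 16, break_s = 44,
                              baseline_s = 0, seed = 1)
  expect_equal(nrow(sch$events), 1L)
  expect_equal(sch$events$onset_s, 0)
  expect_equal(sch$events$n_pulses, 80L)
})

test_that("evoked trace follows the triphasic waveform and adaptation law", {
  wf <- waveform_params(a_inf = 1)         # no adaptation
  sch <- make_group2_schedule(frequencies_hz = 5, blocks_per_freq = 1,
                              block_s = 1, break_s = 10,
                              baseline_s = 1, seed = 1)
  sch$events$n_pulses <- 1L                # isolate a single pulse
  tr <- simulate_evoked_ieeg(sch, wf, fs = 2000)
  # peak magnitude equals the directly evaluated waveform extremum
  tg <- seq(0, 0.12, by = 1e-5)
  direct <- wf$a_pos1 * exp(-((tg - wf$l1)^2) / (2 * wf$w1^2)) +
    wf$a_neg * exp(-((tg - wf$l2)^2) / (2 * wf$w2^2)) +
    wf$a_pos2 * exp(-((tg - wf$l3)^2) / (2 * wf$w3^2))
  expect_equal(max(abs(tr$values)), max(abs(direct)), tolerance = 1e-3)
  # zero outside the response
  expect_equal(tr$values[ts_times(tr) < 0.99], rep(0, sum(ts_times(tr) < 0.99)))
})

test_that("adaptation scales late pulses towards the floor", {
  # 16-s block at 7 Hz: 112 pulses; with a_inf = 0.4 and kappa = 3 the
  # 112th pulse is at the floor: a(112) ~= 0.4 * a(1)
  a <- function(k, a_inf, kappa) a_inf + (1 - a_inf) * exp(-(k - 1) / kappa)
  expect_equal(a(112, 0.4, 3) / a(1, 0.4, 3), 0.4, tolerance = 1e-6)
  wf <- waveform_params(a_inf = 0.4, kappa = 3)
  sch <- make_group2_schedule(frequencies_hz = 7, blocks_per_freq = 1,
                              block_s = 16, break_s = 10,
                              baseline_s = 1, seed = 1)
  tr <- simulate_evoked_ieeg(sch, wf, fs = 2000)
  t <- ts_times(tr)
  # compare negative-lobe magnitudes of first and last pulse
  on <- sch$events$onset_s
  p1 <- max(abs(tr$values[t >= on & t < on + 1 / 7]))
  p112 <- max(abs(tr$values[t >= on + 111 / 7 & t < on + 112 / 7]))
  expect_equal(p112 / p1, 0.4, tolerance = 0.02)
})

test_that("pulse amplitudes are non-increasing within a block", {
  wf <- waveform_params(a_inf = 0.3, kappa = 5)
  k <- 1:50
  amp <- wf$a_inf + (1 - wf$a_inf) * exp(-(k - 1) / wf$kappa(7))
  expect_true(all(diff(amp) <= 0))
})

test_that("empty schedule gives an all-zero trace", {
  sch <- zte_schedule(data.frame(onset_s = numeric(0),
                                 frequency_hz = numeric(0),
                                 n_pulses = integer(0),
                                 duration_s = numeric(0)),
                      baseline_s = 0, total_duration_s = 10)
  tr <- simulate_evoked_ieeg(sch, waveform_params(), fs = 1000)
  expect_equal(tr$values, rep(0, 10000))
})

test_that("recording simulation is the identity under zero noise", {
  sch <- make_group1_schedule(2, seed = 1)
  clean <- simulate_evoked_ieeg(sch, waveform_params(), fs = 1000)
  nz <- noise_params_zero()
  rec <- simulate_ieeg_recording(clean, sch, nz)
  expect_identical(rec$values, clean$values)
})

test_that("pure artifact recording is the template tiled at triggers", {
  sch <- make_group1_schedule(1, seed = 1, cycle_s = 8)
  fs <- 1000
  tmpl <- default_artifact_template(fs, 2, amplitude = 0.3)
  clean <- zte_ts(rep(0, 8 * fs), fs = fs)
  nz <- noise_params(broadband_sd = 0, line_amps_mv = c(0, 0, 0),
                     artifact_template = tmpl, fmri_noise_sd = 0,
                     drift_amplitude = 0)
  rec <- simulate_ieeg_recording(clean, sch, nz)
  expect_equal(rec$values, rep(tmpl, 4))
  # template length mismatch is rejected
  nz2 <- nz; nz2$artifact_template <- tmpl[-1]
  expect_error(simulate_ieeg_recording(clean, sch, nz2), "template")
})

test_that("identical seeds give bit-identical recordings", {
  sch <- make_group1_schedule(2, seed = 1)
  clean <- simulate_evoked_ieeg(sch, waveform_params(), fs = 1000)
  nz <- noise_params(seed = 42)
  nz$artifact_template <- default_artifact_template(1000, 2, 0.3)
  r1 <- simulate_ieeg_recording(clean, sch, nz)
  r2 <- simulate_ieeg_recording(clean, sch, nz)
  expect_identical(r1$values, r2$values)
})

test_that("fMRI forward model is linear and maps an impulse to the IRF", {
  p <- paper_irf()
  fs <- 10
  zero <- zte_ts(rep(0, 400), fs = fs)
  out0 <- simulate_fmri_timecourse(zero, p, gain = 2, dt_out = 0.1)
  expect_equal(out0$values, rep(0, length(out0$values)))
  # homogeneity
  set.seed(7)
  pw <- zte_ts(abs(rnorm(400)), fs = fs)
  o1 <- simulate_fmri_timecourse(pw, p, gain = 1, dt_out = 0.1)
  o2 <- simulate_fmri_timecourse(pw, p, gain = 2, dt_out = 0.1)
  expect_equal(o2$values, 2 * o1$values, tolerance = 1e-12)
  # superposition on two random inputs
  pw2 <- zte_ts(abs(rnorm(400)), fs = fs)
  s12 <- zte_ts(pw$values + pw2$values, fs = fs)
  o12 <- simulate_fmri_timecourse(s12, p, gain = 1, dt_out = 0.1)
  o2b <- simulate_fmri_timecourse(pw2, p, gain = 1, dt_out = 0.1)
  expect_equal(o12$values, o1$values + o2b$values, tolerance = 1e-10)
  # unit-area impulse reproduces the IRF samples
  imp <- zte_ts(c(fs, rep(0, 599)), fs = fs)
  oi <- simulate_fmri_timecourse(imp, p, gain = 1, dt_out = 1 / fs)
  expect_equal(oi$values, gamma_irf(p, (0:599) / fs) / fs * fs,
               tolerance = 1e-9)
})

test_that("NIfTI phantom round-trips the planted ROI time course", {
  tc <- zte_ts(sin(1:12), fs = 0.5)
  paths <- list(series = tempfile(fileext = ".nii.gz"),
                mask = tempfile(fileext = ".nii.gz"))
  write_nifti_phantom(tc, paths$series, paths$mask, dim = 6)
  got <- extract_roi_timecourse(paths$series, paths$mask)
  expect_equal(got$values, tc$values, tolerance = 1e-6)
  expect_equal(got$fs, tc$fs, tolerance = 1e-6)
  unlink(unlist(paths))
})
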