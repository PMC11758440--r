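test_that("gamma IRF follows the shifted-density definition", {
  p <- paper_irf()
  # zero before onset
  expect_equal(gamma_irf(p, c(-1, 0, 0.49)), c(0, 0, 0))
  # mode at tau + (alpha - 1) / beta
  tg <- seq(0, 20, by = 1e-4)
  expect_equal(tg[which.max(gamma_irf(p, tg))],
               0.5 + (2.9 - 1) / 1.2, tolerance = 1e-3)
  # unit mass over [tau, infinity)
  expect_equal(stats::integrate(function(t) gamma_irf(p, t), 0.5, 60,
                                rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  expect_error(irf_params(-1, 1), "alpha")
  expect_error(irf_params(1, 0), "beta")
  expect_error(irf_params(1, 1, -0.1), "tau")
})

test_that("gamma IRF mass is one for random valid parameters", {
  set.seed(42)
  for (i in 1:20) {
    p <- irf_params(runif(1, 0.5, 12), runif(1, 0.3, 10),
                    runif(1, 0, 1))
    upper <- p$tau + qgamma(1 - 1e-12, p$alpha, p$beta)
    expect_equal(stats::integrate(function(t) gamma_irf(p, t),
                                  p$tau, upper,
                                  rel.tol = 1e-10)$value,
                 1, tolerance = 1e-6)
  }
})

test_that("double-gamma reference behaves at its limits", {
  expect_equal(lambers_double_gamma(0), 0)       # p1 > 1 at t = 0
  expect_equal(lambers_double_gamma(-1), 0)      # zero before onset
  # V -> infinity reduces to a single gamma density
  t <- seq(0.1, 10, by = 0.1)
  big_v <- lambers_double_gamma(t, V = 1e12)
  expect_equal(big_v, dgamma(t, shape = 10, rate = 2.5),
               tolerance = 1e-6)
})

test_that("causal convolution maps a unit-area impulse onto the IRF", {
  p <- paper_irf()
  fs <- 50
  n <- 800
  imp <- zte_ts(c(fs, rep(0, n - 1)), fs = fs)   # area 1
  out <- convolve_power_with_irf(imp, p, kernel_span_s = 16,
                                 tail_tol = Inf)
  expect_equal(out$values, gamma_irf(p, (0:(n - 1)) / fs),
               tolerance = 1e-9)
  # zero in, zero out
  z <- convolve_power_with_irf(zte_ts(rep(0, 100), fs = fs), p)
  expect_equal(z$values, rep(0, 100))
  # linearity
  set.seed(3)
  x <- zte_ts(runif(300), fs = fs)
  y <- zte_ts(runif(300), fs = fs)
  mix <- zte_ts(2 * x$values + 5 * y$values, fs = fs)
  expect_equal(convolve_power_with_irf(mix, p)$values,
               2 * convolve_power_with_irf(x, p)$values +
                 5 * convolve_power_with_irf(y, p)$values,
               tolerance = 1e-9)
})

test_that("kernel truncation beyond tolerance is refused with the required span", {
  slow <- irf_params(15, 0.1, 0)          # mean 150 s
  pw <- zte_ts(runif(100), fs = 10)
  err <- tryCatch(convolve_power_with_irf(pw, slow, kernel_span_s = 60),
                  error = function(e) conditionMessage(e))
  expect_match(err, "span >=")
})

test_that("bin down-sampling averages adjacent samples", {
  # constant stays constant
  cst <- downsample_bins(zte_ts(rep(4, 1000), fs = 100), 0.1)
  expect_equal(cst$values, rep(4, 100))
  # 5000 samples at 5 kHz in 100-ms bins -> 10 samples
  x <- downsample_bins(zte_ts(rnorm(5000), fs = 5000), 0.1)
  expect_equal(length(x$values), 10L)
  expect_equal(x$fs, 10)
  # ramp: block means
  r <- downsample_bins(zte_ts(0:99, fs = 10), 1)
  expect_equal(r$values, colMeans(matrix(0:99, nrow = 10)))
  # trailing partial bin dropped
  y <- downsample_bins(zte_ts(1:25, fs = 10), 1)
  expect_equal(length(y$values), 2L)
  # non-commensurate bin rejected
  expect_error(downsample_bins(zte_ts(1:100, fs = 3), 0.5),
               "commensurate")
})

test_that("characterisation reproduces closed forms and shifts", {
  # symmetric triangle peaking at 1 with base [0, 2]
  tri <- function(t) pmax(0, 1 - abs(t - 1))
  ch <- characterize_irf(tri, span = c(0, 3))
  expect_equal(ch$time_to_peak_s, 1.0)
  expect_equal(ch$fwhm_s, 1.0)
  # shift equivariance of the gamma IRF
  p0 <- irf_params(2.9, 1.2, 0.2)
  p1 <- irf_params(2.9, 1.2, 0.7)
  c0 <- characterize_irf(function(t) gamma_irf(p0, t))
  c1 <- characterize_irf(function(t) gamma_irf(p1, t))
  expect_equal(c1$raw$onset_time_s - c0$raw$onset_time_s, 0.5,
               tolerance = 1e-5)
  expect_equal(c1$raw$time_to_peak_s - c0$raw$time_to_peak_s, 0.5,
               tolerance = 1e-5)
  expect_equal(c1$raw$fwhm_s, c0$raw$fwhm_s, tolerance = 1e-5)
  # multimodal pulses are refused
  expect_error(characterize_irf(function(t) sin(t), span = c(0, 20)),
               "multimodal")
  expect_error(characterize_irf(function(t) -abs(t), span = c(0, 2)),
               "positive")
})

test_that("grid fit matches an independent brute-force oracle", {
  set.seed(9)
  fs <- 20
  pw <- zte_ts(c(rep(0, 20), abs(rnorm(20)), rep(0, 100)), fs = fs,
               t0 = -1)
  truth <- irf_params(2, 1, 0.5)
  cv <- convolve_power_with_irf(pw, truth, kernel_span_s = 7,
                                tail_tol = Inf)
  fmri <- downsample_bins(cv, 0.5)
  grid <- irf_grid(alpha = c(1.5, 2, 2.5), beta = c(0.5, 1, 1.5),
                   tau = c(0, 0.5))
  fit <- fit_irf_grid(pw, fmri, grid, bin_s = 0.5)
  oracle <- brute_force_fit(pw, fmri, grid, 0.5)
  expect_equal(fit$best$alpha, oracle$alpha)
  expect_equal(fit$best$beta, oracle$beta)
  expect_equal(fit$best$tau, oracle$tau)
  expect_equal(fit$ssr, oracle$ssr, tolerance = 1e-8)
  expect_equal(fit$scale, oracle$scale, tolerance = 1e-8)
  # the SSR surface agrees pointwise with the naive route
  for (ai in seq_along(grid$alpha)) {
    p <- irf_params(grid$alpha[ai], 1, 0.5)
    cv2 <- convolve_power_with_irf(pw, p, kernel_span_s = 7,
                                   tail_tol = Inf)
    z <- downsample_bins(cv2, 0.5)$values[seq_along(fmri$values)]
    s <- sum(z * fmri$values) / sum(z^2)
    expect_equal(fit$ssr_grid[ai, 2, 2],
                 sum((fmri$values - s * z)^2),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("grid fit recovers on-grid truth exactly, with scale homogeneity", {
  set.seed(2)
  fs <- 20
  pw <- zte_ts(c(rep(0, 60), abs(rnorm(25)), rep(0, 195)), fs = fs,
               t0 = -3)
  truth <- irf_params(2.9, 1.2, 0.5)
  cv <- convolve_power_with_irf(pw, truth, kernel_span_s = 14,
                                tail_tol = Inf)
  fmri <- downsample_bins(cv, 0.1)
  grid <- irf_grid(alpha = seq(2.5, 3.3, by = 0.1),
                   beta = seq(0.8, 1.6, by = 0.1), tau = (0:10) / 10)
  fit <- fit_irf_grid(pw, fmri, grid, bin_s = 0.1)
  expect_equal(fit$best$alpha, 2.9)
  expect_equal(fit$best$beta, 1.2)
  expect_equal(fit$best$tau, 0.5)
  expect_lt(fit$ssr, 1e-16 * sum(fmri$values^2))
  expect_equal(fit$scale, 1, tolerance = 1e-9)
  # tripled fMRI: same argmin, scale 3
  fmri3 <- fmri; fmri3$values <- 3 * fmri$values
  fit3 <- fit_irf_grid(pw, fmri3, grid, bin_s = 0.1)
  expect_equal(fit3$best$alpha, 2.9)
  expect_equal(fit3$scale, 3, tolerance = 1e-9)
})

test_that("degenerate inputs are refused and ties break lexicographically", {
  fs <- 10
  pw <- zte_ts(rep(0, 100), fs = fs)
  fmri0 <- zte_ts(rep(0, 10), fs = 1)
  grid <- irf_grid(alpha = c(1, 2), beta = c(1, 2), tau = c(0, 0.5))
  expect_error(fit_irf_grid(pw, fmri0, grid, bin_s = 1),
               "degenerate")
  # all-zero power: every grid point has identical SSR; the reported
  # argmin is the lexicographically smallest triple
  fmri1 <- zte_ts(rnorm(10), fs = 1)
  fit <- fit_irf_grid(pw, fmri1, grid, bin_s = 1)
  expect_equal(c(fit$best$alpha, fit$best$beta, fit$best$tau),
               c(1, 1, 0))
  expect_error(fit_irf_grid(pw, fmri1, irf_grid(alpha = numeric(0)),
                            bin_s = 1), "non-empty")
})
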