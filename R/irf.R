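#' Gamma impulse response function parameters
#'
#' The hemodynamic impulse response function (IRF) of the package is a
#' gamma probability density in time, shifted by an onset delay:
#' \deqn{f(x) = \frac{(x-\tau)^{\alpha-1}\beta^{\alpha}
#'   e^{-\beta(x-\tau)}}{\Gamma(\alpha)}, \quad x \ge \tau;
#'   \qquad f(x) = 0, \quad x < \tau}
#' with shape \eqn{\alpha > 0} (dimensionless), rate \eqn{\beta > 0}
#' (1/s) and onset time \eqn{\tau \ge 0} (s).  The density integrates
#' to one over \eqn{[\tau, \infty)}, so convolution with it preserves
#' the area of the neuronal input.
#'
#' @param alpha shape parameter (> 0).
#' @param beta rate parameter (1/s, > 0).
#' @param tau onset delay (s, >= 0).
#' @return An `zte_irf` parameter object.
#' @examples
#' p <- irf_params(2.9, 1.2, 0.5)
#' gamma_irf(p, c(0, 0.5, 2.1, 10))
#' @export
irf_params <- function(alpha, beta, tau = 0) {
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0",
                                             call. = FALSE)
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be > 0",
                                           call. = FALSE)
  if (!is.numeric(tau) || tau < 0) stop("`tau` must be >= 0",
                                        call. = FALSE)
  structure(list(alpha = alpha, beta = beta, tau = tau),
            class = "zte_irf")
}

#' @export
print.zte_irf <- function(x, ...) {
  cat(sprintf("<zte_irf> gamma IRF: alpha = %g, beta = %g /s, tau = %g s\n",
              x$alpha, x$beta, x$tau))
  invisible(x)
}

#' Evaluate the gamma IRF
#'
#' @param p an [irf_params()] object.
#' @param t times from stimulus onset (s).
#' @return IRF values at `t` (1/s); zero for `t < tau`.
#' @export
gamma_irf <- function(p, t) {
  stopifnot(inherits(p, "zte_irf"))
  if (!all(is.finite(t))) stop("`t` must be finite", call. = FALSE)
  out <- numeric(length(t))
  pos <- t >= p$tau
  x <- t[pos] - p$tau
  out[pos] <- stats::dgamma(x, shape = p$alpha, rate = p$beta)
  # for alpha < 1 the density diverges at x = 0; on a sampling grid the
  # singular point carries no mass, so it is evaluated as 0
  out[!is.finite(out)] <- 0
  out
}

#' Double-gamma BOLD reference impulse response
#'
#' The BOLD IRF reported by Lambers and colleagues for the rat
#' somatosensory cortex, used here as a literature reference curve:
#' \deqn{f(x) = e^{-bx}\left(\frac{b^{p_1}x^{p_1-1}}{\Gamma(p_1)} -
#'   \frac{b^{p_2}x^{p_2-1}}{V\,\Gamma(p_2)}\right), \quad x \ge 0}
#' The second gamma term produces the post-stimulus undershoot typical
#' of BOLD; `V` sets the peak-to-undershoot ratio.
#'
#' @param t times (s); values for `t < 0` are 0.
#' @param b rate parameter (1/s).
#' @param p1,p2 shape parameters of the main lobe and the undershoot.
#' @param V undershoot attenuation ratio.
#' @return Function values at `t`.
#' @export
lambers_double_gamma <- function(t, b = 2.5, p1 = 10, p2 = 11.7,
                                 V = 1.5) {
  if (any(c(b, p1, p2, V) <= 0)) stop("all parameters must be > 0",
                                      call. = FALSE)
  out <- numeric(length(t))
  pos <- t >= 0
  x <- t[pos]
  out[pos] <- exp(-b * x) *
    (b^p1 * x^(p1 - 1) / gamma(p1) - b^p2 * x^(p2 - 1) / (V * gamma(p2)))
  out[t == 0] <- if (p1 > 1) 0 else out[t == 0]
  out
}

#' Gamma-variate reference curve (literal transcription, ambiguous)
#'
#' Best-effort transcription of the gamma-variate model attributed to
#' Martindale and colleagues, as printed:
#' `f(x) = exp(-x * delta / tau) * x^(delta^2 / x - 1)`.
#' The printed formula is typographically ambiguous and this literal
#' reading does not reproduce the published peak times; the function is
#' provided for completeness only and is not used by any analysis in
#' this package.
#'
#' @param t times (s, > 0 evaluated; 0 elsewhere).
#' @param delta,tau printed parameters (CBV: 2.49 / 1.22; CBF: 2.37 /
#'   0.76).
#' @return Function values at `t`.
#' @export
martindale_gamma_variate <- function(t, delta, tau) {
  out <- numeric(length(t))
  pos <- t > 0
  x <- t[pos]
  out[pos] <- exp(-x * delta / tau) * x^(delta^2 / x - 1)
  out
}

#' Parameter grid for the IRF search
#'
#' The exhaustive search grid for the convolution fit.  The default is
#' the full published grid: shape `0.1, 0.2, ..., 15`, rate `0.1, 0.2,
#' ..., 15` (1/s) and onset `0, 0.1, ..., 1` (s).  Grid values are
#' constructed from integers scaled by ten so that the printed decimals
#' are represented exactly.
#'
#' @param alpha,beta,tau strictly increasing numeric vectors of
#'   candidate values.
#' @return An `zte_irf_grid` object.
#' @export
irf_grid <- function(alpha = (1:150) / 10, beta = (1:150) / 10,
                     tau = (0:10) / 10) {
  chk <- function(v, nm, min_ok) {
    if (length(v) < 1) stop(sprintf("`%s` grid must be non-empty", nm),
                            call. = FALSE)
    if (is.unsorted(v, strictly = TRUE))
      stop(sprintf("`%s` grid must be strictly increasing", nm),
           call. = FALSE)
    if (any(v < min_ok) || (min_ok == 0 && any(v < 0)))
      stop(sprintf("`%s` grid out of range", nm), call. = FALSE)
  }
  chk(alpha, "alpha", .Machine$double.eps)
  chk(beta, "beta", .Machine$double.eps)
  chk(tau, "tau", 0)
  structure(list(alpha = alpha, beta = beta, tau = tau),
            class = "zte_irf_grid")
}

#' @export
print.zte_irf_grid <- function(x, ...) {
  cat(sprintf("<zte_irf_grid> %d alpha x %d beta x %d tau = %d combinations\n",
              length(x$alpha), length(x$beta), length(x$tau),
              length(x$alpha) * length(x$beta) * length(x$tau)))
  invisible(x)
}

#' Convolve a power time course with the gamma IRF
#'
#' Causal discrete convolution at the power series' sampling rate, each
#' term weighted by the sample interval, so that a unit-area impulse
#' maps onto the IRF itself.  The IRF kernel is truncated at
#' `kernel_span_s`; the truncated tail mass must stay below `tail_tol`
#' or an error reports the span that would suffice.
#'
#' @param power a uniformly sampled [zte_ts()].
#' @param p an [irf_params()] object.
#' @param kernel_span_s kernel length (s). Default 60 s, far beyond the
#'   tail of the IRF at physiological parameter values.
#' @param tail_tol maximum tolerated truncated tail mass; `Inf`
#'   disables the check (used when the output window itself limits the
#'   kernel support).
#' @return A [zte_ts()] on the same time base as `power`.
#' @export
convolve_power_with_irf <- function(power, p, kernel_span_s = 60,
                                    tail_tol = 1e-6) {
  stopifnot(inherits(power, "zte_ts"), inherits(p, "zte_irf"))
  if (kernel_span_s <= 0) stop("`kernel_span_s` must be > 0", call. = FALSE)
  if (is.finite(tail_tol)) {
    tail_mass <- stats::pgamma(kernel_span_s - p$tau, shape = p$alpha,
                               rate = p$beta, lower.tail = FALSE)
    if (tail_mass > tail_tol) {
      need <- p$tau + stats::qgamma(1 - tail_tol, shape = p$alpha,
                                    rate = p$beta)
      stop(sprintf(
        "kernel span %g s truncates %.3g of the IRF mass; span >= %.1f s required",
        kernel_span_s, tail_mass, need), call. = FALSE)
    }
  }
  fs <- power$fs
  dt <- 1 / fs
  K <- min(samples_for(kernel_span_s, fs, "kernel span"),
           length(power$values))
  K <- max(K, 1L)
  h <- gamma_irf(p, (seq_len(K) - 1) * dt)
  n <- length(power$values)
  # FFT convolution padded to a highly composite length
  M <- stats::nextn(n + K - 1L, c(2, 3, 5))
  xp <- c(power$values, numeric(M - n))
  hp <- c(h, numeric(M - K))
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(hp),
                        inverse = TRUE)) / M
  zte_ts(dt * full[seq_len(n)], fs = fs, t0 = power$t0, unit = "a.u.")
}

#' Down-sample a time series by averaging adjacent samples in bins
#'
#' Non-overlapping adjacent bins of width `bin_s` are averaged; a
#' trailing partial bin is dropped.  The output keeps the bin-start
#' time convention: output sample `b` is stamped at the start time of
#' bin `b`.
#'
#' @param sig a [zte_ts()].
#' @param bin_s bin width (s); must be an integer multiple of the
#'   sample interval (within half a sample).
#' @return A [zte_ts()] at `1 / bin_s` Hz.
#' @export
downsample_bins <- function(sig, bin_s) {
  stopifnot(inherits(sig, "zte_ts"))
  if (bin_s < 1 / sig$fs - 1e-12)
    stop("`bin_s` must be at least one sample interval", call. = FALSE)
  m <- samples_for(bin_s, sig$fs, "bin width")
  if (m < 1L) stop("`bin_s` shorter than one sample", call. = FALSE)
  n_bins <- length(sig$values) %/% m
  if (n_bins < 1L) stop("signal shorter than one bin", call. = FALSE)
  v <- sig$values[seq_len(n_bins * m)]
  means <- colMeans(matrix(v, nrow = m))
  zte_ts(means, fs = 1 / bin_s, t0 = sig$t0, unit = sig$unit)
}

# Bin-averaged causal-convolution operator: Pmat[k, b] equals
# dt/m * sum over the samples of bin b of the power shifted by (k-1)
# samples, so that the binned convolution with any kernel h is
# t(Pmat) %*% h.  Shared by the vectorised grid fit and by nothing
# else; the naive route (convolve + downsample) is kept independent.
binned_conv_operator <- function(p_values, m, n_bins, dt) {
  n <- length(p_values)
  K <- n
  cp <- cumsum(p_values)
  csum <- function(lo, hi) {
    # sum of p[lo..hi] (1-based), zero outside [1, n]
    hi <- pmin(hi, n)
    lo <- pmax(lo, 1L)
    bad <- hi < lo
    res <- cp[pmax(hi, 1L)] - ifelse(lo > 1L, cp[lo - 1L], 0)
    res[bad] <- 0
    res
  }
  n0 <- (seq_len(n_bins) - 1L) * m      # 0-based start sample of each bin
  P <- matrix(0, nrow = K, ncol = n_bins)
  for (b in seq_len(n_bins)) {
    k <- seq_len(K) - 1L
    lo <- n0[b] - k + 1L
    hi <- n0[b] + m - k
    P[, b] <- csum(lo, hi)
  }
  P * (dt / m)
}

#' Grid-search convolution fit of the IRF
#'
#' The estimator at the heart of the package.  For every combination
#' (alpha, beta, tau) of the grid, the neuronal power epoch is convolved
#' with the gamma IRF at its own sampling rate, bin-averaged down to the
#' fMRI resolution, scaled by a single least-squares amplitude factor
#' (no intercept; both inputs are expected baseline-corrected), and the
#' sum of squared residuals (SSR) against the fMRI epoch is recorded.
#' The fitted IRF is the combination with the smallest SSR, ties broken
#' lexicographically by (alpha, beta, tau).
#'
#' The kernel is truncated at the epoch length, which is exact for the
#' fitted window: output samples inside the epoch never see kernel mass
#' beyond it.
#'
#' @param neural_power_epoch a [zte_ts()]: the mean baseline-corrected
#'   power epoch at its native (high) sampling rate.
#' @param fmri_epoch a [zte_ts()]: the mean baseline-corrected fMRI
#'   epoch, sampled at `1 / bin_s`, covering the same window.
#' @param grid an [irf_grid()].
#' @param bin_s fMRI bin width (s).
#' @return A `zte_irf_fit` with elements `best` ([irf_params()]),
#'   `scale`, `ssr`, `r2` (1 - SSR / sum(y^2), the no-intercept
#'   convention), `ssr_grid` (array alpha x beta x tau), `fitted` (the
#'   best-fit predicted epoch as [zte_ts()]) and `grid`.
#' @export
fit_irf_grid <- function(neural_power_epoch, fmri_epoch, grid,
                         bin_s = 0.1) {
  stopifnot(inherits(neural_power_epoch, "zte_ts"),
            inherits(fmri_epoch, "zte_ts"),
            inherits(grid, "zte_irf_grid"))
  pw <- neural_power_epoch
  y <- fmri_epoch$values
  if (all(abs(y) < .Machine$double.eps))
    stop("degenerate fit: fMRI epoch is identically zero", call. = FALSE)
  if (abs(fmri_epoch$fs - 1 / bin_s) > 1e-6 * fmri_epoch$fs)
    stop("`fmri_epoch` must be sampled at 1 / bin_s", call. = FALSE)
  if (abs(pw$t0 - fmri_epoch$t0) > 0.5 / pw$fs + 1e-9)
    stop("epochs must cover the same window (t0 mismatch)", call. = FALSE)
  m <- samples_for(bin_s, pw$fs, "bin width")
  n_bins <- length(pw$values) %/% m
  if (length(y) != n_bins)
    stop(sprintf(
      "fMRI epoch has %d bins but the power epoch spans %d full bins",
      length(y), n_bins), call. = FALSE)
  dt <- 1 / pw$fs
  P <- binned_conv_operator(pw$values, m, n_bins, dt)
  K <- nrow(P)
  tk <- (seq_len(K) - 1) * dt
  yy <- sum(y * y)
  na <- length(grid$alpha); nb <- length(grid$beta); nt <- length(grid$tau)
  ssr_grid <- array(NA_real_, dim = c(na, nb, nt),
                    dimnames = list(alpha = format(grid$alpha),
                                    beta = format(grid$beta),
                                    tau = format(grid$tau)))
  beta_rep <- rep(grid$beta, times = K)
  for (ti in seq_len(nt)) {
    x <- tk - grid$tau[ti]
    x_rep <- rep(x, each = nb)
    zero_col <- which(x == 0)           # singular sample when alpha < 1
    for (ai in seq_len(na)) {
      # kernel matrix for all beta at this (alpha, tau): nb x K
      # (dgamma returns 0 for x < 0)
      H <- matrix(stats::dgamma(x_rep, shape = grid$alpha[ai],
                                rate = beta_rep),
                  nrow = nb)
      if (grid$alpha[ai] < 1 && length(zero_col)) H[, zero_col] <- 0
      Z <- H %*% P                      # nb x n_bins predicted curves
      zy <- as.vector(Z %*% y)
      zz <- rowSums(Z * Z)
      ssr <- ifelse(zz > 0, yy - zy^2 / zz, yy)
      # numerical floor: exact fits can give tiny negative residue
      ssr_grid[ai, , ti] <- pmax(ssr, 0)
    }
  }
  minv <- min(ssr_grid)
  idx <- which(ssr_grid == minv, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE][1, ]
  best <- irf_params(grid$alpha[idx[1]], grid$beta[idx[2]],
                     grid$tau[idx[3]])
  h <- gamma_irf(best, tk)
  z <- as.vector(crossprod(P, h))
  zz <- sum(z * z)
  scale <- if (zz > 0) sum(z * y) / zz else 0
  ssr <- minv
  fit <- structure(
    list(best = best, scale = scale, ssr = ssr,
         r2 = 1 - ssr / yy, ssr_grid = ssr_grid, grid = grid,
         bin_s = bin_s,
         fitted = zte_ts(scale * z, fs = 1 / bin_s, t0 = fmri_epoch$t0)),
    class = "zte_irf_fit")
  fit
}

#' @export
print.zte_irf_fit <- function(x, ...) {
  cat(sprintf(
    "<zte_irf_fit> alpha = %g, beta = %g /s, tau = %g s | scale = %.4g, SSR = %.4g, R^2 = %.3f\n",
    x$best$alpha, x$best$beta, x$best$tau, x$scale, x$ssr, x$r2))
  invisible(x)
}

# dgamma is slow-pathed above for generality; the alpha-loop keeps peak
# memory below ~300 MB even for the full 150 x 150 x 11 grid.

#' Numerical characterisation of a response kernel
#'
#' Computes the onset time (OT: earliest time at which the function
#' rises above zero), time-to-peak (TTP: location of the positive
#' maximum, fine-grid bracketing refined by local optimisation) and
#' full-width-at-half-maximum (FWHM: distance between the two
#' half-maximum crossings, located by bisection to 1e-6 s) of a
#' single-peaked positive pulse, all rounded to `report_precision_s`.
#'
#' @param f a vectorised function of time (s), e.g.
#'   `function(t) gamma_irf(p, t)`.
#' @param span evaluation window `c(start, end)` in seconds.
#' @param report_precision_s reporting precision (s). Default 0.1 s.
#' @param n_grid number of points of the bracketing grid.
#' @return A `zte_irf_char` list with `onset_time_s`, `time_to_peak_s`,
#'   `fwhm_s` (rounded) and `raw` (unrounded values).
#' @examples
#' characterize_irf(function(t) gamma_irf(irf_params(2.9, 1.2, 0.5), t))
#' @export
characterize_irf <- function(f, span = c(0, 60),
                             report_precision_s = 0.1,
                             n_grid = 20001L) {
  stopifnot(is.function(f), length(span) == 2, span[2] > span[1])
  t <- seq(span[1], span[2], length.out = n_grid)
  v <- f(t)
  peak_i <- which.max(v)
  if (!is.finite(v[peak_i]) || v[peak_i] <= 0)
    stop("characterization error: function has no positive maximum",
         call. = FALSE)
  # the region above half maximum must be one contiguous run, otherwise
  # the pulse is multimodal and FWHM is ill-defined
  above <- v > v[peak_i] / 2
  runs <- rle(above)
  if (sum(runs$values) != 1L)
    stop("characterization error: function is multimodal at half maximum",
         call. = FALSE)
  # onset: earliest positive value, refined by bisection on positivity
  pos_tol <- v[peak_i] * 1e-12
  first_pos <- which(v > pos_tol)[1]
  if (first_pos == 1L) {
    onset <- t[1]
  } else {
    lo <- t[first_pos - 1L]; hi <- t[first_pos]
    while (hi - lo > 1e-9) {
      mid <- (lo + hi) / 2
      if (f(mid) > pos_tol) hi <- mid else lo <- mid
    }
    onset <- hi
  }
  # time-to-peak: local refinement on the bracketing interval
  lo_i <- max(1L, peak_i - 1L); hi_i <- min(n_grid, peak_i + 1L)
  opt <- stats::optimize(f, c(t[lo_i], t[hi_i]), maximum = TRUE,
                         tol = 1e-9)
  ttp <- opt$maximum
  peak_val <- opt$objective
  half <- peak_val / 2
  run_lo <- which(above)[1]
  run_hi <- which(above)[sum(above)]
  bisect <- function(a, b) {
    # f crosses `half` once in [a, b]
    fa <- f(a) - half
    for (i in 1:60) {
      mid <- (a + b) / 2
      fm <- f(mid) - half
      if (identical(sign(fm), sign(fa))) { a <- mid; fa <- fm } else b <- mid
      if (b - a < 1e-7) break
    }
    (a + b) / 2
  }
  left <- if (run_lo == 1L) t[1] else bisect(t[run_lo - 1L], t[run_lo])
  right <- if (run_hi == n_grid) t[n_grid] else bisect(t[run_hi], t[run_hi + 1L])
  prec <- report_precision_s
  rnd <- function(x) round(x / prec) * prec
  structure(
    list(onset_time_s = rnd(onset), time_to_peak_s = rnd(ttp),
         fwhm_s = rnd(right - left),
         raw = list(onset_time_s = onset, time_to_peak_s = ttp,
                    fwhm_s = right - left, peak_value = peak_val)),
    class = "zte_irf_char")
}

#' @export
print.zte_irf_char <- function(x, ...) {
  cat(sprintf("<zte_irf_char> OT = %g s, TTP = %g s, FWHM = %g s\n",
              x$onset_time_s, x$time_to_peak_s, x$fwhm_s))
  invisible(x)
}
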