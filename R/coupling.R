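#' Response size over a time window
#'
#' The response size of an epoch is the sum of its samples whose
#' relative time falls in the half-open window `[window[1], window[2])`.
#' On a 2-s bin grid a "22-s window" therefore comprises 11 bins and a
#' "first 4 s" window 2 bins.
#'
#' @param epoch numeric vector of epoch samples.
#' @param fs sampling rate (samples/s).
#' @param window `c(start, end)` relative to stimulus onset (s).
#' @param rel_t0 relative time of the first sample (s). Default -28.
#' @return Scalar response size (sum of in-window samples).
#' @export
response_size <- function(epoch, fs, window, rel_t0 = -28) {
  t <- rel_t0 + (seq_along(epoch) - 1) / fs
  sel <- t >= window[1] - 1e-9 & t < window[2] - 1e-9
  if (!any(sel))
    stop("response window contains no samples of the epoch",
         call. = FALSE)
  if (window[1] < rel_t0 - 1e-9 ||
      window[2] > rel_t0 + length(epoch) / fs + 1e-9)
    stop("response window outside the epoch", call. = FALSE)
  sum(epoch[sel])
}

#' Response sizes for every epoch of an epoch set
#'
#' @param ep a [zte_epochs()].
#' @param window `c(start, end)` relative to stimulus onset (s).
#' @return Numeric vector, one size per epoch.
#' @export
response_sizes <- function(ep, window) {
  stopifnot(inherits(ep, "zte_epochs"))
  apply(ep$epochs, 1, response_size, fs = ep$fs, window = window,
        rel_t0 = ep$rel_t0)
}

#' Z-score response sizes within each experiment
#'
#' Standardises `fmri_size` and `neural_size` to zero mean and unit
#' standard deviation across the trials of each experiment (sample
#' standard deviation, n - 1 denominator), making response sizes
#' comparable across experiments with different raw signal scales.
#'
#' @param records data.frame with at least `experiment`, `fmri_size`
#'   and `neural_size` columns, one row per stimulation block.
#' @return The records with both size columns standardised.
#' @export
standardize_within_experiment <- function(records) {
  need <- c("experiment", "fmri_size", "neural_size")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (ex in unique(records$experiment)) {
    sel <- records$experiment == ex
    if (sum(sel) < 2L)
      stop(sprintf("experiment '%s' has fewer than 2 records", ex),
           call. = FALSE)
    for (col in c("fmri_size", "neural_size")) {
      v <- records[[col]][sel]
      s <- stats::sd(v)
      if (s == 0)
        stop(sprintf(
          "degenerate standardization: zero variance of %s in experiment '%s'",
          col, ex), call. = FALSE)
      records[[col]][sel] <- (v - mean(v)) / s
    }
  }
  records
}

#' Average standardized responses per subject and frequency
#'
#' One row per (subject, frequency, modality): the mean standardized
#' fMRI and neuronal response size over all trials of that cell, which
#' is the unit of observation of the response-size regressions.
#'
#' @param records standardized response records
#'   ([standardize_within_experiment()]).
#' @return data.frame with columns `subject`, `frequency_hz`,
#'   `modality`, `n_trials`, `fmri_size`, `neural_size`.
#' @export
aggregate_subject_frequency <- function(records) {
  key <- interaction(records$subject, records$frequency_hz,
                     records$modality, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(subject = d$subject[1], frequency_hz = d$frequency_hz[1],
               modality = d$modality[1], n_trials = nrow(d),
               fmri_size = mean(d$fmri_size),
               neural_size = mean(d$neural_size))
  }))
  rownames(out) <- NULL
  out[order(out$modality, out$subject, out$frequency_hz), ]
}

#' Ordinary least-squares fit between response measures
#'
#' Fits `y = x * beta1 + beta0` (or `y = x * beta1` without intercept)
#' by ordinary least squares.  `r2 = 1 - SSR/TSS` with TSS about the
#' mean when an intercept is included and about zero otherwise;
#' `mse = SSR / n`.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @param with_intercept include an intercept term? Default `TRUE`.
#' @return A `zte_linear_fit` with `beta1`, `beta0` (`NA` without
#'   intercept), `r2`, `mse`, `n`.
#' @export
linear_fit <- function(x, y, with_intercept = TRUE) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("`x` and `y` must have equal length >= 2", call. = FALSE)
  if (with_intercept && stats::var(x) == 0)
    stop("singular fit: `x` has no variance", call. = FALSE)
  if (!with_intercept && all(x == 0))
    stop("singular fit: `x` is identically zero", call. = FALSE)
  fit <- if (with_intercept) stats::lm(y ~ x) else stats::lm(y ~ x + 0)
  res <- stats::residuals(fit)
  ssr <- sum(res^2)
  tss <- if (with_intercept) sum((y - mean(y))^2) else sum(y^2)
  cf <- stats::coef(fit)
  structure(
    list(beta1 = unname(if (with_intercept) cf[2] else cf[1]),
         beta0 = unname(if (with_intercept) cf[1] else NA_real_),
         r2 = 1 - ssr / tss, mse = ssr / length(y), n = length(y)),
    class = "zte_linear_fit")
}

#' @export
print.zte_linear_fit <- function(x, ...) {
  cat(sprintf(
    "<zte_linear_fit> beta1 = %.4g%s, R^2 = %.3f, MSE = %.4g (n = %d)\n",
    x$beta1,
    if (is.na(x$beta0)) " (no intercept)" else sprintf(", beta0 = %.4g",
                                                      x$beta0),
    x$r2, x$mse, x$n))
  invisible(x)
}

#' Frequency-wise no-intercept fits of mean time courses
#'
#' Fits the mean IRF-convolved neuronal time course to the mean fMRI
#' time course separately for each stimulation frequency, using the
#' no-intercept model `y = x * beta1`.  A rising profile of `beta1`
#' over frequency indicates frequency-dependent neurovascular gain.
#'
#' @param mean_fmri,mean_convolved_power named lists of [zte_ts()], one
#'   entry per frequency (names are frequencies in Hz), on a common
#'   grid.
#' @return data.frame with `frequency_hz`, `beta1`, `r2`, `mse`.
#' @export
frequency_wise_timecourse_fit <- function(mean_fmri,
                                          mean_convolved_power) {
  if (!identical(sort(names(mean_fmri)),
                 sort(names(mean_convolved_power))))
    stop("the two lists must cover the same frequencies", call. = FALSE)
  rows <- lapply(names(mean_fmri), function(f) {
    yts <- mean_fmri[[f]]
    xts <- mean_convolved_power[[f]]
    if (length(yts$values) != length(xts$values) ||
        abs(yts$fs - xts$fs) > 1e-9 || abs(yts$t0 - xts$t0) > 1e-9)
      stop(sprintf("mismatched grids at %s Hz", f), call. = FALSE)
    x <- xts$values; y <- yts$values
    sxx <- sum(x^2)
    b1 <- if (sxx > 0) sum(x * y) / sxx else 0
    res <- y - b1 * x
    ssr <- sum(res^2)
    tss <- sum(y^2)
    data.frame(frequency_hz = as.numeric(f), beta1 = b1,
               r2 = if (tss > 0) 1 - ssr / tss else NA_real_,
               mse = ssr / length(y))
  })
  out <- do.call(rbind, rows)
  out[order(out$frequency_hz), ]
}

#' Residual time courses under a fixed reference scaling
#'
#' Fits a single no-intercept regression coefficient on the reference
#' frequency's time courses restricted to `ref_window` (by default the
#' first 4 s of the 7-Hz response, the condition closest to the one the
#' IRF was derived under), then applies that one global scaling to
#' every frequency and returns the residual `fmri - beta1 * convolved
#' power` time courses.  Systematic nonzero residuals at other
#' frequencies or later time points expose stimulation-dependent
#' nonlinearities in neurovascular coupling.
#'
#' @param mean_fmri,mean_convolved_power named lists of [zte_ts()] per
#'   frequency on a common grid.
#' @param ref_frequency reference frequency (Hz). Default 7.
#' @param ref_window window for the reference fit (s relative to
#'   onset). Default `c(0, 4)`.
#' @return List with `beta1` and `residuals` (named list of [zte_ts()]).
#' @export
fixed_scaling_residuals <- function(mean_fmri, mean_convolved_power,
                                    ref_frequency = 7,
                                    ref_window = c(0, 4)) {
  key <- as.character(ref_frequency)
  if (!key %in% names(mean_fmri) ||
      !key %in% names(mean_convolved_power))
    stop(sprintf("reference frequency %s Hz not present", key),
         call. = FALSE)
  yts <- mean_fmri[[key]]
  xts <- mean_convolved_power[[key]]
  t <- ts_times(yts)
  sel <- t >= ref_window[1] - 1e-9 & t < ref_window[2] - 1e-9
  if (!any(sel)) stop("reference window outside the epochs", call. = FALSE)
  x <- xts$values[sel]; y <- yts$values[sel]
  sxx <- sum(x^2)
  if (sxx == 0) stop("reference predictor is zero in the window",
                     call. = FALSE)
  b1 <- sum(x * y) / sxx
  res <- lapply(names(mean_fmri), function(f) {
    r <- mean_fmri[[f]]
    r$values <- r$values - b1 * mean_convolved_power[[f]]$values
    r
  })
  names(res) <- names(mean_fmri)
  list(beta1 = b1, residuals = res)
}

#' Grand-mean epoch by unweighted subject averaging
#'
#' First averages all epochs within each subject, then averages the
#' subject means; subjects with different trial counts therefore weigh
#' equally in the grand mean.
#'
#' @param epochs_by_subject either a list (one element per subject) of
#'   numeric matrices/vectors (trials x samples), or a [zte_epochs()]
#'   whose `labels` contain a `subject` column.
#' @return Numeric grand-mean epoch.
#' @export
mean_of_means <- function(epochs_by_subject) {
  if (inherits(epochs_by_subject, "zte_epochs")) {
    ep <- epochs_by_subject
    if (is.null(ep$labels) || is.null(ep$labels$subject))
      stop("epoch set must carry a `subject` label", call. = FALSE)
    epochs_by_subject <- lapply(split(seq_len(nrow(ep$epochs)),
                                      ep$labels$subject),
                                function(i) ep$epochs[i, , drop = FALSE])
  }
  if (length(epochs_by_subject) < 1L)
    stop("need at least one subject", call. = FALSE)
  subj_means <- lapply(epochs_by_subject, function(m) {
    if (is.null(dim(m))) m else colMeans(m)
  })
  Reduce(`+`, subj_means) / length(subj_means)
}
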