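#' High-pass detrending with a 100-s cutoff
#'
#' Removes slow drifts (including DC) from an fMRI time course with a
#' second-order Butterworth high-pass at `1 / cutoff_s` Hz, applied
#' forward-backward with reflection padding (zero phase, no ringing at
#' epoch boundaries).  Components with periods of three times the
#' cutoff or longer are suppressed by more than 95% while periods well
#' below the cutoff pass essentially unattenuated.
#'
#' @param sig a [zte_ts()].
#' @param cutoff_s cutoff period (s). Default 100 s.
#' @return A detrended [zte_ts()].
#' @export
highpass_100s <- function(sig, cutoff_s = 100) {
  stopifnot(inherits(sig, "zte_ts"))
  n <- length(sig$values)
  if (n <= cutoff_s * sig$fs)
    stop(sprintf(
      "recording (%.6g s) must be longer than the cutoff period (%g s)",
      n / sig$fs, cutoff_s), call. = FALSE)
  hp <- signal::butter(2, (1 / cutoff_s) / (sig$fs / 2), type = "high")
  pad <- as.integer(min(n - 1L, ceiling(3 * cutoff_s * sig$fs)))
  out <- filtfilt_reflect(hp$b, hp$a, sig$values, pad)
  zte_ts(out, fs = sig$fs, t0 = sig$t0, unit = sig$unit)
}

#' Extract a region-of-interest time course from a 4-D volume series
#'
#' Per-volume mean over the voxels of a binary mask.  Inputs may be
#' in-memory arrays or NIfTI file paths (read with RNifti); the volume
#' repetition time is taken from the NIfTI header unless overridden.
#'
#' @param volumes 4-D array, RNifti image, or path to a 4-D NIfTI file.
#' @param mask 3-D binary array, RNifti image, or path; must match the
#'   spatial grid of `volumes` and contain at least one voxel.
#' @param tr_s volume repetition time (s); default taken from the
#'   header, falling back to 1.
#' @param flip_x if `TRUE`, volumes are mirrored along the first
#'   (left-right) axis before masking; used for experiments in which
#'   the stimulated side was mirrored to a common hemisphere.
#' @return A [zte_ts()] with one sample per volume.
#' @export
extract_roi_timecourse <- function(volumes, mask, tr_s = NULL,
                                   flip_x = FALSE) {
  if (is.character(volumes)) volumes <- RNifti::readNifti(volumes)
  if (is.character(mask)) mask <- RNifti::readNifti(mask)
  if (is.null(tr_s)) {
    pd <- tryCatch(RNifti::pixdim(volumes), error = function(e) NULL)
    tr_s <- if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  vol <- unclass(volumes)
  msk <- unclass(mask) != 0
  d <- dim(vol)
  if (length(d) != 4L) stop("`volumes` must be 4-D", call. = FALSE)
  if (!identical(dim(msk), d[1:3]))
    stop("mask grid does not match the volume grid", call. = FALSE)
  if (!any(msk)) stop("mask is empty", call. = FALSE)
  if (flip_x) vol <- vol[d[1]:1, , , , drop = FALSE]
  nt <- d[4]
  nvox <- prod(d[1:3])
  m2 <- matrix(vol, nrow = nvox, ncol = nt)
  series <- colMeans(m2[as.vector(msk), , drop = FALSE])
  zte_ts(series, fs = 1 / tr_s, t0 = 0, unit = "a.u.")
}

#' Radial spoke stream
#'
#' Timestamps of the individual radial k-space readouts ("spokes") of a
#' zero-TE acquisition; one spoke is one excitation-acquisition unit of
#' about a millisecond.
#'
#' @param spoke_times_s strictly increasing spoke timestamps (s).
#' @param spoke_tr_s nominal spoke repetition time (s). Default
#'   0.00097 s.
#' @return A `zte_spokes` object.
#' @export
spoke_stream <- function(spoke_times_s, spoke_tr_s = 0.00097) {
  if (length(spoke_times_s) < 1L || is.unsorted(spoke_times_s,
                                                strictly = TRUE))
    stop("`spoke_times_s` must be non-empty and strictly increasing",
         call. = FALSE)
  structure(list(spoke_times_s = as.numeric(spoke_times_s),
                 spoke_tr_s = spoke_tr_s),
            class = "zte_spokes")
}

#' Plan the event-reordered rebinning of radial spokes
#'
#' The temporal-resolution-enhancement scheduler: every spoke whose
#' event-relative time falls in the peristimulus window
#' `[rel_start, rel_end)` is assigned to bin
#' `floor((t_rel - rel_start) / bin_s)`; spokes outside every event
#' window are discarded.  Pooling spokes across many jittered events
#' fills each fine time bin with enough spokes to reconstruct one
#' volume per bin, turning a slow volume series into a fine-grained
#' mean response.
#'
#' @param spokes a [spoke_stream()].
#' @param event_onsets stimulus onset times (s); event windows must not
#'   overlap.
#' @param rel_start,rel_end peristimulus window (s relative to onset).
#' @param bin_s bin width (s); the window must be an integer number of
#'   bins.
#' @return A `zte_rebin_plan` with `n_bins`, `bin_width_s`, `window`,
#'   and `assignment` (data.frame with per-spoke `event` and `bin`,
#'   `NA` for discarded spokes).
#' @export
plan_event_rebin <- function(spokes, event_onsets, rel_start, rel_end,
                             bin_s) {
  stopifnot(inherits(spokes, "zte_spokes"))
  nb <- (rel_end - rel_start) / bin_s
  if (abs(nb - round(nb)) > 1e-9)
    stop("window must be an integer number of bins", call. = FALSE)
  nb <- as.integer(round(nb))
  ons <- sort(event_onsets)
  if (length(ons) > 1L &&
      any(ons[-1] + rel_start < ons[-length(ons)] + rel_end - 1e-12))
    stop("event windows overlap", call. = FALSE)
  t <- spokes$spoke_times_s
  # each window [onset + rel_start, onset + rel_end) picks up its spokes
  win_lo <- ons + rel_start
  ev <- findInterval(t, win_lo)
  ev[ev == 0L] <- NA_integer_
  t_rel <- t - ons[ev]
  inside <- !is.na(ev) & t_rel >= rel_start & t_rel < rel_end
  bin <- rep(NA_integer_, length(t))
  # small epsilon so grid-aligned spoke times land in the intended bin
  bin[inside] <- as.integer(
    floor((t_rel[inside] - rel_start) / bin_s + 1e-7)) + 1L
  bin[!is.na(bin) & bin > nb] <- NA_integer_   # float guard at rel_end
  ev[is.na(bin)] <- NA_integer_
  structure(
    list(n_bins = nb, bin_width_s = bin_s,
         window = c(rel_start, rel_end),
         assignment = data.frame(event = ev, bin = bin),
         n_assigned = sum(!is.na(bin)),
         n_discarded = sum(is.na(bin))),
    class = "zte_rebin_plan")
}

#' @export
print.zte_rebin_plan <- function(x, ...) {
  cat(sprintf(
    "<zte_rebin_plan> %d bins of %g s over [%g, %g) s; %d spokes assigned (mean %.1f/bin), %d discarded\n",
    x$n_bins, x$bin_width_s, x$window[1], x$window[2], x$n_assigned,
    x$n_assigned / x$n_bins, x$n_discarded))
  invisible(x)
}

#' Apply a rebin plan to per-spoke surrogate values
#'
#' Averages the surrogate signal values of all spokes assigned to each
#' peristimulus bin (pooling across events), yielding the
#' enhanced-resolution response time course.  Empty bins are flagged
#' with a warning and set to `NA`.
#'
#' @param plan a [plan_event_rebin()] result.
#' @param spoke_values numeric vector, one value per spoke of the
#'   stream the plan was built from.
#' @return A [zte_ts()] at `1 / bin_width_s` Hz starting at the window
#'   start (relative time).
#' @export
apply_rebin <- function(plan, spoke_values) {
  stopifnot(inherits(plan, "zte_rebin_plan"))
  if (length(spoke_values) != nrow(plan$assignment))
    stop("need exactly one value per spoke", call. = FALSE)
  keep <- !is.na(plan$assignment$bin)
  sums <- tapply(spoke_values[keep], plan$assignment$bin[keep], mean)
  out <- rep(NA_real_, plan$n_bins)
  out[as.integer(names(sums))] <- as.numeric(sums)
  if (anyNA(out))
    warning(sprintf("%d empty bin(s) set to NA", sum(is.na(out))),
            call. = FALSE)
  v <- out
  if (anyNA(v)) v[is.na(v)] <- 0  # zte_ts requires finite; remember NA
  res <- zte_ts(v, fs = 1 / plan$bin_width_s, t0 = plan$window[1],
                unit = "a.u.")
  if (anyNA(out)) {
    res$values[is.na(out)] <- NA_real_
    attr(res, "empty_bins") <- which(is.na(out))
  }
  res
}
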