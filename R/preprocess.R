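# Frequency response magnitudes of the cleaning chain. The filter is applied
# in the frequency domain with a purely real transfer function, which is the
# zero-phase equivalent of forward-backward (filtfilt) application of the
# corresponding IIR cascade: |H(f)|^2 of a 4th-order Butterworth bandpass and
# a biquad notch of quality Q.
butter_bp_mag <- function(f, lo, hi, order = 4) {
  hp <- ifelse(f == 0, 0, 1 / sqrt(1 + (lo / pmax(f, 1e-12))^(2 * order)))
  lp <- 1 / sqrt(1 + (f / hi)^(2 * order))
  hp * lp
}

notch_mag <- function(f, f0, q = 30) {
  num <- abs(f^2 - f0^2)
  den <- sqrt((f^2 - f0^2)^2 + (f * f0 / q)^2)
  ifelse(den == 0, 0, num / den)
}

# zero-phase frequency-domain filtering with reflection padding
fft_filter <- function(x, rate, response_fun) {
  n <- length(x)
  pad <- min(n, rate * 5)
  xe <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1):n]))
  m <- length(xe)
  nfft <- next_smooth(m)
  xe <- c(xe, rep(0, nfft - m))
  f <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * rate / nfft
  h <- response_fun(abs(f))
  y <- Re(stats::fft(stats::fft(xe) * h, inverse = TRUE)) / nfft
  y[(pad + 1):(pad + n)]
}

#' Zero-phase bandpass and notch filtering
#'
#' Applies the magnitude response of a forward-backward 4th-order Butterworth
#' bandpass plus a 60 Hz biquad notch (Q = 30) as a zero-phase frequency-domain
#' filter, channel by channel. Defaults follow the acquisition cleaning chain:
#' 0.5-150 Hz passband, 60 Hz line-noise notch. The operation is linear and
#' introduces no phase distortion.
#'
#' @param recording an `eeg_recording`.
#' @param band length-2 passband edges in Hz.
#' @param notch notch centre frequency in Hz (`NULL` disables it).
#' @param notch_q notch quality factor.
#' @return a filtered copy of the recording with updated provenance.
#' @export
bandpass_notch <- function(recording, band = c(0.5, 150), notch = 60,
                           notch_q = 30) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    stopf("band must be ascending positive edges")
  }
  if (recording$rate <= 2 * band[2]) {
    stopf("passband upper edge %g Hz infeasible at %g Hz sampling",
          band[2], recording$rate)
  }
  resp <- function(f) {
    h <- butter_bp_mag(f, band[1], band[2])^2
    if (!is.null(notch)) h <- h * notch_mag(f, notch, notch_q)^2
    h
  }
  out <- recording
  for (i in seq_len(nrow(out$data))) {
    out$data[i, ] <- fft_filter(out$data[i, ], out$rate, resp)
  }
  out$provenance <- c(out$provenance,
                      sprintf("bandpass_notch(%g-%g Hz, notch %s Hz)",
                              band[1], band[2],
                              if (is.null(notch)) "none" else notch))
  out
}

#' Remove channels by amplitude standard deviation
#'
#' Channels whose sample standard deviation falls below `lo` or above `hi`
#' microvolts are dropped as flat or saturated. (The acquisition protocol
#' states the bounds in millivolts, a unit typo: scalp EEG never spans
#' millivolt standard deviations, so the bounds are read in microvolts.)
#'
#' @param recording an `eeg_recording` (normally already filtered).
#' @param lo,hi standard-deviation bounds in microvolts.
#' @return list with `recording` (channels kept) and `removed`
#'   (data.frame: channel, sd, reason).
#' @export
reject_channels_by_sd <- function(recording, lo = 2, hi = 120) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$data) < 1) stopf("recording has no channels")
  sds <- apply(recording$data, 1, stats::sd)
  bad <- sds < lo | sds > hi
  if (all(bad)) stopf("all channels rejected by SD bounds [%g, %g]", lo, hi)
  removed <- data.frame(channel = recording$channel_names[bad],
                        sd = unname(sds[bad]),
                        reason = ifelse(sds[bad] < lo, "flat", "noisy"))
  out <- recording
  out$data <- out$data[!bad, , drop = FALSE]
  out$channel_names <- out$channel_names[!bad]
  out$provenance <- c(out$provenance,
                      sprintf("reject_channels_by_sd(lo=%g, hi=%g): removed %d",
                              lo, hi, sum(bad)))
  list(recording = out, removed = removed)
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Epochs span the half-open window `[tmin, tmax)` relative to each stimulus
#' onset, so a (-1, 3.5) s window at 1000 Hz gives exactly 4500 samples.
#' Onsets whose epoch would fall partly outside the recording are dropped and
#' logged.
#'
#' @param recording an `eeg_recording`.
#' @param onsets numeric onset times in seconds, or a `trial_schedule`; by
#'   default taken from the recording's event markers.
#' @param tmin,tmax epoch window in seconds relative to onset (`tmin < 0 < tmax`).
#' @return an `epoch_set`: `data` (epochs x channels x samples array),
#'   `times_s`, `tmin_s`, `tmax_s`, `rate`, `channel_names`,
#'   `retained_flags` (per scheduled onset: in range or not), `rejection_log`.
#' @export
epoch_recording <- function(recording, onsets = NULL, tmin = -1, tmax = 3.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!(tmin < 0 && 0 < tmax)) stopf("need tmin < 0 < tmax")
  if (inherits(onsets, "trial_schedule")) onsets <- onsets$onsets
  if (is.null(onsets)) onsets <- recording$events$time_s
  if (!length(onsets)) stopf("no onsets to epoch around")
  rate <- recording$rate
  nsamp <- round((tmax - tmin) * rate)
  ntot <- ncol(recording$data)
  start <- round((onsets + tmin) * rate) + 1L
  ok <- start >= 1L & (start + nsamp - 1L) <= ntot
  if (!any(ok)) stopf("no epoch fits inside the recording")
  kept <- which(ok)
  arr <- array(0, dim = c(length(kept), nrow(recording$data), nsamp),
               dimnames = list(NULL, recording$channel_names, NULL))
  for (k in seq_along(kept)) {
    i0 <- start[kept[k]]
    arr[k, , ] <- recording$data[, i0:(i0 + nsamp - 1L)]
  }
  log <- if (all(ok)) character() else {
    sprintf("onset %.3f s dropped: epoch outside recording", onsets[!ok])
  }
  structure(
    list(data = arr, times_s = tmin + (seq_len(nsamp) - 1) / rate,
         tmin_s = tmin, tmax_s = tmax, rate = rate,
         channel_names = recording$channel_names,
         onset_index = which.min(abs(tmin + (seq_len(nsamp) - 1) / rate)),
         retained_flags = ok, rejection_log = log,
         provenance = c(recording$provenance,
                        sprintf("epoch(%g, %g): %d/%d onsets",
                                tmin, tmax, sum(ok), length(onsets)))),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples [%g, %g) s @ %g Hz\n",
              d[1], d[2], d[3], x$tmin_s, x$tmax_s, x$rate))
  invisible(x)
}

#' Reject epochs exceeding an amplitude threshold
#'
#' An epoch is removed when any sample on any retained channel strictly
#' exceeds `thresh_uv` in absolute value; a sample exactly at the threshold
#' is kept (the tagging rule is "> 200 uV and < -200 uV", a strict
#' inequality). Fully automatic: tagged epochs are removed, no manual pass.
#'
#' @param epochs an `epoch_set`.
#' @param thresh_uv rejection threshold in microvolts.
#' @return the `epoch_set` restricted to surviving epochs, with
#'   `retained_flags` updated and the rejection count logged.
#' @export
reject_epochs_by_amplitude <- function(epochs, thresh_uv = 200) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (thresh_uv <= 0) stopf("threshold must be positive")
  n <- dim(epochs$data)[1]
  bad <- vapply(seq_len(n),
                function(i) any(abs(epochs$data[i, , ]) > thresh_uv),
                logical(1))
  if (all(bad)) stopf("no epoch survives the +/-%g uV threshold", thresh_uv)
  out <- epochs
  out$data <- epochs$data[!bad, , , drop = FALSE]
  keep_flags <- epochs$retained_flags
  keep_flags[keep_flags] <- !bad
  out$retained_flags <- keep_flags
  out$rejection_log <- c(epochs$rejection_log,
                         sprintf("%d epochs removed at +/-%g uV",
                                 sum(bad), thresh_uv))
  out$provenance <- c(epochs$provenance,
                      sprintf("reject_epochs_by_amplitude(%g): %d removed",
                              thresh_uv, sum(bad)))
  out
}

#' Average an epoch set over a region of interest
#'
#' Returns a one-virtual-channel epoch set holding, per epoch and sample, the
#' arithmetic mean over the ROI electrodes that survived channel rejection.
#'
#' @param epochs an `epoch_set`.
#' @param roi_def a `roi_definition` (see [roi_definitions()]) or a character
#'   vector of electrode labels.
#' @return an `epoch_set` with a single channel named after the ROI;
#'   contributing electrodes are logged in `provenance`.
#' @export
roi_average <- function(epochs, roi_def) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(roi_def)) {
    roi_def <- structure(list(name = "custom", electrodes = roi_def),
                         class = "roi_definition")
  }
  present <- intersect(roi_def$electrodes, epochs$channel_names)
  if (!length(present)) {
    stopf("ROI '%s': none of its electrodes (%s) survive in the data",
          roi_def$name, paste(roi_def$electrodes, collapse = ", "))
  }
  idx <- match(present, epochs$channel_names)
  d <- dim(epochs$data)
  avg <- array(0, dim = c(d[1], 1L, d[3]),
               dimnames = list(NULL, roi_def$name, NULL))
  for (i in seq_len(d[1])) {
    sub <- epochs$data[i, idx, , drop = FALSE]
    avg[i, 1, ] <- colMeans(array(sub, dim = c(length(idx), d[3])))
  }
  out <- epochs
  out$data <- avg
  out$channel_names <- roi_def$name
  out$provenance <- c(epochs$provenance,
                      sprintf("roi_average(%s): mean of %s", roi_def$name,
                              paste(present, collapse = "+")))
  out
}
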