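# complex Morlet kernel at frequency f: Gaussian envelope of width
# sigma_t = n_cycles/(2*pi*f), truncated at +/- 3 sigma_t, unit L2 energy
morlet_kernel <- function(f, n_cycles, rate) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- max(1L, ceiling(3 * sigma_t * rate))
  t <- (-half:half) / rate
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w / sqrt(sum(Mod(w)^2))
}

default_cycles <- function(f) pmax(3, f / 2)

#' Complex Morlet wavelet decomposition of ROI epochs
#'
#' Convolves every trial of a single-channel epoch set with unit-energy
#' complex Morlet kernels on a frequency grid. The number of cycles per
#' kernel grows with frequency (`max(3, f/2)` by default: 3 cycles at low
#' frequencies up to 60 at 120 Hz), trading temporal for spectral resolution
#' the way chirp-response analyses require. Coefficients are stored on a
#' decimated time grid; cells closer to an epoch edge than half a kernel
#' length (3 sigma_t) are flagged invalid and excluded from all summaries.
#'
#' @param roi_epochs a single-channel `epoch_set` (see [roi_average()]), or a
#'   trials x samples numeric matrix with attributes supplied via `times_s`/`rate`.
#' @param freqs_hz strictly increasing frequency grid, Hz; all below Nyquist.
#' @param cycles_fun function mapping frequency to cycle count.
#' @param time_step_s spacing of the stored time grid, seconds.
#' @return a `tf_decomposition`: complex `coeffs` (trials x freqs x times),
#'   `freqs_hz`, `times_s`, `valid_mask` (freqs x times), `rate`, `n_trials`,
#'   `cycles_rule`.
#' @export
morlet_tf <- function(roi_epochs, freqs_hz = 2:120,
                      cycles_fun = default_cycles, time_step_s = 0.01) {
  stopifnot(inherits(roi_epochs, "epoch_set"))
  if (dim(roi_epochs$data)[2] != 1L) {
    stopf("morlet_tf expects a single-channel (ROI-averaged) epoch set")
  }
  if (is.unsorted(freqs_hz, strictly = TRUE)) {
    stopf("freqs_hz must be strictly increasing")
  }
  rate <- roi_epochs$rate
  if (max(freqs_hz) >= rate / 2) {
    stopf("max frequency %g Hz is not below Nyquist (%g Hz)",
          max(freqs_hz), rate / 2)
  }
  d <- dim(roi_epochs$data)
  ntr <- d[1]; nsamp <- d[3]
  kernels <- lapply(freqs_hz, function(f) morlet_kernel(f, cycles_fun(f), rate))
  half_len <- vapply(kernels, function(k) (length(k) - 1L) %/% 2L, integer(1))
  if (max(half_len) * 2L + 1L > nsamp) {
    stopf("epoch (%d samples) shorter than the %g Hz kernel (%d samples)",
          nsamp, freqs_hz[which.max(half_len)], max(half_len) * 2L + 1L)
  }

  step <- max(1L, round(time_step_s * rate))
  keep_idx <- seq(1L, nsamp, by = step)
  times_s <- roi_epochs$times_s[keep_idx]
  nf <- length(freqs_hz); nt <- length(keep_idx)

  nfft <- next_smooth(nsamp + max(half_len) * 2L)
  kern_fft <- vector("list", nf)
  for (j in seq_len(nf)) {
    kpad <- c(kernels[[j]], complex(real = rep(0, nfft - length(kernels[[j]]))))
    kern_fft[[j]] <- stats::fft(kpad)
  }

  coeffs <- array(complex(real = 0), dim = c(ntr, nf, nt))
  for (i in seq_len(ntr)) {
    x <- roi_epochs$data[i, 1, ]
    xf <- stats::fft(c(x, rep(0, nfft - nsamp)))
    for (j in seq_len(nf)) {
      conv <- stats::fft(xf * kern_fft[[j]], inverse = TRUE) / nfft
      # 'same' alignment: kernel centre over each sample
      coeffs[i, j, ] <- conv[half_len[j] + keep_idx]
    }
  }

  valid <- matrix(TRUE, nf, nt)
  for (j in seq_len(nf)) {
    valid[j, ] <- keep_idx > half_len[j] & keep_idx <= nsamp - half_len[j]
  }

  structure(
    list(coeffs = coeffs, freqs_hz = freqs_hz, times_s = times_s,
         valid_mask = valid, rate = rate, n_trials = ntr,
         cycles_rule = "n_cycles(f) = max(3, f/2), kernel support +/-3 sigma_t"),
    class = "tf_decomposition"
  )
}

#' @export
print.tf_decomposition <- function(x, ...) {
  cat(sprintf("<tf_decomposition> %d trials x %d freqs (%g-%g Hz) x %d times (%.2f..%.2f s)\n",
              x$n_trials, length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_s), min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Event-related spectral perturbation (dB)
#'
#' Classic divisive ERSP: trial-averaged power at each time-frequency cell
#' expressed in dB relative to the trial-averaged pre-stimulus baseline power
#' of the same frequency, `10*log10(P(f,t) / B(f))`. The baseline statistic
#' at each frequency uses only the valid (edge-free) cells inside the
#' baseline window; a frequency with no valid baseline cell, or zero baseline
#' power, is an error.
#'
#' @param tf a `tf_decomposition`.
#' @param baseline_window_s length-2 window in epoch time, pre-stimulus.
#' @return an `ersp_map`: `values_db` (freqs x times, NA where invalid),
#'   `freqs_hz`, `times_s`, `valid_mask`, `baseline_window_s`, `n_trials`.
#' @export
ersp <- function(tf, baseline_window_s = c(-0.8, -0.2)) {
  stopifnot(inherits(tf, "tf_decomposition"))
  if (baseline_window_s[1] >= baseline_window_s[2] || baseline_window_s[2] > 0) {
    stopf("baseline window must be ascending and pre-stimulus")
  }
  pow <- Mod(tf$coeffs)^2
  mp <- colMeans(pow, dims = 1)                # freqs x times mean power
  in_base <- tf$times_s >= baseline_window_s[1] &
    tf$times_s <= baseline_window_s[2]
  if (!any(in_base)) stopf("baseline window outside the epoch time grid")
  nf <- length(tf$freqs_hz)
  base <- numeric(nf)
  for (j in seq_len(nf)) {
    usable <- in_base & tf$valid_mask[j, ]
    if (!any(usable)) {
      stopf("no valid baseline cell at %g Hz; widen the baseline window",
            tf$freqs_hz[j])
    }
    base[j] <- mean(mp[j, usable])
    if (base[j] <= 0) stopf("zero baseline power at %g Hz", tf$freqs_hz[j])
  }
  vals <- 10 * log10(sweep(mp, 1, base, "/"))
  vals[!tf$valid_mask] <- NA_real_
  structure(
    list(values = vals, freqs_hz = tf$freqs_hz, times_s = tf$times_s,
         valid_mask = tf$valid_mask, baseline_window_s = baseline_window_s,
         n_trials = tf$n_trials, measure = "ERSP_db"),
    class = c("ersp_map", "tf_map")
  )
}

#' Inter-trial coherence
#'
#' The modulus of the trial-mean unit phase vector at each time-frequency
#' cell: 0 for random phases, 1 for perfect phase locking. Trials with a
#' vanishing coefficient at a cell are excluded at that cell.
#'
#' @param tf a `tf_decomposition` with at least 2 trials.
#' @return an `itc_map` with `values` in `[0, 1]` (NA where invalid).
#' @export
itc <- function(tf) {
  stopifnot(inherits(tf, "tf_decomposition"))
  if (tf$n_trials < 2) stopf("ITC requires at least 2 trials")
  z <- tf$coeffs
  m <- Mod(z)
  zero <- m == 0
  z <- z / m
  z[zero] <- NA_complex_
  counts <- colSums(!zero, dims = 1)
  zsum <- colSums(z, na.rm = TRUE, dims = 1)
  vals <- matrix(NA_real_, length(tf$freqs_hz), length(tf$times_s))
  pos <- counts > 0
  vals[pos] <- Mod(zsum[pos] / counts[pos])
  vals[!tf$valid_mask] <- NA_real_
  structure(
    list(values = vals, freqs_hz = tf$freqs_hz, times_s = tf$times_s,
         valid_mask = tf$valid_mask, n_trials = tf$n_trials, measure = "ITC"),
    class = c("itc_map", "tf_map")
  )
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<%s> %s: %d freqs x %d times, %d trials\n",
              class(x)[1], x$measure, length(x$freqs_hz), length(x$times_s),
              x$n_trials))
  invisible(x)
}

#' Expected inter-trial coherence under uniform phases
#'
#' Analytic null: the mean resultant length of `n` i.i.d. uniform phase
#' vectors has expectation `sqrt(pi / (4 n))` (about 0.070 at n = 160).
#'
#' @param n_trials number of trials.
#' @return expected ITC under no phase locking.
#' @export
itc_null_expectation <- function(n_trials) sqrt(pi / (4 * n_trials))
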