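# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures exist on disk.

# single-channel epoch_set from a trials x samples matrix (default grid:
# the standard 4.5 s epoch at 1000 Hz)
toy_epochs <- function(mat, rate = 1000, tmin = -1) {
  if (is.vector(mat)) mat <- matrix(mat, nrow = 1)
  nsamp <- ncol(mat)
  arr <- array(0, dim = c(nrow(mat), 1, nsamp), dimnames = list(NULL, "Fz", NULL))
  arr[, 1, ] <- mat
  structure(
    list(data = arr, times_s = tmin + (seq_len(nsamp) - 1) / rate,
         tmin_s = tmin, tmax_s = tmin + nsamp / rate, rate = rate,
         channel_names = "Fz", onset_index = round(-tmin * rate) + 1L,
         retained_flags = rep(TRUE, nrow(mat)), rejection_log = character(),
         provenance = character()),
    class = "epoch_set"
  )
}

# epochs holding a sinusoid with random phase per trial plus white noise
sine_epochs <- function(n_trials, freq, amp_fun, noise_sd = 0.3, rate = 1000,
                        tmin = -1, nsamp = 4500, seed = 1) {
  t <- tmin + (seq_len(nsamp) - 1) / rate
  withr_seed <- function(expr) chirpent:::with_seed(seed, expr)
  mat <- withr_seed(t(vapply(seq_len(n_trials), function(i) {
    amp_fun(t) * sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(nsamp, 0, noise_sd)
  }, numeric(nsamp))))
  toy_epochs(mat, rate = rate, tmin = tmin)
}

# hand-built tf_decomposition with prescribed complex coefficients
toy_tf <- function(coeffs, freqs_hz, times_s, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, length(freqs_hz), length(times_s))
  structure(
    list(coeffs = coeffs, freqs_hz = freqs_hz, times_s = times_s,
         valid_mask = valid, rate = 1000, n_trials = dim(coeffs)[1],
         cycles_rule = "toy"),
    class = "tf_decomposition"
  )
}

# hand-built itc_map with prescribed values
toy_itc_map <- function(values, freqs_hz, times_s, n_trials = 10) {
  structure(
    list(values = values, freqs_hz = freqs_hz, times_s = times_s,
         valid_mask = !is.na(values), n_trials = n_trials, measure = "ITC"),
    class = c("itc_map", "tf_map")
  )
}

toy_ersp_map <- function(values, freqs_hz, times_s, n_trials = 10) {
  structure(
    list(values = values, freqs_hz = freqs_hz, times_s = times_s,
         valid_mask = !is.na(values), n_trials = n_trials,
         measure = "ERSP_db"),
    class = c("ersp_map", "tf_map")
  )
}

# tiny deterministic recording: named channels built from a generator function
toy_recording <- function(channel_funs, dur_s = 10, rate = 1000,
                          events = data.frame(time_s = numeric(),
                                              label = character())) {
  t <- (seq_len(dur_s * rate) - 1) / rate
  data <- t(vapply(channel_funs, function(f) f(t), numeric(length(t))))
  new_recording(data, names(channel_funs), rate, events = events)
}
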