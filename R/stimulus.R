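#' Build an amplitude-modulated chirp stimulus
#'
#' A pure-tone carrier whose amplitude envelope is a raised sinusoid sweeping
#' linearly in modulation frequency from `am_f0` to `am_f1` over the stimulus
#' duration. The default arguments reproduce the auditory chirp used for
#' steady-state entrainment paradigms: a 1000 Hz tone AM-swept 0 to 120 Hz
#' over 2000 ms.
#'
#' The instantaneous AM frequency at time `t` is
#' `am_f0 + (am_f1 - am_f0) * t / duration_s`; the envelope is
#' `(1 - cos(phase)) / 2`, so it starts at 0 and stays within `[0, 1]`,
#' and the waveform stays within `[-1, 1]`.
#'
#' @param carrier_hz carrier tone frequency in Hz.
#' @param am_f0,am_f1 start and end AM frequency of the linear sweep, Hz.
#'   `am_f0 == am_f1` gives a constant-rate steady-state stimulus.
#' @param duration_s stimulus duration in seconds.
#' @param rate audio sampling rate in Hz; must exceed twice the carrier.
#' @return an object of class `chirp_stimulus` with fields `samples`,
#'   `envelope`, `rate`, `carrier_hz`, `am_f0`, `am_f1`, `duration_s`.
#' @examples
#' stim <- make_chirp_stimulus()
#' am_frequency_at(stim, 1.0) # 60 Hz, midpoint of the 0-120 Hz sweep
#' @export
make_chirp_stimulus <- function(carrier_hz = 1000, am_f0 = 0, am_f1 = 120,
                                duration_s = 2, rate = 44100) {
  if (duration_s <= 0) stopf("duration_s must be positive (got %g)", duration_s)
  if (rate <= 2 * carrier_hz) {
    stopf("rate (%g Hz) must exceed the carrier Nyquist requirement 2 x %g Hz",
          rate, carrier_hz)
  }
  if (am_f0 < 0 || am_f1 < 0) stopf("AM frequencies must be non-negative")
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  # AM phase: integral of the linear instantaneous-frequency sweep
  am_phase <- 2 * pi * (am_f0 * t + (am_f1 - am_f0) * t^2 / (2 * duration_s))
  envelope <- (1 - cos(am_phase)) / 2
  samples <- envelope * sin(2 * pi * carrier_hz * t)
  structure(
    list(samples = samples, envelope = envelope, rate = rate,
         carrier_hz = carrier_hz, am_f0 = am_f0, am_f1 = am_f1,
         duration_s = duration_s),
    class = "chirp_stimulus"
  )
}

#' Instantaneous AM frequency of a chirp stimulus
#'
#' @param stimulus a `chirp_stimulus`.
#' @param t_s time(s) in seconds from stimulus onset.
#' @return AM frequency in Hz (NA outside `[0, duration_s]`).
#' @export
am_frequency_at <- function(stimulus, t_s) {
  stopifnot(inherits(stimulus, "chirp_stimulus"))
  f <- stimulus$am_f0 +
    (stimulus$am_f1 - stimulus$am_f0) * t_s / stimulus$duration_s
  f[t_s < 0 | t_s > stimulus$duration_s] <- NA_real_
  f
}

#' @export
print.chirp_stimulus <- function(x, ...) {
  cat(sprintf(
    "<chirp_stimulus> %g Hz carrier, AM %g-%g Hz over %g s (%d samples @ %g Hz)\n",
    x$carrier_hz, x$am_f0, x$am_f1, x$duration_s, length(x$samples), x$rate))
  invisible(x)
}

#' Randomized trial schedule for repeated stimulus presentation
#'
#' Stimulus onsets are laid out sequentially; the silent gap between the end
#' of one stimulus and the next onset is drawn uniformly within `isi_bounds_ms`.
#' Defaults reproduce the chirp paradigm: 160 presentations with inter-stimulus
#' intervals jittered in 1500-2500 ms.
#'
#' @param n_trials number of presentations (>= 1).
#' @param isi_bounds_ms length-2 ascending bounds of the uniform ISI jitter, ms.
#' @param stimulus_duration_s stimulus length used to place successive onsets.
#' @param seed integer seed; identical seeds give identical schedules.
#' @param lead_in_s silence before the first onset (room for pre-stimulus epochs).
#' @return an object of class `trial_schedule` with fields `onsets` (seconds,
#'   strictly increasing), `isi_ms`, `n_trials`, `isi_bounds_ms`,
#'   `stimulus_duration_s`, `seed`.
#' @export
make_trial_schedule <- function(n_trials = 160, isi_bounds_ms = c(1500, 2500),
                                stimulus_duration_s = 2, seed = 1,
                                lead_in_s = 2) {
  if (n_trials < 1) stopf("n_trials must be >= 1")
  if (length(isi_bounds_ms) != 2 || isi_bounds_ms[1] > isi_bounds_ms[2]) {
    stopf("isi_bounds_ms must be an ascending pair")
  }
  gaps_s <- with_seed(seed, stats::runif(max(n_trials - 1L, 0L),
                                         isi_bounds_ms[1], isi_bounds_ms[2])) / 1000
  onsets <- lead_in_s + c(0, cumsum(stimulus_duration_s + gaps_s))
  structure(
    list(onsets = onsets, isi_ms = gaps_s * 1000, n_trials = as.integer(n_trials),
         isi_bounds_ms = isi_bounds_ms,
         stimulus_duration_s = stimulus_duration_s, seed = seed),
    class = "trial_schedule"
  )
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d trials, ISI %g-%g ms, first onset %.3f s, last %.3f s\n",
              x$n_trials, x$isi_bounds_ms[1], x$isi_bounds_ms[2],
              x$onsets[1], x$onsets[x$n_trials]))
  invisible(x)
}
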