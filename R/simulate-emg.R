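emg_protocols <- function() {
  c("baseline", "SICI2", "SICI4", "ICF10", "ICF15", "SICF3",
    "LICI100", "LICI220", "CSP",
    paste0("IO_", seq(100, 150, 10)))
}

# ISI in ms between conditioning and test pulse, by paired protocol
protocol_isi_ms <- function(protocol) {
  switch(protocol,
         SICI2 = 2, SICI4 = 4, ICF10 = 10, ICF15 = 15, SICF3 = 3,
         LICI100 = 100, LICI220 = 220, NA_real_)
}

#' Parameters for synthetic EMG trial sets
#'
#' Describes one TMS protocol block: 15 trials by default, matching the
#' acquisition ("fifteen trials were obtained for each of these measures").
#' Test stimuli are at 125% of resting motor threshold (rMT), conditioning
#' stimuli at 70% rMT; cortical excitability trials span 100-150% rMT in 10%
#' steps (the `IO_*` protocols).
#'
#' @param protocol one of `baseline`, `SICI2`, `SICI4`, `ICF10`, `ICF15`,
#'   `SICF3`, `LICI100`, `LICI220`, `CSP`, `IO_100` ... `IO_150`.
#' @param programmed_ratio conditioned/baseline (or second/first) MEP ratio
#'   the trials realize on average; `< 1` inhibition, `> 1` facilitation.
#' @param programmed_csp_ms silent-period duration for the CSP protocol, ms.
#' @param mep_amplitude_mv mean baseline MEP peak-to-peak amplitude, mV.
#' @param noise_mv additive trace noise SD, mV.
#' @param n_trials trials per block.
#' @param seed integer seed.
#' @return an `emg_sim_params` object.
#' @export
emg_sim_params <- function(protocol, programmed_ratio = 1,
                           programmed_csp_ms = 150, mep_amplitude_mv = 1,
                           noise_mv = 0.02, n_trials = 15, seed = 1) {
  if (!protocol %in% emg_protocols()) {
    stopf("unknown protocol '%s'; known: %s", protocol,
          paste(emg_protocols(), collapse = ", "))
  }
  if (programmed_ratio <= 0) stopf("programmed_ratio must be > 0")
  if (n_trials < 1 || mep_amplitude_mv <= 0 || noise_mv < 0) {
    stopf("parameters must be positive")
  }
  structure(
    list(protocol = protocol, programmed_ratio = programmed_ratio,
         programmed_csp_ms = programmed_csp_ms,
         mep_amplitude_mv = mep_amplitude_mv, noise_mv = noise_mv,
         n_trials = as.integer(n_trials), seed = seed),
    class = "emg_sim_params"
  )
}

# biphasic MEP template of given duration, normalized to unit peak-to-peak
mep_template <- function(rate, dur_s = 0.012) {
  n <- round(dur_s * rate)
  t <- seq(0, 1, length.out = n)
  w <- sin(2 * pi * t) * sin(pi * t)^2
  w / (max(w) - min(w))
}

# tonic contraction: band-limited noise with a known rectified mean (mV)
contraction_segment <- function(n, rate, rect_mean_mv = 0.15) {
  x <- stats::rnorm(n)
  x <- moving_average(x, round(0.002 * rate))
  x * rect_mean_mv / mean(abs(x))
}

#' Simulate EMG trials for one TMS protocol block
#'
#' Produces surface-EMG-like traces (mV, 5000 Hz) with pulse timestamps.
#' Paired protocols carry a conditioning and a test pulse at the protocol
#' ISI; the conditioned (or second) MEP realizes `programmed_ratio` times
#' the baseline amplitude on average, with small lognormal trial-to-trial
#' jitter. The CSP protocol embeds a tonic pre-pulse contraction, an MEP,
#' then electromyographic silence ending `programmed_csp_ms` after the
#' pulse. Input/output protocols scale the MEP with stimulus intensity
#' through a monotone recruitment curve.
#'
#' @param params an [emg_sim_params()] object.
#' @param rate sampling rate, Hz.
#' @return list of `emg_trial` objects: `trace` (mV), `rate`,
#'   `pulse_times_s`, `protocol`, `intensity_pct_rmt`.
#' @export
simulate_emg_trials <- function(params, rate = 5000) {
  stopifnot(inherits(params, "emg_sim_params"))
  proto <- params$protocol
  with_seed(params$seed, {
    lapply(seq_len(params$n_trials), function(i) {
      simulate_one_emg_trial(params, rate)
    })
  })
}

simulate_one_emg_trial <- function(params, rate) {
  proto <- params$protocol
  dur <- if (grepl("^LICI", proto) || proto == "CSP") 1.0 else 0.6
  n <- round(dur * rate)
  trace <- stats::rnorm(n, 0, params$noise_mv)
  tmpl <- mep_template(rate)
  latency_s <- 0.022
  jitter <- function() stats::rlnorm(1, -0.08^2 / 2, 0.08)
  add_mep <- function(trace, t_pulse, amp) {
    i0 <- round((t_pulse + latency_s) * rate) + 1L
    idx <- i0:(i0 + length(tmpl) - 1L)
    trace[idx] <- trace[idx] + amp * tmpl
    trace
  }
  base_amp <- params$mep_amplitude_mv

  if (proto == "baseline") {
    t1 <- 0.2
    trace <- add_mep(trace, t1, base_amp * jitter())
    pulses <- t1
    inten <- 125
  } else if (proto %in% c("SICI2", "SICI4", "ICF10", "ICF15", "SICF3")) {
    isi <- protocol_isi_ms(proto) / 1000
    t_cs <- 0.2; t_ts <- t_cs + isi
    # subthreshold CS elicits no MEP; the test MEP carries the ratio
    trace <- add_mep(trace, t_ts, params$programmed_ratio * base_amp * jitter())
    pulses <- c(t_cs, t_ts)
    inten <- 125
  } else if (proto %in% c("LICI100", "LICI220")) {
    isi <- protocol_isi_ms(proto) / 1000
    t1 <- 0.2; t2 <- t1 + isi
    a1 <- base_amp * jitter()
    trace <- add_mep(trace, t1, a1)
    trace <- add_mep(trace, t2, params$programmed_ratio * base_amp * jitter())
    pulses <- c(t1, t2)
    inten <- 125
  } else if (proto == "CSP") {
    t1 <- 0.3
    i_pulse <- round(t1 * rate)
    i_end_silence <- round((t1 + params$programmed_csp_ms / 1000) * rate)
    contraction <- contraction_segment(n, rate)
    pre <- seq_len(i_pulse)                       # tonic activity up to pulse
    post <- (i_end_silence + 1L):n                # activity resumes after CSP
    trace[pre] <- trace[pre] + contraction[pre]
    trace[post] <- trace[post] + contraction[post]
    trace <- add_mep(trace, t1, 1.5 * base_amp * jitter())
    pulses <- t1
    inten <- 125
  } else {                                        # IO_100 .. IO_150
    inten <- as.numeric(sub("IO_", "", proto))
    t1 <- 0.2
    amp <- base_amp * (inten - 90) / 35           # monotone recruitment
    trace <- add_mep(trace, t1, amp * jitter())
    pulses <- t1
  }

  structure(
    list(trace = trace, rate = rate, pulse_times_s = pulses,
         protocol = proto, intensity_pct_rmt = inten),
    class = "emg_trial"
  )
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("<emg_trial> %s: %.2f s @ %g Hz, pulses at %s s\n",
              x$protocol, length(x$trace) / x$rate, x$rate,
              paste(format(x$pulse_times_s), collapse = ", ")))
  invisible(x)
}
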