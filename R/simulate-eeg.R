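#' Parameters for a synthetic EEG session
#'
#' Encodes the generative model of a chirp session: pink (1/f) background
#' noise per channel, a phase-locked low-frequency onset burst after each
#' stimulus, an entrained component whose instantaneous frequency tracks the
#' stimulus AM sweep, blink-like frontal transients, and optional bad
#' channels. Trial-to-trial phase variability of the evoked components is von
#' Mises with concentration `phase_locking_kappa` (`0` = uniform phases,
#' i.e. no locking; large values = near-perfect locking).
#'
#' Group defaults encode the contrast the analysis is designed to detect:
#' mutation carriers show stronger, more phase-locked entrainment than
#' controls. Explicit arguments always override the group default.
#'
#' @param group_label `"control"` or `"carrier"`.
#' @param channel_names 10-10 labels; default [default_montage()] (32 sites).
#' @param onset_theta_gain amplitude of the onset theta burst, microvolts.
#' @param onset_theta_freq onset burst frequency, Hz.
#' @param entrain_gain amplitude of the chirp-tracking component, microvolts.
#' @param phase_locking_kappa von Mises concentration of trialwise phases.
#' @param noise_exponent spectral slope of the background (power ~ 1/f^a).
#' @param noise_scale RMS of the background noise per channel, microvolts.
#' @param artifact_rate blink-like transients per minute.
#' @param bad_channel_labels channels rendered flat or saturated.
#' @param seed integer seed: identical parameters + seed give bit-identical data.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(group_label = c("control", "carrier"),
                       channel_names = default_montage(),
                       onset_theta_gain = 5,
                       onset_theta_freq = 5,
                       entrain_gain = if (group_label[1] == "carrier") 5 else 4,
                       phase_locking_kappa = if (group_label[1] == "carrier") 2.2 else 1.1,
                       noise_exponent = 1,
                       noise_scale = 10,
                       artifact_rate = 0,
                       bad_channel_labels = character(),
                       seed = 1) {
  group_label <- match.arg(group_label)
  if (phase_locking_kappa < 0) stopf("phase_locking_kappa must be >= 0")
  if (onset_theta_gain < 0 || entrain_gain < 0 || noise_scale < 0) {
    stopf("gains and noise_scale must be >= 0")
  }
  if (!length(channel_names)) stopf("channel list must not be empty")
  structure(
    list(group_label = group_label, channel_names = channel_names,
         onset_theta_gain = onset_theta_gain,
         onset_theta_freq = onset_theta_freq,
         entrain_gain = entrain_gain,
         phase_locking_kappa = phase_locking_kappa,
         noise_exponent = noise_exponent, noise_scale = noise_scale,
         artifact_rate = artifact_rate,
         bad_channel_labels = bad_channel_labels, seed = seed),
    class = "sim_params"
  )
}

# 1/f^a background noise, unit sd, via random-phase spectral shaping
one_over_f_noise <- function(n, exponent) {
  nfft <- next_smooth(n)
  nf <- nfft %/% 2
  f <- seq_len(nf)
  amp <- f^(-exponent / 2)
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  full <- c(0, spec, Conj(rev(spec[-nf])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# raised-cosine (Hann) window of n samples
hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))

#' Simulate a continuous chirp-EEG session
#'
#' Generates a multi-channel recording at 1000 Hz containing, per scheduled
#' trial, a Hann-windowed theta burst at stimulus onset and an entrained
#' oscillation tracking the stimulus AM instantaneous frequency over the
#' stimulus duration. Both components share a per-trial phase offset drawn
#' von Mises around zero with concentration `phase_locking_kappa`, are scaled
#' by a frontally-dominant channel weighting, and ride on independent 1/f
#' noise per channel. Event markers are embedded at stimulus onsets.
#'
#' The neural entrained component follows the AM envelope frequency (0-120 Hz
#' band), not the 1000 Hz acoustic carrier, matching the physiology of the
#' auditory steady-state following response.
#'
#' @param params a [sim_params()] object.
#' @param schedule a [make_trial_schedule()] object.
#' @param stimulus a [make_chirp_stimulus()] object.
#' @param rate EEG sampling rate, Hz (acquisition default 1000).
#' @param tail_s silence appended after the last stimulus ends.
#' @return an [new_recording()] `eeg_recording` with events labelled `"chirp"`.
#' @export
simulate_eeg_session <- function(params, schedule, stimulus,
                                 rate = 1000, tail_s = 4) {
  stopifnot(inherits(params, "sim_params"),
            inherits(schedule, "trial_schedule"),
            inherits(stimulus, "chirp_stimulus"))
  chans <- params$channel_names
  if (!length(chans)) stopf("channel list must not be empty")
  dur <- max(schedule$onsets) + stimulus$duration_s + tail_s
  n <- ceiling(dur * rate)
  if (schedule$onsets[1] < 0) stopf("schedule starts before the recording")

  with_seed(params$seed, {
    nch <- length(chans)
    data <- matrix(0, nch, n, dimnames = list(chans, NULL))
    for (ci in seq_len(nch)) {
      data[ci, ] <- one_over_f_noise(n, params$noise_exponent) * params$noise_scale
    }

    cw <- montage_component_weights(chans)
    dstim <- stimulus$duration_s
    # evoked templates are built once per trial on the EEG time base
    n_on <- round(0.5 * rate)                      # onset burst: 0-500 ms
    t_on <- (seq_len(n_on) - 1) / rate
    w_on <- hann(n_on)
    n_ent <- round(dstim * rate)                   # entrainment: stimulus span
    t_ent <- (seq_len(n_ent) - 1) / rate
    ramp <- pmin(1, pmin(t_ent, dstim - t_ent) / 0.1)  # 100 ms on/off ramps
    am_phase <- 2 * pi * (stimulus$am_f0 * t_ent +
      (stimulus$am_f1 - stimulus$am_f0) * t_ent^2 / (2 * dstim))

    kap <- params$phase_locking_kappa
    for (tr in seq_len(schedule$n_trials)) {
      i0 <- round(schedule$onsets[tr] * rate) + 1L
      ph_on <- rvonmises(1, 0, kap)
      ph_ent <- rvonmises(1, 0, kap)
      burst <- params$onset_theta_gain * w_on *
        sin(2 * pi * params$onset_theta_freq * t_on + ph_on)
      ent <- params$entrain_gain * ramp * sin(am_phase + ph_ent)
      idx_on <- i0:(i0 + n_on - 1L)
      idx_ent <- i0:(i0 + n_ent - 1L)
      if (max(idx_ent) > n) stopf("schedule exceeds the session length")
      data[, idx_on] <- data[, idx_on] + outer(cw, burst)
      data[, idx_ent] <- data[, idx_ent] + outer(cw, ent)
    }

    if (params$artifact_rate > 0) {
      n_art <- stats::rpois(1, params$artifact_rate * dur / 60)
      if (n_art > 0) {
        bw <- montage_blink_weights(chans)
        n_bl <- round(0.3 * rate)                  # 300 ms blink, < 4 Hz content
        shape <- 350 * hann(n_bl)
        starts <- sort(stats::runif(n_art, 0, dur - 0.4))
        for (s in starts) {
          j0 <- round(s * rate) + 1L
          idx <- j0:(j0 + n_bl - 1L)
          data[, idx] <- data[, idx] + outer(bw, shape)
        }
      }
    }

    for (bi in seq_along(params$bad_channel_labels)) {
      lab <- params$bad_channel_labels[bi]
      ci <- match(lab, chans)
      if (is.na(ci)) next
      if (bi %% 2L == 1L) {
        data[ci, ] <- data[ci, ] * 0.05            # flat: SD well below 2 uV
      } else {
        data[ci, ] <- data[ci, ] + stats::rnorm(n, 0, 150)  # saturated: SD > 120 uV
      }
    }

    new_recording(
      data, chans, rate,
      events = data.frame(time_s = schedule$onsets,
                          label = rep("chirp", schedule$n_trials)),
      provenance = sprintf("simulate_eeg_session(group=%s, kappa=%g, seed=%d)",
                           params$group_label, kap, as.integer(params$seed))
    )
  })
}
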