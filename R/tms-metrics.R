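#' Peak-to-peak MEP amplitude
#'
#' Max minus min of the trace inside a search window after a pulse. The
#' default 15-60 ms window brackets typical first-dorsal-interosseous MEP
#' latencies. Invariant to constant trace offsets.
#'
#' @param trial an `emg_trial`.
#' @param window_s length-2 window in seconds relative to the pulse.
#' @param pulse which pulse the window is anchored to (default: the last,
#'   i.e. the test stimulus of a paired protocol).
#' @return list with `p2p_amplitude` (same units as the trace) and
#'   `search_window_s` (absolute trace time).
#' @export
peak_to_peak <- function(trial, window_s = c(0.015, 0.060),
                         pulse = length(trial$pulse_times_s)) {
  stopifnot(inherits(trial, "emg_trial"))
  t0 <- trial$pulse_times_s[pulse]
  i1 <- round((t0 + window_s[1]) * trial$rate) + 1L
  i2 <- round((t0 + window_s[2]) * trial$rate)
  if (i1 < 1L || i2 > length(trial$trace) || i1 >= i2) {
    stopf("MEP search window [%g, %g] s after pulse %d falls outside the trace",
          window_s[1], window_s[2], pulse)
  }
  seg <- trial$trace[i1:i2]
  list(p2p_amplitude = max(seg) - min(seg),
       search_window_s = c(t0 + window_s[1], t0 + window_s[2]))
}

mean_p2p <- function(trials, ...) {
  mean(vapply(trials, function(tr) peak_to_peak(tr, ...)$p2p_amplitude,
              numeric(1)))
}

#' Paired-pulse ratio over baseline
#'
#' Mean conditioned MEP peak-to-peak amplitude divided by the mean baseline
#' amplitude: `< 1` indexes inhibition (SICI, LICI), `> 1` facilitation
#' (ICF, SICF).
#'
#' @param conditioned_trials,baseline_trials lists of `emg_trial`s.
#' @param window_s MEP search window (seconds after the test pulse).
#' @return the ratio (scalar).
#' @export
paired_pulse_ratio <- function(conditioned_trials, baseline_trials,
                               window_s = c(0.015, 0.060)) {
  if (!length(conditioned_trials) || !length(baseline_trials)) {
    stopf("need at least one trial in each set")
  }
  b <- mean_p2p(baseline_trials, window_s = window_s)
  if (b <= 0) stopf("baseline mean MEP amplitude is zero")
  mean_p2p(conditioned_trials, window_s = window_s) / b
}

#' Long-interval inhibition ratio (per-trial, then averaged)
#'
#' For each two-pulse trial the second MEP's peak-to-peak amplitude is
#' divided by the first's; the per-trial ratios are then averaged. Trials
#' whose first MEP sits at the noise floor are excluded and counted,
#' preventing division blow-ups: the floor is `noise_k` times the
#' peak-to-peak excursion of a pre-pulse segment of the same length as the
#' MEP search window (comparing like statistics - the extreme range of pure
#' noise, not its SD).
#'
#' @param trials list of two-pulse `emg_trial`s.
#' @param window_s MEP search window per pulse.
#' @param noise_k noise-floor multiplier for first-MEP exclusion.
#' @return list with `ratio` (mean over retained trials), `n_used`,
#'   `n_excluded`.
#' @export
lici_ratio <- function(trials, window_s = c(0.015, 0.060), noise_k = 3) {
  ratios <- numeric(0)
  excluded <- 0L
  for (tr in trials) {
    if (length(tr$pulse_times_s) != 2) stopf("LICI trials need exactly 2 pulses")
    win_n <- round(diff(window_s) * tr$rate)
    i_end <- max(win_n + 1L, round((tr$pulse_times_s[1] - 0.005) * tr$rate))
    pre <- tr$trace[max(1L, i_end - win_n):i_end]
    floor_p2p <- max(pre) - min(pre)
    m1 <- peak_to_peak(tr, window_s, pulse = 1)$p2p_amplitude
    m2 <- peak_to_peak(tr, window_s, pulse = 2)$p2p_amplitude
    if (m1 < noise_k * floor_p2p || m1 == 0) {
      excluded <- excluded + 1L
      next
    }
    ratios <- c(ratios, m2 / m1)
  }
  if (!length(ratios)) stopf("no trial with a usable first MEP")
  list(ratio = mean(ratios), n_used = length(ratios), n_excluded = excluded)
}

#' Cortical silent period duration
#'
#' Time from the TMS pulse to the return of voluntary EMG activity. The
#' rectified trace is smoothed with a 5 ms moving average; "return to
#' baseline" is the first instant after the MEP where the smoothed signal
#' re-exceeds `frac` (default 50%) of the mean pre-pulse rectified amplitude
#' and stays there for at least `sustain_ms`. Requires a tonic pre-pulse
#' contraction - without one the CSP is undefined and an error is raised.
#' If no silence is detected the MEP decay time is returned with
#' `flagged_short = TRUE`.
#'
#' @param trial a single-pulse `emg_trial` recorded during contraction.
#' @param baseline_window_s pre-pulse window for the contraction baseline
#'   (seconds, absolute trace time); default the 50-250 ms before the pulse.
#' @param criteria list: `frac` (criterion fraction), `smooth_ms`,
#'   `sustain_ms`, `min_baseline` (rectified-mean floor, trace units).
#' @return list with `csp_ms`, `flagged_short`, `baseline_level`.
#' @export
csp_duration <- function(trial, baseline_window_s = NULL,
                         criteria = list(frac = 0.5, smooth_ms = 5,
                                         sustain_ms = 10, min_baseline = 0.05)) {
  stopifnot(inherits(trial, "emg_trial"))
  frac <- criteria$frac %||% 0.5
  smooth_ms <- criteria$smooth_ms %||% 5
  sustain_ms <- criteria$sustain_ms %||% 10
  min_base <- criteria$min_baseline %||% 0.05
  rate <- trial$rate
  t_pulse <- trial$pulse_times_s[1]
  if (is.null(baseline_window_s)) {
    baseline_window_s <- c(max(0, t_pulse - 0.25), t_pulse - 0.05)
  }
  sm <- moving_average(abs(trial$trace), round(smooth_ms / 1000 * rate))
  bi <- (round(baseline_window_s[1] * rate) + 1L):round(baseline_window_s[2] * rate)
  base <- mean(sm[bi])
  if (base < min_base) {
    stopf("no pre-pulse contraction (rectified mean %.3g below floor %.3g); CSP undefined",
          base, min_base)
  }
  crit <- frac * base
  i_pulse <- round(t_pulse * rate) + 1L
  run <- max(1L, round(sustain_ms / 1000 * rate))
  n <- length(sm)

  sustained_from <- function(flags, start) {
    # first index >= start opening a run of `run` consecutive TRUEs
    i <- start
    while (i + run - 1L <= n) {
      if (all(flags[i:(i + run - 1L)])) return(i)
      i <- i + 1L
    }
    NA_integer_
  }

  # MEP peak, then look for silence
  mep_span <- i_pulse:min(n, i_pulse + round(0.06 * rate))
  i_peak <- mep_span[which.max(sm[mep_span])]
  below <- sm < crit
  i_sil <- sustained_from(below, i_peak)
  if (!is.na(i_sil)) {
    i_ret <- sustained_from(!below, i_sil + run)
    if (is.na(i_ret)) i_ret <- n
    csp_ms <- (i_ret - i_pulse) / rate * 1000
    flagged <- csp_ms < 50
  } else {
    # no silence: EMG continuous; report the MEP decay back to baseline level
    i_dec <- i_peak
    while (i_dec < n && sm[i_dec] > 1.2 * base) i_dec <- i_dec + 1L
    csp_ms <- (i_dec - i_pulse) / rate * 1000
    flagged <- TRUE
  }
  list(csp_ms = csp_ms, flagged_short = flagged, baseline_level = base)
}

#' Input/output (recruitment) curve
#'
#' Mean and SD of MEP peak-to-peak amplitudes per stimulus intensity,
#' sorted by intensity (%rMT).
#'
#' @param trials_by_intensity either a flat list of `emg_trial`s carrying
#'   `intensity_pct_rmt`, or a named list (`IO_100`...) of trial lists.
#' @param window_s MEP search window.
#' @return data.frame with `intensity_pct_rmt`, `mean_p2p`, `sd_p2p`, `n`.
#' @export
io_curve <- function(trials_by_intensity, window_s = c(0.015, 0.060)) {
  if (length(trials_by_intensity) && inherits(trials_by_intensity[[1]], "emg_trial")) {
    flat <- trials_by_intensity
  } else {
    flat <- unlist(trials_by_intensity, recursive = FALSE)
  }
  if (!length(flat)) stopf("no trials given")
  inten <- vapply(flat, function(tr) tr$intensity_pct_rmt, numeric(1))
  if (any(is.na(inten))) stopf("trial without an intensity label")
  p2p <- vapply(flat, function(tr) peak_to_peak(tr, window_s)$p2p_amplitude,
                numeric(1))
  agg <- do.call(rbind, lapply(sort(unique(inten)), function(I) {
    v <- p2p[inten == I]
    data.frame(intensity_pct_rmt = I, mean_p2p = mean(v),
               sd_p2p = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  agg
}

#' Per-subject TMS protocol summary
#'
#' Computes every outcome measure from a named list of trial blocks:
#' conditioned/baseline ratios for SICI/ICF/SICF, per-trial LICI ratios,
#' CSP duration, and the input/output curve.
#'
#' @param subject_id identifier attached to the output.
#' @param trial_sets named list of `emg_trial` lists, keyed by protocol
#'   label. `baseline` is required when any conditioned block is present.
#' @return a `protocol_summary` list: `subject_id`, `ratios` (data.frame
#'   protocol/ratio/interpretation), `csp_ms`, `io_curve`.
#' @export
protocol_summary <- function(subject_id, trial_sets) {
  ratio_protos <- intersect(c("SICI2", "SICI4", "ICF10", "ICF15", "SICF3"),
                            names(trial_sets))
  ratios <- list()
  if (length(ratio_protos)) {
    if (is.null(trial_sets$baseline)) {
      stopf("conditioned protocols present but no baseline block")
    }
    for (p in ratio_protos) {
      r <- paired_pulse_ratio(trial_sets[[p]], trial_sets$baseline)
      ratios[[length(ratios) + 1L]] <- data.frame(
        protocol = p, ratio = r,
        interpretation = if (r < 1) "inhibition" else "facilitation")
    }
  }
  for (p in intersect(c("LICI100", "LICI220"), names(trial_sets))) {
    r <- lici_ratio(trial_sets[[p]])
    ratios[[length(ratios) + 1L]] <- data.frame(
      protocol = p, ratio = r$ratio,
      interpretation = if (r$ratio < 1) "inhibition" else "facilitation")
  }
  csp_ms <- if (!is.null(trial_sets$CSP)) {
    mean(vapply(trial_sets$CSP, function(tr) csp_duration(tr)$csp_ms,
                numeric(1)))
  } else NA_real_
  io_names <- grep("^IO_", names(trial_sets), value = TRUE)
  io <- if (length(io_names)) io_curve(unlist(trial_sets[io_names],
                                             recursive = FALSE)) else NULL
  structure(
    list(subject_id = subject_id,
         ratios = if (length(ratios)) do.call(rbind, ratios) else NULL,
         csp_ms = csp_ms, io_curve = io),
    class = "protocol_summary"
  )
}

#' @export
print.protocol_summary <- function(x, ...) {
  cat(sprintf("<protocol_summary> subject %s\n", x$subject_id))
  if (!is.null(x$ratios)) print(x$ratios, row.names = FALSE)
  if (!is.na(x$csp_ms)) cat(sprintf("  CSP: %.1f ms\n", x$csp_ms))
  if (!is.null(x$io_curve)) {
    cat(sprintf("  IO curve over %d intensities\n", nrow(x$io_curve)))
  }
  invisible(x)
}
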