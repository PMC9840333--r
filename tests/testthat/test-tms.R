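test_that("peak-to-peak measurement and its invariances", {
  # constructed trace: max 1.2, min -0.8 inside the window -> 2.0
  rate <- 5000
  trace <- rep(0, rate)
  trace[round(0.23 * rate)] <- 1.2
  trace[round(0.25 * rate)] <- -0.8
  tr <- structure(list(trace = trace, rate = rate, pulse_times_s = 0.2,
                       protocol = "baseline", intensity_pct_rmt = 125),
                  class = "emg_trial")
  expect_equal(peak_to_peak(tr)$p2p_amplitude, 2.0)

  flat <- tr; flat$trace <- rep(0, rate)
  expect_equal(peak_to_peak(flat)$p2p_amplitude, 0)

  # offset invariance
  off <- tr; off$trace <- tr$trace + 5
  expect_equal(peak_to_peak(off)$p2p_amplitude, 2.0)

  late <- tr; late$pulse_times_s <- 0.999
  expect_error(peak_to_peak(late), "outside the trace")
})

test_that("paired-pulse ratios recover inhibition and facilitation", {
  base <- simulate_emg_trials(emg_sim_params("baseline", seed = 1))
  sici <- simulate_emg_trials(emg_sim_params("SICI2", programmed_ratio = 0.5,
                                             seed = 2))
  icf <- simulate_emg_trials(emg_sim_params("ICF10", programmed_ratio = 2.0,
                                            seed = 3))
  expect_equal(paired_pulse_ratio(sici, base), 0.5, tolerance = 0.1)
  expect_equal(paired_pulse_ratio(icf, base), 2.0, tolerance = 0.1)
  expect_equal(paired_pulse_ratio(base, base), 1.0)   # identical sets

  expect_error(paired_pulse_ratio(list(), base), "at least one")
  zero <- lapply(base, function(tr) { tr$trace[] <- 0; tr })
  expect_error(paired_pulse_ratio(sici, zero), "zero")
})

test_that("programmed ratios are recovered across protocols and levels", {
  base <- simulate_emg_trials(emg_sim_params("baseline", seed = 11))
  for (r in c(0.3, 0.5, 1.0, 1.5, 2.0)) {
    cond <- simulate_emg_trials(emg_sim_params("SICI4", programmed_ratio = r,
                                               seed = 100 + round(10 * r)))
    expect_equal(paired_pulse_ratio(cond, base), r, tolerance = 0.1)
    lt <- simulate_emg_trials(emg_sim_params("LICI220", programmed_ratio = r,
                                             seed = 200 + round(10 * r)))
    expect_equal(lici_ratio(lt)$ratio, r, tolerance = 0.1)
  }
})

test_that("LICI per-trial ratios, exclusions, and consistency with paired ratio", {
  lici <- simulate_emg_trials(emg_sim_params("LICI100", programmed_ratio = 0.4,
                                             noise_mv = 0.005, seed = 4))
  out <- lici_ratio(lici)
  expect_equal(out$ratio, 0.4, tolerance = 0.05)
  expect_equal(out$n_used, 15)
  expect_equal(out$n_excluded, 0)

  # first MEP at the noise floor -> trial excluded
  degraded <- lici
  degraded[[1]]$trace[] <- stats::rnorm(length(degraded[[1]]$trace), 0, 0.005)
  out2 <- lici_ratio(degraded)
  expect_equal(out2$n_excluded, 1)
  expect_equal(out2$n_used, 14)

  expect_error(lici_ratio(simulate_emg_trials(emg_sim_params("baseline"))),
               "2 pulses")

  # all-ratio-1 trials -> mean 1
  ones <- simulate_emg_trials(emg_sim_params("LICI100", programmed_ratio = 1,
                                             noise_mv = 0.002, seed = 6))
  expect_equal(lici_ratio(ones)$ratio, 1.0, tolerance = 0.05)
})

test_that("CSP detection recovers the programmed silent period", {
  csp <- simulate_emg_trials(emg_sim_params("CSP", programmed_csp_ms = 150,
                                            noise_mv = 0.01, seed = 7))
  durs <- vapply(csp, function(tr) csp_duration(tr)$csp_ms, numeric(1))
  expect_equal(mean(durs), 150, tolerance = 5 / 150)
  expect_true(all(abs(durs - 150) < 12))

  longer <- simulate_emg_trials(emg_sim_params("CSP", programmed_csp_ms = 220,
                                               noise_mv = 0.01, seed = 8))
  expect_equal(mean(vapply(longer, function(tr) csp_duration(tr)$csp_ms,
                           numeric(1))), 220, tolerance = 5 / 220)

  # no silence: contraction continues -> short duration, flagged
  nosil <- csp[[1]]
  n <- length(nosil$trace)
  nosil$trace <- nosil$trace +
    chirpent:::contraction_segment(n, nosil$rate)
  res <- csp_duration(nosil)
  expect_true(res$flagged_short)
  expect_lt(res$csp_ms, 60)

  # no pre-pulse contraction -> error
  rest <- csp[[1]]
  rest$trace <- stats::rnorm(n, 0, 0.01)
  expect_error(csp_duration(rest), "contraction")
})

test_that("input/output curves rise monotonically with intensity", {
  sets <- lapply(seq(100, 150, 10), function(I) {
    simulate_emg_trials(emg_sim_params(paste0("IO_", I), seed = I))
  })
  names(sets) <- paste0("IO_", seq(100, 150, 10))
  curve <- io_curve(sets)
  expect_equal(curve$intensity_pct_rmt, seq(100, 150, 10))
  expect_true(all(diff(curve$mean_p2p) > 0))
  expect_true(all(curve$n == 15))

  # single intensity -> one-point curve; mean equals hand computation
  one <- io_curve(sets$IO_120)
  expect_equal(nrow(one), 1)
  hand <- mean(vapply(sets$IO_120, function(tr)
    peak_to_peak(tr)$p2p_amplitude, numeric(1)))
  expect_equal(one$mean_p2p, hand)
})

test_that("simulators are seeded and reject unknown protocols", {
  a <- simulate_emg_trials(emg_sim_params("SICI2", seed = 5))
  b <- simulate_emg_trials(emg_sim_params("SICI2", seed = 5))
  expect_identical(lapply(a, `[[`, "trace"), lapply(b, `[[`, "trace"))
  expect_error(emg_sim_params("FOO"), "unknown protocol")
  expect_error(emg_sim_params("SICI2", programmed_ratio = -1), "> 0")
  # paired protocols carry the labelled ISI
  expect_equal(diff(a[[1]]$pulse_times_s), 0.002)
  expect_equal(length(a[[1]]$pulse_times_s), 2)
})

test_that("protocol_summary assembles all outcome measures", {
  sets <- list(
    baseline = simulate_emg_trials(emg_sim_params("baseline", seed = 1)),
    SICI2 = simulate_emg_trials(emg_sim_params("SICI2", programmed_ratio = 0.5,
                                               seed = 2)),
    ICF10 = simulate_emg_trials(emg_sim_params("ICF10", programmed_ratio = 1.6,
                                               seed = 3)),
    LICI100 = simulate_emg_trials(emg_sim_params("LICI100",
                                                 programmed_ratio = 0.4,
                                                 seed = 4)),
    CSP = simulate_emg_trials(emg_sim_params("CSP", programmed_csp_ms = 150,
                                             seed = 5)),
    IO_100 = simulate_emg_trials(emg_sim_params("IO_100", seed = 6)),
    IO_150 = simulate_emg_trials(emg_sim_params("IO_150", seed = 7)))
  ps <- protocol_summary("subj01", sets)
  expect_equal(nrow(ps$ratios), 3)
  r <- setNames(ps$ratios$ratio, ps$ratios$protocol)
  expect_lt(r[["SICI2"]], 1)
  expect_gt(r[["ICF10"]], 1)
  expect_equal(ps$ratios$interpretation[ps$ratios$protocol == "SICI2"],
               "inhibition")
  expect_equal(ps$csp_ms, 150, tolerance = 0.05)
  expect_equal(nrow(ps$io_curve), 2)

  expect_error(protocol_summary("s", list(SICI2 = sets$SICI2)), "baseline")
})
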