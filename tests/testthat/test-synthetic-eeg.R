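test_that("chirp stimulus realizes a linear AM sweep with a bounded envelope", {
  stim <- make_chirp_stimulus(1000, 0, 120, 2.0, 44100)
  expect_equal(length(stim$samples), round(2.0 * 44100))
  expect_equal(am_frequency_at(stim, 1.0), 60)       # midpoint of 0-120 Hz
  expect_equal(am_frequency_at(stim, 0), 0)
  expect_equal(am_frequency_at(stim, 2), 120)
  expect_gte(min(stim$envelope), 0)
  expect_lte(max(stim$envelope), 1)
  expect_gte(min(stim$samples), -1)
  expect_lte(max(stim$samples), 1)

  # degenerate sweep: constant 40 Hz AM (steady-state control stimulus)
  ss <- make_chirp_stimulus(1000, 40, 40, 2.0, 44100)
  expect_equal(am_frequency_at(ss, c(0.3, 1.7)), c(40, 40))
  # envelope period should be 25 ms: count minima spacing via autocorrelation
  env <- ss$envelope
  expect_equal(which.max(sapply(200:1500, function(l)
    stats::cor(env[1:40000], env[(1 + l):(40000 + l)]))) + 199,
    round(44100 / 40), tolerance = 0.01)

  expect_error(make_chirp_stimulus(duration_s = 0), "positive")
  expect_error(make_chirp_stimulus(carrier_hz = 1000, rate = 1500), "Nyquist")
})

test_that("trial schedule keeps all gaps inside the ISI bounds and is seeded", {
  sch <- make_trial_schedule(160, c(1500, 2500), 2.0, seed = 7)
  expect_length(sch$onsets, 160)
  expect_false(is.unsorted(sch$onsets, strictly = TRUE))
  gaps_ms <- (diff(sch$onsets) - 2.0) * 1000
  expect_length(gaps_ms, 159)
  expect_true(all(gaps_ms >= 1500 & gaps_ms <= 2500))

  expect_identical(sch, make_trial_schedule(160, c(1500, 2500), 2.0, seed = 7))
  sch2 <- make_trial_schedule(160, c(1500, 2500), 2.0, seed = 8)
  expect_false(identical(sch$onsets, sch2$onsets))

  expect_length(make_trial_schedule(1, c(1500, 2500), 2.0, seed = 7)$onsets, 1)
  expect_error(make_trial_schedule(10, c(2500, 1500), 2.0, 1), "ascending")
})

test_that("von Mises sampler matches its analytic resultant length", {
  for (kap in c(0, 1, 4)) {
    th <- chirpent:::with_seed(11, rvonmises(20000, 0, kap))
    r_hat <- Mod(mean(exp(1i * th)))
    expect_lt(abs(r_hat - chirpent:::vm_mean_resultant(kap)), 0.02)
  }
  expect_error(rvonmises(1, 0, -1), "kappa")
})

test_that("simulated sessions are deterministic under the seed", {
  stim <- make_chirp_stimulus()
  sch <- make_trial_schedule(3, seed = 2)
  p <- sim_params("control", channel_names = c("F1", "Fz", "F2"), seed = 5)
  r1 <- simulate_eeg_session(p, sch, stim)
  r2 <- simulate_eeg_session(p, sch, stim)
  expect_identical(r1$data, r2$data)
  p2 <- sim_params("control", channel_names = c("F1", "Fz", "F2"), seed = 6)
  expect_false(identical(r1$data, simulate_eeg_session(p2, sch, stim)$data))
  expect_equal(r1$events$time_s, sch$onsets)
})

test_that("session components land where configured", {
  stim <- make_chirp_stimulus()
  sch <- make_trial_schedule(4, seed = 3)
  # noiseless, perfectly locked: entrained sinusoid at the AM frequency
  p <- sim_params("control", channel_names = c("Fz", "Oz"),
                  onset_theta_gain = 0, entrain_gain = 10,
                  phase_locking_kappa = 1e9, noise_scale = 0, seed = 1)
  rec <- simulate_eeg_session(p, sch, stim)
  i0 <- round(sch$onsets[1] * rec$rate)
  seg <- rec$data["Fz", (i0 + 900):(i0 + 1100)]   # around t = 1 s post-onset
  # dominant frequency of the segment should be near 60 Hz
  sp <- Mod(stats::fft(seg * chirpent:::hann(length(seg))))[1:100]
  f_peak <- (which.max(sp[2:100])) * rec$rate / length(seg)
  expect_lt(abs(f_peak - 60), 8)
  # frontal weighting: occipital copy is scaled down, same shape
  expect_lt(stats::sd(rec$data["Oz", ]), stats::sd(rec$data["Fz", ]))

  # pre-onset baseline carries no signal when noise is zero
  expect_equal(max(abs(rec$data["Fz", 1:(i0 - 600)])), 0)

  # artifacts exceed the rejection threshold and are frontally weighted
  pa <- sim_params("control", channel_names = c("Fp1", "Oz"),
                   onset_theta_gain = 0, entrain_gain = 0, noise_scale = 1,
                   artifact_rate = 20, seed = 9)
  ra <- simulate_eeg_session(pa, sch, stim)
  expect_gt(max(ra$data["Fp1", ]), 200)
  expect_lt(max(ra$data["Oz", ]), 200)

  # bad channels fall outside the SD acceptance band
  pb <- sim_params("control", channel_names = c("F1", "Fz", "F2"),
                   bad_channel_labels = c("F1", "F2"), seed = 4)
  rb <- simulate_eeg_session(pb, sch, stim)
  expect_lt(stats::sd(rb$data["F1", ]), 2)
  expect_gt(stats::sd(rb$data["F2", ]), 120)

  expect_error(sim_params("control", channel_names = character()), "empty")
  expect_error(sim_params("control", phase_locking_kappa = -1), "kappa")
})

test_that("group-effect monotonicity: ITC rises with the locking concentration", {
  stim <- make_chirp_stimulus()
  sch <- make_trial_schedule(15, seed = 21)
  freqs <- seq(30, 55, 5)
  vals <- vapply(c(0.5, 2, 8), function(kap) {
    p <- sim_params("control", channel_names = "Fz", entrain_gain = 6,
                    phase_locking_kappa = kap, seed = 77)
    maps <- run_chirp_pipeline(simulate_eeg_session(p, sch, stim), sch,
                               rois = "Fz", freqs_hz = freqs)
    it <- maps$Fz$itc
    # ridge cells inside the low-gamma band
    sel <- outer(it$freqs_hz >= 45 & it$freqs_hz <= 55,
                 it$times_s >= 0.75 & it$times_s <= 0.95) & it$valid_mask
    mean(it$values[sel], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
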