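rms <- function(x) sqrt(mean(x^2))

test_that("bandpass/notch meets its response contract and is linear", {
  rate <- 1000
  t <- (0:9999) / rate
  mid <- 2000:8000  # avoid edge transients when measuring tones
  rec <- toy_recording(list(
    s60 = function(t) sin(2 * pi * 60 * t),
    s10 = function(t) sin(2 * pi * 10 * t),
    dc = function(t) rep(100, length(t))))
  filt <- bandpass_notch(rec)
  expect_lt(20 * log10(rms(filt$data["s60", mid]) / rms(rec$data["s60", mid])),
            -20)   # notch: >= 20 dB down at 60 Hz
  expect_lt(abs(20 * log10(rms(filt$data["s10", mid]) /
                             rms(rec$data["s10", mid]))), 1)  # passband flat
  expect_lt(abs(mean(filt$data["dc", mid])), 1)   # DC removed

  # linearity: filtering commutes with scaling
  reca <- toy_recording(list(x = function(t) sin(2 * pi * 7 * t) +
                               0.5 * sin(2 * pi * 80 * t)))
  f1 <- bandpass_notch(reca)$data
  rec3 <- reca; rec3$data <- 3 * rec3$data
  f3 <- bandpass_notch(rec3)$data
  expect_equal(f3, 3 * f1, tolerance = 1e-10)

  expect_error(bandpass_notch(reca, band = c(0.5, 600)), "infeasible")
})

test_that("channel rejection drops flat and saturated channels by SD", {
  rec <- toy_recording(list(
    flat = function(t) stats::rnorm(length(t), 0, 1),     # SD 1 -> removed
    ok = function(t) stats::rnorm(length(t), 0, 50),      # SD 50 -> kept
    hot = function(t) stats::rnorm(length(t), 0, 150)))   # SD 150 -> removed
  out <- reject_channels_by_sd(rec, 2, 120)
  expect_identical(out$recording$channel_names, "ok")
  expect_setequal(out$removed$channel, c("flat", "hot"))
  expect_identical(out$removed$reason[out$removed$channel == "flat"], "flat")

  ok3 <- toy_recording(list(a = function(t) stats::rnorm(length(t), 0, 50),
                            b = function(t) stats::rnorm(length(t), 0, 50)))
  expect_equal(nrow(reject_channels_by_sd(ok3)$recording$data), 2)
  allbad <- toy_recording(list(a = function(t) rep(0.1, length(t))))
  expect_error(reject_channels_by_sd(allbad), "all channels")
})

test_that("epoching uses a half-open window and logs out-of-range onsets", {
  rec <- toy_recording(list(Fz = function(t) seq_along(t)), dur_s = 30)
  eps <- epoch_recording(rec, onsets = c(2, 5, 29.7), tmin = -1, tmax = 3.5)
  expect_equal(dim(eps$data), c(2, 1, 4500))          # 4.5 s at 1000 Hz
  expect_equal(eps$retained_flags, c(TRUE, TRUE, FALSE))
  expect_match(eps$rejection_log, "29.7")
  # sample content: epoch 1 starts at (2 - 1) s -> sample index 1001
  expect_equal(unname(eps$data[1, 1, 1]), 1001)
  expect_equal(unname(eps$data[1, 1, 4500]), 5500)

  sch <- make_trial_schedule(5, seed = 1)
  rec2 <- toy_recording(list(Fz = function(t) t), dur_s = 40)
  expect_equal(dim(epoch_recording(rec2, sch)$data)[1], 5)
  expect_error(epoch_recording(rec2, onsets = c(100), tmin = -1, tmax = 3.5),
               "no epoch")
  expect_error(epoch_recording(rec2, onsets = 2, tmin = 1, tmax = 3), "tmin")
})

test_that("amplitude rejection is strict at the threshold", {
  base <- matrix(0, 3, 4500)
  base[1, 100] <- 250        # removed: exceeds +200
  base[2, 200] <- 200        # kept: exactly at threshold (strict >)
  base[3, 300] <- -199       # kept
  eps <- toy_epochs(base)
  out <- reject_epochs_by_amplitude(eps, 200)
  expect_equal(dim(out$data)[1], 2)
  expect_equal(out$retained_flags, c(FALSE, TRUE, TRUE))
  # epoch count conservation across the chain
  expect_equal(sum(out$retained_flags) + sum(!out$retained_flags), 3)

  allbad <- toy_epochs(matrix(500, 2, 100))
  expect_error(reject_epochs_by_amplitude(allbad), "survives|survive")
})

test_that("ROI averaging is the arithmetic mean over surviving electrodes", {
  nsamp <- 500
  sig <- sin(2 * pi * 5 * (1:nsamp) / 1000)
  arr <- array(0, dim = c(2, 5, nsamp),
               dimnames = list(NULL, c("F3", "F1", "Fz", "F2", "F4"), NULL))
  for (k in 1:5) { arr[1, k, ] <- sig; arr[2, k, ] <- k }
  eps <- toy_epochs(matrix(0, 2, nsamp))
  eps$data <- arr
  eps$channel_names <- c("F3", "F1", "Fz", "F2", "F4")
  out <- roi_average(eps, roi_definitions()$Fz)
  expect_equal(out$data[1, 1, ], sig)                # identical channels: identity
  expect_equal(unique(out$data[2, 1, ]), 3)          # mean of 1..5

  # one electrode previously removed: mean over the remaining four
  eps4 <- eps
  eps4$data <- eps$data[, -1, , drop = FALSE]
  eps4$channel_names <- c("F1", "Fz", "F2", "F4")
  out4 <- roi_average(eps4, roi_definitions()$Fz)
  expect_equal(unique(out4$data[2, 1, ]), mean(2:5))
  expect_match(tail(out4$provenance, 1), "F1\\+Fz\\+F2\\+F4")

  eps_none <- eps
  eps_none$channel_names <- c("O1", "O2", "Oz", "PO3", "POz")
  dimnames(eps_none$data)[[2]] <- eps_none$channel_names
  expect_error(roi_average(eps_none, roi_definitions()$Fz), "Fz")
})

test_that("the full cleaning chain is reproducible end to end", {
  stim <- make_chirp_stimulus()
  sch <- make_trial_schedule(5, seed = 31)
  p <- sim_params("control", channel_names = c("F1", "Fz", "F2"),
                  artifact_rate = 10, seed = 13)
  rec <- simulate_eeg_session(p, sch, stim)
  run <- function() {
    cr <- reject_channels_by_sd(bandpass_notch(rec))
    reject_epochs_by_amplitude(epoch_recording(cr$recording, sch))$data
  }
  expect_identical(run(), run())
})
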