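test_that("band-stop notch attenuates 50 Hz and passes 10 Hz", {
  t <- seq(0, 2, by = 1e-3)[-1]
  s50 <- sin(2 * pi * 50 * t)
  s10 <- sin(2 * pi * 10 * t)
  rms <- function(x) sqrt(mean(x^2))
  # oracle: squared (bidirectional) magnitude response of the designed
  # filter, evaluated directly from the transfer-function polynomials
  hmag2 <- function(flt, f_hz, fs = 1000) {
    z <- exp(-1i * 2 * pi * f_hz / fs * (seq_along(flt$b) - 1))
    Mod(sum(flt$b * z) / sum(flt$a * z))^2
  }
  flt <- signal::butter(2, c(45, 55) / 500, type = "stop")
  expect_lt(20 * log10(hmag2(flt, 50)), -20)
  expect_gt(20 * log10(hmag2(flt, 10)), -1)
  core <- 200:1800  # ignore filter edge transients
  att50 <- 20 * log10(rms(bandstop_45_55(s50)[core]) / rms(s50[core]))
  expect_lt(att50, -20)
  att10 <- 20 * log10(rms(bandstop_45_55(s10)[core]) / rms(s10[core]))
  expect_lt(abs(att10), 1)
  # DC gain 1
  expect_equal(bandstop_45_55(rep(5, 1000)), rep(5, 1000), tolerance = 1e-6)
})

test_that("30 Hz low-pass passes 5 Hz, kills 100 Hz, preserves DC", {
  t <- seq(0, 2, by = 1e-3)[-1]
  rms <- function(x) sqrt(mean(x^2))
  core <- 200:1800
  s5 <- sin(2 * pi * 5 * t)
  s100 <- sin(2 * pi * 100 * t)
  expect_lt(abs(20 * log10(rms(lowpass_30(s5)[core]) / rms(s5[core]))), 1)
  expect_lt(20 * log10(rms(lowpass_30(s100)[core]) / rms(s100[core])), -20)
  expect_equal(lowpass_30(rep(-3, 1000)), rep(-3, 1000), tolerance = 1e-6)
  expect_error(lowpass_30(rnorm(20)), "too short")
})

test_that("zero-phase filtering leaves a symmetric pulse's peak in place", {
  x <- exp(-((1:1000) - 500)^2 / (2 * 20^2))
  for (f in list(bandstop_45_55, lowpass_30)) {
    y <- f(x)
    expect_lte(abs(which.max(y) - 500), 1)
  }
})

test_that("epoch extraction uses the [-50, 350) window with t=0 poststimulus", {
  rec <- ramp_recording()
  ep <- extract_epochs(rec)
  # ramp v(t) = t; event at 1000 ms: first epoch sample is v(950 ms)
  expect_equal(ep$data[1, 1, 1], 950)
  expect_equal(ep$data[1, 1, 51], 1000)   # t = 0 sample
  expect_equal(dim(ep$data)[3], 400)
  expect_equal(ep$time_ms, -50:349)
})

test_that("events with out-of-bounds windows are dropped with a warning", {
  rec <- ramp_recording(n_samples = 1500, onsets_ms = c(20, 1000))
  expect_warning(ep <- extract_epochs(rec), "dropped")
  expect_equal(n_trials(ep), 1)
  expect_equal(attr(ep, "n_dropped"), 1)
  # conservation: epochs + dropped = events
  expect_equal(n_trials(ep) + attr(ep, "n_dropped"), nrow(rec$events))
})

test_that("artifact screening flags, marks bad channels, rejects trials", {
  mont <- montage_subset(16)
  dat <- array(0, dim = c(10, 16, 400))
  ep <- eeg_epochs(dat, -50:349, mont$label,
                   data.frame(frequency_hz = rep(250L, 10),
                              modality = rep("left", 10)),
                   montage = mont)
  expect_equal(sum(detect_artifacts(ep)$flags), 0)

  dat[3, 5, 100] <- 150  # one spike
  ep$data <- dat
  rep1 <- detect_artifacts(ep)
  expect_equal(sum(rep1$flags), 1)
  expect_equal(which(rep1$flags, arr.ind = TRUE), cbind(row = 3L, col = 5L),
               ignore_attr = TRUE)
  expect_equal(rep1$rejected_trials, 3L)

  # channel bad in 30% of trials -> globally bad, its trials not rejected
  dat[1:3, 7, 50] <- 200
  ep$data <- dat
  rep2 <- detect_artifacts(ep)
  expect_true(mont$label[7] %in% rep2$bad_channels)
  expect_equal(rep2$interpolated_fraction, 1 / 16)
  expect_equal(rep2$rejected_trials, 3L)  # only the channel-5 spike trial
})

test_that("spherical-spline interpolation reproduces smooth fields", {
  mont <- default_montage()
  nch <- nrow(mont)
  const <- array(7, dim = c(2, nch, 5))
  ep <- eeg_epochs(const, 1:5, mont$label,
                   data.frame(frequency_hz = rep(250L, 2),
                              modality = rep("left", 2)), montage = mont)
  ep$data[, 3, ] <- 0  # corrupt one channel
  fixed <- interpolate_bad_channels(ep, mont$label[3])
  expect_equal(fixed$data[, 3, ], const[, 3, ], tolerance = 1e-6)

  # first-order gradient field: error < 5% of the field range
  grad <- mont$y  # anterior-posterior gradient, degree-1 spherical harmonic
  dat <- array(rep(grad, each = 1), dim = c(1, nch, 1))
  ep2 <- eeg_epochs(dat, 1, mont$label,
                    data.frame(frequency_hz = 250L, modality = "left"),
                    montage = mont)
  bad <- "C3"
  truth <- grad[match(bad, mont$label)]
  ep2$data[1, match(bad, mont$label), 1] <- 99
  fixed2 <- interpolate_bad_channels(ep2, bad)
  err <- abs(fixed2$data[1, match(bad, mont$label), 1] - truth)
  expect_lt(err, 0.05 * diff(range(grad)))

  # no bad channels: identity; majority bad: error
  expect_identical(interpolate_bad_channels(ep, character(0)), ep)
  expect_error(interpolate_bad_channels(ep, mont$label[1:40]), "majority")
})

test_that("baseline correction zeroes the prestimulus mean", {
  dat <- array(rnorm(4 * 3 * 400), dim = c(4, 3, 400))
  ep <- eeg_epochs(dat, -50:349, c("Cz", "T7", "T8"),
                   data.frame(frequency_hz = rep(250L, 4),
                              modality = rep("left", 4)))
  bc <- baseline_correct(ep)
  bl <- apply(bc$data[, , 1:50], c(1, 2), mean)
  expect_true(all(abs(bl) < 1e-9))
  # constant epochs become zero; already-zero baselines are untouched
  ep$data[] <- 7
  expect_true(all(baseline_correct(ep)$data == 0))
  ep$data[] <- 0
  ep$data[, , 51:400] <- 5
  expect_equal(baseline_correct(ep)$data, ep$data)
})

test_that("the full pipeline retains clean trials and rejects spiked ones", {
  # 20 trials so that 2 spiked trials stay under the 20% bad-channel rule
  proto <- freq_protocol(5)
  cfg <- sim_config(n_channels = 16, noise_sd_uV = 3, seed = 6)
  rec <- simulate_recording(cfg, protocol = proto)
  out <- preprocess_pipeline(rec)
  expect_equal(n_trials(out$epochs), nrow(proto))
  expect_equal(length(out$report$rejected_trials), 0)

  # spike two trials far above threshold on one channel
  ev_idx <- c(2, 5)
  for (i in ev_idx) {
    s <- round(rec$events$onset_ms[i]) + 100
    rec$data[4, s:(s + 10)] <- 400
  }
  out2 <- preprocess_pipeline(rec)
  expect_equal(sort(out2$report$rejected_trials), sort(ev_idx))
  expect_equal(n_trials(out2$epochs), nrow(proto) - 2)

  # determinism
  out3 <- preprocess_pipeline(rec)
  expect_identical(out2$epochs$data, out3$epochs$data)
})
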