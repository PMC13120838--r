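test_that("dummy events inherit the most recent same-epoch lag", {
  cfg <- tiny_config(n_trials_per_block = 6, n_blocks = 1)
  s <- build_schedule(cfg, 12)
  tagged <- add_dummy_events(s)
  d12 <- tagged[tagged$event_label %in% c("delay_d12", "dummy_sptms_d12"), ]
  d12 <- d12[order(d12$latency_s), ]
  last_lag <- 2.5 # documented first-trial fallback: grid median
  for (i in seq_len(nrow(d12))) {
    row <- d12[i, ]
    if (row$event_label == "delay_d12" && isTRUE(row$sptms_present)) {
      last_lag <- row$lag_s
    }
    if (row$event_label == "dummy_sptms_d12") {
      expect_equal(row$lag_s, last_lag)
    }
  }
  # dummy latency = delay onset + inherited lag
  for (i in which(tagged$event_label == "dummy_sptms_d12")) {
    onset <- tagged$latency_s[tagged$event_label == "delay_d12" &
                                tagged$trial == tagged$trial[i]]
    expect_equal(tagged$latency_s[i], onset + tagged$lag_s[i])
  }
  # original rows unchanged
  kept <- tagged[!startsWith(tagged$event_label, "dummy_"), ]
  rownames(kept) <- NULL
  expect_equal(as.data.frame(kept), as.data.frame(s), ignore_attr = TRUE)
})

test_that("all-present schedules gain no dummies and all-absent ones warn", {
  cfg <- tiny_config(n_trials_per_block = 4, n_blocks = 1, sptms_prob = 1)
  s <- build_schedule(cfg, 3)
  expect_identical(add_dummy_events(s), s)
  cfg0 <- tiny_config(n_trials_per_block = 4, n_blocks = 1, sptms_prob = 0)
  s0 <- build_schedule(cfg0, 3)
  expect_warning(tag0 <- add_dummy_events(s0), "fallback")
  expect_true(all(tag0$lag_s[tag0$event_label == "dummy_sptms_d12"] == 2.5))
})

test_that("epoching maps the lock event to t = 0 with the stated sample counts", {
  fs <- 500
  rec <- recording(matrix(rnorm(2 * 30 * fs), nrow = 2), fs = fs)
  events <- data.frame(event_label = "sptms_d12", latency_s = c(15, 1),
                       trial = 1:2)
  # -14 to 4.5 s at 500 Hz: 9,251 samples; the second event cannot fit
  expect_message(
    ep <- epoch_around(rec, events, "sptms_d12", c(-14, 4.5)),
    "dropped 1/2")
  expect_equal(dim(ep$data), c(1, 2, 9251))
  expect_equal(ep$time[which.min(abs(ep$time))], 0)
  # lock sample equals the raw recording at the event latency
  expect_equal(ep$data[1, 1, ep$time == 0], rec$data[1, 15 * fs + 1])
  ep2 <- epoch_around(rec, events, "sptms_d12", c(-4.5, 4.5))
  expect_equal(dim(ep2$data)[3], 4501)
  expect_error(epoch_around(rec, events, "nope", c(-1, 1)), "no events")
})

test_that("pulse-gap interpolation reproduces cubics and suppresses spikes", {
  fs <- 500
  t <- (-50:50) / fs # exact sample grid, as epoch_around constructs it
  # the replaced span contains 17 sample times at 500 Hz
  expect_equal(sum(t >= -0.002 & t <= 0.030), 17)
  cubic <- 2 + 3 * t - 40 * t^2 + 500 * t^3
  ep <- epochs_from_matrix(rbind(cubic, cubic), fs, time = t)
  out <- interpolate_pulse_gap(ep)
  expect_equal(out$data, ep$data, tolerance = 1e-8)
  # artifact spike inside the span is flattened to context scale
  sig <- sin(2 * pi * 10 * t)
  spike <- sig
  spike[t >= -0.002 & t <= 0.002] <- 100 * sd(sig)
  ep2 <- epochs_from_matrix(rbind(spike), fs, time = t)
  out2 <- interpolate_pulse_gap(ep2)
  span_vals <- out2$data[1, 1, t >= -0.002 & t <= 0.030]
  ctx_sd <- sd(sig[t < -0.002 | t > 0.030])
  expect_lte(max(abs(span_vals)), 5 * ctx_sd)
  expect_error(interpolate_pulse_gap(ep2, span = c(-1, 1)), "span")
})

test_that("band and notch filtering attenuate and pass where stated", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  centre <- t > 1 & t < 3 # avoid filtfilt edge transients
  mk <- function(f) epochs_from_matrix(rbind(sin(2 * pi * f * t)), fs, t0 = 0)
  rms <- function(ep) sqrt(mean(ep$data[1, 1, centre]^2))
  out60 <- filter_band_notch(mk(60))
  expect_lte(rms(out60), 0.05 * sqrt(0.5))
  out10 <- filter_band_notch(mk(10))
  expect_lt(abs(rms(out10) - sqrt(0.5)) / sqrt(0.5), 0.05)
  zed <- filter_band_notch(epochs_from_matrix(rbind(rep(0, length(t))), fs))
  expect_equal(max(abs(zed$data)), 0)
  expect_error(filter_band_notch(mk(10), band = c(1, 300)), "Nyquist")
})

test_that("resampling preserves sinusoids and the stated sample counts", {
  fs <- 1450
  t <- seq(-2, 2, by = 1 / fs)
  ep <- epochs_from_matrix(rbind(sin(2 * pi * 10 * t)), fs, t0 = -2)
  out <- resample_epochs(ep, 500)
  ideal <- sin(2 * pi * 10 * out$time)
  centre <- out$time > -1.8 & out$time < 1.8
  expect_gte(cor(out$data[1, 1, centre], ideal[centre]), 0.999)
  expect_equal(out$time[which.min(abs(out$time))], 0)
  expect_identical(resample_epochs(ep, fs), ep)
  # 9,251 samples at 500 Hz resample to 1,851 at 100 Hz
  t5 <- seq(-14, 4.5, by = 1 / 500)
  ep5 <- epochs_from_matrix(rbind(sin(2 * pi * 3 * t5)), 500, t0 = -14)
  expect_equal(dim(resample_epochs(ep5, 100)$data)[3], 1851)
  expect_error(resample_epochs(ep5, 600), "upsampling")
})

test_that("baseline correction subtracts the window mean linearly", {
  fs <- 100
  time <- seq(-1, 1, by = 1 / fs)
  x <- sin(2 * pi * 5 * time)
  ep <- epochs_from_trials(rbind(x + 5, x), fs, time)
  out <- baseline_correct(ep, c(-1, 0))
  base_idx <- time >= -1 & time <= 0
  expect_equal(mean(out$data[1, 1, base_idx]), 0, tolerance = 1e-12)
  # adding an offset then correcting equals correcting the original
  expect_equal(out$data[1, 1, ], out$data[2, 1, ], tolerance = 1e-12)
  zm <- x - mean(x[base_idx])
  expect_equal(out$data[2, 1, ], zm, tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(5, 6)), "empty")
})

test_that("channel averaging collapses channels with the expected variance", {
  fs <- 100
  time <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * 7 * time)
  same <- epochs_from_matrix(rbind(x, x, x), fs)
  ts1 <- average_channels(same)
  expect_equal(ts1$data[1, ], x)
  opp <- epochs_from_matrix(rbind(x, -x), fs)
  expect_equal(max(abs(average_channels(opp)$data)), 0)
  # 60 iid channels: variance of the mean ~ per-channel variance / 60
  set.seed(2)
  noise <- matrix(rnorm(60 * 5000), nrow = 60)
  tsn <- average_channels(epochs_from_matrix(noise, fs = 500))
  expect_lt(abs(var(tsn$data[1, ]) - 1 / 60) / (1 / 60), 0.15)
})
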