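test_that("spectral transform concentrates a sinusoid and respects the grid", {
  fs <- 500
  t <- seq(-3, 3, by = 1 / fs)
  ep <- epochs_from_matrix(rbind(sin(2 * pi * 10 * t)), fs, t0 = -3)
  tf <- spectral_transform(ep)
  # centers at multiples of 500 ms, spacing 0.5 s, boundary windows dropped
  expect_equal(diff(tf$times), rep(0.5, length(tf$times) - 1))
  expect_true(0 %in% tf$times && 0.5 %in% tf$times && -0.5 %in% tf$times)
  expect_true(min(tf$times) >= -3 + 0.25 && max(tf$times) <= 3 - 0.25)
  p <- tf$power[1, 1, , which(tf$times == 0)]
  # numerical leakage of a 500 ms Hann window at 2 Hz resolution (frozen from
  # the direct tapered-inner-product oracle): 81.2% of 2-50 Hz power in
  # 9-11 Hz, 98% within the 8-12 Hz mainlobe
  expect_equal(sum(p[tf$freqs >= 9 & tf$freqs <= 11]) / sum(p), 0.8116,
               tolerance = 0.02)
  expect_gte(sum(p[tf$freqs >= 8 & tf$freqs <= 12]) / sum(p), 0.95)
  # unit-amplitude sinusoid at an analysis frequency: power ~ 1
  expect_equal(p[tf$freqs == 10], 1, tolerance = 0.05)
  zep <- epochs_from_matrix(rbind(rep(0, length(t))), fs, t0 = -3)
  expect_equal(max(spectral_transform(zep)$power), 0)
  short <- epochs_from_matrix(rbind(rnorm(50)), fs, t0 = 0)
  expect_error(spectral_transform(short), "short")
})

test_that("log/smooth averages three timepoints with endpoint rule", {
  # constant power: smoothing changes nothing
  pow <- array(100, dim = c(1, 1, 1, 5))
  tf <- structure(list(power = pow, freqs = 10, times = (0:4) * 0.5, fs = 500,
                       trial_meta = data.frame(trial = 1)),
                  class = "timefreq")
  out <- log_and_smooth(tf)
  expect_equal(as.vector(out$power), rep(2, 5))
  # log-power ramp {1,2,3}: middle -> 2, endpoints -> 1.5 and 2.5
  tf$power <- array(10^(1:3), dim = c(1, 1, 1, 3))
  tf$times <- (0:2) * 0.5
  out2 <- log_and_smooth(tf)
  expect_equal(as.vector(out2$power), c(1.5, 2, 2.5))
  # smoothing never increases temporal variance
  set.seed(5)
  tf$power <- array(exp(rnorm(40)), dim = c(2, 1, 1, 20))
  tf$times <- (0:19) * 0.5
  sm <- log_and_smooth(tf)
  raw <- log10(tf$power)
  for (tr in 1:2) {
    expect_lte(var(sm$power[tr, 1, 1, ]), var(raw[tr, 1, 1, ]))
  }
})

test_that("band averaging follows the half-open edge convention", {
  freqs <- 2:50
  pow <- array(rep(freqs, each = 2), dim = c(2, 1, 49, 1))
  tf <- structure(list(power = pow, freqs = freqs, times = 0, fs = 500,
                       trial_meta = data.frame(trial = 1:2)),
                  class = "timefreq")
  out <- band_average(tf, default_band_defs("bands"))
  expect_equal(out$theta$power[1, 1, 1, 1], mean(4:8)) # closed low edge
  expect_equal(out$alpha$power[1, 1, 1, 1], mean(9:13))
  expect_equal(out$low_beta$power[1, 1, 1, 1], mean(14:20))
  expect_equal(out$high_beta$power[1, 1, 1, 1], mean(21:30))
  broad <- band_average(tf, default_band_defs("broadband"))
  expect_equal(broad$beta$power[1, 1, 1, 1], mean(14:30))
  # flat spectrum: every band average equals the flat value
  tf$power <- array(7, dim = dim(pow))
  flat <- band_average(tf, default_band_defs("bands"))
  for (b in flat) expect_equal(as.vector(b$power), c(7, 7))
  expect_error(band_average(tf, list(band_def("empty", 50, 60))), "no bins")
})

test_that("feature assembly yields the stated dimensions and labels", {
  set.seed(9)
  n_tr <- 24; n_ch <- 60
  meta <- data.frame(
    category_cued = rep(c("face", "word", "motion"), length.out = n_tr),
    category_uncued = rep(c("word", "motion", "face"), length.out = n_tr))
  mk_tf <- function() {
    structure(list(power = array(rnorm(n_tr * n_ch * 3, 10),
                                 dim = c(n_tr, n_ch, 1, 3)),
                   freqs = 6, times = c(-0.5, 0, 0.5), fs = 500,
                   trial_meta = meta), class = "timefreq")
  }
  btf <- list(theta = mk_tf(), alpha = mk_tf(), beta = mk_tf())
  fs_b <- assemble_features(btf, 0, "face")
  expect_equal(ncol(fs_b$X), 180)
  expect_equal(nrow(fs_b$X), n_tr)
  fs_1 <- assemble_features(btf, 0, "face", mode = "alpha")
  expect_equal(ncol(fs_1$X), 60)
  # label = category present in the memory array (cued or uncued)
  expect_equal(fs_b$y,
               as.integer(meta$category_cued == "face" |
                            meta$category_uncued == "face"))
  expect_error(assemble_features(btf, 0.123, "face"), "off the grid")
  expect_error(assemble_features(btf, 0, "face", mode = "gamma"), "unknown")
})
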