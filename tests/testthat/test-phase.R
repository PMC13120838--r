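test_that("instantaneous phase tracks a pure and a mixed oscillation", {
  fs <- 100
  t <- seq(-2, 2 - 1 / fs, by = 1 / fs)
  alpha <- band_def("alpha", 8, 13)
  pure <- trial_series_from_matrix(rbind(cos(2 * pi * 10 * t)), fs, t)
  ps <- instantaneous_phase(pure, alpha)
  centre <- which(ps$time > -1 & ps$time < 1)
  # unwrapped phase slope = 2*pi*10 rad/s within 1%
  phi <- ps$phase[1, centre]
  unw <- cumsum(c(phi[1], circ_dist(phi[-1], phi[-length(phi)])))
  slope <- coef(lm(unw ~ ps$time[centre]))[[2]]
  expect_lt(abs(slope - 2 * pi * 10) / (2 * pi * 10), 0.01)
  # phase at a cosine peak is 0
  peak <- which.min(abs(ps$time - 0.1)) # t = 0.1 s: cos(2*pi) peak
  expect_lt(abs(ps$phase[1, peak]), 0.05)
  # an out-of-band 40 Hz component does not disturb the alpha phase
  mixed <- trial_series_from_matrix(
    rbind(cos(2 * pi * 10 * t) + 0.8 * cos(2 * pi * 40 * t)), fs, t)
  pm <- instantaneous_phase(mixed, alpha)
  err <- circ_dist(pm$phase[1, centre], ps$phase[1, centre])
  expect_lt(sqrt(mean(err^2)), 0.1)
  expect_error(instantaneous_phase(pure, band_def("hi", 20, 60)), "Nyquist")
})

test_that("PLV time course hits its algebraic extremes", {
  ph <- matrix(rep(c(0.3, 0.3, 0.3), 4), nrow = 3)
  expect_equal(plv_timecourse(phase_set_from_matrix(ph)), rep(1, 4))
  anti <- rbind(rep(0.5, 4), rep(0.5 - pi, 4))
  expect_equal(plv_timecourse(phase_set_from_matrix(anti)), rep(0, 4),
               tolerance = 1e-12)
  expect_warning(plv_timecourse(phase_set_from_matrix(ph[1, , drop = FALSE])),
                 "single trial")
  # invariant under a global rotation of all phases
  set.seed(3)
  ph2 <- matrix(runif(50, -pi, pi), nrow = 10)
  expect_equal(plv_timecourse(phase_set_from_matrix(ph2)),
               plv_timecourse(phase_set_from_matrix(wmpulse:::wrap_angle(ph2 + 1.1))),
               tolerance = 1e-12)
})

test_that("window candidates use cycle-based lengths on the 10 ms grid", {
  # alpha, 2 cycles at the 10.5 Hz band midpoint: 190.5 ms -> 190 ms
  alpha <- band_def("alpha", 8, 13)
  expect_equal(wmpulse:::band_center(alpha), 10.5)
  expect_equal(floor((2 / 10.5) / 0.01) * 0.01, 0.19)
  # selection returns a valid spec even without any reset; onset respects the
  # 30 ms spTMS floor
  set.seed(12)
  ps_list <- lapply(1:4, function(p) {
    phase_set_from_matrix(matrix(runif(30 * 401, -pi, pi), nrow = 30),
                          time = seq(-2, 2, by = 0.01))
  })
  w <- select_window(ps_list, alpha, "sptms")
  expect_s3_class(w, "window_spec")
  expect_gte(w$onset, 0.030)
  expect_true(w$n_cycles %in% 2:4)
  expect_equal(w$onset, round(w$onset, 2)) # 10 ms grid
  expect_error(select_window(ps_list[1], alpha, "sptms"), "participants")
})

test_that("windowed PLV change and phase shift compute their contracts", {
  time <- seq(-2, 2, by = 0.01)
  w <- window_spec("alpha", "sptms", 2, onset = 0.05, length = 0.2)
  # trials locked post-event, uniform pre-event
  set.seed(6)
  n_tr <- 300
  ph <- matrix(runif(n_tr * length(time), -pi, pi), nrow = n_tr)
  post <- time >= 0.03
  ph[, post] <- matrix(rep(wmpulse:::rvonmises(n_tr, 0, 50), sum(post)),
                       nrow = n_tr)
  ps <- phase_set_from_matrix(ph, time = time)
  chg <- wp_plv_change(ps, w)
  expect_gt(chg, 0.8) # post ~ 1, pre ~ small
  # every trial shifted by +pi/4 between windows
  ph2 <- matrix(rep(runif(n_tr, -pi, pi), length(time)), nrow = n_tr)
  ph2[, post] <- wmpulse:::wrap_angle(ph2[, post] + pi / 4)
  ms <- mean_phase_shift(phase_set_from_matrix(ph2, time = time), w)
  expect_equal(ms$shift, pi / 4, tolerance = 1e-6)
  expect_false(ms$low_confidence)
  # shifts clustered at the wrap point resolve to pi, never 0
  ph3 <- matrix(rep(runif(n_tr, -pi, pi), length(time)), nrow = n_tr)
  ph3[, post] <- wmpulse:::wrap_angle(ph3[, post] + pi +
                                        rnorm(n_tr, sd = 0.02))
  ms3 <- mean_phase_shift(phase_set_from_matrix(ph3, time = time), w)
  expect_lt(abs(circ_dist(ms3$shift, pi)), 0.1)
  expect_gt(abs(ms3$shift), 3)
  # shifts spread evenly over the circle raise the low-confidence flag
  even <- seq(-pi, pi, length.out = n_tr + 1)[-(n_tr + 1)]
  ph5 <- matrix(0, nrow = n_tr, ncol = length(time))
  ph5[, post] <- matrix(rep(even, sum(post)), nrow = n_tr)
  ms4 <- mean_phase_shift(phase_set_from_matrix(ph5, time = time), w)
  expect_true(ms4$low_confidence)
  expect_lt(ms4$confidence_r, 0.01)
  expect_error(wp_plv_change(ps, window_spec("alpha", "sptms", 2, 1.95, 0.2)),
               "outside")
})

test_that("intersubject PLV matches the Bessel oracle and its extremes", {
  expect_equal(intersubject_plv(rep(0.8, 5))$r, 1)
  even <- seq(-pi, pi, length.out = 13)[-13]
  expect_lt(intersubject_plv(even)$r, 1e-10)
  expect_error(intersubject_plv(c(0.1, 0.2)), ">= 3")
  # E[r] for n = 12 von Mises(kappa = 2) draws, against direct simulation
  set.seed(9)
  sims <- replicate(400, {
    intersubject_plv(wmpulse:::rvonmises(12, 0, 2), n_boot = 2)$r
  })
  # finite-sample reference by independent simulation with R's own uniform
  ref <- replicate(2000, {
    u <- wmpulse:::rvonmises(12, 0, 2)
    Mod(mean(exp(1i * u)))
  })
  expect_lt(abs(mean(sims) - mean(ref)), 3 * sd(ref) / sqrt(400))
  expect_gt(mean(sims), expected_plv(2) - 3 * sd(ref) / sqrt(400) - 0.05)
  # bootstrap SE is reproducible given the seed
  s1 <- intersubject_plv(even + 0.3, seed = 5)
  s2 <- intersubject_plv(even + 0.3, seed = 5)
  expect_identical(s1$se, s2$se)
})

test_that("normalization against spTMS-absent trials subtracts both measures", {
  time <- seq(-2, 2, by = 0.01)
  w <- window_spec("alpha", "sptms", 2, onset = 0.05, length = 0.2)
  set.seed(10)
  mk <- function(seed) {
    lapply(1:4, function(p) {
      set.seed(seed + p)
      phase_set_from_matrix(matrix(runif(20 * length(time), -pi, pi),
                                   nrow = 20), time = time)
    })
  }
  pres <- compute_phase_measures(mk(1), w)
  abs_ <- compute_phase_measures(mk(50), w)
  same <- normalize_vs_absent(pres, pres)
  expect_equal(same$wp_plv_change, rep(0, 4))
  expect_equal(same$mean_shift, rep(0, 4))
  norm <- normalize_vs_absent(pres, abs_)
  expect_equal(norm$wp_plv_change, pres$wp_plv_change - abs_$wp_plv_change)
  expect_equal(norm$mean_shift, circ_dist(pres$mean_shift, abs_$mean_shift))
  expect_true(norm$normalized)
  w2 <- window_spec("alpha", "sptms", 3, onset = 0.05, length = 0.2)
  abs2 <- compute_phase_measures(mk(50), w2)
  expect_error(normalize_vs_absent(pres, abs2), "mismatched")
})

test_that("paired permutation p values behave at the extremes and under effects", {
  a <- rnorm(12)
  expect_equal(paired_permutation(a, a, n_iter = 500)$p, 1)
  set.seed(13)
  b <- rnorm(12, sd = 0.1)
  res <- paired_permutation(b + 1, b, n_iter = 2000, seed = 3)
  expect_lte(res$p, 0.01)
  expect_gte(res$p, 1 / 2000)
  expect_error(paired_permutation(a, a, n_iter = 10), "n_iter")
  expect_error(paired_permutation(a, a[1:5]), "unpaired")
  # circular mode: wrapped differences drive the statistic
  sh <- rep(0.1, 10)
  resc <- paired_permutation(wmpulse:::wrap_angle(sh + 3), sh,
                             n_iter = 500, circular = TRUE)
  expect_lt(resc$p, 0.05)
})

test_that("time-resolved consistency produces 10 windows with correct extremes", {
  time <- seq(-2, 2, by = 0.01)
  n_tr <- 15
  mk_locked <- function(angle) {
    ph <- matrix(rep(angle, n_tr * length(time)), nrow = n_tr)
    phase_set_from_matrix(ph, time = time)
  }
  ps_a <- lapply(rep(0.7, 6), mk_locked) # all participants share one angle
  trc <- time_resolved_consistency(ps_a)
  expect_equal(nrow(trc$windows), 10)
  expect_equal(trc$windows$onset_s, seq(0.05, 0.5, by = 0.05))
  expect_equal(trc$windows$r_a, rep(1, 10))
  expect_true(all(trc$windows$p_rayleigh_a < 0.01))
  # paired condition with uniform angles: between-condition test runs, r_b low
  set.seed(14)
  ps_b <- lapply(1:6, function(p) {
    phase_set_from_matrix(matrix(runif(n_tr * length(time), -pi, pi),
                                 nrow = n_tr), time = time)
  })
  trc2 <- time_resolved_consistency(ps_a, ps_b, n_iter = 200, seed = 2)
  expect_true(all(trc2$windows$r_a > trc2$windows$r_b))
  expect_true(all(trc2$windows$p_between >= 1 / 200))
  expect_error(time_resolved_consistency(ps_a, ps_b[1:3]), "paired")
})
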