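test_that("Welch band power: band separation, flat-spectrum proportionality,
           Parseval identity", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 13 * t)
  expect_gt(band_power(x, fs, c(12, 15)) / band_power(x, fs, c(0.1, 3)), 100)
  set.seed(1)
  w <- rnorm(60 * fs)
  p1 <- band_power(w, fs, c(5, 10)) * 5
  p2 <- band_power(w, fs, c(20, 40)) * 20
  expect_lt(abs(p1 / (p2 / 4) - 1), 0.2)  # power ~ bandwidth
  sp <- welch_psd(w, fs)
  total <- sum(sp$psd) * diff(sp$freq[1:2])
  expect_lt(abs(total / var(w) - 1), 0.05)
  expect_error(band_power(w, fs, c(40, 60)), "Nyquist")
  expect_error(welch_psd(rnorm(4), fs), "window")
})

test_that("DOWN-state detection finds the centres of low segments and
           nothing on flat signals", {
  fs <- 100
  x <- rep(c(rep(40, 200), rep(1, 100)), 10)  # 2 s UP / 1 s DOWN
  dn <- detect_down_states(x, fs)
  expect_identical(nrow(dn), 10L)
  centres <- (seq_len(10) - 1) * 3 + 2.5
  expect_true(all(abs(dn$midpoint - centres) < 0.05))
  expect_identical(nrow(detect_down_states(rep(30, 1000), fs)), 0L)
})

test_that("DOWN-spindle pairing respects the 1.5 s window", {
  dn <- data.frame(start = c(1, 10), end = c(2, 11), midpoint = c(1.5, 10.5))
  sp <- data.frame(peak_time = c(2.4, 14))
  pr <- pair_down_spindles(dn, sp, window = 1.5)
  expect_identical(pr$followed, c(TRUE, FALSE))
  expect_equal(pr$delay[1], 0.9)
})

test_that("event-locked averages: template identity, SEM scaling,
           alignment specificity", {
  fs <- 100
  tmpl <- sin(seq(0, 2 * pi, length.out = 2 * fs + 1))
  x <- rep(0, 60 * fs)
  events <- seq(5, 55, by = 5)
  for (e in events) {
    i <- e * fs
    x[(i - fs):(i + fs)] <- x[(i - fs):(i + fs)] + tmpl
  }
  la <- event_locked_average(x, fs, events, window = c(-1, 1))
  expect_equal(la$mean, tmpl, tolerance = 1e-10)
  expect_true(all(la$sem == 0))
  # template + noise: SEM approximates noise SD / sqrt(n)
  set.seed(8)
  n_ev <- 50
  ev2 <- seq(3, 300 - 3, length.out = n_ev)
  y <- rnorm(300 * fs, sd = 0.5)
  la2 <- event_locked_average(y, fs, ev2, window = c(-1, 1))
  expect_lt(abs(mean(la2$sem) / (0.5 / sqrt(n_ev)) - 1), 0.25)
  # random events on a structured signal give a flat average
  la3 <- event_locked_average(x, fs, runif(40, 2, 58), window = c(-1, 1))
  expect_lt(diff(range(la3$mean)), 0.5 * diff(range(tmpl)))
  expect_error(event_locked_average(x, fs, 5, window = c(-1, 1)), "two")
})

test_that("circular statistics: point mass, uniform sample, histogram", {
  cs <- circular_phase_stats(rep(pi / 4, 100))
  expect_equal(cs$mean, pi / 4)
  expect_equal(cs$sd, 0, tolerance = 1e-6)
  ph <- seq(-pi, pi, length.out = 3601)[-3601]
  cs2 <- circular_phase_stats(ph)
  expect_lt(cs2$R, 1e-10)
  expect_gt(cs2$sd, 3)
  expect_identical(sum(cs2$histogram), 3600L)
  expect_error(circular_phase_stats(numeric(0)), "empty")
})

test_that("the coupled fixture generator orders the modulation index by its
           depth, every seed", {
  for (seed in 1:20) {
    k <- vapply(c(0.2, 0.5, 0.9), function(m) {
      x <- generate_pac_signal(m = m, duration_s = 60, noise_sd = 0.05,
                               seed = seed)
      slow <- band_phase_amplitude(x, 100, c(0.1, 3))
      fast <- band_phase_amplitude(x, 100, c(12, 15))
      kl_mi(slow$phase, fast$amplitude)
    }, numeric(1))
    expect_monotone_increasing(k)
  }
  expect_error(generate_pac_signal(m = 2), "m must")
  expect_error(generate_pac_signal(f_slow = 20, f_fast = 10), "f_slow")
})

test_that("the spindle-train generator stores ground truth and rejects
           overlapping bursts", {
  x <- generate_spindle_train(burst_times = c(3, 8), duration_s = 12,
                              seed = 1)
  expect_identical(attr(x, "events")$centre, c(3, 8))
  expect_error(generate_spindle_train(burst_times = c(3, 3.2)), "overlap")
  ev <- detect_spindles(x)
  expect_true(all(abs(ev$mean_frequency - 13) < 0.5))
})

test_that("sweeps are invariant to axis ordering and reruns", {
  g <- sim_grid(15e3, seed = 1)
  s1 <- run_sweep(sweep_spec("thalamus",
                             axes = list(g_LK = c(0.018, 0.031),
                                         g_h = c(0.05, 0.062)),
                             grid = g))
  s2 <- run_sweep(sweep_spec("thalamus",
                             axes = list(g_h = c(0.062, 0.05),
                                         g_LK = c(0.031, 0.018)),
                             grid = g))
  expect_identical(nrow(s1), 4L)
  key <- function(d) paste(d$g_LK, d$g_h)
  reord <- s2[match(key(s1), key(s2)), ]
  expect_equal(s1$spindles_per_second, reord$spindles_per_second)
  s1b <- run_sweep(sweep_spec("thalamus",
                              axes = list(g_LK = c(0.018, 0.031),
                                          g_h = c(0.05, 0.062)),
                              grid = g))
  expect_identical(s1, s1b)
})

test_that("a diverging sweep point is recorded as missing, not fatal", {
  g <- sim_grid(6e3, seed = 1)
  # an absurd conductance drives the state out of range -> NA row
  s <- run_sweep(sweep_spec("thalamus", axes = list(g_LK = c(0.018, 1e9),
                                                    g_h = 0.062),
                            grid = g, transient_s = 1))
  expect_identical(nrow(s), 2L)
  expect_true(is.finite(s$spindles_per_second[s$g_LK == 0.018]))
})

test_that("the short-time Fourier transform localizes the carrier", {
  fs <- 100
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 13 * t) * (t > 10)
  st <- stft_power(x, fs, window_s = 2)
  late <- st$time > 12
  early <- st$time < 8
  i13 <- which.min(abs(st$freq - 13))
  expect_gt(mean(st$power[i13, late]), 100 * mean(st$power[i13, early]))
})
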