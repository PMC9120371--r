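test_that("analytic signal of a sinusoid: flat envelope, linear phase,
           -pi/2 at a positive-going zero crossing", {
  fs <- 100; f <- 13
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- 2.5 * sin(2 * pi * f * t)
  a <- band_phase_amplitude(x, fs, c(12, 15))
  core <- seq(5 * fs, length(t) - 5 * fs)
  expect_lt(max(abs(a$amplitude[core] - 2.5)) / 2.5, 0.02)
  dphi <- diff(a$phase[core]) %% (2 * pi)
  expect_equal(median(dphi), 2 * pi * f / fs, tolerance = 1e-3)
  # positive-going zero crossing of sin at t = 1 s exactly
  i0 <- which.min(abs(t - 10))
  expect_equal(a$phase[i0], -pi / 2, tolerance = 0.02)
})

test_that("band limits are validated", {
  expect_error(band_phase_amplitude(rnorm(1000), 100, c(40, 60)), "fs/2")
  expect_error(band_phase_amplitude(rnorm(4), 100, c(1, 10)), "short")
})

test_that("KL modulation index spans its [0, 1] range at the degenerate
           extremes and is zero-shift invariant", {
  set.seed(1)
  ph <- runif(20000, -pi, pi)
  expect_lt(kl_mi(ph, rep(1, 20000)), 1e-3)       # uniform distribution
  amp <- as.numeric(abs(ph - 0.5) < pi / 18 / 2)  # single-bin mass
  expect_equal(kl_mi(ph, amp, n_bins = 18), 1, tolerance = 0.05)
  expect_error(kl_mi(ph, numeric(20000)), "zero")
  expect_true(kl_mi(ph, rep(1, 20000)) >= 0)
})

test_that("mean vector length: cancellation, point mass, and recovery of the
           generator's preferred phase", {
  n <- 12000
  ph <- rep(seq(-pi, pi, length.out = 121)[-121], length.out = n)
  expect_lt(Mod(mvl(ph, rep(1, n))), 1e-10)
  mass <- as.numeric(abs(ph - 1) < 0.01)
  expect_equal(Arg(mvl(ph, mass)), 1, tolerance = 0.02)
  for (seed in 1:5) {
    x <- generate_pac_signal(m = 0.9, phi0 = pi / 4, duration_s = 120,
                             seed = seed)
    slow <- band_phase_amplitude(x, 100, c(0.1, 3))
    fast <- band_phase_amplitude(x, 100, c(12, 15))
    expect_lt(abs(Arg(mvl(slow$phase, fast$amplitude)) - pi / 4), 0.15)
  }
})

test_that("phase-locking value: identity, constant lag, Rayleigh-level for
           independent phases", {
  n <- 12000
  set.seed(2)
  pa <- runif(n, -pi, pi)
  expect_equal(as.numeric(plv(pa, pa)), 1)
  lag <- plv(pa, (pa - 0.7 + pi) %% (2 * pi) - pi)
  expect_equal(as.numeric(lag), 1, tolerance = 1e-10)
  expect_equal(attr(lag, "offset"), 0.7, tolerance = 1e-6)
  pb <- runif(n, -pi, pi)
  expect_lt(as.numeric(plv(pa, pb)), sqrt(-log(0.05) / n))  # 95th pct null
})

test_that("phase MI: maximal for a bijection, symmetric, near-bias for
           independent phases", {
  n <- 12800
  set.seed(3)
  pa <- runif(n, -pi, pi)
  expect_equal(phase_mi(pa, pa), log(16), tolerance = 1e-10)
  bij <- ((pa * 3 + 1) + pi) %% (2 * pi) - pi  # monotone pieces, bijective
  expect_gt(phase_mi(pa, bij), 0.5 * log(16))
  pb <- runif(n, -pi, pi)
  expect_identical(phase_mi(pa, pb), phase_mi(pb, pa))
  bias <- (16 - 1)^2 / (2 * n)  # first-order plug-in estimator bias
  expect_lt(phase_mi(pa, pb), 3 * bias)
  expect_warning(phase_mi(pa[1:100], pb[1:100]), "undersampled")
})

test_that("IAAFT surrogates preserve the value distribution exactly, the
           spectrum closely, and are seed-deterministic", {
  set.seed(4)
  x <- as.numeric(stats::filter(rnorm(12000), c(1.6, -0.8),
                                method = "recursive"))
  s <- iaaft_surrogates(x, 4, seed = 9)
  for (j in 1:4) expect_identical(sort(s[, j]), sort(x))
  amp0 <- Mod(fft(x))
  for (j in 1:4)
    expect_lt(sqrt(mean((Mod(fft(s[, j])) - amp0)^2)) /
                sqrt(mean(amp0^2)), 0.01)
  expect_identical(iaaft_surrogates(x, 4, seed = 9), s)
  expect_false(identical(s[, 1], s[, 2]))
  expect_error(iaaft_surrogates(rep(1, 100), 2), "constant")
})

test_that("surrogate test: strong coupling is detected, absent coupling is
           rejected at the nominal rate", {
  # a noisy fixture: surrogates of a near-deterministic two-tone signal
  # are close to time shifts of it, against which shift-invariant
  # statistics have no power
  x <- generate_pac_signal(m = 0.9, noise_sd = 0.5, duration_s = 120,
                           seed = 1, modulator = "noise")
  r <- surrogate_test(x, x, 100, "klmi", n_surr = 99, seed = 1)
  expect_equal(r$p_value, 1 / 100)
  expect_gte(r$p_value, 1 / (1 + r$n_surr))  # (1+k)/(1+n) floor
  # type-I calibration on uncoupled fixtures (alpha = 0.05)
  rejections <- 0
  runs <- 40
  for (i in seq_len(runs)) {
    x0 <- generate_pac_signal(m = 0, duration_s = 30, noise_sd = 0.3,
                              seed = 100 + i, modulator = "noise")
    r0 <- surrogate_test(x0, x0, 100, "klmi", n_surr = 39, seed = i)
    if (r0$p_value <= 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / runs, 0.15)
  expect_error(surrogate_test(x, x, 100, "klmi", n_surr = 5), "n_surr")
})

test_that("statistics are invariant to adding a constant to the raw
           signals", {
  x <- generate_pac_signal(m = 0.7, duration_s = 60, seed = 6)
  v1 <- cfc_suite(x, x, 100, n_surr = 20 + 5)  # values only; small null
  v2 <- cfc_suite(x + 100, x + 100, 100, n_surr = 25)
  for (s in c("klmi", "mvl", "plv", "mi"))
    expect_equal(v1[[s]]$value, v2[[s]]$value, tolerance = 1e-6)
})
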