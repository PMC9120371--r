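test_that("transfer tables are finite, nonnegative and monotone in the mean
           input at fixed sigma", {
  tb <- fx_table()
  expect_true(all(is.finite(tb$r)), all(is.finite(tb$V)),
              all(is.finite(tb$tau)))
  expect_true(all(tb$r >= 0))
  for (j in seq_along(tb$sigma_grid))
    expect_monotone_increasing(tb$r[, j], tol = 1e-12)
  # far below rheobase at small sigma the population is silent
  lk <- lookup_transfer(tb, mu = -1.5, sigma = 0.1)
  expect_lt(lk$r, 1e-6)
})

test_that("table rates agree with a Monte-Carlo simulation of independent
           AdEx neurons within 5%", {
  tb <- fx_table()
  pts <- list(c(1, 1.5), c(2, 2), c(3.5, 2.5))
  for (i in seq_along(pts)) {
    mu <- pts[[i]][1]; sg <- pts[[i]][2]
    fp <- 1000 * lookup_transfer(tb, mu, sg)$r
    mc <- mc_eif_rate(adex_params(), mu, sg, n_neuron = 1500,
                      t_total = 4000, seed = 100 + i)
    expect_lt(abs(fp / mc - 1), 0.05)
  }
})

test_that("bilinear lookup: node identity, midpoint average, clamping", {
  tb <- fx_table()
  i <- 60; j <- 5
  mu0 <- tb$mu_grid[i]; sg0 <- tb$sigma_grid[j]
  expect_equal(lookup_transfer(tb, mu0, sg0)$r, tb$r[i, j])
  mid <- lookup_transfer(tb, (tb$mu_grid[i] + tb$mu_grid[i + 1]) / 2, sg0)$r
  expect_equal(mid, (tb$r[i, j] + tb$r[i + 1, j]) / 2)
  below <- lookup_transfer(tb, min(tb$mu_grid) - 5, sg0)
  at_min <- lookup_transfer(tb, min(tb$mu_grid), sg0)
  expect_identical(below$r, at_min$r)
  expect_identical(below$tau, at_min$tau)
})

test_that("synaptic mean fraction has the saturating fixed point
           rbar/(1/tau_s + rbar) and stays in [0, 1]", {
  tau_s <- 5; rbar <- 0.3  # 1/ms
  out <- euler_integrate(function(t, s, d) -s / tau_s + (1 - s) * rbar,
                         0, sim_grid(100, dt = 0.01, dt_samp = 1))
  expect_equal(tail(out$state[, 1], 1), rbar / (1 / tau_s + rbar),
               tolerance = 1e-4)
  expect_true(all(out$state >= 0 & out$state <= 1))
  # zero input: exponential decay with timescale tau_s
  out0 <- euler_integrate(function(t, s, d) -s / tau_s, 0.8,
                          sim_grid(20, dt = 0.01, dt_samp = 1))
  expect_equal(out0$state[, 1], 0.8 * exp(-out0$time / tau_s),
               tolerance = 1e-3)
})

test_that("without adaptation sources the mean adaptation current stays zero", {
  p <- cortical_params(mu_E = 0.56, mu_I = 0.4,
                       neuron = adex_params(a = 0, b = 0))
  s <- simulate_cortex(p, sim_grid(5e3, seed = 1), table = fx_table())
  expect_true(all(abs(s$I_A) < 1e-12))
})

test_that("the four canonical regimes appear at their operating points", {
  tb <- fx_table()
  g <- sim_grid(20e3, seed = 1)
  amp <- function(s) { x <- drop_transient(s)$r_E; diff(range(x)) }
  # DOWN fixed point
  dn <- simulate_cortex(cortical_params(mu_E = 0.45, mu_I = 0.4), g, tb)
  expect_lt(amp(dn), 0.1)
  expect_lt(max(drop_transient(dn)$r_E), 1)
  # UP fixed point at strong drive
  up <- simulate_cortex(cortical_params(mu_E = 0.8, mu_I = 0.4), g, tb)
  expect_lt(amp(up), 0.1)
  expect_gt(tail(up$r_E, 1), 10)
  # adaptation-driven slow limit cycle
  slow <- simulate_cortex(cortical_params(mu_E = 0.56, mu_I = 0.4),
                          sim_grid(30e3, seed = 1), tb)
  expect_gt(amp(slow), 20)
  expect_lte(dominant_frequency(drop_transient(slow)$r_E, 100), 2)
  # fast E-I limit cycle at weak inhibitory drive
  ei <- simulate_cortex(cortical_params(mu_E = 0.4, mu_I = 0.1), g, tb)
  expect_gt(amp(ei), 10)
  f <- dominant_frequency(drop_transient(ei)$r_E, 100, band = c(5, 50))
  expect_gt(f, 15); expect_lt(f, 30)
})

test_that("noise turns the UP fixed point near the cycle border into UP
           activity with irregular DOWN excursions", {
  p <- cortical_params(mu_E = 0.7, mu_I = 0.4, sigma_E = 0.05,
                       sigma_I = 0.05)
  s <- simulate_cortex(p, sim_grid(60e3, seed = 2), table = fx_table())
  x <- drop_transient(s)$r_E
  expect_gt(mean(x), 10)           # predominantly UP
  expect_gt(diff(range(x)), 15)    # with large excursions
  frac_down <- mean(x < 5)
  expect_gt(frac_down, 0.001); expect_lt(frac_down, 0.5)
})

test_that("noise-free cortical trajectories are seed-independent", {
  a <- simulate_cortex(cortical_params(mu_E = 0.56, mu_I = 0.4),
                       sim_grid(8e3, seed = 1), fx_table())
  b <- simulate_cortex(cortical_params(mu_E = 0.56, mu_I = 0.4),
                       sim_grid(8e3, seed = 77), fx_table())
  expect_identical(a$r_E, b$r_E)
})

test_that("transfer-table grids are validated", {
  expect_error(build_transfer_table(mu_grid = c(1, 0.5), sigma_grid = c(1, 2)),
               "increasing")
  expect_error(build_transfer_table(mu_grid = 1, sigma_grid = c(1, 2)),
               "two points")
})
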