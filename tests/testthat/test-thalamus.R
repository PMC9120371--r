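test_that("sigmoid firing rate: midpoint, saturation, monotonicity, symmetry", {
  p <- thalamic_params()
  expect_equal(thalamic_rate(p$theta, p), 1000 * p$Q_max / 2)
  expect_equal(thalamic_rate(200, p), 1000 * p$Q_max, tolerance = 1e-6)
  expect_lt(thalamic_rate(-200, p), 1e-6)
  V <- seq(-100, 0, by = 0.5)
  expect_monotone_increasing(thalamic_rate(V, p))
  # logistic symmetry about the threshold
  expect_equal(thalamic_rate(p$theta + 7, p) + thalamic_rate(p$theta - 7, p),
               1000 * p$Q_max)
})

test_that("intrinsic currents vanish at their reversals and closed gates", {
  p <- thalamic_params()
  expect_equal(thalamic_currents(p$E_K, h = 0.5, p, "TCR")$I_LK, 0)
  for (pop in c("TCR", "TRN")) {
    cur <- thalamic_currents(-60, h = 0, p, pop)
    expect_equal(cur$I_T, 0)
  }
  p0 <- thalamic_params(g_h = 0)
  expect_equal(thalamic_currents(-70, 0.5, p0, "TCR", m_h1 = 0.3)$I_h, 0)
  expect_null(thalamic_currents(-70, 0.5, p, "TRN")$I_h)
  expect_error(thalamic_currents(-70, 0.5, p, "elsewhere"))
})

test_that("second-order synapse: DC gain, alpha-kernel impulse response,
           and agreement with direct convolution", {
  gamma <- 0.07
  rhs <- function(inp) function(t, x, d) c(x[2],
    gamma^2 * (inp(t) - x[1]) - 2 * gamma * x[2])
  # constant input: unit DC gain
  out <- euler_integrate(rhs(function(t) 2.5), c(0, 0),
                         sim_grid(400, dt = 0.05, dt_samp = 1))
  expect_equal(tail(out$state[, 1], 1), 2.5, tolerance = 1e-3)
  # impulse: response proportional to t exp(-gamma t), peak at 1/gamma
  dt <- 0.05
  imp <- function(t) ifelse(t < dt, 1 / dt, 0)
  out <- euler_integrate(rhs(imp), c(0, 0),
                         sim_grid(200, dt = dt, dt_samp = 1))
  tt <- out$time
  expect_equal(tt[which.max(out$state[, 1])], 1 / gamma, tolerance = 0.05)
  ref <- gamma^2 * tt * exp(-gamma * tt)
  expect_lt(max(abs(out$state[, 1] - ref)), 0.02 * max(ref))
  # random rate series: ODE vs discrete convolution with the alpha kernel
  set.seed(3)
  n <- 1000 / dt
  rate <- stats::filter(rnorm(n, 10, 3), rep(1 / 50, 50), sides = 1)
  rate[is.na(rate)] <- 10
  out <- euler_integrate(rhs(function(t) rate[pmin(n, floor(t / dt) + 1)]),
                         c(0, 0), sim_grid(1000, dt = dt, dt_samp = 1))
  tk <- seq(0, 400, by = dt)
  kern <- gamma^2 * tk * exp(-gamma * tk) * dt
  conv <- stats::filter(as.numeric(rate), kern, sides = 1)
  keep <- !is.na(conv)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out$state[-1, 1][keep] - conv[keep]) / rms(conv[keep]), 0.01)
})

test_that("noise-free corner parametrizations settle into constant-rate
           fixed points with near-zero residual derivatives", {
  g <- sim_grid(20e3, seed = 1)
  down <- simulate_thalamus(thalamic_params(g_LK = 0.08, g_h = 0.08), g)
  up <- simulate_thalamus(thalamic_params(g_LK = 0, g_h = 0), g)
  late <- function(s) tail(s$r_TCR, 500)
  expect_lt(diff(range(late(down))), 1e-4)
  expect_lt(diff(range(late(up))), 1e-4)
  expect_gt(tail(up$r_TCR, 1), tail(down$r_TCR, 1))
  # fixed-point consistency: the V-derivative evaluates to ~0 at the
  # settled state (TRN nearly silent, synaptic input negligible)
  p <- thalamic_params(g_LK = 0.08, g_h = 0.08)
  V <- tail(down$V_t, 1)
  gates <- thalamic_gates(V, "TCR")
  mi <- gates$m_inf_h
  # gating fixed points: h = h_inf; m_h1/m_h2 from the calcium equilibrium
  IT <- function(m1, m2) thalamic_currents(V, gates$h_inf, p, "TCR", m1, m2)
  Ca <- p$Ca_0 + p$alpha_Ca * IT(0, 0)$I_T * p$tau_Ca
  P <- p$k1 * Ca^p$n_P / (p$k1 * Ca^p$n_P + p$k2)
  ratio <- p$k3 * P / p$k4
  m1 <- mi / (1 + mi * (1 + ratio)); m2 <- ratio * m1
  cur <- IT(m1, m2)
  dV <- -(V - p$E_L) / p$tau_t - (cur$I_LK + cur$I_T + cur$I_h) / p$C_m
  expect_lt(abs(dV), 0.01)  # mV/ms
})

test_that("spontaneous spindling: two waxing-waning regions along g_LK and a
           continuous sigma oscillation in between", {
  ev1 <- detect_spindles(drop_transient(fx_region1()))
  expect_gt(nrow(ev1), 5)
  expect_equal(dominant_frequency(drop_transient(fx_region1())$r_TCR, 100,
                                  band = c(9, 16)), 13.5, tolerance = 0.08)

  s2 <- simulate_thalamus(thalamic_params(g_LK = 0.031),
                          sim_grid(35e3, seed = 1))
  expect_gt(nrow(detect_spindles(drop_transient(s2))), 3)

  # between the regions: continuous (non-waxing) oscillation, so no
  # discrete events, but large sigma-band amplitude
  s3 <- simulate_thalamus(thalamic_params(g_LK = 0.024),
                          sim_grid(35e3, seed = 1))
  x3 <- drop_transient(s3)
  expect_identical(nrow(detect_spindles(x3)), 0L)
  expect_gt(diff(range(x3$r_TCR)), 50)
  expect_equal(dominant_frequency(x3$r_TCR, 100), 12.6, tolerance = 0.1)

  # below both regions: stable fixed point
  s4 <- simulate_thalamus(thalamic_params(g_LK = 0.014),
                          sim_grid(20e3, seed = 1))
  expect_lt(diff(range(tail(s4$r_TCR, 1000))), 0.5)
})

test_that("background noise induces spindles between the spontaneous regions", {
  s0 <- simulate_thalamus(thalamic_params(g_LK = 0.024),
                          sim_grid(35e3, seed = 9))
  sN <- simulate_thalamus(thalamic_params(g_LK = 0.024),
                          sim_grid(35e3, seed = 9),
                          ou = ou_params(sigma = 0.05))
  expect_identical(nrow(detect_spindles(drop_transient(s0))), 0L)
  expect_gt(nrow(detect_spindles(drop_transient(sN))), 2)
})

test_that("rates respect their bounds and noise-free runs are reproducible", {
  s <- fx_region1()
  expect_true(all(s$r_TCR >= 0 & s$r_TCR <= 400))
  expect_true(all(s$r_TRN >= 0 & s$r_TRN <= 400))
  again <- simulate_thalamus(thalamic_params(), sim_grid(65e3, seed = 99))
  expect_identical(s$r_TCR, again$r_TCR)  # seed-invariant without noise
})

test_that("spindle frequency rises monotonically with relay g_T across the
           fast-spindle band; reticular g_T has a minor effect", {
  f <- vapply(c(2.7, 3.0, 3.3, 3.6), function(gT) {
    s <- simulate_thalamus(thalamic_params(g_T_t = gT),
                           sim_grid(30e3, seed = 1))
    dominant_frequency(drop_transient(s)$r_TCR, 100, band = c(8, 20))
  }, numeric(1))
  expect_monotone_increasing(f)
  expect_lt(f[1], 12.5)
  expect_gt(f[4], 14.5)
  fr <- vapply(c(1.8, 2.8), function(gTr) {
    s <- simulate_thalamus(thalamic_params(g_T_r = gTr),
                           sim_grid(30e3, seed = 1))
    dominant_frequency(drop_transient(s)$r_TCR, 100, band = c(8, 20))
  }, numeric(1))
  expect_lt(abs(diff(fr)), 1)
})

test_that("slow square-wave drive gates spindling into its silent phase", {
  sq <- function(t) 60 * (sin(2 * pi * 0.05 * t / 1000) > 0)
  s <- simulate_thalamus(thalamic_params(g_LK = 0.033, g_h = 0.062),
                         sim_grid(40e3, seed = 1), ext_rate = sq)
  ev <- detect_spindles(drop_transient(s))  # absolute event times
  expect_gt(nrow(ev), 3)
  # no spindle peak well inside the driven (UP) phase; peaks within half a
  # second of a phase switch are boundary effects of the envelope
  phase_pos <- (ev$peak_time %% 20)  # 20 s period: ON 0-10 s, OFF 10-20 s
  mid_on <- phase_pos > 0.5 & phase_pos < 9.5
  expect_true(!any(mid_on))
  expect_gt(mean(sq(1000 * ev$peak_time) == 0), 0.7)
})

test_that("constant drive shifts the spindling region toward lower g_h", {
  top_gh <- vapply(c(0, 30), function(drive) {
    gh <- seq(0.04, 0.09, by = 0.01)
    counts <- vapply(gh, function(g) {
      s <- simulate_thalamus(thalamic_params(g_LK = 0.033, g_h = g),
                             sim_grid(35e3, seed = 1), ext_rate = drive)
      nrow(detect_spindles(drop_transient(s)))
    }, numeric(1))
    max(gh[counts >= 2])
  }, numeric(1))
  expect_lt(top_gh[2], top_gh[1])
})
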