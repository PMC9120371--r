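# Shared, lazily computed fixtures. Everything is generated in code at test
# time; the heavier simulations are cached for the whole test session.
.fx <- new.env()

fx_table <- function() {
  if (is.null(.fx$tb)) .fx$tb <- build_transfer_table()
  .fx$tb
}

# isolated thalamic node in the spontaneously spindling regime, 65 s
fx_region1 <- function() {
  if (is.null(.fx$r1))
    .fx$r1 <- simulate_thalamus(thalamic_params(),
                                sim_grid(65e3, seed = 1))
  .fx$r1
}

# full loop in the short-UP-state regime, 125 s
fx_loop <- function() {
  if (is.null(.fx$loop))
    .fx$loop <- simulate_loop(
      cortical_params(mu_E = 0.61, mu_I = 0.4, sigma_E = 0.05,
                      sigma_I = 0.05),
      thalamic_params(g_LK = 0.033), loop_config(1.2, 0.12),
      sim_grid(125e3, seed = 1), table = fx_table(),
      ou_tcr = ou_params(sigma = 0.005))
  .fx$loop
}

expect_monotone_increasing <- function(x, tol = 0) {
  expect_true(all(diff(x) > -tol))
}
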