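test_that("equilibrium concentration is a linear partition law", {
  expect_equal(equilibrium_concentration(0, 0.0315), 0)
  expect_equal(equilibrium_concentration(2e-3, 0.0315),
               2 * equilibrium_concentration(1e-3, 0.0315))
  # hand evaluation: p / (Vm * H)
  p <- 3120e-6
  expect_equal(equilibrium_concentration(p, 0.0315),
               p / (0.02445 * 0.0315), tolerance = 1e-12)
  expect_error(equilibrium_concentration(1e-3, 0), "config error")
})

test_that("zero transfer leaves the gas unchanged", {
  cfg <- absorber_config(kla = c(SO2 = 0, CO2 = 0), water_vapor_out = 0)
  sim <- simulate_absorber(baseline_gas(), baseline_liquor(), cfg,
                           method = "steady")
  expect_equal(unname(sim$efficiency), c(0, 0), tolerance = 1e-10)
  expect_equal(sim$gas_out$composition[["SO2"]],
               baseline_gas()$composition[["SO2"]], tolerance = 1e-8)
})

test_that("single neutral-tracer stage matches the two-film CSTR balance", {
  # a tracer that never deprotonates carries no speciation: solving the
  # coupled gas/liquid stage balances G(Cin - Cout) = kLa V (Cout/H - T),
  # T = flux/L gives efficiency x / (1 + x + y) with x = kLa V / (G H)
  # and y = kLa V / L (liquid-side washout of the accumulated tracer)
  trc <- acid_system("tracer", 20)
  systems <- c(default_acid_systems(), list(tracer = trc))
  liq <- liquid_stream(200, ionic_totals(c(tracer = 0), systems = systems))
  H <- 0.5
  kla <- 120
  V <- 2
  G <- 5000
  cfg <- absorber_config(n_stages = 1, kla = c(TRC = kla),
                         henry = c(TRC = H), liquid_holdup = V,
                         species_system = c(TRC = "tracer"),
                         water_vapor_out = 0)
  gas <- gas_stream(G, c(TRC = 1000))
  sim <- simulate_absorber(gas, liq, cfg, method = "steady")
  x <- kla * V / (G * H)
  y <- kla * V / 200
  expect_equal(sim$efficiency[["TRC"]] / 100, x / (1 + x + y),
               tolerance = 1e-6)
})

test_that("steady-state path coincides with the dynamic integration", {
  cfg <- absorber_config()
  st <- simulate_absorber(baseline_gas(), baseline_liquor(), cfg,
                          method = "steady")
  dy <- simulate_absorber(baseline_gas(), baseline_liquor(), cfg,
                          horizon = 2)
  expect_true(dy$converged)
  expect_equal(st$efficiency, dy$efficiency, tolerance = 1e-8)
})

test_that("sulfur and carbon are conserved through the column", {
  for (scale in c(0.3, 1, 3)) {
    cfg <- absorber_config(kla_scale = scale)
    sim <- simulate_absorber(baseline_gas(), baseline_liquor(), cfg,
                             method = "steady")
    expect_lt(max(sim$audit), 1e-6)
  }
})

test_that("more transfer capacity and more alkaline liquor absorb more", {
  effs <- vapply(c(0.2, 1, 5), function(s) {
    cfg <- absorber_config(kla_scale = s)
    simulate_absorber(baseline_gas(), baseline_liquor(), cfg,
                      method = "steady")$efficiency[["SO2"]]
  }, 0)
  expect_true(all(diff(effs) > 0))

  # acidic liquor holds free SO2 and pushes back; alkaline liquor pulls
  liq <- liquid_stream(220, ionic_totals(c(sulfurous = 0.05)))
  effs_ph <- vapply(c(2.5, 4.5, 7), function(ph) {
    cfg <- absorber_config(controlled_ph = ph)
    simulate_absorber(baseline_gas(), liq, cfg,
                      method = "steady")$efficiency[["SO2"]]
  }, 0)
  expect_true(all(diff(effs_ph) > -1e-9))
  expect_gt(effs_ph[3], effs_ph[1])
})
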