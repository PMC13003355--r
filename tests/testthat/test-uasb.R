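test_that("stoichiometric models are validated for S and COD closure", {
  m <- default_uasb_model()
  expect_s3_class(m, "stoichiometric_model")
  expect_equal(nrow(m$stoich), 15)
  expect_setequal(unique(m$kinetics$group), c("x_ferm", "x_srb", "x_met"))

  # corrupting one coefficient breaks the COD balance and is rejected
  bad <- m$stoich
  bad[3, "acetate"] <- bad[3, "acetate"] * 1.5
  expect_error(
    stoichiometric_model(m$species, bad, m$kinetics, m$cod_content,
                         m$s_content),
    "COD closure"
  )
  # and an S imbalance is caught independently
  bad2 <- m$stoich
  bad2[9, "sulfate_s"] <- bad2[9, "sulfate_s"] * 0.5
  expect_error(
    stoichiometric_model(m$species, bad2, m$kinetics, m$cod_content,
                         m$s_content),
    "closure"
  )
})

test_that("Monod rates honor saturation, zero-substrate and inhibition", {
  m <- default_uasb_model()
  base <- stats::setNames(numeric(length(m$species)), m$species)
  base[c("x_ferm", "x_srb", "x_met")] <- 1

  # no substrate, no rate
  expect_true(all(reaction_rates(base, m) == 0))

  # saturation limit: rate -> mu_max * X
  sat <- base
  sat["glycerol"] <- 1e4
  r <- reaction_rates(sat, m)
  k <- m$kinetics
  i <- which(k$reaction == "glyc_to_pdo")
  expect_equal(r[i], k$mu_max[i] * 1, tolerance = 1e-3)

  # non-competitive sulfide inhibition halves the rate at I = Ki
  inh <- sat
  inh["sulfide_s"] <- k$Ki_sulfide[i]
  expect_equal(reaction_rates(inh, m)[i] / r[i], 0.5, tolerance = 1e-3)

  expect_error(reaction_rates(replace(base, 1, -1), m), "state error")
})

test_that("film transfer moves species toward saturation", {
  expect_equal(headspace_transfer(2, 2, 200), 0)
  expect_equal(headspace_transfer(1, 2, 0), 0)
  expect_gt(headspace_transfer(1, 2, 200), 0)
  expect_lt(headspace_transfer(3, 2, 200), 0)

  # closed batch approaches saturation exponentially at rate kLa:
  # the distance halves every ln(2)/kLa days
  kla <- 200
  sol <- deSolve::lsoda(c(C = 0), c(0, log(2) / kla),
                        function(t, y, p) {
                          list(headspace_transfer(y, 2, kla))
                        }, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol[2, "C"]), 1, tolerance = 1e-6)
})

test_that("a single mini-CSTR reproduces the chemostat closed form", {
  mu <- 2; Ks <- 0.05; D <- 0.5; V <- 10
  mod <- toy_chemostat_model(mu_max = mu, Ks = Ks)
  feed <- liquid_stream(D * V / 24, solutes = c(s = 2))
  r <- simulate_uasb(feed, mod, n_tanks = 1, volume = V, retention = 0,
                     headspace = uasb_headspace(kla = 0), horizon = 600)
  expect_true(r$converged)
  expect_equal(r$effluent$solutes[["s"]], Ks * D / (mu - D),
               tolerance = 1e-6)
  expect_lt(max(r$audit), 1e-6)
})

test_that("sulfate-free feed passes sulfide through untouched", {
  m <- default_uasb_model()
  feed <- liquid_stream(220, temperature = 35,
                        solutes = c(glycerol = 1, sulfide_s = 0.05))
  r <- simulate_uasb(feed, m, n_tanks = 3, volume = 300,
                     headspace = uasb_headspace(kla = 0), horizon = 300)
  expect_equal(r$effluent$solutes[["sulfide_s"]], 0.05, tolerance = 1e-6)
  # sulfidogenic biomass only decays without its electron acceptor
  expect_lt(max(r$states[, "x_srb"]), 0.5)
})

test_that("carbon dosed above stoichiometric need keeps removal complete", {
  m <- default_uasb_model()
  res <- vapply(c(1.5, 3), function(gly) {
    feed <- liquid_stream(220, temperature = 35,
                          solutes = c(glycerol = gly, sulfate_s = 0.4,
                                      ic = 0.02))
    r <- simulate_uasb(feed, m, n_tanks = 3, volume = 300)
    0.4 - r$effluent$solutes[["sulfate_s"]]
  }, 0)
  # removal is essentially complete at both doses; the surplus must not
  # push it down beyond the equilibrium-residual noise of the extra
  # sulfide inhibition
  expect_true(diff(res) > -1e-4)
  expect_gt(min(res), 0.39)
})

test_that("more tanks at fixed volume sharpen the conversion profile", {
  mod <- toy_chemostat_model(mu_max = 2, Ks = 0.5)
  out <- vapply(c(1, 4), function(n) {
    feed <- liquid_stream(0.5 * 10 / 24, solutes = c(s = 2))
    r <- simulate_uasb(feed, mod, n_tanks = n, volume = 10,
                       retention = 0.9,
                       headspace = uasb_headspace(kla = 0), horizon = 600)
    r$effluent$solutes[["s"]]
  }, 0)
  expect_lte(out[2], out[1] + 1e-9)
})

test_that("elemental S and COD are conserved through the tank chain", {
  m <- default_uasb_model()
  feed <- liquid_stream(220, temperature = 35,
                        solutes = c(glycerol = 2.6, sulfate_s = 0.45,
                                    sulfide_s = 0.3, ic = 0.05))
  r <- simulate_uasb(feed, m, n_tanks = 3, volume = 300)
  expect_true(r$converged)
  expect_lt(r$audit[["S"]], 1e-6)
  expect_lt(r$audit[["COD"]], 1e-6)
  expect_gt(r$biogas$flow_m3_d, 0)
})
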