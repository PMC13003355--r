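test_that("PI step honors bias, clamping and anti-windup", {
  ctl <- pi_controller_config(setpoint = 0.1, Kp = 50, Ki_gain = 25,
                              bounds = c(0, 500), bias = 10)
  # zero error, zero integral: bias output
  s <- pi_step(0, 0, ctl, 1)
  expect_equal(s$airflow, 10)
  expect_equal(s$integral_state, 0)

  # integral accumulates error * dt while unsaturated
  s <- pi_step(0.05, 0, ctl, 0.5)
  expect_equal(s$integral_state, 0.025)

  # persistent large positive error: pinned at the upper bound, integral
  # frozen
  s <- pi_step(100, 50, ctl, 1)
  expect_equal(s$airflow, 500)
  expect_equal(s$integral_state, 50)

  # symmetric freeze at the lower bound
  s <- pi_step(-100, -50, ctl, 1)
  expect_equal(s$airflow, 0)
  expect_equal(s$integral_state, -50)
})

test_that("PI on a first-order plant matches the Laplace closed form", {
  # plant dy/dt = -a y + b u, controller u = Kp e + Ki int(e),
  # step set-point r: y'' + (a + b Kp) y' + b Ki y = b Ki r
  a <- 1; b <- 0.5; Kp <- 4; Ki <- 3; r <- 1
  ctl <- pi_controller_config(setpoint = r, Kp = Kp, Ki_gain = Ki,
                              bounds = c(-1e9, 1e9), bias = 0)
  rhs <- function(t, y, p) {
    e <- r - y[1]
    u <- pi_step(e, y[2], ctl, 0)$airflow
    list(c(-a * y[1] + b * u, e))
  }
  tt <- seq(0, 8, by = 0.25)
  num <- deSolve::lsoda(c(0, 0), tt, rhs, NULL, rtol = 1e-11,
                        atol = 1e-13)[, 2]

  roots <- polyroot(c(b * Ki, a + b * Kp, 1))
  s1 <- roots[1]; s2 <- roots[2]
  # y(0) = 0, y'(0) = b Kp r (proportional kick)
  c2 <- (b * Kp * r - s1 * (0 - r)) / (s2 - s1)
  c1 <- (0 - r) - c2
  ana <- Re(r + c1 * exp(s1 * tt) + c2 * exp(s2 * tt))
  expect_lt(max(abs(num - ana)), 1e-6)
})

test_that("kLa follows the configured power law of the air flow", {
  cfg <- list(alpha = 40, beta = 0.8, volume = 2277)
  expect_equal(kla_from_airflow(0, cfg), 0)
  expect_equal(kla_from_airflow(100, cfg), 40 * (100 / 2277)^0.8)
  lin <- list(alpha = 3, beta = 1, volume = 10)
  expect_equal(kla_from_airflow(8, lin), 2 * kla_from_airflow(4, lin))
  expect_error(kla_from_airflow(1, list(alpha = -1, beta = 1, volume = 1)),
               "config error")
})

test_that("clean feed produces no biosulfur and minimal aeration", {
  feed <- liquid_stream(220, temperature = 35, solutes = c(sulfide_s = 0))
  r <- simulate_oxidizer(feed, oxidizer_config(), horizon = 600)
  expect_equal(r$biosulfur_kg_h, 0, tolerance = 1e-8)
  # the controller drifts onto the lower air bound with nothing to oxidize
  expect_lt(r$air_demand_m3_h - oxidizer_config()$controller$bounds[1],
            0.1)
})

test_that("DO settles on the set-point and sulfur is conserved", {
  # sulfide levels of the UASB effluent feeding this tank at steady state
  set.seed(7)
  for (i in 1:2) {
    feed <- liquid_stream(220, temperature = 35,
                          solutes = c(sulfide_s = runif(1, 1.0, 1.4),
                                      sulfate_s = runif(1, 0, 0.1),
                                      acetate = runif(1, 0, 0.05)))
    r <- simulate_oxidizer(feed, oxidizer_config())
    expect_true(r$converged)
    expect_false(r$infeasible)
    expect_equal(r$do_mg_l, 0.1, tolerance = 0.01)
    expect_lt(r$audit[["S"]], 1e-6)
  }
})

test_that("low DO favors elemental sulfur, high DO favors sulfate", {
  feed <- liquid_stream(220, temperature = 35,
                        solutes = c(sulfide_s = 1.2))
  split <- vapply(c(0.05, 0.5), function(sp) {
    cfg <- oxidizer_config(controller = pi_controller_config(setpoint = sp))
    r <- simulate_oxidizer(feed, cfg)
    s <- r$effluent$solutes
    s[["sulfate_s"]] / (s[["sulfate_s"]] + s[["s0_s"]])
  }, 0)
  expect_gt(split[2], split[1])
})

test_that("air demand grows with the sulfide load", {
  air <- vapply(c(1.0, 1.4), function(sl) {
    feed <- liquid_stream(220, temperature = 35,
                          solutes = c(sulfide_s = sl))
    simulate_oxidizer(feed, oxidizer_config())$air_demand_m3_h
  }, 0)
  expect_gt(air[2], air[1])
})
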