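test_that("published cost lines sum to the published annual cashflows", {
  ref <- reference_cost_summary()
  g <- function(item, col) ref[match(item, ref$item), col]
  cf <- function(col) {
    annual_cashflow(c(g("operative", col), g("labor", col),
                      g("maintenance", col)))
  }
  expect_identical(cf("BS-PG"), -1992974)
  expect_identical(cf("BS-PCG"), -1560117)
  expect_lte(abs(cf("CS") - (-836348)), 1)

  expect_equal(annual_cashflow(c(0, 0, 0)), 0)
  # permutation invariance and linearity
  x <- c(a = -5, b = 3, c = -1)
  expect_equal(annual_cashflow(x), annual_cashflow(rev(x)))
  expect_equal(annual_cashflow(2 * x), 2 * annual_cashflow(x))
})

test_that("NPV discounts by the book", {
  # i = 0: plain sum plus investment
  s0 <- cashflow_series(-100, rep(-10, 5), lifetime = 5, interest = 0)
  expect_equal(npv(s0), -150)

  # single year at 1.5%
  s1 <- cashflow_series(0, 100, lifetime = 1, interest = 0.015)
  expect_equal(npv(s1), 100 / 1.015, tolerance = 1e-12)

  # constant flows match the annuity closed form
  for (i in c(0.015, 0.05, 0.12)) {
    s <- cashflow_series(0, 250, lifetime = 20, interest = i)
    expect_equal(npv(s), 250 * (1 - (1 + i)^-20) / i, tolerance = 1e-9)
  }
})

test_that("cumulative present value runs up to the NPV", {
  s <- cashflow_series(-1000, c(-50, -60, -40), lifetime = 3,
                       interest = 0.015)
  cpv <- cumulative_present_value(s)
  expect_equal(cpv[1], -1000 - 50 / 1.015)
  expect_equal(cpv[3], npv(s), tolerance = 1e-12)

  # i = 0 gives running plain sums
  s0 <- cashflow_series(-10, c(1, 2, 3), 3, 0)
  expect_equal(cumulative_present_value(s0), c(-9, -7, -4))

  set.seed(5)
  for (k in 1:50) {
    n <- sample(2:25, 1)
    s <- cashflow_series(rnorm(1) * 1e5, rnorm(n) * 1e4, n,
                         runif(1, 0, 0.2))
    cpv <- cumulative_present_value(s)
    expect_equal(cpv[n], npv(s), tolerance = 1e-9)
  }
})

test_that("discounting shrinks uniform-sign flows monotonically", {
  set.seed(9)
  for (k in 1:10) {
    flows <- -abs(rnorm(20)) * 1e5
    m <- vapply(c(0.01, 0.05, 0.1), function(i) {
      abs(npv(cashflow_series(0, flows, 20, i)))
    }, 0)
    expect_true(all(diff(m) < 0))
  }
})

test_that("IRR is undefined for an all-negative treatment line", {
  s <- cashflow_series(-1000, rep(-100, 20))
  expect_true(is.na(irr(s)))
  # a sign-changing series has a root
  s2 <- cashflow_series(-1000, rep(200, 10), lifetime = 10)
  expect_equal(npv(cashflow_series(-1000, rep(200, 10), 10, irr(s2))), 0,
               tolerance = 1e-6)
})

test_that("labor costs build up from wage, hours and tax wedge", {
  roles <- data.frame(count = c(1, 2), wage_eur_h = c(30, 20))
  expect_equal(labor_cost(roles),
               (1 * 30 + 2 * 20) * 37.5 * 52 * 1.35)
})

test_that("price table defaults carry the published unit prices", {
  p <- price_table()
  expect_equal(p$naoh_eur_t, 527)
  expect_equal(p$glycerin_eur_t, 745)
  expect_equal(p$purified_glycerol_eur_t, 520)
  expect_equal(p$sulfur_eur_t, 150)
  expect_equal(p$electricity_eur_kwh, 0.088)
  expect_equal(p$natural_gas_eur_m3, 0.354)
  expect_equal(p$freshwater_eur_m3, 0.06)
  expect_equal(p$wastewater_eur_m3, 7.23)
  expect_error(price_table(bogus = 1), "unknown")
})

test_that("breakeven surface is monotone with the baseline in CS territory", {
  gp <- seq(100, 900, length.out = 9)
  ng <- seq(10, 150, length.out = 8)
  be <- breakeven_grid(gp, ng)
  grid <- be$grid

  # baseline market point: bioscrubber NPV below the chemical scrubber
  i <- which.min(abs(grid$glycerol_price - 520) +
                   abs(grid$gas_price - 68.9))
  expect_lt(grid$npv_bs[i], grid$npv_cs[i])

  # NPV_BS non-decreasing in gas price, non-increasing in glycerol price
  for (g in gp) {
    col <- grid[grid$glycerol_price == g, ]
    expect_true(all(diff(col$npv_bs[order(col$gas_price)]) >= -1e-6))
  }
  for (n in ng) {
    row <- grid[grid$gas_price == n, ]
    expect_true(all(diff(row$npv_bs[order(row$glycerol_price)]) <= 1e-6))
  }

  # the monotone corner (cheap glycerol, dear gas) maximizes the delta
  corner <- grid[grid$glycerol_price == min(gp) &
                   grid$gas_price == max(ng), ]
  expect_equal(corner$delta, max(grid$delta))

  # breakeven points interpolate a sign change of the delta
  if (nrow(be$breakeven)) {
    expect_true(all(be$breakeven$gas_price >= min(ng) &
                      be$breakeven$gas_price <= max(ng)))
  }

  # no sign change on a grid deep in CS territory: empty iso-line
  be0 <- breakeven_grid(seq(800, 900, 50), seq(10, 20, 5))
  expect_equal(nrow(be0$breakeven), 0)
})
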