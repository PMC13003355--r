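# compact pipeline configuration so each sweep cell stays cheap
small_bases <- function() {
  list(
    CS = plant_config("CS"),
    `BS-PCG` = plant_config("BS-PCG", uasb_tanks = 2)
  )
}

small_char_table <- function(zero_transports = FALSE) {
  set.seed(101)
  fx <- generate_fixtures(101, file.path(tempdir(), "sw-fixtures"))
  tab <- read_factor_table(fx[["characterization"]])
  if (zero_transports) tab$factor[tab$line == "transports"] <- 0
  tab
}

test_that("sweep specs validate their axes and parameters", {
  expect_error(sweep_spec(list(name = "bogus", values = 1:2),
                          list(name = "distance_km", values = 1:2)),
               "unknown sweep parameter")
  expect_error(sweep_spec(list(name = "gas_flow", values = c(2, 1)),
                          list(name = "distance_km", values = 1:2)),
               "monotone")
})

test_that("a 1x1 sweep reproduces the direct baseline evaluation", {
  bases <- small_bases()
  tab <- small_char_table()
  spec <- sweep_spec(list(name = "distance_km", values = 50),
                     list(name = "purge_percent", values = 1),
                     kpis = c("GWP", "FET", "operational_cost",
                              "investment_cost"))
  sw <- sweep_2d(spec, bases, tab)
  expect_true(all(sw$cells$ok))

  # direct evaluation of the same pipeline
  direct <- lapply(bases, function(cfg) {
    sim <- simulate_plant(cfg)
    inv <- build_inventory(sim, cfg)
    imp <- characterize(inv, tab)
    list(inv = inv, imp = imp, cfg = cfg)
  })
  gwp <- vapply(direct, function(d) {
    d$imp$impact[d$imp$category == "GWP"]
  }, 0)
  expect_identical(sw$cells$rir[sw$cells$kpi == "GWP"],
                   as.numeric(rir(gwp[["BS-PCG"]], gwp[["CS"]])))
  oc <- vapply(direct, function(d) {
    operational_cost(d$inv, d$cfg$scenario)
  }, 0)
  expect_identical(sw$cells$rir[sw$cells$kpi == "operational_cost"],
                   as.numeric(rir(oc[["BS-PCG"]], oc[["CS"]])))
})

test_that("distance sweeps move the cost RIR monotonically and zero-factor
           categories stay constant", {
  bases <- small_bases()
  tab <- small_char_table(zero_transports = TRUE)
  spec <- sweep_spec(list(name = "distance_km", values = c(10, 50, 150)),
                     list(name = "purge_percent", values = 1),
                     kpis = c("GWP", "operational_cost"))
  sw <- sweep_2d(spec, bases, tab)
  expect_true(all(sw$cells$ok))

  oc <- sw$cells[sw$cells$kpi == "operational_cost", ]
  oc <- oc[order(oc$distance_km), ]
  expect_true(all(diff(oc$rir) < 0) || all(diff(oc$rir) > 0))

  # transports carry no characterization factor here: GWP is insensitive
  gwp <- sw$cells[sw$cells$kpi == "GWP", ]
  expect_lt(diff(range(gwp$rir)), 1e-9)

  # determinism: the same sweep reproduces byte-identical contours
  sw2 <- sweep_2d(spec, bases, tab)
  expect_identical(export_contours(sw), export_contours(sw2))
})

test_that("contour export is long-format with recomputable classes", {
  bases <- small_bases()
  tab <- small_char_table()
  spec <- sweep_spec(list(name = "so2_ppmv", values = c(2000, 3120)),
                     list(name = "distance_km", values = c(25, 50)),
                     kpis = c("GWP", "FET", "HCT", "MET", "FE", "TET",
                              "operational_cost", "investment_cost"))
  sw <- sweep_2d(spec, bases, tab)
  out <- export_contours(sw)
  # 2 x 2 grid, 8 KPIs -> 32 rows
  expect_equal(nrow(out), 32)
  expect_named(out, c("so2_ppmv", "distance_km", "kpi", "rir", "class"))
  expect_identical(out$class, classify_rir(out$rir))

  path <- file.path(tempdir(), "contours.csv")
  export_contours(sw, path)
  expect_true(file.exists(path))
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(back), 32)

  empty <- structure(list(spec = spec, cells = sw$cells[0, ],
                          diagnostics = list()), class = "sweep_result")
  expect_equal(nrow(export_contours(empty)), 0)
})

test_that("cell failures are recorded and the sweep continues", {
  bases <- small_bases()
  tab <- small_char_table()
  # a zero purge makes the loop unsolvable: the cell must fail, not abort
  spec <- sweep_spec(list(name = "purge_percent", values = c(0, 1)),
                     list(name = "distance_km", values = 50),
                     kpis = c("GWP"))
  sw <- sweep_2d(spec, bases, tab)
  expect_true(any(!sw$cells$ok))
  expect_true(any(sw$cells$ok))
  expect_gte(length(sw$diagnostics), 1)
})
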