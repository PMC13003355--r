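#' Life-cycle costing: cashflows, NPV, cumulative present value, breakeven
#'
#' The cost layer combines unit prices with inventory quantities (or with
#' user-supplied cost lines where a published cost basis differs from
#' quantity x price), sums signed annual cost lines into a cashflow,
#' discounts it over the plant lifetime (20 yr at 1.5%), and maps the
#' glycerol-price x gas-price plane for the breakeven between the chemical
#' scrubber and the purified-crude-glycerol bioscrubber. For a gas
#' treatment line (no product revenue) cashflow and NPV are negative and
#' the IRR is undefined; the cumulative present value is the discount-rate
#' sensitivity tool instead.
#'
#' @name lcc
NULL

#' Unit price table (2021 European market)
#'
#' Defaults: NaOH 527 EUR/t, pure glycerin 745 EUR/t, purified glycerol
#' 520 EUR/t, sulfur 150 EUR/t, electricity 0.088 EUR/kWh, natural gas
#' 0.354 EUR/m3, freshwater 0.06 EUR/m3, wastewater 7.23 EUR/m3; labor at
#' a 37.5 h week with a 35% tax wedge; maintenance as 2/5/10% of
#' investment by component class. The natural-gas conversion between
#' EUR/m3 and EUR/MWh uses a configurable heating value.
#'
#' @param ... Overrides of the default entries.
#' @return Object of class `price_table` (named list).
#' @export
price_table <- function(...) {
  p <- list(
    naoh_eur_t = 527,
    glycerin_eur_t = 745,
    purified_glycerol_eur_t = 520,
    sulfur_eur_t = 150,
    electricity_eur_kwh = 0.088,
    natural_gas_eur_m3 = 0.354,
    freshwater_eur_m3 = 0.06,
    wastewater_eur_m3 = 7.23,   # disposal incl. transport at the
    wastewater_reference_km = 50, # reference distance to the sea

    labor_hours_week = 37.5,
    labor_tax_wedge = 0.35,
    maintenance_fraction = c(scrubber = 0.02, reactors = 0.05,
                             other = 0.10),
    gas_heating_value_kwh_m3 = 9.97,
    biogas_heating_value_kwh_m3 = 6.0
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown price entries: ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (any(unlist(p[!vapply(p, is.character, TRUE)]) < 0)) {
    stop("prices must be >= 0")
  }
  structure(p, class = "price_table")
}

#' Natural-gas price in EUR/MWh
#'
#' @param prices A [price_table].
#' @return EUR/MWh implied by the volumetric price and heating value.
#' @export
gas_price_eur_mwh <- function(prices) {
  prices$natural_gas_eur_m3 / prices$gas_heating_value_kwh_m3 * 1000
}

#' Annual labor cost of a staffing plan
#'
#' cost = sum over roles of count x wage x hours/week x 52 x (1 + tax
#' wedge).
#'
#' @param roles Data frame with `count` and `wage_eur_h`.
#' @param prices A [price_table].
#' @return EUR/yr (positive magnitude).
#' @export
labor_cost <- function(roles, prices = price_table()) {
  sum(roles$count * roles$wage_eur_h * prices$labor_hours_week * 52 *
        (1 + prices$labor_tax_wedge))
}

#' Published cost summary of the three scenarios
#'
#' The printed summary table of the source plant study (EUR, negative =
#' cost): investment, operative costs and revenues (net of byproducts),
#' byproduct earnings, labor and maintenance, per scenario. These printed
#' lines are the inputs for the cashflow arithmetic and the breakeven
#' analysis; the package's own model-derived costs are available via
#' [cost_lines_from_inventory()].
#'
#' @return Data frame with one row per cost item and one column per
#'   scenario.
#' @export
reference_cost_summary <- function() {
  data.frame(
    item = c("investment", "operative", "byproduct_earnings", "labor",
             "maintenance"),
    CS = c(-51672, -827067, 0, -6395, -2885),
    `BS-PG` = c(-3191321, -1832802, 335701, -28473, -131699),
    `BS-PCG` = c(-3191322, -1399945, 335701, -28473, -131699),
    check.names = FALSE
  )
}

#' Model-derived annual cost lines from an inventory
#'
#' Quantity x unit price for every priced inventory line (costs negative,
#' byproduct revenues positive).
#'
#' @param inventory An `inventory_table`.
#' @param prices A [price_table].
#' @return Named vector of signed EUR/yr lines.
#' @export
cost_lines_from_inventory <- function(inventory, prices = price_table()) {
  v <- function(line) inventory_value(inventory, line)
  elec <- inventory_value(inventory, "power_transformation")
  c(
    naoh = -v("naoh") * prices$naoh_eur_t,
    glycerine = -v("glycerine") * prices$glycerin_eur_t,
    purified_glycerol = -v("purified_glycerol") *
      prices$purified_glycerol_eur_t,
    electricity = -elec * prices$electricity_eur_kwh,
    freshwater = -v("total_freshwater") * prices$freshwater_eur_m3,
    # volumetric disposal price refers to the reference distance, so the
    # line scales with the transport burden (t km)
    wastewater = -v("transports") * prices$wastewater_eur_m3 /
      prices$wastewater_reference_km,
    sulfur = -v("sulfur") * prices$sulfur_eur_t, # line is negative
    biogas = -v("biogas") * prices$biogas_heating_value_kwh_m3 / 1000 *
      gas_price_eur_mwh(prices)
  )
}

#' Annual net cashflow from signed cost lines
#'
#' @param cost_lines Named numeric vector or list of signed EUR/yr lines
#'   (costs negative, revenues positive).
#' @return Signed sum (EUR/yr).
#' @export
annual_cashflow <- function(cost_lines) {
  sum(unlist(cost_lines))
}

#' Cashflow series of an investment
#'
#' @param investment Year-0 outflow (signed EUR, typically negative).
#' @param annual Annual net cashflow (scalar recycled over `lifetime`, or
#'   vector of length `lifetime`).
#' @param lifetime N years (>= 1).
#' @param interest Interest rate i (fraction, > -1).
#' @return Object of class `cashflow_series`.
#' @export
cashflow_series <- function(investment, annual, lifetime = 20,
                            interest = 0.015) {
  stopifnot(lifetime >= 1, interest > -1)
  if (length(annual) == 1) annual <- rep(annual, lifetime)
  stopifnot(length(annual) == lifetime)
  structure(
    list(investment = investment, annual = annual,
         lifetime = as.integer(lifetime), interest = interest),
    class = "cashflow_series"
  )
}

#' Net present value
#'
#' NPV = investment + sum_{t=1..N} R_t / (1+i)^t, the investment entering
#' undiscounted at year 0.
#'
#' @param series A [cashflow_series].
#' @return NPV (EUR).
#' @export
npv <- function(series) {
  t <- seq_len(series$lifetime)
  series$investment + sum(series$annual / (1 + series$interest)^t)
}

#' Cumulative present value by year
#'
#' Running sum of the discounted flows; element N equals [npv()].
#'
#' @param series A [cashflow_series].
#' @return Numeric vector of length N (year 1..N), each element the
#'   investment plus the discounted flows up to that year.
#' @export
cumulative_present_value <- function(series) {
  t <- seq_len(series$lifetime)
  series$investment + cumsum(series$annual / (1 + series$interest)^t)
}

#' Internal rate of return (reported, not solved, for all-negative flows)
#'
#' For a gas-treatment line with uniformly negative flows the NPV has no
#' root and the IRR is undefined; `NA` is returned in that case.
#'
#' @param series A [cashflow_series].
#' @return IRR as a fraction, or `NA` when undefined.
#' @export
irr <- function(series) {
  flows <- c(series$investment, series$annual)
  if (all(flows <= 0) || all(flows >= 0)) return(NA_real_)
  f <- function(i) {
    series$interest <- i
    npv(series)
  }
  tryCatch(stats::uniroot(f, c(-0.99, 10), tol = 1e-12)$root,
           error = function(e) NA_real_)
}

#' NPV surface over glycerol and natural-gas prices, with breakeven line
#'
#' Recomputes the bioscrubber-PCG NPV on every grid cell: the carbon-source
#' cost line scales linearly with the glycerol price and the biogas revenue
#' line with the gas price (both through their baseline values), while the
#' chemical-scrubber NPV is price-independent on these axes. The breakeven
#' iso-line NPV_BS = NPV_CS is extracted by linear interpolation between
#' sign changes along each glycerol-price column.
#'
#' @param glycerol_price Axis (EUR/t), monotone.
#' @param gas_price Axis (EUR/MWh), monotone.
#' @param cost_summary Baseline cost table (default
#'   [reference_cost_summary()]).
#' @param prices A [price_table] carrying the baseline prices the cost
#'   lines were computed at.
#' @param sulfur_t_yr Annual sulfur byproduct (t/yr, positive); its revenue
#'   (quantity x sulfur price) is gas-price-independent, the remainder of
#'   the byproduct earnings is biogas revenue and scales with the gas
#'   price.
#' @param carbon_cost_eur_yr Baseline carbon-source cost line (signed,
#'   EUR/yr) that scales with the glycerol price.
#' @param baseline_gas_eur_mwh Market gas price the baseline byproduct
#'   earnings refer to (EUR/MWh).
#' @param lifetime,interest Discounting parameters.
#' @return List with `grid` (long data.frame: glycerol_price, gas_price,
#'   npv_bs, npv_cs, delta) and `breakeven` (data.frame of iso-line
#'   points; empty when no sign change).
#' @export
breakeven_grid <- function(glycerol_price, gas_price,
                           cost_summary = reference_cost_summary(),
                           prices = price_table(),
                           sulfur_t_yr = 356.92,
                           carbon_cost_eur_yr = -1198862,
                           baseline_gas_eur_mwh = 68.9,
                           lifetime = 20, interest = 0.015) {
  stopifnot(all(diff(glycerol_price) > 0), all(diff(gas_price) > 0))
  g <- function(item, col) {
    cost_summary[match(item, cost_summary$item), col]
  }
  cs_cf <- g("operative", "CS") + g("labor", "CS") + g("maintenance", "CS")
  npv_cs <- npv(cashflow_series(g("investment", "CS"), cs_cf, lifetime,
                                interest))

  # decompose the baseline PCG cashflow into price-scalable pieces:
  # operative is net of byproducts; sulfur revenue is fixed on these axes,
  # the rest of the byproduct earnings is biogas revenue
  base_glyc_price <- prices$purified_glycerol_eur_t
  sulfur_rev <- sulfur_t_yr * prices$sulfur_eur_t
  biogas_rev <- g("byproduct_earnings", "BS-PCG") - sulfur_rev
  operative_ex_rev <- g("operative", "BS-PCG") -
    g("byproduct_earnings", "BS-PCG")
  fixed_costs <- operative_ex_rev - carbon_cost_eur_yr +
    g("labor", "BS-PCG") + g("maintenance", "BS-PCG")
  inv_bs <- g("investment", "BS-PCG")

  grid <- expand.grid(glycerol_price = glycerol_price,
                      gas_price = gas_price)
  cf_bs <- fixed_costs +
    carbon_cost_eur_yr * grid$glycerol_price / base_glyc_price +
    sulfur_rev +
    biogas_rev * grid$gas_price / baseline_gas_eur_mwh
  grid$npv_bs <- vapply(cf_bs, function(cf) {
    npv(cashflow_series(inv_bs, cf, lifetime, interest))
  }, 0)
  grid$npv_cs <- npv_cs
  grid$delta <- grid$npv_bs - grid$npv_cs

  iso <- NULL
  for (gp in glycerol_price) {
    col <- grid[grid$glycerol_price == gp, ]
    s <- sign(col$delta)
    ix <- which(s[-1] * s[-length(s)] < 0)
    for (i in ix) {
      x1 <- col$gas_price[i]
      x2 <- col$gas_price[i + 1]
      d1 <- col$delta[i]
      d2 <- col$delta[i + 1]
      iso <- rbind(iso, data.frame(
        glycerol_price = gp,
        gas_price = x1 - d1 * (x2 - x1) / (d2 - d1)
      ))
    }
  }
  list(grid = grid,
       breakeven = if (is.null(iso)) {
         data.frame(glycerol_price = numeric(0), gas_price = numeric(0))
       } else iso)
}
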