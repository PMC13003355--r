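#' Two-dimensional sensitivity sweeps over plant parameters
#'
#' Re-runs the full pipeline (simulate -> inventory -> characterization /
#' costing -> RIR) over a grid of two operating parameters (gas flow x
#' inlet SO2, or purge fraction x disposal distance) for a scenario pair,
#' producing per-KPI RIR grids for contour plotting. Reactor volumes and
#' the recirculation loop scale with the treated gas flow (constant
#' retention times), and the bioreactor investment scales with the reactor
#' volumes.
#'
#' @name sweeps
NULL

.SWEEP_PARAMS <- c("gas_flow", "so2_ppmv", "purge_percent", "distance_km")

#' Sweep specification
#'
#' @param axis1,axis2 Lists with `name` (a [plant_config] parameter:
#'   gas_flow, so2_ppmv, purge_percent or distance_km) and `values`
#'   (monotone numeric grid, length >= 1).
#' @param kpis KPI names: impact-category codes plus
#'   `"operational_cost"` and/or `"investment_cost"`.
#' @param scenario_pair Character pair, reference scenario first.
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(axis1, axis2,
                       kpis = c("HCT", "FET", "MET", "FE", "TET", "GWP",
                                "operational_cost", "investment_cost"),
                       scenario_pair = c("CS", "BS-PCG")) {
  for (ax in list(axis1, axis2)) {
    if (!ax$name %in% .SWEEP_PARAMS) {
      stop("unknown sweep parameter '", ax$name, "'; must be one of: ",
           paste(.SWEEP_PARAMS, collapse = ", "))
    }
    if (length(ax$values) < 1 ||
        (length(ax$values) > 1 && any(diff(ax$values) <= 0))) {
      stop("axis values must be a monotone increasing grid")
    }
  }
  structure(list(axis1 = axis1, axis2 = axis2, kpis = kpis,
                 scenario_pair = scenario_pair),
            class = "sweep_spec")
}

# apply axis overrides to a plant config, scaling unit sizes with gas flow
.apply_overrides <- function(cfg, overrides) {
  bad <- setdiff(names(overrides), .SWEEP_PARAMS)
  if (length(bad)) {
    stop("parameter(s) not in plant config: ", paste(bad, collapse = ", "))
  }
  base_gas <- cfg$gas_flow
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  if (!is.null(overrides$gas_flow)) {
    ratio <- cfg$gas_flow / base_gas
    cfg$uasb_volume <- cfg$uasb_volume * ratio
    cfg$oxidizer$volume <- cfg$oxidizer$volume * ratio
    cfg$absorber$liquid_holdup <- cfg$absorber$liquid_holdup * ratio
  }
  cfg
}

#' Investment cost of a scenario configuration
#'
#' The chemical scrubber investment is size-insensitive at this scale; the
#' bioreactor-dominated bioscrubber investment scales linearly with the
#' reactor volumes around the baseline, with a fixed share for controls
#' and auxiliaries.
#'
#' @param cfg A [plant_config].
#' @param base_investment Named baseline magnitudes (EUR).
#' @param fixed_share Size-independent share of the bioscrubber
#'   investment.
#' @return Positive investment magnitude (EUR).
#' @export
investment_cost <- function(cfg,
                            base_investment = c(CS = 51672,
                                                BS = 3191322),
                            fixed_share = 0.12) {
  if (cfg$scenario == "CS") return(base_investment[["CS"]])
  vol_ratio <- (cfg$uasb_volume + cfg$oxidizer$volume) / (1000.3 + 2277)
  base_investment[["BS"]] * (fixed_share + (1 - fixed_share) * vol_ratio)
}

#' Annual operational cost magnitude of a simulated scenario
#'
#' Model-derived operative lines (resources, electricity, disposal, net of
#' byproduct revenues) plus the scenario's published labor and maintenance
#' lines.
#'
#' @param inventory An `inventory_table`.
#' @param scenario Scenario tag.
#' @param prices A [price_table].
#' @return Positive cost magnitude (EUR/yr).
#' @export
operational_cost <- function(inventory, scenario,
                             prices = price_table()) {
  ref <- reference_cost_summary()
  col <- if (scenario == "CS") "CS" else scenario
  fixed <- ref[match(c("labor", "maintenance"), ref$item), col]
  -(annual_cashflow(cost_lines_from_inventory(inventory, prices)) +
      sum(fixed))
}

#' Run a 2-D sensitivity sweep
#'
#' Every cell is a full pipeline run for both scenarios of the pair; cell
#' failures are recorded (`ok = FALSE`, message in `diagnostics`) and the
#' sweep continues. Scenario loop solutions are warm-started from the
#' previous cell, which leaves the results unchanged (the loop solves a
#' fixed point) but shortens the solve.
#'
#' @param spec A [sweep_spec].
#' @param base Named list of baseline [plant_config]s, one per scenario of
#'   the pair.
#' @param char_table A [characterization_table()].
#' @param prices A [price_table].
#' @return Object of class `sweep_result`: long data.frame `cells` with
#'   one row per (cell, KPI) and a `diagnostics` list.
#' @export
sweep_2d <- function(spec, base, char_table, prices = price_table()) {
  stopifnot(inherits(spec, "sweep_spec"))
  pair <- spec$scenario_pair
  if (!all(pair %in% names(base))) {
    stop("base configs must be named by scenario: ",
         paste(pair, collapse = ", "))
  }
  cat_kpis <- setdiff(spec$kpis, c("operational_cost", "investment_cost"))
  grid <- expand.grid(v1 = spec$axis1$values, v2 = spec$axis2$values)
  warm <- list()
  cells <- NULL
  diagnostics <- list()
  for (i in seq_len(nrow(grid))) {
    overrides <- stats::setNames(list(grid$v1[i], grid$v2[i]),
                                 c(spec$axis1$name, spec$axis2$name))
    res <- tryCatch({
      vals <- lapply(pair, function(scn) {
        cfg <- .apply_overrides(base[[scn]], overrides)
        sim <- simulate_plant(cfg, tear0 = warm[[scn]])
        warm[[scn]] <<- sim$tear
        inv <- build_inventory(sim, cfg)
        imp <- characterize(inv, char_table)
        kv <- stats::setNames(
          imp$impact[match(cat_kpis, imp$category)], cat_kpis)
        if ("operational_cost" %in% spec$kpis) {
          kv[["operational_cost"]] <- operational_cost(inv, scn, prices)
        }
        if ("investment_cost" %in% spec$kpis) {
          kv[["investment_cost"]] <- investment_cost(cfg)
        }
        kv
      })
      names(vals) <- pair
      vals
    }, error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics[[length(diagnostics) + 1L]] <- list(
        cell = i, v1 = grid$v1[i], v2 = grid$v2[i],
        message = conditionMessage(res)
      )
      cells <- rbind(cells, data.frame(
        v1 = grid$v1[i], v2 = grid$v2[i], kpi = spec$kpis,
        value_ref = NA_real_, value_alt = NA_real_, rir = NA_real_,
        ok = FALSE
      ))
    } else {
      rr <- vapply(spec$kpis, function(k) {
        as.numeric(rir(res[[pair[2]]][[k]], res[[pair[1]]][[k]]))
      }, 0)
      cells <- rbind(cells, data.frame(
        v1 = grid$v1[i], v2 = grid$v2[i], kpi = spec$kpis,
        value_ref = unlist(res[[pair[1]]][spec$kpis]),
        value_alt = unlist(res[[pair[2]]][spec$kpis]),
        rir = rr, ok = TRUE
      ))
    }
  }
  names(cells)[1:2] <- c(spec$axis1$name, spec$axis2$name)
  rownames(cells) <- NULL
  structure(list(spec = spec, cells = cells, diagnostics = diagnostics),
            class = "sweep_result")
}

#' Export a sweep as long-format contour data
#'
#' @param result A `sweep_result`.
#' @param path Optional CSV path; a one-line unit/provenance header is
#'   prepended as a comment.
#' @return Long data.frame (param1, param2, kpi, rir, class), classes from
#'   [classify_rir()].
#' @export
export_contours <- function(result, path = NULL) {
  stopifnot(inherits(result, "sweep_result"))
  cells <- result$cells
  if (is.null(cells) || !nrow(cells)) {
    return(data.frame(kpi = character(0), rir = numeric(0),
                      class = character(0)))
  }
  out <- cells[cells$ok & !is.na(cells$rir), , drop = FALSE]
  if (nrow(out)) {
    out$class <- classify_rir(out$rir)
  } else {
    out$class <- character(0)
  }
  keep <- c(names(out)[1:2], "kpi", "rir", "class")
  out <- out[keep]
  rownames(out) <- NULL
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(sprintf("# RIR contour data: %s x %s (dimensionless)",
                       names(out)[1], names(out)[2]), con)
    utils::write.csv(out, con, row.names = FALSE)
    close(con)
  }
  out
}
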