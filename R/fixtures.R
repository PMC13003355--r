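#' Scenario files, deterministic fixtures and the end-to-end pipeline
#'
#' Assessment-layer inputs (characterization and normalization factors,
#' unit prices) are user-supplied data; this module generates deterministic
#' synthetic stand-ins keyed to the inventory line names so every layer is
#' testable without licensed databases or downloads, and provides the
#' one-scenario-one-file YAML convention plus the end-to-end
#' [run_pipeline()] driver.
#'
#' @name cli_fixtures
NULL

.LINE_COMPONENT <- c(
  naoh = "Resources", glycerine = "Resources",
  purified_glycerol = "Resources", total_freshwater = "Resources",
  recirculation_pump = "Energy", caustic_pump = "Energy",
  discharge_pump = "Energy", freshwater_pump = "Energy",
  carbon_source_pump = "Energy", centrifuge_feed_pump = "Energy",
  dryer_inlet_pump = "Energy", dryer_blower = "Energy",
  aeration_blower = "Energy", reactors_heating_pump = "Energy",
  centrifuge = "Energy", power_transformation = "Energy",
  wastewater = "End of life", transports = "End of life",
  co2_cstr = "Air emissions", so2_cstr = "Air emissions",
  co2_flashlight = "Air emissions",
  biogas = "Byproducts", sulfur = "Byproducts"
)

#' Generate the deterministic synthetic fixture set
#'
#' Writes, under `dir`: `characterization.csv` (18 categories x the
#' characterized inventory lines, positive log-normal factors; synthetic
#' stand-ins for licensed database values), `normalization.csv` (positive
#' per-category person-equivalent factors), `prices.csv` (the published
#' 2021 unit prices), a balanced stoichiometric model
#' (`stoich_matrix.csv` / `stoich_kinetics.csv`) and one scenario YAML per
#' scenario. Identical seeds yield byte-identical files.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
generate_fixtures <- function(seed, dir) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(as.integer(seed))
  lines <- names(.LINE_COMPONENT)
  cats <- impact_categories()

  ct <- expand.grid(category = cats, line = lines,
                    stringsAsFactors = FALSE)
  ct$factor <- round(exp(stats::rnorm(nrow(ct), mean = -1, sd = 1.2)), 6)
  # byproduct lines carry the same positive factors; their negative
  # inventory amounts turn them into avoided impacts
  ct$component <- .LINE_COMPONENT[ct$line]
  ct <- ct[order(ct$category, ct$line), ]
  rownames(ct) <- NULL

  nt <- data.frame(category = cats,
                   factor = round(exp(stats::rnorm(length(cats), 9, 0.8)),
                                  3))

  pt <- price_table()
  scalar <- !vapply(pt, function(x) length(x) > 1, TRUE)
  pr <- data.frame(name = names(pt)[scalar],
                   value = unlist(pt[scalar], use.names = FALSE))

  model <- default_uasb_model()
  sm <- data.frame(reaction = rownames(model$stoich),
                   round(model$stoich, 8), check.names = FALSE)

  paths <- c(
    characterization = file.path(dir, "characterization.csv"),
    normalization = file.path(dir, "normalization.csv"),
    prices = file.path(dir, "prices.csv"),
    stoich_matrix = file.path(dir, "stoich_matrix.csv"),
    stoich_kinetics = file.path(dir, "stoich_kinetics.csv")
  )
  hdr <- sprintf("# synthetic fixture (seed %d)", as.integer(seed))
  wr <- function(df, path, unit_note) {
    con <- file(path, "w")
    writeLines(c(hdr, paste0("# ", unit_note)), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(ct, paths[["characterization"]],
     "factor: impact unit per inventory unit")
  wr(nt, paths[["normalization"]],
     "factor: impact unit per person-equivalent")
  wr(pr, paths[["prices"]], "value: EUR per unit named in the entry")
  wr(sm, paths[["stoich_matrix"]],
     "coefficients: g per g biomass COD grown (organics g COD, S species g S, ic g C)")
  wr(model$kinetics, paths[["stoich_kinetics"]],
     "mu_max 1/d; Ks, Ki_sulfide, Ks_acceptor g/L")

  for (scn in c("CS", "BS-PG", "BS-PCG")) {
    p <- file.path(dir, paste0("scenario_", gsub("-", "_", scn), ".yaml"))
    yaml::write_yaml(list(
      scenario = scn, seed = as.integer(seed),
      gas_flow = 32000, so2_ppmv = 3120, co2_ppmv = 3200,
      gl_ratio = 145.5, purge_percent = 1, distance_km = 50,
      tables = list(characterization = "characterization.csv",
                    normalization = "normalization.csv",
                    prices = "prices.csv")
    ), p)
    paths[paste0("scenario_", scn)] <- p
  }
  invisible(paths)
}

#' Read a characterization or normalization CSV written by the fixture
#' generator (comment lines allowed)
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_factor_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and validate a scenario file
#'
#' @param path YAML scenario path.
#' @return Validated scenario list; table paths resolved relative to the
#'   scenario file.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  required <- c("scenario", "seed", "gas_flow", "so2_ppmv", "co2_ppmv",
                "purge_percent", "distance_km", "tables")
  miss <- setdiff(required, names(sc))
  if (length(miss)) {
    stop("invalid scenario file: missing field(s) ",
         paste(miss, collapse = ", "))
  }
  if (!sc$scenario %in% c("CS", "BS-PG", "BS-PCG")) {
    stop("invalid scenario file: unknown scenario tag '", sc$scenario, "'")
  }
  for (tb in c("characterization", "normalization", "prices")) {
    if (is.null(sc$tables[[tb]])) {
      stop("invalid scenario file: tables$", tb, " missing")
    }
    full <- file.path(dirname(path), sc$tables[[tb]])
    if (!file.exists(full)) {
      stop("invalid scenario file: referenced table not found: ", full)
    }
    sc$tables[[tb]] <- full
  }
  sc
}

#' Build a plant configuration from a scenario list
#'
#' @param scenario A list from [read_scenario()] (or equivalent).
#' @param ... Overrides forwarded to [plant_config()] (e.g. reduced tank
#'   counts for quick runs).
#' @return A [plant_config].
#' @export
scenario_config <- function(scenario, ...) {
  plant_config(
    scenario = scenario$scenario,
    gas_flow = scenario$gas_flow, so2_ppmv = scenario$so2_ppmv,
    co2_ppmv = scenario$co2_ppmv,
    gl_ratio = scenario$gl_ratio %||% 145.5,
    purge_percent = scenario$purge_percent,
    distance_km = scenario$distance_km,
    ...
  )
}

#' Run the full assessment pipeline for one scenario
#'
#' simulate -> inventory -> characterization -> normalization -> costing.
#' Stage failures are re-raised with the failing stage named. All output
#' tables carry the scenario seed in their provenance header when written.
#'
#' @param scenario Path to a scenario YAML, or a list from
#'   [read_scenario()].
#' @param out_dir Optional directory for CSV exports.
#' @param ... Config overrides forwarded to [scenario_config()].
#' @return List with `config`, `plant`, `inventory`, `impacts`,
#'   `normalized`, `cost_lines`, `cashflow`, `npv` and `seed`.
#' @export
run_pipeline <- function(scenario, out_dir = NULL, ...) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cfg <- stage("configure", scenario_config(scenario, ...))
  sim <- stage("simulate", simulate_plant(cfg))
  inv <- stage("inventory", build_inventory(sim, cfg))
  ctab <- stage("characterization",
                characterization_table(
                  read_factor_table(scenario$tables$characterization)))
  imp <- stage("characterization", characterize(inv, ctab))
  nt <- stage("normalization",
              read_factor_table(scenario$tables$normalization))
  norm <- stage("normalization", normalize_and_select(imp, nt))
  prices <- price_table()
  cl <- stage("costing", cost_lines_from_inventory(inv, prices))
  ref <- reference_cost_summary()
  fixed <- ref[match(c("labor", "maintenance"), ref$item), cfg$scenario]
  cf <- annual_cashflow(c(cl, fixed))
  series <- cashflow_series(ref[ref$item == "investment", cfg$scenario],
                            cf)
  bundle <- list(
    config = cfg, plant = sim, inventory = inv, impacts = imp,
    normalized = norm, cost_lines = cl, cashflow = cf,
    npv = npv(series), seed = scenario$seed
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    hdr <- sprintf("# scenario %s (seed %d)", cfg$scenario,
                   as.integer(scenario$seed))
    wcsv <- function(df, name, note) {
      p <- file.path(out_dir, name)
      con <- file(p, "w")
      writeLines(c(hdr, paste0("# ", note)), con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    wcsv(inv, "inventory.csv", "value: unit named per line")
    wcsv(as.data.frame(imp), "impacts.csv", "impact: category unit per yr")
    wcsv(norm$pe, "normalized.csv", "pe: person-equivalents")
    wcsv(data.frame(line = names(cl), eur_yr = as.numeric(cl)),
         "cost_lines.csv", "eur_yr: signed EUR per year")
  }
  bundle
}
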