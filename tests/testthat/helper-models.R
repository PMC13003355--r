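# Shared fixtures built in code, plus memoized expensive runs.

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# single Monod reaction with a COD-closing product: the chemostat toy
toy_chemostat_model <- function(mu_max = 2, Ks = 0.05, Y = 0.2) {
  stoichiometric_model(
    species = c("s", "x", "p"),
    stoich = matrix(c(-1 / Y, 1, 1 / Y - 1), 1, 3),
    kinetics = data.frame(reaction = "growth", group = "x",
                          substrate = "s", mu_max = mu_max, Ks = Ks),
    cod_content = c(s = 1, x = 1, p = 1),
    s_content = c()
  )
}

baseline_gas <- function() {
  gas_stream(32000, c(SO2 = 3120, CO2 = 3200))
}

# pH-controlled scrubber liquor resembling the bioscrubber return stream
baseline_liquor <- function(flow = 220) {
  tot <- ionic_totals(c(carbonate = 2e-3, sulfide = 1e-3, sulfurous = 0),
                      strong_cations = 1e-2)
  liquid_stream(flow, tot)
}

# default bioscrubber run, shared across tests (loop converged, uncalibrated)
baseline_bs_result <- function() {
  cached("bs_result", {
    cfg <- plant_config("BS-PCG")
    list(cfg = cfg, res = simulate_plant(cfg))
  })
}

baseline_cs_result <- function() {
  cached("cs_result", {
    cfg <- plant_config("CS")
    list(cfg = cfg, res = simulate_plant(cfg))
  })
}
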