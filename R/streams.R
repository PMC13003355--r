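#' Process streams
#'
#' Composition-carrying gas and liquid streams exchanged between plant
#' stages. Gas compositions are ppmv of trace species in a carrier
#' (combustion gas); liquid streams carry an [ionic_totals] composition plus
#' any stage-specific solutes.
#'
#' @name streams
NULL

# molar volume of an ideal gas at 25 degC, 1 atm (m^3/mol); ppmv <-> molar
# conversions are done on this fixed basis throughout the plant model
MOLAR_VOLUME_M3 <- 0.02445

#' Gas stream
#'
#' @param volumetric_flow Flow (m^3/h at 25 degC, 1 atm basis).
#' @param composition Named ppmv vector of trace species (e.g.
#'   `c(SO2 = 3120, CO2 = 3200)`).
#' @param temperature degC (informational; conversions use the 25 degC basis).
#' @param pressure atm.
#' @return Object of class `gas_stream`.
#' @export
gas_stream <- function(volumetric_flow, composition, temperature = 25,
                       pressure = 1) {
  stopifnot(volumetric_flow >= 0, all(composition >= 0),
            sum(composition) < 1e6)
  structure(
    list(
      volumetric_flow = volumetric_flow,
      composition = composition,
      temperature = temperature,
      pressure = pressure
    ),
    class = "gas_stream"
  )
}

#' @export
print.gas_stream <- function(x, ...) {
  cat(sprintf("<gas_stream> %.1f m3/h @ %.0f degC, %.2f atm\n",
              x$volumetric_flow, x$temperature, x$pressure))
  for (nm in names(x$composition)) {
    cat(sprintf("  %-6s %10.1f ppmv\n", nm, x$composition[[nm]]))
  }
  invisible(x)
}

#' Molar flow of one gas species (mol/h)
#'
#' @param gas A [gas_stream].
#' @param species Species name in the composition.
#' @export
gas_molar_flow <- function(gas, species) {
  gas$volumetric_flow * gas$composition[[species]] * 1e-6 / MOLAR_VOLUME_M3
}

#' Total molar flow of the gas stream (mol/h)
#' @param gas A [gas_stream].
#' @export
gas_total_molar_flow <- function(gas) {
  gas$volumetric_flow / MOLAR_VOLUME_M3
}

#' Liquid stream
#'
#' @param volumetric_flow Flow (m^3/h).
#' @param totals An [ionic_totals] composition (mol/L).
#' @param temperature degC.
#' @param solutes Named numeric vector of additional solutes (g/L), e.g.
#'   biological species not in the acid-base description.
#' @return Object of class `liquid_stream`.
#' @export
liquid_stream <- function(volumetric_flow, totals = ionic_totals(),
                          temperature = 25, solutes = numeric(0)) {
  stopifnot(volumetric_flow >= 0)
  structure(
    list(
      volumetric_flow = volumetric_flow,
      totals = totals,
      temperature = temperature,
      solutes = solutes
    ),
    class = "liquid_stream"
  )
}

#' @export
print.liquid_stream <- function(x, ...) {
  cat(sprintf("<liquid_stream> %.2f m3/h @ %.0f degC\n",
              x$volumetric_flow, x$temperature))
  print(x$totals)
  if (length(x$solutes)) {
    cat("  solutes (g/L):",
        paste(sprintf("%s=%.3g", names(x$solutes), x$solutes),
              collapse = ", "), "\n")
  }
  invisible(x)
}
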