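#' Acid-base systems and pH charge-balance speciation
#'
#' The liquid phases of every stage (scrubber liquor, UASB broth, oxidation
#' tank) are buffered mixtures of weak polyprotic acid systems (inorganic
#' carbon, sulfurous acid from absorbed SO2, sulfide) plus strong ions
#' (Na+ from caustic dosing, Cl-/SO4^2- counted as fully dissociated).
#' Speciation matters twice: only the neutral, fully protonated species
#' exchanges with the gas phase, and the strong-ion dose needed to hold a pH
#' set-point is what drives the plant's NaOH/HCl demand.
#'
#' Concentrations are treated as activities (no ionic-strength correction)
#' and all constants are 25 degC values; temperature is not a state variable
#' of the plant model.
#'
#' @name chemistry
NULL

#' Define a polyprotic acid system
#'
#' @param name Character tag, e.g. `"carbonate"`.
#' @param pKa Numeric vector of acid dissociation exponents, strictly
#'   increasing (dimensionless, 25 degC).
#' @param charge0 Integer charge of the fully protonated species (0 for
#'   H2CO3*, H2S, H2SO3).
#' @return An object of class `acid_system`.
#' @examples
#' carb <- acid_system("carbonate", c(6.35, 10.33))
#' @export
acid_system <- function(name, pKa, charge0 = 0L) {
  stopifnot(is.character(name), length(name) == 1L)
  pKa <- as.numeric(pKa)
  if (length(pKa) < 1L || anyNA(pKa)) {
    stop("pKa must be a non-empty numeric vector")
  }
  if (length(pKa) > 1L && any(diff(pKa) <= 0)) {
    stop("pKa values must be strictly increasing")
  }
  structure(
    list(name = name, pKa = pKa, charge0 = as.integer(charge0)),
    class = "acid_system"
  )
}

#' @export
print.acid_system <- function(x, ...) {
  cat(sprintf(
    "<acid_system> %s: pKa = %s, charge of H(n)A = %+d\n",
    x$name, paste(format(x$pKa), collapse = ", "), x$charge0
  ))
  invisible(x)
}

#' Default acid systems of the scrubbing liquor
#'
#' Inorganic carbon (pKa 6.35, 10.33), sulfide (pKa1 7.05; the second
#' ionization is negligible at process pH and is omitted) and sulfurous acid
#' (pKa 1.85, 7.2). Sulfate is handled as a fully dissociated strong anion,
#' not as an acid system.
#'
#' @return Named list of [acid_system] objects.
#' @export
default_acid_systems <- function() {
  list(
    carbonate = acid_system("carbonate", c(6.35, 10.33)),
    sulfide   = acid_system("sulfide", 7.05),
    sulfurous = acid_system("sulfurous", c(1.85, 7.2))
  )
}

#' Read acid-system constants from a config table
#'
#' Accepts a CSV (columns `name`, `pKa` as a semicolon-separated list,
#' `charge0`) or a YAML file with the same fields.
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` file.
#' @return Named list of [acid_system] objects.
#' @export
read_acid_systems <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    systems <- lapply(raw, function(r) {
      acid_system(r$name, as.numeric(r$pKa), r$charge0 %||% 0L)
    })
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    systems <- lapply(seq_len(nrow(tab)), function(i) {
      acid_system(
        tab$name[i],
        as.numeric(strsplit(as.character(tab$pKa[i]), ";")[[1]]),
        if ("charge0" %in% names(tab)) tab$charge0[i] else 0L
      )
    })
  }
  names(systems) <- vapply(systems, `[[`, "", "name")
  systems
}

#' Equilibrium fractions of the protonation states of an acid system
#'
#' Closed-form ladder fractions: state j (j protons removed from the fully
#' protonated form) has unnormalized weight 10^sum_{k<=j}(pH - pKa_k). The
#' fractions are total-independent.
#'
#' @param system An [acid_system].
#' @param pH Scalar pH (finite).
#' @return Numeric vector of length `length(pKa) + 1` summing to 1; names are
#'   `H<n>A` ... `A`, element j+1 being the state with j protons removed.
#' @export
species_fractions <- function(system, pH) {
  stopifnot(inherits(system, "acid_system"), is.finite(pH))
  # cumulative log-weights; log-sum-exp guard against overflow at extreme pH
  lw <- c(0, cumsum(pH - system$pKa))
  w <- 10^(lw - max(lw))
  f <- w / sum(w)
  n <- length(system$pKa)
  names(f) <- paste0("H", n - seq(0, n), "A")
  names(f)[1L] <- paste0("H", n, "A")
  names(f)[n] <- "HA"
  names(f)[n + 1L] <- "A"
  f
}

#' Mean charge carried per mole of an acid-system total at a given pH
#' @noRd
mean_charge <- function(system, pH) {
  f <- species_fractions(system, pH)
  j <- seq_along(f) - 1L
  sum(f * (system$charge0 - j))
}

#' Total element/acid-system concentrations of a liquid phase
#'
#' @param totals Named numeric vector (mol/L), names matching entries of
#'   `systems`; totals of each acid system.
#' @param strong_cations Strong-cation charge concentration (mol charge/L,
#'   e.g. Na+ from NaOH).
#' @param strong_anions Strong-anion charge concentration (mol charge/L,
#'   e.g. Cl- from HCl plus 2x sulfate molarity).
#' @param systems Named list of [acid_system] objects; defaults to
#'   [default_acid_systems()].
#' @return An object of class `ionic_totals`.
#' @export
ionic_totals <- function(totals = numeric(0), strong_cations = 0,
                         strong_anions = 0, systems = default_acid_systems()) {
  totals <- unlist(totals)
  if (length(totals) && is.null(names(totals))) {
    stop("totals must be named by acid system")
  }
  unknown <- setdiff(names(totals), names(systems))
  if (length(unknown)) {
    stop("totals name(s) not in systems: ", paste(unknown, collapse = ", "))
  }
  if (any(totals < 0) || strong_cations < 0 || strong_anions < 0) {
    stop("concentrations must be >= 0")
  }
  structure(
    list(
      totals = totals, strong_cations = strong_cations,
      strong_anions = strong_anions, systems = systems
    ),
    class = "ionic_totals"
  )
}

#' @export
print.ionic_totals <- function(x, ...) {
  cat("<ionic_totals> (mol/L)\n")
  if (length(x$totals)) {
    for (nm in names(x$totals)) {
      cat(sprintf("  %-10s %.4g\n", nm, x$totals[[nm]]))
    }
  }
  cat(sprintf(
    "  strong cations %.4g | strong anions %.4g\n",
    x$strong_cations, x$strong_anions
  ))
  invisible(x)
}

#' Charge-balance residual at a trial pH
#'
#' Residual = cations + H+ - anions - OH- + sum over systems of
#' total x mean species charge. Strictly decreasing in pH.
#'
#' @param totals An [ionic_totals] object.
#' @param pH Trial pH.
#' @param pKw Ion product exponent of water (default 14).
#' @return Signed residual (mol charge/L).
#' @export
charge_residual <- function(totals, pH, pKw = 14) {
  res <- totals$strong_cations - totals$strong_anions +
    10^(-pH) - 10^(pH - pKw)
  for (nm in names(totals$totals)) {
    res <- res + totals$totals[[nm]] * mean_charge(totals$systems[[nm]], pH)
  }
  res
}

#' Solve the equilibrium pH of a liquid phase
#'
#' Finds the unique root of the charge balance on pH in [0, 14] by bracketed
#' Brent iteration ([stats::uniroot]), then reports the per-system species
#' split at that pH.
#'
#' @param totals An [ionic_totals] object.
#' @param tol Absolute tolerance on the charge residual (mol/L).
#' @return A `speciation_result`: list with `pH`, `species` (named mol/L),
#'   and `charge_residual`.
#' @export
solve_ph <- function(totals, tol = 1e-10) {
  f <- function(p) charge_residual(totals, p)
  f0 <- f(0)
  f14 <- f(14)
  if (sign(f0) == sign(f14)) {
    stop(
      "degenerate input: charge balance has no root in pH [0, 14] ",
      sprintf("(residual %.3g at pH 0, %.3g at pH 14)", f0, f14)
    )
  }
  root <- stats::uniroot(f, c(0, 14), f.lower = f0, f.upper = f14,
                         tol = 1e-13)$root
  res <- f(root)
  if (abs(res) > tol) {
    # Brent met its pH tolerance; polish by secant steps on the residual
    for (i in 1:5) {
      h <- 1e-7
      d <- (f(root + h) - f(root - h)) / (2 * h)
      if (!is.finite(d) || d == 0) break
      root <- root - res / d
      res <- f(root)
      if (abs(res) <= tol) break
    }
  }
  species <- list()
  for (nm in names(totals$totals)) {
    fr <- species_fractions(totals$systems[[nm]], root)
    sp <- fr * totals$totals[[nm]]
    names(sp) <- paste0(nm, ".", names(fr))
    species <- c(species, as.list(sp))
  }
  structure(
    list(pH = root, species = unlist(species), charge_residual = res),
    class = "speciation_result"
  )
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf("<speciation_result> pH %.4f (residual %.2e mol/L)\n",
              x$pH, x$charge_residual))
  invisible(x)
}

#' Strong-ion dose required to reach a target pH
#'
#' The dose is the exact charge defect at the target pH: adding `dose` to the
#' strong cations (base, e.g. NaOH) when positive, or `-dose` to the strong
#' anions (acid, e.g. HCl) when negative, makes the target pH the root of the
#' charge balance.
#'
#' @param totals An [ionic_totals] object.
#' @param target_pH Target pH in (0, 14).
#' @return Signed dose (mol charge/L); positive = base.
#' @export
dose_to_setpoint <- function(totals, target_pH) {
  stopifnot(target_pH > 0, target_pH < 14)
  -charge_residual(totals, target_pH)
}

#' Apply a signed strong-ion dose to a liquid composition
#'
#' @param totals An [ionic_totals] object.
#' @param dose Signed dose (mol charge/L); positive adds strong cations.
#' @return Updated [ionic_totals].
#' @export
apply_dose <- function(totals, dose) {
  if (dose >= 0) {
    totals$strong_cations <- totals$strong_cations + dose
  } else {
    totals$strong_anions <- totals$strong_anions - dose
  }
  totals
}

`%||%` <- function(a, b) if (is.null(a)) b else a
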