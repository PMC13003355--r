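#' Sulfidogenic UASB reactor model
#'
#' The upflow anaerobic sludge blanket reactor is represented as a chain of
#' mini-CSTRs (plug-flow-like granular bed) running a data-driven
#' stoichiometric kinetic model: 15 reactions carried by 3 trophic groups
#' (8 fermentative routes for the glycerol carbon source, 5 sulfate-reduction
#' routes on H2/acetate/propionate/butyrate/glycerol, 2 methanogenic routes),
#' Monod growth kinetics with non-competitive sulfide inhibition, granule
#' retention of biomass, and headspace gas transfer (CH4/CO2/H2S) at the top
#' of the reactor under a slight overpressure.
#'
#' Organic species, H2, CH4 and biomass are carried in g COD/L; sulfur
#' species in g S/L; inorganic carbon in g C/L. Every reaction row of the
#' stoichiometric matrix must close its elemental S and COD balance; the
#' matrix is data, so a published coefficient set can be dropped in
#' verbatim.
#'
#' @name uasb
NULL

#' Construct and validate a stoichiometric kinetic model
#'
#' @param species Character vector of species names (columns of `stoich`).
#' @param stoich Reaction x species matrix; row j holds the mass produced
#'   (positive) or consumed (negative) of each species per unit biomass
#'   grown in reaction j (the biomass column of the reaction's group is +1).
#' @param kinetics Data frame with one row per reaction: `reaction` (name),
#'   `group` (biomass species doing the reaction), `substrate` (rate-limiting
#'   species), `mu_max` (1/d), `Ks` (g/L), `Ki_sulfide` (g S/L,
#'   non-competitive; `NA` disables), `acceptor` (electron-acceptor species
#'   for dual-Monod kinetics; `NA` disables), `Ks_acceptor` (g/L).
#' @param cod_content Named vector: g COD per g of species (used by the
#'   load-time balance validator).
#' @param s_content Named vector: g S per g of species.
#' @param decay Optional data frame (`group`, `rate` in 1/d, `product`):
#'   first-order biomass decay routed 1:1 (COD basis) to a lysis-product
#'   species; group and product must carry equal COD content so the
#'   balance closes.
#' @param balance_tol Relative closure tolerance per reaction.
#' @return Object of class `stoichiometric_model`.
#' @export
stoichiometric_model <- function(species, stoich, kinetics,
                                 cod_content, s_content, decay = NULL,
                                 balance_tol = 1e-6) {
  stoich <- as.matrix(stoich)
  if (ncol(stoich) != length(species)) {
    stop("stoichiometry matrix dimensions inconsistent with species list")
  }
  colnames(stoich) <- species
  if (nrow(stoich) != nrow(kinetics)) {
    stop("kinetics table must have one row per reaction")
  }
  need <- c("reaction", "group", "substrate", "mu_max", "Ks")
  if (!all(need %in% names(kinetics))) {
    stop("kinetics table missing columns: ",
         paste(setdiff(need, names(kinetics)), collapse = ", "))
  }
  if (!"Ki_sulfide" %in% names(kinetics)) kinetics$Ki_sulfide <- NA_real_
  if (!"acceptor" %in% names(kinetics)) kinetics$acceptor <- NA_character_
  if (!"Ks_acceptor" %in% names(kinetics)) kinetics$Ks_acceptor <- NA_real_
  rownames(stoich) <- kinetics$reaction
  stopifnot(all(kinetics$group %in% species),
            all(kinetics$substrate %in% species),
            all(kinetics$mu_max >= 0), all(kinetics$Ks > 0))
  cod <- stats::setNames(numeric(length(species)), species)
  cod[intersect(names(cod_content), species)] <-
    cod_content[intersect(names(cod_content), species)]
  s <- stats::setNames(numeric(length(species)), species)
  s[intersect(names(s_content), species)] <-
    s_content[intersect(names(s_content), species)]
  for (j in seq_len(nrow(stoich))) {
    for (w in list(list(v = cod, lab = "COD"), list(v = s, lab = "S"))) {
      terms <- stoich[j, ] * w$v
      scale <- max(sum(abs(terms)), 1e-12)
      if (abs(sum(terms)) > balance_tol * scale) {
        stop(sprintf(
          "reaction '%s' violates %s closure (relative residual %.3g)",
          kinetics$reaction[j], w$lab, abs(sum(terms)) / scale
        ))
      }
    }
  }
  if (!is.null(decay)) {
    stopifnot(all(c("group", "rate", "product") %in% names(decay)),
              all(decay$group %in% species),
              all(decay$product %in% species), all(decay$rate >= 0))
    if (any(abs(cod[decay$group] - cod[decay$product]) > 1e-12)) {
      stop("decay products must match the COD content of their group")
    }
  }
  structure(
    list(
      species = species, stoich = stoich, kinetics = kinetics,
      cod_content = cod, s_content = s, decay = decay,
      # precomputed integer indices for the integration hot path
      fast = list(
        mu = kinetics$mu_max, ks = kinetics$Ks,
        i_sub = match(kinetics$substrate, species),
        i_grp = match(kinetics$group, species),
        i_acc = match(kinetics$acceptor, species),
        ks_acc = kinetics$Ks_acceptor,
        ki = kinetics$Ki_sulfide,
        i_sulfide = match("sulfide_s", species),
        stoich_t = t(stoich),
        is_x = species %in% unique(kinetics$group),
        i_dgrp = if (is.null(decay)) integer(0) else
          match(decay$group, species),
        i_dprod = if (is.null(decay)) integer(0) else
          match(decay$product, species),
        drate = if (is.null(decay)) numeric(0) else decay$rate
      )
    ),
    class = "stoichiometric_model"
  )
}

#' @export
print.stoichiometric_model <- function(x, ...) {
  cat(sprintf(
    "<stoichiometric_model> %d reactions x %d species; groups: %s\n",
    nrow(x$stoich), length(x$species),
    paste(unique(x$kinetics$group), collapse = ", ")
  ))
  invisible(x)
}

#' Default sulfidogenic glycerol-fed reaction network
#'
#' Fifteen COD- and S-balanced reactions over three trophic groups:
#' glycerol fermentation to 1,3-propanediol / propionate / acetate /
#' butyrate (+H2) with secondary fermentations, complete-oxidizing sulfate
#' reduction on five electron donors, and acetoclastic plus hydrogenotrophic
#' methanogenesis. Coefficients are a documented COD-balanced default (the
#' engine treats the matrix as data); kinetic parameters are typical values
#' for mesophilic sulfidogenic granular sludge, exposed for configuration.
#'
#' @param yield Named list of biomass yields (g COD X per g COD substrate)
#'   per group: `ferm`, `srb`, `met`.
#' @param Ki_sulfide Named list of non-competitive total-sulfide inhibition
#'   constants (g S/L) per group.
#' @param mu_scale Named list of multipliers on the group mu_max values
#'   (calibration hooks; default 1).
#' @param decay_rate First-order biomass decay (1/d), routed to acetate as
#'   lysis product; bounds the granule biomass hold-up.
#' @param Ks_sulfate Apparent sulfate half-saturation of the
#'   sulfate-reduction routes (g S/L); granule diffusion limitation makes
#'   this an effective, calibratable constant that sets the residual
#'   sulfate of the reactor (see [calibrate_uasb_residual()]).
#' @return A [stoichiometric_model].
#' @export
default_uasb_model <- function(yield = list(ferm = 0.10, srb = 0.05,
                                            met = 0.05),
                               Ki_sulfide = list(ferm = 0.80, srb = 0.55,
                                                 met = 0.25),
                               mu_scale = list(ferm = 1, srb = 1, met = 1),
                               decay_rate = 0.04, Ks_sulfate = 0.02) {
  species <- c("glycerol", "pdo", "propionate", "butyrate", "acetate", "h2",
               "ch4", "sulfate_s", "sulfide_s", "ic",
               "x_ferm", "x_srb", "x_met")
  cod <- c(glycerol = 1, pdo = 1, propionate = 1, butyrate = 1, acetate = 1,
           h2 = 1, ch4 = 1, sulfate_s = 0, sulfide_s = 2, ic = 0,
           x_ferm = 1, x_srb = 1, x_met = 1)
  s <- c(sulfate_s = 1, sulfide_s = 1)

  rows <- list()
  kin <- list()
  add <- function(name, group, substrate, mu, Ks, prods, acceptor = NA,
                  Ks_acc = NA, ic_coef = 0) {
    Y <- switch(group, x_ferm = yield$ferm, x_srb = yield$srb,
                x_met = yield$met)
    u <- 1 / Y - 1 # g COD routed to products per g COD biomass formed
    row <- stats::setNames(numeric(length(species)), species)
    row[substrate] <- -1 / Y
    row[group] <- 1
    for (p in names(prods)) row[p] <- row[p] + u * prods[[p]]
    if (!is.na(acceptor)) {
      # complete oxidation with sulfate as acceptor: the electron equivalents
      # leave as sulfide-COD (2 g COD per g S)
      row["sulfide_s"] <- row["sulfide_s"] + u / 2
      row["sulfate_s"] <- row["sulfate_s"] - u / 2
    }
    row["ic"] <- ic_coef
    Kig <- switch(group, x_ferm = Ki_sulfide$ferm, x_srb = Ki_sulfide$srb,
                  x_met = Ki_sulfide$met)
    mus <- switch(group, x_ferm = mu_scale$ferm, x_srb = mu_scale$srb,
                  x_met = mu_scale$met)
    rows[[name]] <<- row
    kin[[name]] <<- data.frame(
      reaction = name, group = group, substrate = substrate,
      mu_max = mu * mus, Ks = Ks, Ki_sulfide = Kig,
      acceptor = if (is.na(acceptor)) NA_character_ else acceptor,
      Ks_acceptor = Ks_acc, stringsAsFactors = FALSE
    )
  }

  # fermentation (8 routes)
  add("glyc_to_pdo", "x_ferm", "glycerol", 1.2, 0.30, list(pdo = 1),
      ic_coef = 0.02)
  add("glyc_to_prop", "x_ferm", "glycerol", 0.8, 0.30,
      list(propionate = 1), ic_coef = 0.04)
  add("glyc_to_ac_h2", "x_ferm", "glycerol", 1.5, 0.30,
      list(acetate = 0.7, h2 = 0.3), ic_coef = 0.06)
  add("glyc_to_but_h2", "x_ferm", "glycerol", 0.9, 0.30,
      list(butyrate = 0.8, h2 = 0.2), ic_coef = 0.04)
  add("pdo_to_prop", "x_ferm", "pdo", 1.0, 0.30,
      list(propionate = 0.8, h2 = 0.2), ic_coef = 0.02)
  add("pdo_to_ac_h2", "x_ferm", "pdo", 0.8, 0.30,
      list(acetate = 0.7, h2 = 0.3), ic_coef = 0.04)
  add("prop_to_ac_h2", "x_ferm", "propionate", 0.45, 0.25,
      list(acetate = 0.57, h2 = 0.43), ic_coef = 0.03)
  add("but_to_ac_h2", "x_ferm", "butyrate", 0.60, 0.25,
      list(acetate = 0.8, h2 = 0.2), ic_coef = 0.02)
  # sulfate reduction (5 donors, complete oxidation)
  add("sr_h2", "x_srb", "h2", 1.8, 1e-3, list(), "sulfate_s", Ks_sulfate,
      ic_coef = -0.03)
  add("sr_acetate", "x_srb", "acetate", 0.55, 0.04, list(), "sulfate_s",
      Ks_sulfate, ic_coef = 0.08)
  add("sr_propionate", "x_srb", "propionate", 0.48, 0.10, list(),
      "sulfate_s", Ks_sulfate, ic_coef = 0.08)
  add("sr_butyrate", "x_srb", "butyrate", 0.50, 0.10, list(), "sulfate_s",
      Ks_sulfate, ic_coef = 0.08)
  add("sr_glycerol", "x_srb", "glycerol", 1.2, 0.20, list(), "sulfate_s",
      Ks_sulfate, ic_coef = 0.08)
  # methanogenesis (2 routes)
  add("met_acetate", "x_met", "acetate", 0.40, 0.12, list(ch4 = 1),
      ic_coef = 0.19)
  add("met_h2", "x_met", "h2", 2.0, 1e-3, list(ch4 = 1), ic_coef = -0.07)

  stoich <- do.call(rbind, rows)
  kinetics <- do.call(rbind, kin)
  decay <- data.frame(group = c("x_ferm", "x_srb", "x_met"),
                      rate = decay_rate, product = "acetate")
  stoichiometric_model(species, stoich, kinetics, cod, s, decay = decay)
}

#' Monod reaction rates of a stoichiometric model
#'
#' rate_j = mu_max_j * X_group * S/(Ks+S) * [A/(Ks_A+A)] *
#' [Ki/(Ki + sulfide)] in g COD biomass/(L d).
#'
#' @param state Named numeric vector of concentrations (g/L), covering all
#'   model species.
#' @param model A [stoichiometric_model].
#' @return Numeric rate vector (one per reaction), all >= 0.
#' @export
reaction_rates <- function(state, model) {
  if (any(state[model$species] < 0 | is.na(state[model$species]))) {
    stop("state error: negative or missing concentration")
  }
  .rates_fast(as.numeric(state[model$species]), model$fast)
}

# hot path: integer-indexed Monod rates over an unnamed state vector
.rates_fast <- function(conc, f) {
  S <- conc[f$i_sub]
  r <- f$mu * conc[f$i_grp] * S / (f$ks + S)
  acc <- !is.na(f$i_acc)
  if (any(acc)) {
    A <- conc[f$i_acc[acc]]
    r[acc] <- r[acc] * A / (f$ks_acc[acc] + A)
  }
  ki <- !is.na(f$ki)
  if (any(ki) && !is.na(f$i_sulfide)) {
    r[ki] <- r[ki] * f$ki[ki] / (f$ki[ki] + conc[f$i_sulfide])
  }
  r
}

# first-order biomass decay routed to lysis products (COD-conserving);
# indexed assignment is looped because product indices may repeat
.apply_decay <- function(dc, conc, f) {
  for (k in seq_along(f$i_dgrp)) {
    rd <- f$drate[k] * conc[f$i_dgrp[k]]
    dc[f$i_dgrp[k]] <- dc[f$i_dgrp[k]] - rd
    dc[f$i_dprod[k]] <- dc[f$i_dprod[k]] + rd
  }
  dc
}

#' Gas-liquid film flux toward saturation
#'
#' Rate of change of the liquid concentration: kLa * (C_sat - C_liq).
#'
#' @param liquid_conc Liquid concentration (g/L).
#' @param saturation_conc Equilibrium concentration with the headspace
#'   partial pressure (g/L).
#' @param kla Volumetric transfer coefficient (1/d), >= 0.
#' @return Flux (g/(L d)), positive into the liquid.
#' @export
headspace_transfer <- function(liquid_conc, saturation_conc, kla) {
  stopifnot(all(kla >= 0))
  kla * (saturation_conc - liquid_conc)
}

#' Headspace configuration of the UASB
#'
#' @param kla Gas-liquid transfer coefficient at the reactor top (1/d).
#' @param pressure Headspace absolute pressure (atm; slight overpressure).
#' @param ph Liquor pH at the reactor top used for the exchangeable free
#'   H2S fraction (the biological units are pH-controlled).
#' @param henry_molar Named Henry solubilities (mol/(L atm), 25-35 degC) of
#'   the stripped species.
#' @export
uasb_headspace <- function(kla = 200, pressure = 1.05, ph = 7,
                           henry_molar = c(ch4 = 0.0014, ic = 0.034,
                                           sulfide_s = 0.1)) {
  stopifnot(kla >= 0, pressure > 0)
  list(kla = kla, pressure = pressure, ph = ph, henry_molar = henry_molar)
}

# Quasi-steady headspace: the vented biogas flow q (mol/d) and partial
# pressures p satisfy film transfer = vent outflow per species,
#   b_i (c_i - p_i h_i) = q p_i / P,   q = sum of the left sides,
# which reduces to a scalar root for q: P = sum b_i c_i / (q/P + b_i h_i).
# When the equilibrium pressures sum below P the vent is closed (q = 0).
# c_i: exchangeable liquid conc (g/L); b_i: kla*V*1000/mw (mol/d per g/L);
# h_i: Henry (g/L per atm).
.headspace_qs <- function(cl, b, h, pressure) {
  peq <- ifelse(h > 0, cl / h, 0)
  if (sum(peq) <= pressure || all(cl <= 0)) {
    return(list(q = 0, p = peq, tr_mol = numeric(length(cl))))
  }
  f <- function(q) sum(b * cl / (q / pressure + b * h)) - pressure
  hi <- sum(b * cl) / pressure
  lo <- 0
  for (i in 1:80) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  q <- 0.5 * (lo + hi)
  p <- b * cl / (q / pressure + b * h)
  list(q = q, p = p, tr_mol = q * p / pressure)
}

# g per mol on each species' own mass basis (COD, C or S)
.UASB_GAS_MW <- c(ch4 = 64, ic = 12, sulfide_s = 32)

# Newton polish of an ODE steady state (numerical Jacobian); returns the
# input unchanged when the iteration leaves the feasible region
.steady_polish <- function(y, rhs, tol = 1e-12, max_iter = 25) {
  n <- length(y)
  y_in <- y
  for (it in seq_len(max_iter)) {
    dy <- rhs(0, y, NULL)[[1L]]
    if (max(abs(dy) / pmax(abs(y), 1e-8)) < tol) return(y)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(1e-9, 1e-7 * abs(y[j]))
      yp <- y
      yp[j] <- yp[j] + h
      J[, j] <- (rhs(0, yp, NULL)[[1L]] - dy) / h
    }
    step <- tryCatch(solve(J, -dy), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(y_in)
    # damp steps that would drive states strongly negative
    lam <- 1
    while (lam > 1e-3 && any(y + lam * step < -1e-6 * pmax(abs(y), 1e-6))) {
      lam <- lam / 2
    }
    y <- pmax(y + lam * step, 0)
  }
  y
}

# RHS for one mini-CSTR; gas = TRUE adds the quasi-steady headspace vent
# of the top tank
.uasb_tank_rhs <- function(model, D, feed, retention, gas, hs, V_tank) {
  ns <- length(model$species)
  fast <- model$fast
  is_x <- fast$is_x
  f_h2s <- .alpha0_vec(7.05, hs$ph)
  gas_sp <- intersect(c("ch4", "ic", "sulfide_s"), model$species)
  if (!length(gas_sp)) gas <- FALSE
  gidx <- match(gas_sp, model$species)
  i_h2s <- match("sulfide_s", gas_sp)
  h <- hs$henry_molar[gas_sp] * .UASB_GAS_MW[gas_sp] # g/L per atm
  mw <- .UASB_GAS_MW[gas_sp]
  b <- hs$kla * V_tank * 1000 / mw                   # mol/d per g/L
  function(t, y, parms) {
    conc <- pmax(y[seq_len(ns)], 0)
    r <- .rates_fast(conc, fast)
    dc <- .apply_decay(as.numeric(fast$stoich_t %*% r), conc, fast)
    # advection; retained biomass leaves at (1 - retention) of its tank conc
    out <- conc
    out[is_x] <- out[is_x] * (1 - retention)
    dc <- dc + D * (feed - out)
    if (gas && hs$kla > 0) {
      cl <- conc[gidx]
      if (!is.na(i_h2s)) cl[i_h2s] <- cl[i_h2s] * f_h2s
      qs <- .headspace_qs(cl, b, h, hs$pressure)
      # vented moles leave the liquid film: g/(L d)
      dc[gidx] <- dc[gidx] - qs$tr_mol * mw / (V_tank * 1000)
    }
    list(dc)
  }
}

#' Simulate the UASB tank chain to steady state
#'
#' Solves the mini-CSTRs sequentially (the liquid couples strictly forward;
#' headspace transfer acts on the top tank), each integrated with
#' [deSolve::lsoda] in chunks until the state is stationary.
#'
#' @param feed A [liquid_stream] whose `solutes` carry the model species
#'   (g/L); missing species enter at 0.
#' @param model A [stoichiometric_model].
#' @param n_tanks Number of mini-CSTRs.
#' @param volume Total reactor liquid volume (m^3).
#' @param horizon Maximum integration time per tank (d).
#' @param retention Granule retention factor in [0, 1): fraction of biomass
#'   held back from the effluent of every tank.
#' @param headspace A [uasb_headspace] configuration.
#' @param x_seed Inoculum concentration added to every tank's initial state
#'   for each biomass group (g COD/L).
#' @param init Optional tanks x species state matrix (e.g. `states` of a
#'   previous run) used to warm-start the solve.
#' @param steady_tol Relative rate-of-change threshold (1/d) flagging
#'   steady state.
#' @return List with `effluent` ([liquid_stream]), `biogas` (list: flow
#'   m^3/d at 25 degC, molar fractions, g/d of CH4-COD, CO2-C, H2S-S),
#'   `states` (tanks x species matrix), `headspace_atm`, `converged`, and
#'   `audit` (relative S and COD conservation residuals).
#' @export
simulate_uasb <- function(feed, model, n_tanks = 10, volume = 1000.3,
                          horizon = 400, retention = 0.995,
                          headspace = uasb_headspace(),
                          x_seed = 0.5, init = NULL, steady_tol = 1e-8) {
  stopifnot(inherits(feed, "liquid_stream"),
            inherits(model, "stoichiometric_model"),
            n_tanks >= 1, volume > 0, retention >= 0, retention < 1)
  Q <- feed$volumetric_flow # m^3/h
  if (Q <= 0) stop("hydraulic retention time must be > 0 (zero feed flow)")
  V_tank <- volume / n_tanks
  D <- Q * 24 / V_tank # 1/d per tank
  ns <- length(model$species)
  is_x <- model$fast$is_x

  feed_vec <- stats::setNames(numeric(ns), model$species)
  common <- intersect(names(feed$solutes), model$species)
  feed_vec[common] <- feed$solutes[common]

  states <- matrix(0, n_tanks, ns, dimnames = list(NULL, model$species))
  dstates <- states
  cur_feed <- feed_vec
  hs_final <- NULL
  biogas <- NULL
  converged <- TRUE
  gas_sp <- intersect(c("ch4", "ic", "sulfide_s"), model$species)

  for (tk in seq_len(n_tanks)) {
    gas <- tk == n_tanks && length(gas_sp) > 0
    y0_cold <- cur_feed
    y0_cold[is_x] <- pmax(y0_cold[is_x], x_seed)
    y0 <- y0_cold
    if (!is.null(init)) {
      y0 <- pmax(as.numeric(init[tk, ]), 0)
      y0[is_x] <- pmax(y0[is_x], 1e-4) # keep a viable inoculum
    }
    rhs <- .uasb_tank_rhs(model, D, cur_feed, retention, gas, headspace,
                          V_tank)
    t_done <- 0
    chunk <- min(horizon, 80)
    y <- y0
    solved <- FALSE
    if (!is.null(init)) {
      # warm start: Newton directly from the previous steady state; fall
      # back to time marching when it wanders or fails
      yp <- .steady_polish(y0, rhs)
      m <- max(abs(rhs(0, yp, NULL)[[1L]]) / pmax(abs(yp), 1e-8))
      moved <- max(abs(yp - y0) / pmax(abs(y0), 1e-3))
      if (m < steady_tol && moved < 2) {
        y <- yp
        metric <- m
        solved <- TRUE
      }
      if (isTRUE(getOption("bioscrub.uasb_trace"))) {
        cat(sprintf("      tank %d polish: metric %.1e moved %.2f -> %s\n",
                    tk, m, moved, if (solved) "accept" else "integrate"))
      }
    }
    stalls <- 0
    if (!solved) repeat {
      sol <- suppressWarnings(
        deSolve::lsoda(y, c(0, chunk), rhs, NULL,
                       rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
      )
      last <- nrow(sol)
      t_reached <- sol[last, 1]
      if (t_reached <= 0 || anyNA(sol[last, -1])) {
        stop("numerical error: stiff integration of UASB tank ", tk,
             " failed")
      }
      y <- pmax(as.numeric(sol[last, -1]), 0)
      t_done <- t_done + t_reached
      dy <- rhs(0, y, NULL)[[1L]]
      tiny <- y < 1e-12 & dy < 0 # washout tails
      if (any(tiny)) {
        y[tiny] <- 0
        dy <- rhs(0, y, NULL)[[1L]]
      }
      metric <- max(abs(dy) / pmax(abs(y), 1e-8))
      # Newton close-out after every chunk (cheap relative to the chunk)
      yp <- .steady_polish(y, rhs)
      mp <- max(abs(rhs(0, yp, NULL)[[1L]]) / pmax(abs(yp), 1e-8))
      if (mp < metric) {
        y <- yp
        metric <- mp
      }
      if (metric < steady_tol || t_done >= horizon) break
      if (t_reached < 0.05 * chunk) {
        # the integrator stalled far from stationarity: try Newton from
        # here, then one coarse rescue pass, before giving up
        stalls <- stalls + 1
        yp <- .steady_polish(y, rhs)
        mp <- max(abs(rhs(0, yp, NULL)[[1L]]) / pmax(abs(yp), 1e-8))
        if (mp < steady_tol) {
          y <- yp
          metric <- mp
          break
        }
        if (stalls == 1 && !is.null(init)) {
          # a mismatched warm start can sit on a pathological transient:
          # restart the march from the feed-based cold state
          y <- y0_cold
          t_done <- 0
          next
        }
        sol2 <- suppressWarnings(
          deSolve::lsoda(y, c(0, chunk), rhs, NULL,
                         rtol = 1e-6, atol = 1e-8, maxsteps = 50000)
        )
        l2 <- nrow(sol2)
        if (sol2[l2, 1] > 0 && !anyNA(sol2[l2, -1])) {
          y <- pmax(as.numeric(sol2[l2, -1]), 0)
          t_done <- t_done + sol2[l2, 1]
          yp <- .steady_polish(y, rhs)
          mp <- max(abs(rhs(0, yp, NULL)[[1L]]) / pmax(abs(yp), 1e-8))
          metric <- max(abs(rhs(0, y, NULL)[[1L]]) / pmax(abs(y), 1e-8))
          if (mp < metric) {
            y <- yp
            metric <- mp
          }
          if (metric < steady_tol) break
        }
        if (stalls >= 3) {
          stop("numerical error: stiff integration of UASB tank ", tk,
               " stalled repeatedly (state may sustain oscillations)")
        }
      }
    }
    if (metric >= steady_tol) converged <- FALSE
    states[tk, ] <- y[seq_len(ns)]
    dstates[tk, ] <- rhs(0, y, NULL)[[1L]][seq_len(ns)]
    if (gas && headspace$kla > 0) {
      f_h2s <- .alpha0_vec(7.05, headspace$ph)
      hv <- headspace$henry_molar[gas_sp] * .UASB_GAS_MW[gas_sp]
      mw <- .UASB_GAS_MW[gas_sp]
      cl <- y[match(gas_sp, model$species)]
      names(cl) <- gas_sp
      if ("sulfide_s" %in% gas_sp) cl["sulfide_s"] <- cl["sulfide_s"] * f_h2s
      qs <- .headspace_qs(cl, headspace$kla * V_tank * 1000 / mw, hv,
                          headspace$pressure)
      hs_final <- stats::setNames(qs$p, gas_sp)
      strip_mol <- stats::setNames(qs$tr_mol, gas_sp)
      strip_g <- strip_mol * mw
      qmol <- qs$q # mol/d
      biogas <- list(
        flow_m3_d = qmol * MOLAR_VOLUME_M3,
        fractions = if (qmol > 0) strip_mol / qmol else strip_mol,
        ch4_cod_g_d = if ("ch4" %in% gas_sp) strip_g[["ch4"]] else 0,
        co2_c_g_d = if ("ic" %in% gas_sp) strip_g[["ic"]] else 0,
        h2s_s_g_d = if ("sulfide_s" %in% gas_sp) strip_g[["sulfide_s"]]
                    else 0
      )
    }
    out <- states[tk, ]
    out[is_x] <- out[is_x] * (1 - retention)
    cur_feed <- out
  }

  ql_d <- Q * 24 * 1000 # L/d
  effl <- cur_feed
  gas_s <- biogas$h2s_s_g_d %||% 0
  # stripped H2S carries 2 g COD per g S, like dissolved sulfide
  gas_cod <- (biogas$ch4_cod_g_d %||% 0) + 2 * gas_s
  acc_s <- sum(dstates %*% model$s_content) * V_tank * 1000
  acc_cod <- sum(dstates %*% model$cod_content) * V_tank * 1000
  s_in <- sum(feed_vec * model$s_content) * ql_d
  s_out <- sum(effl * model$s_content) * ql_d + gas_s
  cod_in <- sum(feed_vec * model$cod_content) * ql_d
  cod_out <- sum(effl * model$cod_content) * ql_d + gas_cod
  audit <- c(
    S = abs(s_in - s_out - acc_s) / max(s_in, 1e-9),
    COD = abs(cod_in - cod_out - acc_cod) / max(cod_in, 1e-9)
  )

  effluent <- liquid_stream(Q, feed$totals, temperature = 35,
                            solutes = effl)
  list(
    effluent = effluent, biogas = biogas, states = states,
    headspace_atm = hs_final, converged = converged, audit = audit,
    dilution_per_tank_d = D
  )
}
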