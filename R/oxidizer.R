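#' Microaerobic sulfide-oxidation CSTR
#'
#' Aerated mixed tank in which sulfur-oxidizing bacteria (SOB) partially
#' oxidize the sulfide delivered by the UASB to elemental biosulfur, with
#' further oxidation to sulfate and a thiosulfate route, plus facultative
#' heterotrophs degrading residual soluble COD (single aerobic growth
#' process with ASM2-typical defaults). Dissolved oxygen is held at a low
#' set-point (0.1 mg O2/L) by a proportional-integral controller acting on
#' the air flow; the volumetric transfer coefficient follows a configurable
#' power law of the specific air flow. Low DO starves the sulfate route
#' (higher oxygen half-saturation), which is what makes the partial
#' oxidation selective for elemental sulfur.
#'
#' @name oxidizer
NULL

#' PI controller configuration
#'
#' @param setpoint DO set-point (mg O2/L).
#' @param Kp Proportional gain (m^3/h air per mg/L error).
#' @param Ki_gain Integral gain (m^3/h air per mg h/L integrated error).
#' @param bounds Output bounds (m^3/h air).
#' @param bias Feed-forward output at zero error and zero integral (m^3/h).
#' @param anti_windup Freeze the integral while the output is saturated.
#' @return Object of class `pi_controller_config`.
#' @export
pi_controller_config <- function(setpoint = 0.1, Kp = 50, Ki_gain = 25,
                                 bounds = c(0, 500), bias = 10,
                                 anti_windup = TRUE) {
  stopifnot(Kp >= 0, Ki_gain >= 0, length(bounds) == 2,
            bounds[1] < bounds[2])
  structure(
    list(setpoint = setpoint, Kp = Kp, Ki_gain = Ki_gain, bounds = bounds,
         bias = bias, anti_windup = anti_windup),
    class = "pi_controller_config"
  )
}

#' One step of the PI control law
#'
#' Output = bias + Kp e + Ki I, clamped to the configured bounds; while the
#' unclamped output is saturated in the direction of the error the integral
#' is frozen (anti-windup).
#'
#' @param error Set-point minus measurement (mg/L).
#' @param integral_state Accumulated error (mg h/L).
#' @param cfg A [pi_controller_config].
#' @param dt Step length (h), > 0 (or 0 to evaluate the output only).
#' @return List with `airflow` (m^3/h) and `integral_state`.
#' @export
pi_step <- function(error, integral_state, cfg, dt) {
  stopifnot(dt >= 0)
  u_raw <- cfg$bias + cfg$Kp * error + cfg$Ki_gain * integral_state
  airflow <- min(max(u_raw, cfg$bounds[1]), cfg$bounds[2])
  saturated <- (u_raw > cfg$bounds[2] && error > 0) ||
    (u_raw < cfg$bounds[1] && error < 0)
  new_int <- if (cfg$anti_windup && saturated) {
    integral_state
  } else {
    integral_state + error * dt
  }
  list(airflow = airflow, integral_state = new_int)
}

#' Volumetric oxygen transfer coefficient from the air flow
#'
#' Power-law correlation kLa = alpha * (airflow / V)^beta: zero at zero and
#' monotone increasing.
#'
#' @param airflow Air flow (m^3/h), >= 0.
#' @param cfg List with `alpha` (1/h at unit specific air flow), `beta`
#'   (dimensionless) and `volume` (m^3).
#' @return kLa (1/h).
#' @export
kla_from_airflow <- function(airflow, cfg) {
  if (cfg$alpha <= 0 || cfg$beta <= 0) {
    stop("config error: power-law coefficients must be > 0")
  }
  stopifnot(all(airflow >= 0))
  cfg$alpha * (airflow / cfg$volume)^cfg$beta
}

#' Oxidizer configuration
#'
#' Kinetic defaults follow the three-step SOB electron-donor chain
#' (sulfide to S0, S0 to sulfate, thiosulfate to sulfate), dual-Monod in
#' donor and dissolved oxygen, with ASM2-typical heterotroph parameters.
#'
#' @param volume Tank liquid volume (m^3).
#' @param do_sat DO saturation (mg/L) at the 35 degC process temperature.
#' @param controller A [pi_controller_config].
#' @param kla_alpha,kla_beta Power-law coefficients of the kLa correlation.
#' @param sob Named list of SOB parameters: `q1`, `q2`, `q3` (g S per
#'   g COD biomass per day), `K1`, `K2`, `K3` (g S/L), `Ko1`, `Ko2`, `Ko3`
#'   (mg O2/L) and `yield` (g COD biomass per g S oxidized).
#' @param het Heterotroph parameters: `mu_max` (1/d), `Ks` (g COD/L),
#'   `yield` (g COD X per g COD substrate).
#' @return Object of class `oxidizer_config`.
#' @export
oxidizer_config <- function(volume = 2277, do_sat = 8.0,
                            controller = pi_controller_config(),
                            kla_alpha = 40, kla_beta = 0.8,
                            sob = list(q1 = 42, K1 = 0.35, Ko1 = 0.02,
                                       q2 = 10, K2 = 0.50, Ko2 = 0.50,
                                       q3 = 15, K3 = 0.10, Ko3 = 0.10,
                                       yield = 0.10),
                            het = list(mu_max = 6, Ks = 0.004,
                                       yield = 0.63)) {
  stopifnot(volume > 0, do_sat > 0)
  structure(
    list(volume = volume, do_sat = do_sat, controller = controller,
         kla_alpha = kla_alpha, kla_beta = kla_beta, sob = sob, het = het),
    class = "oxidizer_config"
  )
}

.OX_STATES <- c("sulfide_s", "s0_s", "thiosulfate_s", "sulfate_s", "cod",
                "do", "x_sob", "x_het", "pi_integral")

.oxidizer_rhs <- function(cfg, D, feed) {
  ctl <- cfg$controller
  kla_cfg <- list(alpha = cfg$kla_alpha, beta = cfg$kla_beta,
                  volume = cfg$volume)
  p <- cfg$sob
  h <- cfg$het
  function(t, y, parms) {
    y <- pmax(y, 0)
    names(y) <- .OX_STATES
    e <- ctl$setpoint - y[["do"]]
    ctrl <- pi_step(e, y[["pi_integral"]], ctl, 0)
    u <- ctrl$airflow
    kla <- kla_from_airflow(u, kla_cfg)
    DO <- y[["do"]]
    # S conversions, g S/(L h)
    r1 <- p$q1 / 24 * y[["x_sob"]] * y[["sulfide_s"]] /
      (p$K1 + y[["sulfide_s"]]) * DO / (p$Ko1 + DO)
    r2 <- p$q2 / 24 * y[["x_sob"]] * y[["s0_s"]] /
      (p$K2 + y[["s0_s"]]) * DO / (p$Ko2 + DO)
    r3 <- p$q3 / 24 * y[["x_sob"]] * y[["thiosulfate_s"]] /
      (p$K3 + y[["thiosulfate_s"]]) * DO / (p$Ko3 + DO)
    # heterotroph growth, g COD X/(L h)
    rh <- h$mu_max / 24 * y[["x_het"]] * y[["cod"]] / (h$Ks + y[["cod"]]) *
      DO / (0.2 + DO)
    our <- 1000 * (0.5 * r1 + 1.5 * r2 + 1.0 * r3 +
                     (1 / h$yield - 1) * rh) # mg O2/(L h)
    u_raw <- ctl$bias + ctl$Kp * e + ctl$Ki_gain * y[["pi_integral"]]
    windup <- ctl$anti_windup &&
      ((u_raw > ctl$bounds[2] && e > 0) || (u_raw < ctl$bounds[1] && e < 0))
    d <- c(
      sulfide_s = D * (feed[["sulfide_s"]] - y[["sulfide_s"]]) - r1,
      s0_s = D * (feed[["s0_s"]] - y[["s0_s"]]) + r1 - r2,
      thiosulfate_s = D * (feed[["thiosulfate_s"]] -
                             y[["thiosulfate_s"]]) - r3,
      sulfate_s = D * (feed[["sulfate_s"]] - y[["sulfate_s"]]) + r2 + r3,
      cod = D * (feed[["cod"]] - y[["cod"]]) - rh / h$yield,
      do = kla * (cfg$do_sat - DO) - our - D * DO,
      x_sob = -D * y[["x_sob"]] + p$yield * (r1 + r2 + r3),
      x_het = -D * y[["x_het"]] + rh,
      pi_integral = if (windup) 0 else e
    )
    list(unname(d), airflow = u)
  }
}

#' Simulate the oxidation tank to steady state
#'
#' @param feed A [liquid_stream]; solutes may carry `sulfide_s`, `s0_s`,
#'   `thiosulfate_s`, `sulfate_s` (g S/L) and `cod` (g COD/L). Solutes named
#'   as UASB organics (`glycerol`, `acetate`, ...) are pooled into `cod`.
#' @param cfg An [oxidizer_config].
#' @param horizon Maximum integration time (h).
#' @param init Optional state vector of a previous run used to warm-start
#'   the solve.
#' @param steady_tol Relative rate-of-change threshold (1/h).
#' @return List with `effluent` ([liquid_stream]), `biosulfur_kg_h`,
#'   `air_demand_m3_h`, `do_mg_l`, `states`, `converged`, `infeasible`
#'   (TRUE when the air demand exceeds the controller bound), `audit`
#'   (relative S conservation residual) and `trajectory`.
#' @export
simulate_oxidizer <- function(feed, cfg, horizon = 3000, init = NULL,
                              steady_tol = 1e-9) {
  stopifnot(inherits(feed, "liquid_stream"),
            inherits(cfg, "oxidizer_config"))
  Q <- feed$volumetric_flow
  if (Q <= 0) stop("feed flow must be > 0")
  D <- Q / cfg$volume # 1/h
  fv <- stats::setNames(numeric(5), .OX_STATES[1:5])
  sol <- feed$solutes
  organics <- c("glycerol", "pdo", "propionate", "butyrate", "acetate",
                "h2", "cod")
  for (nm in intersect(names(sol), names(fv))) fv[nm] <- sol[[nm]]
  fv["cod"] <- sum(sol[intersect(names(sol), organics)])
  rhs <- .oxidizer_rhs(cfg, D, fv)

  y0 <- c(fv, do = cfg$controller$setpoint, x_sob = 0.02, x_het = 0.02,
          pi_integral = 0)
  names(y0) <- .OX_STATES
  if (!is.null(init)) {
    y0 <- stats::setNames(pmax(as.numeric(init), 0), .OX_STATES)
    # keep a viable inoculum: a warm start must never freeze the biomass
    # in the washed-out (absorbing) state
    y0[c("x_sob", "x_het")] <- pmax(y0[c("x_sob", "x_het")], 2e-3)
  }
  t_done <- 0
  chunk <- 400
  y <- y0
  traj <- NULL
  solved <- FALSE
  stalls <- 0
  if (!is.null(init)) {
    yp <- .steady_polish(y0, rhs)
    dyp <- rhs(0, yp, NULL)[[1L]]
    m <- max(abs(dyp[1:8]) / pmax(abs(yp[1:8]), 1e-8))
    if (m < steady_tol && max(abs(yp - y0) / pmax(abs(y0), 1e-3)) < 2) {
      y <- stats::setNames(yp, .OX_STATES)
      metric <- m
      solved <- TRUE
    }
  }
  if (!solved) repeat {
    times <- seq(0, min(chunk, horizon - t_done), length.out = 9)
    out <- suppressWarnings(
      deSolve::lsoda(y, times, rhs, NULL, rtol = 1e-9, atol = 1e-11,
                     maxsteps = 50000)
    )
    last <- nrow(out)
    if (out[last, 1] <= 0 || anyNA(out[last, ])) {
      stop("numerical error: oxidizer integration failed")
    }
    block <- as.data.frame(out)
    block$time <- block$time + t_done
    traj <- rbind(traj, block)
    y <- pmax(as.numeric(out[last, 1 + seq_along(y0)]), 0)
    names(y) <- .OX_STATES
    t_done <- t_done + out[last, 1]
    dy <- rhs(0, y, NULL)[[1L]]
    # washed-out populations decay exponentially forever; snap them to
    # zero so stationarity is detectable
    tiny <- y < 1e-9 & dy < 0
    if (any(tiny)) {
      y[tiny] <- 0
      dy <- rhs(0, y, NULL)[[1L]]
    }
    scale <- pmax(abs(y), 1e-8)
    metric <- max(abs(dy[1:8]) / scale[1:8]) # integral excluded
    # Newton close-out after every chunk (cheap relative to the chunk)
    yp <- .steady_polish(y, rhs)
    dyp <- rhs(0, yp, NULL)[[1L]]
    mp <- max(abs(dyp[1:8]) / pmax(abs(yp[1:8]), 1e-8))
    if (mp < metric) {
      y <- stats::setNames(yp, .OX_STATES)
      metric <- mp
    }
    if (metric < steady_tol || t_done >= horizon) break
    if (out[last, 1] < 0.2 * chunk) {
      # controller chatter near a bound can stall the integrator; Newton
      # from here usually lands the interior steady state directly
      stalls <- stalls + 1
      yp <- .steady_polish(y, rhs)
      dyp <- rhs(0, yp, NULL)[[1L]]
      mp <- max(abs(dyp[1:8]) / pmax(abs(yp[1:8]), 1e-8))
      if (mp < steady_tol) {
        y <- stats::setNames(yp, .OX_STATES)
        metric <- mp
        break
      }
      if (stalls >= 4) {
        stop("numerical error: oxidizer integration stalled repeatedly")
      }
    }
  }
  converged <- metric < steady_tol
  ev <- rhs(0, y, NULL)
  airflow <- ev$airflow
  infeasible <- airflow >= cfg$controller$bounds[2] - 1e-9 &&
    y[["do"]] < cfg$controller$setpoint - 0.01
  if (infeasible) {
    warning("oxidizer control infeasible: air demand exceeds the maximum ",
            "air flow; DO below set-point")
  }

  # S conservation at the converged state (flows + accumulation)
  sidx <- 1:4
  dy <- ev[[1L]]
  s_in <- sum(fv[1:4]) * Q * 1000
  s_out <- sum(y[sidx]) * Q * 1000
  s_acc <- sum(dy[sidx]) * cfg$volume * 1000
  audit <- c(S = abs(s_in - s_out - s_acc) / max(s_in, 1e-9))

  eff_sol <- c(y[1:5])
  names(eff_sol) <- .OX_STATES[1:5]
  effluent <- liquid_stream(Q, feed$totals, temperature = 35,
                            solutes = eff_sol)
  list(
    effluent = effluent,
    biosulfur_kg_h = Q * y[["s0_s"]], # g/L * m^3/h = kg/h
    air_demand_m3_h = airflow,
    do_mg_l = y[["do"]],
    states = y,
    converged = converged,
    infeasible = infeasible,
    audit = audit,
    trajectory = traj
  )
}
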