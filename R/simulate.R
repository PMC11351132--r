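#' Simulator parameters for a VHG ethanol fermentation cycle
#'
#' Kinetic constants, sensor maps, temperature-cascade setpoints, noise scales
#' and between-experiment variability for the very-high-gravity (VHG)
#' fermentation simulator. The kinetic core is Monod growth with linear
#' ethanol inhibition and a substrate-gated maintenance term:
#' \deqn{dX/dt = \mu_{max} \frac{S}{K_s+S} \max(0, 1-P/P_{max}) X}
#' \deqn{dS/dt = -(1/Y_{xs}) dX/dt - m \frac{S}{K_s+S} X, \quad
#'       dP/dt = -Y_{ps} \, dS/dt}
#' Defaults are tuned so a noise-free cycle converts ~230 g/L of sugar and
#' plateaus near 108 g/L ethanol over 10 h, with the temperature cascade
#' stepping 34 -> 28 degC in 2 degC drops keyed to ethanol concentration.
#'
#' @param duration_h Cycle duration in hours.
#' @param n_points Number of evenly spaced grid points (1-min-scale sampling).
#' @param mu_max Maximum specific growth rate (1/h).
#' @param K_s Substrate affinity constant (g/L).
#' @param Y_ps Ethanol yield on substrate (g/g).
#' @param Y_xs Cell yield on substrate (g/g).
#' @param m Maintenance coefficient (g substrate / g cells / h).
#' @param P_max Ethanol concentration at full growth inhibition (g/L).
#' @param S0,X0,P0 Initial substrate, cells, ethanol (g/L).
#' @param cascade_levels Temperature setpoints (degC), strictly decreasing in
#'   2 degC steps.
#' @param cascade_thresholds Ethanol concentrations (g/L) triggering each
#'   drop; strictly increasing, length `length(cascade_levels) - 1`.
#' @param aeration_trigger Ethanol concentration (g/L) starting micro-aeration.
#' @param aeration_window_h Length of the aeration window (h); flagged only,
#'   no kinetic effect.
#' @param cap_gain,cap_baseline Capacitance map: pF/cm per g/L viable cells
#'   and baseline pF/cm.
#' @param redox_baseline,redox_coeff Redox map: baseline mV and decline per
#'   g/L ethanol.
#' @param pH_setpoint,pH_drift pH control setpoint and drift amplitude.
#' @param noise_sd Named numeric vector of additive Gaussian noise standard
#'   deviations, one per channel (see [ferm_channels()]).
#' @param between_experiment_cv Coefficient of variation of the lognormal
#'   multipliers applied per experiment to the kinetic constants and initial
#'   conditions.
#' @return A `ferm_sim_params` list.
#' @export
ferm_sim_params <- function(duration_h = 10, n_points = 500,
                            mu_max = 0.08, K_s = 5, Y_ps = 0.47,
                            Y_xs = 0.05, m = 0.12, P_max = 125,
                            S0 = 232, X0 = 30, P0 = 0,
                            cascade_levels = c(34, 32, 30, 28),
                            cascade_thresholds = c(30, 60, 90),
                            aeration_trigger = 108,
                            aeration_window_h = 3.5,
                            cap_gain = 0.9, cap_baseline = 2,
                            redox_baseline = -80, redox_coeff = 0.9,
                            pH_setpoint = 4.5, pH_drift = 0.15,
                            noise_sd = c(pH = 0.02, redox = 3,
                                         capacitance = 0.5,
                                         temperature = 0.05,
                                         ethanol = 1.5, substrate = 2.5,
                                         cells = 0.5),
                            between_experiment_cv = 0.05) {
  p <- list(duration_h = duration_h, n_points = as.integer(n_points),
            mu_max = mu_max, K_s = K_s, Y_ps = Y_ps, Y_xs = Y_xs, m = m,
            P_max = P_max, S0 = S0, X0 = X0, P0 = P0,
            cascade_levels = cascade_levels,
            cascade_thresholds = cascade_thresholds,
            aeration_trigger = aeration_trigger,
            aeration_window_h = aeration_window_h,
            cap_gain = cap_gain, cap_baseline = cap_baseline,
            redox_baseline = redox_baseline, redox_coeff = redox_coeff,
            pH_setpoint = pH_setpoint, pH_drift = pH_drift,
            noise_sd = noise_sd,
            between_experiment_cv = between_experiment_cv)
  validate_sim_params(p)
  structure(p, class = "ferm_sim_params")
}

validate_sim_params <- function(p) {
  if (p$n_points < 2L) stop("n_points must be >= 2")
  if (p$duration_h <= 0) stop("duration_h must be positive")
  conc <- c(p$K_s, p$Y_ps, p$Y_xs, p$m, p$P_max, p$S0, p$X0, p$P0, p$mu_max)
  if (any(conc < 0)) stop("concentrations, yields and rates must be >= 0")
  dl <- diff(p$cascade_levels)
  if (any(dl != -2)) stop("cascade_levels must decrease in 2 degC steps")
  if (length(p$cascade_thresholds) != length(p$cascade_levels) - 1L) {
    stop("cascade_thresholds must have length(cascade_levels) - 1 entries")
  }
  if (any(diff(p$cascade_thresholds) <= 0)) {
    stop("cascade_thresholds must be strictly increasing")
  }
  miss <- setdiff(FERM_CHANNELS, names(p$noise_sd))
  if (length(miss)) stop("noise_sd missing channels: ",
                         paste(miss, collapse = ", "))
  invisible(p)
}

#' Kinetic right-hand side of the fermentation model
#'
#' Derivatives of (cells, substrate, ethanol) in g/L/h under Monod growth
#' with linear ethanol inhibition and substrate-gated maintenance. All three
#' derivatives vanish when biomass is absent, substrate is exhausted, or (at
#' `m = 0`) ethanol reaches `P_max`.
#'
#' @param state Numeric triple `(X, S, P)` = cells, substrate, ethanol (g/L);
#'   must be non-negative.
#' @param t Time (h); the autonomous model ignores it but the argument is
#'   kept for ODE-solver compatibility.
#' @param params A [ferm_sim_params()] object.
#' @return Numeric triple `(dX/dt, dS/dt, dP/dt)`.
#' @export
kinetic_rhs <- function(state, t, params) {
  if (length(state) != 3L) stop("state must be (cells, substrate, ethanol)")
  if (any(state < 0)) stop("negative state rejected")
  unname(ferm_rhs_core(state, params))
}

## Core derivatives; tolerant to the tiny negative excursions an adaptive
## solver may probe.
ferm_rhs_core <- function(state, p) {
  X <- max(state[1], 0); S <- max(state[2], 0); P <- max(state[3], 0)
  monod <- S / (p$K_s + S)
  inhib <- max(0, 1 - P / p$P_max)
  dX <- p$mu_max * monod * inhib * X
  cons <- dX / p$Y_xs + p$m * monod * X   # substrate consumption, g/L/h
  c(dX, -cons, p$Y_ps * cons)
}

## Lognormal multiplier with mean 1 and coefficient of variation cv.
lognormal_multipliers <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one fermentation experiment
#'
#' Integrates the kinetic model on an even time grid, derives the probe
#' channels through the sensor maps (capacitance affine in cells, redox
#' declining affinely in ethanol, pH drifting around its setpoint), applies
#' the ethanol-keyed temperature cascade, and adds per-channel Gaussian
#' noise. Per-experiment lognormal multipliers (CV `between_experiment_cv`)
#' perturb the kinetic constants and initial conditions before integration.
#' Deterministic for a fixed seed.
#'
#' @param params A [ferm_sim_params()] object.
#' @param seed Integer seed.
#' @param id Experiment identifier.
#' @return A [ferm_experiment()].
#' @export
simulate_experiment <- function(params, seed = 1L, id = "exp1") {
  validate_sim_params(params)
  p <- params
  with_seed(derive_seed(seed, "experiment-params"), {
    mult <- lognormal_multipliers(7, p$between_experiment_cv)
    p$mu_max <- p$mu_max * mult[1]
    p$K_s    <- p$K_s    * mult[2]
    p$Y_ps   <- p$Y_ps   * mult[3]
    p$Y_xs   <- p$Y_xs   * mult[4]
    p$m      <- p$m      * mult[5]
    p$S0     <- p$S0     * mult[6]
    p$X0     <- p$X0     * mult[7]
  })

  time <- seq(0, p$duration_h, length.out = p$n_points)
  sol <- deSolve::ode(
    y = c(X = p$X0, S = p$S0, P = p$P0), times = time,
    func = function(t, y, parms) list(ferm_rhs_core(y, parms)),
    parms = p, method = "lsoda", rtol = 1e-8, atol = 1e-8
  )
  state <- unclass(sol)[, c("X", "S", "P"), drop = FALSE]
  if (any(!is.finite(state))) {
    stop("integration produced non-finite state (mu_max=", signif(p$mu_max, 4),
         ", K_s=", signif(p$K_s, 4), ", S0=", signif(p$S0, 4), ")")
  }
  state[state < 0] <- 0
  X <- state[, "X"]; S <- state[, "S"]; P <- state[, "P"]

  temp_idx <- findInterval(P, p$cascade_thresholds) + 1L
  temperature <- p$cascade_levels[temp_idx]
  capacitance <- p$cap_gain * X + p$cap_baseline
  redox <- p$redox_baseline - p$redox_coeff * P
  pH <- p$pH_setpoint - p$pH_drift * sin(pi * time / p$duration_h)

  data <- cbind(pH = pH, redox = redox, capacitance = capacitance,
                temperature = temperature, ethanol = P, substrate = S,
                cells = X)
  with_seed(derive_seed(seed, "experiment-noise"), {
    for (ch in FERM_CHANNELS) {
      sd_ch <- p$noise_sd[[ch]]
      if (sd_ch > 0) data[, ch] <- data[, ch] + stats::rnorm(nrow(data), 0, sd_ch)
    }
  })

  exp <- ferm_experiment(time, data, id = id, provenance = "original")
  cross <- which(P >= p$aeration_trigger)
  attr(exp, "aeration_start_h") <- if (length(cross)) time[cross[1]] else NA_real_
  exp
}

#' Specify a sensor fault
#'
#' @param kind `"missing_channel"` (entire channel unrecorded) or
#'   `"offset_channel"` (constant additive bias, e.g. an uncalibrated probe).
#' @param channel One of the four input channels
#'   (`pH`, `redox`, `capacitance`, `temperature`).
#' @param offset Offset in channel units (required for `offset_channel`).
#' @param experiment_index 1-based index of the affected experiment in the
#'   study collection.
#' @return A `ferm_fault` list.
#' @export
fault_spec <- function(kind = c("missing_channel", "offset_channel"),
                       channel, offset = NULL, experiment_index = 1L) {
  kind <- match.arg(kind)
  if (!channel %in% FERM_INPUT_CHANNELS) {
    stop("fault channel must be one of: ",
         paste(FERM_INPUT_CHANNELS, collapse = ", "))
  }
  if (kind == "offset_channel") {
    if (is.null(offset) || !is.finite(offset)) {
      stop("offset_channel requires a finite offset")
    }
  } else {
    offset <- NULL
  }
  structure(list(kind = kind, channel = channel, offset = offset,
                 experiment_index = as.integer(experiment_index)),
            class = "ferm_fault")
}

#' Default fault plan for a simulated study
#'
#' One experiment with a completely failed redox probe and one with a
#' systematically offset (uncalibrated) capacitance probe, on distinct
#' experiments.
#'
#' @param missing_index,offset_index Affected experiment indices.
#' @param capacitance_offset Offset in pF/cm.
#' @return List of [fault_spec()] objects.
#' @export
default_fault_plan <- function(missing_index = 4L, offset_index = 9L,
                               capacitance_offset = 10) {
  list(
    fault_spec("missing_channel", "redox", experiment_index = missing_index),
    fault_spec("offset_channel", "capacitance", offset = capacitance_offset,
               experiment_index = offset_index)
  )
}

#' Inject a sensor fault into an experiment
#'
#' `missing_channel` masks the whole channel as missing (`NA`);
#' `offset_channel` adds a constant offset, leaving the missing mask
#' untouched. All other channels are returned bit-identical.
#'
#' @param series A [ferm_experiment()].
#' @param fault A [fault_spec()].
#' @return The modified `ferm_experiment`.
#' @export
inject_fault <- function(series, fault) {
  stopifnot(inherits(series, "ferm_experiment"), inherits(fault, "ferm_fault"))
  if (!fault$channel %in% colnames(series$data)) {
    stop("fault channel not present: ", fault$channel)
  }
  if (fault$kind == "missing_channel") {
    series$data[, fault$channel] <- NA_real_
    series$faults <- c(series$faults, paste0("missing_channel:", fault$channel))
  } else if (fault$kind == "offset_channel") {
    series$data[, fault$channel] <- series$data[, fault$channel] + fault$offset
    series$faults <- c(series$faults,
                       paste0("offset_channel:", fault$channel, ":",
                              format(fault$offset)))
  } else {
    stop("unknown fault kind: ", fault$kind)
  }
  series
}

#' Simulate a multi-cycle fermentation study
#'
#' Generates `n_experiments` cycles with hierarchically derived sub-seeds
#' (adding experiments never perturbs earlier ones) and applies the fault
#' plan. The default plan reproduces the two probe problems of the emulated
#' study: one fully missing redox channel and one offset capacitance channel.
#'
#' @param params A [ferm_sim_params()] object.
#' @param n_experiments Number of cycles (default 11).
#' @param fault_plan List of [fault_spec()] objects (may be empty).
#' @param seed Integer study seed.
#' @return A [ferm_collection()] with provenance `"original"`.
#' @export
simulate_study <- function(params = ferm_sim_params(), n_experiments = 11L,
                           fault_plan = default_fault_plan(), seed = 1L) {
  if (n_experiments < 2L) stop("n_experiments must be >= 2")
  idx <- vapply(fault_plan, `[[`, integer(1), "experiment_index")
  if (length(idx) && (any(idx < 1L) || any(idx > n_experiments))) {
    stop("fault experiment_index out of range 1..", n_experiments)
  }
  experiments <- lapply(seq_len(n_experiments), function(i) {
    simulate_experiment(params, seed = derive_seed(seed, "study", i),
                        id = sprintf("exp%02d", i))
  })
  for (fault in fault_plan) {
    i <- fault$experiment_index
    experiments[[i]] <- inject_fault(experiments[[i]], fault)
  }
  ferm_collection(experiments)
}
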