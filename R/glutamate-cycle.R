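# Compartmental glutamate/glutamine/GABA cycling between the extracellular
# space, the astrocyte and the GABAergic neuron:
#   glu_ecm --MM uptake--> glu_astro --GS (caps at 90%)--> gln_astro
#     --export--> gln_neuron --glutaminase--> glu_neuron --GAD--> gaba_neuron
# Optional neuronal re-release (glu_neuron -> glu_ecm) and an exogenous
# extracellular input close/open the loop; with both at their defaults the
# cycle is closed and total glutamate-carbon is conserved.

.nrl_cycle_pools <- c("glu_ecm", "glu_astro", "gln_astro", "gln_neuron",
                      "glu_neuron", "gaba_neuron")
.nrl_cycle_state <- c(.nrl_cycle_pools,
                      "atp_consumed", "cum_uptake", "cum_converted",
                      "cum_input")

#' Construct a glutamate-cycle state
#'
#' @param time Time, s.
#' @param pools Named numeric vector over
#'   `glu_ecm, glu_astro, gln_astro, gln_neuron, glu_neuron, gaba_neuron`
#'   (mol/m^3); missing names default to 0.
#' @param atp_consumed Cumulative ATP expenditure, mol/m^3.
#' @return An object of class `nrl_cycle_state`.
#' @export
cycle_state <- function(time = 0, pools = c(glu_ecm = 0.53),
                        atp_consumed = 0) {
  x <- stats::setNames(numeric(length(.nrl_cycle_state)), .nrl_cycle_state)
  unknown <- setdiff(names(pools), .nrl_cycle_pools)
  if (length(unknown)) {
    stop("unknown pool(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  x[names(pools)] <- pools
  x["atp_consumed"] <- atp_consumed
  if (any(x < 0)) stop("pools must be >= 0", call. = FALSE)
  structure(list(time = time, conc = x), class = "nrl_cycle_state")
}

# Smooth completion switch: C1 smoothstep that is exactly 1 well below the
# cap and exactly 0 at/above it (a logistic tail would let conversion creep
# past the cap over long horizons).
.nrl_gs_switch <- function(frac, cap, width) {
  s <- (cap - frac) / (width * cap)
  s <- pmin(pmax(s, 0), 1)
  s * s * (3 - 2 * s)
}

# Internal RHS over the named state vector; `cy` is params$cycle.
.nrl_cycle_rates <- function(x, cy) {
  uptake <- cy$uptake_Vmax * x[["glu_ecm"]] / (cy$uptake_KM + x[["glu_ecm"]])
  frac <- x[["cum_converted"]] / max(x[["cum_uptake"]], 1e-300)
  gs_unc <- cy$gs_rate * x[["glu_astro"]]
  gs <- if (cy$switch == "hard") {
    # projected cap: the flux is limited to the value that steers the
    # converted fraction onto the boundary (cap * uptake holds it there, the
    # gain term pulls it back after overshoot).  A raw on/off switch
    # chatters on the boundary and defeats the stiff integrator.
    cap <- cy$completion_cap
    allowed <- cap * uptake + 100 * (cap - frac) * x[["cum_uptake"]]
    min(gs_unc, max(0, allowed))
  } else {
    gs_unc * .nrl_gs_switch(frac, cy$completion_cap, cy$switch_width)
  }
  export <- cy$gln_transfer_rate * x[["gln_astro"]]
  glnase <- cy$glnase_rate * x[["gln_neuron"]]
  gad <- cy$gad_rate * x[["glu_neuron"]]
  rerelease <- cy$release_rate * x[["glu_neuron"]]
  c(glu_ecm = cy$ecm_input + rerelease - uptake,
    glu_astro = uptake - gs,
    gln_astro = gs - export,
    gln_neuron = export - glnase,
    glu_neuron = glnase - gad - rerelease,
    gaba_neuron = gad,
    atp_consumed = cy$atp_per_glu * uptake,
    cum_uptake = uptake,
    cum_converted = gs,
    cum_input = cy$ecm_input)
}

#' Time derivatives of the glutamate-cycle pools
#'
#' Astrocytic uptake is Michaelis-Menten in extracellular glutamate; the
#' glutamine-synthetase flux is first-order in astrocytic glutamate and shuts
#' off smoothly once the cumulative converted fraction reaches the completion
#' cap (default 90% of cumulative uptake); glutaminase, glutamine export and
#' glutamate decarboxylase are first-order stages; ATP accrues at
#' `atp_per_glu` per glutamate taken up (NH3 is constant and folded into the
#' conversion rate).
#'
#' @param state An `nrl_cycle_state`.
#' @param params An `nrl_params` bundle (uses `$cycle`).
#' @return Named numeric vector of time derivatives (mol/(m^3 s)) over the
#'   pools and cumulative trackers.
#' @export
cycle_rhs <- function(state, params) {
  stopifnot(inherits(state, "nrl_cycle_state"), inherits(params, "nrl_params"))
  .nrl_cycle_rates(state$conc, params$cycle)
}

#' Integrate the glutamate cycle
#'
#' @param state0 Initial `nrl_cycle_state`; defaults to the post-injury
#'   extracellular level in `params$cycle$glu_ecm0`.
#' @param params An `nrl_params` bundle.
#' @param t_end End time, s (> 0); defaults to `params$cycle$t_end`.
#' @param dt_out Output sampling interval, s.
#' @param rtol,atol Integrator tolerances.
#' @return A data frame of class `nrl_cycle_trajectory` with `time`, the six
#'   pools, `atp_consumed`, `cum_uptake`, `cum_converted`, `cum_input`.
#' @export
integrate_cycle <- function(state0 = NULL, params, t_end = NULL,
                            dt_out = 0.1, rtol = 1e-10, atol = 1e-14) {
  stopifnot(inherits(params, "nrl_params"))
  cy <- params$cycle
  if (is.null(state0)) {
    state0 <- cycle_state(pools = c(glu_ecm = cy$glu_ecm0))
  }
  if (is.null(t_end)) t_end <- cy$t_end
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  rhs <- function(t, y, parms) {
    list(unname(.nrl_cycle_rates(stats::setNames(y, .nrl_cycle_state), cy)))
  }
  times <- seq(state0$time, state0$time + t_end, by = dt_out)
  out <- deSolve::lsoda(y = unname(state0$conc), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    cond <- simpleError("cycle integrator failed")
    cond$last_state <- out[nrow(out), ]
    stop(cond)
  }
  traj <- as.data.frame(out)
  names(traj) <- c("time", .nrl_cycle_state)
  traj[traj < 0 & as.matrix(traj) > -1e3 * atol] <- 0
  class(traj) <- c("nrl_cycle_trajectory", "data.frame")
  traj
}

#' Times at which extracellular glutamate crosses thresholds
#'
#' For each threshold, the first time `glu_ecm` falls below it (linear
#' interpolation between samples); the excitotoxicity band of interest is
#' 0.05-0.10 mM.
#'
#' @param trajectory An `nrl_cycle_trajectory`.
#' @param thresholds Numeric vector of thresholds, mol/m^3 (= mM).
#' @return Named numeric vector of crossing times, s; `NA_real_` where a
#'   threshold is never reached.
#' @export
threshold_times <- function(trajectory, thresholds = c(0.10, 0.05)) {
  if (!nrow(trajectory)) stop("trajectory is empty", call. = FALSE)
  y <- trajectory$glu_ecm
  tt <- trajectory$time
  vapply(thresholds, function(thr) {
    if (y[1] < thr) return(tt[1])
    below <- which(y < thr)
    if (!length(below)) return(NA_real_)
    i <- below[1]
    tt[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (tt[i] - tt[i - 1])
  }, numeric(1), USE.NAMES = FALSE) -> out
  stats::setNames(out, paste0("below_", thresholds))
}

#' Minimum extracellular glutamate over a trajectory
#'
#' @param trajectory An `nrl_cycle_trajectory`.
#' @return Minimum of `glu_ecm`, mol/m^3 (numerically equal to mM).
#' @export
min_extracellular_glu <- function(trajectory) {
  if (!nrow(trajectory)) stop("trajectory is empty", call. = FALSE)
  min(trajectory$glu_ecm)
}

#' Asymptotic converted fraction of the glutamine-synthetase stage
#'
#' @param trajectory An `nrl_cycle_trajectory`.
#' @return `cum_converted / cum_uptake` at the final sample (dimensionless).
#' @export
conversion_fraction <- function(trajectory) {
  n <- nrow(trajectory)
  if (!n) stop("trajectory is empty", call. = FALSE)
  trajectory$cum_converted[n] / max(trajectory$cum_uptake[n], 1e-300)
}

# Total glutamate-carbon; constant along closed-cycle runs (ecm_input
# contributions are subtracted via the cum_input tracker).
.nrl_cycle_carbon <- function(trajectory) {
  rowSums(trajectory[, .nrl_cycle_pools]) - trajectory$cum_input
}
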