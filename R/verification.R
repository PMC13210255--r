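# Numerical-verification studies: mesh convergence at the 1% criterion,
# time-step independence with an oscillation detector, and conservation
# audits for batch, cycle and spatial runs.

#' Mesh-convergence study
#'
#' Runs the spatial scenario at successive uniform x2 refinements of the
#' grid and tracks the maximum concentration (over cells and stored times)
#' of one species.  The grid is considered converged when the relative
#' change `|m_{k+1} - m_k| / m_{k+1}` between the two finest levels falls
#' below the criterion (default 1%).
#'
#' @param base_params An `nrl_params` bundle; level 1 uses its `nr`/`nz`.
#' @param levels Number of refinement levels (>= 2).
#' @param species Tracked species (default the released scaffold `SC`,
#'   standing in for the free glutamate-bearing payload).
#' @param criterion Pass threshold on the finest relative change.
#' @return An object of class `nrl_convergence_report`: data frame of
#'   levels (`nr`, `nz`, `metric`, `rel_change`) plus attributes `pass`,
#'   `criterion`, `species`, and `incomplete`/`cause` if a level failed.
#' @export
mesh_convergence_study <- function(base_params, levels = 3, species = NULL,
                                   criterion = 0.01) {
  stopifnot(inherits(base_params, "nrl_params"))
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  if (is.null(species)) species <- base_params$spatial$tracked_species
  nr0 <- base_params$spatial$nr
  nz0 <- base_params$spatial$nz
  rows <- list()
  cause <- NULL
  for (k in seq_len(levels)) {
    p <- base_params
    p$spatial$nr <- nr0 * 2^(k - 1)
    p$spatial$nz <- nz0 * 2^(k - 1)
    metric <- tryCatch(max_concentration(run_spatial(p), species),
                       error = function(e) e)
    if (inherits(metric, "error")) {
      cause <- conditionMessage(metric)
      break
    }
    rows[[k]] <- data.frame(level = k, nr = p$spatial$nr, nz = p$spatial$nz,
                            metric = metric)
  }
  if (length(rows) == 0) {
    rep <- data.frame(level = integer(), nr = integer(), nz = integer(),
                      metric = numeric())
  } else {
    rep <- do.call(rbind, rows)
  }
  rep$rel_change <- c(if (nrow(rep) > 0) NA,
                      abs(diff(rep$metric)) / rep$metric[-1])
  n <- nrow(rep)
  pass <- n == levels && is.finite(rep$rel_change[n]) &&
    rep$rel_change[n] < criterion
  structure(rep, class = c("nrl_convergence_report", "data.frame"),
            pass = pass, criterion = criterion, species = species,
            incomplete = !is.null(cause), cause = cause)
}

# Fixed-step RK4 batch trajectory (time-step study; the production batch
# integrator is adaptive and would hide the dt dependence).
.nrl_batch_rk4 <- function(state0, params, dt, t_end) {
  k <- params$kinetics
  rhs <- function(t, y, parms) {
    r <- .nrl_net_rates(y[1], y[2], y[3], y[4], y[5],
                        k$kf1, k$kr1, k$Vmax, k$KM, k$Ssa)
    list(c(r$SC, r$p, r$pSC, r$mp, r$mpSC, 0, r$GABA, r$CO2))
  }
  times <- seq(0, t_end, by = dt)
  out <- deSolve::rk4(y = unname(state0$conc), times = times, func = rhs,
                      parms = NULL)
  traj <- as.data.frame(out)
  names(traj) <- c("time", .nrl_batch_species)
  traj
}

# Oscillation detector: TRUE when the series shows alternating first
# differences whose magnitudes both exceed tol * range (numerical ringing,
# as opposed to smooth non-monotonicity).
.nrl_oscillates <- function(y, tol = 1e-3) {
  if (any(!is.finite(y))) return(TRUE)
  d <- diff(y)
  rng <- max(abs(y)) - min(abs(y))
  scale <- max(rng, max(abs(y)) * 1e-12, .Machine$double.xmin)
  big <- abs(d) > tol * scale
  sgn <- sign(d)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0 & big[-1] & big[-length(big)])
  length(flips) >= 2
}

#' Time-step independence study
#'
#' Re-integrates the default batch transient with a fixed-step RK4 march at
#' each candidate time step, compares the tracked series against the finest
#' step (sup-norm at the coarsest common sample times), and flags numerical
#' oscillation (alternating-sign differences beyond tolerance) per run.
#'
#' @param base_params An `nrl_params` bundle.
#' @param dts Candidate time steps, s (>= 2 distinct values).
#' @param species Tracked species (default `mpSC`).
#' @param t_end Transient length, s (default the spatial `t_end`).
#' @return An object of class `nrl_dt_report`: data frame with `dt`,
#'   `sup_diff` (vs the finest dt), `oscillation`.
#' @export
timestep_study <- function(base_params, dts = c(0.02, 0.01, 0.005),
                           species = "mpSC", t_end = NULL) {
  stopifnot(inherits(base_params, "nrl_params"))
  dts <- sort(unique(dts), decreasing = TRUE)
  if (length(dts) < 2) stop("need >= 2 distinct time steps", call. = FALSE)
  if (is.null(t_end)) t_end <- base_params$spatial$t_end
  ld <- base_params$loading
  state0 <- equilibrate(ld$total_scaffold, ld$total_peptide,
                        ld$bound_fraction, base_params)
  runs <- lapply(dts, function(dt) {
    tryCatch(.nrl_batch_rk4(state0, base_params, dt, t_end),
             error = function(e) NULL)
  })
  common <- seq(0, t_end, by = dts[1])
  fine <- runs[[length(runs)]]
  pick <- function(traj) {
    if (is.null(traj)) return(rep(NaN, length(common)))
    stats::approx(traj$time, traj[[species]], xout = common)$y
  }
  fine_y <- pick(fine)
  rep <- data.frame(
    dt = dts,
    sup_diff = vapply(runs, function(tr) {
      d <- abs(pick(tr) - fine_y)
      if (any(!is.finite(d))) Inf else max(d)
    }, numeric(1)),
    oscillation = vapply(runs, function(tr) {
      is.null(tr) || .nrl_oscillates(tr[[species]])
    }, logical(1)))
  structure(rep, class = c("nrl_dt_report", "data.frame"),
            species = species, t_end = t_end)
}

#' Conservation audit
#'
#' Maximum relative drift of each conserved quantity along a run: scaffold
#' and peptide moieties plus the enzyme for batch trajectories and spatial
#' records, total glutamate-carbon for cycle trajectories.  Pass thresholds:
#' 1e-8 relative for ODE (batch/cycle) runs, 1e-6 for spatial runs.
#'
#' @param x An `nrl_batch_trajectory`, `nrl_cycle_trajectory` or
#'   `nrl_spatial_record`.
#' @param params An `nrl_params` bundle (needed for batch trajectories;
#'   spatial records carry their own).
#' @return List with `drift` (named relative drifts), `tolerance`, `pass`.
#' @export
conservation_audit <- function(x, params = NULL) {
  rel_drift <- function(series) {
    ref <- abs(series[1])
    if (ref == 0) return(max(abs(series)))
    max(abs(series - series[1])) / ref
  }
  if (inherits(x, "nrl_batch_trajectory")) {
    stopifnot(inherits(params, "nrl_params"))
    m <- .nrl_trajectory_moieties(x, params)
    drift <- c(scaffold_moiety = rel_drift(m$scaffold_moiety),
               peptide_moiety = rel_drift(m$peptide_moiety),
               enzyme = rel_drift(m$enzyme))
    tol <- 1e-8
  } else if (inherits(x, "nrl_cycle_trajectory")) {
    drift <- c(glutamate_carbon = rel_drift(.nrl_cycle_carbon(x)))
    tol <- 1e-8
  } else if (inherits(x, "nrl_spatial_record")) {
    ssa <- x$params$kinetics$Ssa
    tot <- t(vapply(x$fields,
                    function(f) .nrl_spatial_moieties(f, x$grid, ssa),
                    numeric(3)))
    drift <- apply(tot, 2, rel_drift)
    tol <- 1e-6
  } else {
    stop("unsupported input for conservation_audit", call. = FALSE)
  }
  list(drift = drift, tolerance = tol, pass = all(drift < tol))
}
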