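# Well-mixed ("batch reactor") model of the five-species release network:
#   SC + p   <-> pSC     (kf1 / kr1)
#   SC + mp  <-> mpSC    (kf1 / kr1)
#   mp   --MM--> p       (enzymatic matrix degradation)
#   mpSC --MM--> pSC + GABA + CO2
# Bulk species (SC, p, pSC, GABA, CO2, enzyme) are mol/m^3; matrix-bound
# species (mp, mpSC) are per-area (mol/m^2) and enter bulk balances times
# the specific surface area Ssa.

.nrl_batch_species <- c("SC", "p", "pSC", "mp", "mpSC", "enzyme", "GABA", "CO2")

#' Michaelis-Menten rate
#'
#' Saturating enzymatic rate `Vmax * c / (KM + c)`; bounded above by `Vmax`,
#' first-order with slope `Vmax/KM` for `c << KM`.
#'
#' @param c Substrate concentration, mol/m^3 (>= 0); vectorised.
#' @param Vmax Maximum rate, mol/(m^3 s) (>= 0).
#' @param KM Michaelis constant, mol/m^3 (> 0).
#' @return Rate in mol/(m^3 s).
#' @export
mm_rate <- function(c, Vmax, KM) {
  if (!is.numeric(KM) || length(KM) != 1 || !is.finite(KM) || KM <= 0) {
    stop("KM must be a single positive number", call. = FALSE)
  }
  if (any(c < 0) || Vmax < 0) {
    stop("c and Vmax must be non-negative", call. = FALSE)
  }
  Vmax * c / (KM + c)
}

#' Construct a batch-reactor state
#'
#' @param time Time in seconds.
#' @param conc Named numeric vector over the eight batch species
#'   (`SC, p, pSC, mp, mpSC, enzyme, GABA, CO2`); missing names default to 0.
#'   Bulk species in mol/m^3, matrix-bound (`mp`, `mpSC`) in mol/m^2.
#' @return An object of class `nrl_batch_state`.
#' @export
batch_state <- function(time = 0, conc = numeric()) {
  x <- stats::setNames(numeric(length(.nrl_batch_species)), .nrl_batch_species)
  if (length(conc)) {
    unknown <- setdiff(names(conc), .nrl_batch_species)
    if (length(unknown)) {
      stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    x[names(conc)] <- conc
  }
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(list(time = time, conc = x), class = "nrl_batch_state")
}

# Internal RHS shared by the batch integrator and the spatial solver.
# Arguments are plain numerics/vectors; no validation (hot path).  `vmax`
# may be 0 to disable degradation (cellular zone / surrounding media).
.nrl_net_rates <- function(csc, cp, cpsc, cmp, cmpsc, kf1, kr1, vmax, km, ssa) {
  cmp_b <- cmp * ssa    # matrix-bound pools as bulk-equivalents
  cmpsc_b <- cmpsc * ssa
  RMMmp <- vmax * cmp_b / (km + cmp_b)
  RMMmpsc <- vmax * cmpsc_b / (km + cmpsc_b)
  assoc_p <- kf1 * csc * cp - kr1 * cpsc      # SC + p -> pSC net
  assoc_mp <- kf1 * csc * cmp - kr1 * cmpsc   # SC + mp -> mpSC net (per area)
  list(
    SC = -(assoc_p + assoc_mp * ssa),
    p = -assoc_p + RMMmp,
    pSC = assoc_p + RMMmpsc,
    mp = -assoc_mp - RMMmp / ssa,
    mpSC = assoc_mp - RMMmpsc / ssa,
    GABA = RMMmpsc,   # decarboxylation of the liberated PGA shell
    CO2 = RMMmpsc,
    RMMmp = RMMmp,
    RMMmpSC = RMMmpsc
  )
}

#' Net reaction rates of the release network
#'
#' Evaluates the full binding/dissociation + Michaelis-Menten degradation
#' rate expressions at a state.  The enzyme is inert (its concentration is
#' folded into `Vmax`), and GABA/CO2 are produced 1:1 with the degradation of
#' the scaffold-bearing matrix complex mpSC.
#'
#' @param state An `nrl_batch_state`.
#' @param params An `nrl_params` bundle (uses `$kinetics`).
#' @return A list of class `nrl_rate_terms`: net rate per species (mol/(m^3 s)
#'   for bulk, mol/(m^2 s) for `mp`/`mpSC`) plus the two degradation fluxes
#'   `RMMmp` and `RMMmpSC` (mol/(m^3 s)).
#' @export
rate_vector <- function(state, params) {
  stopifnot(inherits(state, "nrl_batch_state"), inherits(params, "nrl_params"))
  x <- state$conc
  if (any(x < 0)) {
    stop("negative concentration in state; integration contract violated",
         call. = FALSE)
  }
  k <- params$kinetics
  r <- .nrl_net_rates(x[["SC"]], x[["p"]], x[["pSC"]], x[["mp"]], x[["mpSC"]],
                      k$kf1, k$kr1, k$Vmax, k$KM, k$Ssa)
  r$enzyme <- 0
  structure(r[c(.nrl_batch_species, "RMMmp", "RMMmpSC")],
            class = "nrl_rate_terms")
}

#' Partition depot loadings at binding equilibrium
#'
#' Distributes the total scaffold and peptide loadings among SC, p, pSC, mp
#' and mpSC so that both association reactions satisfy detailed balance
#' (`kf1*cSC*cp = kr1*cpSC` and `kf1*cSC*cmp = kr1*cmpSC`) while conserving
#' both moiety totals exactly; the release network starts "in balance" before
#' the onset of release.
#'
#' @param total_scaffold Total scaffold moiety, mol/m^3-equivalent.
#' @param total_peptide Total peptide moiety, mol/m^3-equivalent.
#' @param bound_fraction Fraction of the peptide moiety immobilised on the
#'   matrix (mp + mpSC side), in `[0, 1]`.
#' @param params An `nrl_params` bundle.
#' @return An `nrl_batch_state` at `time = 0` with enzyme at
#'   `params$kinetics$enzyme0` and GABA/CO2 at 0.
#' @export
equilibrate <- function(total_scaffold, total_peptide, bound_fraction,
                        params) {
  stopifnot(inherits(params, "nrl_params"))
  if (total_scaffold < 0 || total_peptide < 0) {
    stop("loadings must be >= 0", call. = FALSE)
  }
  if (bound_fraction < 0 || bound_fraction > 1) {
    stop("bound_fraction must lie in [0, 1]", call. = FALSE)
  }
  k <- params$kinetics
  K <- k$kf1 / k$kr1
  # Free-scaffold root of  K*s^2 + (1 + K*(TP - TS))*s - TS = 0
  b <- 1 + K * (total_peptide - total_scaffold)
  disc <- b * b + 4 * K * total_scaffold
  s <- if (K > 0) (-b + sqrt(disc)) / (2 * K) else total_scaffold
  if (!is.finite(s) || s < -1e-15) {
    stop("internal error: no admissible equilibrium root", call. = FALSE)
  }
  s <- max(s, 0)
  denom <- 1 + K * s
  cp <- (1 - bound_fraction) * total_peptide / denom
  cmp_b <- bound_fraction * total_peptide / denom # cmp * Ssa
  batch_state(time = 0, conc = c(
    SC = s, p = cp, pSC = K * s * cp,
    mp = cmp_b / k$Ssa, mpSC = K * s * cmp_b / k$Ssa,
    enzyme = k$enzyme0, GABA = 0, CO2 = 0))
}

#' Integrate the batch reactor
#'
#' Stiff-safe integration of the release network with `deSolve::lsoda`,
#' sampled on a uniform output grid.
#'
#' @param state0 Initial `nrl_batch_state` (typically from [equilibrate()]).
#' @param params An `nrl_params` bundle.
#' @param t_end End time, s (> 0).
#' @param dt_out Output sampling interval, s.
#' @param rtol,atol Integrator tolerances.
#' @return A data frame of class `nrl_batch_trajectory` with columns `time`
#'   and one column per species.
#' @export
integrate_batch <- function(state0, params, t_end = 60, dt_out = 0.05,
                            rtol = 1e-10, atol = 1e-14) {
  stopifnot(inherits(state0, "nrl_batch_state"), inherits(params, "nrl_params"))
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  k <- params$kinetics
  rhs <- function(t, y, parms) {
    r <- .nrl_net_rates(y[1], y[2], y[3], y[4], y[5],
                        k$kf1, k$kr1, k$Vmax, k$KM, k$Ssa)
    list(c(r$SC, r$p, r$pSC, r$mp, r$mpSC, 0, r$GABA, r$CO2))
  }
  times <- seq(state0$time, state0$time + t_end, by = dt_out)
  out <- deSolve::lsoda(y = unname(state0$conc), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    last <- out[nrow(out), ]
    cond <- simpleError(paste0("batch integrator failed at t = ", last[1]))
    cond$last_state <- last
    stop(cond)
  }
  traj <- as.data.frame(out)
  names(traj) <- c("time", .nrl_batch_species)
  # lsoda may undershoot zero by ~atol; snap round-off negatives only
  m <- as.matrix(traj)
  if (any(m < -1e3 * atol)) {
    stop("batch integration produced significantly negative concentrations",
         call. = FALSE)
  }
  traj[traj < 0] <- 0
  class(traj) <- c("nrl_batch_trajectory", "data.frame")
  traj
}

#' Time to fall below a fraction of the initial concentration
#'
#' First time at which a species' concentration drops below
#' `fraction * initial`, linearly interpolated between output samples.
#'
#' @param trajectory An `nrl_batch_trajectory` (or any data frame with a
#'   `time` column and a column named for `species`).
#' @param species Species column name.
#' @param fraction Threshold fraction in (0, 1).
#' @return Crossing time in seconds, or `NA_real_` if the threshold is never
#'   reached (the "not reached" sentinel).
#' @export
depletion_time <- function(trajectory, species = "mpSC", fraction = 0.01) {
  if (!nrow(trajectory)) stop("trajectory is empty", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!species %in% names(trajectory)) {
    stop("no such species in trajectory: ", species, call. = FALSE)
  }
  y <- trajectory[[species]]
  thr <- fraction * y[1]
  below <- which(y < thr)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(trajectory$time[1])
  t0 <- trajectory$time[i - 1]; t1 <- trajectory$time[i]
  y0 <- y[i - 1]; y1 <- y[i]
  t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
}

#' Conserved moiety totals of a batch state
#'
#' The closed reactor conserves the scaffold moiety
#' `SC + pSC + mpSC*Ssa` and the peptide moiety
#' `p + pSC + (mp + mpSC)*Ssa` (degradation converts bound to free, binding
#' converts partners; nothing leaves), plus the inert enzyme.
#'
#' @param state An `nrl_batch_state`.
#' @param params An `nrl_params` bundle (for `Ssa`).
#' @return Named numeric vector `c(scaffold_moiety, peptide_moiety, enzyme)`
#'   in mol/m^3.
#' @export
conservation_totals <- function(state, params) {
  stopifnot(inherits(state, "nrl_batch_state"), inherits(params, "nrl_params"))
  x <- state$conc
  ssa <- params$kinetics$Ssa
  c(scaffold_moiety = x[["SC"]] + x[["pSC"]] + x[["mpSC"]] * ssa,
    peptide_moiety = x[["p"]] + x[["pSC"]] + (x[["mp"]] + x[["mpSC"]]) * ssa,
    enzyme = x[["enzyme"]])
}

# Moiety totals for every row of a batch trajectory (used by the audits).
.nrl_trajectory_moieties <- function(trajectory, params) {
  ssa <- params$kinetics$Ssa
  data.frame(
    time = trajectory$time,
    scaffold_moiety = trajectory$SC + trajectory$pSC + trajectory$mpSC * ssa,
    peptide_moiety = trajectory$p + trajectory$pSC +
      (trajectory$mp + trajectory$mpSC) * ssa,
    enzyme = trajectory$enzyme
  )
}
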