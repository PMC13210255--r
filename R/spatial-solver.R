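# 2D axisymmetric finite-volume reaction-diffusion solver on the
# 12 mm x 3 mm tissue cylinder.  Cell-centred structured grid in (r, z);
# all boundaries are no-flux (symmetry axis at r = 0, "symmetric" outer
# boundaries), so the domain is closed and every species total is a
# discrete invariant of the diffusion operator.  Domains: k1 = cellular
# zone, k2 = biomaterial depot, k3 = surrounding media; full kinetics
# (binding + MM degradation) run in k2, binding/dissociation only in
# k1/k3; matrix-bound species live on depot cells and do not diffuse.

#' Build an axisymmetric cell-centred grid
#'
#' Uniform structured grid on the cylinder `0 <= r <= R`, `0 <= z <= L`;
#' cell volumes `2*pi*r_i*dr*dz` sum exactly to `pi*R^2*L`.
#'
#' @param nr,nz Cell counts in r and z (>= 4).
#' @param R Cylinder radius, m (default 3 mm).
#' @param L Cylinder length, m (default 12 mm).
#' @return An object of class `nrl_grid` with cell-centre coordinates `r`,
#'   `z`, spacings `dr`, `dz`, per-row cell volumes `vol_r` (nr) and the
#'   full volume matrix `vol` (nr x nz).
#' @export
build_grid <- function(nr, nz, R = 3e-3, L = 12e-3) {
  if (nr < 4 || nz < 4) stop("nr and nz must be >= 4", call. = FALSE)
  if (R <= 0 || L <= 0) stop("R and L must be > 0", call. = FALSE)
  dr <- R / nr
  dz <- L / nz
  r <- (seq_len(nr) - 0.5) * dr
  z <- (seq_len(nz) - 0.5) * dz
  vol_r <- 2 * pi * r * dr * dz
  structure(list(nr = nr, nz = nz, R = R, L = L, dr = dr, dz = dz,
                 r = r, z = z, r_face = (0:nr) * dr,
                 vol_r = vol_r,
                 vol = matrix(vol_r, nr, nz)),
            class = "nrl_grid")
}

#' Label grid cells with biological domains
#'
#' Classifies every cell centre into the cellular zone (k = 1), the
#' biomaterial depot (k = 2) or the surrounding media (k = 3).  Named
#' presets: `"standard"` puts the depot coaxially at `r <= R/2` over the
#' central third of the length with a cellular end-cap slab over the top
#' sixth (`z >= 5L/6`); `"depot-only"` labels every cell k = 2.  An explicit
#' layout is a list with optional elements `k1` and `k2`, each a list of
#' `r = c(lo, hi)`, `z = c(lo, hi)` extents (cells classified by the
#' centre-in-region rule; unlabelled cells become k = 3).
#'
#' @param layout Preset name or explicit extent list.
#' @param grid An `nrl_grid`.
#' @return Integer matrix (nr x nz) of class `nrl_domain_map` with values
#'   in `{1, 2, 3}`.
#' @export
assign_domains <- function(layout = "standard", grid) {
  stopifnot(inherits(grid, "nrl_grid"))
  map <- matrix(3L, grid$nr, grid$nz)
  rc <- matrix(grid$r, grid$nr, grid$nz)
  zc <- matrix(grid$z, grid$nr, grid$nz, byrow = TRUE)
  if (is.character(layout)) {
    if (layout == "depot-only") {
      map[] <- 2L
    } else if (layout == "standard") {
      map[zc >= 5 * grid$L / 6] <- 1L
      map[rc <= grid$R / 2 & zc >= grid$L / 3 & zc < 2 * grid$L / 3] <- 2L
    } else {
      stop("unknown layout preset: ", layout, call. = FALSE)
    }
  } else if (is.list(layout)) {
    in_region <- function(reg) {
      ok <- matrix(TRUE, grid$nr, grid$nz)
      if (!is.null(reg$r)) ok <- ok & rc >= reg$r[1] & rc <= reg$r[2]
      if (!is.null(reg$z)) ok <- ok & zc >= reg$z[1] & zc <= reg$z[2]
      ok
    }
    if (!is.null(layout$k1)) map[in_region(layout$k1)] <- 1L
    if (!is.null(layout$k2)) map[in_region(layout$k2)] <- 2L
  } else {
    stop("layout must be a preset name or an extent list", call. = FALSE)
  }
  if (!any(map == 2L)) stop("layout leaves the depot empty", call. = FALSE)
  structure(map, class = c("nrl_domain_map", class(map)))
}

#' Axisymmetric finite-volume diffusion operator
#'
#' Divergence of the diffusive flux for one species on the closed cylinder:
#' flux form with face areas `2*pi*r_face*dz` (radial) and `2*pi*r*dr`
#' (axial), zero flux on all boundaries (including the `r = 0` symmetry
#' axis) and harmonic-mean face diffusivity across domain boundaries.  The
#' volume-weighted sum of the result is zero to round-off (discrete
#' conservation).
#'
#' @param field Concentration matrix (nr x nz), mol/m^3.
#' @param D Diffusivity: scalar or per-cell matrix, m^2/s.
#' @param grid An `nrl_grid`.
#' @return Matrix (nr x nz) of `div(D grad c)` values, mol/(m^3 s).
#' @export
axisym_laplacian <- function(field, D, grid) {
  stopifnot(inherits(grid, "nrl_grid"))
  if (!is.matrix(D)) D <- matrix(D, grid$nr, grid$nz)
  .nrl_lap_apply(field, .nrl_lap_coeffs(D, grid), grid)
}

# Precompute per-face transfer coefficients for a (constant-in-time)
# diffusivity map: harmonic-mean face diffusivity times face geometry.
.nrl_lap_coeffs <- function(D, grid) {
  nr <- grid$nr; nz <- grid$nz
  hmean <- function(a, b) {
    s <- a + b
    h <- 2 * a * b
    h[s > 0] <- h[s > 0] / s[s > 0]
    h
  }
  # radial faces between rows i and i+1 sit at r_face[i+1] = i*dr;
  # 2*pi*dz of the face area cancels against the same factor in the volume
  cr <- grid$r_face[2:nr] *
    hmean(D[-nr, , drop = FALSE], D[-1, , drop = FALSE]) / grid$dr
  cz <- hmean(D[, -nz, drop = FALSE], D[, -1, drop = FALSE]) / grid$dz
  list(cr = cr, cz = cz, inv_rdr = 1 / (grid$r * grid$dr), inv_dz = 1 / grid$dz)
}

.nrl_lap_apply <- function(field, co, grid) {
  nr <- grid$nr; nz <- grid$nz
  out <- matrix(0, nr, nz)
  fa <- co$cr * (field[-1, , drop = FALSE] - field[-nr, , drop = FALSE])
  out[-nr, ] <- fa
  out[-1, ] <- out[-1, , drop = FALSE] - fa
  out <- out * co$inv_rdr
  fz <- co$cz * (field[, -1, drop = FALSE] - field[, -nz, drop = FALSE])
  div <- matrix(0, nr, nz)
  div[, -nz] <- fz
  div[, -1] <- div[, -1, drop = FALSE] - fz
  out + div * co$inv_dz
}

# Per-species diffusion operators: per-cell diffusivity (in-water value
# times the per-domain hindrance factor) with precomputed face coefficients.
.nrl_diffusivity_maps <- function(params, domain_map, grid) {
  fac <- params$spatial$domain_factors[domain_map]
  fac <- matrix(fac, nrow(domain_map), ncol(domain_map))
  sp <- params$species
  maps <- list()
  for (s in .nrl_batch_species) {
    i <- match(s, sp$name)
    maps[[s]] <- if (sp$diffusive[i]) {
      D <- sp$D_water[i] * fac
      list(D = D, co = .nrl_lap_coeffs(D, grid))
    } else NULL
  }
  maps
}

#' Time derivatives of all spatial fields
#'
#' Reaction terms: the full release-network rates (including MM degradation)
#' in depot cells, binding/dissociation only (`Vmax` forced to 0) in the
#' cellular zone and surrounding media.  Diffusion for diffusive bulk
#' species only; matrix-bound species are immobile.
#'
#' @param fields Named list of (nr x nz) concentration matrices over the
#'   eight release-network species.
#' @param params An `nrl_params` bundle.
#' @param domain_map An `nrl_domain_map`.
#' @param grid An `nrl_grid`.
#' @param D_maps Optional precomputed per-species diffusion operators
#'   (internal caching; built with the per-domain hindrance factors when
#'   omitted).
#' @return Named list of derivative matrices.
#' @export
spatial_rhs <- function(fields, params, domain_map, grid,
                        D_maps = .nrl_diffusivity_maps(params, domain_map,
                                                       grid)) {
  k <- params$kinetics
  vmax <- k$Vmax * (unclass(domain_map) == 2L)
  r <- .nrl_net_rates(fields$SC, fields$p, fields$pSC, fields$mp,
                      fields$mpSC, k$kf1, k$kr1, vmax, k$KM, k$Ssa)
  d <- list(SC = r$SC, p = r$p, pSC = r$pSC, mp = r$mp, mpSC = r$mpSC,
            enzyme = matrix(0, grid$nr, grid$nz), GABA = r$GABA, CO2 = r$CO2)
  for (s in names(D_maps)) {
    if (!is.null(D_maps[[s]])) {
      d[[s]] <- d[[s]] + .nrl_lap_apply(fields[[s]], D_maps[[s]]$co, grid)
    }
  }
  d
}

#' Run the axisymmetric reaction-diffusion simulation
#'
#' Method-of-lines integration of the spatial model with a fixed-step
#' classical Runge-Kutta (RK4) march at the configured time step (default
#' 0.01 s), storing fields at the requested output times only.  Runge-Kutta
#' steps preserve the linear moiety invariants of the closed domain exactly,
#' so global conservation holds to round-off.
#'
#' @param params An `nrl_params` bundle (geometry, grid size, dt, t_end and
#'   layout preset are read from `$spatial`), or a config path / list
#'   accepted by [load_params()].
#' @param fields0 Optional named list of initial field matrices; defaults to
#'   [make_initial_fields()] on the configured layout and depot loading.
#' @param out_times Output times, s; default is `0` plus a geometric
#'   schedule of 24 points ending at `t_end` (snapped to multiples of `dt`).
#' @param domain_map Optional explicit `nrl_domain_map` overriding the
#'   configured layout preset.
#' @return An object of class `nrl_spatial_record`: list with `times`,
#'   `fields` (list over times of named matrices), `grid`, `domain_map`,
#'   `params`.
#' @export
run_spatial <- function(params, fields0 = NULL, out_times = NULL,
                        domain_map = NULL) {
  if (!inherits(params, "nrl_params")) params <- load_params(params)
  spa <- params$spatial
  grid <- build_grid(spa$nr, spa$nz, spa$R, spa$L)
  if (is.null(domain_map)) domain_map <- assign_domains(spa$preset, grid)
  if (is.null(fields0)) {
    fields0 <- make_initial_fields(grid, domain_map, params)
  }
  dt <- spa$dt
  t_end <- spa$t_end
  if (is.null(out_times)) {
    sched <- 10^seq(log10(max(10 * dt, t_end / 100)), log10(t_end),
                    length.out = 24)
    out_times <- unique(c(0, round(sched / dt) * dt))
  }
  n_steps <- round(t_end / dt)
  out_steps <- sort(unique(pmin(round(out_times / dt), n_steps)))
  out_times <- out_steps * dt # snap labels to actual step times
  D_maps <- .nrl_diffusivity_maps(params, domain_map, grid)
  f <- fields0
  record <- vector("list", length(out_times))
  ridx <- 1L
  if (out_steps[1] == 0L) {
    record[[1]] <- f
    ridx <- 2L
  }
  axpy <- function(a, x, s) Map(function(u, v) u + s * v, a, x)
  for (step in seq_len(n_steps)) {
    k1 <- spatial_rhs(f, params, domain_map, grid, D_maps)
    k2 <- spatial_rhs(axpy(f, k1, dt / 2), params, domain_map, grid, D_maps)
    k3 <- spatial_rhs(axpy(f, k2, dt / 2), params, domain_map, grid, D_maps)
    k4 <- spatial_rhs(axpy(f, k3, dt), params, domain_map, grid, D_maps)
    f <- Map(function(y, a, b, c_, d) y + dt / 6 * (a + 2 * b + 2 * c_ + d),
             f, k1, k2, k3, k4)
    bad <- vapply(f, function(m) anyNA(m) || any(m < -1e-9), logical(1))
    if (any(bad)) {
      stop("spatial integration unstable at t = ", step * dt,
           " s (NaN or negative concentration beyond tolerance); ",
           "reduce dt or refine the grid", call. = FALSE)
    }
    if (ridx <= length(out_steps) && step == out_steps[ridx]) {
      record[[ridx]] <- lapply(f, function(m) pmax(m, 0))
      ridx <- ridx + 1L
    }
  }
  structure(list(times = out_times, fields = record, grid = grid,
                 domain_map = domain_map, params = params),
            class = "nrl_spatial_record")
}

#' Volume-averaged bulk concentration time series
#'
#' Volume-weighted mean concentration of one species over all cells at each
#' stored output time (the "total bulk concentration" readout).
#'
#' @param record An `nrl_spatial_record`.
#' @param species Species name.
#' @return Data frame with columns `time` and `mean_conc` (mol/m^3).
#' @export
total_bulk_concentration <- function(record, species) {
  stopifnot(inherits(record, "nrl_spatial_record"))
  v <- record$grid$vol
  vt <- sum(v)
  mean_conc <- vapply(record$fields, function(f) {
    if (!species %in% names(f)) stop("no such species: ", species,
                                     call. = FALSE)
    sum(f[[species]] * v) / vt
  }, numeric(1))
  data.frame(time = record$times, mean_conc = mean_conc)
}

# Total moles of each conserved moiety in a field set (bound pools enter
# via Ssa: area per cell = Ssa * V).
.nrl_spatial_moieties <- function(fields, grid, ssa) {
  v <- grid$vol
  c(scaffold_moiety = sum((fields$SC + fields$pSC) * v) +
      sum(fields$mpSC * ssa * v),
    peptide_moiety = sum((fields$p + fields$pSC) * v) +
      sum((fields$mp + fields$mpSC) * ssa * v),
    enzyme = sum(fields$enzyme * v))
}

#' Maximum concentration of a species over cells and stored times
#'
#' The metric tracked by the mesh-convergence study.
#'
#' @param record An `nrl_spatial_record`.
#' @param species Species name.
#' @return Maximum concentration, mol/m^3.
#' @export
max_concentration <- function(record, species) {
  stopifnot(inherits(record, "nrl_spatial_record"))
  max(vapply(record$fields, function(f) max(f[[species]]), numeric(1)))
}
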