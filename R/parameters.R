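# Species tracked by the release network and the spatial model.  mp and mpSC
# are matrix-bound (per-area concentrations, no diffusion); everything else
# is a bulk species.
.nrl_species_names <- c("SC", "p", "pSC", "mp", "mpSC",
                        "enzyme", "GABA", "GLU", "GLN", "NH3", "CO2")

.nrl_default_species <- function() {
  data.frame(
    name = .nrl_species_names,
    # Placeholder bulk-average molecular weights (Da): peptide ~1 kDa,
    # scaffold ~10 kDa, complexes = sum of constituents, enzyme at the
    # glutamate-decarboxylase scale; small molecules at their exact MW.
    molecular_weight = c(10000, 1000, 11000, 1000, 11000,
                         65000, 103.12, 147.13, 146.15, 17.03, 44.01),
    phase = c("bulk", "bulk", "bulk", "matrix-bound", "matrix-bound",
              "bulk", "bulk", "bulk", "bulk", "bulk", "bulk"),
    diffusive = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                  TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Diffusivity of a species in water from its molecular weight
#'
#' Empirical power law for macromolecular diffusion, `D = A * MW^(-1/3) *
#' prefactor_scale` evaluated in cm^2/s and converted to m^2/s.  With the
#' default prefactor `A = 260` cm^2/(s*Da) and scale `1e-7` this gives
#' protein-scale diffusivities (2.6e-10 m^2/s at 1 kDa), consistent with the
#' Saltzman relation for protein transport in porous hydrogels.
#'
#' @param molecular_weight Molecular weight in Daltons (> 0); vectorised.
#' @param A_const Prefactor in cm^2/(s*Da), default 260.
#' @param prefactor_scale Dimensionless scale applied to the cm^2/s value,
#'   default 1e-7.
#' @return Diffusivity in m^2/s.
#' @examples
#' water_diffusivity(1000) # 2.6e-10 m^2/s
#' @export
water_diffusivity <- function(molecular_weight, A_const = 260,
                              prefactor_scale = 1e-7) {
  if (!is.numeric(molecular_weight) || any(!is.finite(molecular_weight)) ||
      any(molecular_weight <= 0)) {
    stop("molecular_weight must be a finite positive number", call. = FALSE)
  }
  d_cm2 <- A_const * molecular_weight^(-1 / 3) * prefactor_scale
  d_cm2 * 1e-4 # cm^2/s -> m^2/s
}

#' Diffusivity in the gel phase
#'
#' Hindered diffusion in the hydrogel: the in-water diffusivity reduced by a
#' constant obstruction factor (default 0.9).
#'
#' @param D_water Diffusivity in water, m^2/s (>= 0); vectorised.
#' @param gel_factor Dimensionless reduction factor in (0, 1], default 0.9.
#' @return Diffusivity in the gel, m^2/s.
#' @export
gel_diffusivity <- function(D_water, gel_factor = 0.9) {
  if (!is.numeric(D_water) || any(!is.finite(D_water)) || any(D_water < 0)) {
    stop("D_water must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(gel_factor) || length(gel_factor) != 1 ||
      gel_factor <= 0 || gel_factor > 1) {
    stop("gel_factor must be a single value in (0, 1]", call. = FALSE)
  }
  gel_factor * D_water
}

.nrl_default_transport <- function() {
  list(A_const = 260, prefactor_scale = 1e-7, gel_factor = 0.9)
}

.nrl_default_kinetics <- function() {
  # Association/dissociation at affinity-delivery scales (Kd = kr1/kf1 =
  # 0.1 mol/m^3 = 100 uM); Vmax frozen by the package's one-time calibration
  # of the default depot scenario.
  list(kf1 = 1.0,      # m^3/(mol s)
       kr1 = 0.1,      # 1/s
       Vmax = 6.98e-3, # mol/(m^3 s)
       KM = 1e-2,      # mol/m^3
       Ssa = 1e4,      # 1/m
       enzyme0 = 2e-6) # mol/m^3
}

.nrl_default_loading <- function() {
  # Depot loading in mol/m^3-equivalents (matrix-bound pools expressed as
  # per-area concentration times Ssa); 90% of the peptide is covalently
  # immobilised to the matrix before release.
  list(total_scaffold = 0.01, total_peptide = 0.1, bound_fraction = 0.9)
}

.nrl_default_cycle <- function() {
  list(uptake_Vmax = 0.01,   # mol/(m^3 s), astrocytic MM uptake
       uptake_KM = 0.03,     # mol/m^3 (30 uM)
       gs_rate = 0.05,       # 1/s, glutamine synthetase
       completion_cap = 0.90,
       switch = "smooth",    # "smooth" | "hard"
       switch_width = 0.01,  # fraction of completion_cap
       gln_transfer_rate = 0.05, # 1/s, astrocyte -> neuron glutamine export
       glnase_rate = 0.05,   # 1/s, neuronal glutaminase
       gad_rate = 0.05,      # 1/s, glutamate decarboxylase
       atp_per_glu = 1.5,    # ATP per glutamate taken up (> 1)
       release_rate = 0,     # 1/s, neuronal glutamate re-release (off)
       ecm_input = 0,        # mol/(m^3 s), exogenous extracellular input
       glu_ecm0 = 0.53,      # mol/m^3 = 0.53 mM post-injury level
       t_end = 120)          # s
}

.nrl_default_spatial <- function() {
  # Domain-k diffusivity factors: gel hindrance inside the depot only.
  list(R = 3e-3, L = 12e-3, nr = 16, nz = 64, dt = 0.01, t_end = 60,
       preset = "standard", tracked_species = "SC",
       enzyme_in_cellular_zone = TRUE,
       domain_factors = c(k1 = 1.0, k2 = 0.9, k3 = 1.0))
}

#' Construct a validated parameter bundle
#'
#' Collects species properties, transport constants, kinetic constants, depot
#' loading, glutamate-cycle parameters and spatial-solver settings into one
#' validated bundle.  Any component not supplied takes the documented
#' defaults; per-species diffusivities (in water and in gel) are derived from
#' the molecular weights unless a `D_water` column is supplied.
#'
#' @param species Data frame with columns `name`, `molecular_weight`,
#'   `phase`, `diffusive` (and optionally `D_water`).
#' @param transport,kinetics,loading,cycle,spatial Named lists overriding
#'   individual defaults.
#' @return An object of class `nrl_params`.
#' @export
nrl_params <- function(species = NULL, transport = list(), kinetics = list(),
                       loading = list(), cycle = list(), spatial = list()) {
  p <- list(
    species = if (is.null(species)) .nrl_default_species() else species,
    transport = utils::modifyList(.nrl_default_transport(), transport),
    kinetics = utils::modifyList(.nrl_default_kinetics(), kinetics),
    loading = utils::modifyList(.nrl_default_loading(), loading),
    cycle = utils::modifyList(.nrl_default_cycle(), cycle),
    spatial = utils::modifyList(.nrl_default_spatial(), spatial)
  )
  p <- .nrl_derive_diffusivities(p)
  class(p) <- "nrl_params"
  validate_params(p)
  p
}

.nrl_derive_diffusivities <- function(p) {
  sp <- p$species
  if (is.null(sp$D_water)) {
    sp$D_water <- water_diffusivity(sp$molecular_weight,
                                    A_const = p$transport$A_const,
                                    prefactor_scale = p$transport$prefactor_scale)
  }
  sp$D_gel <- gel_diffusivity(sp$D_water, p$transport$gel_factor)
  p$species <- sp
  p
}

#' Validate a parameter bundle
#'
#' Checks the structural invariants of the bundle: positive molecular
#' weights, matrix-bound species flagged non-diffusive, positive kinetic
#' constants, diffusivities in the physically plausible macromolecule range
#' (1e-12 to 1e-8 m^2/s), `D_gel = gel_factor * D_water`, and a valid
#' completion cap and ATP stoichiometry for the glutamate cycle.
#'
#' @param p An `nrl_params` object.
#' @return `TRUE` invisibly; stops with a descriptive error on violation.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "nrl_params"))
  sp <- p$species
  need <- c("name", "molecular_weight", "phase", "diffusive")
  if (!all(need %in% names(sp))) {
    stop("species table missing columns: ",
         paste(setdiff(need, names(sp)), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(sp$name, .nrl_species_names)
  if (length(unknown)) {
    stop("unknown species name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(sp$molecular_weight <= 0)) {
    stop("molecular_weight must be > 0 for every species", call. = FALSE)
  }
  bad <- sp$phase == "matrix-bound" & sp$diffusive
  if (any(bad)) {
    stop("matrix-bound species must be non-diffusive: ",
         paste(sp$name[bad], collapse = ", "), call. = FALSE)
  }
  if (any(sp$D_water < 1e-12 | sp$D_water > 1e-8)) {
    stop("derived diffusivities outside 1e-12..1e-8 m^2/s; check ",
         "molecular weights / prefactor", call. = FALSE)
  }
  if (max(abs(sp$D_gel - p$transport$gel_factor * sp$D_water)) > 0) {
    stop("D_gel must equal gel_factor * D_water exactly", call. = FALSE)
  }
  k <- p$kinetics
  for (nm in c("kf1", "kr1", "Vmax", "KM", "Ssa")) {
    if (!is.numeric(k[[nm]]) || length(k[[nm]]) != 1 || !is.finite(k[[nm]]) ||
        k[[nm]] <= 0) {
      stop("kinetics$", nm, " must be a single positive number", call. = FALSE)
    }
  }
  if (k$enzyme0 < 0) stop("kinetics$enzyme0 must be >= 0", call. = FALSE)
  ld <- p$loading
  if (ld$total_scaffold < 0 || ld$total_peptide < 0) {
    stop("loadings must be >= 0", call. = FALSE)
  }
  if (ld$bound_fraction < 0 || ld$bound_fraction > 1) {
    stop("bound_fraction must lie in [0, 1]", call. = FALSE)
  }
  cy <- p$cycle
  if (cy$completion_cap <= 0 || cy$completion_cap >= 1) {
    stop("cycle$completion_cap must lie in (0, 1)", call. = FALSE)
  }
  if (cy$atp_per_glu <= 1) {
    stop("cycle$atp_per_glu must be > 1 (more than one ATP per glutamate)",
         call. = FALSE)
  }
  if (!cy$switch %in% c("smooth", "hard")) {
    stop("cycle$switch must be 'smooth' or 'hard'", call. = FALSE)
  }
  spa <- p$spatial
  if (spa$R <= 0 || spa$L <= 0 || spa$nr < 4 || spa$nz < 4) {
    stop("spatial geometry requires R, L > 0 and nr, nz >= 4", call. = FALSE)
  }
  if (spa$dt <= 0 || spa$t_end <= 0) {
    stop("spatial dt and t_end must be > 0", call. = FALSE)
  }
  invisible(TRUE)
}

.nrl_config_sections <- c("species", "transport", "kinetics", "loading",
                          "cycle", "spatial")

#' Load a parameter bundle from a config file
#'
#' Reads a YAML config with sections `species`, `transport`, `kinetics`,
#' `loading`, `cycle`, `spatial`; values absent from the file take the
#' documented defaults, unknown sections or keys are rejected.  An empty or
#' `NULL` source yields the complete default bundle (enzyme at 2e-6 mol/m^3,
#' the 12 mm x 3 mm cylinder, dt = 0.01 s).
#'
#' @param config_source Path to a YAML file, a named list with the same
#'   structure, or `NULL` for pure defaults.
#' @return An `nrl_params` bundle.
#' @seealso [write_params()] for the lossless inverse.
#' @export
load_params <- function(config_source = NULL) {
  cfg <- if (is.null(config_source)) {
    list()
  } else if (is.character(config_source)) {
    if (!file.exists(config_source)) {
      stop("config file not found: ", config_source, call. = FALSE)
    }
    out <- yaml::read_yaml(config_source)
    if (is.null(out)) list() else out
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("config_source must be a path, a list, or NULL", call. = FALSE)
  }
  unknown <- setdiff(names(cfg), .nrl_config_sections)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in c("transport", "kinetics", "loading", "cycle", "spatial")) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]),
                     names(switch(sec,
                                  transport = .nrl_default_transport(),
                                  kinetics = .nrl_default_kinetics(),
                                  loading = .nrl_default_loading(),
                                  cycle = .nrl_default_cycle(),
                                  spatial = .nrl_default_spatial())))
      if (length(bad)) {
        stop("unknown key(s) in section '", sec, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  species <- NULL
  if (!is.null(cfg$species)) {
    species <- .nrl_species_from_config(cfg$species)
  }
  dom_fac <- .nrl_default_spatial()$domain_factors
  spa <- cfg$spatial %||% list()
  if (!is.null(spa$domain_factors)) {
    spa$domain_factors <- unlist(spa$domain_factors)[names(dom_fac)]
  }
  nrl_params(species = species,
             transport = cfg$transport %||% list(),
             kinetics = cfg$kinetics %||% list(),
             loading = cfg$loading %||% list(),
             cycle = cfg$cycle %||% list(),
             spatial = spa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.nrl_species_from_config <- function(sp_cfg) {
  base <- .nrl_default_species()
  for (nm in names(sp_cfg)) {
    i <- match(nm, base$name)
    if (is.na(i)) stop("unknown species name: ", nm, call. = FALSE)
    entry <- sp_cfg[[nm]]
    bad <- setdiff(names(entry),
                   c("molecular_weight", "phase", "diffusive", "D_water"))
    if (length(bad)) {
      stop("unknown species field(s) for ", nm, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (f in names(entry)) {
      if (f == "D_water" && is.null(base$D_water)) base$D_water <- NA_real_
      base[[f]][i] <- entry[[f]]
    }
  }
  base
}

#' Write a parameter bundle to a config file
#'
#' Serialises the bundle to YAML at full floating precision so that
#' `load_params(write_params(p, f))` reproduces `p` exactly.
#'
#' @param p An `nrl_params` bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "nrl_params"))
  sp <- p$species
  species <- stats::setNames(lapply(seq_len(nrow(sp)), function(i) {
    list(molecular_weight = sp$molecular_weight[i], phase = sp$phase[i],
         diffusive = sp$diffusive[i], D_water = sp$D_water[i])
  }), sp$name)
  spa <- p$spatial
  spa$domain_factors <- as.list(spa$domain_factors)
  cfg <- list(species = species, transport = p$transport,
              kinetics = p$kinetics, loading = p$loading,
              cycle = p$cycle, spatial = spa)
  # emit doubles as shortest-exact %.17g scalars: the emitter's own precision
  # option counts decimal places, which truncates small magnitudes
  dbl <- function(x) {
    txt <- sprintf("%.17g", x)
    exact <- vapply(seq_along(x), function(i) {
      cand <- sprintf("%.*g", 1:17, x[i])
      cand[match(TRUE, as.numeric(cand) == x[i])]
    }, character(1))
    txt[!is.na(exact)] <- exact[!is.na(exact)]
    # YAML 1.1 resolves exponent forms without a dot ("1e+04") as strings
    bare_exp <- grepl("^[0-9+-]+e", txt)
    txt[bare_exp] <- sub("e", ".0e", txt[bare_exp])
    plain <- !grepl("[.eE]", txt) & !is.na(x)
    txt[plain] <- paste0(txt[plain], ".0")
    structure(txt, class = "verbatim")
  }
  writeLines(yaml::as.yaml(cfg, handlers = list(numeric = dbl)), path)
  invisible(path)
}

#' @export
print.nrl_params <- function(x, ...) {
  cat("<nrl_params> release-model parameter bundle\n")
  cat("  species: ", nrow(x$species), " (",
      sum(x$species$phase == "matrix-bound"), " matrix-bound)\n", sep = "")
  k <- x$kinetics
  cat(sprintf("  kinetics: kf1=%g kr1=%g Vmax=%g KM=%g Ssa=%g enzyme0=%g\n",
              k$kf1, k$kr1, k$Vmax, k$KM, k$Ssa, k$enzyme0))
  cat(sprintf("  geometry: R=%g m, L=%g m, grid %dx%d, dt=%g s\n",
              x$spatial$R, x$spatial$L, x$spatial$nr, x$spatial$nz,
              x$spatial$dt))
  invisible(x)
}
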