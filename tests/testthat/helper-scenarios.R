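# Shared fixtures, all generated in code.

default_params <- function(...) nrl_params(...)

# Small spatial configuration for fast solver tests.
small_spatial_params <- function(nr = 4, nz = 8, t_end = 2, dt = 0.01, ...) {
  nrl_params(spatial = list(nr = nr, nz = nz, t_end = t_end, dt = dt, ...))
}

# Equilibrium batch state for the default depot loading.
default_state0 <- function(params = nrl_params()) {
  ld <- params$loading
  equilibrate(ld$total_scaffold, ld$total_peptide, ld$bound_fraction, params)
}

# Uniform field set replicating a batch state on every cell of a grid
# (for batch-reduction tests of the spatial solver).
uniform_fields <- function(state, grid) {
  lapply(as.list(state$conc), function(v) matrix(v, grid$nr, grid$nz))
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.xmin)
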