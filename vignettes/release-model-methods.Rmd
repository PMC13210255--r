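---
title: "Methods: enzymatically triggered release and glutamate cycling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enzymatically triggered release and glutamate cycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurorelease)
```

## Scope

`neurorelease` models the enzymatically triggered release of a neuropeptide
from a core--shell scaffold depot implanted in injured neural tissue, and the
downstream clearance of excitotoxic extracellular glutamate through the
astrocyte--neuron glutamate/glutamine/GABA cycle.  Three simulation surfaces
share one parameter bundle:

1. a **well-mixed batch reactor** for the five-species release network,
2. a **compartmental glutamate-cycle ODE** for the tissue response, and
3. a **2-D axisymmetric reaction--diffusion solver** for the cylindrical
   depot-in-tissue geometry.

Numerical-verification studies (mesh convergence, time-step independence,
conservation audits), a deterministic scenario generator and a CLI wrap
these cores.  Out of scope: fluid dynamics of scaffold fabrication
(printing/electrospinning), material synthesis and toxicity, and import of
third-party simulation files.

## The release network

Five species take part.  `SC` is the free scaffold--chitosan carrier, `p`
the free neuropeptide, `pSC` their dissolved complex; `mp` and `mpSC` are
the matrix-bound peptide and bound complex.  Matrix-bound pools live on the
depot surface and are stored per unit area (mol/m²); the specific surface
area `Ssa` (1/m) converts them to volumetric terms, so every bulk balance
uses `c_mp * Ssa` and `c_mpSC * Ssa`.

Reversible binding (association `kf1`, dissociation `kr1`) couples the
carrier to both peptide pools:

* `R_SC = -kf1 * c_SC * (c_mp Ssa + c_p) + kr1 (c_mpSC Ssa + c_pSC)`
* `R_p  = -kf1 * c_SC * c_p + kr1 * c_pSC + R_MM(mp)`
* `R_pSC = kf1 * c_SC * c_p - kr1 * c_pSC + R_MM(mpSC)`

where `R_MM(x) = Vmax * c_x Ssa / (KM + c_x Ssa)` is the Michaelis--Menten
degradation of the matrix by the triggering enzyme; the per-area balances of
`mp` and `mpSC` carry `-R_MM/Ssa` plus their binding terms.  GABA and CO₂
are produced 1:1 with the degradation of the *bound* pool `mpSC`: that is
the pool whose release liberates the glutamate-bearing shell for
decarboxylation, while degradation of bare `mp` frees peptide only.  The
enzyme itself appears with a zero net rate: it triggers degradation (through
`Vmax`) without being consumed, and in the spatial model it simply diffuses.

Two moieties are conserved exactly by construction and audited in the
tests:

* scaffold: `c_SC + c_pSC + c_mpSC * Ssa`
* peptide: `c_p + c_pSC + (c_mp + c_mpSC) * Ssa`

`equilibrate()` partitions a depot loading (total scaffold `TS`, total
peptide `TP`, matrix-bound fraction β) at binding equilibrium by solving the
quadratic `K s² + (1 + K (TP - TS)) s - TS = 0` for the free carrier `s`
(`K = kf1 / kr1`), which makes the initial state a fixed point whenever
degradation is switched off.  `integrate_batch()` drives the network with
`deSolve::lsoda` at tight tolerances (`rtol = 1e-10`, `atol = 1e-14`).

## The glutamate cycle

Six pools: extracellular glutamate (initialised at the post-injury level
0.53 mM), astrocytic glutamate, astrocytic glutamine, neuronal glutamine,
neuronal glutamate and neuronal GABA (mol/m³ ≡ mM throughout).  Astrocytic
uptake is Michaelis--Menten in extracellular glutamate and costs
`atp_per_glu = 1.5` ATP per glutamate.  Glutamine synthetase (GS),
glutamine export, glutaminase and glutamate decarboxylase are first-order
stages.

The GS stage shuts off once the cumulative converted fraction
`cum_converted / cum_uptake` reaches the completion cap (default 90%).  The
default switch is a C¹ smoothstep in that fraction: unlike a logistic
factor, it is *exactly* zero at and above the cap, so conversion cannot
creep past it over long horizons.  A `"hard"` variant implements the cap as
a projected flux limit (`cap * uptake` plus a proportional pull-back term);
a raw on/off switch would chatter on the boundary and defeat the stiff
integrator.

Optional terms — neuronal re-release and a constant exogenous extracellular
input, both zero by default — open the loop.  With the defaults the cycle
is closed and total glutamate-carbon is conserved; with an input, the
`cum_input` tracker restores the ledger.

## The spatial model

The domain is a cylinder of length 12 mm and radius 3 mm, discretised with
a cell-centred uniform finite-volume grid in `(r, z)`.  Cell volumes
`2π r_i Δr Δz` sum exactly to `π R² L`.  Face fluxes use harmonic-mean
diffusivities, and every boundary is no-flux (a closed test volume), so
discrete mass conservation holds to round-off for pure diffusion.  Three
zones: a cellular zone (enzyme source, top sixth of the cylinder), the
scaffold depot (inner half-radius, middle third), and culture media
elsewhere.  Matrix degradation (`Vmax`) acts only inside the depot, where
the matrix physically resides; the enzyme is an inert diffusing tracer.

Diffusivities come from the molecular-weight correlation
`D = 260 · MW^(-1/3) × 10⁻⁷ cm²/s`, converted to m²/s, with a factor 0.9
inside the depot gel; a plausibility band (10⁻¹² to 10⁻⁸ m²/s) is enforced
at validation.  Matrix-bound pools do not diffuse.

Time integration is a fixed-step classical RK4 march at `dt = 0.01 s`.
A fixed-step explicit scheme was chosen over an adaptive stiff integrator
for the PDE stage because it preserves the *linear* moiety invariants
exactly per stage, makes the time-step-independence study meaningful, and
keeps the per-step cost linear in the number of cells; the batch and cycle
ODEs, which are small and stiff, use `lsoda` instead.  The solver aborts
with a descriptive error on NaN or significantly negative concentrations
rather than returning garbage.

## Parameters and provenance

Defaults are frozen in the package and documented per value in
`default_scenario()$provenance`:

| Parameter | Default | Units | Provenance |
|---|---|---|---|
| enzyme0 | 2e-6 | mol/m³ | stated operating concentration |
| geometry R × L | 3 mm × 12 mm | m | stated |
| dt | 0.01 | s | stated |
| D correlation | 260 · MW^(-1/3) × 10⁻⁷ | cm²/s | stated constant; exponent corrected to the physical 10⁻⁷ scale (the 10⁷ form yields nonphysical diffusivities) |
| gel factor | 0.9 | – | stated |
| kf1 | 1.0 | m³/(mol s) | calibrated default at affinity-delivery scales |
| kr1 | 0.1 | 1/s | calibrated default |
| Vmax | 6.98e-3 | mol/(m³ s) | one-time calibration of the depletion transient to ≈16 s; frozen thereafter |
| KM | 1e-2 | mol/m³ | calibrated default |
| Ssa | 1e4 | 1/m | calibrated default |
| loading TS, TP, β | 0.01, 0.1, 0.9 | mol/m³, – | calibrated default depot loading |
| uptake Vmax, KM | 0.01, 0.03 | mol/(m³ s), mol/m³ | calibrated defaults in the physiological uptake range |
| stage rates (GS, export, glutaminase, GAD) | 0.05 | 1/s | calibrated defaults |
| glu_ecm0 | 0.53 | mol/m³ | stated post-injury level |
| completion cap | 0.90 | – | stated GS completion fraction |
| atp_per_glu | 1.5 | – | stated stoichiometry |

"Calibrated default" marks rate constants whose literature values are not
fixed by the sources above; they are plausible order-of-magnitude choices
frozen *before* the test expectations were written, and the headline
behaviours they support are checked with wide, physically motivated
tolerances rather than tuned matches.

## Synthetic scenarios versus real data

Everything the pipeline consumes is generated in code: `default_scenario()`
builds the frozen fixture (grid, domain map, equilibrium loading, initial
fields, provenance notes) and `sample_params()` draws seeded log-uniform
ensembles of the four kinetic constants for sensitivity sweeps.  The
generator covers *model inputs only* — it does not emulate measured release
curves, assay noise, or animal data, and conclusions drawn from it are
statements about the model, not about experiments.

## Verification

* **Mesh convergence** (`mesh_convergence_study`): three successive ×2
  uniform refinements; the tracked metric is the maximum concentration over
  cells and stored times; pass when the relative change between the two
  finest levels is below 1%.  The default study refines 8×32 → 16×64 →
  32×128, a ladder chosen to keep the full study within desk-scale runtimes
  while ending at the production resolution.
* **Time-step independence** (`timestep_study`): fixed-step RK4 re-runs of
  the batch transient across candidate steps, compared in sup-norm against
  the finest step, with an alternating-sign oscillation detector.
* **Conservation audits** (`conservation_audit`): relative drift of the
  scaffold/peptide moieties and the enzyme (batch, spatial) or total
  glutamate-carbon (cycle); thresholds 1e-8 for ODE runs and 1e-6 for the
  spatial march.

The test suite pins the kinetics to independently hand-evaluated rate
values, checks the radial heat-kernel solution against the solver at 2%
accuracy, verifies second-order spatial convergence on a smooth problem,
and reduces the spatial solver to the batch oracle when diffusion is
switched off.

## Limitations

* The spatial solver is explicit; very fine grids need proportionally small
  `dt` (the solver detects instability but does not adapt).
* Binding kinetics use a single site class; no peptide degradation or
  enzyme inactivation.
* The glutamate cycle is compartmental, not spatially resolved, and its
  stage rates are calibrated defaults, so its time axis is indicative.
* Domain zones are axis-aligned boxes in `(r, z)`; curved depot shapes are
  not representable.
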