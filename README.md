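# neurorelease

Simulation of enzymatically triggered neuropeptide release from a
core–shell scaffold depot in injured neural tissue, and of the clearance of
excitotoxic extracellular glutamate through the astrocyte–neuron
glutamate/glutamine/GABA cycle.

Three simulation surfaces share one validated parameter bundle:

- **Batch release network** — five species (free carrier `SC`, free peptide
  `p`, dissolved complex `pSC`, matrix-bound peptide `mp`, bound complex
  `mpSC`) with reversible binding and Michaelis–Menten matrix degradation
  by a triggering enzyme; GABA/CO₂ are produced as the bound matrix
  degrades.
- **Glutamate cycle** — compartmental ODE from the post-injury
  extracellular level (0.53 mM) through astrocytic uptake, glutamine
  synthetase (capped at 90 % completion), glutamine transfer, glutaminase
  and GAD to neuronal GABA.
- **2-D axisymmetric spatial solver** — conservative finite-volume
  reaction–diffusion march on the 12 mm × 3 mm cylindrical
  depot-in-tissue geometry, with cellular / depot / media zones.

Verification studies (mesh convergence at the 1 % criterion, time-step
independence, conservation audits), a deterministic scenario generator and
a CLI (`batch`, `cycle`, `spatial`, `converge`, `dtstudy`, `make-fixture`,
`sweep`) wrap the cores.  See the methods vignette
(`vignettes/release-model-methods.Rmd`) for model equations, parameter
provenance and numerical choices.

## Worked example

```r
library(neurorelease)

sc <- default_scenario()           # frozen fixture, provenance-tagged
sc$state0$conc
#>           SC            p          pSC           mp         mpSC
#> 5.124922e-03 9.512492e-03 4.875078e-04 8.561243e-06 4.387570e-07
#>       enzyme         GABA          CO2
#> 2.000000e-06 0.000000e+00 0.000000e+00

# batch release: the matrix-bound complex depletes in about 16 s
traj <- integrate_batch(sc$state0, sc$params, t_end = 60, dt_out = 0.01)
depletion_time(traj, "mpSC", fraction = 0.01)
#> [1] 16.00141

# glutamate clearance from the post-injury level
cyc <- integrate_cycle(params = sc$params, t_end = 300)
threshold_times(cyc)               # crossing the 0.10 / 0.05 mM band
#>  below_0.1 below_0.05
#>   48.00312   55.08260
conversion_fraction(cyc)           # synthetase stops at 90 %
#> [1] 0.899975

# spatial run with a conservation audit (drift at machine precision)
p <- sc$params; p$spatial$nr <- 8; p$spatial$nz <- 32; p$spatial$t_end <- 2
rec <- run_spatial(p)
conservation_audit(rec)$drift
#> scaffold_moiety  peptide_moiety          enzyme
#>    1.950369e-16    1.560295e-16    2.380821e-16
```

From the command line (wrapper installed under
`system.file("scripts", "neurorelease", package = "neurorelease")`):

```sh
Rscript inst/scripts/neurorelease batch --out-dir out/
Rscript inst/scripts/neurorelease converge --out-dir out/   # exit 4 on criterion failure
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "neurorelease", load_package = "installed")'
```

The suite pins hand-evaluated kinetic oracles, an analytic radial
heat-kernel solution, mesh/time-step convergence, moiety conservation and
the CLI exit-code contract.

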