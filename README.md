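# hepatoflow

Spatially resolved simulation of first-pass drug perfusion, distribution and
metabolization in the liver.

Compartmental pharmacokinetic models describe the liver as well-stirred
subcompartments — accurate once blood and tissue are in quasi-equilibrium,
but blind to the first instants after a drug reaches the organ. `hepatoflow`
targets exactly that regime, in the setting of an isolated perfused liver
(no recirculation): a supplying (portal-vein-like) and a draining
(hepatic-vein-like) vascular tree, coupled through a homogenized hepatic
space (HHS) treated as a porous continuum of five subspaces (red blood
cells, plasma, interstitium, cells, rest).

The model core:

* **Vascular synthesis** — constrained constructive optimization (CCO):
  terminals are added inside a voxelized organ mask through bifurcations
  placed to minimize total intravascular volume `Σ π r² L` under equal
  terminal flows and a Murray radius rule `r_p³ = Σ r_c³`; the
  Fåhræus–Lindqvist viscosity law (Pries et al. in-vitro form) supplies
  radius-dependent hydraulic resistance.
* **Perfusion** — 1D advection `∂c/∂t + v ∂c/∂x = 0` per vessel edge (flow
  splitting at supplying junctions, flow-weighted instant mixing at
  draining junctions) and Darcy flow in the HHS,
  `v = -(K/φ_sin) ∇p`, `-∇·(K ∇p) = q`, driven by line sources/sinks along
  the terminal edges (trilinear finite elements, pure-Neumann nullspace
  fixed by mean-zero normalization).
* **Kinetics** — pointwise passive exchange between subspaces,
  `dc_a/dt = -(P_ab/f_a)(c_a - K_ab c_b)`, plus cellular metabolization
  (first-order or Michaelis–Menten) as a pure sink, integrated per voxel by
  adaptive Runge–Kutta–Fehlberg 4(5).
* **Pathology** — steatosis as a lipid volume-ratio field ρ(x) shifting the
  cellular partition coefficient, `K_cell(ρ) = K_cell(1-ρ) + k_lip ρ`, and
  pericentral necrosis replacing cellular by interstitial space in the
  volume fraction γ closest to the draining terminals.
* **Reference & validation machinery** — a well-stirred compartment model
  with identical kinetics, mass-balance auditing, outflow-curve summaries
  (peak, FWHM, AUC, mean transit time), Lin's concordance correlation
  coefficient, and clearance-parameter recovery by simulation-based
  least squares.

All transport is exactly mass-conservative by construction (flux-form
upwind finite volumes with Courant-limited sub-stepping); a full bolus run
closes its inflow/outflow/stored/metabolized ledger to ~1e-15 relative.

## A worked example

```r
library(hepatoflow)

cfg <- simulation_config(duration = 60, compound = "tracer")  # standard fixture
res <- run_simulation(cfg)
res
#> <simulation_result> tracer: 120 steps to t = 60 s
#>   outflow peak 25.62 umol/L at t = 11 s; cumulative inflow 0.015 umol,
#>   outflow 0.01383 umol, metabolized -2.168e-19 umol; ledger closure 3.50e-15

summarize_outflow(res$times, res$outflow, inflow_centroid = 5)
#> $peak_time   [1] 11       # s; the well-stirred reference peaks at 10 s
#> $peak_height [1] 25.6     # umol/L, versus a 50 umol/L inflow bolus
#> $fwhm        [1] 14.1     # s, width of the first-pass peak
#> $mtt         [1] 13.4     # s, mean transit time estimate
```

The run simulates a 10 s, 50 µmol/L bolus of an inert lipophilic tracer
through a synthetic two-lobe liver (ellipsoid mask at 0.5 mm spacing, two
64-terminal CCO trees, total perfusion 30 mm³/s). The outflow peak is
delayed and attenuated relative to the inflow because the bolus disperses
over heterogeneous vascular-tissue-vascular path lengths and partitions
transiently into the interstitial and cellular spaces. `mass_balance_report(res)`
breaks the final ledger down by subspace.

Pathology runs add a `pathology` entry to the config:

```r
cfg_st <- simulation_config(duration = 60, compound = "mmdrug",
  pathology = list(steatosis = list(
    ranges = list("1" = c(0.25, 0.45), "2" = c(0.05, 0.15)),
    mode = "heterogeneous")))
```

A command-line front end lives at `inst/cli/hepatoflow`
(`generate-mask`, `generate-tree`, `fixtures`, `run`, `fit`).

## Package layout

| path | contents |
|---|---|
| `R/mask.R`, `R/tree.R`, `R/cco.R`, `R/viscosity.R` | organ masks, vascular trees, CCO synthesis |
| `R/advection1d.R`, `R/darcy.R`, `R/hhs.R` | vascular and tissue transport |
| `R/pbpk.R`, `R/pathology.R` | exchange/metabolization kinetics, steatosis and necrosis |
| `R/simulator.R`, `R/calibration.R`, `R/fixtures.R` | operator-split time loop, fitting and concordance, synthetic fixtures |
| `vignettes/liver-first-pass-model.Rmd` | the model, its assumptions, parameters and limitations |
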