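---
title: "A spatially resolved model of hepatic first-pass perfusion and metabolization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatially resolved model of hepatic first-pass perfusion and metabolization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Classical physiologically based pharmacokinetic (PBPK) models treat the liver
as a handful of well-stirred compartments. That description is accurate once
blood and tissue have reached quasi-equilibrium, but it cannot represent the
first instants after a drug reaches the organ: the bolus front travelling
through the portal tree, the heterogeneous transit times through the tissue,
and the spatially varying exposure of hepatocytes. `hepatoflow` implements a
spatially resolved alternative, corresponding experimentally to an isolated
perfused liver (no recirculation): one supplying and one draining vascular
tree coupled through a homogenized hepatic space (HHS), a porous-continuum
representation of everything between the resolved vessels.

The model has three tiers:

1. **Vascular trees.** Strictly bifurcative cylinder trees, either supplied
   by the user (JSON) or synthesized by constrained constructive
   optimization (CCO) inside a voxelized organ mask: each added terminal is
   connected through a new bifurcation placed to minimize the total
   intravascular volume `sum(pi r^2 L)`, under equal terminal flows and a
   Murray power-law radius rule (`r_p^3 = sum r_c^3` by default). Transport
   in the trees is 1D advection at the per-edge mean velocity `v = Q / (pi
   r^2)`; concentrations pass junctions unchanged on the supplying side and
   mix flow-weighted ("instant mixing") on the draining side.
2. **Homogenized hepatic space.** Five subspaces per voxel — red blood
   cells, plasma, interstitium, cells, and a rest space that carries no
   compound — with volume fractions summing to one. The sinusoidal blood
   (rbc + plasma) percolates by Darcy flow: a pure-Neumann pressure problem
   `-div(K grad p) = q` driven by line sources along supplying terminal
   edges and line sinks along draining terminals, discretized with trilinear
   finite elements on the voxel grid, with the effective permeability fixed
   at one (only `grad p` matters; `p` is a relative pressure). The advected
   phases move with the face fluxes derived from `p`; draining terminals
   drain the volume-weighted average concentration of their neighborhood.
3. **Pointwise kinetics.** Passive, gradient-driven exchange across up to
   four subspace interfaces, each with a partition coefficient `K_ab`
   (exchange vanishes when `c_a = K_ab c_b`) and a volume-normalized
   permeability `P_ab` in 1/min; cellular metabolization as a pure sink with
   linear or Michaelis-Menten kinetics. These ODEs are integrated per voxel
   with an adaptive Runge-Kutta-Fehlberg 4(5) scheme.

One macro time step applies, in order: supplying-tree advection, HHS
advection with the terminal source/sink coupling, pointwise
exchange+metabolization, draining-tree advection fed by the neighborhood
averages. This is plain first-order operator splitting; the self-convergence
test (halving the macro step moves the outflow peak by less than one step)
guards the choice, and Strang splitting was deliberately not attempted.

## Discretization choices

**Advection.** Both the 1D and the 3D advection use a conservative explicit
upwind finite-volume scheme with characteristic-consistent sub-stepping: the
sub-step is the largest integer fraction of the macro step with Courant
number at most one on every cell. This realizes the contract of the
Eulerian-Lagrangian class of schemes this model family uses — exact mass
conservation (the per-step ledger closes to rounding, about 1e-15 relative),
no spurious oscillations, positivity preservation — at the cost of
first-order numerical diffusion. The diffusion shrinks under sub-grid
refinement (a tested property) and is partly physical in spirit: it mimics
the unresolved dispersion of sinusoidal transit times.

**Divergence mismatch.** Because the pressure comes from a finite-element
discretization and the advective fluxes from face-centered difference
quotients, the discrete velocity field is not exactly divergence-free near
the line sources. The transport is formulated in flux form, so the mismatch
can only dilute or concentrate locally; globally every unit of injected and
withdrawn mass is accounted in the coupling ledger, which is required to
agree with the vascular bookkeeping exactly.

**Draining sinks.** Each draining terminal withdraws `Q_leaf c_avg dt`,
distributed along its rasterized centerline proportionally to the line
weights and capped at the locally available mass (cap events are counted);
the concentration actually handed to the draining tree is
`removed / (Q_leaf dt)`, which makes the two modules' ledgers agree by
construction. The neighborhood radius for `c_avg` defaults to twice the
grid spacing; the averaging is volume-weighted and uniform in distance —
the distance-weighted alternative was considered and rejected for lack of a
physical argument at this resolution.

**Pure-Neumann nullspace.** The closed-organ pressure problem determines
`p` only up to a constant. The load is projected onto the compatible space
(mean zero over the element-supported nodes), one node is grounded for the
sparse Cholesky solve, and the solution is re-centered to zero mean.
Foreground voxels that belong to no complete hexahedral element (isolated
surface corners of the rasterized ellipsoid) carry no pressure degree of
freedom and no flux. On grids up to 12^3 the sparse path is tested against
a dense direct solve of the same assembled system at 1e-8.

**RKF45.** Classical Fehlberg tableau, local extrapolation off (the 4th
order solution advances), step-size update `0.9 (tol/err)^(1/5)` clipped to
a factor of 5 per step. The per-voxel ODEs are vectorized across grid nodes
with a shared adaptive step whose error bound is the maximum over nodes, so
the accepted step satisfies every node's local tolerance; this is the
vector-performance equivalent of integrating each node independently.

## Parameters and defaults

All defaults are desk-scale, synthetic study conditions, chosen once for
physiological plausibility in a mouse liver; none is a literature claim and
every one is a config value.

| parameter | default | unit | rationale |
|---|---|---|---|
| organ half axes | 8, 6, 4 | mm | ellipsoid of ~800 mm^3, mouse-liver scale |
| grid spacing `h` | 0.5 | mm | of the order of a lobule radius |
| `Q_liv` | 30 | mm^3/s | ~1.8 mL/min total hepatic perfusion |
| terminals per tree | 64 | — | desk-scale stand-in for production trees with hundreds of terminals |
| terminal radius | 0.15 | mm | keeps terminal velocities at a few mm/s at `Q_liv/64` per leaf |
| volume fractions | 0.062/0.098/0.163/0.577/0.1 | — | rbc/pls/int/cell/rest; PBPK-style proportions with a 10% rest space |
| macro step `dt` | 0.5 | s | fastest vascular edge needs < 10 Courant sub-steps |
| inflow | 50 umol/L for 10 s | — | square bolus; dose-based specification available |
| min edge length | `1.0 h` | mm | pruning/contraction threshold, exposed in config |
| neighborhood radius | `2 h` | mm | draining average support |
| hematocrit | 0.45 | — | in-vitro viscosity law reference value |

The three shipped compounds are synthetic archetypes: an inert lipophilic
tracer (`K_cell = 4`, no metabolization), a linearly cleared drug
(`k_met = 1.5`/min) and a high-clearance Michaelis-Menten drug
(`V_max = 60` umol/L/min, `K_m = 15` umol/L). Interface topology is the
serial chain rbc-pls, pls-int, int-cell; a fourth interface slot exists but
is off by default because no physiological pairing is singled out by the
model structure. The cell-interstitium interface is oriented so that its
partition coefficient is the cellular accumulation ratio
(`c_cell = K_cell c_int` at equilibrium).

The Fåhræus-Lindqvist effect uses the Pries et al. (1992) in-vitro law for
relative apparent viscosity as a function of vessel diameter and
hematocrit; the formula is reproduced in the `effective_viscosity()` help
page. In the current radius rule viscosity informs the hydraulic-resistance
diagnostics (`tree_resistance()`), while sibling radii follow Murray's law
from a fixed terminal radius — the standard choice in the constructive
optimization literature when only volume is optimized.

## Pathology models

**Steatosis** is a lipid volume-ratio field `rho(x)` in [0, 1). The
heterogeneous mode draws i.i.d. uniform noise on a grid four times coarser
than the computational resolution, interpolates it multilinearly, and maps
it through the enclosing lobe's `[lo, hi]` range — the mapping (rather than
interpolating already-mapped values) keeps every voxel inside its own
lobe's range and makes the per-lobe means equal the range midpoints, so the
homogeneous field (the volume-weighted mean of the midpoints) has the same
liver-wide lipid content by construction. Defaults give the first lobe
(playing the left-lateral role) the range [0.25, 0.45] and the rest
[0.05, 0.15]. Steatosis acts on kinetics only, through the cellular
partition coefficient: `K_cell(rho) = K_cell (1 - rho) + k_lip rho`, a
volume-weighted mixing of aqueous and lipid affinity anchored at the
healthy value. For lipophilic compounds (`k_lip > K_cell`) accumulation and
hence metabolization increase with `rho`. The mixing rule is a pluggable
strategy (`form` argument) so the exact mechanistic distribution-model
formula can be substituted.

**Pericentral necrosis** marks the fraction `gamma` (default 0.2) of the
organ closest to the draining terminal centerlines (exact point-to-segment
distances), replaces cellular by interstitial space there, and forces the
local metabolization and the cell-interstitium permeability to zero. The
volume-fraction sum stays one at every voxel. Perfusion is deliberately
unchanged — a known simplification of this minimal model.

## What the synthetic fixtures do and do not show

The standard fixture (two-lobe ellipsoid at 32^3 scale, 64 terminals per
tree) emulates the geometry class of a real study — a lobed organ, two
interdigitated trees, lobule-scale grid — but not a real liver: no true
lobe shapes, no image-derived vessel trunks, no anisotropic lobular
microarchitecture, and a terminal count well below a fully resolved organ.
Tests passing on it demonstrate the *mechanics* (conservation, convergence,
orderings, parameter recovery), not agreement with animal data. The
qualitative first-pass signatures it reproduces — the spatial outflow peak
arriving later and wider than the well-stirred reference, steatosis
increasing and necrosis decreasing the metabolized fraction, homogeneous
and heterogeneous steatosis of equal mean lipid giving distinguishable
outflow curves — are exactly the claims that survive the transfer to real
geometry in this model family.

Problem sizes used by the test-suite and the acceptance script: the 32^3
standard fixture (~6400 foreground voxels) for end-to-end runs of 60 s
simulated time, a coarser 16-terminal geometry for the clearance-recovery
fit, grids up to 12^3 for the dense-oracle checks, and 100 random trees for
the ledger property.

## Degenerate inputs and edge cases

* Disconnected mask foreground is accepted; the pressure problem lives on
  the element-supported connected component containing the sources, and
  element-unsupported voxels are flux-isolated.
* A zero-velocity edge simply holds its concentrations (no sub-step bound
  is derived from it).
* Draining sink withdrawal is capped at the locally available mass; every
  cap event is counted in the run metadata.
* The trunk (root edge) is never pruned or contracted; eliminating it
  degenerates the tree and raises an error when it is terminal.
* `gamma = 0` and `min_length = 0` are exact identities; `gamma = 1` marks
  the entire organ necrotic and provably metabolizes nothing.

## A worked run

```{r}
library(hepatoflow)

cfg <- simulation_config(duration = 60, compound = "mmdrug",
  pathology = list(steatosis = list(
    ranges = list("1" = c(0.25, 0.45), "2" = c(0.05, 0.15)),
    mode = "heterogeneous")))
res <- run_simulation(cfg)
res
mass_balance_report(res)
summarize_outflow(res$times, res$outflow, inflow_centroid = 5)
```

The same configuration with `mode = "homogeneous"` has the identical mean
lipid burden; comparing the two outflow curves pointwise is the package's
core heterogeneity experiment.

## Known limitations

First-order splitting and first-order upwind transport (numerical
dispersion is resolution-dependent); no molecular diffusion term; no
recirculation, bile ducts, separate hepatic-artery tree, or organ
deformation; metabolites are not tracked (metabolization is a sink);
steatosis affects only the cellular partition coefficient, not organ
volume, microcirculation or enzyme expression; necrosis does not alter
perfusion. Heterogeneous or anisotropic permeability is out of scope.
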