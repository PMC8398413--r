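---
title: "Modeling the mechanical microenvironment of perfused trabecular-bone scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the mechanical microenvironment of perfused trabecular-bone scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mesenchymal stromal cells seeded into decellularized trabecular-bone
scaffolds and cultured under continuous medium perfusion sense a mechanical
stimulus — wall shear stress of the order of millipascals — that cannot be
measured directly inside the construct. `trabeflow` reconstructs that
stimulus computationally. It models a perfusion-bioreactor cartridge holding
a stack of trabecular scaffolds at two levels of detail:

1. a **reduced-order Darcy model** of the cartridge: the scaffold stack is a
   porous plug of permeability $k$, calibrated from measured differential
   pressure via Darcy's law
   $$k = \frac{Q\,\eta\,L}{A\,\Delta p},$$
   with $Q$ the flow rate, $\eta$ the medium viscosity, $L$ the plug length
   and $A$ the cartridge cross-section;
2. a **pore-scale creeping-flow model**: the steady incompressible Stokes
   equations solved directly on the voxelized trabecular geometry, from
   which the wall shear stress $\tau = \eta\,\|\partial u_t/\partial n\|$
   on the solid–fluid interface, velocity and pressure statistics, and an
   effective (geometric) permeability are extracted.

Because no scan of the original scaffolds is available, the package also
provides a **synthetic microstructure generator** calibrated to the
morphometry reported for these scaffolds — porosity 90%, trabecular
thickness (Tb.Th) 120.7 µm, Gaussian pore-size distribution with mean
839 µm — plus the small scalar characterizations that accompany them
(compressive elastic modulus by stress–strain regression; EDS Ca/P weight
ratio).

The bundled operating point (`paper_fluid()`, `paper_cartridge()`,
`paper_flow()`, `paper_scaffold_spec()`, `paper_preset()`) is: medium
treated as water at 37 °C ($\eta = 0.6913$ mPa·s, $\rho = 993$ kg/m³),
$Q = 1.7$ mL/min, cartridge area $A = 78.5$ mm², scaffold stack
$L = 9$ mm. The pore Reynolds number at this point is
$\mathrm{Re} = \rho v d/\eta \approx 0.45$, firmly in the creeping-flow
regime, which is what justifies dropping inertia.

## The synthetic scaffold generator

### What it emulates

Trabecular bone of the femoral head is a network of connected plates and
rods. The generator builds a binary voxel image with three superimposed
Gaussian-random-field components:

* **Plates.** A band $|g_1| < t$ around the zero level of a *band-pass*
  ("single wavelength" $\lambda$) random field. Unlike a low-pass field,
  whose level bands have strongly variable spacing, the level surfaces of a
  band-pass field form a labyrinth of curved sheets with near-regular
  spacing $\lambda/2$ — which is what gives the generated scaffold a
  well-defined pore size.
* **Fenestrations.** A level band is a watertight surface: it would
  separate the pore space into two disconnected halves. Real trabecular
  plates are perforated, and so are ours: an independent low-pass field
  removes ~44% of the plate area as holes, so the fluid phase on both
  sides of every plate is one connected component.
* **Nodes.** A sparse set of thick blobs (~3% of volume) from a third
  low-pass field, emulating rod/node thickenings. Plates alone cannot
  reproduce the reported Tb.Th-to-pore ratio at 90% porosity: at a fixed
  solid budget of 10%, sheet thickness is tied to sheet spacing; the nodes
  lift the thickness mean without disturbing the pore size.

Porosity is imposed by quantile thresholding, so it is exact before
cleaning. After generation the grid is cleaned (`clean_islands()`): solid
not 26-connected to the main component is deleted, pore space not
6-connected to the inlet face is sealed, and the two passes iterate to a
fixed point so the operation is idempotent.

### Calibration

Three generator parameters map almost one-to-one onto the three target
statistics, which keeps the calibration loop trivial and monotone:

| knob | target | default (preset) |
|---|---|---|
| labyrinth wavelength $\lambda$ | mean pore diameter | 1250 µm |
| node volume fraction | Tb.Th | 0.028 |
| requested solid fraction | porosity after cleaning | 0.105 |

The loop regenerates (the white noise is drawn once per seed, so the loop
is deterministic and a fixed spec yields bit-identical grids), cleans,
measures with the package's own morphometry, and nudges each knob against
its own misfit, for at most 20 iterations; it fails loudly, naming the
violated statistic, if the targets cannot be met within ±0.02 (porosity)
or ±10% (Tb.Th, pore mean). The preset constants above were calibrated
once against the generator's own morphometry at the default resolution and
are shipped as starting values, so the default preset converges in one to
a few passes. Default resolution is 20 µm voxels in a 4 mm cube: Tb.Th is
then ~6 voxels, which the inscribed-sphere estimator resolves well; at
40 µm (used for the flow solve) it is ~3 voxels and visibly quantized.

### What it does not emulate

The synthetic pore-size distribution is narrower than the wide 100–2000 µm
Gaussian reported for real scaffolds (the regular labyrinth spacing is
exactly what makes the mean controllable), the structure is isotropic
whereas femoral-head trabeculae are oriented, and there is no sub-voxel
surface texture (lacunae, canaliculi). Tests passing on synthetic grids
therefore validate the estimators and the solver contract, not the
biological variability of real scaffolds.

## Morphometry

* **Porosity**: fluid voxels / total voxels.
* **Tb.Th**: mean over solid voxels of the local thickness map — the
  diameter of the largest sphere fully inside the solid containing each
  voxel, computed from the exact 3D Euclidean distance transform with
  sphere centres restricted to distance-ridge voxels (the classical
  maximal-inscribed-sphere definition used in bone morphometry). The
  estimator is exact to ±1 voxel on slab, cylinder and sphere phantoms.
* **Pore diameters**: the automated analogue of manually calipering 50
  pores: candidate centres are the 26-neighbourhood local maxima of the
  fluid-phase distance transform, ranked by size, greedily accepted with a
  minimum centre separation of one mean pore diameter (so one large void is
  not sampled twice), top `n_pore_samples` kept. A Gaussian fit is reported
  by moment matching (mean/SD of the sample); the truncated support of the
  real distribution is reported but not corrected for. Note the ranked
  sampling makes the statistic an extreme-value-weighted one: it grows
  mildly with domain size, which is why calibration targets it at the
  default domain.
* **Specific surface**: voxel-face interface area per total volume; on
  stair-step voxel surfaces this overestimates the smooth-surface area by
  up to ~1.5×, a known property shared by every voxel-counting method.

## The pore-scale Stokes solver

### Discretization and solution

The steady Stokes system is discretized on a staggered (MAC) grid —
velocities on cell faces, pressure in cell centres — which is exactly
mass-conservative and inf-sup stable. The scaffold is placed in a straight
duct with ≥5 all-fluid buffer layers upstream and downstream; boundary
conditions are a uniform velocity inlet (the flow distributed over the
inlet-face fluid cells), a do-nothing outflow with outlet gauge pressure
pinned to zero, and no-slip on solid walls and on the duct side walls.
No-slip at interior walls uses the halfway (ghost-reflection) convention:
the wall plane lies midway between the last fluid and first solid voxel
centre. When the domain is a subsection of the real cartridge, the
operating point is mapped by superficial velocity: the inlet carries
$v_s = Q/A_{cartridge}$ (0.361 mm/s at the preset), not the full device
flow.

The resulting symmetric saddle-point system (momentum rows scaled by
$h^2/\eta$, pressure variable $q = p\,h/\eta$ so all entries are O(1)) is
solved matrix-free by MINRES with Jacobi preconditioning on the velocity
block. A Krylov solve was chosen over pseudo-time relaxation because the
iteration count is set by the pore size rather than the domain size, and
over a direct factorization because a 100³ domain has ~4.5 million
unknowns. The iteration order is fixed, so identical inputs give
bit-identical fields, and — the rounding of scaling by two being exact —
doubling $Q$ doubles every velocity and pressure value exactly, a property
the tests assert literally.

Convergence: relative preconditioned residual below `tol`, default
$10^{-5}$. The pipeline preset and the acceptance runs use $10^{-4}$ on
the 100³ domain (~2600 iterations, minutes on one core); at that tolerance
cross-section flux is conserved to ~$10^{-5}$ relative, far inside the 1%
contract. Non-convergence within `max_iter` is never silent: the field is
returned with a flag and a warning, and the CLI exits with status 2.

Verification is by a Poiseuille suite: the developed profile in a square
duct matches the classical Fourier-series solution to <1% at 24 voxels
across (5% asserted); the error decreases monotonically under refinement;
a wide-slit geometry reproduces the plane-Poiseuille wall stress
$6\eta\bar v/h$ and the channel permeability $\varphi h^2/12$.

### Wall shear stress: two estimators

For every solid–fluid voxel face the per-face estimator is
$\tau = \eta\,\|u_t\|/(h/2)$ — a one-sided first-order gradient between
the no-slip wall (half a voxel away) and the tangential velocity at the
first fluid cell. This is the distributional estimator: median,
percentiles, the fraction of surface inside the 0.5–10 mPa band reported
to be osteogenic, and per-slab profiles all come from it. It is accurate
on wall-aligned geometry (within ~$h/2H$ of the plane-Poiseuille value)
but on oblique, stair-stepped walls it systematically under-reads the
surface-averaged stress of the underlying smooth wall: part of the true
surface traction appears as pressure (form) drag on the step faces rather
than resolved shear. No surface smoothing is applied.

The report therefore also carries a momentum-balance mean. For developed
flow in a prismatic pore space the axial force balance is exact:
$\bar\tau\,S_{wall} = \Delta p\,A_{fluid}$, so the area-weighted mean
wall shear stress is

$$\bar\tau = \frac{\Delta p \, A_{fluid}}{S_{wall}},$$

with $\Delta p$ the solved plane-averaged pressure drop across the
scaffold region, $A_{fluid}$ the pore (fluid) cross-section of that
region — using the full duct area instead would book the blunt-frontal
pressure drag on the solid as shear — and $S_{wall}$ the interface area.
This estimator is resolution-robust, agrees with the per-face mean on
wall-aligned geometry (asserted on a long slit, where the residual
difference is the entrance/exit pressure loss), and is the package's
headline mean WSS. At the preset operating point on the default synthetic
scaffold the per-face mean reads ~3.3 mPa while the momentum-balance mean
reads ~6.5 mPa — the difference is the stair-step form-drag fraction at
40 µm resolution.

### Effective permeability and the cross-model check

`effective_permeability()` applies Darcy's law to the solved field using
the pressure drop between the buffer planes bounding the scaffold. On the
90%-porous synthetic geometry it lands in the $10^{-9}$–$10^{-8}$ m²
range, consistent with a Kozeny–Carman estimate
$k \approx \varphi^3/(5 S_v^2)$ from the measured specific surface — and
three orders of magnitude above the $6.64\times10^{-12}$ m² obtained from
the measured circuit differential pressure. The package reports both and
does not reconcile them: a measured $\Delta p$ across the whole cartridge
circuit includes non-scaffold resistances, so a permeability calibrated
from it is an effective circuit property, not a property of a 90%-porous
plug. For the same reason the reduced-order model's printed-geometry
superficial velocity ($Q/A = 0.361$ mm/s) is reported alongside — not
reconciled with — the 0.16–0.166 mm/s figures quoted for the original CFD
models, which imply an effective flow area never stated in the printed
geometry.

## Characterization module

* `elastic_modulus()` is an ordinary-least-squares slope of stress on
  strain (`stats::lm`), over the full loading range by default since no
  linear-region selection is specified for these tests; a strain window
  argument is exposed for toe-region exclusion. The synthetic generator
  produces $\sigma_i = E\,\varepsilon_i(1+\epsilon_i)$ with multiplicative
  Gaussian noise, deterministic per seed.
* `ca_p_ratio()` is a weight (not molar) ratio: 0.47/0.6 wt% = 0.78, the
  convention under which residual mineral in partially decalcified
  scaffolds is quoted.

## Numerical choices and degenerate inputs

* All internal fluid quantities are SI (m, Pa, m³/s); grids carry spacing
  in µm; reports use mPa and mm/s. `flow_condition()` converts mL/min
  ($1$ mL/min $= \tfrac16\times10^{-7}$ m³/s).
* Connectivity: 26 for solid, 6 for fluid (the standard voxel-percolation
  convention); component ties broken by first-discovered label, fixed scan
  order.
* Distance transform: exact Euclidean, separable lower-envelope algorithm.
* All-solid or all-fluid grids: porosity is returned, thickness/pore
  statistics are `NA`. Porosity targets above 0.98 put the generator in a
  degenerate regime where only porosity is calibrated.
* Randomness: every stochastic component (noise fields, stress–strain
  noise) derives from an explicit integer seed through an RNG-state-safe
  wrapper; no global RNG state leaks.

## Problem sizes

Defaults were chosen so a full analysis runs on a laptop core: generation
and morphometry on 200³ voxels (4 mm at 20 µm) in ~20 s; the pore-scale
solve on ~100³ (4 mm at 40 µm, ~4.5 M unknowns) in a few minutes; the
verification suite on ducts of 10⁴–10⁵ cells in seconds. The original
study's 36-million-node scan-based mesh is deliberately out of reach at
desk scale; the factor-2 acceptance band on mean WSS reflects that.

## Known limitations

* Stair-step walls bias the per-face WSS distribution low and the specific
  surface high; both biases are documented rather than smoothed away.
* The synthetic pore-size spread is narrower than real scaffolds'; the
  Gaussian fit's SD should not be compared against the reported 100–2000 µm
  support.
* The reduced-order cartridge model neglects viscous tubing losses and
  pump pulsatility; the pore-scale model does not resolve the inlet/outlet
  pipes of the real cartridge, only a straight duct.
* Cyclic compression (the study's second stimulus) is out of scope: only
  the perfusion environment is modeled.
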