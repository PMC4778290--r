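---
title: "Modeling hepatic lobule perfusion and drug metabolism on a DLA lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hepatic lobule perfusion and drug metabolism on a DLA lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobulesim)
```

## The model

The liver lobule is approximated here as a hexagonal prism perfused from a
central portal inlet toward six hepatic-vein outlets at the hexagon
corners (the "portal lobule" orientation). Two continuum phases share a
regular lattice of 6 um cells: the **sinusoid** network (porosity 0.7854,
permeability 1.125 um^2 = 1.140 Darcy) and the **hepatocyte tissue**
continuum (porosity 0.2382, permeability 7.35e-2 um^2), with Newtonian
blood at 3.5 cP. Flow is slow and incompressible, so the pressure field
obeys Darcy's law,

$$ \nabla \cdot \left( \frac{K}{\mu} \nabla p \right) = 0, $$

with Dirichlet pressures on the inlet and outlet well cells. Dissolved
species (paclitaxel PAC, its hydroxylated metabolite PAC-OH, and a
normalized oxygen tracer) ride on the solved flux field by first-order
upwind convection, exchange between phases by harmonic-interface
diffusion, and react in tissue cells by saturable Michaelis-Menten
elimination $v = v_{max} x / (K_m + x)$, which at the studied injection
level ($1.8\times10^{-8}$ mole fraction, far below
$K_m = 1.8\times10^{-7}$) is effectively the linear rate
$v_{max}/K_m = 6\times10^{-3}\ \mathrm{min^{-1}}$.

All internal computation is SI (m, s, Pa, mole fraction); tabulated
working-unit values (um^2, Darcy, cm^2/min, uM, cP, cm^3/min) are
converted once at the boundary by `convert_unit()`. Micromolar and mole
fraction interconvert through the molar concentration of water, a named
and overridable constant (55.5 mol/L): 10 uM corresponds to 1.8e-7 mole
fraction. One Darcy is taken as exactly 0.9869 um^2.

## Sinusoid morphogenesis by sequential DLA

The sinusoid network is grown by five stages of on-lattice
diffusion-limited aggregation (`build_lobule_2d()`):

1. a main aggregation of `N_par` walkers (default 9500 on a 256-cell
   grid) nucleated at the grid centre;
2. a "de-crowding" erase aggregation (1200 walkers) on the central
   half-size subdomain, whose occupancy is subtracted;
3. a refill aggregation (800 walkers of size 2 x 2) on the same
   subdomain;
4. six corner aggregations (500 walkers each) on M/3 subdomains centred
   on the hexagon corners;
5. clipping to the bounding hexagon (across-corner diameter `M_dim`
   cells, area $S = 3\sqrt{3} d^2 / 8$), with the remainder labeled
   tissue.

The growth process itself is specified only loosely by the recipe, so the
walk rule is an explicit design choice: walkers launch at uniformly
random free cells and, at each step, move one footprint toward the
nucleus with probability `bias` and in a uniformly random 8-neighbour
direction otherwise; a walker leaving its subdomain is relaunched, and it
sticks as soon as any footprint cell is 8-adjacent to the cluster. A
nucleus footprint is pre-placed so the first walker has a sticking
partner. A sensitivity scan over `bias` from 0.05 to 1.0 (8 seeds each at
full scale) moved the areal density by less than one percentage point and
the realization-to-realization flow variability by less than a factor of
two, so the default is kept at 0.5, which gives the dense inward-reaching
aggregates the recipe is meant to produce.

Ports are the 3 x 3 in-hexagon blocks at the centre and the six corners,
forced to sinusoid; labels `A`-`F` run counter-clockwise from the east
corner and are stable but otherwise arbitrary. After clipping, any
sinusoid fragment not 8-connected to the inlet is bridged onto the main
network by a thin shortest path (0-1 breadth-first search that prefers
existing sinusoid cells), so the flow problem is well-posed for every
seed.

**What the areal density metric does and does not measure.**
`sinusoid_area_fraction()` counts labeled sinusoid lattice cells over
in-hexagon cells. With the default counts this is bounded above by
$(9500 + 4\cdot800 + 6\cdot500)/42{,}567 \approx 37\%$ and lands near
30% in practice (overlap, central erasure, corner clipping). Image-based
estimates of sinusoid areal coverage in real lobule micrographs are
higher (~45%) because the measured sinusoid lumen plus the space of
Disse is wider than one 6-um cell; a raw occupancy count on this lattice
is therefore expected to sit well below such image-derived figures, and
we deliberately do not inflate the metric (e.g. by dilation) to match
them.

### The 3D stack

`build_lobule_3d()` stacks independently generated DLA layers (6 um
thick) separated by `M_skip = 2` hepatocyte tissue layers (12 um thick,
the hepatocyte thickness scale), beginning and ending on a DLA layer: the
reference stack is 33 DLA + 64 tissue layers (`M_z_dim = 97`), height
966 um, bulk volume $S \times h \approx 1.48\ \mathrm{mm^3}$ at
$S = 1.53\times10^6\ \mathrm{um^2}$. Vertical sinusoid connectors — a
configurable fraction (default 1%) of in-hexagon columns per tissue
slab, restricted to columns with sinusoid within one cell in both
bounding DLA layers — approximate the inter-layer channels around
hepatocytes; they are straight 1-cell columns, a deliberate
simplification of the real, cell-shaped geometry. The central and corner
vein columns pierce every layer, so each layer is fed and drained in
parallel. Per-layer thicknesses (6/12 um) enter the solver through the
vertical transmissibilities rather than by resampling.

## Flow discretization

Finite volumes on the cell-centred lattice with harmonic-mean interface
permeability; sinusoid-tissue exchange is an ordinary lattice
transmissibility between unlike cells (no separate membrane resistance —
the space-of-Disse transfer is pressure-driven). Two stencils are
provided:

* `five_point` — faces only;
* `nine_point` (default) — faces carry 2/3 and in-plane diagonals 1/3 of
  the transmissibility, the "areal 9-point" style used by reservoir
  simulators to reduce grid-orientation bias. The diagonal link uses the
  physical diagonal geometry (length $\sqrt{2}h$, width $h/\sqrt{2}$,
  i.e. half a face's geometric factor), which makes the uniform-medium
  effective conductivity of the two schemes agree exactly; they match
  within 1% on a uniform hexagon in practice.

Wells are plain Dirichlet pressure cells (no Peaceman index): the model
fixes a pressure difference and lets rates emerge. The reduced system is
symmetric positive definite and solved by sparse Cholesky factorization,
with a residual check at 1e-10 and a conservation check
$\sum_\mathrm{ports} Q = Q_\mathrm{in}$ at 1e-8. Because the problem is
linear in the pressure drop, `calibrate_delta_p()` matches any target
total inflow exactly from a single unit-pressure solve; the reference 2D
calibration (total inflow 4.491e-6 cm^3/min) corresponds to roughly
100 Pa (~0.8 mmHg) across the lobule, a physiologically sensible portal
pressure gradient.

On a mirror-symmetric uniform hexagon the residual port-to-port spread
(max/min about 1.05) is dominated by the discretization of the hexagon
boundary and port blocks, not by stencil anisotropy; the 9-point scheme's
benefit shows as angular isotropy of the pressure field, which is the
property the test suite asserts.

## Transport

The dilute-tracer assumption decouples flow from composition: pressure is
solved once and species are superimposed. Each time step is operator
split:

1. **convection** — explicit first-order upwinding on the same link set
   as the pressure stencil; the step is bounded by the CFL limit
   `stable_dt()` $= 0.9 \min_i \phi_i V_i / \sum q_i^{out}$ (about
   1.8e-4 min at the reference 2D calibration);
2. **diffusion** — implicit backward Euler with harmonic-interface
   $\phi D$ coefficients, pre-factorized once per run (so it never
   limits the step); diffusivities are 2.5e-4 cm^2/min in sinusoid and
   2.5e-5 cm^2/min in tissue for both PAC and PAC-OH (similar-size
   molecules);
3. **reaction** — tissue cells only, 1:1 substrate-to-product; the
   linear mode uses the exact exponential decrement over the step and
   the Michaelis-Menten mode an unconditionally positive implicit
   update (closed-form quadratic), so the fast preset
   (6e-1 min^-1) is not stiffness-limited.

Upwind bookkeeping is telescoping, so the mass balance
(injected = in place + produced + reacted, and PAC consumed = PAC-OH
generated) closes to machine precision; `mass_balance()` flags any
closure error above 1e-6. A conservative tracer also satisfies the
discrete maximum principle, $0 \le x \le x_\mathrm{inject}$.

Under these conditions the lobule turns over roughly one pore volume per
minute, and the earliest outlet sees 50% breakthrough in ~0.6 min.
Conversion fractions scale as (linear rate) x (tissue residence), so at
the base rate only a small share of a transient bolus is metabolized
within the first minutes — diffusion, which carries drug into the
low-velocity tissue where it dwells, visibly raises conversion, and the
slow/base/fast presets order cumulative metabolite production
accordingly.

## Oxygen-driven zonation

CYP-mediated metabolism is not uniform across the lobule; its spatial
pattern is tied to the oxygen gradient. The oxygen model here is a
deliberate reconstruction, kept as simple as the stated behaviors allow:
steady linear convection-diffusion with first-order uptake
(`k_o2 = 10 min^-1`) in tissue, inlet level normalized to 1.0 ("normal")
or 0.1 ("low"), solved by sparse LU on the upwind operator. The CYP
multiplier is a linear, decreasing function of oxygen — the perivenal
("reversed") pattern, with more enzyme where oxygen is low — clamped
against a **fixed absolute reference level** `o2_ref` (the normal inlet
value) rather than min-max rescaled per scenario. The absolute reference
matters: the steady oxygen equation is linear, so per-scenario rescaling
would make every scenario's map identical; against a fixed reference, the
uniformly hypoxic "low" scenario maps to a nearly uniform multiplier
(range under 0.05 after normalization) while the "normal" scenario spans
a strong periportal-to-perivenal gradient (roughly 0.7-1.2). The
multiplier is normalized to unit mean over tissue so total enzymatic
capacity matches the uniform base case; a periportal (inverted) response
is a one-flag option.

Because all zonation quantities are reconstructed, the package asserts
only orderings and closeness, never magnitudes: the low scenario's
production is within 2% of the no-zonation case; at the slow rate the
normal scenario departs measurably and converts *less* (the enzyme is
displaced downstream, where less substrate reaches it before exiting).

## What the generator does and does not emulate

The synthetic morphologies reproduce: a spanning, branched, seedable
sinusoid network with realistic areal porosity contrast; corner drainage
structures; layered 3D organization with sparse vertical anastomoses;
and port-to-port flow asymmetry (~15% CV at full scale, visibly smoothed
in 3D). They do not reproduce: curved or image-traced vessel paths,
hepatocyte-scale discreteness, disease remodeling, or the large
realization-to-realization conductance spread reported for some lobule
ensembles — with a fixed occupied-cell budget and a 15x permeability
contrast, total conductance self-averages over the ~42,600-cell lattice
(realization CV ~2%). Passing tests therefore certify the physics and
bookkeeping of the solver on this geometry class, not fidelity to any
particular imaged lobule.

## Numerical choices and degenerate inputs

* Indexing is (row, col[, layer]), 1-based in R, 0-based row-major in
  the text containers; documented once in `write_morphology()`.
* All randomness flows from one master seed: stage sub-seeds (main,
  erase, refill, six corners; per-layer and connector streams in 3D) are
  drawn from it by a fixed rule, so builds are bitwise reproducible.
* Walkers that exceed 200 x `M_dim` steps or exit their subdomain are
  relaunched; a saturated walk domain (possible for reduced-scale
  recipes, since the main particle count scales linearly with `M_dim`
  while cell counts scale quadratically) stops attaching with a warning
  rather than spinning.
* Degenerate cases: an all-outside morphology, overlapping wells, a
  disconnected inlet, CFL violations, negative concentrations beyond
  -1e-14, and mismatched zonation grids all raise immediate errors; a
  degenerate (uniform) oxygen field maps to a multiplier of exactly 1.
* Ties in the centre-seeking walk step are broken by a fixed direction
  order; hexagon corner cells round toward the grid centre so opposite
  ports are exact mirrors, and the inlet block is centred on
  `ceiling(M/2)`.
* Test problem sizes: module tests run on 32-cell lobules built with
  area-scaled particle counts (so the reduced lattice keeps the
  reference subdomain densities and stays two-phase); the end-to-end
  checks build full 256-cell lobules, where a morphology takes ~0.1 s,
  a pressure solve ~1.5 s, and a breakthrough transport run a few
  seconds.

## Known limitations

* Single inlet: no hepatic-artery supply, no transient pressure, no
  compressibility, Newtonian blood only.
* No protein binding, transporter kinetics, or multi-drug competition;
  metabolism is a single 1:1 conversion confined to tissue cells.
* The oxygen/zonation submodel is a minimal reconstruction; its
  parameters (`k_o2`, diffusivities, multiplier range) are exposed
  configuration, not fitted quantities.
* First-order upwinding is monotone but diffusive; halving the time step
  changes port curves by well under 1%, but sharp fronts are smeared by
  a few cells.
* The areal density of the generated networks (~30% of the hexagon) is a
  consequence of the fixed particle budget, as discussed above; studies
  needing denser networks should raise `N_par` explicitly.
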