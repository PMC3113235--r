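---
title: "Steady-state VEGF isoform transport around a capillary sprout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state VEGF isoform transport around a capillary sprout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vegfgrad)
```

## The model

`vegfgrad` computes the steady-state extracellular distribution of a single
VEGF-A splice isoform (and its proteolytic fragment) in an axisymmetric
tissue cylinder centred on a capillary sprout, together with the occupancy
state of the sprout's VEGF receptors. The domain is z ∈ [−80, +80] μm,
r ∈ [0, 50] μm; the sprout occupies r < 2 μm for z < 0, with the tip cell
spanning the front 40 μm of its surface (515 μm² of membrane).

Four interstitial species are tracked per unit of *available* interstitial
fluid volume (the matrix excludes a fraction 1 − K_ECM = 0.15 of tissue
volume):

* `V` — soluble full-length VEGF of the secreted isoform. It diffuses
  (D = 68.6 μm²/s), binds HSPG sites, is cleaved at rate k_P, and may be
  degraded at k_deg_V.
* `VH` — matrix-bound VEGF. Immobile; unbinds at koff = 0.01 s⁻¹, is
  cleaved at k_P (releasing the fragment and its site), and may be degraded
  at k_deg_VH.
* `Vc` — the cleaved fragment (VEGF114). Diffusible, non-heparin-binding,
  non-NRP1-binding, receptor kinetics identical to VEGF121. It is not
  cleaved further and not subject to k_deg (see *Design choices*).
* `H` — free HSPG sites, algebraically `H_total(z) − VH`; destruction of a
  `VH` complex returns its site, so sites are conserved.

HSPG on-rates follow from measured equilibrium constants,
kon = koff/Kd (6.06·10⁴ M⁻¹s⁻¹ for VEGF165 at Kd = 165 nM, 1.18·10⁶ at
8.5 nM for VEGF189); with [V] ~ 1 pM ≪ Kd the sites never approach
saturation and the bound pool is locally proportional to the soluble pool.
At steady state this makes the soluble field *independent of reversible
matrix binding* — the starting paradox the degradation variants resolve.

Model variants switch the loss terms:

| variant | k_deg_V | k_deg_VH | HSPG profile |
|---|---|---|---|
| `hspg_only` | 0 | 0 | uniform 750 nM |
| `hspg_gradient` | 0 | 0 | 750 nM at z = 0, +30%/40 μm toward the source |
| `soluble_deg` | 10⁻³ s⁻¹ | 0 | uniform |
| `matrix_deg` | 10⁻³ s⁻¹ | 10⁻³ s⁻¹ | uniform |

`matrix_deg` implements *isoform-specific degradation*: all species share
one rate constant, but isoforms with higher matrix affinity spend more of
their lifetime bound, so their effective loss rate is amplified by
(1 + H_total/Kd). Equivalently the total pool diffuses with
D_eff = D/(1 + H_total/Kd) against a first-order sink — matrix binding
potentiates both proteolysis and degradation.

The sprout surface carries VEGFR1, VEGFR2 and NRP1 (10⁴/10⁴/3·10⁴ per tip
cell area, uniformly over the whole sprout). The network comprises direct
ligand binding to each receptor, bridging of V·R2 with NRP1 (and V·N1 with
R2), coupling of free VEGFR1 with NRP1 (which sequesters almost all VEGFR1
as R1N1 at these densities), binding of non-NRP1-binding ligands to that
preformed complex, and internalization of every surface species at
k_int = 2.8·10⁻⁴ s⁻¹ balanced by insertion of unligated receptors — so
surface totals are constant at steady state. Surface reactions enter the
transport problem as homogenized sinks in the adjacent control volumes.

Hypothetical isoforms along the HSPG-affinity continuum interpolate the
canonical ones: the NRP1 on-rate and the V·R2–NRP1 coupling rate scale with
165/Kd (preserving the thermodynamic cycle), while the forward rates toward
the VEGFR1–NRP1 complex ramp as (Kd − 165)/165 above Kd = 165 nM, clamped
at the full VEGF121 rate (10⁷) so the non-binding limit recovers VEGF121
exactly. The clamp is one consistent reading of a ramp that would otherwise
diverge; it confines the transition to Kd ∈ (165, 330] nM.

## Boundary drive and calibration

VEGF is secreted at z = +L (flux q, full-length only) and cleared at
z = −L (first-order velocity k_clear, both soluble species); the outer
radius and the axis are no-flux. Because receptor uptake distorts the field
near the sprout, q and k_clear are *calibrated*: stage 1 solves with
Dirichlet values V0(1 ± g0·L/L_tip) (V0 = 1 pM, g0 = 5%/40 μm) with
degradation and proteolysis off; stage 2 converts the converged boundary
fluxes to the Neumann pair by area-averaging (q from the secretion face,
k_clear as flux over mean adjacent concentration at the clearance face).
The averaging preserves V0 and g0 only approximately. HSPGs may be present
or absent during stage 1 without changing the result (a tested property).
The preset scenarios carry the calibrated table values
(q = 5.27·10⁻⁵ molecules μm⁻²s⁻¹, k_clear = 0.0399 μm/s with receptors;
4.39·10⁻⁵ and 0.0948 without), and `calibrate_neumann()` re-derives them.

## Numerical method

Finite volumes on a tensor (z, r) mesh: 8 μm axial spacing; radially one
cell spans the sprout radius and 8 μm rings continue outward (pass
`dr_fine = 4` to `build_grid()` for a refined band next to the sprout).
The r = 0 axis is a zero-area face, so no coordinate singularity arises;
the sprout end-cap area is folded into the frontmost lateral patch and tip
patch areas are normalised to the stated 515 μm², because receptor totals,
not patch geometry, drive the results.

The steady state is found by a fully implicit first-order pseudo-transient
march (dt from 1 s, ×1.5 growth, capped at 2000 s). Within each step the
linear interstitial systems are relaxed by red–black SOR (ω = 1.5 by
default; the result must be and is relaxation-independent), the immobile
bound pool is eliminated analytically into the soluble equation (avoiding a
stall on the fast binding-exchange equilibrium), and the surface network is
advanced by a stiff ODE integration with local concentrations frozen —
operator splitting whose error vanishes at the fixed point. Convergence
requires a per-node relative change below 10⁻⁷ at the maximal step; a final
*polish* phase iterates the steady equations directly (the infinite-step
limit) so the global mass balance closes to ~10⁻⁷ relative even for slow
mass-loading modes (the VEGF189 bound pool turns over in days of model
time). Degenerate meshes are supported and exact where symmetry allows: a
single radial ring reproduces sprout-free solutions, which the sweep engine
exploits.

Verification is two-route throughout: closed-form and dense (0.1 μm) 1D
finite-difference oracles for the transport problem, and a damped
fixed-point solver for the surface network, none of which share
discretisation code with the production solver.

## Metrics conventions

Tip gradients are evaluated between the *front* (z = 0) and *back*
(z = −40 μm) faces of the tip cell; with 8 μm rows the face values are
linear interpolations of adjacent rows. Interstitial fields are read at a
fixed sensing radius r = 6 μm (the centre of the first 8-μm interstitial
ring of the reference mesh); this makes the gradient metrics insensitive to
the radial discretisation (≈1–2% across a fourfold refinement) where
reading the adjacent-cell value directly would move with the mesh. Because
the surface patches do not couple laterally, the receptor densities at the
tip faces are computed exactly as the network's steady response to the face
ligand concentrations. Absolute gradients (AG) are reported in pM per
40 μm; fractional gradients normalise by mean tip total soluble VEGF (FG)
or by the species' own tip mean (IFG); receptor gradients normalise by
occupied or total receptor; sensitivities are S = IFG(complex)/IFG(ligand),
which equals 1 − FO for a single receptor–ligand pair. A `bands = "row"`
variant reports coarser single-row front/back bands rescaled to 40 μm.

Molecule totals integrate concentration × available volume per cell
(surface species: density × patch area). The capture fraction divides
internalization flux by total secretion; both the whole-sprout and the
tip-cell-only fractions are reported, since receptors cover the entire
sprout but the tip cell is the sensing unit.

## Design choices where the formulation was open

* **Cleaved VEGF and degradation.** The fragment escapes the degradation
  term entirely (it is removed only by clearance and receptor capture).
  This is consistent with degradation mechanisms that act through the
  heparin-binding/NRP1 domain the fragment lacks, it makes total soluble
  VEGF strictly increase with protease activity across the whole sweep grid
  in the matrix-degradation variant, and it reproduces the reference
  compartment totals for the matrix-binding isoforms under proteolysis far
  better than the alternative (degrading the fragment at k_deg_V caps total
  VEGF at influx/k_deg, which those totals exceed). The trade-off: a
  VEGF121 system is then *not* indifferent to proteases in the degradation
  variants, because cleavage converts a degradable species into a
  non-degradable one.
* **Matrix-degradation totals.** Under the receptor-free drive, global mass
  balance bounds total molecules by influx/k_deg ≈ 345; reference totals
  for VEGF165/189 sit at or above this ceiling and are therefore not
  exactly reproducible under the stated conditions — the package computes
  ≈ 320 and ≈ 345 (no protease). VEGF121 (229) is reproduced exactly. The
  acceptance tests assert the reference values and document the residual as
  irreducible.
* **HSPG gradient direction** (`hspg_gradient`): increasing toward the
  secretion face, anchored at 750 nM at z = 0.
* **Sprout coverage.** Receptors populate the full sprout surface at
  tip-cell density; covering only the tip is inconsistent with the
  calibrated clearance velocity (it roughly doubles it).
* **Whether intact VEGF189 binds VEGFR2** is uncertain; the
  `allow_V189_R2` flag defaults to binding with VEGF165 kinetics, and the
  receptor-binding map is insensitive to the choice because the long
  isoform is mostly cleaved or degraded wherever receptors see it.

## What the presets emulate — and what they do not

The preset scenarios (`build_figure_scenario()`) encode idealised
single-isoform secretion into an acellular, uniformly parameterised matrix:
spatially uniform protease activity and degradation, a single static
sprout, receptor totals held constant by turnover, and clearance lumped
into one boundary velocity. Real tissues add cellular uptake throughout the
interstitium, spatially structured matrix and basement membranes, protease
activation/inhibition dynamics, ligand-induced receptor trafficking,
direct signalling by matrix-bound VEGF, and moving sprouts with filopodia
that sample beyond the tip surface. Passing tests therefore demonstrate the
internal consistency of this transport model and its numerical solution —
not that tissue VEGF gradients are quantitatively predicted.

## Known limitations

* Steady state only; pseudo-time is not physical time and transient
  redistribution after a perturbation is out of scope.
* The surface network omits lateral receptor diffusion (Damköhler number
  ≈ 160 makes reactions surface-local) and any species beyond the eleven
  complexes of the canonical systems (e.g. a cleaved-VEGF·NRP1 complex,
  which the fragment cannot form).
* The C-terminal cleavage fragment of HSPG-bound VEGF is not tracked; with
  sites far from saturation it does not feed back on the balance.
* Concentrations are deterministic continuum fields; at ~1 pM the domain
  holds only hundreds of free molecules, so stochastic effects on single
  filopodia are outside the model.
* Reported problem sizes: the reference mesh has 20 × 8 control volumes
  (130 interstitial unknowns) and 10 surface patches; sweeps use the exact
  radially-degenerate mesh. These resolutions change every reported metric
  by under 5% relative to a twofold refinement (a tested property).
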