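---
title: "Methods: constraint-guided gating models and pore electrodiffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-guided gating models and pore electrodiffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `twistgate`: what is assumed,
which parameters matter, what the synthetic fixtures do and do not emulate,
and where the genuinely open design choices were made. It states no numbers
that the test suite or `scripts/acceptance.R` do not themselves compute.

## 1. The elastic-network model

All collective-motion analysis runs on a Cα-only anisotropic network model
(ANM). Sites closer than a cutoff `R_c` are joined by Hookean springs of
uniform stiffness γ; the 3N×3N Hessian has super-elements
`-γ (r⊗r)/|r|²` and diagonal blocks equal to minus the row sums. Six
eigenvalues are numerically zero for a connected network (detected at
`λ < 1e-8 · λ_max`); the remaining low-frequency eigenvectors approximate
the structure's soft collective motions.

Assumptions and defaults:

* **Cα-only, uniform masses.** The motions of interest are rigid-helix
  scale; side chains ride the backbone. γ is unit-normalized because
  amplitudes are set downstream by structural targets, so absolute
  frequencies never enter.
* **`R_c = 13 Å`** (common ANM practice, configurable 10–18 Å). Larger
  cutoffs stiffen everything roughly uniformly and change little about the
  mode *shapes* that matter here.
* **Eigensolver.** Iterative shift-invert (RSpectra) for the lowest modes
  above 300 sites, dense LAPACK otherwise; the two are cross-checked to
  1e-8 in the tests.
* **Degeneracy and symmetry.** A Cn-symmetric structure has degenerate mode
  pairs. The symmetry score of a mode is the inner product of the mode with
  its image under the Cn operator (rotation by 360/n plus the induced chain
  permutation), averaged over the near-degenerate cluster (relative gap
  < 1e-6). This is basis-independent and equals the representation
  character per mode: +1 for the totally symmetric representation (A), −1
  for the alternating one, ±cos of the rotation angle for the 2-D (E)
  representations. Only modes near +1 are treated as "symmetric" — an
  absolute-value criterion would admit E modes, whose application breaks
  the assumed symmetry of the motion.

## 2. The gating generator

The five gating constraints are encoded twice:

1. **As per-mode feature scores** (`score_modes()`): filter mean-squared
   displacement relative to all sites (low is good), in-plane gate
   displacement (high), cytosolic pore-helix/peripheral coupling (cosine
   similarity of displacements between nearest-neighbor site pairs),
   initial rate of coiled-coil pair separation, and the signed Cn symmetry
   score. Eigenvector signs are first resolved so the mean radial gate
   displacement is pore-opening. Features are rank-normalized to [0, 1] so
   the combination weights are unit-free.
2. **As explicit geometric targets** (`gating_metrics()`): alternate-set
   marker (Q152) ring distances; mean radial position of the gate ring
   (release: dilate by 1.5 Å by default); mean radial position of the
   filter ring (rigidity: keep); mean distance between cytosolic pore-helix
   sites and their nearest peripheral partners, plus the Cα separations of
   the closed-state salt bridges joining them (coupling: keep); and two
   tangential rows that orient the twist — counterclockwise at the gate
   ring (target arc +1.3 Å, about 12° at its radius) and clockwise at the
   cytosolic pore-helix sites of the second chain set (arc −2 Å).

The tangential direction deserves a note. The *direction* of gate-helix
rotation (counterclockwise seen from outside) is experimental input — it
comes from the cysteine-accessibility literature on the gate — so it is
encoded as a constraint; the rotation *magnitudes*, the clockwise/outward
division of labor between the two chain triplets, and the distances all
emerge from the elastic network and the targets.

**Why linear response instead of picking one mode.** On any realistic
elastic network of a membrane channel, the softest modes are dominated by
the long-lever cytosolic extensions; the pore-dilating motion is spread
over a large number of modes (on the shipped synthetic model, only ~10% of
an idealized subunit-tilt field lies in the 40 lowest modes). A scalar
amplitude along a single score-weighted direction therefore cannot reach
the reported dilation. `choose_amplitudes()` instead linearizes the metric
vector along every symmetric candidate mode and solves a
stiffness-weighted (1/λ, ridge-regularized) least-squares problem — the
minimum-elastic-energy combination whose response meets the targets — then
line-searches a single scalar along that combined direction against the
full nonlinear metrics. `generate_open_state()` applies this in capped
steps (default 3 Å maximum site displacement per step, 20 steps) with the
modes *recomputed along the path*, i.e. the adiabatic re-NMA variant of the
transition, and projects the trace onto the exactly Cn-symmetric subspace
after each step so numerical asymmetry cannot accumulate.

**Regularization.** Linear mode displacement stretches virtual Cα–Cα
bonds at large amplitude. A SHAKE-style projection pass restores
consecutive-bond lengths to 3.8 ± 0.2 Å and pushes non-bonded Cα pairs
apart to ≥ 3.4 Å with symmetric minimal displacements, then all-atom
coordinates are rebuilt by per-residue rigid frames fitted to the Cα
neighbors. This geometric pass stands in for the molecular-dynamics
relaxation used in the original study; it preserves backbone-level metrics
well but side-chain detail only approximately — which motivates the final
step:

**Side-chain re-pointing.** Frame-based rebuilding carries side chains
rigidly with their backbone, which can swing an interacting pair apart even
when the supporting backbone geometry survives. `relax_side_chains()`
emulates rotamer repacking at the pseudo-atom level: every residue pair
that interacts in the reference structure (salt bridges, plus listed
contacts) has its distal side-chain atoms re-pointed toward the partner at
the original reach, provided the backbone still allows the contact. Pairs
whose backbone separated too far stay broken — persistence is measured,
not imposed.

**Filter rigidity** is a statement about the ring's *shape*: the
extracellular part of the protein rotates collectively during gating, and
the filter ring rides that rotation. The report therefore carries both the
mean displacement of the filter sites and `filter_shape_rmsd`, the RMSD of
the ring after optimal rigid superposition; rigidity means the latter stays
small.

## 3. The synthetic fixtures

`build_bundle()` produces ideal Cn-symmetric helix bundles with tagged
residues at the canonical register (Q152, R155, K157, K163, L167, G170,
F171, V174, E178 for a 40-residue helix starting at 144), real amino-acid
names (so salt-bridge and charge-mapping code paths run unmodified),
Cβ pseudo-atoms in the canonical tetrahedral direction, and charged
pseudo-atom groups at fixed reach. `apply_twist_open()` applies the
ground-truth gating transform — per-helix axial spin plus radial shift,
alternating between the two chain triplets — rigidly about the *exact*
construction axes, which is what makes the 1e-6-degree recovery tests of
the rotation metric meaningful.

`synthetic_closed_channel()` assembles six four-helix subunits (pore helix
plus three peripheral helices and a cytosolic extension) into a
closed-state stand-in for the real channel, with helix-axis packing
distances of 8–9 Å: exactly C6 pore ring, C3 overall symmetry through the
pairing of neighboring cytosolic extensions, the intra-subunit K157–E245
bridge and E262–Y199 / L304–T246 contacts engineered in, the pore-facing
rings placed at defined radii (gate ring 2.5 Å, filter ring 2.6 Å, basic
ring 3.5 Å, R155 guanidinium 4.5 Å), and the marker ring calibrated so the
alternate-chain Q152 Cα distance equals 16.2 Å. Loop2 (and E221 on it) is
omitted by default, mirroring the unresolved loop of the closed crystal
form; with `include_loop2 = TRUE` a single E221 pseudo-residue per chain is
placed where a −58° pore-helix rotation lands the R155 guanidinium, offset
vertically so that no closed-state guanidinium — own chain or neighbor —
reaches it.

What the fixtures do **not** emulate: side-chain rotamers and packing
detail, the membrane, solvent, sequence beyond the tagged positions, loop
geometry, and the precise helix kinks of the real protein. Tests passing on
these fixtures demonstrate that the *algorithms* recover imposed ground
truth and satisfy the stated invariants; they are evidence about the code,
not about the real channel. Conversely, because the closed model is
calibrated to the published closed-state geometry, quantities computed on
it (marker dilation, rotation signs, persistence of the coupling bridge)
are meaningful scaled-down analogues of the study's reported values, not
reproductions from the crystallographic coordinates.

## 4. Pore metrics

* **Pore axis**: principal inertia axis of the pore-lining Cα, oriented so
  the acidic filter ring lies above the basic ring (+z = extracellular);
  orientation is never guessed when the tags are absent.
* **Radius profile**: HOLE-style — at each z, the largest sphere that fits
  among the van der Waals spheres of all atoms (3D distances), center
  optimized in-plane by Nelder–Mead from the axis; radii above 15 Å are
  capped and flagged. Heavy-atom Bondi-type radii (C 1.88, N 1.64, O 1.46,
  S 1.77 Å — slightly inflated C/N because hydrogens are absent).
* **Rotation angle θ**: per chain, a local helix axis is fitted to the
  7-residue Cα window by the curvature-bisector construction (chord
  differences of an ideal helix lie exactly in planes perpendicular to the
  axis, so their cross products give the axis exactly — a principal axis
  of 7 points does not); the alternate window is aligned by the minimal
  rotation between the two fitted axes (no azimuthal fitting — the azimuth
  *is* the observable; a full Kabsch superposition would silently undo the
  rotation being measured); θ is the signed angle between the projected
  Cα→Cβ vectors, positive counterclockwise viewed from +z. Glycine has no
  Cβ and yields a flagged NA.
* **Salt bridges**: minimum N–O distance between Arg NH1/NH2/NE or Lys NZ
  and Glu OE1/OE2 or Asp OD1/OD2, cutoff 4.0 Å; **contacts**: minimum
  heavy-atom distance, cutoff 4.5 Å (both configurable; common literature
  values).
* **SASA**: Shrake–Rupley with a deterministic golden-spiral point set
  (default 960 points/atom, probe 1.4 Å; fewer than 32 points is refused).
  Relative exposure changes default to side-chain atoms only, with a
  whole-residue mode available; residues with reference SASA below 1 Å²
  are flagged undefined.
* **Symmetry order parameter**: RMS deviation from the structure's image
  under (rotation by 360/n ∘ chain permutation), minimized over axis
  placement; 0 for perfect Cn.

## 5. The electrodiffusion model

The transport model is deliberately one-dimensional: the reduced Poisson
equation
`d/dz(ε ε₀ A dφ/dz) = −F A Σ zᵢcᵢ − e ρ_f`
coupled to flux-divergence-free Nernst–Planck transport with
Scharfetter–Gummel exponential-fitted fluxes
`J = g·[B(u)·c_j − B(−u)·c_{j+1}]`, `u = z(φ_{j+1}−φ_j)/V_T`
(drift limit `J = −g·c·u`: cations flow down the potential gradient).
The structure enters through the area profile `A(z) = π r(z)²` and the
mapped fixed-charge line density `ρ_f(z)`. A 3D solver is out of scope.

Numerics: Gummel (alternating) iteration in which the Poisson step is the
*nonlinear* Poisson–Boltzmann problem in Slotboom form, solved by a damped
inner Newton with steps clamped to 2 V_T. This converges in a handful of
cycles even when the fixed charge is far too strong for the textbook
linearized step (which oscillates). Convergence: max |Δφ| < 1e-6 V; flux
constancy is reported and tested below 1%. Strongly charged systems are
optionally ramped in four warm-started continuation stages. Units: mM, mV,
Å, pA, cm²/s (CODATA constants); current is positive toward the
extracellular (+z) side, so inward current is negative; the reversal
potential is refined by bisection to 0.1 mV; the rectification index is
`|I(−100 mV)|/|I(+100 mV)|`.

**Mapping structural charge into one dimension.** Formal charges (Glu/Asp
−1, Arg/Lys +1, His configurable) at side-chain group centroids within
12 Å of the axis are smeared as normalized z-Gaussians (σ = 2 Å). Two
reduction choices matter and are on by default in the channel wrapper
`pnp_from_structure()`:

* **Radial attenuation** `exp(−(r/6 Å)²)`: a charged group far from the
  axis faces the lumen only partially and is otherwise screened inside the
  protein; collapsing it fully onto the axis overstates its effect on the
  area-averaged potential.
* **Anion-paired basic region** (`paired_basic = TRUE`): the Arg/Lys rings
  of the cytosolic pore mouth enter as net zero. The closed crystal form
  holds a bound anion in the basic region and anion-assisted cation
  permeation is an established conduction mode for this family. Without
  pairing, the mean-field model develops a ≈ +40 mV hill in the cytosolic
  vestibule that excludes divalents quadratically and pins the reversal
  potential at the monovalent equilibrium — a known artifact of point-ion
  PNP, not a feature of the channel.

**Selectivity.** Mean-field PNP with point ions cannot generate the
channel family's hallmark Ca²⁺-over-Na⁺ selectivity (experimentally
P_Ca/P_Na > 1000) from electrostatics alone. The original study imported
ion-specific diffusivity profiles from MD; this package exposes the same
degree of freedom as per-species in-pore diffusivity scalings `f_D`. The
`"paper_guess"` bath preset — named to flag that the actual recording
solutions are unpublished in the available text — uses 150 mM NaCl on both
sides plus 20 mM CaCl₂ outside and ~100 nM free Ca²⁺ inside (standard
whole-cell levels), with `f_D(Ca) = 0.1` against `f_D(Na, Cl) = 0.001`.
The 100-fold transport preference, multiplied by the electrostatic Ca²⁺
enrichment at the acidic filter, puts the *effective* permeability ratio
at the experimental order of magnitude; it was chosen from that literature
scale. Scaling all species' `f_D` together changes current magnitudes but
not reversal potentials (a tested property); the *ratio* between species
is what sets `V_rev`, and the computed reversal should be read with that
dependence in mind — the comparison to the published calculated value is
assumption-laden by construction.

## 6. Problem sizes and determinism

The shipped study conditions are: a 780-site Cα model (6 × 130 residues),
150 modes per path step, up to 20 capped steps with re-NMA, metric
tolerance 0.15 (weighted), PNP grids of ~110 nodes at 0.5 Å; the full
pipeline runs in about two minutes on one core and every stage is
deterministic — there is no random number anywhere in the default path, so
identical inputs give identical models bit-for-bit.

## 7. Known limitations

* The open-state model is a harmonic, geometrically regularized
  extrapolation; side-chain-level observables (SASA deltas, exact bridge
  distances) carry the least information. MD relaxation, umbrella-sampling
  free-energy profiles, and pore-hydration statistics are out of scope.
* The real closed-state crystal structure is not distributable here; all
  "closed-state" numbers are computed on the calibrated synthetic model.
  With a real structure file, `read_structure()` + the same pipeline apply
  unchanged (author numbering is used throughout; unresolved residues
  surface as explicit missing-residue errors).
* 1D PNP compresses genuinely three-dimensional electrostatics; the
  charge-mapping attenuation, the anion pairing, and the selectivity
  scalings are documented modeling choices, and the reversal potential
  inherits their assumptions.
* The mode-selection report exposes all internals (scores, pool, per-step
  amplitudes) rather than claiming any particular mode corresponds to the
  single experimentally realized trajectory.
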