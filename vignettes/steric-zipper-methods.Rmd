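---
title: "Models and methods: parallel vs antiparallel steric-zipper assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: parallel vs antiparallel steric-zipper assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stericzipper)
```

This vignette is the package's own account of the science it implements:
the geometric model of steric-zipper nanocrystals, the scattering and
hydrogen-bond observables, the coarse-grained energy model and its
replica-exchange and block-cutting protocols, and the design decisions
taken where more than one defensible choice existed.

## The geometric model

A hexapeptide strand is built by forward kinematics from ideal bond
lengths and angles (Engh–Huber-type values) at a fixed pleated (φ, ψ) =
(−120°, 115°). Backbone N, H, CA, C and O atoms are exact; the C-terminal
carboxylate is represented by its single carbonyl oxygen, and side chains
stop at Cβ with one idealized geometry. Because side chains carry no
torsional degrees of freedom at this resolution, no clash-relief
minimization is needed at build time; the builder instead validates that
no two heavy atoms of different peptides approach below 1.8 Å. Termini
carry the formal +1/−1 charges of the protonated amine and carboxylate,
reflecting their expected protonation near neutral pH.

The lattice axes follow the cross-β convention: a (terminus-terminus)
along x, b (side-chain stacking) in the x–y plane at γ from a, c
(hydrogen bonding) along z, with defaults a = 20.6 Å, b = 19.1 Å, γ = 82°
and a per-strand rise of 4.8 Å (parallel) or 4.85 Å (antiparallel, so the
translated-equivalent repeat is 9.7 Å). The printed 4.8/9.7 pair is not an
exact doubling; we privilege the repeat distances, so the AP rise is
4.85 Å by construction.

The eight symmetry classes are encoded as three binary choices. Only the
P = 1–4 / AP = 5–8 split is fixed by the cross-β literature; the
within-group assignment of face packing (face-to-face vs face-to-back) and
sheet orientation (up-up vs up-down) is a documented lookup table
(`symmetry_classes()`). Face-to-face turns sheet 2 around by a 180°
rotation about a (preserving strand sense, as required for the parallel
classes' uniform sense pattern); up-down staggers sheet 2 by half the
rise. Antiparallel sheets alternate strand sense along c by a 180°
rotation about the sheet normal b (classes 5, 7; side-chain face registry
preserved) or about c (classes 6, 8; face registry flipped). Reversed
strands related by the b-axis two-fold also take a 2.0 Å registry shift
along a: this clears the charged termini of adjacent strands and restores
the inter-strand hydrogen-bond geometry, in the same spirit as the manual
adjustments that atomic steric-zipper models typically require. The two
sheets of an antiparallel zipper meet anti-phase, so strand pairs facing
each other across the zipper interface are antiparallel; this is the
registry freedom of the dry interface, and it is what makes the zipper
term distinguish the two classes at coarse-grained resolution.

Only symmetry-level fidelity is claimed for classes other than 1 and 5:
atomic-resolution poses of all eight classes are not uniquely determined
by the lattice metadata the model starts from.

## Scattering

Solution scattering is the exact orientational average over pair
distances (the Debye equation) with contrast-corrected form factors
`f'(q) = f(q) − ρ_s V exp(−q² V^(2/3)/4π)` — 4-Gaussian Cromer–Mann
factors minus a Gaussian dummy atom of the element's displaced volume at
the solvent density (0.334 e Å⁻³ for water; 0 for vacuum). Hydrogens are
explicit. A spherical-harmonics engine would be faster for single
particles, but peak positions, not absolute envelopes, are the relevant
output here, and the direct double sum is exact. Two evaluation paths are
provided: the O(N²·n_q) reference sum and a binned pair-distance path
that uses the per-bin mean distance (error second-order in the 0.01 Å bin
width; the two paths agree to ~10⁻⁵ relative on test blocks, far inside
the 0.5 % contract).

The P/AP diagnostic works as follows. A class-1 (parallel) block has
identical strands every 4.8 Å along c, giving the dominant wide-angle
reflection at d = 4.8 Å. In a class-5 block the strands alternate sense,
so the true translational repeat is 9.7 Å; the 9.7 Å reflection appears
(via mixed reflections involving the a/b axes) and the residual 4.85 Å
pseudo-reflection is attenuated. At Cβ resolution a strand's z-projected
density is close to even, so the pseudo-reflection decays with crystal
length rather than vanishing by symmetry; the diagnostic therefore
compares matched 4 × 4 × 96 blocks, where the Laue width separates the
class-5 peak (at 4.855 Å) from the 4.8 Å position and the class-1/class-5
intensity ratio at q = 2π/4.8 (median-normalized per profile) exceeds 5.
The choice of an elongated-in-c geometry mirrors the physical habit of
these crystallites, which are much longer along the hydrogen-bonding axis
than across it.

Guinier fits (`guinier_rg()`) iterate the admitted window to
q·Rg ≤ 1.3 by default; the sphere benchmark in the test suite uses 0.8,
where the systematic bias of the Guinier approximation for compact bodies
drops below 1 %. Experimental radii of gyration for polydisperse amyloid
suspensions are comparison references only — polydispersity biases them —
and are not computed as targets anywhere in the package.

Peak finding reports local maxima annotated with d = 2π/q, with a
prominence threshold expressed as a fraction (default 0.02) of the
intensity range in the examined window; ties break toward lower q.

## Hydrogen-bond topology

A backbone hydrogen bond is H···O < 2.5 Å with N–H···O > 135°; both
cutoffs are exposed because published analyses rarely state their
criterion and absolute counts are criterion-dependent — only trends and
ratios are treated as meaningful. Pairing is defined strand-wise: each
strand's direction is the signed N→C principal axis of its Cα positions,
and a bond inherits P (direction dot ≥ 0.5), AP (≤ −0.5) or unclassified
from its two strands; unclassified bonds count toward neither series.
Time series are per-frame (N_P, N_AP) counts with a centered boxcar
moving average (truncated windows at the edges, so the smoothed series
has the length of the raw one). For coarse-grained bead frames, which
have no amide hydrogens, backbone-bead contacts within 5.5 Å serve as the
hydrogen-bond surrogate with the same strand-wise classification.

## The coarse-grained energy model

One bead per residue at Cα plus one side-chain bead at Cβ; terminal
backbone beads carry the ±1 charges. Terms (kcal/mol, Å, K):

- **bonded**: harmonic bonds (Cα–Cα 3.80 Å, Cα–Cβ 1.53 Å, k = 20) and a
  backbone angle term (139°, k = 5) keeping chains near-extended;
- **electrostatics**: screened Coulomb 332.06 q₁q₂ e^(−r/λ_D)/(ε_r r)
  with ε_r = 80 and λ_D = 7 Å (the Bjerrum length in water, so two unit
  charges at 7 Å interact at about k_BT);
- **hydrogen-bond surrogate**: a Gaussian well (depth 1.0, center 4.8 Å,
  width 0.7 Å) between backbone beads of different peptides,
  orientation-independent;
- **packing**: a Gaussian well (depth 0.2, center 5.5 Å, width 1.5 Å)
  between side-chain beads, plus an extra depth 1.0 for *mutually facing*
  side chains of the same residue index — homotypic in-register stacking,
  the coarse-grained expression of the interdigitated zipper. The facing
  gate uses the Cα→Cβ directions, so it engages across a zipper interface
  but not between side chains stacked within one sheet;
- **repulsion**: soft half-harmonic below 4.0 Å;
- **solvation**: a smooth exposure penalty proportional to each bead's
  coordination deficit, standing in for a continuum-solvent surface term.

Two qualitative behaviors are design targets, stated here openly. First,
antiparallel neighbors along c are electrostatically favored: this is
*emergent* from the terminal charges (head-to-tail vs head-to-head) and is
cross-checked in the tests against a direct four-charge sum. Second, the
parallel zipper packs better than the antiparallel one: this enters
through the homotypic stacking bonus, which parallel in-register
interfaces can collect and anti-phase antiparallel interfaces cannot. The
default weights were chosen once so that both directions hold robustly;
absolute free-energy magnitudes are explicitly out of scope — the model
is a sign-and-trend instrument, not a calibrated force field.

Minimization is gradient descent with backtracking line search (accepted
steps never increase the energy) in two modes: Cartesian, and rigid-body
per peptide (net force + torque only). The facing gate's orientational
derivative is neglected in the gradient; the line search on exact
energies keeps descent monotone regardless.

## Hamiltonian replica exchange

Replica i adds U(x, λᵢ) = ½ λᵢ |x|² to the physical Hamiltonian, where x
is the vector of bead displacements from a rigid extended reference
superimposed (proper-rotation Kabsch fit) on each peptide at every
evaluation; λᵢ = λ_max (i/(M−1))² with λ_max = 0.032 kcal mol⁻¹ Å⁻² and
M = 64 by default, so replica 0 samples the unbiased ensemble.
Exchanges between adjacent pairs alternate even/odd pairings at 5 ps
intervals with the Metropolis rule (accept if ΔU ≤ 0, else with
probability e^(−βΔU)); ΔU depends only on the restraint terms since the
physical Hamiltonian is shared. The restraint force uses λ(x − T(ref)),
exact at the optimal superposition. Dynamics between attempts are
overdamped Langevin (default dt = 0.002 ps nominal, friction 1); peptide
centroids are confined by a half-harmonic wall at 50 Å radius (64
peptides in that sphere ≈ 0.2 M effective concentration). An optional
extra restraint flattening strands toward the x–y plane is *not*
implemented by default — the Hamiltonian above is the entire bias; desk
scale runs (8 replicas × 8 peptides) aggregate without it, with
antiparallel contacts dominating the unbiased endpoint.

The aggregation stage evaluates the physical Hamiltonian with the
peptide-interior dielectric, ε_r = 15: the terminal charges that decide
the pairing sense meet at ~5 Å separations, where the interaction path
runs through the forming assembly rather than through bulk water (through
a peptide assembly the Bjerrum length is ~37 Å, versus ~7 Å through
water). With the water-like ε_r = 80 the electrostatic discrimination at
contact is below k_BT and small toy systems can freeze into
parallel-paired states; the low-dielectric contact model anneals them
reliably. The lattice free-energy comparisons, by contrast, relax whole
minimized blocks in a water-like continuum and keep ε_r = 80.

All randomness flows through R's RNG, so a single `set.seed()` makes runs
bit-identical, including the exchange log.

## Block-cutting interface thermodynamics

Reference block free energies G are averages of the relaxed
coarse-grained energy over blocks cut (by lattice index, coordinates
untouched) from trajectory snapshots; the estimator refuses fewer than 50
samples unless explicitly overridden, and records the override. The
relaxation is rigid-body per peptide inside a 0.15 Å trust region: cut
blocks are *regularized* toward the crystal basin rather than re-folded,
because the sampled intrachain conformations are the data and the
coarse-grained model's distant minima are not physically meaningful
lattice states. Then

- ΔG_c° = [G(1×1×14) − 2 G(1×1×7)] / 2, the per-buried-peptide free
  energy of the hydrogen-bonding-axis interface of a single sheet (sheet
  elongation along c precedes assembly in the other directions, so the
  single-sheet regime is the relevant one);
- ΔG_zip° = [G(1×2×14) − 2 G(1×1×14)] / 28, the steric-zipper interface
  per peptide, every peptide of the two sheets touching the interface.

The normalizations (2 and 2·n_c buried peptides) are this package's
documented convention; they set the scale but not the sign of the
comparisons. ΔΔG(1−5) = ΔG(class 1) − ΔG(class 5) is positive when the
antiparallel arrangement is stronger. On the published per-class values
the table reproduces the printed differences exactly (+0.8/−2.3 for
ILQINS through +3.4/−8.6 for TFQINS, increasingly pronounced with in
vitro amyloidogenicity); on the package's own toy model the directions
ΔΔG_c > 0 and ΔΔG_zip < 0 are reproduced, with magnitudes that are not
comparable to the atomistic values and are not claimed to be.

The linearity assumption behind per-peptide normalization (valid for
blocks larger than the relevant Bjerrum length — about 7 Å through
water, about 37 Å through a peptide assembly at ε_r = 15) is checked in
the tests: 1×1×8 and 1×1×12 splits agree within 10 % per buried peptide.

## Synthetic data

The generator produces exactly the inputs the analyses need and nothing
more: point lattices with known spacings (closed-form peak oracles);
ideal dimers, sheets and zippers built by the lattice module; dispersed
random starting configurations in a sphere; and noisy multi-frame
trajectories — the ideal assembly plus seeded isotropic Gaussian
displacements (default σ = 0.1 Å for thermodynamic snapshots), an
optional linear noise-inflation schedule for decay tests, and a labeled
burn-in fraction mapped to the "converged part" notion of production
simulations. What it does *not* emulate: anharmonic and collective
fluctuations, the structured water of real nanocrystal channels, or
force-field-specific fluctuation spectra. Tests passing on these fixtures
therefore validate the pipeline's logic and its qualitative physics, not
atomistic accuracy on real data.

## Problem sizes and numerical choices

The shipped analyses use desk-scale sizes chosen once: 4 × 4 × 16 blocks
(~9,000 atoms) for peak-position work and matched 4 × 4 × 96 blocks for
the P/AP suppression ratio; 14-strand sheets and zippers with 8–50
snapshots for free energies; 8 replicas × 8 peptides × 4·10⁴ Langevin
steps for replica exchange. The 6 × 12 × 18 (1296-peptide) production
block is built and counted but not routinely scattered. Histogram bin
width 0.01 Å; minimizer tolerance 0.01–0.05 kcal mol⁻¹ Å⁻¹; Metropolis
and statistical checks use fixed seeds stated in the tests.

## Known limitations

Cβ-level side chains cannot reproduce rotamer-dependent zipper packing;
the homotypic stacking term is an explicit surrogate. The zipper
comparison's sign depends on the dielectric assigned to the interface:
with the water-like continuum default the parallel zipper wins, while
taking the interface dielectric as low as the peptide interior would let
terminal-charge attraction across the anti-phase antiparallel zipper
dominate — a reminder that the model resolves directions, not
magnitudes. The AP 4.8 Å
suppression is size-mediated rather than symmetry-forbidden at this
resolution (see above). Absolute energies, absolute hydrogen-bond counts
and experimental radii of gyration are out of scope by design. Classes
2–4 and 6–8 are symmetry-level constructions without atomic-resolution
validation.
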