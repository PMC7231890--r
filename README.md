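# stericzipper

Amyloid-forming hexapeptides such as ILQINS (and its variants IFQINS and
TFQINS) assemble into cross-β nanocrystals in which β-strands stack along a
hydrogen-bonding axis (c) and pairs of β-sheets interdigitate their side
chains into a dry "steric zipper" (across b). The strands within a sheet can
run parallel (P) or antiparallel (AP), giving the eight canonical steric
zipper symmetry classes (1–4 P, 5–8 AP). Which arrangement wins — and at
which stage of assembly — is a thermodynamic question with a structural
fingerprint: P sheets produce a wide-angle X-ray peak at the 4.8 Å strand
repeat, while AP sheets double the translated-equivalent repeat to 9.7 Å and
suppress the 4.8 Å reflection.

`stericzipper` is a desk-scale R toolkit for exploring this competition:

- **Lattice construction** — idealized extended strands built by forward
  kinematics (`build_extended_strand()`), posed into any of the eight
  symmetry classes (`make_unit_cell()`, `symmetry_classes()`) and replicated
  into nanocrystal blocks on the oblique lattice a = 20.6 Å, b = 19.1 Å,
  γ = 82° (`build_block()`), with PDB output for >62 chains.
- **Scattering prediction** — exact orientationally averaged Debye sums with
  excluded-volume solvent contrast (`debye_profile()`), with an accelerated
  binned-distance path for large blocks, Guinier fits (`guinier_rg()`) and
  Bragg-spacing peak extraction (`find_peaks()`).
- **Sheet topology** — geometric backbone hydrogen-bond detection,
  parallel/antiparallel strand classification, and P/AP bond-count time
  series with moving averages (`hbond_series()`).
- **Energy model** — a coarse-grained peptide force field (screened
  electrostatics between the charged termini, a backbone hydrogen-bond well,
  side-chain packing with an in-register stacking bonus, implicit-solvent
  exposure term) with reports, minimization and electrostatic utilities
  (`total_energy()`, `minimize_configuration()`, `bjerrum_length()`).
- **Hamiltonian replica exchange** — the restraint Hamiltonian
  U(x, λ) = ½ λ |x|² toward a rigid extended reference, the quadratic ladder
  λᵢ = λ_max (i/(M−1))², Metropolis exchanges between adjacent replicas,
  spherical confinement and mixing diagnostics (`run_hremd()`).
- **Interface thermodynamics** — block-cutting free-energy decomposition:
  ΔG_c° from splitting a 1×1×14 sheet in half along c, ΔG_zip° from
  splitting a 1×2×14 zipper into its sheets, and ΔΔG(1−5) comparison tables
  (`dg_c()`, `dg_zip()`, `ddg_table()`).

Everything runs from synthetic inputs generated in code (`point_lattice()`,
`make_ideal_assembly()`, `synth_trajectory()`, `initial_gas()`); no
downloads are required.

## Worked example

```r
library(stericzipper)

strand <- build_extended_strand("ILQINS")

# P and AP nanocrystals and their wide-angle scattering
p_block  <- strand |> make_unit_cell(1) |> build_block(4, 4, 16)
ap_block <- strand |> make_unit_cell(5) |> build_block(4, 4, 16)
prof <- debye_profile(p_block, seq(1.0, 1.5, by = 0.002), method = "binned")
find_peaks(prof, c(1.0, 1.5))
#> # A tibble: 3 x 4
#>   q_peak d_spacing  height prominence
#>    <dbl>     <dbl>   <dbl>      <dbl>
#> 1   1.03      6.09 270174.     65925.
#> 2   1.31      4.81 954531.    707485.
#> 3   1.45      4.33 413665.    110967.
```

The dominant peak at d ≈ 4.8 Å is the parallel-β strand-repeat signature;
building the same block in class 5 moves the c-axis reflection to
d ≈ 9.7 Å (the AP translated-equivalent repeat) and suppresses the 4.8 Å
intensity.

```r
# published per-class interface free energies -> difference table
ddg_table(reference_interface_table())
#> # A tibble: 3 x 11
#>   sequence dg_c_1 dg_c_5 dg_zip_1 dg_zip_5 ... ddg_c ddg_zip
#> 1 ILQINS    -28.1  -28.9    -18.6    -16.3     0.800    -2.3
#> 2 IFQINS    -27.1  -29.3    -20.5    -16.4     2.2      -4.1
#> 3 TFQINS    -26.1  -29.5    -21.7    -13.1     3.4      -8.6

bjerrum_length(80, 300)          # 6.96 A: unit charges in water at kBT
effective_concentration(64, 50)  # 0.203 M: the replica-exchange system
```

Positive ΔΔG_c means the AP sheet gains more free energy per buried peptide
when elongating along the hydrogen-bonding axis; negative ΔΔG_zip means the
P steric zipper is the stronger two-sheet interface. The same direction
(ΔΔG_c > 0, ΔΔG_zip < 0) emerges from the package's own coarse-grained
model via `toy_ddg_table()`, and a small seeded replica-exchange run
(`run_hremd()`) shows antiparallel contacts dominating the unbiased
replica's endpoint.

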