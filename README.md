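# synthonic

Multi-scale synthonic modelling of molecular-crystal polymorphs in R: from a
crystal structure (CIF) to lattice energy, intermolecular synthons, predicted
morphology and face-specific surface energetics.

The package was built around the classic conformational-polymorphism case of
ritonavir, whose two forms differ in both molecular conformation (trans vs
cis carbamate) and crystal packing: the metastable form I packs more densely
but hydrogen-bonds weakly; the stable form II pays an ~8 kcal/mol
conformational penalty to expose its hydroxyl group and build stronger
hydrogen-bonded chains. Quantifying that balance requires exactly the chain
of quantities this package computes.

## What it computes

For a crystal structure with unit cell, symmetry operators and
asymmetric-unit atoms:

- **Lattice energy** by direct atom–atom summation over whole molecules
  within a radius, in the handshake convention

  E_cr = ½ Σ_k E(0, k),

  with Dreiding-style components: Lennard-Jones 12-6 van der Waals, a
  directional 12-10 hydrogen-bond term D_hb[5(R_hb/r)¹² − 6(R_hb/r)¹⁰]cos⁴θ
  on detected D–H···A triplets, and Coulomb sums over Gasteiger–Marsili
  partial charges. Convergence is profiled on a 1 Å radius grid with
  coordination-shell decompositions.
- **Synthons**: symmetry-unique pair interactions ranked by strength with
  multiplicities, component breakdowns, generating symmetry (translation /
  screw) and H-Bond/vdW tags; fragment partitioning of E_cr onto
  user-defined molecular fragments; a hydrogen-bond inventory with
  geometry (r(H···A), r(D···A), θ) and donor/acceptor charges.
- **Morphology**: BFDH ranking of (hkl) forms with 2₁ screw-axis absence
  corrections; the attachment-energy partition for each face,

  E_cr = E_sl^hkl + E_att^hkl,

  (intrinsic synthons lie within a centroid slab of thickness d_hkl); a
  Wulff construction with centre-to-plane distances ∝ |E_att| giving facet
  areas and habit aspect ratios.
- **Surfaces**: anisotropy factor ξ_hkl = E_sl/E_cr (synthon saturation),
  surface energies γ_hkl = Z |E_att| d_hkl / (2 V_cell N_A) with vdW /
  H-bond / electrostatic components, the area-weighted particle surface
  energy γ_particle = Σ γ_hkl · SA_hkl, and rugosity (centred RMS atomic
  height about the face plane).
- **Conformers**: signed torsion angles with cis/trans classification, and
  deformation-energy bookkeeping from externally supplied single-point
  energies.
- **Synthetic data**: deterministic toy crystals (translation chain,
  screw-axis hydrogen-bonded chain, random P1 packings) written as CIF, and
  a brute-force supercell oracle, so the whole pipeline is testable without
  any licensed database entry.

## Worked example

A one-dimensional chain crystal with a single −10 kcal/mol translation
synthon along b (repeat 5.215 Å), run through the whole pipeline:

```r
library(synthonic)

fx  <- make_chain_fixture(spacing = 5.215, pair_energy = -10)
cfg <- run_config(fx$path, charges = c(C1 = 0), params = fx$params,
                  radius = 21,
                  hkl = list(c(0,1,0), c(1,0,0), c(0,0,1), c(1,0,1)))
rep <- run_pipeline(cfg)

rep$lattice$e_cr
#> [1] -10.37557
identify_synthons(fx$structure, fx$params, radius = 8)
#>   label multiplicity e_vdw e_hbond e_coulomb e_total  dist    symmetry type
#> 1     A            2   -10       0         0     -10 5.215 translation  vdW
wulff_extent(rep$wulff, c(0,1,0)) / wulff_extent(rep$wulff, c(1,0,0))
#> [1] 624.1162
```

The lattice energy is the constructed pair energy (−10, plus −0.38 of
longer-range Lennard-Jones tails at the 21 Å radius); the only first-shell
synthon is the ±b translation pair; and the predicted habit is a needle
along the chain axis, the attachment-energy picture of 1-D hydrogen-bonded
crystals.

On the published ritonavir record the same functions reproduce the printed
arithmetic, e.g.

```r
cells <- table2_cells()
d_spacing(cells$form_I$cell, c(0, 0, 1))   # 25.96025 A
anisotropy_factor(-9.87, -78.29)           # 87.39303 %
surface_energy(2, -9.87, 25.96, 1806.55)   # 98.54002 mJ/m^2
conformation_adjusted_difference(-78.29, -92.33, -8.09)   # 5.95 kcal/mol
```

## Analysis scripts

`analysis/01…05` are thin narrative drivers over the package: reference-cell
crystallography and BFDH tables, lattice-energy validation against the
supercell oracle, chain-fixture morphology, per-face surface energetics for
both polymorphs, and the conformation/packing balance. Each writes its
tables under `results/`.

## Scope notes

Structures are taken as given (rigid molecules, ordered single components);
there is no force-field geometry optimisation, no Ewald summation (the
radius-convergence design makes the direct sum the object of study), no DFT
(conformer energies enter as plain numbers), and no solvent-specific growth
modelling. Absolute lattice energies depend on the force-field
parameterisation and are validated structurally (against the oracle and the
partition identities), not against the published absolute values; see the
methods vignette for the reasoning.
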