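---
title: "Synthonic modelling of crystal polymorphs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthonic modelling of crystal polymorphs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthonic)
```

# The problem

Conformational polymorphs are crystal forms of the same molecule that differ
both in molecular conformation and in packing. Ritonavir is the canonical
pharmaceutical example: its metastable form I (P2~1~, Z = 2) packs a compact
trans-carbamate conformer densely but leaves the central hydroxyl able to
act only as a hydrogen-bond donor, while the stable form II
(P2~1~2~1~2~1~, Z = 4) pays a conformational penalty of about 8 kcal/mol to
open the molecule up, letting the hydroxyl donate *and* accept and building
markedly stronger 1-D hydrogen-bonded chains. Understanding which form wins,
how each grows, and what its particle surfaces look like requires a chain of
linked quantities — lattice energy and its convergence, the synthon
inventory, attachment energies, face areas, surface energies — and this
package computes that chain end to end.

# The energy model

All intermolecular energies are atom–atom sums over rigid molecules, in
kcal/mol and Å.

**Van der Waals.** Lennard-Jones 12-6,
$E = D_0[(R_0/r)^{12} - 2(R_0/r)^6]$, with per-element Dreiding well depths
and equilibrium distances (geometric-mean $D_0$, arithmetic-mean $R_0$
combining). The force field named by the original workflow exists in both
12-6 and exponential-6 flavours and its hydrogen-bond constants are not
published alongside the results; we use the common 12-6 defaults and make
every parameter overridable (`energy_params()`), so absolute lattice
energies are *structurally* validated (see "What the tests show") rather
than matched bit-for-bit.

**Hydrogen bonds.** A directional 12-10 term on detected D–H···A triplets,
$E = D_{hb}[5(R_{hb}/r_{DA})^{12} - 6(R_{hb}/r_{DA})^{10}]\cos^4\theta$,
with $D_{hb} = 9.5$ kcal/mol and $R_{hb} = 2.75$ Å. Detection: donors are
N/O/S with a covalently bound H, acceptors are N/O/S, a triplet activates
when r(H···A) < 3.0 Å and θ(D–H···A) > 90°; the Lennard-Jones terms of the
H···A and D···A pairs are replaced by the hydrogen-bond term. The term is
zero below 90°, −D~hb~ exactly at (R~hb~, 180°). All thresholds sit in
`energy_params()` with units documented there.

**Electrostatics.** Direct Coulomb sums, $E = 332.0637\,q_1 q_2 / r$
(vacuum), over per-atom partial charges. Charges come from an external file
(which always takes precedence) or from the built-in Gasteiger–Marsili
partial-equalisation scheme: electronegativity $\chi(q) = a + bq + cq^2$
per element/connectivity class, per-bond transfers damped by $(1/2)^k$,
converged when the largest transfer drops below 10⁻⁵ e. No Ewald summation
is used — deliberately: the radius-convergence behaviour of the direct sum
is itself one of the observables (metastable, denser packings converge at
smaller radii), and a reciprocal-space sum would erase it. The cost is that
very slowly decaying Coulomb tails are truncated; the convergence profile
makes that truncation visible rather than hiding it.

# Lattice energy, synthons, fragments

The lattice energy is the handshake sum
$E_{cr} = \tfrac12\sum_k E(0,k)$ over all whole molecules whose centroid
lies within the summation radius of the central molecule's centroid
(molecules are in or out as a whole; this matches the "number of molecules
per shell" bookkeeping). For Z′ > 1 the mean over central molecules is
reported and per-central values retained. `convergence_profile()` records
the cumulative energy on a 1 Å grid, per-shell percentages for configurable
bins (default (0,9], (9,19], (19,22] Å) and the convergence radius —
defined, since the original account gives radii ("about 18 Å / 21 Å") but
no criterion, as the smallest grid radius within 1% of the final value
(relative tolerance, configurable).

Synthons are groups of pair interactions equal in |E| (±0.01 kcal/mol) and
centroid distance (±0.01 Å), labelled A, B, … by descending strength,
tagged H-Bond when the hydrogen-bond component exceeds 0.5 kcal/mol, and
classified by generating operator (pure translation / screw / other). Two
percentage normalisations are emitted — multiplicity·E/(2|E~cr~|), which
closes exactly to 100%, and multiplicity·E/|E~cr~| — because published
synthon tables in this area commonly print the second convention while
their totals imply the first, and the ritonavir record's own percentage
column is inconsistent with its printed total; we reproduce both and match
neither by construction.

Fragment partitioning splits every atom–atom energy half to each partner
atom's fragment, so fragment totals conserve E~cr~ to rounding; the 3-body
hydrogen-bond term is booked on its donor–acceptor atom pair.

# Morphology and surfaces

`bfdh_forms()` ranks candidate habit faces by interplanar spacing with
systematic-absence corrections: a 2~1~ screw along an axis forbids odd
axial reflections, so the growth slice of e.g. an axial face in
P2~1~2~1~2~1~ is the halved {0 0 2} slice. Index search runs to |h|,|k|,|l|
≤ 3 by default; parallel higher-order planes collapse onto the largest
allowed spacing; ties break by lower index sum then lexicographic order.

`slice_partition()` implements the attachment-energy partition
$E_{cr} = E_{sl} + E_{att}$: a pair interaction is *intrinsic* (within the
growth slice) when its centroid separation projected on the face normal is
smaller in magnitude than d~hkl~/2. The original account defines intrinsic
synthons verbally ("fully coordinated within the growth layer"); the
centroid-slab criterion is the standard operational form of that idea and
makes the partition identity exact by construction, for every face, which
the tests assert at 10⁻⁶ kcal/mol. Relative growth rates are taken
proportional to |E~att~|.

`wulff_construction()` intersects half-spaces at distances ∝ |E~att~| for
every Laue-orbit equivalent of each form (Friedel pairs carry equal
distances — polar forms are treated as equivalent, reproducing rather than
resolving the inherent limitation of attachment-energy models for polar
crystals). Vertices are enumerated from plane triples; unboundedness is
detected from the recession cone and reported with the open direction.
Fractional areas per form are scale-invariant and sum to 1. In
`run_pipeline()`, faces whose attachment energy is exactly zero at the
chosen radius (possible in toy fixtures where all interactions are
coplanar) are given a nominal 1% growth rate so the habit stays bounded;
the warning says so.

Surface energetics: ξ~hkl~ = E~sl~/E~cr~ as a percentage ("synthon
saturation"); γ~hkl~ = Z|E~att~|d~hkl~/(2V~cell~N~A~) converted with
1 kcal = 4184 J (attachment energies are negative, surface energies
positive — the magnitude convention is forced by the positivity of every
published value); γ~particle~ = Σγ~hkl~·SA~hkl~ with areas used as given,
un-renormalised; rugosity as the centred RMS of asymmetric-unit atomic
heights along the face normal (the reference height is the mean height —
the published definition does not fix an origin, and centring makes the
measure translation-invariant).

# Descriptors and conformers

Molecular volume is the voxel-counted union of Bondi vdW spheres (default
grid 0.2 Å) with a one-voxel-layer error bound; surface area is the voxel
face area of the union boundary and is reported as approximate. Void space
is the percentage of cell voxels farther than a probe radius (default
1.2 Å, grid 0.3 Å) from every sphere surface of the packed cell. The
published void percentages come from a program whose exact algorithm and
probe settings are not stated, so these values are compared qualitatively
only. Density is Z·M/(N~A~V~cell~); with the published molecular weight
(720.9 g/mol) it gives 1.325 g/cc for form I where the record prints 1.28 —
the printed value evidently uses the exact formula mass of the deposited
structure, and the difference is documented rather than tuned away.

Torsions use the standard signed-dihedral convention with a 90° cis/trans
threshold (the record labels carbamate conformers cis/trans without numeric
bounds). Quantum-chemical energies are out of scope by design: conformer
single-point energies enter as plain numbers with a provenance tag, and the
conformation-adjusted stability gap is
|E~cr~(B)| − |E~cr~(A)| − |ΔE~conf~|.

# Synthetic fixtures and what the tests show

The licensed database entries for the two ritonavir forms cannot be
redistributed, so the pipeline's correctness argument has two legs:

1. **Printed-record arithmetic.** The published unit cells, per-face
   attachment energies and areas, component energies and conformer energies
   are shipped as numeric inputs (`ritonavir_reference()`,
   `table2_cells()`). Everything that is pure arithmetic on those inputs —
   d-spacings, anisotropy factors, surface energies, particle surface
   energies, packing coefficient, component percentages, the ~6 kcal/mol
   adjusted stability gap — is recomputed and must match print (the two
   rows of the published face table that fail their own internal arithmetic,
   {1 0 −1} of form I and {1 0 1} of form II, are asserted *as*
   inconsistencies).
2. **Property-based validation on fixtures.** Deterministic toy crystals —
   a P1 translation chain with an analytically known lattice energy, a
   P2~1~2~1~2~1~ crystal with exactly one engineered O–H···O bond
   (r(H···A) solved exactly in [1.9, 2.4] Å, θ in [150°, 180°]), and seeded
   random P1 packings — are written as CIF and re-read, so the full
   parse-to-report path is exercised. On these, the lattice energy must
   equal a brute-force supercell double loop to ~10⁻¹⁴ kcal/mol, the
   slice/attachment identity must hold on every face, synthon
   multiplicity-weighted sums must close to 2E~cr~, fragment partitions
   must conserve E~cr~, Wulff areas must normalise, and a single 1-D
   synthon must elongate the habit along its axis.

What passing these tests does *not* show: agreement of absolute lattice
energies, synthon energies or hydrogen-bond geometries with the published
values (those were produced with a different charge model — Gasteiger here,
MOPAC there — and unpublished force-field constants), nor realism of the toy
molecules (3–6 atoms, no conformational flexibility, no disorder). The
fixtures validate the machinery, not the force field.

Fixture generation parameters were fixed at design time: the chain repeat
is 5.215 Å (the b-axis hydrogen-bond repeat of form I) with a −10 kcal/mol
pair energy of convenient magnitude; the engineered hydrogen-bond geometry
spans the range of the published bond table (H···A 1.98–2.41 Å, θ
134–169°); random packings use 4–6 atom molecules in cells sized to keep
nearest intermolecular contacts above 2.6 Å, which is where organic vdW
contacts live.

# Numerical choices and problem sizes

- Duplicate-site guard 0.3 Å; bond perception with Cordero covalent radii
  + 0.40 Å tolerance, honouring all periodic images (recording *every*
  bonding image lets the unwrap step detect covalent networks, which are
  rejected as non-molecular).
- Cluster membership is centroid-based and deterministic (sorted by
  distance, then operator, then translation), so synthon labels are
  reproducible run to run; rerunning a pipeline writes byte-identical
  reports.
- Default summation radius in examples and tests is 8–21 Å on fixtures
  whose interactions decay within a few Å — chosen so the full suite runs
  in well under a minute while the convergence check (outermost 2 Å
  window, 1% relative) still has teeth. The supercell oracle uses 5×5×5
  blocks (7×7×7 for the hydrogen-bonded fixture, whose cell is short along
  the chain).
- The Wulff vertex enumeration is O(planes³) with exact 3×3 solves; at the
  ≤ 30 planes of any realistic form list this is instantaneous and avoids
  external geometry dependencies.

# Known limitations

Rigid molecules only (no intramolecular terms); no disorder handling; space
groups limited to explicit operators or the built-in P1 / P2~1~ /
P2~1~2~1~2~1~ trio; no solvent-specific growth modification (solvent
effects on habit are discussed qualitatively via which faces dominate); no
temperature, phonon or free-energy corrections. The attachment-energy model
itself assumes growth-rate ∝ |E~att~|, which underestimates the kinetic
elongation of needle formers — the observed crystals of both ritonavir
forms are more needle-like than the prediction, a known and expected bias
of the method.
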