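Package: synthonic
Title: Synthonic Modelling of Molecular Crystal Polymorphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-scale workflow for molecular-crystal polymorphs: parses
    crystal structures from CIF, expands symmetry and perceives whole
    molecules, evaluates atom-atom intermolecular energies (Lennard-Jones
    12-6, directional 12-10 hydrogen bond, Coulomb) with Gasteiger partial
    charges, sums lattice energies with radial convergence profiling,
    classifies and ranks intermolecular synthons, partitions energy onto
    molecular fragments, predicts crystal morphology by BFDH ranking and
    attachment energies with a Wulff construction, and derives face-specific
    anisotropy factors, surface energies, particle-weighted surface energy
    and rugosity, together with conformer torsion and deformation-energy
    bookkeeping. Includes deterministic synthetic crystal generators and
    brute-force supercell oracles so the whole pipeline is testable without
    any structural-database download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
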