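#!/usr/bin/env Rscript
# Stage 1 - crystallographic groundwork for the two ritonavir polymorphs.
# Builds the published unit cells, checks their volumes against the printed
# record, ranks candidate habit faces by BFDH (with screw-axis absence
# corrections) and computes the packing-coefficient/density arithmetic.
# Writes results/dspacings_*.csv and results/descriptor_arithmetic.csv.

suppressPackageStartupMessages(library(synthonic))
dir.create("results", showWarnings = FALSE)

cells <- table2_cells()
ref <- ritonavir_reference()

cat("== Unit cells ==\n")
for (f in names(cells)) {
  x <- cells[[f]]
  cat(sprintf("%s (%s, Z = %d): V = %.2f A^3 (printed %.2f)\n",
              f, x$spacegroup, x$Z, x$cell$volume, x$v_printed))
}

# BFDH candidate forms from cell + symmetry alone (one placeholder atom)
dummy <- data.frame(label = "C1", element = "C", fx = .13, fy = .21, fz = .17)
for (f in c("form_I", "form_II")) {
  x <- cells[[f]]
  st <- crystal_structure(x$cell, spacegroup_ops(x$spacegroup), dummy,
                          spacegroup = x$spacegroup)
  forms <- bfdh_forms(st, n_forms = 10)
  out <- sprintf("results/dspacings_%s.csv", f)
  write.csv(forms, out, row.names = FALSE)
  cat(sprintf("\n== BFDH ranking, %s -> %s ==\n", f, out))
  print(forms, row.names = FALSE)
}
cat("\nThe form II axial forms appear as {0 0 2}/{0 2 0}/{2 0 0}: all three\n")
cat("2_1 screw axes forbid odd axial reflections, halving those slices.\n")

# packing coefficient / density arithmetic from the printed molecular data
desc <- data.frame(
  form = c("I", "II"),
  packing_coefficient = c(
    packing_coefficient(NULL, ref$descriptors$molecular_volume[1], Z = 2,
                        v_cell = cells$form_I$cell$volume),
    packing_coefficient(NULL, ref$descriptors$molecular_volume[2], Z = 4,
                        v_cell = cells$form_II$cell$volume)),
  density = c(
    crystal_density(NULL, Z = 2, mol_mass = ref$descriptors$mol_mass[1],
                    v_cell = cells$form_I$cell$volume),
    crystal_density(NULL, Z = 4, mol_mass = ref$descriptors$mol_mass[2],
                    v_cell = cells$form_II$cell$volume)))
write.csv(desc, "results/descriptor_arithmetic.csv", row.names = FALSE)
cat("\n== Packing arithmetic (printed: 0.80 / 0.73) ==\n")
print(desc, row.names = FALSE)
cat("\nForm I packs more densely despite its larger molecular volume -\n")
cat("the compact trans-carbamate conformer trades hydrogen bonding for\n")
cat("close packing.\n")
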