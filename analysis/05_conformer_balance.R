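#!/usr/bin/env Rscript
# Stage 5 - the conformation/packing balance. Form II packs ~14 kcal/mol
# more strongly, but its in-crystal conformer pays an ~8 kcal/mol
# deformation penalty; netting the two gives the effective stability gap.
# Writes results/conformer_balance.csv.

suppressPackageStartupMessages(library(synthonic))
dir.create("results", showWarnings = FALSE)

ref <- ritonavir_reference()
e <- ref$conformer_energies
de <- deformation_energy(e[["form_I"]], e[["form_II"]],
                         provenance = "published DFT single points")
e_cr <- c(I = -78.29, II = -92.33)
adj <- conformation_adjusted_difference(e_cr[["I"]], e_cr[["II"]], de)

tab <- data.frame(
  quantity = c("E_conf form I", "E_conf form II", "delta E_conf",
               "E_cr form I", "E_cr form II", "raw lattice difference",
               "conformation-adjusted difference"),
  kcal_mol = c(e[["form_I"]], e[["form_II"]], as.numeric(de),
               e_cr[["I"]], e_cr[["II"]],
               abs(e_cr[["II"]]) - abs(e_cr[["I"]]), as.numeric(adj)))
write.csv(tab, "results/conformer_balance.csv", row.names = FALSE)

cat("== Conformation vs packing ==\n")
print(tab, row.names = FALSE)
cat(sprintf("\nThe form I conformer is %.2f kcal/mol more stable in the gas\n",
            abs(as.numeric(de))))
cat("phase (trans carbamate, shielded hydroxyl), yet form II's packing is\n")
cat(sprintf("%.2f kcal/mol stronger; net of the conformational penalty the\n",
            abs(e_cr[["II"]]) - abs(e_cr[["I"]])))
cat(sprintf("stability gap shrinks to ~%.2f kcal/mol (~6 kcal/mol), the\n",
            as.numeric(adj)))
cat("scale on which the two polymorphs actually compete.\n")
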