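#!/usr/bin/env Rscript
# Stage 3 - attachment-energy morphology on the chain fixture. A single
# dominant 1-D synthon should give a needle along the chain axis, mirroring
# the needle/lath habits that strong 1-D hydrogen bonding produces in the
# real polymorphs. Writes results/chain_faces.csv and results/chain_wulff.off.

suppressPackageStartupMessages(library(synthonic))
dir.create("results", showWarnings = FALSE)

ch <- make_chain_fixture()
cfg <- run_config(ch$path, charges = c(C1 = 0), params = ch$params,
                  radius = 21,
                  hkl = list(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1), c(1, 0, 1)),
                  descriptors = FALSE, outdir = NULL)
rep <- suppressWarnings(run_pipeline(cfg))

cat("== Face table (chain along b) ==\n")
faces <- rep$surfaces$faces
print(faces[, c("h", "k", "l", "d_hkl", "e_att", "xi", "sa_pct",
                "gamma_total")], row.names = FALSE)
write.csv(faces, "results/chain_faces.csv", row.names = FALSE)
write_off(rep$wulff, "results/chain_wulff.off")
write_ply(rep$wulff, "results/chain_wulff.ply")

cat(sprintf("\nEq. E_cr = E_sl + E_att holds on every face to %.1e kcal/mol\n",
            max(vapply(rep$partitions, function(p)
              abs(p$e_sl$total + p$e_att$total - rep$lattice$e_cr),
              numeric(1)))))
cat(sprintf("habit extent along b / along a = %.0f: a needle along the\n",
            wulff_extent(rep$wulff, c(0, 1, 0)) /
              wulff_extent(rep$wulff, c(1, 0, 0))))
cat("chain axis, as attachment-energy theory predicts for a 1-D synthon.\n")
cat("(The capping face carries all the attachment energy; the side faces\n")
cat("are fully coordinated within their growth slices, xi = 100%.)\n")
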