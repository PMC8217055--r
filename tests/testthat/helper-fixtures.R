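# Shared fixture builders; generated once per test session and cached.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- make()
  .fx_cache[[key]]
}

chain_fx <- function() cached("chain", function() make_chain_fixture())
hbond_fx <- function(seed = 1) {
  cached(paste0("hbond", seed), function() make_hbonded_fixture(seed))
}
random_fx <- function(seed = 1) {
  cached(paste0("rand", seed), function() make_random_p1_fixture(seed))
}

# a bare molecule (no structure) from coordinates
bare_mol <- function(elements, pos, bonds = NULL, charges = 0) {
  n <- length(elements)
  list(atoms = data.frame(label = paste0(elements, seq_len(n)),
                          element = elements,
                          cx = pos[, 1], cy = pos[, 2], cz = pos[, 3],
                          charge = rep_len(charges, n),
                          stringsAsFactors = FALSE),
       bonds = bonds, centroid = colMeans(pos))
}

# the two published cells wrapped in placeholder structures (one dummy atom)
# for the purely geometric stages (d-spacings, BFDH)
ritonavir_cell_structure <- function(form = c("I", "II")) {
  form <- match.arg(form)
  tc <- table2_cells()
  x <- if (form == "I") tc$form_I else tc$form_II
  crystal_structure(x$cell, spacegroup_ops(x$spacegroup),
                    data.frame(label = "C1", element = "C",
                               fx = 0.13, fy = 0.21, fz = 0.17),
                    spacegroup = x$spacegroup)
}
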