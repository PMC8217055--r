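test_that("chain lattice energy is the constructed pair energy", {
  fx <- chain_fx()
  le <- lattice_energy(fx$structure, fx$params, radius = 8)
  expect_equal(le$e_cr, fx$pair_energy, tolerance = 1e-9)
  expect_equal(le$breakdown$coulomb, 0)
  expect_equal(le$breakdown$hbond, 0)
})

test_that("lattice energy equals the brute-force supercell oracle", {
  for (s in 1:5) {
    fx <- random_fx(s)
    r <- fx$radius_hint
    le <- suppressWarnings(lattice_energy(fx$structure, fx$params,
                                          radius = r))
    expect_equal(le$e_cr, supercell_oracle(fx$structure, fx$params,
                                           n = 5, radius = r),
                 tolerance = 1e-10)
  }
  fx <- hbond_fx()
  le <- suppressWarnings(lattice_energy(fx$structure, fx$params, radius = 12))
  expect_equal(le$e_cr, supercell_oracle(fx$structure, fx$params,
                                         n = 7, radius = 12),
               tolerance = 1e-10)
})

test_that("oracle truncation error is bounded by the block size", {
  fx <- chain_fx()
  e3 <- supercell_oracle(fx$structure, fx$params, n = 3, radius = 8)
  e5 <- supercell_oracle(fx$structure, fx$params, n = 5, radius = 8)
  expect_equal(e3, e5, tolerance = 1e-12)   # radius already inside n = 3
  expect_equal(e3, -10, tolerance = 1e-9)
})

test_that("doubling all charges quadruples the Coulomb component exactly", {
  fx <- hbond_fx()
  st <- fx$structure
  le1 <- suppressWarnings(lattice_energy(st, fx$params, 10))
  st2 <- assign_charges(st, st$atoms$charge * 2)
  le2 <- suppressWarnings(lattice_energy(st2, fx$params, 10))
  expect_equal(le2$breakdown$coulomb, 4 * le1$breakdown$coulomb,
               tolerance = 1e-10)
  expect_equal(le2$breakdown$vdw, le1$breakdown$vdw, tolerance = 1e-12)
})

test_that("convergence profile: chain fixture shells and radius", {
  fx <- chain_fx()
  cp <- convergence_profile(fx$structure, fx$params, radius = 8)
  expect_equal(cp$e_cr, -10, tolerance = 1e-9)
  expect_equal(cp$convergence_radius, 6)
  expect_equal(cp$shells$pct_lattice_energy[1], 100, tolerance = 1e-9)
  expect_equal(cp$shells$n_molecules[1], 2)
  # telescoping: shell percentages cover the whole sum
  expect_equal(sum(cp$shells$pct_lattice_energy), 100, tolerance = 1e-6)
})

test_that("shell percentages always telescope to 100", {
  fx <- hbond_fx()
  cp <- convergence_profile(fx$structure, fx$params, radius = 14,
                            shell_bins = c(0, 6, 10, 14))
  expect_equal(sum(cp$shells$pct_lattice_energy), 100, tolerance = 1e-6)
  expect_equal(sum(cp$shells$n_molecules),
               utils::tail(cp$profile$n_molecules, 1))
})

test_that("molecule counts per shell equal brute-force enumeration", {
  fx <- random_fx(4)
  r <- fx$radius_hint
  cp <- convergence_profile(fx$structure, fx$params, radius = r,
                            shell_bins = c(0, r / 2, r))
  st <- fx$structure
  c0 <- st$molecules[[1]]$centroid
  fr <- as.matrix(st$molecules[[1]]$atoms[, c("fx", "fy", "fz")])
  counts <- c(0, 0)
  for (t1 in -4:4) for (t2 in -4:4) for (t3 in -4:4) {
    if (t1 == 0 && t2 == 0 && t3 == 0) next
    cen <- colMeans(frac_to_cart(st$cell, sweep(fr, 2, c(t1, t2, t3), "+")))
    d <- sqrt(sum((cen - c0)^2))
    if (d <= r / 2) counts[1] <- counts[1] + 1
    else if (d <= r) counts[2] <- counts[2] + 1
  }
  expect_equal(cp$shells$n_molecules, counts)
})

test_that("synthon table: chain has one first-shell synthon of multiplicity 2", {
  fx <- chain_fx()
  syn <- identify_synthons(fx$structure, fx$params, radius = 8)
  expect_equal(nrow(syn), 1L)
  expect_equal(syn$label, "A")
  expect_equal(syn$multiplicity, 2L)
  expect_equal(syn$type, "vdW")
  expect_equal(syn$symmetry, "translation")
})

test_that("synthons rank H-bonded contacts above vdW and tag them", {
  fx <- hbond_fx()
  syn <- identify_synthons(fx$structure, fx$params, radius = 12)
  expect_equal(syn$label[1], "A")
  expect_equal(syn$type[1], "H-Bond")
  expect_equal(syn$symmetry[1], "screw")
  expect_equal(syn$multiplicity[1], 2L)
  expect_true(all(syn$type[-1] == "vdW"))
  expect_true(all(diff(abs(syn$e_total)) <= 1e-12))  # descending strength
})

test_that("multiplicity-weighted synthon sum equals twice the lattice energy", {
  for (s in c(1, 2, 5)) {
    fx <- random_fx(s)
    r <- fx$radius_hint
    env <- pair_environment(fx$structure, fx$params, r)
    syn <- identify_synthons(env)
    le <- suppressWarnings(lattice_energy(env))
    expect_equal(sum(syn$multiplicity * syn$e_total), 2 * le$e_cr,
                 tolerance = 1e-9)
    # completeness: members cover every pair exactly once
    expect_equal(sort(attr(syn, "members")$pair_row),
                 seq_len(nrow(env$pairs)))
  }
})

test_that("fragment partition conserves the lattice energy", {
  fx <- hbond_fx()
  st <- assign_fragments(fx$structure,
                         c(C1 = "core", O1 = "core", O2 = "hydroxyl",
                           H2 = "hydroxyl", H1 = "core"))
  env <- pair_environment(st, fx$params, 12)
  fp <- fragment_partition(env)
  le <- suppressWarnings(lattice_energy(env))
  expect_equal(sum(fp$energy), le$e_cr, tolerance = 1e-6)
  expect_equal(sum(fp$pct), 100, tolerance = 1e-9)
  # independent accumulation from the per-pair atom matrices
  acc <- c(core = 0, hydroxyl = 0)
  for (k in seq_along(env$detail)) {
    d <- env$detail[[k]]
    for (f in names(acc)) {
      acc[f] <- acc[f] +
        (sum(d$atom_pair[d$central_atoms$fragment == f, , drop = FALSE]) +
         sum(d$atom_pair[, d$neighbour_atoms$fragment == f, drop = FALSE])) / 4
    }
  }
  expect_equal(fp$energy[match(names(acc), fp$fragment)], unname(acc),
               tolerance = 1e-9)
})

test_that("single-fragment and symmetric-fragment partitions behave", {
  fx <- chain_fx()
  st <- assign_fragments(fx$structure, c(C1 = "all"))
  fp <- fragment_partition(st, fx$params, radius = 8)
  expect_equal(fp$pct, 100, tolerance = 1e-9)
  # unmapped atom errors with the label
  st2 <- fx$structure
  expect_error(fragment_partition(st2, fx$params, radius = 8), "C1")
})

test_that("hydrogen-bond inventory reports the constructed geometry", {
  # collinear O-H...O built at r(H..A) = 2.0, O-H = 0.97
  cell <- unit_cell(20, 14, 14)
  atoms <- data.frame(
    label = c("O1", "H1", "O2", "H2"),
    element = c("O", "H", "O", "H"),
    fx = c(0.30, 0.30 + 0.97 / 20, 0.30 + 2.97 / 20, 0.30 + 3.94 / 20),
    fy = c(0.5, 0.5, 0.5, 0.5), fz = c(0.5, 0.5, 0.5, 0.5))
  st <- perceive_molecules(crystal_structure(cell, list(parse_symop("x,y,z")),
                                             atoms))
  expect_equal(st$zprime, 2L)
  st <- assign_charges(st, c(O1 = -0.4, H1 = 0.3, O2 = -0.4, H2 = 0.3))
  hb <- hbond_inventory(st, energy_params(), radius = 8)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$r_ha, 2.0, tolerance = 1e-8)
  expect_equal(hb$r_da, 2.97, tolerance = 1e-8)
  expect_equal(hb$theta, 180, tolerance = 1e-6)
  expect_equal(hb$q_diff, 0.3 - (-0.4), tolerance = 1e-12)
})

test_that("right-angle contacts are excluded from the inventory", {
  cell <- unit_cell(18, 14, 14)
  # D-H along +y, acceptor along +x from H: theta = 90
  atoms <- data.frame(
    label = c("O1", "H1", "O2"),
    element = c("O", "H", "O"),
    fx = c(0.30, 0.30, 0.30 + 2.0 / 18),
    fy = c(0.5 + 0.97 / 14, 0.5, 0.5),
    fz = 0.5)
  st <- perceive_molecules(crystal_structure(cell, list(parse_symop("x,y,z")),
                                             atoms))
  st <- assign_charges(st, c(O1 = -0.4, H1 = 0.3, O2 = -0.2))
  hb <- hbond_inventory(st, energy_params(), radius = 8)
  expect_equal(nrow(hb), 0L)
})

test_that("screw-chain fixture gives one unique bond of multiplicity 2", {
  fx <- hbond_fx(4)
  hb <- hbond_inventory(fx$structure, fx$params, radius = 12)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$multiplicity, 2)
  expect_gte(hb$r_ha, 1.9); expect_lte(hb$r_ha, 2.4)
  expect_gte(hb$theta, 150); expect_lte(hb$theta, 180)
  expect_gt(hb$r_da, hb$r_ha)
})

test_that("lattice energy is invariant under coordinate shifts", {
  # P1: any constant fractional shift leaves the packing unchanged
  fx <- random_fx(2)
  st <- fx$structure
  r <- fx$radius_hint
  e1 <- suppressWarnings(lattice_energy(st, fx$params, r))$e_cr
  at2 <- st$atoms
  at2$fx <- at2$fx + 0.217; at2$fy <- at2$fy + 0.391; at2$fz <- at2$fz - 0.154
  st2 <- perceive_molecules(crystal_structure(st$cell, st$ops, at2,
                                              st$spacegroup))
  st2 <- assign_charges(st2, stats::setNames(st$atoms$charge,
                                             st$atoms$label))
  e2 <- suppressWarnings(lattice_energy(st2, fx$params, r))$e_cr
  expect_equal(e1, e2, tolerance = 1e-9)
  # screw-axis group: a full lattice-vector shift leaves it unchanged
  fx2 <- hbond_fx()
  sth <- fx2$structure
  eh1 <- suppressWarnings(lattice_energy(sth, fx2$params, 10))$e_cr
  at3 <- sth$atoms
  at3$fx <- at3$fx + 1; at3$fz <- at3$fz - 2
  st3 <- perceive_molecules(crystal_structure(sth$cell, sth$ops, at3,
                                              sth$spacegroup))
  st3 <- assign_charges(st3, stats::setNames(sth$atoms$charge,
                                             sth$atoms$label))
  eh2 <- suppressWarnings(lattice_energy(st3, fx2$params, 10))$e_cr
  expect_equal(eh1, eh2, tolerance = 1e-9)
})

test_that("fixtures are deterministic given their seed", {
  da <- tempfile("fxa"); db <- tempfile("fxb"); dc <- tempfile("fxc")
  for (d in c(da, db, dc)) dir.create(d)
  a <- make_hbonded_fixture(9, dir = da)
  b <- make_hbonded_fixture(9, dir = db)
  expect_identical(readLines(a$path), readLines(b$path))
  expect_identical(readLines(a$charge_path), readLines(b$charge_path))
  c2 <- make_hbonded_fixture(10, dir = dc)
  expect_false(identical(readLines(a$path), readLines(c2$path)))
})
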