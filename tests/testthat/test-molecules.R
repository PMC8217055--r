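big_cell_structure <- function(atoms, a = 15, ops = list(parse_symop("x,y,z")),
                               sg = "P1") {
  crystal_structure(unit_cell(a, a, a), ops, atoms, spacegroup = sg)
}

test_that("bond perception follows covalent radii sums", {
  # C-H at 1.0 A: bonded, one molecule of two atoms
  st <- big_cell_structure(data.frame(
    label = c("C1", "H1"), element = c("C", "H"),
    fx = c(0.5, 0.5 + 1.0 / 15), fy = 0.5, fz = 0.5))
  st <- perceive_molecules(st)
  expect_equal(st$zprime, 1L)
  expect_equal(nrow(st$molecules[[1]]$atoms), 2L)
  expect_equal(nrow(st$molecules[[1]]$bonds), 1L)

  # two water-like molecules with O...O 2.8 A: bonds only intramolecular
  st <- big_cell_structure(data.frame(
    label = c("O1", "H1", "H2", "O2", "H3", "H4"),
    element = c("O", "H", "H", "O", "H", "H"),
    fx = c(0.3, 0.3 + 0.96 / 15, 0.3 - 0.30 / 15,
           0.3 + 2.8 / 15, 0.3 + (2.8 + 0.96) / 15, 0.3 + (2.8 - 0.3) / 15),
    fy = c(0.5, 0.5, 0.5 + 0.91 / 15, 0.5, 0.5, 0.5 + 0.91 / 15),
    fz = 0.5))
  st <- perceive_molecules(st)
  expect_equal(st$zprime, 2L)
  expect_equal(sort(vapply(st$molecules, function(m) nrow(m$atoms),
                           integer(1))), c(3L, 3L))
})

test_that("molecules straddling the cell boundary are made whole", {
  # 3-atom chain crossing the c face of a P21 cell, stored wrapped
  cell <- unit_cell(12, 8, 10)
  atoms <- data.frame(
    label = c("C1", "C2", "O3"), element = c("C", "C", "O"),
    fx = c(0.30, 0.30, 0.30),
    fy = c(0.20, 0.20, 0.20),
    fz = c(0.93, (0.93 + 1.5 / 10) %% 1, (0.93 + 2.9 / 10) %% 1))
  st <- crystal_structure(cell, spacegroup_ops("P21"), atoms,
                          spacegroup = "P21")
  st <- perceive_molecules(st)
  expect_equal(st$zprime, 1L)
  m <- st$molecules[[1]]
  expect_equal(nrow(m$atoms), 3L)
  # whole molecule: no 1.5 A bond stretched across the cell
  z <- sort(m$atoms$fz * 10)
  expect_equal(diff(z), c(1.5, 1.4), tolerance = 1e-6)
  expect_equal(structure_Z(st), 2L)
})

test_that("a periodic covalent network is rejected", {
  # chain of C at 1.45 A spacing closing on itself through the lattice
  st <- crystal_structure(unit_cell(2.9, 15, 15), list(parse_symop("x,y,z")),
                          data.frame(label = c("C1", "C2"),
                                     element = c("C", "C"),
                                     fx = c(0.0, 0.5), fy = 0.5, fz = 0.5))
  expect_error(perceive_molecules(st), "not a molecular crystal")
})

test_that("cluster expansion returns the right neighbours on the chain", {
  fx <- chain_fx()
  expect_length(expand_cluster(fx$structure, 6), 2L)
  expect_length(expand_cluster(fx$structure, 11), 4L)
  # deterministic ordering by distance
  d <- vapply(expand_cluster(fx$structure, 11), function(m)
    sqrt(sum((m$centroid - fx$structure$molecules[[1]]$centroid)^2)),
    numeric(1))
  expect_equal(d, sort(d))
})

test_that("cluster membership equals brute-force supercell enumeration", {
  fx <- random_fx(2)
  st <- fx$structure
  r <- fx$radius_hint
  nb <- expand_cluster(st, r)
  # independent triple loop over lattice translations
  c0 <- st$molecules[[1]]$centroid
  fr <- as.matrix(st$molecules[[1]]$atoms[, c("fx", "fy", "fz")])
  count <- 0
  for (t1 in -4:4) for (t2 in -4:4) for (t3 in -4:4) {
    if (t1 == 0 && t2 == 0 && t3 == 0) next
    cen <- colMeans(frac_to_cart(st$cell, sweep(fr, 2, c(t1, t2, t3), "+")))
    if (sqrt(sum((cen - c0)^2)) <= r) count <- count + 1
  }
  expect_equal(length(nb), count)
})

test_that("cluster membership is invariant under the symmetry image of the central", {
  fx <- hbond_fx()
  st <- fx$structure
  d1 <- sort(vapply(expand_cluster(st, 10), function(m)
    sqrt(sum((m$centroid - st$molecules[[1]]$centroid)^2)), numeric(1)))
  # rebuild the structure with the asymmetric unit replaced by its op-2 image
  fr <- as.matrix(st$atoms[, c("fx", "fy", "fz")])
  fr2 <- apply_symop(st$ops[[2]], fr)
  st2 <- crystal_structure(st$cell, st$ops,
                           transform(st$atoms, fx = fr2[, 1], fy = fr2[, 2],
                                     fz = fr2[, 3]),
                           spacegroup = st$spacegroup)
  st2 <- perceive_molecules(st2)
  d2 <- sort(vapply(expand_cluster(st2, 10), function(m)
    sqrt(sum((m$centroid - st2$molecules[[1]]$centroid)^2)), numeric(1)))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("centroid equals the unweighted mean of atomic positions", {
  fx <- random_fx(1)
  m <- fx$structure$molecules[[1]]
  expect_equal(m$centroid,
               colMeans(cbind(m$atoms$cx, m$atoms$cy, m$atoms$cz)))
})

test_that("the add-hydrogen utility places an explicit hydroxyl H", {
  st <- big_cell_structure(data.frame(
    label = c("C1", "O1"), element = c("C", "O"),
    fx = c(0.5, 0.5 + 1.4 / 15), fy = 0.5, fz = 0.5))
  expect_message(st2 <- add_hydroxyl_hydrogen(st, "O1", c(1, 0, 0)),
                 "added hydroxyl hydrogen")
  expect_equal(nrow(st2$atoms), 3L)
  o <- frac_to_cart(st2$cell, as.numeric(st2$atoms[2, c("fx", "fy", "fz")]))
  h <- frac_to_cart(st2$cell, as.numeric(st2$atoms[3, c("fx", "fy", "fz")]))
  expect_equal(sqrt(sum((h - o)^2)), 0.97, tolerance = 1e-8)
  expect_error(add_hydroxyl_hydrogen(st, "O9", c(1, 0, 0)), "no atom")
})
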