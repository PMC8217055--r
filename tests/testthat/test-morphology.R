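cubic_laue_ops <- function() {
  lapply(c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z", "y,z,x", "z,x,y"),
         parse_symop)
}

test_that("d-spacings follow the reciprocal metric", {
  cl <- unit_cell(10, 10, 10)
  expect_equal(d_spacing(cl, c(1, 0, 0)), 10)
  expect_equal(d_spacing(cl, c(1, 1, 0)), 10 / sqrt(2))
  expect_error(d_spacing(cl, c(0, 0, 0)), "0 0 0")
  # monoclinic closed form on the published form I cell
  tc <- table2_cells()
  beta <- 103.456 * pi / 180
  expect_equal(d_spacing(tc$form_I$cell, c(0, 0, 1)), 26.693 * sin(beta),
               tolerance = 1e-10)
})

test_that("systematic absences halve axial growth slices on screw axes", {
  # P21 (b-unique): (0 1 0) -> (0 2 0); (0 0 1) unaffected
  stI <- ritonavir_cell_structure("I")
  f <- bfdh_forms(stI, n_forms = 40, max_index = 2)
  expect_false(any(f$h == 0 & f$k == 1 & f$l == 0))
  expect_true(any(f$h == 0 & f$k == 2 & f$l == 0))
  expect_true(any(f$h == 0 & f$k == 0 & f$l == 1))
  k020 <- which(f$h == 0 & f$k == 2 & f$l == 0)
  expect_equal(f$d_hkl[k020], 5.2150 / 2, tolerance = 1e-9)

  # P212121: every axial reflection is halved, e.g. {0 0 2} not {0 0 1}
  stII <- ritonavir_cell_structure("II")
  f2 <- bfdh_forms(stII, n_forms = 40, max_index = 2)
  expect_false(any(f2$h == 0 & f2$k == 0 & f2$l == 1))
  k002 <- which(f2$h == 0 & f2$k == 0 & f2$l == 2)
  expect_equal(f2$d_hkl[k002], 10.13, tolerance = 0.001)
})

test_that("P1 cubic cell: axial forms tie with multiplicity 2", {
  st <- crystal_structure(unit_cell(10, 10, 10),
                          list(parse_symop("x,y,z")),
                          data.frame(label = "C1", element = "C",
                                     fx = 0.3, fy = 0.3, fz = 0.3))
  f <- bfdh_forms(st, n_forms = 3)
  expect_equal(f$d_hkl, rep(10, 3))
  expect_equal(f$multiplicity, rep(2L, 3))
  keys <- apply(abs(f[, c("h", "k", "l")]), 1, paste, collapse = "")
  expect_setequal(keys, c("100", "010", "001"))
})

test_that("BFDH ranking on the published form II cell starts with {0 1 1}", {
  f <- bfdh_forms(ritonavir_cell_structure("II"), n_forms = 2)
  expect_equal(unlist(f[1, c("h", "k", "l")], use.names = FALSE), c(0, 1, 1))
  expect_equal(f$d_hkl[1], 13.655, tolerance = 1e-4)
  expect_equal(f$multiplicity[1], 4L)
})

test_that("slice partition on the chain: all-or-nothing faces", {
  fx <- chain_fx()
  env <- pair_environment(fx$structure, fx$params, 8)
  f010 <- slice_partition(env, c(0, 1, 0))
  expect_equal(f010$e_sl$total, 0)
  expect_equal(f010$e_att$total, -10, tolerance = 1e-9)
  expect_equal(f010$xi, 0, tolerance = 1e-9)
  f100 <- slice_partition(env, c(1, 0, 0))
  expect_equal(f100$e_sl$total, -10, tolerance = 1e-9)
  expect_equal(f100$e_att$total, 0)
  expect_equal(f100$xi, 100, tolerance = 1e-9)
})

test_that("E_cr = E_sl + E_att on every face of every fixture", {
  for (s in c(1, 3)) {
    fx <- random_fx(s)
    env <- pair_environment(fx$structure, fx$params, fx$radius_hint)
    e_cr <- suppressWarnings(lattice_energy(env))$e_cr
    for (hkl in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 2),
                     c(2, 1, -1))) {
      fp <- slice_partition(env, hkl)
      expect_equal(fp$e_sl$total + fp$e_att$total, e_cr, tolerance = 1e-9)
    }
  }
})

test_that("attachment energy equals a direct half-space classification", {
  fx <- random_fx(5)
  env <- pair_environment(fx$structure, fx$params, fx$radius_hint)
  hkl <- c(1, 1, 0)
  fp <- slice_partition(env, hkl)
  # independent classification of each neighbour by projection
  nrm <- plane_normal(fx$structure$cell, hkl)
  d <- d_spacing(fx$structure$cell, hkl)
  p <- env$pairs
  ext <- abs(cbind(p$dx, p$dy, p$dz) %*% nrm) >= d / 2
  expect_equal(fp$e_att$total, sum(p$e_total[ext]) / 2, tolerance = 1e-12)
})

test_that("extrinsic synthon multiplicities are tallied per face", {
  fx <- chain_fx()
  env <- pair_environment(fx$structure, fx$params, 8)
  syn <- identify_synthons(env)
  fp <- slice_partition(env, c(0, 1, 0), synthons = syn)
  expect_equal(as.integer(fp$extrinsic_counts["A"]), 2L)
  fp2 <- slice_partition(env, c(1, 0, 0), synthons = syn)
  expect_equal(as.integer(fp2$extrinsic_counts["A"]), 0L)
})

test_that("Wulff construction: single cubic form gives a cube", {
  w <- wulff_construction(unit_cell(10, 10, 10), cubic_laue_ops(),
                          data.frame(h = 1, k = 0, l = 0, growth = 1))
  expect_equal(length(w$facets), 6L)
  expect_equal(nrow(w$vertices), 8L)
  expect_equal(w$total_area, 24, tolerance = 1e-9)
  expect_equal(w$sa_frac, 1, tolerance = 1e-12)
  # Euler characteristic: V - E + F = 2 (each edge shared by 2 facets)
  E <- sum(lengths(w$facets)) / 2
  expect_equal(nrow(w$vertices) - E + length(w$facets), 2)
})

test_that("cube-octahedron truncation areas match the analytic values", {
  t111 <- 1.2
  w <- wulff_construction(unit_cell(10, 10, 10), cubic_laue_ops(),
                          data.frame(h = c(1, 1), k = c(0, 1), l = c(0, 1),
                                     growth = c(1, t111)))
  # corner triangles: plane x+y+z = t*sqrt(3) cuts the unit cube corner
  cut <- 3 - sqrt(3) * t111
  a111 <- 8 * (sqrt(3) / 2) * cut^2
  a100 <- 6 * (4 - 2 * cut^2)
  expect_equal(w$areas[2], a111, tolerance = 1e-9)
  expect_equal(w$areas[1], a100, tolerance = 1e-9)
  expect_equal(sum(w$sa_frac), 1, tolerance = 1e-12)
})

test_that("Wulff fractional areas are scale-invariant and normalised", {
  faces <- data.frame(h = c(1, 1), k = c(0, 1), l = c(0, 1),
                      growth = c(1, 1.2))
  w1 <- wulff_construction(unit_cell(10, 10, 10), cubic_laue_ops(), faces)
  faces2 <- faces; faces2$growth <- faces2$growth * 7.3
  w2 <- wulff_construction(unit_cell(10, 10, 10), cubic_laue_ops(), faces2)
  expect_equal(w1$sa_frac, w2$sa_frac, tolerance = 1e-9)
  expect_equal(sum(w1$sa_frac), 1, tolerance = 1e-9)
  expect_equal(w1$aspect_ratio, w2$aspect_ratio, tolerance = 1e-9)
})

test_that("missing capping forms give an unbounded-form error", {
  expect_error(
    wulff_construction(unit_cell(10, 10, 10), list(parse_symop("x,y,z")),
                       data.frame(h = 1, k = 0, l = 0, growth = 1)),
    "unbounded")
})

test_that("a 1-D synthon chain elongates the habit along the chain axis", {
  fx <- chain_fx()
  # 21 A reaches the first perpendicular neighbours (padding 20 A), so the
  # side faces acquire small but non-zero attachment energies
  env <- pair_environment(fx$structure, fx$params, 21)
  faces <- data.frame(h = c(0, 1, 0, 1), k = c(1, 0, 0, 0),
                      l = c(0, 0, 1, 1), growth = NA)
  faces$growth <- vapply(seq_len(nrow(faces)), function(i) {
    abs(slice_partition(env, as.numeric(faces[i, c("h", "k", "l")]))$e_att$total)
  }, numeric(1))
  expect_true(all(faces$growth > 0))
  w <- wulff_construction(fx$structure$cell, fx$structure$ops, faces)
  along_b <- wulff_extent(w, c(0, 1, 0))
  along_a <- wulff_extent(w, c(1, 0, 0))
  along_c <- wulff_extent(w, c(0, 0, 1))
  expect_gt(along_b / along_a, 3)
  expect_gt(along_b / along_c, 3)
})

test_that("polyhedron exports are valid OFF/PLY text", {
  w <- wulff_construction(unit_cell(10, 10, 10), cubic_laue_ops(),
                          data.frame(h = 1, k = 0, l = 0, growth = 1))
  f1 <- tempfile(fileext = ".off"); f2 <- tempfile(fileext = ".ply")
  write_off(w, f1); write_ply(w, f2)
  off <- readLines(f1)
  expect_equal(off[1], "OFF")
  expect_equal(strsplit(off[2], " ")[[1]][1:2], c("8", "6"))
  ply <- readLines(f2)
  expect_equal(ply[1], "ply")
  expect_true(any(grepl("element vertex 8", ply)))
})
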