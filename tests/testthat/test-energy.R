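test_that("Lennard-Jones well shape: minimum, asymptote, algebra", {
  expect_equal(vdw_energy(3.5, 0.2, 3.5), -0.2)
  # monotone decay to zero from beyond the minimum
  r <- seq(3.5, 40, by = 0.5)
  e <- vdw_energy(r, 0.2, 3.5)
  expect_true(all(diff(e) > 0))
  expect_true(all(e < 0))
  expect_lt(abs(vdw_energy(40, 0.2, 3.5)), 1e-6)
  # (R0/r)^6 = 1/2  =>  E = -(3/4) D0
  expect_equal(vdw_energy(3.5 * 2^(1 / 6), 0.2, 3.5), -0.75 * 0.2)
  expect_error(vdw_energy(0.05, 0.2, 3.5), "overlap")
})

test_that("hydrogen-bond term hits its stated special values", {
  p <- energy_params()
  expect_equal(hbond_energy(p$r_hb, 180, p), -p$d_hb)
  expect_equal(hbond_energy(p$r_hb, 90, p), 0)
  expect_equal(hbond_energy(p$r_hb, 120, p), -p$d_hb / 16)
  expect_equal(hbond_energy(p$r_hb, 45, p), 0)   # below 90: zeroed
})

test_that("Coulomb term uses the 332.0637 conversion", {
  expect_equal(coulomb_energy(1, 1, 1), 332.0637)
  expect_equal(coulomb_energy(3.320637, 1, -1), -100)
  expect_equal(coulomb_energy(2.5, 0, 0.7), 0)
})

test_that("Gasteiger charges conserve charge and respect symmetry", {
  pos <- rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.363, 1.027, 0),
               c(-0.363, -0.513, 0.889), c(-0.363, -0.513, -0.889))
  methane <- bare_mol(c("C", "H", "H", "H", "H"), pos,
                      bonds = cbind(1L, 2:5))
  q <- gasteiger_charges(methane)
  expect_equal(sum(q), 0, tolerance = 1e-10)
  expect_equal(stats::sd(q[2:5]), 0, tolerance = 1e-12)
  expect_lt(q[[1]], 0)                     # carbon slightly negative
  expect_error(gasteiger_charges(bare_mol("P", matrix(0, 1, 3))),
               "no Gasteiger parameters")
})

test_that("methane Gasteiger charge matches an independent hand iteration", {
  # scalar recursion of the partial-equalisation scheme, written separately
  a <- c(7.98, 7.17); b <- c(9.18, 6.24); cc <- c(1.88, -0.56)
  chip <- c(sum(c(7.98, 9.18, 1.88)), 20.02)   # cation electronegativities
  qC <- 0; qH <- 0
  for (k in 1:20) {
    chiC <- a[1] + b[1] * qC + cc[1] * qC^2
    chiH <- a[2] + b[2] * qH + cc[2] * qH^2
    if (chiH < chiC) tr <- (chiC - chiH) / chip[2] * 0.5^k
    else tr <- -(chiH - chiC) / chip[1] * 0.5^k
    # one transfer per C-H bond: H loses tr, C gains
    qH <- qH + tr
    qC <- qC - 4 * tr
  }
  pos <- rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.363, 1.027, 0),
               c(-0.363, -0.513, 0.889), c(-0.363, -0.513, -0.889))
  methane <- bare_mol(c("C", "H", "H", "H", "H"), pos,
                      bonds = cbind(1L, 2:5))
  q <- gasteiger_charges(methane)
  expect_equal(q[[1]], qC, tolerance = 1e-3)
  expect_equal(q[[2]], qH, tolerance = 1e-3)
})

test_that("pair interaction: single-atom pair at R0 and swap symmetry", {
  p <- energy_params()
  r0 <- p$vdw$r0[p$vdw$element == "C"]
  d0 <- p$vdw$d0[p$vdw$element == "C"]
  m1 <- bare_mol("C", matrix(c(0, 0, 0), 1))
  m2 <- bare_mol("C", matrix(c(r0, 0, 0), 1))
  e <- pair_interaction(m1, m2, p)
  expect_equal(e$total, -d0, tolerance = 1e-12)
  expect_equal(e$coulomb, 0)
  expect_equal(e$hbond, 0)
  # swap symmetry on a less trivial pair
  fx <- random_fx(3)
  nb <- expand_cluster(fx$structure, fx$radius_hint)
  eab <- pair_interaction(fx$structure$molecules[[1]], nb[[1]], fx$params)
  eba <- pair_interaction(nb[[1]], fx$structure$molecules[[1]], fx$params)
  expect_equal(eab$total, eba$total)
  expect_equal(eab$vdw, eba$vdw)
  expect_equal(eab$coulomb, eba$coulomb)
  expect_equal(eab$hbond, eba$hbond)
  # overlap guard
  m3 <- bare_mol("C", matrix(c(0.2, 0, 0), 1))
  expect_error(pair_interaction(m1, m3, p), "overlap")
})

test_that("pair interaction equals a direct double-loop recomputation", {
  set.seed(11)
  p <- energy_params()
  el <- c("C", "H", "C", "H", "C")
  posA <- matrix(rnorm(15, sd = 0.8), 5, 3)
  posB <- matrix(rnorm(15, sd = 0.8), 5, 3) + matrix(c(6, 0, 0), 5, 3,
                                                     byrow = TRUE)
  qA <- runif(5, -0.2, 0.2); qB <- runif(5, -0.2, 0.2)
  mA <- bare_mol(el, posA, charges = qA)
  mB <- bare_mol(el, posB, charges = qB)
  e <- pair_interaction(mA, mB, p)
  # independent O(N^2) loop (no N/O/S hydrogens, so no H-bond channel)
  ev <- 0; ec <- 0
  for (i in 1:5) for (j in 1:5) {
    r <- sqrt(sum((posA[i, ] - posB[j, ])^2))
    ia <- match(el[i], p$vdw$element); ib <- match(el[j], p$vdw$element)
    d0 <- sqrt(p$vdw$d0[ia] * p$vdw$d0[ib])
    r0 <- (p$vdw$r0[ia] + p$vdw$r0[ib]) / 2
    ev <- ev + d0 * ((r0 / r)^12 - 2 * (r0 / r)^6)
    ec <- ec + 332.0637 * qA[i] * qB[j] / r
  }
  expect_equal(e$vdw, ev, tolerance = 1e-12)
  expect_equal(e$coulomb, ec, tolerance = 1e-12)
  expect_equal(e$total, ev + ec, tolerance = 1e-12)
})

test_that("component additivity holds for every evaluated pair", {
  env <- pair_environment(hbond_fx()$structure, hbond_fx()$params, 12)
  expect_true(nrow(env$pairs) > 10)
  expect_equal(env$pairs$e_total,
               env$pairs$e_vdw + env$pairs$e_hbond + env$pairs$e_coulomb,
               tolerance = 1e-12)
  # the per-atom-pair detail matrices sum back to the pair totals
  devs <- vapply(seq_along(env$detail), function(k)
    abs(sum(env$detail[[k]]$atom_pair) - env$pairs$e_total[k]), numeric(1))
  expect_lt(max(devs), 1e-10)
})

test_that("all components decay below 1e-4 kcal/mol past 40 A", {
  p <- energy_params()
  mA <- bare_mol(c("C", "H"), rbind(c(0, 0, 0), c(1.09, 0, 0)),
                 charges = c(-0.05, 0.05))
  mB <- bare_mol(c("C", "H"), rbind(c(45, 0, 0), c(46.09, 0, 0)),
                 charges = c(-0.05, 0.05))
  e <- pair_interaction(mA, mB, p)
  expect_lt(abs(e$vdw), 1e-4)
  expect_lt(abs(e$coulomb), 1e-4)
  expect_equal(e$hbond, 0)
})
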