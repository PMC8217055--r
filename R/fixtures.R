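# Deterministic synthetic crystal fixtures and brute-force oracles. The
# generators write CIF (and charge files) and read them back, so every
# fixture exercises the full parse path; molecules are kept small (<= 12
# atoms) so the whole pipeline runs in seconds. These toy structures stand
# in for licensed database entries in all tests.

#' One-dimensional chain fixture
#'
#' A P1 crystal whose dominant interaction is a single translation-related
#' neighbour pair along one axis: one atom per cell with a custom
#' Lennard-Jones well placing the energy minimum exactly at the chain
#' spacing, and long perpendicular axes pushing all other contacts far
#' away. Within a summation radius below twice the spacing the lattice
#' energy is the pair energy by construction.
#'
#' @param spacing chain repeat along b, Angstrom
#' @param pair_energy energy of the nearest-neighbour pair, kcal/mol
#'   (negative)
#' @param padding length of the two perpendicular axes, Angstrom
#' @param dir directory for the CIF (default `tempdir()`)
#' @return list: `structure` (parsed back from the CIF, molecules
#'   perceived, zero charges assigned), `params` (the matching
#'   [energy_params()]), `path`, `spacing`, `pair_energy`, `axis`
#' @export
make_chain_fixture <- function(spacing = 5.215, pair_energy = -10,
                               padding = 20, dir = tempdir()) {
  stopifnot(spacing > 0.5, pair_energy < 0, padding > 2 * spacing)
  cell <- unit_cell(padding, spacing, padding)
  atoms <- data.frame(label = "C1", element = "C",
                      fx = 0.31, fy = 0.42, fz = 0.37,
                      charge = 0, stringsAsFactors = FALSE)
  st <- crystal_structure(cell, list(parse_symop("x,y,z")), atoms,
                          spacegroup = "P1")
  path <- file.path(dir, sprintf("chain_%.3f.cif", spacing))
  write_cif(st, path, data_name = "chain_fixture")
  st2 <- perceive_molecules(read_cif(path))
  st2 <- assign_charges(st2, c(C1 = 0))
  params <- energy_params(vdw = data.frame(element = "C", r0 = spacing,
                                           d0 = abs(pair_energy)))
  list(structure = st2, params = params, path = path,
       spacing = spacing, pair_energy = pair_energy, axis = "b")
}

#' Hydrogen-bonded screw-axis fixture
#'
#' A P2\eqn{_1}2\eqn{_1}2\eqn{_1} crystal of a 5-atom molecule carrying one
#' hydroxyl donor and one carbonyl-like acceptor, arranged so that exactly
#' one symmetry-unique O-H...O hydrogen bond links screw-related molecules
#' into chains along a. The H...A distance is drawn in [1.9, 2.4] A and the
#' D-H...A angle falls in [150, 180] deg; both are solved for exactly at
#' generation time. Gasteiger charges are computed, written next to the CIF
#' and assigned.
#'
#' @param seed integer seed; fixtures are bit-identical for equal seeds
#' @param dir directory for the CIF and charge file
#' @return list: `structure`, `params`, `path`, `charge_path`, `r_ha`
#'   (generated H...A distance), `theta` (approximate D-H...A angle),
#'   `manifest` (generation record)
#' @export
make_hbonded_fixture <- function(seed = 1L, dir = tempdir()) {
  set.seed(seed)
  r_ha <- stats::runif(1, 1.9, 2.4)
  phi <- stats::runif(1, 0, 12) * pi / 180     # donor O-H tilt in the xy plane
  b <- 9.5; cc <- 11.5
  # local Cartesian geometry (5 atoms): C centre, carbonyl-like acceptor,
  # hydroxyl donor oxygen + hydrogen, one C-H
  local <- rbind(
    C1 = c(0, 0, 0),
    O1 = c(-1.2, 0.15, 0.10),                       # acceptor
    O2 = c(1.0, -0.20, 0.10),                       # donor oxygen
    H2 = c(1.0 + 0.97 * cos(phi), -0.20 + 0.97 * sin(phi), 0.10),
    H1 = c(0, -1.05, -0.30))
  # screw image along a sits at +a/2 with y,z mirrored about the chosen
  # centre; solve the a axis so that |image(O1) - H2| = r_ha
  # with centre (cx, b/4, cz) the screw image of O1 sits at
  # (cx - 1.2 + a/2, b/4 - 0.15, -cz - 0.10); H2 at centre + local H2
  cz <- -0.10
  dy <- (-0.15) - local["H2", 2]
  dz <- (-cz - 0.10) - (cz + 0.10)                  # = 0 for cz = -0.10
  dx <- sqrt(r_ha^2 - dy^2 - dz^2)
  a <- 2 * (dx + 1.2 + local["H2", 1])
  cell <- unit_cell(a, b, cc)
  centre <- c(1.0, b / 4, cz)
  cart <- sweep(local, 2, centre, "+")
  fr <- cart %*% t(cell$cart_to_frac)
  atoms <- data.frame(label = rownames(local),
                      element = c("C", "O", "O", "H", "H"),
                      fx = fr[, 1], fy = fr[, 2], fz = fr[, 3],
                      stringsAsFactors = FALSE)
  st <- crystal_structure(cell, spacegroup_ops("P212121"), atoms,
                          spacegroup = "P212121")
  path <- file.path(dir, sprintf("hbond_seed%d.cif", seed))
  write_cif(st, path, data_name = "hbond_fixture")
  st2 <- perceive_molecules(read_cif(path))
  q <- gasteiger_charges(st2$molecules[[1]])
  charge_path <- file.path(dir, sprintf("hbond_seed%d.chg", seed))
  write_charges(q, charge_path)
  st2 <- assign_charges(st2, read_charges(charge_path))
  vDH <- cart["H2", ] - cart["O2", ]
  vHA <- c(dx, dy, dz)
  theta <- acos(-sum(vDH * vHA) / sqrt(sum(vDH^2) * sum(vHA^2))) * 180 / pi
  list(structure = st2, params = energy_params(), path = path,
       charge_path = charge_path, r_ha = r_ha, theta = theta,
       manifest = list(seed = seed, space_group = "P212121",
                       cell = c(a = a, b = b, c = cc),
                       r_ha = r_ha, phi_deg = phi * 180 / pi))
}

#' Random rigid-molecule P1 fixture
#'
#' A small (4-6 atom) organic-like molecule grown as a bonded random walk
#' and placed in a P1 cell large enough that periodic images do not clash;
#' Gasteiger charges give a mixed-charge Coulomb case. Used by the
#' brute-force oracle property tests.
#'
#' @param seed integer seed
#' @param dir directory for the CIF
#' @return list: `structure`, `params`, `path`, `radius_hint` (a summation
#'   radius guaranteed to include the first coordination shell)
#' @export
make_random_p1_fixture <- function(seed = 1L, dir = tempdir()) {
  set.seed(seed)
  repeat {
    n <- sample(4:6, 1)
    heavy <- sample(c("C", "N", "O"), n - 1, replace = TRUE,
                    prob = c(0.6, 0.2, 0.2))
    el <- c(heavy, "H")
    pos <- matrix(0, n, 3)
    for (i in 2:(n - 1)) {
      # bond to a random earlier heavy atom at ~1.45 A
      j <- sample(seq_len(i - 1), 1)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      pos[i, ] <- pos[j, ] + 1.45 * u
    }
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    pos[n, ] <- pos[n - 1, ] + 1.0 * u              # terminal H
    # reject self-clashes
    dmin <- min(stats::dist(pos))
    if (dmin < 0.95) next
    ext <- max(stats::dist(pos))
    axis <- ext + stats::runif(3, 3.2, 4.5)
    cell <- unit_cell(axis[1], axis[2], axis[3])
    fr <- sweep(pos, 2, c(axis[1] / 2, axis[2] / 2, axis[3] / 2), "+") %*%
      t(cell$cart_to_frac)
    atoms <- data.frame(label = paste0(el, seq_len(n)), element = el,
                        fx = fr[, 1], fy = fr[, 2], fz = fr[, 3],
                        stringsAsFactors = FALSE)
    st <- crystal_structure(cell, list(parse_symop("x,y,z")), atoms)
    path <- file.path(dir, sprintf("random_p1_seed%d.cif", seed))
    write_cif(st, path, data_name = "random_p1")
    st2 <- perceive_molecules(read_cif(path))
    if (st2$zprime != 1) next                        # walk must stay bonded
    # nearest intermolecular image contact must be clean
    nb <- expand_cluster(st2, max(axis) * 1.2)
    ok <- TRUE
    cm <- st2$molecules[[1]]
    xa <- cbind(cm$atoms$cx, cm$atoms$cy, cm$atoms$cz)
    for (m in nb) {
      xb <- cbind(m$atoms$cx, m$atoms$cy, m$atoms$cz)
      d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
        outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
      if (min(d2) < 2.6^2) { ok <- FALSE; break }
    }
    if (!ok) next
    st2 <- assign_charges(st2, gasteiger_charges(st2$molecules[[1]]))
    return(list(structure = st2, params = energy_params(), path = path,
                radius_hint = max(axis) * 1.1))
  }
}

#' The two published ritonavir unit cells
#'
#' Cell constants, space groups and Z of the two polymorphs, exactly as
#' printed in the published crystallographic record (cells only, no
#' atoms), for interplanar-spacing and surface-energy arithmetic.
#'
#' @return list with elements `form_I` and `form_II`, each carrying `cell`
#'   (a [unit_cell()]), `spacegroup`, `Z`, `zprime` and the printed cell
#'   volume `v_printed`
#' @export
table2_cells <- function() {
  list(
    form_I = list(cell = unit_cell(13.344, 5.2150, 26.693, 90, 103.456, 90),
                  spacegroup = "P21", Z = 2L, zprime = 1L,
                  v_printed = 1806.55),
    form_II = list(cell = unit_cell(9.831, 18.485, 20.261, 90, 90, 90),
                   spacegroup = "P212121", Z = 4L, zprime = 1L,
                   v_printed = 3681.95))
}

#' Brute-force supercell lattice-energy oracle
#'
#' Independent check of the lattice summation: a direct double loop over
#' every molecule generated in an n x n x n block of cells (all symmetry
#' operators, all translations), with plain scalar atom-atom loops for the
#' energies - no neighbour lists, no cluster machinery. Returns half the
#' sum over all pairs between the central molecule and block molecules
#' whose centroid lies within `radius`.
#'
#' @param st a `crystal_structure` with molecules perceived and charges
#'   assigned
#' @param params an [energy_params()]
#' @param n cells per axis (odd, >= 3)
#' @param radius comparison radius, Angstrom
#' @param central central asymmetric-unit molecule index
#' @return lattice energy in kcal/mol
#' @export
supercell_oracle <- function(st, params = energy_params(), n = 5L,
                             radius = 10, central = 1L) {
  stopifnot(n %% 2 == 1, n >= 3)
  half <- (n - 1) / 2
  M <- st$cell$frac_to_cart
  cmol <- st$molecules[[central]]
  c0 <- cmol$centroid
  vp <- .vdw_params_for(params, cmol$atoms$element)
  e_sum <- 0
  for (t1 in -half:half) for (t2 in -half:half) for (t3 in -half:half) {
    for (oi in seq_along(st$ops)) {
      for (mi in seq_along(st$molecules)) {
        mol <- st$molecules[[mi]]
        fr <- as.matrix(mol$atoms[, c("fx", "fy", "fz")])
        frn <- apply_symop(st$ops[[oi]], fr) +
          matrix(c(t1, t2, t3), nrow(fr), 3, byrow = TRUE)
        cart <- frn %*% t(M)
        cen <- colMeans(cart)
        dd <- sqrt(sum((cen - c0)^2))
        if (dd < 1e-6 || dd > radius) next
        e_sum <- e_sum + .oracle_pair_energy(cmol, mol, cart, params, vp)
      }
    }
  }
  e_sum / 2
}

# Scalar atom-atom energy between the central molecule and one image whose
# Cartesian coordinates are `cart`. Deliberately loop-based.
.oracle_pair_energy <- function(cmol, mol, cart, params, vpa) {
  xa <- cbind(cmol$atoms$cx, cmol$atoms$cy, cmol$atoms$cz)
  qa <- cmol$atoms$charge; qb <- mol$atoms$charge
  vpb <- .vdw_params_for(params, mol$atoms$element)
  na <- nrow(xa); nb <- nrow(cart)
  # detect hydrogen-bond triplets first (both directions)
  skip <- matrix(FALSE, na, nb)
  e <- 0
  dpA <- .donor_pairs(cmol); dpB <- .donor_pairs(mol)
  accB <- which(mol$atoms$element %in% c("N", "O", "S"))
  accA <- which(cmol$atoms$element %in% c("N", "O", "S"))
  if (!is.null(dpA)) for (r in seq_len(nrow(dpA))) {
    d <- dpA[r, 1]; h <- dpA[r, 2]
    for (ac in accB) {
      r_ha <- sqrt(sum((xa[h, ] - cart[ac, ])^2))
      if (r_ha > params$hb_r_ha_max) next
      vDH <- xa[d, ] - xa[h, ]; vHA <- cart[ac, ] - xa[h, ]
      th <- acos(max(-1, min(1, sum(vDH * vHA) /
                               sqrt(sum(vDH^2) * sum(vHA^2))))) * 180 / pi
      if (th <= params$hb_theta_min) next
      r_da <- sqrt(sum((xa[d, ] - cart[ac, ])^2))
      e <- e + hbond_energy(r_da, th, params)
      skip[h, ac] <- TRUE; skip[d, ac] <- TRUE
    }
  }
  if (!is.null(dpB)) for (r in seq_len(nrow(dpB))) {
    d <- dpB[r, 1]; h <- dpB[r, 2]
    for (ac in accA) {
      r_ha <- sqrt(sum((cart[h, ] - xa[ac, ])^2))
      if (r_ha > params$hb_r_ha_max) next
      vDH <- cart[d, ] - cart[h, ]; vHA <- xa[ac, ] - cart[h, ]
      th <- acos(max(-1, min(1, sum(vDH * vHA) /
                               sqrt(sum(vDH^2) * sum(vHA^2))))) * 180 / pi
      if (th <= params$hb_theta_min) next
      r_da <- sqrt(sum((cart[d, ] - xa[ac, ])^2))
      e <- e + hbond_energy(r_da, th, params)
      skip[ac, h] <- TRUE; skip[ac, d] <- TRUE
    }
  }
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      r <- sqrt(sum((xa[i, ] - cart[j, ])^2))
      e <- e + params$coulomb_k * qa[i] * qb[j] / r
      if (skip[i, j]) next
      d0 <- sqrt(vpa$d0[i] * vpb$d0[j])
      r0 <- (vpa$r0[i] + vpb$r0[j]) / 2
      s6 <- (r0 / r)^6
      e <- e + d0 * (s6^2 - 2 * s6)
    }
  }
  e
}
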