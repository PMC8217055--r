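# Atom-atom intermolecular energy model: Lennard-Jones 12-6 dispersion-
# repulsion with geometric/arithmetic combining, a directional 12-10
# hydrogen-bond term with a cos^4 angular weight replacing the vdW term of
# the D-H...A triplet, and a direct-space Coulomb sum over assigned partial
# charges. Units: kcal/mol and Angstrom throughout.

#' Default force-field parameters
#'
#' Per-element Lennard-Jones well depths / equilibrium distances (Dreiding
#' values), hydrogen-bond constants (12-10 with cos^4 angular term,
#' D_hb = 9.5 kcal/mol, R_hb = 2.75 A), detection thresholds for D-H...A
#' triplets, and the Coulomb constant 332.0637 kcal A / (mol e^2).
#'
#' @param vdw optional data frame with columns `element`, `r0`, `d0`
#'   overriding entries of the built-in table
#' @param d_hb,r_hb hydrogen-bond well depth (kcal/mol) and equilibrium
#'   donor-acceptor distance (A)
#' @param hb_exponent angular exponent n of cos^n(theta)
#' @param hb_r_ha_max maximum H...A distance for triplet detection (A)
#' @param hb_theta_min minimum D-H...A angle for triplet detection (deg)
#' @param hb_tag_threshold |E_hbond| above which a synthon is tagged H-Bond
#' @param coulomb_k Coulomb conversion constant
#' @return list of class `energy_params`
#' @export
energy_params <- function(vdw = NULL, d_hb = 9.5, r_hb = 2.75,
                          hb_exponent = 4L, hb_r_ha_max = 3.0,
                          hb_theta_min = 90, hb_tag_threshold = 0.5,
                          coulomb_k = 332.0637) {
  tab <- .element_table[, c("element", "lj_r0", "lj_d0")]
  names(tab) <- c("element", "r0", "d0")
  if (!is.null(vdw)) {
    stopifnot(all(c("element", "r0", "d0") %in% names(vdw)))
    for (i in seq_len(nrow(vdw))) {
      j <- match(vdw$element[i], tab$element)
      if (is.na(j)) tab <- rbind(tab, vdw[i, c("element", "r0", "d0")])
      else tab[j, c("r0", "d0")] <- vdw[i, c("r0", "d0")]
    }
  }
  stopifnot(all(tab$r0 > 0), all(tab$d0 > 0), d_hb > 0, r_hb > 0)
  structure(list(vdw = tab, d_hb = d_hb, r_hb = r_hb,
                 hb_exponent = as.integer(hb_exponent),
                 hb_r_ha_max = hb_r_ha_max, hb_theta_min = hb_theta_min,
                 hb_tag_threshold = hb_tag_threshold,
                 coulomb_k = coulomb_k),
            class = "energy_params")
}

.vdw_params_for <- function(params, elements) {
  idx <- match(elements, params$vdw$element)
  if (anyNA(idx)) {
    stop("no vdW parameters for element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  }
  list(r0 = params$vdw$r0[idx], d0 = params$vdw$d0[idx])
}

#' Lennard-Jones 12-6 pair energy
#'
#' E(r) = D0 [ (R0/r)^12 - 2 (R0/r)^6 ], minimum -D0 at r = R0. For two
#' unlike atoms, D0 is the geometric and R0 the arithmetic mean.
#'
#' @param r interatomic distance(s), Angstrom
#' @param d0 well depth, kcal/mol (combined value)
#' @param r0 equilibrium distance, Angstrom (combined value)
#' @return energy in kcal/mol
#' @export
vdw_energy <- function(r, d0, r0) {
  if (any(r < 0.1)) stop("atomic overlap: distance below 0.1 A")
  s6 <- (r0 / r)^6
  d0 * (s6^2 - 2 * s6)
}

#' Directional 12-10 hydrogen-bond energy
#'
#' E = D_hb [ 5 (R_hb/r_DA)^12 - 6 (R_hb/r_DA)^10 ] cos^n(theta), applied to
#' detected D-H...A triplets; zero for theta < 90 deg. At r_DA = R_hb and
#' theta = 180 deg the energy is exactly -D_hb.
#'
#' @param r_da donor-acceptor distance, Angstrom
#' @param theta_dha D-H...A angle, degrees
#' @param params an [energy_params()]
#' @return energy in kcal/mol
#' @export
hbond_energy <- function(r_da, theta_dha, params = energy_params()) {
  stopifnot(all(r_da > 0), all(theta_dha >= 0), all(theta_dha <= 180))
  s <- params$r_hb / r_da
  ang <- ifelse(theta_dha < 90, 0,
                cos(theta_dha * pi / 180)^params$hb_exponent)
  params$d_hb * (5 * s^12 - 6 * s^10) * ang
}

#' Coulomb pair energy
#'
#' E = k q1 q2 / r with k = 332.0637 kcal A / (mol e^2) (vacuum).
#'
#' @param r distance, Angstrom
#' @param q1,q2 partial charges, electron units
#' @param k conversion constant
#' @return energy in kcal/mol
#' @export
coulomb_energy <- function(r, q1, q2, k = 332.0637) {
  stopifnot(all(r > 0))
  k * q1 * q2 / r
}

#' Component breakdown of an interaction energy
#' @param vdw,hbond,coulomb components in kcal/mol
#' @return object of class `energy_breakdown` with fields `vdw`, `hbond`,
#'   `coulomb`, `total`
#' @export
energy_breakdown <- function(vdw = 0, hbond = 0, coulomb = 0) {
  structure(list(vdw = vdw, hbond = hbond, coulomb = coulomb,
                 total = vdw + hbond + coulomb),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("E_total %.4f kcal/mol (vdW %.4f, H-bond %.4f, Coulomb %.4f)\n",
              x$total, x$vdw, x$hbond, x$coulomb))
  invisible(x)
}

# Hydrogen-bond donor triplets (D, H) of one molecule: D in {N, O, S}
# covalently bound to H.
.donor_pairs <- function(mol) {
  el <- mol$atoms$element
  out <- NULL
  if (length(mol$bonds) == 0) return(out)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
    if (el[i] %in% c("N", "O", "S") && el[j] == "H") out <- rbind(out, c(i, j))
    if (el[j] %in% c("N", "O", "S") && el[i] == "H") out <- rbind(out, c(j, i))
  }
  out
}

#' Intermolecular pair interaction energy
#'
#' Sums Lennard-Jones and Coulomb terms over all intermolecular atom pairs;
#' detected D-H...A triplets contribute the directional hydrogen-bond term
#' instead of the Lennard-Jones terms of their H...A and D...A pairs.
#'
#' @param molA,molB molecules (distinct, non-overlapping) carrying Cartesian
#'   coordinates and charges
#' @param params an [energy_params()]
#' @param detail if TRUE, attach the per-atom-pair energy matrix
#'   (`attr(,"atom_pair")`, rows = atoms of `molA`) and the detected
#'   hydrogen-bond triplet table (`attr(,"hbonds")`)
#' @return an [energy_breakdown()]
#' @export
pair_interaction <- function(molA, molB, params = energy_params(),
                             detail = FALSE) {
  xa <- cbind(molA$atoms$cx, molA$atoms$cy, molA$atoms$cz)
  xb <- cbind(molB$atoms$cx, molB$atoms$cy, molB$atoms$cz)
  na <- nrow(xa); nb <- nrow(xb)
  D <- sqrt(pmax(outer(rowSums(xa^2), rep(1, nb)) +
                 outer(rep(1, na), rowSums(xb^2)) - 2 * (xa %*% t(xb)), 0))
  if (any(D < 0.5)) stop("molecular overlap: interatomic distance below 0.5 A")

  pa <- .vdw_params_for(params, molA$atoms$element)
  pb <- .vdw_params_for(params, molB$atoms$element)
  D0 <- sqrt(outer(pa$d0, pb$d0))
  R0 <- outer(pa$r0, pb$r0, "+") / 2
  s6 <- (R0 / D)^6
  Evdw_mat <- D0 * (s6^2 - 2 * s6)

  qa <- molA$atoms$charge; qb <- molB$atoms$charge
  if (anyNA(qa) || anyNA(qb)) stop("partial charges not assigned")
  Ecoul_mat <- params$coulomb_k * outer(qa, qb) / D

  # D-H...A triplets in both directions
  Ehb <- 0
  hb_rows <- NULL
  Ehb_mat <- matrix(0, na, nb)
  scan <- function(donors, xd, xacc, acc_ok, DH_dist, forward) {
    if (is.null(donors)) return(invisible(NULL))
    for (r in seq_len(nrow(donors))) {
      d <- donors[r, 1]; h <- donors[r, 2]
      for (aidx in which(acc_ok)) {
        r_ha <- DH_dist(h, aidx)
        if (r_ha > params$hb_r_ha_max) next
        vDH <- xd[d, ] - xd[h, ]
        vHA <- xacc[aidx, ] - xd[h, ]
        ct <- sum(vDH * vHA) / sqrt(sum(vDH^2) * sum(vHA^2))
        theta <- acos(pmin(1, pmax(-1, ct))) * 180 / pi    # D-H...A angle
        if (theta <= params$hb_theta_min) next
        r_da <- sqrt(sum((xd[d, ] - xacc[aidx, ])^2))
        e <- hbond_energy(r_da, theta, params)
        Ehb <<- Ehb + e
        if (forward) {
          Ehb_mat[d, aidx] <<- Ehb_mat[d, aidx] + e
          Evdw_mat[h, aidx] <<- 0; Evdw_mat[d, aidx] <<- 0
          hb_rows <<- rbind(hb_rows, data.frame(
            donor = molA$atoms$label[d], h = molA$atoms$label[h],
            acceptor = molB$atoms$label[aidx],
            r_ha = r_ha, r_da = r_da, theta = theta, energy = e,
            donor_in = "A", stringsAsFactors = FALSE))
        } else {
          Ehb_mat[aidx, d] <<- Ehb_mat[aidx, d] + e
          Evdw_mat[aidx, h] <<- 0; Evdw_mat[aidx, d] <<- 0
          hb_rows <<- rbind(hb_rows, data.frame(
            donor = molB$atoms$label[d], h = molB$atoms$label[h],
            acceptor = molA$atoms$label[aidx],
            r_ha = r_ha, r_da = r_da, theta = theta, energy = e,
            donor_in = "B", stringsAsFactors = FALSE))
        }
      }
    }
  }
  accB <- molB$atoms$element %in% c("N", "O", "S")
  accA <- molA$atoms$element %in% c("N", "O", "S")
  scan(.donor_pairs(molA), xa, xb, accB, function(h, a) D[h, a], TRUE)
  scan(.donor_pairs(molB), xb, xa, accA, function(h, a) D[a, h], FALSE)

  out <- energy_breakdown(vdw = sum(Evdw_mat), hbond = Ehb,
                          coulomb = sum(Ecoul_mat))
  if (detail) {
    attr(out, "atom_pair") <- Evdw_mat + Ecoul_mat + Ehb_mat
    attr(out, "hbonds") <- hb_rows
  }
  out
}

# Gasteiger-Marsili PEOE electronegativity parameters a + b q + c q^2,
# keyed by element and connectivity-derived hybridisation.
.gasteiger_params <- function(element, degree) {
  pick <- function(el, dg) {
    switch(el,
      H = c(7.17, 6.24, -0.56),
      C = if (dg >= 4) c(7.98, 9.18, 1.88)
          else if (dg == 3) c(8.79, 9.32, 1.51)
          else c(10.39, 9.45, 0.73),
      N = if (dg >= 3) c(11.54, 10.82, 1.36)
          else if (dg == 2) c(12.87, 11.15, 0.85)
          else c(15.68, 11.70, -0.27),
      O = if (dg >= 2) c(14.18, 12.92, 1.39) else c(17.07, 13.79, 0.47),
      S = c(10.14, 9.13, 1.38),
      F = c(14.66, 13.85, 2.31),
      Cl = c(11.00, 9.69, 1.35),
      Br = c(10.08, 8.47, 1.16),
      I = c(9.90, 7.96, 0.96),
      stop("no Gasteiger parameters for element ", el)
    )
  }
  t(mapply(pick, element, degree))
}

#' Gasteiger-Marsili partial charges
#'
#' Iterative partial equalisation of orbital electronegativity over the
#' molecular bond graph. Electronegativity chi(q) = a + b q + c q^2 with
#' parameters chosen by element and connectivity; per-bond transfers are
#' damped by (1/2)^k at iteration k and divided by the cation
#' electronegativity of the electron-donating atom (20.02 for hydrogen).
#'
#' @param mol a molecule with atoms and bonds (as built by
#'   [perceive_molecules()])
#' @param iterations maximum number of iterations
#' @param tol convergence threshold on the largest per-iteration transfer (e)
#' @return named numeric vector of charges (sums to 0 for neutral
#'   molecules), with `attr(,"provenance") = "gasteiger"`
#' @export
gasteiger_charges <- function(mol, iterations = 50L, tol = 1e-5) {
  el <- mol$atoms$element
  n <- length(el)
  degree <- if (length(mol$bonds)) tabulate(c(mol$bonds), nbins = n)
            else integer(n)
  par <- .gasteiger_params(el, degree)
  chi_plus <- ifelse(el == "H", 20.02, rowSums(par))
  q <- numeric(n)
  if (length(mol$bonds) > 0) {
    for (k in seq_len(iterations)) {
      chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
      damp <- 0.5^k
      dq <- numeric(n)
      for (b in seq_len(nrow(mol$bonds))) {
        i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
        if (chi[i] == chi[j]) next
        lo <- if (chi[i] < chi[j]) i else j   # electron donor
        hi <- if (lo == i) j else i
        tr <- (chi[hi] - chi[lo]) / chi_plus[lo] * damp
        dq[lo] <- dq[lo] + tr
        dq[hi] <- dq[hi] - tr
      }
      q <- q + dq
      if (max(abs(dq)) < tol) break
    }
  }
  structure(stats::setNames(q, mol$atoms$label), provenance = "gasteiger")
}
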