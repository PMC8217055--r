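# Surface stage: anisotropy factors, surface energies from attachment
# energies, particle-weighted surface energy, and rugosity.

.KCAL_TO_J <- 4184
.AVOGADRO <- 6.02214076e23

#' Surface anisotropy factor
#'
#' xi_hkl = E_sl / E_cr = (E_cr - E_att) / E_cr, the fraction of a
#' molecule's lattice coordination satisfied within the growth slice
#' ("synthon saturation"), reported in percent.
#'
#' @param e_att attachment energy, kcal/mol (negative for cohesive faces)
#' @param e_cr lattice energy, kcal/mol (negative)
#' @return percentage
#' @examples
#' anisotropy_factor(-9.87, -78.29)   # 87.39
#' @export
anisotropy_factor <- function(e_att, e_cr) {
  stopifnot(e_cr < 0)
  if (any(abs(e_att) > abs(e_cr))) {
    warning("non-physical partition: |E_att| exceeds |E_cr|")
  }
  100 * (e_cr - e_att) / e_cr
}

#' Surface energy of a crystal face
#'
#' gamma_hkl = Z |E_att| d_hkl / (2 V_cell N_A), converted to mJ/m^2
#' (1 kcal = 4184 J). Attachment energies are negative; the magnitude is
#' used so that surface energies are positive. Passing component-wise
#' attachment energies yields component-wise surface energies.
#'
#' @param Z molecules per unit cell
#' @param e_att attachment energy (or one component of it), kcal/mol
#' @param d_hkl interplanar spacing, Angstrom
#' @param v_cell unit-cell volume, Angstrom^3
#' @return surface energy in mJ/m^2
#' @examples
#' surface_energy(2, -9.87, 25.96, 1806.55)   # ~98.5
#' @export
surface_energy <- function(Z, e_att, d_hkl, v_cell) {
  stopifnot(Z > 0, d_hkl > 0, v_cell > 0)
  gamma_j_m2 <- Z * abs(e_att) * .KCAL_TO_J * (d_hkl * 1e-10) /
    (2 * (v_cell * 1e-30) * .AVOGADRO)
  1000 * gamma_j_m2
}

#' Particle-weighted (whole crystal) surface energy
#'
#' Surface-area weighted average gamma_particle = sum gamma_hkl x SA_hkl
#' over the habit forms; the fractional areas are used as given (already
#' aggregated over form multiplicity), without renormalisation.
#'
#' @param gamma_hkl per-form surface energies, mJ/m^2
#' @param sa_frac per-form fractional surface areas (should sum to ~1)
#' @return particle surface energy, mJ/m^2
#' @export
particle_surface_energy <- function(gamma_hkl, sa_frac) {
  stopifnot(length(gamma_hkl) == length(sa_frac), all(sa_frac >= 0))
  s <- sum(sa_frac)
  if (s < 0.98 || s > 1.02) {
    warning(sprintf("fractional areas sum to %.3f, outside [0.98, 1.02]", s))
  }
  sum(gamma_hkl * sa_frac)
}

#' Surface rugosity of a face
#'
#' Root-mean-squared variation of the atomic positions of the asymmetric
#' unit along the (hkl) plane normal, measured about their mean height
#' (centred RMS). A perfectly flat molecular layer parallel to the face
#' gives 0.
#'
#' @param st a `crystal_structure` with molecules perceived
#' @param hkl face index
#' @return rugosity in Angstrom
#' @export
rugosity <- function(st, hkl) {
  if (is.null(st$molecules)) stop("run perceive_molecules() first")
  nrm <- plane_normal(st$cell, hkl)
  pos <- do.call(rbind, lapply(st$molecules, function(m)
    cbind(m$atoms$cx, m$atoms$cy, m$atoms$cz)))
  h <- pos %*% nrm
  sqrt(mean((h - mean(h))^2))
}

#' Face-by-face surface report
#'
#' Combines slice partitions, Wulff fractional areas and the surface-energy
#' formulas into the per-face table (d-spacing, area fraction, multiplicity,
#' attachment energy, anisotropy factor, component-wise and total surface
#' energies, rugosity) plus the particle-weighted surface energy.
#'
#' @param st a `crystal_structure` (charges assigned)
#' @param partitions list of `habit_face` objects from [slice_partition()]
#' @param forms the [bfdh_forms()] table used (for multiplicities)
#' @param poly the [wulff_construction()] polyhedron for the same forms
#' @return list with `faces` (data frame) and `gamma_particle` (mJ/m^2)
#' @export
surface_report <- function(st, partitions, forms, poly) {
  Z <- structure_Z(st)
  v_cell <- st$cell$volume
  rows <- lapply(seq_along(partitions), function(i) {
    fp <- partitions[[i]]
    g_tot <- surface_energy(Z, fp$e_att$total, fp$d_hkl, v_cell)
    data.frame(
      h = fp$hkl[1], k = fp$hkl[2], l = fp$hkl[3],
      d_hkl = fp$d_hkl,
      sa_pct = 100 * poly$sa_frac[i],
      multiplicity = forms$multiplicity[i],
      e_att = fp$e_att$total,
      xi = fp$xi,
      gamma_vdw = surface_energy(Z, fp$e_att$vdw, fp$d_hkl, v_cell),
      gamma_hbond = surface_energy(Z, fp$e_att$hbond, fp$d_hkl, v_cell),
      gamma_coulomb = surface_energy(Z, fp$e_att$coulomb, fp$d_hkl, v_cell),
      gamma_total = g_tot,
      rugosity = rugosity(st, fp$hkl))
  })
  faces <- do.call(rbind, rows)
  gp <- particle_surface_energy(faces$gamma_total, poly$sa_frac)
  list(faces = faces, gamma_particle = gp)
}
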