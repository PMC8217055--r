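# Conformer bookkeeping: torsion fingerprints, deformation energies from
# externally supplied single-point energies, and the conformation-adjusted
# lattice-energy difference between polymorphs.

#' Signed torsion (dihedral) angle
#'
#' Standard IUPAC convention: looking down the central bond 2-3, the angle
#' through which atoms 1 and 4 are rotated, in (-180, 180]. The four atoms
#' must form a bonded chain when `mol` carries a bond list.
#'
#' @param mol a molecule with Cartesian coordinates
#' @param labels four site labels defining the chain 1-2-3-4
#' @param cis_threshold |angle| below which the torsion is classified cis
#' @return angle in degrees with `attr(,"classification")` ("cis"/"trans")
#' @export
torsion_angle <- function(mol, labels, cis_threshold = 90) {
  idx <- match(labels, mol$atoms$label)
  if (anyNA(idx)) {
    stop("unknown atom label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  }
  if (length(unique(idx)) != 4) stop("need four distinct atoms")
  if (length(mol$bonds) > 0) {
    has_bond <- function(i, j) any((mol$bonds[, 1] == i & mol$bonds[, 2] == j) |
                                   (mol$bonds[, 1] == j & mol$bonds[, 2] == i))
    for (k in 1:3) {
      if (!has_bond(idx[k], idx[k + 1])) {
        stop("atoms ", labels[k], "-", labels[k + 1], " are not bonded")
      }
    }
  }
  p <- cbind(mol$atoms$cx, mol$atoms$cy, mol$atoms$cz)[idx, ]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  if (sqrt(sum(b2^2)) < 1e-8) stop("undefined torsion: central atoms coincide")
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    stop("undefined torsion: collinear atoms about the central bond")
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  structure(ang,
            classification = if (abs(ang) < cis_threshold) "cis" else "trans")
}

#' Conformational deformation energy
#'
#' Difference of two single-point conformer energies computed at the same
#' level of theory (the caller's responsibility; echoed in the provenance
#' attribute). Antisymmetric under argument swap.
#'
#' @param e_a,e_b conformer single-point energies, kcal/mol
#' @param provenance free-text description of the energy source
#' @return E_a - E_b in kcal/mol with `attr(,"provenance")`
#' @export
deformation_energy <- function(e_a, e_b, provenance = "external single-point") {
  structure(e_a - e_b, provenance = provenance)
}

#' Conformation-adjusted lattice-energy difference
#'
#' The packing advantage of polymorph B over polymorph A net of B's
#' conformational penalty: |E_cr(B)| - |E_cr(A)| - |dE_conf|.
#'
#' @param e_cr_a,e_cr_b lattice energies (negative), kcal/mol
#' @param de_conf conformational deformation energy, kcal/mol
#' @return adjusted difference in kcal/mol
#' @examples
#' conformation_adjusted_difference(-78.29, -92.33, -8.09)  # 5.95
#' @export
conformation_adjusted_difference <- function(e_cr_a, e_cr_b, de_conf) {
  abs(e_cr_b) - abs(e_cr_a) - abs(de_conf)
}
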