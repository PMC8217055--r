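#' Element property tables
#'
#' Lookup tables used throughout the package: Cordero covalent radii (for bond
#' perception), Bondi van der Waals radii (for volume/packing descriptors),
#' standard atomic masses, and Dreiding-style Lennard-Jones well depths /
#' equilibrium distances.
#'
#' @format A data frame with one row per supported element.
#' @keywords internal
.element_table <- data.frame(
  element = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  # Cordero et al. covalent radii, Angstrom (sp3 carbon)
  r_cov   = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02, 1.20, 1.39),
  # Bondi van der Waals radii, Angstrom
  r_vdw   = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98),
  # standard atomic masses, g/mol
  mass    = c(1.008, 12.011, 14.007, 15.999, 18.998, 30.974, 32.06,
              35.45, 79.904, 126.904),
  # Dreiding Lennard-Jones 12-6 parameters: R0 (A), D0 (kcal/mol)
  lj_r0   = c(3.195, 3.8983, 3.6621, 3.4046, 3.4720, 4.1500, 4.0300,
              3.9503, 3.95, 4.15),
  lj_d0   = c(0.0152, 0.0951, 0.0774, 0.0957, 0.0725, 0.3200, 0.3440,
              0.2833, 0.37, 0.51),
  stringsAsFactors = FALSE
)

.element_prop <- function(elements, what) {
  idx <- match(elements, .element_table$element)
  if (anyNA(idx)) {
    stop("unknown element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  }
  .element_table[[what]][idx]
}

#' Covalent radius of an element
#' @param elements character vector of element symbols
#' @return numeric vector, Angstrom
#' @export
covalent_radius <- function(elements) .element_prop(elements, "r_cov")

#' Van der Waals radius of an element (Bondi set)
#' @param elements character vector of element symbols
#' @return numeric vector, Angstrom
#' @export
vdw_radius <- function(elements) .element_prop(elements, "r_vdw")

#' Standard atomic mass
#' @param elements character vector of element symbols
#' @return numeric vector, g/mol
#' @export
atomic_mass <- function(elements) .element_prop(elements, "mass")
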