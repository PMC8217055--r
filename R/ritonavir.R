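#' Published reference data for the ritonavir polymorphs
#'
#' The printed crystallographic and energetic record of ritonavir forms I
#' (P2\eqn{_1}, Z = 2) and II (P2\eqn{_1}2\eqn{_1}2\eqn{_1}, Z = 4), used
#' as numeric inputs to the arithmetic stages of the workflow: unit cells,
#' single-point conformer energies, lattice-energy component breakdowns,
#' the per-face habit table (d-spacings, fractional areas, multiplicities,
#' attachment energies, anisotropy factors, surface energies) and the
#' molecular-fragment contributions. The licensed database structures
#' themselves are neither shipped nor required.
#'
#' @return a list:
#' \describe{
#'   \item{cells}{[table2_cells()] output}
#'   \item{descriptors}{molecular volume / surface area, packing
#'     coefficient, void space, density, molar mass per form}
#'   \item{conformer_energies}{DFT single-point energies of the two
#'     conformers (kcal/mol)}
#'   \item{lattice_components}{vdW / Coulomb / H-bond components and total
#'     lattice energy per form (kcal/mol)}
#'   \item{faces}{per-face habit table for both forms}
#'   \item{fragments}{fragment contributions to the lattice energy (%)}
#' }
#' @export
ritonavir_reference <- function() {
  faces <- data.frame(
    form = c(rep("I", 4), rep("II", 4)),
    h = c(0, 1, 1, 0, 0, 0, 1, 1),
    k = c(0, 0, 0, 1, 1, 0, 0, 1),
    l = c(1, 0, -1, 1, 1, 2, 1, 0),
    d_hkl = c(25.96, 12.98, 12.87, 5.11, 13.65, 10.13, 8.84, 8.68),
    sa_pct = c(58.72, 15.08, 14.68, 11.32, 58.48, 12.52, 25.4, 3.56),
    multiplicity = c(2, 2, 2, 4, 4, 2, 4, 4),
    e_att = c(-9.87, -22.30, -22.19, -57.29, -27.01, -29.23, -42.43, -50.66),
    xi = c(87.39, 71.53, 73.18, 26.82, 70.75, 68.34, 54.04, 45.13),
    gamma_vdw = c(89.75, 93.27, 98.21, 73.82, 116.48, 93.69, 51.95, 76.51),
    gamma_hbond = c(NA, NA, NA, 21.86, NA, NA, 58.09, 60.17),
    gamma_coulomb = c(8.87, 18.08, 11.69, 16.91, 22.51, 18.12, 25.24, 30.62),
    gamma_total = c(98.62, 111.35, 109.90, 112.59, 138.99, 111.81, 135.28,
                    167.30),
    stringsAsFactors = FALSE)
  lattice_components <- data.frame(
    component = c("vdw", "coulomb", "hbond", "total"),
    form_I = c(-53.77, -11.39, -13.13, -78.29),
    form_II = c(-55.55, -18.54, -18.24, -92.33),
    pct_I = c(68.6, 14.5, 16.8, 100),
    pct_II = c(60.2, 20.1, 19.8, 100),
    stringsAsFactors = FALSE)
  fragments <- data.frame(
    fragment = c("alpha", "beta", "gamma", "delta"),
    pct_I = c(11.27, 28.2, 37.40, 23.01),
    pct_II = c(16.71, 28.28, 38.24, 16.79),
    stringsAsFactors = FALSE)
  descriptors <- data.frame(
    form = c("I", "II"),
    molecular_volume = c(721.24, 676.74),
    molecular_surface_area = c(656.46, 645.09),
    packing_coefficient = c(0.80, 0.73),
    void_pct = c(0.3, 0.9),
    density = c(1.28, 1.25),
    mol_mass = c(720.9, 720.9),
    stringsAsFactors = FALSE)
  list(cells = table2_cells(),
       descriptors = descriptors,
       conformer_energies = c(form_I = -1842838.84, form_II = -1842830.75),
       lattice_components = lattice_components,
       faces = faces,
       fragments = fragments,
       particle_surface_energy = c(form_I = 103.58, form_II = 135.60))
}
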