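# Molecular and crystal packing descriptors: vdW-sphere molecular volume
# and surface area by voxel counting, packing coefficient, probe-based void
# space and crystallographic density.

#' Molecular volume from the union of van der Waals spheres
#'
#' Voxel counting on a regular grid over the molecular bounding box; the
#' reported error bound is one voxel layer over the union surface.
#'
#' @param mol a molecule with Cartesian coordinates
#' @param grid_step voxel edge in Angstrom (0.05 to 0.5)
#' @return volume in Angstrom^3, with `attr(,"error")` (one-layer bound) and
#'   `attr(,"surface_area")` (voxel-face area of the union surface,
#'   approximate)
#' @export
molecular_volume <- function(mol, grid_step = 0.2) {
  stopifnot(grid_step >= 0.05, grid_step <= 0.5)
  if (nrow(mol$atoms) == 0) stop("empty molecule")
  pos <- cbind(mol$atoms$cx, mol$atoms$cy, mol$atoms$cz)
  rad <- vdw_radius(mol$atoms$element)
  lo <- apply(pos - rad, 2, min) - grid_step
  hi <- apply(pos + rad, 2, max) + grid_step
  gx <- seq(lo[1] + grid_step / 2, hi[1], by = grid_step)
  gy <- seq(lo[2] + grid_step / 2, hi[2], by = grid_step)
  gz <- seq(lo[3] + grid_step / 2, hi[3], by = grid_step)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  occ <- array(FALSE, c(nx, ny, nz))
  for (a in seq_len(nrow(pos))) {
    ix <- which(abs(gx - pos[a, 1]) <= rad[a])
    iy <- which(abs(gy - pos[a, 2]) <= rad[a])
    iz <- which(abs(gz - pos[a, 3]) <= rad[a])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - pos[a, 1])^2
    dy2 <- (gy[iy] - pos[a, 2])^2
    dz2 <- (gz[iz] - pos[a, 3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rad[a]^2
    occ[ix, iy, iz] <- occ[ix, iy, iz] | inside
  }
  nvox <- sum(occ)
  vol <- nvox * grid_step^3
  # boundary voxels: occupied with at least one unoccupied 6-neighbour
  pad <- array(FALSE, c(nx + 2, ny + 2, nz + 2))
  pad[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] <- occ
  core <- pad[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)]
  nfaces <- sum(core & !pad[1:nx, 2:(ny + 1), 2:(nz + 1)]) +
    sum(core & !pad[3:(nx + 2), 2:(ny + 1), 2:(nz + 1)]) +
    sum(core & !pad[2:(nx + 1), 1:ny, 2:(nz + 1)]) +
    sum(core & !pad[2:(nx + 1), 3:(ny + 2), 2:(nz + 1)]) +
    sum(core & !pad[2:(nx + 1), 2:(ny + 1), 1:nz]) +
    sum(core & !pad[2:(nx + 1), 2:(ny + 1), 3:(nz + 2)])
  structure(vol,
            error = nfaces * grid_step^3,
            surface_area = nfaces * grid_step^2)
}

#' Crystal packing coefficient
#'
#' C_k = Z x V_mol / V_cell: the fraction of the unit cell filled by the
#' molecular vdW volume.
#'
#' @param st a `crystal_structure` (molecules perceived), or NULL when `Z`
#'   and `v_cell` are given directly
#' @param v_mol molecular volume in Angstrom^3
#' @param Z,v_cell override molecules-per-cell and cell volume
#' @return dimensionless coefficient in (0, 1) for physical packings
#' @examples
#' packing_coefficient(NULL, 721.24, Z = 2, v_cell = 1806.55)  # 0.7985
#' @export
packing_coefficient <- function(st, v_mol, Z = NULL, v_cell = NULL) {
  stopifnot(v_mol > 0)
  if (is.null(Z)) Z <- structure_Z(st)
  if (is.null(v_cell)) v_cell <- st$cell$volume
  Z * v_mol / v_cell
}

#' Void space of a packed cell
#'
#' Percentage of the cell volume not reachable: voxels whose distance to
#' every vdW sphere surface exceeds `probe_radius`, accumulated over the
#' packed cell (all symmetry images, periodic).
#'
#' @param st a `crystal_structure` with molecules perceived
#' @param probe_radius probe radius in Angstrom (default 1.2)
#' @param grid_step voxel edge in Angstrom (default 0.3)
#' @return percentage of the cell volume
#' @export
void_space <- function(st, probe_radius = 1.2, grid_step = 0.3) {
  stopifnot(probe_radius >= 0)
  cell <- st$cell
  # all atoms of the packed cell plus a periodic shell
  pos <- NULL; rad <- NULL
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (oi in seq_along(st$ops)) {
    for (m in st$molecules) {
      fr <- as.matrix(m$atoms[, c("fx", "fy", "fz")])
      fb <- apply_symop(st$ops[[oi]], fr)
      for (s in seq_len(nrow(shifts))) {
        frs <- sweep(fb, 2, shifts[s, ], "+")
        # keep atoms whose sphere can reach the cell box
        keep <- frs[, 1] > -0.35 & frs[, 1] < 1.35 &
                frs[, 2] > -0.35 & frs[, 2] < 1.35 &
                frs[, 3] > -0.35 & frs[, 3] < 1.35
        if (!any(keep)) next
        pos <- rbind(pos, frs[keep, , drop = FALSE] %*% t(cell$frac_to_cart))
        rad <- c(rad, vdw_radius(m$atoms$element[keep]))
      }
    }
  }
  gx <- seq(0.5 / ceiling(cell$a / grid_step), 1,
            by = 1 / ceiling(cell$a / grid_step))
  gy <- seq(0.5 / ceiling(cell$b / grid_step), 1,
            by = 1 / ceiling(cell$b / grid_step))
  gz <- seq(0.5 / ceiling(cell$c / grid_step), 1,
            by = 1 / ceiling(cell$c / grid_step))
  grid_f <- as.matrix(expand.grid(gx, gy, gz))
  grid_c <- grid_f %*% t(cell$frac_to_cart)
  if (is.null(pos)) return(100)
  free <- rep(TRUE, nrow(grid_c))
  reach <- rad + probe_radius
  for (a in seq_len(nrow(pos))) {
    if (!any(free)) break
    d2 <- (grid_c[free, 1] - pos[a, 1])^2 +
          (grid_c[free, 2] - pos[a, 2])^2 +
          (grid_c[free, 3] - pos[a, 3])^2
    free[free] <- d2 > reach[a]^2
  }
  100 * sum(free) / nrow(grid_c)
}

#' Crystallographic density
#'
#' rho = Z M / (N_A V_cell) in g/cc.
#'
#' @param st a `crystal_structure` with molecules perceived, or NULL when
#'   the values are given directly
#' @param Z,mol_mass,v_cell override molecules per cell, molar mass (g/mol)
#'   and cell volume (Angstrom^3)
#' @return density in g/cc
#' @export
crystal_density <- function(st, Z = NULL, mol_mass = NULL, v_cell = NULL) {
  if (is.null(Z)) Z <- structure_Z(st)
  if (is.null(v_cell)) v_cell <- st$cell$volume
  if (is.null(mol_mass)) {
    mol_mass <- mean(vapply(st$molecules, function(m)
      sum(atomic_mass(m$atoms$element)), numeric(1)))
  }
  Z * mol_mass / (.AVOGADRO * v_cell * 1e-24)
}

#' Descriptor report for a structure
#'
#' Molecular volume and surface area (voxel union), packing coefficient,
#' void space and density, in one table.
#'
#' @param st a `crystal_structure` with molecules perceived
#' @param grid_step voxel edge for the volume/void grids
#' @param probe_radius probe radius for the void-space scan
#' @return data frame with one row of descriptors
#' @export
descriptor_report <- function(st, grid_step = 0.2, probe_radius = 1.2) {
  vm <- mean(vapply(st$molecules, function(m)
    as.numeric(molecular_volume(m, grid_step)), numeric(1)))
  sa <- mean(vapply(st$molecules, function(m)
    attr(molecular_volume(m, grid_step), "surface_area"), numeric(1)))
  data.frame(
    molecular_volume = vm,
    molecular_surface_area = sa,
    packing_coefficient = packing_coefficient(st, vm),
    void_pct = void_space(st, probe_radius, max(grid_step, 0.3)),
    density = crystal_density(st))
}
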