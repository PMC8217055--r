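#' Perceive whole molecules in the asymmetric unit
#'
#' Bonds are assigned between atoms whose interatomic distance (honouring
#' periodic images) is below the sum of covalent radii plus `tol`.
#' Connected components become molecules; molecules straddling the cell
#' boundary are made whole by translating atoms by lattice vectors. A
#' component that closes on itself through a lattice translation is a
#' covalent network, not a molecular crystal, and raises an error.
#'
#' @param st a `crystal_structure`
#' @param tol bond tolerance in Angstrom added to the covalent-radius sum
#' @return the structure with `molecules` (list) and `zprime` filled in.
#'   Each molecule carries `atoms` (with fractional and Cartesian
#'   coordinates and `asym_index` back-references), a two-column `bonds`
#'   matrix, the Cartesian `centroid` and an identifier
#'   `id = c(asym, op, t1, t2, t3)`.
#' @export
perceive_molecules <- function(st, tol = 0.40) {
  at <- st$atoms
  n <- nrow(at)
  if (n == 0) stop("structure has no atoms")
  fr <- as.matrix(at[, c("fx", "fy", "fz")])
  rc <- covalent_radius(at$element)
  M <- st$cell$frac_to_cart

  shifts27 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  # an atom bonded to its own periodic image is already an infinite chain
  selfdist <- sqrt(rowSums((shifts27[rowSums(abs(shifts27)) > 0, ,
                                     drop = FALSE] %*% t(M))^2))
  for (i in seq_len(n)) {
    if (any(selfdist < 2 * rc[i] + tol)) {
      stop("not a molecular crystal: atom ", at$label[i],
           " bonds to its own lattice image")
    }
  }
  bond_i <- integer(0); bond_j <- integer(0); bond_s <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d0 <- fr[i, ] - fr[j, ]
        base <- round(d0)
        cand <- sweep(shifts27, 2, base, "+")      # shifts applied to atom j
        diff <- matrix(d0, nrow(cand), 3, byrow = TRUE) - cand
        dc <- diff %*% t(M)
        dist2 <- rowSums(dc^2)
        # record EVERY image within bonding distance: the same pair bonded
        # through two different lattice shifts is a periodic network and is
        # caught by the unwrap conflict below
        for (k in which(dist2 < (rc[i] + rc[j] + tol)^2 & dist2 > 0.09)) {
          bond_i <- c(bond_i, i); bond_j <- c(bond_j, j)
          bond_s[[length(bond_s) + 1L]] <- cand[k, ]
        }
      }
    }
  }

  # BFS over the bond graph, unwrapping lattice shifts; a shift conflict
  # means the component is periodically infinite.
  comp <- rep(NA_integer_, n)
  shift <- matrix(NA_real_, n, 3)
  ncomp <- 0L
  adj <- vector("list", n)
  for (b in seq_along(bond_i)) {
    i <- bond_i[b]; j <- bond_j[b]
    adj[[i]] <- rbind(adj[[i]], c(j, bond_s[[b]]))       # j sits at fr_j + s
    adj[[j]] <- rbind(adj[[j]], c(i, -bond_s[[b]]))
  }
  for (seed in seq_len(n)) {
    if (!is.na(comp[seed])) next
    ncomp <- ncomp + 1L
    comp[seed] <- ncomp
    shift[seed, ] <- c(0, 0, 0)
    queue <- seed
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- adj[[i]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        j <- nb[r, 1]
        sj <- shift[i, ] + nb[r, 2:4]
        if (is.na(comp[j])) {
          comp[j] <- ncomp
          shift[j, ] <- sj
          queue <- c(queue, j)
        } else if (any(abs(shift[j, ] - sj) > 1e-6)) {
          stop("not a molecular crystal: atoms ", at$label[i], "-", at$label[j],
               " close a periodic covalent network")
        }
      }
    }
  }

  mols <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    sel <- which(comp == k)
    a <- at[sel, , drop = FALSE]
    frw <- fr[sel, , drop = FALSE] + shift[sel, , drop = FALSE]
    # canonical placement: centroid inside [0,1)^3
    cen_f <- colMeans(frw)
    frw <- sweep(frw, 2, floor(cen_f), "-")
    cart <- frw %*% t(M)
    a$fx <- frw[, 1]; a$fy <- frw[, 2]; a$fz <- frw[, 3]
    a$cx <- cart[, 1]; a$cy <- cart[, 2]; a$cz <- cart[, 3]
    a$asym_index <- sel
    bsel <- which(bond_i %in% sel & bond_j %in% sel)
    bonds <- cbind(match(bond_i[bsel], sel), match(bond_j[bsel], sel))
    mols[[k]] <- list(atoms = a, bonds = bonds,
                      centroid = colMeans(cart),
                      id = c(asym = k, op = 1L, t1 = 0L, t2 = 0L, t3 = 0L))
  }
  # deterministic order: by first asym atom index
  ord <- order(vapply(mols, function(m) min(m$atoms$asym_index), integer(1)))
  st$molecules <- mols[ord]
  for (k in seq_along(st$molecules)) st$molecules[[k]]$id["asym"] <- k
  st$zprime <- ncomp
  st
}

# Symmetry/lattice image of an asymmetric-unit molecule. Applying the affine
# operator to the unwrapped fractional coordinates keeps the molecule whole.
.molecule_image <- function(st, mol, op_idx, tvec) {
  op <- st$ops[[op_idx]]
  fr <- as.matrix(mol$atoms[, c("fx", "fy", "fz")])
  frn <- apply_symop(op, fr) + matrix(tvec, nrow(fr), 3, byrow = TRUE)
  cart <- frn %*% t(st$cell$frac_to_cart)
  a <- mol$atoms
  a$fx <- frn[, 1]; a$fy <- frn[, 2]; a$fz <- frn[, 3]
  a$cx <- cart[, 1]; a$cy <- cart[, 2]; a$cz <- cart[, 3]
  list(atoms = a, bonds = mol$bonds, centroid = colMeans(cart),
       id = c(asym = unname(mol$id["asym"]), op = op_idx,
              t1 = tvec[1], t2 = tvec[2], t3 = tvec[3]))
}

#' Expand a cluster of whole molecules around a central molecule
#'
#' Returns every whole symmetry/lattice image whose centroid lies within
#' `radius` of the centroid of the chosen central (asymmetric-unit)
#' molecule. Membership is centroid-based: a molecule is in or out as a
#' whole. Ordering is deterministic: by centroid distance, then operator
#' index, then lattice translation.
#'
#' @param st a `crystal_structure` after [perceive_molecules()]
#' @param radius cluster radius in Angstrom (> 0)
#' @param central index of the central asymmetric-unit molecule (1..Z')
#' @return list of molecules (the central one excluded)
#' @export
expand_cluster <- function(st, radius, central = 1L) {
  if (is.null(st$molecules)) stop("run perceive_molecules() first")
  stopifnot(radius > 0, central >= 1, central <= st$zprime)
  cmol <- st$molecules[[central]]
  c0 <- cmol$centroid
  # molecular extent: max centroid-to-atom distance over the asymmetric unit
  rmol <- max(vapply(st$molecules, function(m) {
    cc <- cbind(m$atoms$cx, m$atoms$cy, m$atoms$cz)
    sqrt(max(rowSums(sweep(cc, 2, m$centroid)^2)))
  }, numeric(1)))
  reach <- radius + 2 * rmol + 1
  Gs <- st$cell$reciprocal_metric
  nmax <- ceiling(reach * sqrt(diag(Gs)))     # axial plane spacings d_i = 1/|a_i*|
  grid <- as.matrix(expand.grid(-nmax[1]:nmax[1],
                                -nmax[2]:nmax[2],
                                -nmax[3]:nmax[3]))
  out <- list()
  dist <- numeric(0)
  okey <- numeric(0)
  M <- st$cell$frac_to_cart
  for (oi in seq_along(st$ops)) {
    for (mi in seq_along(st$molecules)) {
      mol <- st$molecules[[mi]]
      fr <- as.matrix(mol$atoms[, c("fx", "fy", "fz")])
      base_f <- colMeans(apply_symop(st$ops[[oi]], fr))
      cen <- sweep(grid, 2, base_f, "+") %*% t(M)
      dd <- sqrt(rowSums(sweep(cen, 2, c0)^2))
      keep <- which(dd > 1e-6 & dd <= radius)
      for (k in keep) {
        out[[length(out) + 1L]] <- .molecule_image(st, mol, oi, grid[k, ])
        dist <- c(dist, dd[k])
        okey <- c(okey, oi * 1e9 + mi * 1e6 +
                    (grid[k, 1] + 500) * 1e3 + (grid[k, 2] + 500) +
                    (grid[k, 3] + 500) * 1e-3)
      }
    }
  }
  out[order(dist, okey)]
}

#' Add a missing hydroxyl hydrogen
#'
#' Explicit utility for structures whose donor hydrogen is absent from the
#' deposited data: places an H at `bond_length` from the named oxygen along
#' a caller-chosen Cartesian direction. The placement is reported via a
#' message, never silent.
#'
#' @param st a `crystal_structure`
#' @param oxygen_label site label of the hydroxyl oxygen
#' @param direction length-3 Cartesian direction for the O-H vector
#' @param bond_length O-H distance in Angstrom (default 0.97)
#' @param label label for the new hydrogen site
#' @return the structure with the added atom (molecules re-perceived if they
#'   had been perceived before)
#' @export
add_hydroxyl_hydrogen <- function(st, oxygen_label, direction,
                                  bond_length = 0.97,
                                  label = paste0("H", oxygen_label)) {
  i <- match(oxygen_label, st$atoms$label)
  if (is.na(i)) stop("no atom with label ", oxygen_label)
  u <- direction / sqrt(sum(direction^2))
  o_cart <- frac_to_cart(st$cell, as.numeric(st$atoms[i, c("fx", "fy", "fz")]))
  h_frac <- cart_to_frac(st$cell, o_cart + bond_length * u)
  newrow <- st$atoms[i, ]
  newrow$label <- label
  newrow$element <- "H"
  newrow$fx <- h_frac[1]; newrow$fy <- h_frac[2]; newrow$fz <- h_frac[3]
  newrow$charge <- NA_real_
  had_mols <- !is.null(st$molecules)
  st$atoms <- rbind(st$atoms, newrow)
  message("added hydroxyl hydrogen '", label, "' at ", bond_length,
          " A from ", oxygen_label)
  st$molecules <- NULL; st$zprime <- NA_integer_
  if (had_mols) st <- perceive_molecules(st)
  st
}
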