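# Lattice-energy summation and synthon analysis. All downstream stages
# (convergence profile, synthon ranking, fragment partition, H-bond
# inventory, slice/attachment partition) consume the same pair environment
# so no quantity is computed twice.

#' Pair environment of the central molecule(s)
#'
#' Enumerates every whole molecule whose centroid lies within `radius` of
#' each central (asymmetric-unit) molecule and evaluates the component-wise
#' pair interaction energies. This is the single source for the lattice
#' energy, the convergence profile, synthon identification, fragment
#' partitioning and the slice/attachment partition.
#'
#' @param st a `crystal_structure` with molecules perceived and charges
#'   assigned
#' @param params an [energy_params()]
#' @param radius summation radius in Angstrom
#' @return object of class `pair_environment`: a data frame `pairs` with one
#'   row per central/neighbour pair (identifiers, centroid separation vector
#'   and distance, energy components) plus per-pair detail (atom-pair energy
#'   matrices, hydrogen-bond triplets)
#' @export
pair_environment <- function(st, params = energy_params(), radius = 15) {
  if (is.null(st$molecules)) stop("run perceive_molecules() first")
  if (anyNA(st$atoms$charge)) stop("assign charges before lattice sums")
  rows <- list(); detail <- list()
  for (ci in seq_len(st$zprime)) {
    cmol <- st$molecules[[ci]]
    nbs <- expand_cluster(st, radius, central = ci)
    for (nb in nbs) {
      e <- pair_interaction(cmol, nb, params, detail = TRUE)
      sep <- nb$centroid - cmol$centroid
      rows[[length(rows) + 1L]] <- data.frame(
        central = ci, asym = unname(nb$id["asym"]), op = unname(nb$id["op"]),
        t1 = unname(nb$id["t1"]), t2 = unname(nb$id["t2"]),
        t3 = unname(nb$id["t3"]),
        dx = sep[1], dy = sep[2], dz = sep[3],
        dist = sqrt(sum(sep^2)),
        e_vdw = e$vdw, e_hbond = e$hbond, e_coulomb = e$coulomb,
        e_total = e$total)
      detail[[length(detail) + 1L]] <- list(
        atom_pair = attr(e, "atom_pair"), hbonds = attr(e, "hbonds"),
        central_atoms = cmol$atoms, neighbour_atoms = nb$atoms)
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) {
    pairs <- data.frame(central = integer(0), asym = integer(0),
                        op = integer(0), t1 = integer(0), t2 = integer(0),
                        t3 = integer(0), dx = numeric(0), dy = numeric(0),
                        dz = numeric(0), dist = numeric(0),
                        e_vdw = numeric(0), e_hbond = numeric(0),
                        e_coulomb = numeric(0), e_total = numeric(0))
  }
  structure(list(structure = st, params = params, radius = radius,
                 pairs = pairs, detail = detail),
            class = "pair_environment")
}

#' Crystal lattice energy
#'
#' E_cr = 1/2 sum of all pair interactions between a central molecule and
#' the whole molecules within the summation radius (handshake convention,
#' energy per molecule); for Z' > 1 the arithmetic mean over the central
#' molecules is reported and per-central values retained.
#'
#' @param st a `crystal_structure` (charges assigned), or a precomputed
#'   [pair_environment()]
#' @param params an [energy_params()] (ignored when `st` is an environment)
#' @param radius summation radius in Angstrom (>= 5; ignored likewise)
#' @param conv_tol warn if |E(r) - E(r-2)| exceeds this fraction of |E(r)|
#' @return object of class `lattice_energy`: `e_cr` (kcal/mol), `breakdown`
#'   ([energy_breakdown()]), `radius`, `per_central`, `environment`
#' @export
lattice_energy <- function(st, params = energy_params(), radius = 15,
                           conv_tol = 0.01) {
  env <- if (inherits(st, "pair_environment")) st
         else pair_environment(st, params, radius)
  if (!inherits(st, "pair_environment") && radius < 5) {
    stop("summation radius below 5 A")
  }
  p <- env$pairs
  if (nrow(p) == 0) stop("no molecules within the summation radius")
  centrals <- sort(unique(p$central))
  per_central <- vapply(centrals,
                        function(ci) sum(p$e_total[p$central == ci]) / 2,
                        numeric(1))
  comp <- function(col) mean(vapply(centrals,
    function(ci) sum(p[[col]][p$central == ci]) / 2, numeric(1)))
  bd <- energy_breakdown(vdw = comp("e_vdw"), hbond = comp("e_hbond"),
                         coulomb = comp("e_coulomb"))
  # convergence check over the outermost 2 A window
  e_r <- mean(per_central)
  inner <- p[p$dist <= env$radius - 2, ]
  e_inner <- mean(vapply(centrals,
    function(ci) sum(inner$e_total[inner$central == ci]) / 2, numeric(1)))
  if (abs(e_r - e_inner) > conv_tol * abs(e_r)) {
    warning(sprintf(
      "lattice sum not converged at %.1f A: |E(r)-E(r-2)| = %.4f kcal/mol",
      env$radius, abs(e_r - e_inner)))
  }
  structure(list(e_cr = e_r, breakdown = bd, radius = env$radius,
                 per_central = stats::setNames(per_central, centrals),
                 environment = env),
            class = "lattice_energy")
}

#' @export
print.lattice_energy <- function(x, ...) {
  cat(sprintf("lattice energy E_cr = %.4f kcal/mol at %.0f A\n",
              x$e_cr, x$radius))
  print(x$breakdown)
  invisible(x)
}

#' Radial convergence profile of the lattice energy
#'
#' Cumulative lattice energy on a 1 A radius grid, per-shell percentages of
#' the converged value for the given shell bins, molecule counts per shell,
#' and the convergence radius (smallest grid radius whose cumulative energy
#' is within `tol` of the final value).
#'
#' @param st a `crystal_structure` or a [pair_environment()]
#' @param params an [energy_params()]
#' @param radius outer summation radius (default 30 A)
#' @param shell_bins boundaries of the coordination-shell report, Angstrom
#' @param tol relative convergence tolerance (default 1%)
#' @return object of class `convergence_profile`: data frame `profile`
#'   (radius, cumulative energy, molecule count), data frame `shells`
#'   (range, molecule count, % lattice energy), `convergence_radius`, `e_cr`
#' @export
convergence_profile <- function(st, params = energy_params(), radius = 30,
                                shell_bins = c(0, 9, 19, 22), tol = 0.01) {
  env <- if (inherits(st, "pair_environment")) st
         else pair_environment(st, params, radius)
  p <- env$pairs
  centrals <- sort(unique(p$central))
  nz <- length(centrals)
  radii <- seq(1, env$radius)
  cum_e <- vapply(radii, function(r) {
    sum(p$e_total[p$dist <= r]) / 2 / nz
  }, numeric(1))
  n_mol <- vapply(radii, function(r) sum(p$dist <= r) / nz, numeric(1))
  e_final <- cum_e[length(cum_e)]
  conv_r <- radii[abs(cum_e - e_final) <= tol * abs(e_final)]
  conv_r <- if (length(conv_r)) min(conv_r) else NA_real_

  lo <- shell_bins[-length(shell_bins)]
  hi <- shell_bins[-1]
  shells <- data.frame(
    shell = seq_along(lo),
    from = lo, to = hi,
    n_molecules = vapply(seq_along(lo), function(i)
      sum(p$dist > lo[i] & p$dist <= hi[i]) / nz, numeric(1)),
    pct_lattice_energy = vapply(seq_along(lo), function(i)
      100 * (sum(p$e_total[p$dist > lo[i] & p$dist <= hi[i]]) / 2 / nz) /
        e_final, numeric(1)))
  structure(list(profile = data.frame(radius = radii, cum_energy = cum_e,
                                      n_molecules = n_mol),
                 shells = shells, convergence_radius = conv_r,
                 e_cr = e_final, tol = tol),
            class = "convergence_profile")
}

# Symmetry class of a generating operator: pure lattice translation,
# screw (proper rotation + intrinsic translation), or other.
.symop_class <- function(op) {
  R <- op$R
  if (all(abs(R - diag(3)) < 1e-8)) return("translation")
  if (abs(det(R) - 1) < 1e-8 && any(abs(op$t) > 1e-8)) return("screw")
  "other"
}

#' Identify and rank intermolecular synthons
#'
#' Groups the pair interactions of a central molecule into symmetry-unique
#' synthons (equal |E_total| within `e_tol` and centroid distance within
#' `d_tol`), labels them A, B, ... by descending interaction strength,
#' reports multiplicities, component breakdowns and generating symmetry
#' class, and tags each synthon H-Bond or vdW. Because Z' = 1 structures
#' have one pair list per molecule, the multiplicity-weighted total equals
#' twice the lattice energy.
#'
#' Two percentage normalisations are reported: `pct_half` =
#' multiplicity x E / (2 |E_cr|) (consistent with the handshake total) and
#' `pct_full` = multiplicity x E / |E_cr|.
#'
#' @param st a `crystal_structure` or [pair_environment()]
#' @param params an [energy_params()]
#' @param radius summation radius in Angstrom
#' @param central which central molecule to analyse (1..Z')
#' @param e_tol,d_tol grouping tolerances (kcal/mol, Angstrom)
#' @return data frame of class `synthon_table`, one row per synthon, with
#'   `attr(,"members")` mapping pair rows to labels and `attr(,"e_cr")`
#' @export
identify_synthons <- function(st, params = energy_params(), radius = 15,
                              central = 1L, e_tol = 0.01, d_tol = 0.01) {
  env <- if (inherits(st, "pair_environment")) st
         else pair_environment(st, params, radius)
  p <- env$pairs
  sel <- which(p$central == central)
  p <- p[sel, , drop = FALSE]
  e_c <- sum(p$e_total) / 2
  ord <- order(-abs(p$e_total), p$dist, p$op, p$t1, p$t2, p$t3)
  group <- integer(nrow(p))
  ge <- numeric(0); gd <- numeric(0)
  for (i in ord) {
    hit <- which(abs(abs(p$e_total[i]) - ge) < e_tol & abs(p$dist[i] - gd) < d_tol)
    if (length(hit)) group[i] <- hit[1]
    else {
      ge <- c(ge, abs(p$e_total[i])); gd <- c(gd, p$dist[i])
      group[i] <- length(ge)
    }
  }
  ng <- length(ge)
  rows <- lapply(seq_len(ng), function(g) {
    m <- p[group == g, , drop = FALSE]
    cls <- vapply(env$structure$ops[m$op], .symop_class, character(1))
    data.frame(
      multiplicity = nrow(m),
      e_vdw = mean(m$e_vdw), e_hbond = mean(m$e_hbond),
      e_coulomb = mean(m$e_coulomb), e_total = mean(m$e_total),
      dist = mean(m$dist),
      symmetry = if (length(unique(cls)) == 1) cls[1] else "mixed",
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord2 <- order(-abs(tab$e_total), tab$dist)
  tab <- tab[ord2, , drop = FALSE]
  relabel <- match(group, ord2)
  n_lab <- nrow(tab)
  labels <- if (n_lab <= 26) LETTERS[seq_len(n_lab)]
            else paste0("S", seq_len(n_lab))
  tab <- cbind(label = labels, tab)
  tab$type <- ifelse(abs(tab$e_hbond) > env$params$hb_tag_threshold,
                     "H-Bond", "vdW")
  tab$pct_half <- 100 * tab$multiplicity * tab$e_total / (2 * e_c)
  tab$pct_full <- 100 * tab$multiplicity * tab$e_total / e_c
  rownames(tab) <- NULL
  members <- data.frame(pair_row = sel, label = labels[relabel],
                        stringsAsFactors = FALSE)
  structure(tab, members = members, e_cr = e_c,
            class = c("synthon_table", "data.frame"))
}

#' Partition the lattice energy onto molecular fragments
#'
#' Every atom-atom pair energy is split half to the fragment of each
#' partner atom, so the fragment totals conserve the lattice energy
#' exactly. Fragment tags must be assigned ([assign_fragments()]) to every
#' atom.
#'
#' @param st a `crystal_structure` with fragments assigned, or a
#'   [pair_environment()] built from one
#' @param params an [energy_params()]
#' @param radius summation radius in Angstrom
#' @return data frame: fragment, energy (kcal/mol), pct (of E_cr), with
#'   `attr(,"e_cr")`
#' @export
fragment_partition <- function(st, params = energy_params(), radius = 15) {
  env <- if (inherits(st, "pair_environment")) st
         else pair_environment(st, params, radius)
  frag_all <- env$structure$atoms$fragment
  if (anyNA(frag_all)) {
    stop("unmapped atom(s): ",
         paste(env$structure$atoms$label[is.na(frag_all)], collapse = ", "))
  }
  frags <- sort(unique(frag_all))
  acc <- stats::setNames(numeric(length(frags)), frags)
  nz <- length(unique(env$pairs$central))
  for (k in seq_along(env$detail)) {
    d <- env$detail[[k]]
    fa <- d$central_atoms$fragment
    fb <- d$neighbour_atoms$fragment
    rowsum_a <- rowSums(d$atom_pair)
    colsum_b <- colSums(d$atom_pair)
    for (f in frags) {
      acc[f] <- acc[f] + (sum(rowsum_a[fa == f]) + sum(colsum_b[fb == f])) / 2
    }
  }
  # handshake halving and Z' averaging
  acc <- acc / 2 / nz
  e_cr <- sum(acc)
  out <- data.frame(fragment = frags, energy = as.numeric(acc),
                    pct = 100 * as.numeric(acc) / e_cr,
                    stringsAsFactors = FALSE)
  attr(out, "e_cr") <- e_cr
  out
}

#' Inventory of symmetry-unique hydrogen bonds
#'
#' Collects all D-H...A triplets detected in the pair environment of the
#' central molecule(s), with geometry (r(H...A), r(D...A), theta(D-H...A)),
#' donor/acceptor partial charges and their difference
#' q_diff = q_D - q_A (donor hydrogens carry positive, acceptors negative
#' charge, so the reported difference is positive for ordinary hydrogen
#' bonds). Triplets identical in donor, acceptor and geometry are merged;
#' the multiplicity counts both the donated and the accepted image of each
#' bond as seen from the central molecule.
#'
#' @param st a `crystal_structure` or [pair_environment()]
#' @param params an [energy_params()]
#' @param radius summation radius in Angstrom
#' @return data frame: donor, h, acceptor, multiplicity, q_d, q_a, q_diff,
#'   r_ha, r_da, theta, energy
#' @export
hbond_inventory <- function(st, params = energy_params(), radius = 15) {
  env <- if (inherits(st, "pair_environment")) st
         else pair_environment(st, params, radius)
  hb <- do.call(rbind, lapply(env$detail, function(d) d$hbonds))
  if (is.null(hb) || nrow(hb) == 0) {
    return(data.frame(donor = character(0), h = character(0),
                      acceptor = character(0), multiplicity = integer(0),
                      q_d = numeric(0), q_a = numeric(0), q_diff = numeric(0),
                      r_ha = numeric(0), r_da = numeric(0),
                      theta = numeric(0), energy = numeric(0)))
  }
  nz <- length(unique(env$pairs$central))
  key <- paste(hb$donor, hb$h, hb$acceptor,
               round(hb$r_ha, 3), round(hb$r_da, 3), round(hb$theta, 2))
  qs <- stats::setNames(env$structure$atoms$charge, env$structure$atoms$label)
  out <- do.call(rbind, lapply(split(hb, key), function(g) {
    data.frame(donor = g$donor[1], h = g$h[1], acceptor = g$acceptor[1],
               multiplicity = nrow(g) / nz,
               q_d = unname(qs[g$h[1]]), q_a = unname(qs[g$acceptor[1]]),
               q_diff = unname(qs[g$h[1]] - qs[g$acceptor[1]]),
               r_ha = g$r_ha[1], r_da = g$r_da[1], theta = g$theta[1],
               energy = g$energy[1], stringsAsFactors = FALSE)
  }))
  out <- out[order(-abs(out$energy), out$r_ha), , drop = FALSE]
  rownames(out) <- NULL
  out
}
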