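# Morphology stage: BFDH form ranking with systematic-absence corrections,
# slice/attachment partition of the lattice energy for each (hkl), and the
# Wulff construction giving facet areas and habit shape.

# Which crystal axes carry a 2_1 screw: proper 2-fold rotation about an
# axis with a half-lattice intrinsic translation along that axis.
.screw_axes <- function(ops) {
  screw <- c(FALSE, FALSE, FALSE)
  for (op in ops) {
    R <- op$R
    if (abs(det(R) - 1) > 1e-8) next
    if (abs(sum(diag(R)) + 1) > 1e-8) next      # proper 2-fold has trace -1
    for (i in 1:3) {
      if (abs(R[i, i] - 1) < 1e-8 && abs(op$t[i] %% 1 - 0.5) < 1e-8) {
        screw[i] <- TRUE
      }
    }
  }
  screw
}

# Axial reflections h00/0k0/00l along a 2_1 screw require an even index.
.reflection_allowed <- function(hkl, screw) {
  nz <- which(hkl != 0)
  if (length(nz) == 1 && screw[nz] && hkl[nz] %% 2 != 0) return(FALSE)
  TRUE
}

# Orbit of a reflection under the Laue rotations; indices transform as
# row vectors h' = h R.
.hkl_orbit <- function(hkl, rots) {
  orb <- t(vapply(rots, function(R) drop(hkl %*% R), numeric(3)))
  orb <- round(orb)
  orb[!duplicated(apply(orb, 1, paste, collapse = ",")), , drop = FALSE]
}

.hkl_representative <- function(orbit) {
  ord <- order(-orbit[, 1], -orbit[, 2], -orbit[, 3])
  orbit[ord[1], ]
}

#' BFDH form ranking
#'
#' Enumerates (hkl) up to `max_index`, reduces to symmetry-unique forms
#' with multiplicities from the Laue-group orbit, applies the systematic-
#' absence rule for 2\eqn{_1} screw axes (forbidden axial reflections are
#' replaced by their first allowed multiple, halving the growth-slice
#' thickness), and ranks by corrected interplanar spacing.
#'
#' @param st a `crystal_structure`
#' @param n_forms number of top-ranked forms to return
#' @param max_index index search limit (default 3)
#' @param min_frac forms whose corrected d falls below `min_frac` of the
#'   best d are dropped
#' @return data frame: h, k, l (absence-corrected representative), d_hkl,
#'   multiplicity, rank
#' @export
bfdh_forms <- function(st, n_forms = 4L, max_index = 3L, min_frac = 0.01) {
  rots <- laue_rotations(st$ops)
  screw <- .screw_axes(st$ops)
  idx <- expand.grid(h = -max_index:max_index, k = -max_index:max_index,
                     l = -max_index:max_index)
  idx <- idx[rowSums(idx != 0) > 0, ]
  seen <- character(0)
  rows <- list()
  for (r in seq_len(nrow(idx))) {
    hkl <- as.numeric(idx[r, ])
    # effective (allowed) reflection for the growth slice
    eff <- hkl
    m <- 1
    while (!.reflection_allowed(eff, screw)) {
      m <- m + 1
      eff <- hkl * m
    }
    orb <- .hkl_orbit(eff, rots)
    rep_ <- .hkl_representative(orb)
    key <- paste(rep_, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    # multiplicity counts the faces of the parent form (uncorrected index)
    mult <- nrow(.hkl_orbit(.hkl_representative(.hkl_orbit(hkl, rots)), rots))
    rows[[length(rows) + 1L]] <- data.frame(
      h = rep_[1], k = rep_[2], l = rep_[3],
      d_hkl = d_spacing(st$cell, rep_), multiplicity = mult)
  }
  tab <- do.call(rbind, rows)
  # drop higher-order parallel planes (keep largest d along each normal)
  dirkey <- apply(tab[, c("h", "k", "l")], 1, function(v) {
    g <- Reduce(function(a, b) if (b == 0) a else .gcd(a, abs(b)), v, 0)
    paste(v / max(g, 1), collapse = ",")
  })
  keep <- unlist(lapply(split(seq_len(nrow(tab)), dirkey), function(ii) {
    ii[which.max(tab$d_hkl[ii])]
  }))
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[tab$d_hkl >= min_frac * max(tab$d_hkl), , drop = FALSE]
  ties <- rowSums(abs(tab[, c("h", "k", "l")]))
  tab <- tab[order(-tab$d_hkl, ties, -tab$h, -tab$k, -tab$l), , drop = FALSE]
  tab <- utils::head(tab, n_forms)
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Slice/attachment partition of the lattice energy for a face
#'
#' Pair interactions whose centroid separation projected on the (hkl) plane
#' normal is smaller in magnitude than d_hkl/2 lie within the growth slice
#' (intrinsic synthons, E_sl); the remainder are extrinsic and sum to the
#' attachment energy E_att. The identity E_cr = E_sl + E_att holds by
#' construction for every face.
#'
#' @param st a `crystal_structure` or [pair_environment()]
#' @param hkl face index (length-3)
#' @param params an [energy_params()]
#' @param radius summation radius in Angstrom
#' @param d_hkl growth-slice thickness; defaults to the interplanar spacing
#'   of `hkl` (pass the absence-corrected value when relevant)
#' @param synthons optional [identify_synthons()] table; when given, the
#'   extrinsic multiplicity per synthon label is tallied
#' @return object of class `habit_face`: `hkl`, `d_hkl`, `e_sl`, `e_att`
#'   ([energy_breakdown()]s), `e_cr`, `xi` (anisotropy factor, %),
#'   `extrinsic_counts`
#' @export
slice_partition <- function(st, hkl, params = energy_params(), radius = 15,
                            d_hkl = NULL, synthons = NULL) {
  env <- if (inherits(st, "pair_environment")) st
         else pair_environment(st, params, radius)
  if (is.null(d_hkl)) d_hkl <- d_spacing(env$structure$cell, hkl)
  nrm <- plane_normal(env$structure$cell, hkl)
  p <- env$pairs
  proj <- abs(p$dx * nrm[1] + p$dy * nrm[2] + p$dz * nrm[3])
  intr <- proj < d_hkl / 2
  nz <- length(unique(p$central))
  half <- function(sel, col) sum(p[[col]][sel]) / 2 / nz
  e_sl <- energy_breakdown(vdw = half(intr, "e_vdw"),
                           hbond = half(intr, "e_hbond"),
                           coulomb = half(intr, "e_coulomb"))
  e_att <- energy_breakdown(vdw = half(!intr, "e_vdw"),
                            hbond = half(!intr, "e_hbond"),
                            coulomb = half(!intr, "e_coulomb"))
  e_cr <- e_sl$total + e_att$total
  counts <- NULL
  if (!is.null(synthons)) {
    mem <- attr(synthons, "members")
    ext_rows <- mem$pair_row %in% which(!intr)
    counts <- table(factor(mem$label[ext_rows], levels = synthons$label))
  }
  structure(list(hkl = as.numeric(hkl), d_hkl = d_hkl,
                 e_sl = e_sl, e_att = e_att, e_cr = e_cr,
                 xi = 100 * e_sl$total / e_cr,
                 extrinsic_counts = counts),
            class = "habit_face")
}

#' @export
print.habit_face <- function(x, ...) {
  cat(sprintf("face {%d %d %d}: d = %.3f A, E_sl = %.4f, E_att = %.4f, xi = %.2f%%\n",
              x$hkl[1], x$hkl[2], x$hkl[3], x$d_hkl,
              x$e_sl$total, x$e_att$total, x$xi))
  invisible(x)
}

#' Wulff construction
#'
#' Builds the convex growth form as the intersection of half-spaces at
#' centre-to-plane distances proportional to |E_att| for every Laue-orbit
#' equivalent of each form (Friedel pairs carry the same distance). Facet
#' areas are accumulated per form into fractional surface areas.
#'
#' @param cell a [unit_cell()]
#' @param ops symmetry operators of the structure (for the face orbit)
#' @param faces data frame with columns `h`, `k`, `l` and `growth` (a
#'   positive relative growth rate, typically |E_att|)
#' @return object of class `wulff_polyhedron`: `vertices` (n x 3 matrix),
#'   `facets` (list of vertex index rings), `facet_form` (form index per
#'   facet), `areas` (per form, absolute), `sa_frac` (per form, sums to 1),
#'   `total_area`, `aspect_ratio` (longest/shortest caliper), `faces`
#' @export
wulff_construction <- function(cell, ops, faces) {
  stopifnot(all(c("h", "k", "l", "growth") %in% names(faces)))
  if (any(faces$growth <= 0)) stop("all growth rates must be > 0")
  rots <- laue_rotations(ops)
  normals <- NULL; offsets <- numeric(0); form_of <- integer(0)
  for (f in seq_len(nrow(faces))) {
    orb <- .hkl_orbit(as.numeric(faces[f, c("h", "k", "l")]), rots)
    for (r in seq_len(nrow(orb))) {
      n <- plane_normal(cell, orb[r, ])
      # skip duplicate normals across forms (keep the closer plane)
      if (!is.null(normals)) {
        dup <- which(colSums((t(normals) - n)^2) < 1e-16)
        if (length(dup)) {
          if (faces$growth[f] < offsets[dup[1]]) {
            offsets[dup[1]] <- faces$growth[f]; form_of[dup[1]] <- f
          }
          next
        }
      }
      normals <- rbind(normals, n)
      offsets <- c(offsets, faces$growth[f])
      form_of <- c(form_of, f)
    }
  }
  np <- nrow(normals)
  scale <- stats::median(offsets)
  tol <- 1e-9 * scale

  # unbounded direction check: extreme rays of the recession cone
  cand <- rbind(normals, -normals, diag(3), -diag(3))
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    cr <- c(normals[i, 2] * normals[j, 3] - normals[i, 3] * normals[j, 2],
            normals[i, 3] * normals[j, 1] - normals[i, 1] * normals[j, 3],
            normals[i, 1] * normals[j, 2] - normals[i, 2] * normals[j, 1])
    if (sum(cr^2) > 1e-12) cand <- rbind(cand, cr, -cr)
  }
  feas <- normals %*% t(cand)
  open_dir <- which(apply(feas <= 1e-9, 2, all))
  if (length(open_dir)) {
    d <- cand[open_dir[1], ]
    stop(sprintf("unbounded Wulff form: no capping plane along (%.3f %.3f %.3f)",
                 d[1], d[2], d[3]))
  }
  if (np < 4) stop("need at least 4 half-spaces for a bounded form")

  verts <- NULL
  combs <- utils::combn(np, 3)
  for (k in seq_len(ncol(combs))) {
    ii <- combs[, k]
    A <- normals[ii, , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    v <- solve(A, offsets[ii])
    if (all(normals %*% v <= offsets + tol)) verts <- rbind(verts, v)
  }
  if (is.null(verts) || nrow(verts) < 4) stop("degenerate Wulff form")
  # dedupe vertices
  keys <- apply(round(verts / scale, 7), 1, paste, collapse = ",")
  verts <- verts[!duplicated(keys), , drop = FALSE]

  facets <- list(); facet_form <- integer(0)
  areas <- numeric(nrow(faces))
  for (i in seq_len(np)) {
    on <- which(abs(verts %*% normals[i, ] - offsets[i]) < 1e-7 * scale)
    if (length(on) < 3) next
    pts <- verts[on, , drop = FALSE]
    ctr <- colMeans(pts)
    u <- pts[1, ] - ctr; u <- u / sqrt(sum(u^2))
    w <- c(normals[i, 2] * u[3] - normals[i, 3] * u[2],
           normals[i, 3] * u[1] - normals[i, 1] * u[3],
           normals[i, 1] * u[2] - normals[i, 2] * u[1])
    ang <- atan2((pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)) %*% w,
                 (pts - matrix(ctr, nrow(pts), 3, byrow = TRUE)) %*% u)
    ringo <- on[order(ang)]
    pts <- verts[ringo, , drop = FALSE]
    n2 <- nrow(pts)
    ar <- 0
    for (q in seq_len(n2)) {
      p1 <- pts[q, ] - ctr
      p2 <- pts[if (q == n2) 1 else q + 1, ] - ctr
      cr <- c(p1[2] * p2[3] - p1[3] * p2[2],
              p1[3] * p2[1] - p1[1] * p2[3],
              p1[1] * p2[2] - p1[2] * p2[1])
      ar <- ar + 0.5 * sqrt(sum(cr^2))
    }
    facets[[length(facets) + 1L]] <- ringo
    facet_form <- c(facet_form, form_of[i])
    areas[form_of[i]] <- areas[form_of[i]] + ar
  }
  total <- sum(areas)
  # caliper extents: longest vertex-vertex distance over shortest facet-
  # normal width
  dmax <- 0
  nv <- nrow(verts)
  for (i in seq_len(nv - 1)) {
    dd <- sqrt(rowSums((verts[(i + 1):nv, , drop = FALSE] -
                          matrix(verts[i, ], nv - i, 3, byrow = TRUE))^2))
    dmax <- max(dmax, dd)
  }
  widths <- apply(normals, 1, function(n) {
    pr <- verts %*% n; max(pr) - min(pr)
  })
  structure(list(vertices = verts, facets = facets, facet_form = facet_form,
                 areas = areas, sa_frac = areas / total, total_area = total,
                 aspect_ratio = dmax / min(widths),
                 faces = faces),
            class = "wulff_polyhedron")
}

#' @export
print.wulff_polyhedron <- function(x, ...) {
  cat("Wulff polyhedron:", nrow(x$vertices), "vertices,",
      length(x$facets), "facets\n")
  for (f in seq_len(nrow(x$faces))) {
    cat(sprintf("  {%d %d %d}: SA = %.4f\n",
                x$faces$h[f], x$faces$k[f], x$faces$l[f], x$sa_frac[f]))
  }
  invisible(x)
}

#' Caliper extent of a Wulff polyhedron along a direction
#' @param poly a `wulff_polyhedron`
#' @param dir length-3 Cartesian direction
#' @return extent (max minus min projection of the vertices)
#' @export
wulff_extent <- function(poly, dir) {
  u <- dir / sqrt(sum(dir^2))
  pr <- poly$vertices %*% u
  max(pr) - min(pr)
}

#' Export a polyhedron as OFF
#' @param poly a `wulff_polyhedron`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_off <- function(poly, path) {
  v <- poly$vertices
  lines <- c("OFF",
             sprintf("%d %d 0", nrow(v), length(poly$facets)),
             sprintf("%.8f %.8f %.8f", v[, 1], v[, 2], v[, 3]),
             vapply(poly$facets, function(f)
               paste(c(length(f), f - 1L), collapse = " "), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Export a polyhedron as ASCII PLY
#' @inheritParams write_off
#' @export
write_ply <- function(poly, path) {
  v <- poly$vertices
  lines <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", length(poly$facets)),
             "property list uchar int vertex_indices", "end_header",
             sprintf("%.8f %.8f %.8f", v[, 1], v[, 2], v[, 3]),
             vapply(poly$facets, function(f)
               paste(c(length(f), f - 1L), collapse = " "), character(1)))
  writeLines(lines, path)
  invisible(path)
}
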