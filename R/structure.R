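#' Crystal structure container
#'
#' Holds the unit cell, the symmetry operator set, the asymmetric-unit atoms
#' (fractional coordinates) and, after [perceive_molecules()], the whole
#' molecules of the asymmetric unit. Z is the number of molecules per cell,
#' Z' the number per asymmetric unit.
#'
#' @param cell a [unit_cell()]
#' @param ops list of [symop()]
#' @param atoms data frame with columns `label`, `element`, `fx`, `fy`, `fz`
#'   and optionally `charge` and `fragment`
#' @param spacegroup space-group label (informational)
#' @return object of class `crystal_structure`
#' @export
crystal_structure <- function(cell, ops, atoms, spacegroup = "P1") {
  stopifnot(inherits(cell, "unit_cell"), length(ops) >= 1)
  need <- c("label", "element", "fx", "fy", "fz")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$fragment)) atoms$fragment <- NA_character_
  if (!all(is.finite(as.matrix(atoms[, c("fx", "fy", "fz")])))) {
    stop("non-finite fractional coordinates")
  }
  vdw_radius(atoms$element)  # validates the element symbols
  st <- structure(list(cell = cell, ops = ops, atoms = atoms,
                       spacegroup = spacegroup,
                       molecules = NULL, zprime = NA_integer_),
                  class = "crystal_structure")
  .check_duplicate_sites(st)
  st
}

# Duplicate-site guard: no two symmetry-generated atoms closer than `tol` A.
.check_duplicate_sites <- function(st, tol = 0.3) {
  fr <- as.matrix(st$atoms[, c("fx", "fy", "fz")])
  allf <- do.call(rbind, lapply(st$ops, apply_symop, x = fr))
  n <- nrow(allf)
  if (n < 2) return(invisible(TRUE))
  d <- allf[rep(seq_len(n), each = n), ] - allf[rep(seq_len(n), n), ]
  d <- d - round(d)                        # minimum image in fractional space
  cart <- d %*% t(st$cell$frac_to_cart)
  dist2 <- rowSums(cart^2)
  same <- rep(seq_len(n), each = n) == rep(seq_len(n), n)
  if (any(dist2[!same] < tol^2)) {
    stop("duplicate-site guard: symmetry-generated atoms closer than ",
         tol, " A (over-generated symmetry or bad coordinates)")
  }
  invisible(TRUE)
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat("crystal structure [", x$spacegroup, "], ",
      length(x$ops), " symmetry ops, ",
      nrow(x$atoms), " asymmetric-unit atoms", sep = "")
  if (!is.null(x$molecules)) {
    cat(", Z' = ", x$zprime, ", Z = ", structure_Z(x), sep = "")
  }
  cat("\n")
  print(x$cell)
  invisible(x)
}

#' Number of molecules per unit cell (Z)
#' @param st a `crystal_structure` after molecule perception
#' @return integer Z = Z' x |ops|
#' @export
structure_Z <- function(st) {
  if (is.na(st$zprime)) stop("run perceive_molecules() first")
  st$zprime * length(st$ops)
}

#' Assign partial charges to the asymmetric-unit atoms
#'
#' Charges given per site label, e.g. read from a two-column charge file
#' ([read_charges()]) or computed by [gasteiger_charges()]. Molecule copies
#' generated by symmetry inherit the charge of their parent site.
#'
#' @param st a `crystal_structure`
#' @param charges named numeric vector (names = site labels) or a numeric
#'   vector in atom order
#' @return the structure with charges set (atoms and molecules)
#' @export
assign_charges <- function(st, charges) {
  if (!is.null(names(charges)) && any(nzchar(names(charges)))) {
    idx <- match(st$atoms$label, names(charges))
    if (anyNA(idx)) {
      stop("no charge given for site(s): ",
           paste(st$atoms$label[is.na(idx)], collapse = ", "))
    }
    st$atoms$charge <- as.numeric(charges[idx])
  } else {
    if (length(charges) != nrow(st$atoms)) {
      stop("charge vector length does not match atom count")
    }
    st$atoms$charge <- as.numeric(charges)
  }
  if (!is.null(st$molecules)) {
    st$molecules <- lapply(st$molecules, function(m) {
      m$atoms$charge <- st$atoms$charge[m$atoms$asym_index]
      m
    })
  }
  st
}

#' Tag atoms with fragment labels
#'
#' @param st a `crystal_structure`
#' @param fragments named character vector (names = site labels) or a
#'   character vector in atom order
#' @return the structure with fragment tags set
#' @export
assign_fragments <- function(st, fragments) {
  if (!is.null(names(fragments)) && any(nzchar(names(fragments)))) {
    idx <- match(st$atoms$label, names(fragments))
    if (anyNA(idx)) {
      stop("no fragment tag for site(s): ",
           paste(st$atoms$label[is.na(idx)], collapse = ", "))
    }
    st$atoms$fragment <- as.character(fragments[idx])
  } else {
    if (length(fragments) != nrow(st$atoms)) {
      stop("fragment vector length does not match atom count")
    }
    st$atoms$fragment <- as.character(fragments)
  }
  if (!is.null(st$molecules)) {
    st$molecules <- lapply(st$molecules, function(m) {
      m$atoms$fragment <- st$atoms$fragment[m$atoms$asym_index]
      m
    })
  }
  st
}
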