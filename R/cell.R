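#' Construct a crystallographic unit cell
#'
#' Builds a unit cell object carrying the direct and reciprocal metric
#' tensors, the cell volume and the fractional/Cartesian conversion matrices.
#' The Cartesian frame follows the standard crystallographic convention:
#' x along a, y in the a-b plane, z completing a right-handed set.
#'
#' @param a,b,c cell lengths in Angstrom
#' @param alpha,beta,gamma cell angles in degrees
#' @return an object of class `unit_cell` with fields `a,b,c,alpha,beta,gamma`,
#'   `metric` (3x3 direct metric tensor, A^2), `reciprocal_metric`, `volume`
#'   (A^3), `frac_to_cart` and `cart_to_frac` (3x3 matrices).
#' @examples
#' cl <- unit_cell(10, 10, 10)
#' cl$volume   # 1000
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  G <- matrix(c(a * a,      a * b * cg, a * c * cb,
                a * b * cg, b * b,      b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  vol <- sqrt(det(G))
  if (!is.finite(vol) || vol <= 0) stop("degenerate unit cell")
  cz <- vol / (a * b * sg)
  M <- matrix(c(a, b * cg, c * cb,
                0, b * sg, c * (ca - cb * cg) / sg,
                0, 0,      cz), 3, 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 metric = G, reciprocal_metric = solve(G),
                 volume = vol,
                 frac_to_cart = M, cart_to_frac = solve(M)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

.coord_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' Convert fractional to Cartesian coordinates
#' @param cell a `unit_cell`
#' @param x numeric vector of length 3 or an n x 3 matrix of fractional coords
#' @return coordinates in Angstrom, same shape as input
#' @export
frac_to_cart <- function(cell, x) {
  xm <- .coord_matrix(x)
  out <- xm %*% t(cell$frac_to_cart)
  if (is.null(dim(x))) drop(out) else out
}

#' Convert Cartesian to fractional coordinates
#' @inheritParams frac_to_cart
#' @param x numeric vector of length 3 or an n x 3 matrix of Cartesian coords
#' @export
cart_to_frac <- function(cell, x) {
  xm <- .coord_matrix(x)
  out <- xm %*% t(cell$cart_to_frac)
  if (is.null(dim(x))) drop(out) else out
}

#' Interplanar spacing d(hkl)
#'
#' d = 1 / sqrt(h' G* h) with G* the reciprocal metric tensor.
#'
#' @param cell a `unit_cell`
#' @param hkl integer vector of length 3, not all zero
#' @return spacing in Angstrom
#' @examples
#' d_spacing(unit_cell(10, 10, 10), c(1, 0, 0))  # 10
#' @export
d_spacing <- function(cell, hkl) {
  hkl <- as.numeric(hkl)
  if (length(hkl) != 3 || all(hkl == 0)) {
    stop("hkl must be a length-3 index distinct from (0 0 0)")
  }
  1 / sqrt(drop(t(hkl) %*% cell$reciprocal_metric %*% hkl))
}

#' Unit normal of the (hkl) plane family in the Cartesian frame
#'
#' The plane normal is the reciprocal-lattice vector h a* + k b* + l c*.
#' @inheritParams d_spacing
#' @return unit vector, length 3
#' @export
plane_normal <- function(cell, hkl) {
  # reciprocal vectors in cartesian: rows of t(inv(M)) give a*, b*, c*
  n <- drop(t(cell$cart_to_frac) %*% as.numeric(hkl))
  n / sqrt(sum(n^2))
}
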