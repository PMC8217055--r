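#' Symmetry operators in fractional coordinates
#'
#' A symmetry operator is stored as a list with a 3x3 rotation part `R`
#' (integer-valued in fractional coordinates) and a length-3 translation
#' part `t`, so that x' = R x + t.
#'
#' @param R 3x3 matrix
#' @param t length-3 numeric
#' @return an object of class `symop`
#' @export
symop <- function(R, t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  dt <- det(R)
  if (abs(abs(dt) - 1) > 1e-8) stop("rotation part must have determinant +/-1")
  structure(list(R = R, t = as.numeric(t)), class = "symop")
}

#' @export
print.symop <- function(x, ...) {
  cat("symop:", symop_to_xyz(x), "\n")
  invisible(x)
}

#' Parse a `_symmetry_equiv_pos_as_xyz` string
#'
#' Accepts strings such as `"x, y, z"`, `"-x, y+1/2, -z"` or
#' `"1/2+x, 1/2-y, -z"`. Coefficients are recovered by evaluating each
#' component at the origin and the three unit points, which is exact for
#' the affine expressions the CIF dictionary allows.
#'
#' @param s a single operator string with three comma-separated components
#' @return a `symop`
#' @export
parse_symop <- function(s) {
  parts <- strsplit(s, ",")[[1]]
  if (length(parts) != 3) stop("symmetry operator must have 3 components: ", s)
  ok <- grepl("^[-+0-9xyzXYZ/. ]+$", parts)
  if (!any(nzchar(gsub("[[:space:]]", "", parts))) || !all(ok)) {
    stop("cannot parse symmetry operator: ", s)
  }
  evalxyz <- function(expr, x, y, z) {
    eval(parse(text = tolower(expr)), list(x = x, y = y, z = z))
  }
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    t[i] <- evalxyz(parts[i], 0, 0, 0)
    for (j in 1:3) {
      e <- c(0, 0, 0); e[j] <- 1
      R[i, j] <- evalxyz(parts[i], e[1], e[2], e[3]) - t[i]
    }
  }
  symop(R, t %% 1)
}

#' Render a `symop` back to its x,y,z string form
#' @param op a `symop`
#' @return character scalar
#' @export
symop_to_xyz <- function(op) {
  frac_str <- function(v) {
    # common crystallographic fractions
    for (den in c(1, 2, 3, 4, 6)) {
      num <- v * den
      if (abs(num - round(num)) < 1e-8) {
        num <- round(num)
        if (num == 0) return("")
        if (den == 1) return(sprintf("%+d", num))
        return(sprintf("%+d/%d", num, den))
      }
    }
    sprintf("%+.6f", v)
  }
  vars <- c("x", "y", "z")
  comps <- vapply(1:3, function(i) {
    s <- ""
    for (j in 1:3) {
      co <- op$R[i, j]
      if (abs(co) > 1e-8) {
        sgn <- if (co > 0) "+" else "-"
        mag <- abs(co)
        s <- paste0(s, sgn, if (abs(mag - 1) > 1e-8) paste0(mag, "*") else "",
                    vars[j])
      }
    }
    s <- paste0(s, frac_str(op$t[i]))
    sub("^\\+", "", s)
  }, character(1))
  paste(comps, collapse = ",")
}

#' Apply a symmetry operator to fractional coordinates
#' @param op a `symop`
#' @param x length-3 vector or n x 3 matrix of fractional coordinates
#' @return transformed coordinates, same shape
#' @export
apply_symop <- function(op, x) {
  xm <- .coord_matrix(x)
  out <- xm %*% t(op$R) + matrix(op$t, nrow(xm), 3, byrow = TRUE)
  if (is.null(dim(x))) drop(out) else out
}

# Built-in operator sets for the three supported groups.
.builtin_spacegroups <- function() {
  list(
    "P1" = c("x,y,z"),
    # b-unique monoclinic screw
    "P21" = c("x,y,z", "-x,y+1/2,-z"),
    "P212121" = c("x,y,z",
                  "x+1/2,-y+1/2,-z",
                  "-x,y+1/2,-z+1/2",
                  "-x+1/2,-y,z+1/2")
  )
}

.normalise_sg_symbol <- function(symbol) {
  s <- toupper(gsub("[[:space:]_()]", "", symbol))
  s <- gsub("21", "21", s, fixed = TRUE)
  if (s %in% c("P1")) return("P1")
  if (s %in% c("P21", "P1211", "P21/B:NO")) return("P21")
  if (s %in% c("P212121")) return("P212121")
  NA_character_
}

#' Symmetry operators for a space-group symbol
#'
#' Only P1, P2\eqn{_1} (b-unique) and P2\eqn{_1}2\eqn{_1}2\eqn{_1} carry
#' built-in operator tables; other groups must supply explicit operators
#' in the CIF.
#'
#' @param symbol Hermann-Mauguin symbol, e.g. `"P 21 21 21"`
#' @return list of `symop`
#' @export
spacegroup_ops <- function(symbol) {
  key <- .normalise_sg_symbol(symbol)
  tabs <- .builtin_spacegroups()
  if (is.na(key) || !key %in% names(tabs)) {
    stop("unsupported space-group symbol '", symbol,
         "' and no explicit symmetry operators given")
  }
  lapply(tabs[[key]], parse_symop)
}

#' Point-group (Laue) rotations of an operator set
#'
#' Returns the unique rotation parts of the operators augmented with the
#' inversion (Friedel symmetry), as used for reflection multiplicities and
#' the Wulff face orbit.
#'
#' @param ops list of `symop`
#' @return list of 3x3 matrices
#' @export
laue_rotations <- function(ops) {
  rots <- lapply(ops, function(o) o$R)
  rots <- c(rots, lapply(rots, function(R) -R))
  keys <- vapply(rots, function(R) paste(round(R, 6), collapse = ","),
                 character(1))
  rots[!duplicated(keys)]
}
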