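# Minimal CIF (core dictionary) reader and writer covering the dialect the
# pipeline needs: cell tags, symmetry operator loop or space-group symbol,
# and the atom-site loop. Values with standard uncertainties "1.234(5)" are
# accepted; quoted strings and loop_ blocks are handled; multi-line text
# fields are not part of the dialect.

.cif_tokenize_line <- function(line) {
  line <- sub("^([^#']*?)#.*$", "\\1", line)   # comments outside quotes
  out <- character(0)
  rest <- trimws(line)
  while (nzchar(rest)) {
    if (substr(rest, 1, 1) %in% c("'", '"')) {
      q <- substr(rest, 1, 1)
      end <- regexpr(paste0(q, "([[:space:]]|$)"), substr(rest, 2, nchar(rest)))
      if (end < 0) stop("unterminated quoted string in CIF: ", line)
      out <- c(out, substr(rest, 2, end))
      rest <- trimws(substr(rest, end + 2, nchar(rest)))
    } else {
      sp <- regexpr("[[:space:]]", rest)
      if (sp < 0) { out <- c(out, rest); rest <- "" }
      else {
        out <- c(out, substr(rest, 1, sp - 1))
        rest <- trimws(substr(rest, sp, nchar(rest)))
      }
    }
  }
  out
}

.cif_parse <- function(lines) {
  toks <- unlist(lapply(lines, .cif_tokenize_line), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  items <- list(); loops <- list()
  i <- 1L; n <- length(toks)
  is_tag <- function(t) startsWith(t, "_")
  while (i <= n) {
    t <- toks[i]
    if (grepl("^data_", t, ignore.case = TRUE)) { i <- i + 1L; next }
    if (tolower(t) == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && is_tag(toks[i])) { tags <- c(tags, toks[i]); i <- i + 1L }
      vals <- character(0)
      while (i <= n && !is_tag(toks[i]) &&
             tolower(toks[i]) != "loop_" &&
             !grepl("^data_", toks[i], ignore.case = TRUE)) {
        vals <- c(vals, toks[i]); i <- i + 1L
      }
      if (length(tags) == 0 || length(vals) %% length(tags) != 0) {
        stop("malformed CIF loop (", length(vals), " values for ",
             length(tags), " tags)")
      }
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- tolower(tags)
      loops[[length(loops) + 1L]] <- df
    } else if (is_tag(t)) {
      if (i + 1L > n) stop("CIF tag without value: ", t)
      items[[tolower(t)]] <- toks[i + 1L]
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  list(items = items, loops = loops)
}

.cif_number <- function(x) {
  as.numeric(sub("\\(.*\\)$", "", x))   # strip standard uncertainty
}

.cif_find_loop <- function(loops, tag) {
  for (df in loops) if (tag %in% names(df)) return(df)
  NULL
}

#' Read a crystal structure from a CIF file
#'
#' Parses the cell block, the symmetry operators (from
#' `_symmetry_equiv_pos_as_xyz` / `_space_group_symop_operation_xyz`, or a
#' built-in table for P1, P2\eqn{_1} and P2\eqn{_1}2\eqn{_1}2\eqn{_1} when
#' only a symbol is given) and the atom-site loop. Optional
#' `_atom_site_charge` and `_atom_site_fragment` columns are honoured.
#'
#' @param path CIF file path
#' @return a [crystal_structure()] (molecules not yet perceived)
#' @seealso [perceive_molecules()], [write_cif()]
#' @export
read_cif <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  parsed <- .cif_parse(readLines(path, warn = FALSE))
  it <- parsed$items
  cell_tags <- paste0("_cell_length_", c("a", "b", "c"))
  ang_tags <- paste0("_cell_angle_", c("alpha", "beta", "gamma"))
  if (!all(c(cell_tags, ang_tags) %in% names(it))) {
    stop("CIF parse error: missing _cell block (need ",
         paste(c(cell_tags, ang_tags), collapse = ", "), ")")
  }
  cell <- unit_cell(.cif_number(it[["_cell_length_a"]]),
                    .cif_number(it[["_cell_length_b"]]),
                    .cif_number(it[["_cell_length_c"]]),
                    .cif_number(it[["_cell_angle_alpha"]]),
                    .cif_number(it[["_cell_angle_beta"]]),
                    .cif_number(it[["_cell_angle_gamma"]]))

  symloop <- .cif_find_loop(parsed$loops, "_symmetry_equiv_pos_as_xyz")
  symtag <- "_symmetry_equiv_pos_as_xyz"
  if (is.null(symloop)) {
    symloop <- .cif_find_loop(parsed$loops, "_space_group_symop_operation_xyz")
    symtag <- "_space_group_symop_operation_xyz"
  }
  sg <- it[["_symmetry_space_group_name_h-m"]]
  if (is.null(sg)) sg <- it[["_space_group_name_h-m_alt"]]
  if (!is.null(symloop)) {
    ops <- lapply(symloop[[symtag]], parse_symop)
    if (is.null(sg)) sg <- sprintf("unknown (%d ops)", length(ops))
  } else {
    if (is.null(sg)) {
      stop("CIF parse error: no symmetry operator loop and no space-group symbol")
    }
    ops <- spacegroup_ops(sg)
  }

  atl <- .cif_find_loop(parsed$loops, "_atom_site_fract_x")
  if (is.null(atl)) {
    stop("CIF parse error: missing _atom_site loop")
  }
  lab <- if (!is.null(atl[["_atom_site_label"]])) atl[["_atom_site_label"]]
         else sprintf("X%d", seq_len(nrow(atl)))
  el <- atl[["_atom_site_type_symbol"]]
  if (is.null(el)) el <- gsub("[0-9']+.*$", "", lab)  # element from label
  atoms <- data.frame(label = lab, element = el,
                      fx = .cif_number(atl[["_atom_site_fract_x"]]),
                      fy = .cif_number(atl[["_atom_site_fract_y"]]),
                      fz = .cif_number(atl[["_atom_site_fract_z"]]),
                      stringsAsFactors = FALSE)
  if (!is.null(atl[["_atom_site_charge"]])) {
    atoms$charge <- .cif_number(atl[["_atom_site_charge"]])
  }
  if (!is.null(atl[["_atom_site_fragment"]])) {
    atoms$fragment <- atl[["_atom_site_fragment"]]
  }
  crystal_structure(cell, ops, atoms, spacegroup = if (is.null(sg)) "P1" else sg)
}

#' Write a crystal structure to CIF
#'
#' Emits the same dialect [read_cif()] consumes (cell, symmetry operator
#' loop, atom-site loop with optional charge and fragment columns), so
#' fixtures can exercise the full parse path.
#'
#' @param st a `crystal_structure`
#' @param path output file
#' @param data_name CIF data block name
#' @return `path`, invisibly
#' @export
write_cif <- function(st, path, data_name = "synthonic") {
  at <- st$atoms
  lines <- c(
    paste0("data_", data_name),
    sprintf("_symmetry_space_group_name_H-M '%s'", st$spacegroup),
    sprintf("_cell_length_a %.6f", st$cell$a),
    sprintf("_cell_length_b %.6f", st$cell$b),
    sprintf("_cell_length_c %.6f", st$cell$c),
    sprintf("_cell_angle_alpha %.6f", st$cell$alpha),
    sprintf("_cell_angle_beta %.6f", st$cell$beta),
    sprintf("_cell_angle_gamma %.6f", st$cell$gamma),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    vapply(st$ops, function(o) sprintf("'%s'", symop_to_xyz(o)), character(1)),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z"
  )
  cols <- sprintf("%s %s %.8f %.8f %.8f", at$label, at$element,
                  at$fx, at$fy, at$fz)
  if (!all(is.na(at$charge))) {
    lines <- c(lines, "_atom_site_charge")
    cols <- paste(cols, sprintf("%.6f", ifelse(is.na(at$charge), 0, at$charge)))
  }
  if (!all(is.na(at$fragment))) {
    lines <- c(lines, "_atom_site_fragment")
    cols <- paste(cols, ifelse(is.na(at$fragment), ".", at$fragment))
  }
  writeLines(c(lines, cols), path)
  invisible(path)
}

#' Read per-site partial charges from a two-column text file
#'
#' Format: whitespace-separated `label charge` pairs, `#` comments allowed.
#' @param path file path
#' @return named numeric vector of charges (electron units)
#' @export
read_charges <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("label", "charge"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$charge), df$label)
}

#' Write per-site partial charges to a two-column text file
#' @param charges named numeric vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_charges <- function(charges, path) {
  writeLines(sprintf("%s %.8f", names(charges), as.numeric(charges)), path)
  invisible(path)
}

#' Export a molecule cluster as XYZ
#' @param molecules list of molecules (as from [expand_cluster()])
#' @param path output file
#' @param comment second-line comment
#' @return `path`, invisibly
#' @export
write_xyz <- function(molecules, path, comment = "cluster") {
  ats <- do.call(rbind, lapply(molecules, function(m) {
    data.frame(element = m$atoms$element, m$atoms[, c("cx", "cy", "cz")])
  }))
  writeLines(c(sprintf("%d", nrow(ats)), comment,
               sprintf("%-2s %12.6f %12.6f %12.6f",
                       ats$element, ats$cx, ats$cy, ats$cz)), path)
  invisible(path)
}
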