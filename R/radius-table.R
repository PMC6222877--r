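#' Bundled van der Waals radius table
#'
#' Bondi-style van der Waals radii in Angstrom for the elements commonly
#' present in protein structures. The table is swappable: pass any named
#' numeric vector of positive radii (names are upper-case element symbols)
#' wherever a radius table is accepted, or load one from file with
#' [read_radius_table()].
#'
#' @return Named numeric vector of radii with attribute `"table_name"`.
#' @examples
#' default_radius_table()[["C"]] # 1.70
#' @export
default_radius_table <- function() {
  tab <- c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
  )
  attr(tab, "table_name") <- "bondi-1964"
  tab
}

#' Read a van der Waals radius table from a two-column TSV file
#'
#' The file has a header line `element radius` and one element per row.
#'
#' @param path Path to the table file.
#' @return Named numeric vector of radii.
#' @export
read_radius_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("element", "radius") %in% names(df))) {
    stop("radius table must have columns 'element' and 'radius'")
  }
  if (any(df$radius <= 0)) stop("radius table entries must be positive")
  tab <- stats::setNames(as.numeric(df$radius), toupper(df$element))
  attr(tab, "table_name") <- basename(path)
  tab
}

validate_radius_table <- function(table) {
  if (is.null(names(table)) || any(!nzchar(names(table)))) {
    stop("radius table must be a named numeric vector")
  }
  if (any(table <= 0)) stop("all van der Waals radii must be positive")
  needed <- c("C", "N", "O", "S")
  miss <- setdiff(needed, names(table))
  if (length(miss)) {
    stop("radius table must cover at least C, N, O, S; missing: ",
         paste(miss, collapse = ", "))
  }
  invisible(table)
}

#' Assign van der Waals radii to every atom of a molecule
#'
#' Replaces each atom's radius with the table entry for its element symbol.
#'
#' @param molecule A [read_pdb()] molecule.
#' @param table Named numeric radius vector (see [default_radius_table()]).
#' @return The molecule with updated atom radii.
#' @export
assign_radii <- function(molecule, table = default_radius_table()) {
  validate_radius_table(table)
  lookup <- function(atoms, where) {
    if (is.null(atoms) || nrow(atoms) == 0L) return(atoms)
    el <- toupper(atoms$element)
    bad <- !(el %in% names(table))
    if (any(bad)) {
      stop("no van der Waals radius for element(s) ",
           paste(unique(el[bad]), collapse = ", "),
           " (atoms ", paste(atoms$name[bad], collapse = ", "),
           " in ", where, ")")
    }
    atoms$radius <- unname(table[el])
    atoms
  }
  molecule$residues <- lapply(molecule$residues, function(res) {
    res$main_chain <- lookup(res$main_chain, res$key)
    res$side_chain <- lookup(res$side_chain, res$key)
    res
  })
  molecule$hetero <- lookup(molecule$hetero, "HETATM")
  molecule$radius_table <- attr(table, "table_name")
  molecule
}
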