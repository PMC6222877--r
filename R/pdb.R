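# Atom tables are plain data frames with columns:
#   serial, name, element, x, y, z, radius
# A residue key is "chain:resno" (or "chain:resno:ins" with an insertion
# code); keys are unique within a molecule and the residue list is ordered
# by chain, residue number, insertion code.

residue_key <- function(chain, resno, insert = "") {
  ins <- ifelse(is.na(insert) | insert == "", "", paste0(":", insert))
  paste0(chain, ":", resno, ins)
}

empty_atom_table <- function() {
  data.frame(
    serial = integer(0), name = character(0), element = character(0),
    x = numeric(0), y = numeric(0), z = numeric(0), radius = numeric(0),
    stringsAsFactors = FALSE
  )
}

atom_xyz <- function(atoms) {
  if (is.null(atoms) || nrow(atoms) == 0L) {
    return(matrix(numeric(0), ncol = 3L))
  }
  cbind(atoms$x, atoms$y, atoms$z)
}

# Water residue names dropped on input.
.water_resids <- c("HOH", "WAT", "H2O", "DOD", "SOL", "TIP3", "TIP4")

# Derive the element symbol from a PDB atom name when columns 77-78 are
# blank: strip digits and primes, take the leading letters; a leading digit
# followed by H (e.g. "1HB") is hydrogen.
elem_from_name <- function(name) {
  vapply(name, function(nm) {
    nm <- toupper(trimws(nm))
    if (grepl("^[0-9]H", nm)) return("H")
    letters_only <- gsub("[^A-Z]", "", nm)
    if (!nzchar(letters_only)) return("")
    # two-letter symbols used in practice for hetero atoms
    two <- substr(letters_only, 1L, 2L)
    if (two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "NA", "CA")) {
      # ambiguous with C-alpha style names; protein atom names CA/CB/... are
      # carbon, so only trust two-letter symbols for non-standard names
      if (nchar(letters_only) == 2L && !two %in% c("CA", "NA")) return(two)
    }
    substr(letters_only, 1L, 1L)
  }, character(1L), USE.NAMES = FALSE)
}

#' Partition a residue's atoms into main chain and side chain
#'
#' Atoms named N, CA, C, O form the main chain; every other atom belongs to
#' the side chain. When both CA and CB are present, the rotation axis runs
#' from the CA center to the CB center. A residue is rotatable when its type
#' is not GLY, ALA or PRO, the axis exists, and the side chain is non-empty:
#' glycine has no C-beta, alanine's C-beta lies on the axis (rotation is the
#' identity), and proline's ring closes onto the backbone.
#'
#' @param atoms Atom table for one residue (unique atom names).
#' @param type Three-letter amino-acid code.
#' @param chain,resno,insert Residue identity.
#' @return An object of class `"tf_residue"`.
#' @export
partition_residue <- function(atoms, type, chain = "A", resno = 1L,
                              insert = "") {
  if (anyDuplicated(atoms$name)) {
    stop("duplicate atom names in residue ", residue_key(chain, resno, insert),
         ": ", paste(atoms$name[duplicated(atoms$name)], collapse = ", "))
  }
  is_mc <- atoms$name %in% c("N", "CA", "C", "O")
  main_chain <- atoms[is_mc, , drop = FALSE]
  side_chain <- atoms[!is_mc, , drop = FALSE]
  rownames(main_chain) <- rownames(side_chain) <- NULL
  axis <- NULL
  ca <- main_chain[main_chain$name == "CA", , drop = FALSE]
  cb <- side_chain[side_chain$name == "CB", , drop = FALSE]
  if (nrow(ca) == 1L && nrow(cb) == 1L) {
    axis <- axis_through(
      c(ca$x, ca$y, ca$z),
      c(cb$x, cb$y, cb$z)
    )
  }
  rotatable <- !(toupper(type) %in% c("GLY", "ALA", "PRO")) &&
    !is.null(axis) && nrow(side_chain) > 0L
  structure(
    list(
      key = residue_key(chain, resno, insert),
      chain = chain, resno = as.integer(resno), insert = insert,
      type = toupper(type),
      main_chain = main_chain, side_chain = side_chain,
      axis = axis, rotatable = rotatable
    ),
    class = "tf_residue"
  )
}

new_molecule <- function(residues, hetero = empty_atom_table()) {
  keys <- vapply(residues, `[[`, character(1L), "key")
  if (anyDuplicated(keys)) {
    stop("duplicate residue keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  ord <- order(
    vapply(residues, `[[`, character(1L), "chain"),
    vapply(residues, `[[`, integer(1L), "resno"),
    vapply(residues, `[[`, character(1L), "insert")
  )
  residues <- residues[ord]
  names(residues) <- vapply(residues, `[[`, character(1L), "key")
  structure(list(residues = residues, hetero = hetero),
            class = "tf_molecule")
}

#' Read a protein structure from a PDB file into the sphere model
#'
#' Parses ATOM/HETATM records with `bio3d`, then: keeps only the requested
#' model; drops hydrogens and deuteriums (their volume is negligible next to
#' the heavy-atom spheres); drops waters; resolves alternate locations to
#' the highest-occupancy copy (ties favor altloc "A"); keeps non-water
#' HETATM groups as static obstacle spheres when `keep_hetero` is `TRUE`;
#' and assigns van der Waals radii from `radius_table`.
#'
#' @param path Path to a PDB file.
#' @param model Model number to read (default 1).
#' @param chains Optional character vector restricting to these chain ids.
#' @param radius_table Named radius vector, see [default_radius_table()].
#' @param keep_hetero Keep non-water hetero atoms as static obstacles.
#' @return A molecule: ordered residue list plus hetero atom table.
#' @export
read_pdb <- function(path, model = 1L, chains = NULL,
                     radius_table = default_radius_table(),
                     keep_hetero = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE,
                         rm.alt = FALSE, hex = TRUE)
  atoms <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models) {
    stop("model ", model, " not present (file has ", n_models, " model(s))")
  }
  if (model > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  }
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  if (nrow(atoms[atoms$type == "ATOM", , drop = FALSE]) == 0L) {
    stop("no ATOM records in ", path)
  }

  el <- toupper(trimws(ifelse(is.na(atoms$elesy), "", atoms$elesy)))
  fallback <- !nzchar(el)
  el[fallback] <- elem_from_name(atoms$elety[fallback])
  atoms$element <- el
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms <- atoms[!(toupper(atoms$resid) %in% .water_resids), , drop = FALSE]

  # altloc: within each (chain, resno, insert, name) group keep the
  # highest-occupancy record; ties resolve to the alphabetically first
  # altloc, so 'A' wins.
  alt <- ifelse(is.na(atoms$alt), "", atoms$alt)
  occ <- ifelse(is.na(atoms$o), 1, atoms$o)
  grp <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$type,
               atoms$elety, sep = "\r")
  pos0 <- seq_len(nrow(atoms))
  keep_order <- order(grp, -occ, alt)
  keep <- keep_order[!duplicated(grp[keep_order])]
  atoms <- atoms[sort(pos0[keep]), , drop = FALSE] # restore record order

  as_atom_table <- function(df) {
    data.frame(
      serial = as.integer(df$eleno), name = trimws(df$elety),
      element = df$element,
      x = df$x, y = df$y, z = df$z, radius = NA_real_,
      stringsAsFactors = FALSE
    )
  }

  prot <- atoms[atoms$type == "ATOM", , drop = FALSE]
  het <- atoms[atoms$type == "HETATM", , drop = FALSE]
  ins <- ifelse(is.na(prot$insert), "", prot$insert)
  split_id <- paste(prot$chain, prot$resno, ins, sep = "\r")
  residues <- lapply(split(seq_len(nrow(prot)), split_id), function(ii) {
    sub <- prot[ii, , drop = FALSE]
    partition_residue(
      as_atom_table(sub), type = sub$resid[1L],
      chain = sub$chain[1L], resno = sub$resno[1L],
      insert = ifelse(is.na(sub$insert[1L]), "", sub$insert[1L])
    )
  })
  hetero <- if (keep_hetero && nrow(het) > 0L) {
    as_atom_table(het)
  } else {
    empty_atom_table()
  }
  mol <- new_molecule(unname(residues), hetero)
  assign_radii(mol, radius_table)
}

#' @export
print.tf_molecule <- function(x, ...) {
  n_at <- sum(vapply(x$residues, function(r) {
    nrow(r$main_chain) + nrow(r$side_chain)
  }, integer(1L)))
  cat("tunnelflex molecule:", length(x$residues), "residues,",
      n_at, "heavy atoms,", nrow(x$hetero), "hetero atoms\n")
  invisible(x)
}

# All atoms of a molecule as one table (main + side chains + hetero),
# with the owning residue key ("" for hetero) and a main-chain flag.
molecule_atoms <- function(molecule) {
  parts <- lapply(molecule$residues, function(res) {
    mc <- res$main_chain
    sc <- res$side_chain
    if (nrow(mc)) { mc$residue_key <- res$key; mc$main_chain <- TRUE }
    if (nrow(sc)) { sc$residue_key <- res$key; sc$main_chain <- FALSE }
    rbind(
      if (nrow(mc)) mc else NULL,
      if (nrow(sc)) sc else NULL
    )
  })
  het <- molecule$hetero
  if (nrow(het)) { het$residue_key <- ""; het$main_chain <- FALSE }
  out <- do.call(rbind, c(parts, if (nrow(het)) list(het) else NULL))
  if (is.null(out)) {
    out <- cbind(empty_atom_table(),
                 data.frame(residue_key = character(0),
                            main_chain = logical(0)))
  }
  rownames(out) <- NULL
  out
}
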