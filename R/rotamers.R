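# A rotamer set holds, for one residue, every discretized side-chain pose:
#   residue_key, rotatable,
#   rotamers: list of list(index, angle, atoms, xyz, radii)
#   bsv: sphere containing every rotamer AND the residue's main chain
# Rotamer indices are 0-based; index 0 is the input pose.

atom_spheres <- function(atoms) {
  lapply(seq_len(nrow(atoms)), function(i) {
    sphere(c(atoms$x[i], atoms$y[i], atoms$z[i]), atoms$radius[i])
  })
}

make_rotamer <- function(residue, index, angle, atoms) {
  list(
    index = as.integer(index), angle = angle, atoms = atoms,
    xyz = atom_xyz(atoms), radii = atoms$radius
  )
}

#' Generate the discretized rotamer set of a residue
#'
#' A rotatable residue's whole side chain is rotated rigidly about its
#' C-alpha/C-beta axis every `step` degrees, giving `360 / step` rotamers
#' (12 at the default 30 degree step); rotamer 0 is the input pose,
#' untouched. Non-rotatable residues (GLY, ALA, PRO, or no side chain)
#' contribute a single rotamer: the input pose.
#'
#' The set's bounding sphere volume (BSV) contains every rotamer and the
#' residue's main-chain atoms: for rotatable residues it merges the per-atom
#' swept bounds about the axis with the main-chain spheres; otherwise it
#' encloses the literal atoms.
#'
#' @param residue A [partition_residue()] residue.
#' @param step Rotation step in degrees; must divide 360.
#' @return A rotamer set (see Details).
#' @export
generate_rotamers <- function(residue, step = 30) {
  if (step <= 0 || 360 %% step != 0) {
    stop("step must be a positive divisor of 360")
  }
  sc <- residue$side_chain
  mc_spheres <- atom_spheres(residue$main_chain)
  if (!residue$rotatable) {
    rot <- list(make_rotamer(residue, 0L, 0, sc))
    bsv <- enclosing_sphere(c(mc_spheres, atom_spheres(sc)))
  } else {
    if (is.null(residue$axis)) {
      stop("residue ", residue$key, " flagged rotatable but has no axis")
    }
    n_rot <- as.integer(360 / step)
    xyz0 <- atom_xyz(sc)
    rot <- lapply(seq_len(n_rot) - 1L, function(j) {
      atoms <- sc
      if (j > 0L) {
        xyz <- rotate_about_axis(xyz0, residue$axis, j * step)
        atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
      }
      make_rotamer(residue, j, j * step, atoms)
    })
    swept <- lapply(atom_spheres(sc), swept_bound, axis = residue$axis)
    bsv <- enclosing_sphere(c(mc_spheres, swept))
  }
  structure(
    list(residue_key = residue$key, rotatable = residue$rotatable,
         step = step, rotamers = rot, bsv = bsv),
    class = "tf_rotamer_set"
  )
}

#' Rotamer sets for every residue of a molecule
#'
#' @param molecule A molecule.
#' @param step Rotation step in degrees.
#' @return Named list of rotamer sets, in molecule residue order.
#' @export
build_rotamer_sets <- function(molecule, step = 30) {
  lapply(molecule$residues, generate_rotamers, step = step)
}

rotamer_indices <- function(rotamer_set) {
  vapply(rotamer_set$rotamers, `[[`, integer(1L), "index")
}

get_rotamer <- function(rotamer_set, index) {
  for (rot in rotamer_set$rotamers) if (rot$index == index) return(rot)
  stop("rotamer ", index, " not present for residue ",
       rotamer_set$residue_key)
}

new_adjacent_set <- function(residues, rotamer_sets) {
  structure(
    list(residues = residues, rotamer_sets = rotamer_sets[residues],
         n = length(residues)),
    class = "tf_adjacent_set"
  )
}

#' @export
print.tf_adjacent_set <- function(x, ...) {
  counts <- vapply(x$rotamer_sets, function(rs) length(rs$rotamers),
                   integer(1L))
  cat("tunnel-adjacent set:", x$n, "residues;",
      "rotamers per residue:", paste(counts, collapse = " "), "\n")
  invisible(x)
}

# Case-1 self-check exclusion: pairs whose distance is invariant under the
# axis rotation, i.e. pairs where either atom lies on the C-alpha/C-beta
# axis itself (CA and C-beta do; so does CA against every side-chain
# atom). Such contacts are fixed properties of the given input structure,
# which the model takes as valid, so they either veto all rotamers or
# none and carry no information about a pose; they also cover the
# covalently forced near-contacts (C-beta against CA/N/C, gamma atoms
# against CA) that tetrahedral geometry produces in every side chain.
# Pose-dependent pairs (gamma and beyond against N, C, O) stay checked.
self_exclusion_matrix <- function(rot_atoms, mc_atoms, axis) {
  if (is.null(axis) || nrow(rot_atoms) == 0L || nrow(mc_atoms) == 0L) {
    return(NULL)
  }
  k <- unit(axis$point_b - axis$point_a)
  on_axis <- function(atoms) {
    v <- sweep(atom_xyz(atoms), 2L, axis$point_a)
    perp <- v - outer(as.numeric(v %*% k), k)
    sqrt(rowSums(perp^2)) < 1e-6
  }
  ex <- outer(on_axis(rot_atoms), rep(TRUE, nrow(mc_atoms)), "&") |
    outer(rep(TRUE, nrow(rot_atoms)), on_axis(mc_atoms), "&")
  if (any(ex)) ex else NULL
}

#' Remove invalid rotamers (static-environment pruning)
#'
#' Drops every rotamer that collides with the static environment:
#' \describe{
#'   \item{Case 1}{collision with any main-chain atom of any residue. The
#'     check against the rotamer's own main chain (enabled by
#'     `self_main_chain`) exempts the covalently forced pairs C-beta/C-alpha,
#'     C-beta/N and C-beta/C.}
#'   \item{Case 2}{collision with any atom of a residue outside the
#'     tunnel-adjacent set, or with a hetero obstacle.}
#' }
#' A removal log (one row per dropped rotamer, with the offending atom pair)
#' is attached as attribute `"removal_log"`.
#'
#' @param adjacent Adjacent set from [tunnel_adjacent_residues()].
#' @param molecule The molecule the set was built from.
#' @param tol Collision tolerance, squared Angstrom.
#' @param self_main_chain Check rotamers against their own main chain.
#' @return The pruned adjacent set.
#' @export
remove_invalid_rotamers <- function(adjacent, molecule, tol = 1e-9,
                                    self_main_chain = TRUE) {
  in_s <- names(molecule$residues) %in% adjacent$residues

  mc_tables <- lapply(molecule$residues, `[[`, "main_chain")
  outside <- c(
    lapply(molecule$residues[!in_s], function(res) {
      rbind(res$main_chain, res$side_chain)
    }),
    if (nrow(molecule$hetero)) list(molecule$hetero) else NULL
  )
  bind_named <- function(tabs, label_fmt) {
    tabs <- tabs[vapply(tabs, nrow, integer(1L)) > 0L]
    if (!length(tabs)) return(NULL)
    labs <- names(tabs)
    if (is.null(labs)) labs <- rep("", length(tabs))
    out <- do.call(rbind, tabs)
    out$owner <- rep(labs, vapply(tabs, nrow, integer(1L)))
    rownames(out) <- NULL
    out
  }
  names(outside) <- c(names(molecule$residues)[!in_s],
                      if (nrow(molecule$hetero)) "HETATM")[seq_along(outside)]
  outside_tab <- bind_named(outside)
  out_xyz <- if (is.null(outside_tab)) NULL else atom_xyz(outside_tab)

  log_rows <- list()
  pruned_sets <- adjacent$rotamer_sets
  for (key in adjacent$residues) {
    rs <- pruned_sets[[key]]
    other_mc <- bind_named(mc_tables[setdiff(names(mc_tables), key)])
    omc_xyz <- if (is.null(other_mc)) NULL else atom_xyz(other_mc)
    own_mc <- mc_tables[[key]]
    keep <- logical(length(rs$rotamers))
    for (ri in seq_along(rs$rotamers)) {
      rot <- rs$rotamers[[ri]]
      offender <- NULL
      # Case 1: main chains of every residue (own chain with exclusions)
      if (!is.null(omc_xyz)) {
        hit <- collide_sets_which(rot$xyz, rot$radii, omc_xyz,
                                  other_mc$radius, tol)
        if (!is.null(hit)) {
          offender <- c("case1", rot$atoms$name[hit[1L]],
                        paste0(other_mc$owner[hit[2L]], "/",
                               other_mc$name[hit[2L]]))
        }
      }
      if (is.null(offender) && self_main_chain && nrow(own_mc) > 0L &&
          nrow(rot$atoms) > 0L) {
        hit <- collide_sets_which(
          rot$xyz, rot$radii, atom_xyz(own_mc), own_mc$radius, tol,
          exclude = self_exclusion_matrix(rot$atoms, own_mc,
                                          molecule$residues[[key]]$axis)
        )
        if (!is.null(hit)) {
          offender <- c("case1", rot$atoms$name[hit[1L]],
                        paste0(key, "/", own_mc$name[hit[2L]]))
        }
      }
      # Case 2: anything outside S (plus hetero obstacles)
      if (is.null(offender) && !is.null(out_xyz)) {
        hit <- collide_sets_which(rot$xyz, rot$radii, out_xyz,
                                  outside_tab$radius, tol)
        if (!is.null(hit)) {
          offender <- c("case2", rot$atoms$name[hit[1L]],
                        paste0(outside_tab$owner[hit[2L]], "/",
                               outside_tab$name[hit[2L]]))
        }
      }
      keep[ri] <- is.null(offender)
      if (!is.null(offender)) {
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          residue = key, rotamer = rot$index, case = offender[1L],
          rotamer_atom = offender[2L], static_atom = offender[3L],
          stringsAsFactors = FALSE
        )
      }
    }
    if (!any(keep)) {
      stop("residue ", key, " has no valid rotamer left: the static ",
           "environment already contradicts the model")
    }
    rs$rotamers <- rs$rotamers[keep]
    pruned_sets[[key]] <- rs
  }
  out <- new_adjacent_set(adjacent$residues, pruned_sets)
  attr(out, "removal_log") <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(residue = character(0), rotamer = integer(0),
               case = character(0), rotamer_atom = character(0),
               static_atom = character(0), stringsAsFactors = FALSE)
  }
  out
}
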