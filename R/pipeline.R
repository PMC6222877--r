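#' Enumerate every valid side-chain conformation around a tunnel
#'
#' The full pipeline: discretize rotamers for every residue, select the
#' tunnel-adjacent set by BSV/tunnel overlap, prune rotamers invalid
#' against the static environment, build the BSV-overlap and collision
#' graphs, enumerate amino-collision cliques, build each clique's
#' collision-free rotamer graph, extract local valid conformations, and
#' combine them into the global set.
#'
#' @param molecule A [read_pdb()] molecule (or a fixture molecule).
#' @param tunnel A tunnel profile.
#' @param step Rotamer step in degrees (default 30, i.e. 12 rotamers).
#' @param tol Collision tolerance, squared Angstrom.
#' @param self_main_chain Check rotamers against their own main chain
#'   during pruning.
#' @param max_conformations Enumeration guard, see [combine_all()].
#' @return List with `adjacent` (pruned set), `tg`, `cg`, `cliques`,
#'   `local_sets`, and `globals`.
#' @export
enumerate_conformations <- function(molecule, tunnel, step = 30,
                                    tol = 1e-9, self_main_chain = TRUE,
                                    max_conformations = Inf) {
  rotamer_sets <- build_rotamer_sets(molecule, step = step)
  adjacent <- tunnel_adjacent_residues(molecule, rotamer_sets, tunnel,
                                       tol = tol)
  adjacent <- remove_invalid_rotamers(adjacent, molecule, tol = tol,
                                      self_main_chain = self_main_chain)
  tg <- build_temporary_graph(adjacent, tol = tol)
  cg <- build_collision_graph(adjacent, tg, tol = tol)
  cliques <- amino_collision_cliques(cg)
  local_sets <- lapply(cliques, function(clq) {
    fg <- build_collision_free_graph(clq, adjacent, tol = tol)
    local_valid_conformations(fg, clq, adjacent)
  })
  globals <- combine_all(local_sets, adjacent,
                         max_conformations = max_conformations)
  list(adjacent = adjacent, tg = tg, cg = cg, cliques = cliques,
       local_sets = local_sets, globals = globals)
}

#' Maximum bottleneck of a flexibly deformed tunnel
#'
#' Convenience wrapper: [enumerate_conformations()] followed by
#' [analyze_bottlenecks()].
#'
#' @inheritParams enumerate_conformations
#' @param ... Passed on to [enumerate_conformations()].
#' @return List with the enumeration result (`pipeline`) and the
#'   bottleneck `report`.
#' @export
max_tunnel_bottleneck <- function(molecule, tunnel, ...) {
  pipe <- enumerate_conformations(molecule, tunnel, ...)
  report <- analyze_bottlenecks(tunnel, pipe$globals, pipe$adjacent,
                                molecule)
  list(pipeline = pipe, report = report)
}

#' Candidate-space size of the rotamer discretization
#'
#' With `k` rotamers per rotatable residue (12 at the default 30 degree
#' step) and `n` residues, the unpruned search space holds `k^n` candidate
#' conformations. The finer multi-axis picture, with three staggered
#' positions per torsion axis and up to four axes, gives `3^4 = 81`
#' conformations for a long side chain; the single-axis 30 degree sweep is
#' the package's (and the underlying method's) working approximation of
#' that space.
#'
#' @param n_residues Number of rotatable residues.
#' @param rotamers_per_residue Rotamers per residue.
#' @return Number of candidate conformations.
#' @export
candidate_space_size <- function(n_residues, rotamers_per_residue = 12) {
  rotamers_per_residue^n_residues
}

#' @rdname candidate_space_size
#' @param n_axes Number of torsion axes of one side chain.
#' @param positions_per_axis Staggered positions per axis.
#' @export
multi_axis_conformation_count <- function(n_axes = 4,
                                          positions_per_axis = 3) {
  positions_per_axis^n_axes
}
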