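#' Select the residues adjacent to a tunnel
#'
#' A residue belongs to the tunnel-adjacent set S when its bounding sphere
#' volume has a non-empty intersection with at least one swept-ball sample
#' of the tunnel (touching counts). Because the BSV spans every rotamer,
#' this covers both residues contacting the tunnel in the input pose and
#' residues whose rotamers could reach into it.
#'
#' @param molecule A molecule.
#' @param rotamer_sets Rotamer sets for all residues
#'   ([build_rotamer_sets()]).
#' @param tunnel A tunnel profile.
#' @param tol Overlap tolerance, squared Angstrom.
#' @return An adjacent set (ordered residue keys plus their rotamer sets).
#' @export
tunnel_adjacent_residues <- function(molecule, rotamer_sets, tunnel,
                                     tol = 1e-9) {
  s <- tunnel$samples
  balls <- lapply(seq_len(nrow(s)), function(i) {
    sphere(c(s$x[i], s$y[i], s$z[i]), s$r[i])
  })
  keys <- names(molecule$residues)
  hit <- vapply(keys, function(key) {
    bsv <- rotamer_sets[[key]]$bsv
    any(vapply(balls, spheres_touch, logical(1L), s2 = bsv, tol = tol))
  }, logical(1L))
  if (!any(hit)) stop("tunnel touches no residue")
  new_adjacent_set(keys[hit], rotamer_sets)
}

# Discrete local minima of a radius profile, plateau-aware: a run of equal
# minimal radii flanked on both sides by strictly larger radii is reported
# at its first sample; endpoints are never bottlenecks.
bottleneck_indices <- function(r) {
  runs <- rle(r)
  n_runs <- length(runs$values)
  if (n_runs < 3L) return(integer(0))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  mid <- 2:(n_runs - 1L)
  is_min <- runs$values[mid - 1L] > runs$values[mid] &
    runs$values[mid + 1L] > runs$values[mid]
  starts[mid][is_min]
}

#' Find the bottlenecks of a tunnel profile
#'
#' A bottleneck is a discrete strict local minimum of the sampled radius
#' profile: a sample whose radius is smaller than both neighbours one
#' sample step away. A plateau of equal minimal radii flanked by strictly
#' larger radii counts once, at its first sample. Endpoints are never
#' bottlenecks.
#'
#' @param tunnel A tunnel profile.
#' @return Data frame with columns `sample_index` (1-based), `t`, `radius`;
#'   zero rows when no interior local minimum exists.
#' @export
find_bottlenecks <- function(tunnel) {
  idx <- bottleneck_indices(tunnel$samples$r)
  data.frame(
    sample_index = idx,
    t = tunnel$samples$t[idx],
    radius = tunnel$samples$r[idx]
  )
}

#' Minimum bottleneck radius of a tunnel
#'
#' The minimum radius over all bottlenecks; the largest spherical ligand
#' that can traverse the tunnel has exactly this radius. When the profile
#' has no interior local minimum (monotone radii), the narrowest sample
#' still limits passage, so the global minimum radius is returned.
#'
#' @param tunnel A tunnel profile.
#' @return Radius in Angstrom.
#' @export
min_bottleneck_radius <- function(tunnel) {
  b <- find_bottlenecks(tunnel)
  if (nrow(b) == 0L) min(tunnel$samples$r) else min(b$radius)
}

# Obstacle atoms that never move: main chains of every residue, all atoms
# of residues outside S, and hetero atoms. Returns list(xyz, radius).
static_obstacles <- function(molecule, adjacent) {
  in_s <- names(molecule$residues) %in% adjacent$residues
  tabs <- c(
    lapply(molecule$residues, `[[`, "main_chain"),
    lapply(molecule$residues[!in_s], `[[`, "side_chain"),
    if (nrow(molecule$hetero)) list(molecule$hetero) else NULL
  )
  tabs <- tabs[vapply(tabs, nrow, integer(1L)) > 0L]
  if (!length(tabs)) {
    return(list(xyz = matrix(numeric(0), ncol = 3L), radius = numeric(0)))
  }
  all <- do.call(rbind, lapply(tabs, function(x) x[, c("x", "y", "z", "radius")]))
  list(xyz = as.matrix(all[, c("x", "y", "z")]), radius = all$radius)
}

# Minimum clearance (distance to sphere surface) from each row of `centers`
# to an atom set; +Inf when the set is empty.
clearance_to <- function(centers, xyz, radius) {
  if (nrow(xyz) == 0L) return(rep(Inf, nrow(centers)))
  d2 <- outer(rowSums(centers^2), rowSums(xyz^2), "+") -
    2 * tcrossprod(centers, xyz)
  d2[d2 < 0] <- 0
  apply(sweep(sqrt(d2), 2L, radius), 1L, min)
}

#' Recompute tunnel radii under a side-chain conformation
#'
#' Keeps the original centerline and parameters and replaces every sample
#' radius with the clearance radius at that center: the minimum over all
#' obstacle atoms of (distance to atom center) minus (atom radius), where
#' the obstacles are the static environment plus the side chains of the
#' selected rotamers. Radii are clamped to `[0, r_cap]`; the cap (default
#' twice the original maximum radius) bounds the profile where the
#' centerline leaves the protein.
#'
#' This fixed-centerline clearance recomputation stands behind a plug-in
#' interface: a full tunnel-detection program could replace it, at the cost
#' of determinism and self-containment.
#'
#' @param tunnel A tunnel profile.
#' @param conformation Integer vector, one 0-based rotamer index per
#'   residue of `adjacent` (no sentinel entries).
#' @param adjacent The (pruned) adjacent set.
#' @param molecule The molecule.
#' @param r_cap Clearance cap in Angstrom.
#' @return A tunnel profile with identical `t` and centers, new radii.
#' @export
recompute_tunnel <- function(tunnel, conformation, adjacent, molecule,
                             r_cap = 2 * max(tunnel$samples$r)) {
  conformation <- as.integer(conformation)
  if (length(conformation) != adjacent$n) {
    stop("conformation length must equal the adjacent-set size")
  }
  if (any(conformation < 0L)) {
    stop("conformation contains sentinel entries; a fully assigned, valid ",
         "conformation is required")
  }
  st <- static_obstacles(molecule, adjacent)
  side <- lapply(seq_len(adjacent$n), function(i) {
    rot <- get_rotamer(adjacent$rotamer_sets[[i]], conformation[i])
    list(xyz = rot$xyz, radius = rot$radii)
  })
  xyz <- do.call(rbind, c(list(st$xyz), lapply(side, `[[`, "xyz")))
  radius <- c(st$radius, unlist(lapply(side, `[[`, "radius")))
  centers <- as.matrix(tunnel$samples[, c("x", "y", "z")])
  clear <- clearance_to(centers, xyz, radius)
  r_new <- pmin(pmax(clear, 0), r_cap)
  out <- tunnel
  out$samples$r <- r_new
  # clamped-to-zero samples mean "fully blocked"; the profile keeps them so
  # downstream minima are honest, bypassing the >0 constructor invariant
  out
}
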