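# Deterministic synthetic inputs. Everything here is synthetic by design:
# pseudo-residues are sphere arms with a genuine C-alpha/C-beta axis, not
# physically realistic amino acids. They exist so that every pipeline stage
# is testable without downloading a structure.

toy_atom_table <- function(serial, name, element, xyz, radius) {
  xyz <- matrix(xyz, ncol = 3L)
  data.frame(
    serial = as.integer(serial), name = name, element = element,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], radius = radius,
    stringsAsFactors = FALSE
  )
}

#' Abstract worked example: three residues, three rotamers each
#'
#' A pre-built collision-free rotamer graph over residues A2, A3, A5, each
#' with rotamers R0..R2, where A2.R0 and A3.R2 were removed as invalid and
#' the rotamer pairs (A2.R2, A3.R0), (A2.R2, A5.R1) and (A3.R1, A5.R0)
#' collide. All other surviving inter-residue pairs are collision-free
#' edges. This pins the printed clique and conformation counts of the
#' example independent of any geometry.
#'
#' @return List with `adjacent` (a minimal adjacent-set stub), `clique`
#'   (the single amino-collision clique), `fg` (the collision-free graph),
#'   `invalid` (removed rotamer labels) and `collisions` (the colliding
#'   surviving pairs, 2-column matrix).
#' @export
worked_example_graph <- function() {
  survivors <- list(A2 = c(1L, 2L), A3 = c(0L, 1L), A5 = c(0L, 1L, 2L))
  keys <- names(survivors)
  rotamer_sets <- lapply(keys, function(key) {
    structure(
      list(residue_key = key, rotatable = TRUE, step = 120,
           rotamers = lapply(survivors[[key]], function(j) {
             list(index = j, angle = 120 * j,
                  atoms = empty_atom_table(),
                  xyz = matrix(numeric(0), ncol = 3L), radii = numeric(0))
           }),
           bsv = sphere(c(0, 0, 0), 1)),
      class = "tf_rotamer_set"
    )
  })
  names(rotamer_sets) <- keys
  adjacent <- new_adjacent_set(keys, rotamer_sets)

  colliding <- rbind(
    c("A2.R2", "A3.R0"),
    c("A2.R2", "A5.R1"),
    c("A3.R1", "A5.R0")
  )
  verts <- unlist(lapply(keys, function(key) {
    vapply(survivors[[key]], function(j) rotamer_vertex(key, j),
           character(1L))
  }))
  owner <- sub("\\.R\\d+$", "", verts)
  pairs <- list()
  for (i in seq_len(length(verts) - 1L)) {
    for (j in (i + 1L):length(verts)) {
      if (owner[i] == owner[j]) next
      pr <- sort(c(verts[i], verts[j]))
      if (any(colliding[, 1L] == pr[1L] & colliding[, 2L] == pr[2L])) next
      pairs[[length(pairs) + 1L]] <- pr
    }
  }
  clique <- list(index = 1L, members = keys)
  fg <- new_graph(verts, do.call(rbind, pairs), "rotamer")
  attr(fg, "clique") <- clique
  list(adjacent = adjacent, clique = clique, fg = fg,
       invalid = c("A2.R0", "A3.R2"), collisions = colliding)
}

# One synthetic rotatable residue: 4 main-chain spheres at z = 0 around the
# base point, CB on the vertical axis at z = 1, and a single arm atom in
# the z = 2 plane at polar angle `alpha0` (the input pose) and radius `rho`
# from the axis. All atoms have radius 0.5. With a 120-degree step, the
# three rotamer tips sit at alpha0, alpha0 + 120, alpha0 + 240.
worked_example_residue <- function(resno, base, alpha0, rho, serial0) {
  cx <- base[1L]; cy <- base[2L]
  tip <- c(cx + rho * cos(alpha0), cy + rho * sin(alpha0), 2)
  atoms <- toy_atom_table(
    serial0 + 0:5,
    c("N", "CA", "C", "O", "CB", "SG"),
    rep("C", 6L),
    rbind(
      c(cx - 1.2, cy + 0.3, 0), c(cx, cy, 0),
      c(cx + 1.2, cy + 0.3, 0), c(cx + 1.8, cy + 1.3, 0),
      c(cx, cy, 1), tip
    ),
    0.5
  )
  partition_residue(atoms, "CYS", chain = "A", resno = resno)
}

worked_example_static <- function(resno, coords, serial0) {
  atoms <- toy_atom_table(
    serial0 + 0:3, c("N", "CA", "C", "O"), rep("C", 4L), coords, 0.5
  )
  partition_residue(atoms, "GLY", chain = "A", resno = resno)
}

#' Geometric worked example: a molecule realizing the printed relations
#'
#' A concrete sphere-model molecule plus a tunnel profile engineered so
#' that the full pipeline, run with a coarse 120-degree rotamer step
#' (three rotamers per residue), reproduces exactly the abstract worked
#' example of [worked_example_graph()]: the tunnel-adjacent set is
#' \{A:2, A:3, A:5\}, pruning removes exactly A:2.R0 (it collides with the
#' main chain of static residue A:1) and A:3.R2 (static residue A:4), and
#' the only colliding surviving rotamer pairs are (A:2.R2, A:3.R0),
#' (A:2.R2, A:5.R1) and (A:3.R1, A:5.R0). The constructor asserts the
#' planted collision structure and fails loudly if it is not realized.
#'
#' The layout is two-dimensional at heart: all rotamer tips move on
#' circles in the z = 2 plane; A:5's center is derived from a
#' rotation-center construction so that its R0 and R1 tips land on the two
#' planted collision sites 120 degrees apart.
#'
#' @return List with `molecule`, `tunnel`, and `step` (120).
#' @export
worked_example_geometry <- function() {
  deg <- pi / 180
  # A2: R2 tip planted at (3, -0.5)
  c2 <- c(0, 0)
  p2 <- c(3, -0.5)
  rho2 <- sqrt(sum((p2 - c2)^2))
  alpha2 <- atan2(p2[2L] - c2[2L], p2[1L] - c2[1L]) - 240 * deg
  # A3: R0 tip planted at (3.8, -0.5)
  c3 <- c(7.5, 0.2)
  p3 <- c(3.8, -0.5)
  rho3 <- sqrt(sum((p3 - c3)^2))
  alpha3 <- atan2(p3[2L] - c3[2L], p3[1L] - c3[1L])
  # A5: R0 tip at t0 (next to A3.R1), R1 tip at t1 (next to A2.R2); the
  # center is the point about which a +120 degree turn maps t0 to t1
  t0 <- c(10.258, -3.253)
  t1 <- c(2.5, -1.1)
  mid <- (t0 + t1) / 2
  v <- t1 - t0
  len <- sqrt(sum(v^2))
  rho5 <- len / sqrt(3)
  c5 <- mid - (rho5 / 2) * c(v[2L], -v[1L]) / len
  alpha5 <- atan2(t0[2L] - c5[2L], t0[1L] - c5[1L])

  residues <- list(
    worked_example_static(1L, rbind(
      c(-2.2, 3.2, 2), c(-1.0, 2.9, 2), c(0.2, 3.2, 2), c(0.8, 4.2, 2)
    ), 100L),
    worked_example_residue(2L, c2, alpha2, rho2, 200L),
    worked_example_residue(3L, c3, alpha3, rho3, 300L),
    worked_example_static(4L, rbind(
      c(7.5, 4.1, 2), c(8.7, 3.8, 2), c(9.9, 4.1, 2), c(10.5, 5.1, 2)
    ), 400L),
    worked_example_residue(5L, c5, alpha5, rho5, 500L)
  )
  molecule <- new_molecule(residues)
  tunnel <- new_tunnel_profile(data.frame(
    t = c(0, 0.25, 0.5, 0.75, 1),
    x = c(1.5, 2.5, 3.5, 4.5, 5.5),
    y = -0.7, z = 2,
    r = c(0.9, 0.7, 0.5, 0.7, 0.9)
  ))
  assert_worked_example(molecule, tunnel)
  list(molecule = molecule, tunnel = tunnel, step = 120)
}

# Internal consistency check: the geometric fixture must realize the
# abstract relations exactly.
assert_worked_example <- function(molecule, tunnel) {
  rotamer_sets <- build_rotamer_sets(molecule, step = 120)
  adjacent <- tunnel_adjacent_residues(molecule, rotamer_sets, tunnel)
  if (!identical(adjacent$residues, c("A:2", "A:3", "A:5"))) {
    stop("worked example fixture: tunnel-adjacent set is not {A:2, A:3, A:5}")
  }
  pruned <- remove_invalid_rotamers(adjacent, molecule)
  log <- attr(pruned, "removal_log")
  removed <- sort(paste0(log$residue, ".R", log$rotamer))
  if (!identical(removed, c("A:2.R0", "A:3.R2"))) {
    stop("worked example fixture: pruning removed {",
         paste(removed, collapse = ", "), "} instead of {A:2.R0, A:3.R2}")
  }
  hits <- list()
  keys <- pruned$residues
  for (i in 1:2) {
    for (j in (i + 1L):3L) {
      for (rx in pruned$rotamer_sets[[i]]$rotamers) {
        for (ry in pruned$rotamer_sets[[j]]$rotamers) {
          if (collide_sets(rx$xyz, rx$radii, ry$xyz, ry$radii)) {
            hits[[length(hits) + 1L]] <- c(
              rotamer_vertex(keys[i], rx$index),
              rotamer_vertex(keys[j], ry$index)
            )
          }
        }
      }
    }
  }
  got <- sort(vapply(hits, paste, character(1L), collapse = "~"))
  want <- sort(c("A:2.R2~A:3.R0", "A:2.R2~A:5.R1", "A:3.R1~A:5.R0"))
  if (!identical(got, want)) {
    stop("worked example fixture: planted collision matrix not realized; ",
         "got {", paste(got, collapse = ", "), "}")
  }
  invisible(TRUE)
}

# --- randomized toys -------------------------------------------------------

unit <- function(v) v / sqrt(sum(v^2))

random_unit <- function() unit(stats::rnorm(3L))

toy_centerline <- function(t, length_x) {
  amp <- 0.12 * length_x # scale-invariant bend
  cbind(length_x * t, amp * sin(pi * t), 0.5 * amp * sin(2 * pi * t))
}

toy_frame <- function(t, length_x) {
  amp <- 0.12 * length_x
  tang <- unit(c(length_x, amp * pi * cos(pi * t),
                 amp * pi * cos(2 * pi * t)))
  up <- c(0, 0, 1)
  n1 <- unit(c(
    tang[2L] * up[3L] - tang[3L] * up[2L],
    tang[3L] * up[1L] - tang[1L] * up[3L],
    tang[1L] * up[2L] - tang[2L] * up[1L]
  ))
  n2 <- c(
    tang[2L] * n1[3L] - tang[3L] * n1[2L],
    tang[3L] * n1[1L] - tang[1L] * n1[3L],
    tang[1L] * n1[2L] - tang[2L] * n1[1L]
  )
  list(tangent = tang, n1 = n1, n2 = n2)
}

toy_residue_from_draw <- function(draw, resno, length_x, table) {
  fr <- toy_frame(draw$t, length_x)
  center <- as.numeric(toy_centerline(draw$t, length_x))
  u <- cos(draw$phi) * fr$n1 + sin(draw$phi) * fr$n2
  ca <- center + (1.0 + 1.2 + draw$d) * u
  w <- unit(u + 0.65 * draw$w_jit)
  # backbone runs tangentially along the tunnel (N and C on opposite
  # sides, O trailing C away from the side chain): it neither dips into
  # the tube nor sits under the rotating arm, so the arm keeps valid
  # poses while backbone-backbone crowding still prunes some rotamers
  perp <- function(v) unit(v - sum(v * w) * w)
  tang <- unit(fr$tangent - sum(fr$tangent * w) * w)
  n_dir <- unit(tang - 0.45 * w + 0.25 * perp(draw$n_dir))
  c_dir <- unit(-tang - 0.45 * w + 0.25 * perp(draw$c_dir))
  o_dir <- unit(-tang - 0.35 * w + 0.1 * perp(draw$o_dir))
  coords <- rbind(
    ca + 1.45 * n_dir,     # N
    ca,                    # CA
    ca + 1.52 * c_dir,     # C
    ca + 1.52 * c_dir + 1.23 * o_dir # O
  )
  names_mc <- c("N", "CA", "C", "O")
  cb <- ca + 1.53 * w
  side <- list(cb)
  side_names <- "CB"
  # fluorine-sized arm spheres (1.47 A): with full carbon radii the forced
  # gamma-versus-backbone contact of a compact pseudo-residue would leave
  # almost no admissible pose at coarse rotamer steps
  arm_names <- c("FG", "FD", "FE", "FZ", "FH", "FQ", "FT")
  # the arm bends well off the axis in one persistent direction, so its
  # rotation circle is wide: rotamers genuinely sweep space instead of
  # clustering near the axis where a single obstacle would veto them all
  bend <- perp(draw$arm_jit[[1L]])
  pos <- cb
  for (k in seq_len(draw$n_arm)) {
    kick <- if (k == 1L) 0 else 0.3 * perp(draw$arm_jit[[k]])
    pos <- pos + 1.8 * unit(w + 1.1 * bend + kick)
    side[[length(side) + 1L]] <- pos
    side_names <- c(side_names, arm_names[k])
  }
  xyz <- round(rbind(coords, do.call(rbind, side)), 3L)
  el <- c("N", "C", "C", "O", "C", rep("F", length(side) - 1L))
  atoms <- toy_atom_table(
    serial = (resno - 1L) * 20L + seq_len(nrow(xyz)),
    name = c(names_mc, side_names), element = el, xyz = xyz,
    radius = unname(table[el])
  )
  partition_residue(atoms, "LYS", chain = "A", resno = resno)
}

toy_build <- function(draws, n, length_x, table) {
  new_molecule(lapply(seq_len(n), function(i) {
    toy_residue_from_draw(draws[[i]], i, length_x, table)
  }))
}

bsv_overlap_fraction <- function(molecule, step) {
  sets <- build_rotamer_sets(molecule, step = step)
  bsvs <- lapply(sets, `[[`, "bsv")
  n <- length(bsvs)
  if (n < 2L) return(0)
  hits <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (spheres_collide(bsvs[[i]], bsvs[[j]])) hits <- hits + 1L
    }
  }
  hits / (n * (n - 1L) / 2L)
}

#' Randomized toy molecule and tunnel with planted collision structure
#'
#' Generates a seeded, reproducible toy system: `n_residues`
#' pseudo-residues (four main-chain atoms plus a short side-chain arm with
#' a genuine C-alpha/C-beta axis) scattered around a curved tunnel
#' centerline. The `packing` knob targets the fraction of residue pairs
#' whose BSVs overlap: the generator scales the centerline length (and
#' with it the inter-residue spacing) by bisection until the achieved
#' fraction is within 0.2 of the target (`packing = 0` demands exactly
#' none). Tunnel radii are clamped below the identity-pose clearance, so
#' the initial tunnel is collision-free by construction. Draws that leave
#' some residue with no valid rotamer are retried a bounded number of
#' times; persistent failure raises an "infeasible packing" error.
#'
#' @param n_residues Number of pseudo-residues.
#' @param atoms_per_side_chain Side-chain atoms per residue (incl. CB).
#' @param packing Target BSV-overlap fraction in [0, 1].
#' @param seed Integer seed; same seed, same toy, bit for bit.
#' @param tunnel_samples Number of swept-ball samples.
#' @param step Rotamer step used for BSV calibration and pruning checks.
#' @return List with `molecule`, `tunnel`, `spec`, `packing_achieved`.
#' @export
random_toy <- function(n_residues, atoms_per_side_chain = 2L,
                       packing = 0.3, seed = 1L, tunnel_samples = 8L,
                       step = 30) {
  stopifnot(n_residues >= 1L, atoms_per_side_chain >= 1L,
            packing >= 0, packing <= 1, tunnel_samples >= 2L)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  table <- default_radius_table()
  n <- n_residues
  base_length <- 5 * max(n, 2L)

  for (attempt in seq_len(16L)) {
    # residues cluster around one side of the tube: a shared base azimuth
    # with moderate spread lets neighbouring arms genuinely reach each
    # other, which is what plants rotamer-level collision structure
    phi0 <- stats::runif(1L, 0, 2 * pi)
    draws <- lapply(seq_len(n), function(i) {
      list(
        t = (i - 0.5) / n + stats::runif(1L, -0.2, 0.2) / n,
        phi = phi0 + stats::rnorm(1L, 0, 0.8),
        d = stats::runif(1L, 0.7, 1.6),
        w_jit = random_unit(), n_dir = random_unit(),
        c_dir = random_unit(), o_dir = random_unit(),
        n_arm = atoms_per_side_chain - 1L,
        arm_jit = replicate(max(atoms_per_side_chain - 1L, 1L),
                            random_unit(), simplify = FALSE)
      )
    })
    radius_phase <- stats::runif(1L, 0, 2 * pi)

    # bisection on the centerline scale toward the packing target
    lo <- 0.25; hi <- 12
    gamma <- 1
    best <- NULL
    for (it in seq_len(28L)) {
      gamma <- (lo + hi) / 2
      mol <- toy_build(draws, n, base_length * gamma, table)
      frac <- bsv_overlap_fraction(mol, step)
      d_new <- abs(frac - packing)
      # ties prefer the roomier layout: overlap fractions plateau in gamma,
      # and a longer centerline keeps the identity-pose tunnel clearances
      # comfortable
      if (is.null(best) || d_new < abs(best$frac - packing) ||
          (d_new == abs(best$frac - packing) && gamma > best$gamma)) {
        best <- list(gamma = gamma, frac = frac, mol = mol)
      }
      if (frac > packing) lo <- gamma else hi <- gamma
    }
    if (packing == 0) {
      # back off from the just-barely-disjoint boundary
      gamma <- best$gamma * 1.25
      mol <- toy_build(draws, n, base_length * gamma, table)
      if (bsv_overlap_fraction(mol, step) == 0) {
        best <- list(gamma = gamma, frac = 0, mol = mol)
      }
    }
    ok_packing <- if (packing == 0) best$frac == 0 else
      abs(best$frac - packing) <= 0.2
    if (!ok_packing) next
    molecule <- best$mol
    length_x <- base_length * best$gamma

    ts <- seq(0, 1, length.out = tunnel_samples)
    centers <- round(toy_centerline(ts, length_x), 3L)
    nominal <- 1.0 + 0.3 * sin(2 * pi * ts + radius_phase)
    all_atoms <- molecule_atoms(molecule)
    clear <- clearance_to(centers, atom_xyz(all_atoms), all_atoms$radius)
    radii <- round(pmin(nominal, 0.95 * clear), 4L)
    if (any(radii < 0.15)) next
    tunnel <- new_tunnel_profile(data.frame(
      t = ts, x = centers[, 1L], y = centers[, 2L], z = centers[, 3L],
      r = radii
    ))

    sets <- build_rotamer_sets(molecule, step = step)
    adjacent <- tryCatch(
      remove_invalid_rotamers(
        tunnel_adjacent_residues(molecule, sets, tunnel), molecule
      ),
      error = function(e) NULL
    )
    if (is.null(adjacent)) next
    return(list(
      molecule = molecule, tunnel = tunnel,
      spec = list(n_residues = n_residues,
                  atoms_per_side_chain = atoms_per_side_chain,
                  packing = packing, seed = seed,
                  tunnel_samples = tunnel_samples, step = step),
      packing_achieved = best$frac
    ))
  }
  stop("random_toy: infeasible packing after bounded retries ",
       "(seed ", seed, ", packing ", packing, ")")
}

# Minimal fixed-width PDB writer for toy molecules (synthetic fixtures
# only; writing PDB is otherwise out of scope).
write_toy_pdb <- function(molecule, path) {
  lines <- character(0)
  for (res in molecule$residues) {
    atoms <- rbind(res$main_chain, res$side_chain)
    for (i in seq_len(nrow(atoms))) {
      nm <- atoms$name[i]
      nm4 <- if (nchar(nm) <= 3L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        atoms$serial[i], nm4, res$type, res$chain, res$resno,
        atoms$x[i], atoms$y[i], atoms$z[i], 1.00, 0.00, atoms$element[i]
      ))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a toy system to disk
#'
#' Emits `molecule.pdb`, `tunnel.tsv` and `provenance.json` (the generating
#' spec and seed) so that the file-reading paths can be exercised against
#' generated data.
#'
#' @param toy A [random_toy()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
make_toy_files <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_toy_pdb(toy$molecule, file.path(dir, "molecule.pdb"))
  write_tunnel(toy$tunnel, file.path(dir, "tunnel.tsv"))
  jsonlite::write_json(
    c(toy$spec, list(packing_achieved = toy$packing_achieved,
                     generator = "tunnelflex::random_toy")),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
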