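# Independent oracles, deliberately written as plain loops against the
# definitions, not via the package's internal code paths.

# Maximal cliques by 2^n subset enumeration (n <= ~15).
oracle_cliques <- function(vertices, edges) {
  vertices <- sort(vertices)
  n <- length(vertices)
  has_edge <- function(a, b) {
    any((edges[, 1L] == a & edges[, 2L] == b) |
          (edges[, 1L] == b & edges[, 2L] == a))
  }
  is_clique <- function(idx) {
    if (length(idx) < 2L) return(TRUE)
    for (i in seq_len(length(idx) - 1L)) {
      for (j in (i + 1L):length(idx)) {
        if (!has_edge(vertices[idx[i]], vertices[idx[j]])) return(FALSE)
      }
    }
    TRUE
  }
  subsets <- lapply(seq_len(2^n - 1L), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
  })
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(s) {
    !any(vapply(cliques, function(o) {
      length(o) > length(s) && all(s %in% o)
    }, logical(1L)))
  }, cliques)
  out <- lapply(maximal, function(idx) vertices[idx])
  out[order(vapply(out, paste, character(1L), collapse = "\r"))]
}

# Discrete local-minimum bottlenecks straight from the definition, with the
# plateau-at-first-sample rule: for each interior index find the enclosing
# run of equal radii and compare against the nearest differing neighbours.
oracle_bottleneck_indices <- function(r) {
  n <- length(r)
  out <- integer(0)
  for (i in seq_len(n)) {
    a <- i
    while (a > 1L && r[a - 1L] == r[i]) a <- a - 1L
    b <- i
    while (b < n && r[b + 1L] == r[i]) b <- b + 1L
    if (i != a) next            # only the first sample of a plateau
    if (a == 1L || b == n) next # endpoints are never bottlenecks
    if (r[a - 1L] > r[i] && r[b + 1L] > r[i]) out <- c(out, i)
  }
  out
}

# All atoms of one rotamer choice for one residue, as xyz/radii.
rotamer_atoms_of <- function(adjacent, i, index) {
  rs <- adjacent$rotamer_sets[[i]]
  for (rot in rs$rotamers) if (rot$index == index) return(rot)
  stop("no such rotamer")
}

# TRUE when a fully assigned conformation has zero inter-residue atom
# collisions (strict sphere overlap), checked pair by pair.
oracle_conformation_valid <- function(conformation, adjacent, tol = 1e-9) {
  n <- adjacent$n
  if (n < 2L) return(TRUE)
  rots <- lapply(seq_len(n), function(i) {
    rotamer_atoms_of(adjacent, i, conformation[i])
  })
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- rots[[i]]; b <- rots[[j]]
      if (nrow(a$xyz) == 0L || nrow(b$xyz) == 0L) next
      for (p in seq_len(nrow(a$xyz))) {
        for (q in seq_len(nrow(b$xyz))) {
          d2 <- sum((a$xyz[p, ] - b$xyz[q, ])^2)
          if (d2 < (a$radii[p] + b$radii[q])^2 - tol) return(FALSE)
        }
      }
    }
  }
  TRUE
}

# A single free-standing synthetic rotatable residue for unit tests: CA at
# `base`, vertical CA-CB axis, one arm atom `rho` off the axis.
test_residue <- function(base = c(0, 0, 0), rho = 2, resno = 1L,
                         radius = 0.5, arm_z = 2) {
  atoms <- data.frame(
    serial = 1:6,
    name = c("N", "CA", "C", "O", "CB", "SG"),
    element = "C",
    x = base[1L] + c(-1.2, 0, 1.2, 1.8, 0, rho),
    y = base[2L] + c(0.3, 0, 0.3, 1.3, 0, 0),
    z = base[3L] + c(0, 0, 0, 0, 1, arm_z),
    radius = radius,
    stringsAsFactors = FALSE
  )
  partition_residue(atoms, "CYS", chain = "A", resno = resno)
}

# Seeded toy configurations that the generator can realize (n = 2 only
# with extreme packings, since a single pair has overlap fraction 0 or 1).
toy_case_table <- function() {
  data.frame(
    seed = 1:20,
    n = c(3, 4, 5, 3, 3, 4, 5, 2, 3, 4, 3, 5, 3, 4, 3, 5, 4, 3, 2, 4),
    arm = c(2, 3, 1, 3, 1, 1, 2, 3, 1, 2, 2, 1, 2, 2, 2, 2, 1, 3, 1, 3),
    pack = c(0.5, 0.8, 0.2, 0.8, 0.2, 0.2, 0.5, 0.8, 0.2, 0.5,
             0.6, 0.3, 0.6, 0.4, 0.6, 0.4, 0.3, 0.7, 0, 0.5),
    step = c(90, 90, 90, 90, 90, 90, 90, 90, 90, 90,
             30, 90, 30, 90, 30, 90, 120, 90, 30, 90)
  )
}

make_toy_case <- function(row) {
  random_toy(row$n, row$arm, packing = row$pack, seed = row$seed,
             tunnel_samples = 8L, step = row$step)
}
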