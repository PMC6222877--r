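# Graphs are lists: list(vertices = character, edges = 2-column character
# matrix with each row sorted, kind = "temporary" | "collision" | "rotamer").

new_graph <- function(vertices, edges, kind) {
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- t(apply(edges, 1L, sort))
    if (ncol(edges) != 2L) edges <- matrix(edges, ncol = 2L) # 1-row apply quirk
    edges <- edges[!duplicated(paste(edges[, 1L], edges[, 2L])), ,
                   drop = FALSE]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  structure(list(vertices = vertices, edges = edges, kind = kind),
            class = "tf_graph")
}

graph_has_edge <- function(graph, a, b) {
  e <- graph$edges
  v <- sort(c(a, b))
  any(e[, 1L] == v[1L] & e[, 2L] == v[2L])
}

#' Temporary BSV-overlap graph over the adjacent set
#'
#' Vertices are the tunnel-adjacent residues; an edge joins two residues
#' whose bounding sphere volumes collide. The graph is a cheap broad-phase
#' filter: pairs without an edge cannot have any colliding rotamer pair, so
#' only its edges need the exact rotamer-level scan.
#'
#' @param adjacent Adjacent set with BSVs.
#' @param tol Collision tolerance, squared Angstrom.
#' @return A residue graph of kind `"temporary"`.
#' @export
build_temporary_graph <- function(adjacent, tol = 1e-9) {
  keys <- adjacent$residues
  bsvs <- lapply(adjacent$rotamer_sets, `[[`, "bsv")
  pairs <- list()
  if (length(keys) >= 2L) {
    for (i in seq_len(length(keys) - 1L)) {
      for (j in (i + 1L):length(keys)) {
        if (spheres_collide(bsvs[[i]], bsvs[[j]], tol)) {
          pairs[[length(pairs) + 1L]] <- c(keys[i], keys[j])
        }
      }
    }
  }
  new_graph(keys, do.call(rbind, pairs), "temporary")
}

# TRUE when any rotamer of set_x collides with any rotamer of set_y.
rotamer_sets_collide <- function(set_x, set_y, tol = 1e-9) {
  for (rx in set_x$rotamers) {
    for (ry in set_y$rotamers) {
      if (collide_sets(rx$xyz, rx$radii, ry$xyz, ry$radii, tol)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Collision graph over the adjacent set
#'
#' For each edge of the temporary graph only, all rotamer pairs between the
#' two residues are scanned at atom level; a collision-graph edge records
#' that at least one pair collides. Pairs without a temporary-graph edge
#' are never scanned (the BSV guarantee makes the filter lossless).
#'
#' @param adjacent Adjacent set (normally pruned).
#' @param tg Temporary graph from [build_temporary_graph()].
#' @param tol Collision tolerance, squared Angstrom.
#' @return A residue graph of kind `"collision"`; its edge set is a subset
#'   of the temporary graph's.
#' @export
build_collision_graph <- function(adjacent, tg, tol = 1e-9) {
  keep <- logical(nrow(tg$edges))
  for (k in seq_len(nrow(tg$edges))) {
    x <- tg$edges[k, 1L]; y <- tg$edges[k, 2L]
    keep[k] <- rotamer_sets_collide(adjacent$rotamer_sets[[x]],
                                    adjacent$rotamer_sets[[y]], tol)
  }
  new_graph(adjacent$residues, tg$edges[keep, , drop = FALSE], "collision")
}

#' Maximal cliques of an undirected graph (Bron-Kerbosch with pivoting)
#'
#' Enumerates exactly the maximal complete subgraphs. Isolated vertices
#' yield singleton cliques. The pivot is the candidate with the most
#' neighbours in P, ties broken by sorted vertex order, and output is
#' deterministic: each clique sorted, cliques in lexicographic order.
#'
#' @param graph A graph: list with `vertices` (character) and `edges`
#'   (2-column character matrix).
#' @return List of character vectors, one per maximal clique.
#' @export
maximal_cliques <- function(graph) {
  verts <- sort(graph$vertices)
  n <- length(verts)
  if (n == 0L) return(list())
  adj <- matrix(FALSE, n, n)
  if (nrow(graph$edges) > 0L) {
    i <- match(graph$edges[, 1L], verts)
    j <- match(graph$edges[, 2L], verts)
    if (anyNA(i) || anyNA(j)) stop("edge endpoint not in vertex set")
    adj[cbind(i, j)] <- TRUE
    adj[cbind(j, i)] <- TRUE
  }
  out <- list()
  n_out <- 0L
  emit <- function(clq) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- clq # lists auto-grow; amortized fine at these sizes
  }
  bk <- function(r, p, x) {
    if (length(p) == 0L && length(x) == 0L) {
      emit(sort(r))
      return(invisible())
    }
    cand <- c(p, x)
    deg <- vapply(cand, function(u) sum(adj[u, p]), integer(1L))
    pivot <- cand[which.max(deg)] # cand ascends p then x; ties -> lowest
    for (v in p[!adj[pivot, p]]) {
      nb <- which(adj[v, ])
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  out <- out[seq_len(n_out)]
  cliques <- lapply(out, function(ii) verts[ii])
  keys <- vapply(cliques, paste, character(1L), collapse = "\r")
  cliques[order(keys)]
}

#' Amino-collision cliques of the collision graph
#'
#' The maximal cliques of the collision graph localize every possible
#' rotamer conflict: two residues in different cliques (and outside the
#' cliques' intersection) are guaranteed to share no colliding rotamer
#' pair. A residue may belong to several cliques; consistency across
#' overlapping cliques is enforced later when local conformations are
#' combined.
#'
#' @param cg Collision graph.
#' @return List of cliques, each a list with `index` and `members`.
#' @export
amino_collision_cliques <- function(cg) {
  cl <- maximal_cliques(cg)
  lapply(seq_along(cl), function(k) list(index = k, members = cl[[k]]))
}

rotamer_vertex <- function(key, index) sprintf("%s.R%d", key, index)

parse_rotamer_vertex <- function(v) {
  m <- regmatches(v, regexec("^(.*)\\.R(\\d+)$", v))
  lapply(m, function(parts) {
    if (length(parts) != 3L) stop("malformed rotamer vertex label: ", v)
    list(key = parts[2L], index = as.integer(parts[3L]))
  })
}

#' Collision-free rotamer graph of one amino-collision clique
#'
#' Vertices are all surviving rotamers of the clique members (labelled
#' `"<residue>.R<index>"`); an edge joins two rotamers of different
#' residues exactly when no atom pair between them collides.
#'
#' @param clique A clique from [amino_collision_cliques()].
#' @param adjacent The pruned adjacent set.
#' @param tol Collision tolerance, squared Angstrom.
#' @return A graph of kind `"rotamer"` with the clique attached as
#'   attribute `"clique"`.
#' @export
build_collision_free_graph <- function(clique, adjacent, tol = 1e-9) {
  members <- sort(clique$members)
  sets <- adjacent$rotamer_sets[members]
  verts <- unlist(lapply(members, function(key) {
    vapply(sets[[key]]$rotamers, function(rot) {
      rotamer_vertex(key, rot$index)
    }, character(1L))
  }))
  pairs <- list()
  if (length(members) >= 2L) {
    for (i in seq_len(length(members) - 1L)) {
      for (j in (i + 1L):length(members)) {
        for (rx in sets[[i]]$rotamers) {
          for (ry in sets[[j]]$rotamers) {
            if (!collide_sets(rx$xyz, rx$radii, ry$xyz, ry$radii, tol)) {
              pairs[[length(pairs) + 1L]] <- c(
                rotamer_vertex(members[i], rx$index),
                rotamer_vertex(members[j], ry$index)
              )
            }
          }
        }
      }
    }
  }
  g <- new_graph(verts, do.call(rbind, pairs), "rotamer")
  attr(g, "clique") <- clique
  g
}

#' Local valid conformations of one amino-collision clique
#'
#' Runs maximal-clique enumeration on the collision-free graph and keeps
#' only cliques whose vertex count equals the number of clique members:
#' those necessarily pick exactly one rotamer per residue and are the local
#' valid conformations. Smaller maximal cliques mean some residue cannot
#' join compatibly and are rejected. A singleton residue clique yields one
#' conformation per surviving rotamer.
#'
#' @param fg Collision-free graph from [build_collision_free_graph()].
#' @param clique The amino-collision clique behind `fg`.
#' @param adjacent The pruned adjacent set (defines vector positions).
#' @return List with `clique_index`, `members`, `conformations` (integer
#'   matrix, one row per conformation, -1 sentinel outside the clique) and
#'   `count`.
#' @export
local_valid_conformations <- function(fg, clique, adjacent) {
  members <- sort(clique$members)
  cliques <- maximal_cliques(fg)
  full <- cliques[vapply(cliques, length, integer(1L)) == length(members)]
  conf <- matrix(-1L, nrow = length(full), ncol = adjacent$n)
  for (r in seq_along(full)) {
    for (part in parse_rotamer_vertex(full[[r]])) {
      pos <- match(part$key, adjacent$residues)
      conf[r, pos] <- part$index
    }
  }
  if (nrow(conf) > 1L) {
    conf <- conf[do.call(order, as.data.frame(conf)), , drop = FALSE]
  }
  list(clique_index = clique$index, members = members,
       conformations = conf, count = nrow(conf))
}
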