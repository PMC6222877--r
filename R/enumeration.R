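# A conformation vector is an integer vector over the adjacent-set order:
# entry >= 0 is a 0-based rotamer index, -1 means "unconstrained here".

#' Compatibility of two (partial) conformation vectors
#'
#' Two vectors are compatible when no position carries two different
#' non-sentinel rotamer indices. Rotamer index 0 (the input pose) is a
#' regular assignment, so the test is on "both entries non-negative", not
#' "both positive".
#'
#' @param a,b Integer conformation vectors of equal length.
#' @return Logical scalar.
#' @export
compatible <- function(a, b) {
  if (length(a) != length(b)) {
    stop("conformation vectors differ in length")
  }
  !any(a >= 0L & b >= 0L & a != b)
}

#' Merge two compatible conformation vectors
#'
#' Per position: the non-sentinel value when either side has one, else -1.
#'
#' @param a,b Compatible conformation vectors.
#' @return The merged conformation vector.
#' @export
merge_conformations <- function(a, b) {
  if (!compatible(a, b)) {
    stop("cannot merge incompatible conformation vectors")
  }
  ifelse(a >= 0L, a, b)
}

new_global_set <- function(conformations, n) {
  if (is.null(conformations) || length(conformations) == 0L) {
    conformations <- matrix(integer(0), ncol = n)
  }
  if (nrow(conformations) > 0L) {
    conformations <- conformations[
      !duplicated(apply(conformations, 1L, paste, collapse = ",")), ,
      drop = FALSE]
    conformations <- conformations[
      do.call(order, as.data.frame(conformations)), , drop = FALSE]
  }
  rownames(conformations) <- NULL
  structure(list(conformations = conformations,
                 count = nrow(conformations)),
            class = "tf_global_set")
}

#' @export
print.tf_global_set <- function(x, ...) {
  cat("global valid conformations:", x$count, "over",
      ncol(x$conformations), "residues\n")
  invisible(x)
}

#' Combine local valid conformations into global ones
#'
#' Depth-first recursion over the amino-collision cliques (largest member
#' count first, a pure performance choice): at each level every local
#' conformation of the clique is merged into the partial assignment, and a
#' branch is pruned as soon as the compatibility test fails. At the last
#' level the fully merged vector is emitted. Because every residue of the
#' adjacent set belongs to at least one clique (isolated residues form
#' singleton cliques), emitted vectors are fully assigned. Overlapping
#' cliques can reach the same assignment along different branches, so the
#' output is deduplicated and sorted; memory grows with the number of
#' local conformations, not with their product.
#'
#' @param local_sets List of [local_valid_conformations()] results, one per
#'   amino-collision clique.
#' @param adjacent The pruned adjacent set.
#' @param max_conformations Abort (with an error) when more than this many
#'   global conformations accumulate.
#' @return Global conformation set: deduplicated, sorted integer matrix.
#' @export
combine_all <- function(local_sets, adjacent,
                        max_conformations = Inf) {
  n <- adjacent$n
  covered <- sort(unique(unlist(lapply(local_sets, `[[`, "members"))))
  missing <- setdiff(adjacent$residues, covered)
  if (length(missing)) {
    stop("local conformation sets do not cover residue(s): ",
         paste(missing, collapse = ", "))
  }
  m <- length(local_sets)
  ord <- order(-vapply(local_sets, function(s) length(s$members),
                       integer(1L)))
  acc <- list()
  n_acc <- 0L
  rec <- function(level, pre) {
    confs <- local_sets[[ord[level]]]$conformations
    for (r in seq_len(nrow(confs))) {
      cur <- confs[r, ]
      if (any(pre >= 0L & cur >= 0L & pre != cur)) next # prune branch
      upd <- ifelse(pre >= 0L, pre, cur)
      if (level == m) {
        n_acc <<- n_acc + 1L
        if (n_acc > max_conformations) {
          stop("more than max_conformations = ", max_conformations,
               " global conformations; raise the cap to enumerate them")
        }
        acc[[n_acc]] <<- upd
      } else {
        rec(level + 1L, upd)
      }
    }
  }
  if (m > 0L && all(vapply(local_sets, `[[`, integer(1L), "count") > 0L)) {
    rec(1L, rep(-1L, n))
  }
  new_global_set(do.call(rbind, acc), n)
}

#' Brute-force enumeration of all valid conformations
#'
#' Verification oracle: walks the full Cartesian product of surviving
#' rotamer indices and keeps exactly the tuples with zero inter-residue
#' atom collisions. Independent of the graph/clique pipeline, so agreement
#' with [combine_all()] is a meaningful check. Guarded by a candidate
#' bound since the product space grows as fast as 12^n.
#'
#' @param adjacent The pruned adjacent set.
#' @param tol Collision tolerance, squared Angstrom.
#' @param max_candidates Error out when the product space exceeds this.
#' @return Global conformation set, same form as [combine_all()].
#' @export
brute_force_enumerate <- function(adjacent, tol = 1e-9,
                                  max_candidates = 1e6) {
  sets <- adjacent$rotamer_sets
  n <- adjacent$n
  counts <- vapply(sets, function(s) length(s$rotamers), integer(1L))
  if (prod(counts) > max_candidates) {
    stop("candidate space ", prod(counts), " exceeds max_candidates = ",
         max_candidates)
  }
  # pairwise validity tables over surviving-rotamer positions
  valid <- vector("list", n * n)
  dim(valid) <- c(n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- matrix(TRUE, counts[i], counts[j])
        for (a in seq_len(counts[i])) {
          ra <- sets[[i]]$rotamers[[a]]
          for (b in seq_len(counts[j])) {
            rb <- sets[[j]]$rotamers[[b]]
            v[a, b] <- !collide_sets(ra$xyz, ra$radii, rb$xyz, rb$radii,
                                     tol)
          }
        }
        valid[[i, j]] <- v
      }
    }
  }
  grid <- as.matrix(expand.grid(lapply(counts, seq_len),
                                KEEP.OUT.ATTRS = FALSE))
  keep <- rep(TRUE, nrow(grid))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        keep <- keep & valid[[i, j]][cbind(grid[, i], grid[, j])]
      }
    }
  }
  grid <- grid[keep, , drop = FALSE]
  # map survivor positions back to original 0-based rotamer indices
  idx <- lapply(sets, rotamer_indices)
  conf <- vapply(seq_len(n), function(i) idx[[i]][grid[, i]],
                 integer(nrow(grid)))
  if (nrow(grid) == 1L) conf <- matrix(conf, nrow = 1L)
  if (nrow(grid) == 0L) conf <- matrix(integer(0), ncol = n)
  new_global_set(conf, n)
}
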