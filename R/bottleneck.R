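#' Bottleneck analysis over all global conformations
#'
#' For every global valid conformation the tunnel is recomputed along its
#' fixed centerline ([recompute_tunnel()]) and its minimum bottleneck
#' radius is recorded. The maximum of those minima is the maximum
#' bottleneck: the largest spherical ligand that can pass through the
#' flexibly deformed tunnel. The min/mean/max summary describes the spread
#' of the per-conformation bottlenecks; a value of 0 means that
#' conformation blocks the tunnel completely.
#'
#' The clearance at each sample decomposes into a static part and a
#' per-residue, per-rotamer part, so each is computed once and the per-
#' conformation profile is assembled by table lookup. The result is
#' identical to calling [recompute_tunnel()] conformation by conformation.
#'
#' @param tunnel A tunnel profile.
#' @param globals Global conformation set from [combine_all()] (non-empty).
#' @param adjacent The pruned adjacent set.
#' @param molecule The molecule.
#' @param r_cap Clearance cap, as in [recompute_tunnel()].
#' @return A bottleneck report: `per_conformation` (named numeric vector,
#'   ids are row indices of the sorted global set), `max_bottleneck`,
#'   `argmax_conformation` (lowest id on ties), and `summary`.
#' @export
analyze_bottlenecks <- function(tunnel, globals, adjacent, molecule,
                                r_cap = 2 * max(tunnel$samples$r)) {
  if (is.null(globals$count) || globals$count == 0L) {
    stop("no global conformations to analyze")
  }
  centers <- as.matrix(tunnel$samples[, c("x", "y", "z")])
  st <- static_obstacles(molecule, adjacent)
  static_clear <- clearance_to(centers, st$xyz, st$radius)
  # clearance table: per residue, per surviving rotamer, per sample
  clear_tab <- lapply(seq_len(adjacent$n), function(i) {
    rs <- adjacent$rotamer_sets[[i]]
    t(vapply(rs$rotamers, function(rot) {
      clearance_to(centers, rot$xyz, rot$radii)
    }, numeric(nrow(centers))))
  })
  idx_maps <- lapply(adjacent$rotamer_sets, rotamer_indices)
  per <- numeric(globals$count)
  for (cid in seq_len(globals$count)) {
    conf <- globals$conformations[cid, ]
    clear <- static_clear
    for (i in seq_len(adjacent$n)) {
      pos <- match(conf[i], idx_maps[[i]])
      clear <- pmin(clear, clear_tab[[i]][pos, ])
    }
    r_new <- pmin(pmax(clear, 0), r_cap)
    idx <- bottleneck_indices(r_new)
    per[cid] <- if (length(idx)) min(r_new[idx]) else min(r_new)
  }
  names(per) <- as.character(seq_len(globals$count))
  structure(
    list(
      per_conformation = per,
      max_bottleneck = max(per),
      argmax_conformation = unname(which.max(per)), # ties: lowest id
      summary = c(min = min(per), mean = mean(per), max = max(per))
    ),
    class = "tf_bottleneck_report"
  )
}

#' @export
print.tf_bottleneck_report <- function(x, ...) {
  cat("bottleneck report over", length(x$per_conformation),
      "conformations\n")
  cat(sprintf("  max bottleneck: %.3f A (conformation %d)\n",
              x$max_bottleneck, x$argmax_conformation))
  cat(sprintf("  min / mean / max of per-conformation bottlenecks: %.3f / %.3f / %.3f A\n",
              x$summary[["min"]], x$summary[["mean"]], x$summary[["max"]]))
  invisible(x)
}
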