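# The tunnel dialect: a TSV file with header `t x y z r` (one swept-ball
# sample per row, coordinates and radius in Angstrom, t strictly increasing
# in [0, 1]) or, equivalently, a JSON array of {t, x, y, z, r} objects.

new_tunnel_profile <- function(samples) {
  samples <- as.data.frame(samples)[, c("t", "x", "y", "z", "r")]
  if (nrow(samples) < 2L) stop("a tunnel profile needs at least 2 samples")
  if (anyNA(samples)) stop("tunnel profile contains missing values")
  if (any(diff(samples$t) <= 0)) {
    stop("tunnel parameter t must be strictly increasing")
  }
  if (any(samples$t < 0 | samples$t > 1)) {
    stop("tunnel parameter t must lie in [0, 1]")
  }
  if (any(samples$r <= 0)) stop("tunnel radii must be positive")
  rownames(samples) <- NULL
  structure(list(samples = samples), class = "tf_tunnel")
}

#' Read a tunnel profile
#'
#' Accepts the TSV dialect (header `t x y z r`) or a JSON array of
#' `{t, x, y, z, r}` objects; the format is chosen by file extension
#' (".json") unless given explicitly.
#'
#' @param path Path to the profile file.
#' @param format `"tsv"`, `"json"`, or `"auto"`.
#' @return A tunnel profile: ordered swept-ball samples.
#' @export
read_tunnel <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (!file.exists(path)) stop("cannot read tunnel file: ", path)
  samples <- if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  if (!all(c("t", "x", "y", "z", "r") %in% names(samples))) {
    stop("tunnel file must provide columns t, x, y, z, r")
  }
  new_tunnel_profile(samples)
}

#' Write a tunnel profile
#'
#' Values are written at full double precision so that
#' `read_tunnel(write_tunnel(x))` reproduces the sample list bit-exactly.
#'
#' @param tunnel A tunnel profile.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_tunnel <- function(tunnel, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  s <- tunnel$samples
  if (format == "json") {
    jsonlite::write_json(s, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  } else {
    fmt <- function(v) sprintf("%.17g", v)
    lines <- c(
      "t\tx\ty\tz\tr",
      paste(fmt(s$t), fmt(s$x), fmt(s$y), fmt(s$z), fmt(s$r), sep = "\t")
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
print.tf_tunnel <- function(x, ...) {
  r <- x$samples$r
  cat("tunnel profile:", nrow(x$samples), "samples, radius range [",
      sprintf("%.3f", min(r)), ",", sprintf("%.3f", max(r)), "] A\n")
  invisible(x)
}

#' Write global conformations as TSV or JSON
#'
#' One row per global valid conformation; columns are the tunnel-adjacent
#' residue keys and cells are 0-based rotamer indices.
#'
#' @param globals A [combine_all()] result.
#' @param adjacent The adjacent set that defines the residue order.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_conformations <- function(globals, adjacent, path,
                                format = c("tsv", "json")) {
  format <- match.arg(format)
  m <- globals$conformations
  colnames(m) <- adjacent$residues
  if (format == "json") {
    jsonlite::write_json(
      list(residues = adjacent$residues, conformations = unname(m)),
      path, digits = NA
    )
  } else {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a bottleneck report as JSON
#'
#' @param report An [analyze_bottlenecks()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bottleneck_report <- function(report, path) {
  jsonlite::write_json(
    list(
      per_conformation = report$per_conformation,
      max_bottleneck = report$max_bottleneck,
      argmax_conformation = report$argmax_conformation,
      summary = as.list(report$summary)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
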