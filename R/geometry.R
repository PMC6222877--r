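#' Sphere constructor
#'
#' A sphere is the basic geometric primitive of the package: atoms, bounding
#' sphere volumes (BSVs), and tunnel samples are all spheres.
#'
#' @param center Numeric 3-vector, Angstrom.
#' @param radius Non-negative scalar, Angstrom.
#' @return An object of class `"tf_sphere"`: a list with `center` and `radius`.
#' @export
sphere <- function(center, radius) {
  center <- as.numeric(center)
  radius <- as.numeric(radius)
  if (length(center) != 3L || anyNA(center)) {
    stop("sphere center must be a numeric 3-vector")
  }
  if (length(radius) != 1L || is.na(radius) || radius < 0) {
    stop("sphere radius must be a non-negative scalar")
  }
  structure(list(center = center, radius = radius), class = "tf_sphere")
}

#' Rotation axis through two points
#'
#' For rotatable residues the axis runs from the C-alpha center to the
#' C-beta center.
#'
#' @param point_a,point_b Numeric 3-vectors. Must be distinct.
#' @return An object of class `"tf_axis"`.
#' @export
axis_through <- function(point_a, point_b) {
  point_a <- as.numeric(point_a)
  point_b <- as.numeric(point_b)
  if (length(point_a) != 3L || length(point_b) != 3L) {
    stop("axis points must be numeric 3-vectors")
  }
  if (sqrt(sum((point_b - point_a)^2)) <= 0) {
    stop("degenerate axis: the two points coincide")
  }
  structure(list(point_a = point_a, point_b = point_b), class = "tf_axis")
}

#' Strict sphere-sphere collision test
#'
#' Two spheres collide when the squared distance between their centers is
#' strictly smaller than the squared sum of their radii. Tangency is not a
#' collision. A small tolerance `tol` (applied on the squared-distance scale)
#' keeps floating-point tangency from flipping the outcome.
#'
#' @param s1,s2 Spheres (see [sphere()]).
#' @param tol Non-negative tolerance, squared Angstrom. Default `1e-9`.
#' @return Logical scalar.
#' @export
spheres_collide <- function(s1, s2, tol = 1e-9) {
  if (tol < 0) stop("tol must be non-negative")
  d2 <- sum((s1$center - s2$center)^2)
  d2 < (s1$radius + s2$radius)^2 - tol
}

# Inclusive overlap: non-empty intersection, tangency counts. Used where the
# model asks for set intersection (tunnel adjacency) rather than collision.
spheres_touch <- function(s1, s2, tol = 1e-9) {
  sum((s1$center - s2$center)^2) <= (s1$radius + s2$radius)^2 + tol
}

#' Rigid rotation about an axis
#'
#' Rotates one point (3-vector) or a matrix of row points about the line
#' through `axis`, right-handed about the unit vector from `point_a` to
#' `point_b`, by `angle` degrees (Rodrigues formula).
#'
#' @param p Numeric 3-vector or an n x 3 matrix of points.
#' @param axis A [axis_through()] object.
#' @param angle Rotation angle in degrees.
#' @return Rotated point(s), same shape as `p`.
#' @export
rotate_about_axis <- function(p, axis, angle) {
  k <- axis$point_b - axis$point_a
  nk <- sqrt(sum(k^2))
  if (nk <= 0) stop("degenerate axis")
  k <- k / nk
  was_vector <- is.null(dim(p))
  pm <- if (was_vector) matrix(p, nrow = 1L) else as.matrix(p)
  th <- angle * pi / 180
  v <- sweep(pm, 2L, axis$point_a)
  kdotv <- as.numeric(v %*% k)
  kxv <- cbind(
    k[2L] * v[, 3L] - k[3L] * v[, 2L],
    k[3L] * v[, 1L] - k[1L] * v[, 3L],
    k[1L] * v[, 2L] - k[2L] * v[, 1L]
  )
  out <- v * cos(th) + kxv * sin(th) + outer(kdotv, k) * (1 - cos(th))
  out <- sweep(out, 2L, axis$point_a, "+")
  if (was_vector) as.numeric(out) else out
}

#' Bounding sphere of an atom swept around an axis
#'
#' The smallest sphere centered on the axis that contains the atom sphere at
#' every rotation angle: its center is the orthogonal projection of the atom
#' center onto the axis line, and its radius is the atom's distance from the
#' axis plus the atom radius.
#'
#' @param atom A [sphere()].
#' @param axis A [axis_through()] object.
#' @return A [sphere()] containing every rotated copy of `atom`.
#' @export
swept_bound <- function(atom, axis) {
  a <- axis$point_a
  k <- axis$point_b - a
  nk2 <- sum(k^2)
  if (nk2 <= 0) stop("degenerate axis")
  tproj <- sum((atom$center - a) * k) / nk2
  foot <- a + tproj * k
  d <- sqrt(sum((atom$center - foot)^2))
  sphere(foot, d + atom$radius)
}

#' Near-minimal enclosing sphere of a set of spheres
#'
#' Deterministic Ritter-style two-pass construction over the sphere
#' surfaces: seed the ball on the two mutually farthest surface points
#' (found by two farthest-point sweeps), then grow it over every sphere
#' not yet contained; a final fix-up sets the radius to the exact maximum
#' of `distance(center, center_i) + r_i`, so containment is guaranteed.
#' The result is conservative, not exactly minimal; an oversized bound
#' only weakens the broad-phase filter, never correctness.
#'
#' @param spheres Non-empty list of [sphere()] objects.
#' @return A [sphere()] containing every input sphere.
#' @export
enclosing_sphere <- function(spheres) {
  if (length(spheres) == 0L) stop("enclosing_sphere: empty sphere list")
  centers <- do.call(rbind, lapply(spheres, `[[`, "center"))
  radii <- vapply(spheres, `[[`, numeric(1L), "radius")
  far_surface_point <- function(from) {
    dx <- sweep(centers, 2L, from)
    d <- sqrt(rowSums(dx^2))
    i <- which.max(d + radii) # ties: lowest index, deterministic
    if (d[i] > 0) centers[i, ] + dx[i, ] / d[i] * radii[i]
    else centers[i, ] + c(radii[i], 0, 0)
  }
  p <- far_surface_point(centers[1L, ])
  q <- far_surface_point(p)
  ctr <- (p + q) / 2
  rad <- sqrt(sum((p - q)^2)) / 2
  for (pass in 1:2) {
    for (i in seq_along(radii)) {
      dx <- centers[i, ] - ctr
      d <- sqrt(sum(dx^2))
      need <- d + radii[i]
      if (need > rad && d > 0) {
        grown <- (rad + need) / 2
        ctr <- ctr + dx / d * (grown - rad)
        rad <- grown
      } else if (need > rad) {
        rad <- need
      }
    }
  }
  # polish with a short farthest-point descent (keeping the best center
  # seen): the Ritter seed is close already, so a few dozen steps pull the
  # ball within a percent or two of minimal and keep its size stable under
  # small input changes
  cs2 <- rowSums(centers^2)
  best_ctr <- ctr
  best_rad <- Inf
  for (k in seq_len(61L)) {
    d <- sqrt(pmax(cs2 - 2 * as.numeric(centers %*% ctr) + sum(ctr^2), 0))
    reach <- d + radii
    i <- which.max(reach)
    if (reach[i] < best_rad) {
      best_rad <- reach[i]
      best_ctr <- ctr
    }
    far <- if (d[i] > 0) {
      centers[i, ] + (centers[i, ] - ctr) / d[i] * radii[i]
    } else {
      centers[i, ]
    }
    ctr <- ctr + (far - ctr) / (k + 1)
  }
  sphere(best_ctr, best_rad)
}

# Pairwise collision between two atom sets given as coordinate matrices plus
# radius vectors; returns TRUE on the first strict overlap. `exclude` is an
# optional logical matrix (nrow(m1) x nrow(m2)) of pairs to skip.
collide_sets <- function(m1, r1, m2, r2, tol = 1e-9, exclude = NULL) {
  if (is.null(m1) || is.null(m2) || nrow(m1) == 0L || nrow(m2) == 0L) {
    return(FALSE)
  }
  d2 <- outer(rowSums(m1^2), rowSums(m2^2), "+") - 2 * tcrossprod(m1, m2)
  hit <- d2 < outer(r1, r2, "+")^2 - tol
  if (!is.null(exclude)) hit[exclude] <- FALSE
  any(hit)
}

# As collide_sets(), but returns the (i, j) indices of the first colliding
# pair (row-major over m1), or NULL when the sets are collision-free.
collide_sets_which <- function(m1, r1, m2, r2, tol = 1e-9, exclude = NULL) {
  if (is.null(m1) || is.null(m2) || nrow(m1) == 0L || nrow(m2) == 0L) {
    return(NULL)
  }
  d2 <- outer(rowSums(m1^2), rowSums(m2^2), "+") - 2 * tcrossprod(m1, m2)
  hit <- d2 < outer(r1, r2, "+")^2 - tol
  if (!is.null(exclude)) hit[exclude] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  idx[1L, ]
}
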