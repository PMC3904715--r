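#' Axis-aligned spheroid particles
#'
#' A `spheroid_set` is a plain `data.frame` holding axis-aligned ellipsoids,
#' the geometric primitive of the whole package: chloroplast-like particles
#' (`role = "particle"`) and convex cell bodies (`role = "cell_body"`).
#' Spheroids are never rotated; the z semi-axis `rz` carries the caliper
#' "height" along the sectioning (optical) axis, so a particle's z-caliper is
#' `2 * rz`. Columns: `id`, `parent_id`, `cx`, `cy`, `cz`, `rx`, `ry`, `rz`,
#' `role`.
#'
#' @param id integer ids (unique within a set).
#' @param center numeric length-3 vector, or an n x 3 matrix of centers (um).
#' @param semi_axes numeric length-3 vector, or an n x 3 matrix of positive
#'   semi-axes `(rx, ry, rz)` (um).
#' @param role `"particle"` or `"cell_body"` (recycled).
#' @param parent_id integer id of the hosting cell body for particles, `NA`
#'   otherwise (recycled).
#' @return A `spheroid_set` data.frame.
#' @examples
#' spheroids(1, c(0, 0, 10), c(2.5, 2.5, 2))
#' @export
spheroids <- function(id, center, semi_axes, role = "particle",
                      parent_id = NA_integer_) {
  center <- rbind(center)
  semi_axes <- rbind(semi_axes)
  n <- max(length(id), nrow(center), nrow(semi_axes))
  if (nrow(center) == 1L) center <- center[rep(1L, n), , drop = FALSE]
  if (nrow(semi_axes) == 1L) semi_axes <- semi_axes[rep(1L, n), , drop = FALSE]
  id <- rep_len(as.integer(id), n)
  role <- rep_len(role, n)
  parent_id <- rep_len(as.integer(parent_id), n)
  if (ncol(center) != 3L || ncol(semi_axes) != 3L)
    stop("`center` and `semi_axes` must have 3 columns", call. = FALSE)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("all semi-axes must be positive and finite", call. = FALSE)
  if (anyDuplicated(id))
    stop("spheroid ids must be unique", call. = FALSE)
  if (!all(role %in% c("particle", "cell_body")))
    stop('`role` must be "particle" or "cell_body"', call. = FALSE)
  out <- data.frame(
    id = id, parent_id = parent_id,
    cx = center[, 1], cy = center[, 2], cz = center[, 3],
    rx = semi_axes[, 1], ry = semi_axes[, 2], rz = semi_axes[, 3],
    role = role, stringsAsFactors = FALSE
  )
  class(out) <- c("spheroid_set", "data.frame")
  out
}

#' @rdname spheroids
#' @export
spheroid <- function(id, center, semi_axes, role = "particle",
                     parent_id = NA_integer_) {
  spheroids(id, center, semi_axes, role, parent_id)
}

as_spheroid_set <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("id", "parent_id", "cx", "cy", "cz", "rx", "ry", "rz", "role")
  if (!all(need %in% names(x)))
    stop("not a spheroid_set: missing columns", call. = FALSE)
  class(x) <- c("spheroid_set", "data.frame")
  x
}

#' Axis-aligned box region
#'
#' Closed 3D box `[x0, x0+w] x [y0, y0+d] x [z0, z0+h]`, used for tissue
#' domains, disector probe blocks and slabs.
#'
#' @param origin numeric length-3 `(x0, y0, z0)` (um).
#' @param size numeric length-3 positive extents `(w, d, h)` (um).
#' @return A `box3` object.
#' @examples
#' box3(c(0, 0, 0), c(100, 100, 20))
#' @export
box3 <- function(origin, size) {
  stopifnot(is.numeric(origin), length(origin) == 3L, all(is.finite(origin)))
  check_len3_pos(size, "size")
  structure(list(origin = as.numeric(origin), size = as.numeric(size)),
            class = "box3")
}

box3_lo <- function(b) b$origin
box3_hi <- function(b) b$origin + b$size

#' @export
print.box3 <- function(x, ...) {
  cat(sprintf("<box3> [%g, %g] x [%g, %g] x [%g, %g] um\n",
              x$origin[1], x$origin[1] + x$size[1],
              x$origin[2], x$origin[2] + x$size[2],
              x$origin[3], x$origin[3] + x$size[3]))
  invisible(x)
}

#' Bounded planar surface (exclusion-plane geometry)
#'
#' A closed planar set inside an axis-aligned plane: a rectangle (possibly
#' unbounded on some sides, encoding half-planes and full planes). These are
#' the exclusion and inclusion surfaces of the disector brick: the look-up
#' face, the side walls and their extensions.
#'
#' @param axis `"x"`, `"y"` or `"z"`: the plane's normal axis.
#' @param coord position of the plane along `axis` (um).
#' @param bounds1,bounds2 length-2 `c(lo, hi)` in-plane bounds for the two
#'   remaining axes taken in `(x, y, z)` order (e.g. for `axis = "y"` these
#'   bound x and z). `-Inf`/`Inf` allowed.
#' @return A `planar_surface` object.
#' @examples
#' # bottom look-up face of a brick
#' planar_surface("z", 0, c(0, 50), c(0, 50))
#' # a half-plane: x = 0 plane, y >= 10, all z
#' planar_surface("x", 0, c(10, Inf), c(-Inf, Inf))
#' @export
planar_surface <- function(axis = c("x", "y", "z"), coord,
                           bounds1 = c(-Inf, Inf), bounds2 = c(-Inf, Inf)) {
  axis <- match.arg(axis)
  check_scalar(coord, "coord")
  stopifnot(length(bounds1) == 2L, length(bounds2) == 2L,
            bounds1[1] <= bounds1[2], bounds2[1] <= bounds2[2])
  structure(list(axis = axis, coord = coord,
                 bounds1 = as.numeric(bounds1), bounds2 = as.numeric(bounds2)),
            class = "planar_surface")
}

# axis index and the indices of the two in-plane axes, in (x, y, z) order
axis_index <- function(axis) match(axis, c("x", "y", "z"))

#' z-extent of spheroids
#'
#' Caliper bookkeeping along the sectioning axis: the closed interval
#' `[cz - rz, cz + rz]` covered by each spheroid. The z-caliper height is
#' `2 * rz`; for the default chloroplast-like particle (`rz = 2` um) this is
#' the 4 um mean chloroplast height.
#'
#' @param s a `spheroid_set`.
#' @return n x 2 matrix with columns `z_min`, `z_max` (um).
#' @examples
#' z_extent(spheroid(1, c(0, 0, 10), c(3, 3, 2)))  # 8, 12
#' @export
z_extent <- function(s) {
  s <- as_spheroid_set(s)
  cbind(z_min = s$cz - s$rz, z_max = s$cz + s$rz)
}

#' Planar section of spheroids: elliptical profiles
#'
#' Cuts every spheroid with the horizontal plane at height `z`. A spheroid is
#' hit when `|z - cz| <= rz` (closed convention: the tangent plane yields a
#' degenerate point profile); the cut is the axis-aligned ellipse with
#' semi-axes `rx * sqrt(1 - ((z - cz)/rz)^2)` and likewise for `ry`.
#'
#' @param s a `spheroid_set`.
#' @param z section height (um).
#' @return A `profile_set` data.frame with columns `particle_id`, `z`, `cx`,
#'   `cy`, `ax`, `ay`; one row per spheroid hit by the plane.
#' @examples
#' plane_profile(spheroid(1, c(0, 0, 0), c(3, 3, 3)), 0)  # circle radius 3
#' @export
plane_profile <- function(s, z) {
  s <- as_spheroid_set(s)
  check_scalar(z, "z")
  d <- z - s$cz
  hit <- abs(d) <= s$rz
  f <- sqrt(pmax(0, 1 - (d[hit] / s$rz[hit])^2))
  out <- data.frame(
    particle_id = s$id[hit], z = rep(z, sum(hit)),
    cx = s$cx[hit], cy = s$cy[hit],
    ax = s$rx[hit] * f, ay = s$ry[hit] * f,
    stringsAsFactors = FALSE
  )
  class(out) <- c("profile_set", "data.frame")
  out
}

#' Construct a set of 2D elliptical profiles directly
#'
#' @param particle_id integer ids.
#' @param z section coordinate (um).
#' @param center n x 2 matrix (or length-2 vector) of ellipse centers (um).
#' @param semi_axes n x 2 matrix (or length-2 vector) of non-negative
#'   in-plane semi-axes `(ax, ay)` (um).
#' @return A `profile_set` data.frame.
#' @export
profiles <- function(particle_id, z = 0, center, semi_axes) {
  center <- rbind(center)
  semi_axes <- rbind(semi_axes)
  n <- max(length(particle_id), nrow(center), nrow(semi_axes))
  if (nrow(center) == 1L) center <- center[rep(1L, n), , drop = FALSE]
  if (nrow(semi_axes) == 1L) semi_axes <- semi_axes[rep(1L, n), , drop = FALSE]
  if (any(semi_axes < 0)) stop("profile semi-axes must be >= 0", call. = FALSE)
  out <- data.frame(
    particle_id = as.integer(particle_id), z = rep_len(z, n),
    cx = center[, 1], cy = center[, 2],
    ax = semi_axes[, 1], ay = semi_axes[, 2],
    stringsAsFactors = FALSE
  )
  class(out) <- c("profile_set", "data.frame")
  out
}

#' Exact spheroid / box intersection test
#'
#' Closed-set test: `TRUE` iff the closed spheroid and the closed box share at
#' least one point (touching counts). Exact for axis-aligned spheroids: the
#' per-axis scaling that maps the spheroid to the unit sphere keeps the box
#' axis-aligned, so the closest-point-on-box criterion applies.
#'
#' @param s a `spheroid_set`.
#' @param b a [box3()].
#' @return logical vector, one entry per spheroid.
#' @examples
#' b <- box3(c(0, 0, 0), c(10, 10, 10))
#' intersects_box(spheroid(1, c(5, 5, 5), c(1, 1, 1)), b)   # TRUE
#' intersects_box(spheroid(1, c(16, 5, 5), c(1, 1, 1)), b)  # FALSE
#' @export
intersects_box <- function(s, b) {
  s <- as_spheroid_set(s)
  stopifnot(inherits(b, "box3"))
  lo <- box3_lo(b); hi <- box3_hi(b)
  gx <- interval_dist(s$cx, lo[1], hi[1])
  gy <- interval_dist(s$cy, lo[2], hi[2])
  gz <- interval_dist(s$cz, lo[3], hi[3])
  q <- sq_ratio(gx, s$rx) + sq_ratio(gy, s$ry) + sq_ratio(gz, s$rz)
  q <= 1
}

#' Spheroid contact with a bounded planar surface
#'
#' Closed-set test used by the disector exclusion rule: `TRUE` iff the closed
#' spheroid intersects the closed planar set. The plane slices the spheroid in
#' an ellipse (possibly degenerate); the in-plane ellipse-versus-rectangle
#' overlap is then exact by per-axis scaling and clamping. Growing any
#' semi-axis can only keep or create contact (monotone).
#'
#' @param s a `spheroid_set`.
#' @param surf a [planar_surface()].
#' @return logical vector, one entry per spheroid.
#' @export
touches_surface <- function(s, surf) {
  s <- as_spheroid_set(s)
  stopifnot(inherits(surf, "planar_surface"))
  k <- axis_index(surf$axis)
  others <- setdiff(1:3, k)
  cen <- cbind(s$cx, s$cy, s$cz)
  ax <- cbind(s$rx, s$ry, s$rz)
  d <- surf$coord - cen[, k]
  hit <- abs(d) <= ax[, k]
  f <- sqrt(pmax(0, 1 - (d / ax[, k])^2))
  a1 <- ax[, others[1]] * f
  a2 <- ax[, others[2]] * f
  g1 <- interval_dist(cen[, others[1]], surf$bounds1[1], surf$bounds1[2])
  g2 <- interval_dist(cen[, others[2]], surf$bounds2[1], surf$bounds2[2])
  q <- sq_ratio(g1, a1) + sq_ratio(g2, a2)
  hit & q <= 1
}

#' Conservative spheroid-in-spheroid containment
#'
#' Sufficient closed-containment test after mapping the outer spheroid to the
#' unit sphere: the inner body is contained whenever the scaled centre norm
#' plus its largest scaled semi-axis is at most 1. The test never accepts a
#' body that protrudes; it can reject bodies hugging the boundary, which the
#' generators exploit to keep particles strictly interior.
#'
#' @param outer single-row `spheroid_set` (the hosting cell body).
#' @param inner `spheroid_set` of candidate contained bodies.
#' @return logical vector, one entry per inner spheroid.
#' @export
spheroid_contains <- function(outer, inner) {
  outer <- as_spheroid_set(outer)
  inner <- as_spheroid_set(inner)
  stopifnot(nrow(outer) == 1L)
  R <- c(outer$rx, outer$ry, outer$rz)
  dc <- cbind((inner$cx - outer$cx) / R[1],
              (inner$cy - outer$cy) / R[2],
              (inner$cz - outer$cz) / R[3])
  amax <- pmax(inner$rx / R[1], inner$ry / R[2], inner$rz / R[3])
  sqrt(rowSums(dc^2)) + amax <= 1
}

# Conservative pairwise disjointness between spheroid a (1 row) and set b:
# TRUE guarantees empty intersection (Minkowski bound: the sum body of two
# axis-aligned ellipsoids is contained in the ellipsoid of summed semi-axes).
spheroids_surely_disjoint <- function(a, b) {
  q <- ((b$cx - a$cx) / (a$rx + b$rx))^2 +
    ((b$cy - a$cy) / (a$ry + b$ry))^2 +
    ((b$cz - a$cz) / (a$rz + b$rz))^2
  q > 1
}

# Is each spheroid wholly inside the closed box? (exact per-axis test)
spheroid_in_box <- function(s, b) {
  lo <- box3_lo(b); hi <- box3_hi(b)
  s$cx - s$rx >= lo[1] & s$cx + s$rx <= hi[1] &
    s$cy - s$ry >= lo[2] & s$cy + s$ry <= hi[2] &
    s$cz - s$rz >= lo[3] & s$cz + s$rz <= hi[3]
}
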