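# Shared fixtures and independent oracles, built in code at test time.

# Random spheroid set with centers in `center_box` (a box3) and semi-axes
# uniform in [r_lo, r_hi].
random_spheroids <- function(n, center_box, r_lo = 0.5, r_hi = 3) {
  lo <- center_box$origin
  hi <- center_box$origin + center_box$size
  cen <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  ax <- matrix(runif(3 * n, r_lo, r_hi), n, 3)
  spheroids(seq_len(n), cen, ax)
}

# Independent spheroid/box intersection oracle: minimise the spheroid's
# quadratic form over the box (box-constrained optimisation); the closed sets
# meet iff the minimum is <= 1.
oracle_box_overlap <- function(s_row, b) {
  cen <- c(s_row$cx, s_row$cy, s_row$cz)
  ax <- c(s_row$rx, s_row$ry, s_row$rz)
  lo <- b$origin
  hi <- b$origin + b$size
  f <- function(x) sum(((x - cen) / ax)^2)
  gr <- function(x) 2 * (x - cen) / ax^2
  start <- pmin(pmax(cen, lo), hi)
  opt <- stats::optim(start, f, gr, method = "L-BFGS-B",
                      lower = lo, upper = hi)
  opt$value <= 1 + 1e-9
}

# Dense points on the surface of a spheroid (for containment oracles).
surface_points <- function(s_row, n = 500) {
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(u %*% diag(c(s_row$rx, s_row$ry, s_row$rz)), 2,
        c(s_row$cx, s_row$cy, s_row$cz), "+")
}

# Is a point set inside a closed spheroid?
points_in_spheroid <- function(pts, s_row, tol = 1e-9) {
  q <- ((pts[, 1] - s_row$cx) / s_row$rx)^2 +
    ((pts[, 2] - s_row$cy) / s_row$ry)^2 +
    ((pts[, 3] - s_row$cz) / s_row$rz)^2
  q <= 1 + tol
}

# A grid of contiguous disector bricks tiling a region.
tile_bricks <- function(origin, size, nx, ny, nz, look_up = "bottom") {
  out <- list()
  for (k in seq_len(nz) - 1L) {
    for (j in seq_len(ny) - 1L) {
      for (i in seq_len(nx) - 1L) {
        b <- box3(origin + c(i * size[1], j * size[2], k * size[3]), size)
        out[[length(out) + 1L]] <- disector_brick(b, look_up)
      }
    }
  }
  out
}

# A grid of contiguous counting frames tiling part of the plane.
tile_frames <- function(x0, y0, w, h, nx, ny) {
  out <- list()
  for (j in seq_len(ny) - 1L) {
    for (i in seq_len(nx) - 1L) {
      out[[length(out) + 1L]] <- counting_frame(x0 + i * w, y0 + j * h, w, h)
    }
  }
  out
}

# How many probes of a list count each particle id? Returns a named vector
# over all ids appearing in any count.
count_multiplicity <- function(ids_list) {
  tab <- table(unlist(ids_list))
  stats::setNames(as.integer(tab), names(tab))
}

# Zero-row spheroid set (degenerate-input fixtures).
empty_spheroid_set_for_tests <- function() {
  spheroid(1, c(0, 0, 0), c(1, 1, 1))[0, ]
}
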