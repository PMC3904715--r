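test_that("z_extent is the closed caliper interval along the optical axis", {
  e <- z_extent(spheroid(1, c(0, 0, 10), c(3, 3, 2)))
  expect_equal(unname(e[1, ]), c(8, 12))
  # a default chloroplast-like particle has a 4 um caliper height
  chl <- spheroid(1, c(0, 0, 0), c(2.5, 2.5, 2))
  expect_equal(diff(unname(z_extent(chl)[1, ])), 4)
  # degenerate, nearly flat particle
  e <- z_extent(spheroid(1, c(0, 0, 0), c(1, 1, 0.001)))
  expect_equal(diff(unname(e[1, ])), 0.002)
})

test_that("plane sections produce the correct ellipse profiles", {
  s <- spheroid(7, c(0, 0, 0), c(3, 3, 3))
  p <- plane_profile(s, 0)
  expect_equal(nrow(p), 1L)
  expect_equal(p$ax, 3)
  expect_equal(p$ay, 3)
  expect_equal(p$particle_id, 7L)
  # tangent plane: degenerate point profile (closed convention)
  p <- plane_profile(s, 3)
  expect_equal(nrow(p), 1L)
  expect_equal(p$ax, 0)
  # just beyond the pole: no profile
  expect_equal(nrow(plane_profile(s, 3 + 1e-9)), 0L)
  # off-equator section of a spheroid: ax = rx * sqrt(1 - ((z-cz)/rz)^2)
  s <- spheroid(1, c(1, 2, 5), c(2.5, 2.5, 2))
  p <- plane_profile(s, 6)
  expect_equal(p$ax, 2.5 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(p$ay, 2.5 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(c(p$cx, p$cy), c(1, 2))
})

test_that("profile areas integrate to the spheroid volume", {
  set.seed(11)
  for (i in 1:5) {
    ax <- runif(3, 0.5, 4)
    s <- spheroid(1, runif(3, -5, 5), ax)
    step <- ax[3] / 150
    zs <- seq(s$cz - s$rz, s$cz + s$rz, by = step)
    areas <- vapply(zs, function(z) {
      p <- plane_profile(s, z)
      if (nrow(p)) pi * p$ax * p$ay else 0
    }, numeric(1))
    trap <- sum((areas[-1] + areas[-length(areas)]) / 2) * step
    expect_equal(trap, 4 / 3 * pi * prod(ax), tolerance = 1e-3)
  }
})

test_that("spheroid/box intersection matches an independent optimisation oracle", {
  set.seed(21)
  n_agree <- 0L
  for (i in 1:300) {
    s <- random_spheroids(1, box3(c(-6, -6, -6), c(12, 12, 12)),
                          r_lo = 0.3, r_hi = 3)
    b <- box3(runif(3, -4, 0), runif(3, 1, 6))
    got <- intersects_box(s, b)
    want <- oracle_box_overlap(s[1, ], b)
    expect_identical(got, want)
    n_agree <- n_agree + as.integer(got == want)
  }
  expect_equal(n_agree, 300L)
})

test_that("box intersection honours the closed-set convention", {
  b <- box3(c(0, 0, 0), c(10, 10, 10))
  # surface exactly touching a box face
  expect_true(intersects_box(spheroid(1, c(-1, 5, 5), c(1, 1, 1)), b))
  # a hair away
  expect_false(intersects_box(spheroid(1, c(-1 - 1e-9, 5, 5), c(1, 1, 1)), b))
  # containment and clear separation
  expect_true(intersects_box(spheroid(1, c(5, 5, 5), c(1, 1, 1)), b))
  expect_false(intersects_box(spheroid(1, c(16, 5, 5), c(1, 1, 1)), b))
})

test_that("planar-surface contact distinguishes plane, rectangle and half-plane", {
  full_plane <- planar_surface("z", 0)
  s_near <- spheroid(1, c(0, 0, 0.5), c(1, 1, 1))
  s_far <- spheroid(1, c(0, 0, 2), c(1, 1, 1))
  expect_true(touches_surface(s_near, full_plane))
  expect_false(touches_surface(s_far, full_plane))
  # tangent contact counts (closed convention)
  expect_true(touches_surface(spheroid(1, c(0, 0, 1), c(1, 1, 1)), full_plane))

  # sphere cut by the plane of a half-plane surface but wholly on the open
  # side of its edge: no contact
  half <- planar_surface("z", 0, bounds1 = c(5, Inf), bounds2 = c(-Inf, Inf))
  s <- spheroid(1, c(0, 0, 0.2), c(1, 1, 1))
  expect_false(touches_surface(s, half))
  # same sphere against the covering full plane does touch
  expect_true(touches_surface(s, full_plane))
  # moved so the slice disc reaches past the closed edge: contact
  expect_true(touches_surface(spheroid(1, c(4.1, 0, 0.2), c(1, 1, 1)), half))

  # rejection-sampling oracle for the half-plane case: the slice disc at
  # z = 0 has radius sqrt(1 - 0.2^2) around x = 0; no sampled point reaches
  # the x >= 5 half-plane
  set.seed(4)
  th <- runif(2000, 0, 2 * pi); r <- sqrt(runif(2000)) * sqrt(1 - 0.04)
  expect_false(any(r * cos(th) >= 5))

  # bounded rectangle in a plane
  rect <- planar_surface("x", 0, bounds1 = c(0, 2), bounds2 = c(0, 2))
  expect_true(touches_surface(spheroid(1, c(0.5, 1, 1), c(1, 1, 1)), rect))
  expect_false(touches_surface(spheroid(1, c(0.5, 5, 5), c(1, 1, 1)), rect))
})

test_that("surface contact is monotone in the semi-axes", {
  set.seed(31)
  for (i in 1:200) {
    s <- random_spheroids(1, box3(c(-4, -4, -4), c(8, 8, 8)),
                          r_lo = 0.2, r_hi = 2)
    surf <- planar_surface(sample(c("x", "y", "z"), 1), runif(1, -3, 3),
                           bounds1 = sort(runif(2, -4, 4)),
                           bounds2 = c(runif(1, -4, 0), Inf))
    before <- touches_surface(s, surf)
    grown <- s
    k <- sample(c("rx", "ry", "rz"), 1)
    grown[[k]] <- grown[[k]] * runif(1, 1, 3)
    after <- touches_surface(grown, surf)
    if (before) expect_true(after)
  }
})

test_that("conservative containment never accepts a protruding particle", {
  set.seed(41)
  outer <- spheroid(99, c(1, -2, 3), c(10, 8, 20), role = "cell_body")
  inner <- random_spheroids(150, box3(c(-8, -10, -15), c(18, 16, 36)),
                            r_lo = 0.5, r_hi = 4)
  ok <- spheroid_contains(outer, inner)
  for (i in which(ok)) {
    pts <- surface_points(inner[i, ], 400)
    expect_true(all(points_in_spheroid(pts, outer[1, ])))
  }
  expect_gt(sum(ok), 0)  # the test exercises accepted cases
})

test_that("spheroid constructor validates its invariants", {
  expect_error(spheroid(1, c(0, 0, 0), c(1, -1, 1)), "positive")
  expect_error(spheroids(c(1, 1), rbind(c(0, 0, 0), c(1, 1, 1)), c(1, 1, 1)),
               "unique")
  expect_error(spheroid(1, c(0, 0, 0), c(1, 1, 1), role = "mitochondrion"),
               "role")
})
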