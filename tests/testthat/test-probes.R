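test_that("the brick rule counts by intersection minus exclusion contact", {
  brick <- disector_brick(box3(c(0, 0, 0), c(20, 20, 10)))
  # strictly inside: always counted
  expect_equal(brick_count(spheroid(1, c(10, 10, 5), c(2, 2, 2)), brick), 1L)
  # intersecting only the reference (top) plane: counted
  expect_equal(brick_count(spheroid(1, c(10, 10, 11), c(2, 2, 2)), brick), 1L)
  # shifted down to touch the look-up plane: not counted
  expect_equal(length(brick_count(spheroid(1, c(10, 10, 1), c(2, 2, 2)),
                                  brick)), 0L)
  # crossing an exclusion side wall: not counted
  expect_equal(length(brick_count(spheroid(1, c(0.5, 10, 5), c(2, 2, 2)),
                                  brick)), 0L)
  # crossing an inclusion side face: counted
  expect_equal(brick_count(spheroid(1, c(19.5, 10, 5), c(2, 2, 2)), brick), 1L)
  # far away: not a candidate
  expect_equal(length(brick_count(spheroid(1, c(50, 50, 5), c(2, 2, 2)),
                                  brick)), 0L)
})

test_that("bricks tiling space count every interior particle exactly once", {
  set.seed(52)
  for (trial in 1:3) {
    bricks <- tile_bricks(c(0, 0, 0), c(11, 13, 9), 4, 4, 4)
    # particles kept clear of the outer boundary of the tiled region
    parts <- random_spheroids(250, box3(c(8, 8, 8), c(28, 36, 20)),
                              r_lo = 0.3, r_hi = 3.5)
    counts <- lapply(bricks, function(b) brick_count(parts, b))
    mult <- count_multiplicity(counts)
    # no particle sampled by two probes
    expect_true(all(mult <= 1L))
    # every particle in the interior sampled by exactly one probe
    expect_setequal(as.integer(names(mult)), parts$id)
  }
})

test_that("frames tiling the plane count every profile exactly once", {
  set.seed(53)
  for (trial in 1:3) {
    frames <- tile_frames(0, 0, 12, 9, 5, 5)
    profs <- profiles(1:250, 0,
                      cbind(runif(250, 10, 50), runif(250, 8, 37)),
                      matrix(runif(500, 0.2, 4), 250, 2))
    counts <- lapply(frames, function(f) frame_count(profs, f))
    mult <- count_multiplicity(counts)
    expect_true(all(mult <= 1L))
    expect_setequal(as.integer(names(mult)), profs$particle_id)
  }
})

test_that("the counting frame applies the forbidden-line rule", {
  fr <- counting_frame(0, 0, 10, 10)
  # wholly inside
  expect_equal(frame_count(profiles(1, 0, c(5, 5), c(1, 1)), fr), 1L)
  # crossing only the left (forbidden) edge
  expect_equal(length(frame_count(profiles(1, 0, c(0.2, 5), c(1, 1)), fr)), 0L)
  # crossing only the right (allowed) edge
  expect_equal(frame_count(profiles(1, 0, c(9.8, 5), c(1, 1)), fr), 1L)
  # touching the upward extension of the left edge line, above the frame,
  # while dipping into the frame
  expect_equal(length(frame_count(profiles(1, 0, c(1.5, 10.5), c(2, 1)), fr)),
               0L)
  # touching the downward extension through the bottom-right corner
  expect_equal(length(frame_count(profiles(1, 0, c(10, -0.5), c(1, 1)), fr)),
               0L)
})

test_that("single bricks are unbiased on uniform random particle fields", {
  # independent replicate fields so the Monte-Carlo SE covers field noise
  set.seed(61)
  n <- 800
  side <- 100
  field_means <- replicate(20, {
    parts <- random_spheroids(n, box3(c(0, 0, 0), c(side, side, side)),
                              r_lo = 0.5, r_hi = 2.5)
    mean(replicate(25, {
      org <- runif(3, 6, side - 6 - c(20, 20, 5))
      length(brick_count(parts, disector_brick(box3(org, c(20, 20, 5))))) /
        (20 * 20 * 5)
    }))
  })
  nv_true <- n / side^3
  expect_lt(abs(mean(field_means) - nv_true),
            2 * stats::sd(field_means) / sqrt(20))
})

test_that("the double disector doubles the probe height and stays unbiased", {
  slab <- box3(c(0, 0, 0), c(20, 20, 10))
  dd <- double_disector_count(empty_spheroid_set_for_tests(), slab)
  expect_equal(dd$Q, 0L)
  expect_equal(dd$h, 20)          # slab of 10 um reports a 20 um probe
  expect_equal(dd$volume, 20 * 20 * 20)

  set.seed(62)
  n <- 800
  side <- 100
  field_means <- replicate(20, {
    parts <- random_spheroids(n, box3(c(0, 0, 0), c(side, side, side)),
                              r_lo = 0.5, r_hi = 2.5)
    mean(replicate(25, {
      org <- runif(3, 6, side - 6 - c(20, 20, 10))
      dd <- double_disector_count(parts, box3(org, c(20, 20, 10)))
      dd$Q / dd$volume
    }))
  })
  expect_lt(abs(mean(field_means) - n / side^3),
            2 * stats::sd(field_means) / sqrt(20))
})

test_that("point-grid hits estimate areas without bias", {
  fr <- counting_frame(0, 0, 10, 10)
  g <- point_grid(c(1, 1), c(0.5, 0.5))
  # region = entire frame: every point hits
  all_in <- point_grid_hits(function(x, y) rep(TRUE, length(x)), g, fr)
  expect_equal(all_in$P, all_in$p)
  expect_equal(all_in$p, 100L)
  # left half of the frame with a fine grid
  fine <- point_grid(c(0.1, 0.1), c(0.05, 0.05))
  half <- point_grid_hits(function(x, y) x <= 5, fine, fr)
  expect_equal(half$P / half$p, 0.5, tolerance = 0.02)

  # disc of known area: E[P * a / p] = A over random grid offsets
  set.seed(63)
  fr2 <- counting_frame(0, 0, 40, 40)
  A <- pi * 8^2
  disc <- function(x, y) (x - 20)^2 + (y - 17)^2 <= 64
  ests <- replicate(600, {
    g <- point_grid(c(5, 5), runif(2, 0, 5))
    hit <- point_grid_hits(disc, g, fr2)
    hit$P * fr2$area / hit$p
  })
  expect_lt(abs(mean(ests) - A), 2 * stats::sd(ests) / sqrt(600))

  # mask-based region
  mask <- matrix(0L, 20, 20); mask[, 1:10] <- 1L
  hit <- point_grid_hits(list(mask = mask, origin = c(0, 0), pixel_size = 0.5),
                         fine, fr)
  expect_equal(hit$P / hit$p, 0.5, tolerance = 0.02)
})

test_that("stack-based disector counting follows the optical convention", {
  # one sphere wholly above the look-up plane: counted, with the probe
  # height from section spacing
  m <- spheroid(5, c(10, 10, 13.5), c(2, 2, 2))
  st <- render_label_stack(m, stack_spec(c(0, 0, 16), c(20, 20), 12, 0.5, 0.5))
  got <- brick_count_stack(st, counting_frame(2, 2, 16, 16), 0, 11)
  expect_equal(as.integer(got), 5L)
  expect_equal(attr(got, "h"), 5.5)  # 12 sections 0.5 um apart

  # a particle visible in the look-up section is excluded
  m2 <- spheroid(6, c(10, 10, 9.5), c(2, 2, 2))
  st2 <- render_label_stack(m2, stack_spec(c(0, 0, 12), c(20, 20), 8, 0.5, 0.5))
  got2 <- brick_count_stack(st2, counting_frame(2, 2, 16, 16), 0, 7)
  expect_equal(length(got2), 0L)
})
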