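test_that("the default model cell holds 210 contained chloroplasts", {
  m <- generate_model_cell(model_cell_spec(seed = 2))
  expect_equal(nrow(m$particles), 210L)
  expect_true(all(m$particles$parent_id == m$cell$id[1]))
  expect_true(all(spheroid_contains(m$cell, m$particles)))
  # independent oracle on a subsample: dense surface points stay inside
  for (i in sample(nrow(m$particles), 15)) {
    pts <- surface_points(m$particles[i, ], 300)
    expect_true(all(points_in_spheroid(pts, m$cell[1, ])))
  }
  # cell caliper within the declared validity range
  expect_true(2 * m$cell$rz[1] >= 40 && 2 * m$cell$rz[1] <= 60)
})

test_that("model-cell generation handles degenerate and invalid inputs", {
  m0 <- generate_model_cell(model_cell_spec(n_chloroplasts = 0, seed = 1))
  expect_equal(nrow(m0$particles), 0L)
  expect_s3_class(m0, "cell_model")
  # particle that cannot fit
  expect_error(generate_model_cell(model_cell_spec(
    n_chloroplasts = 1, chl_semi_axes_mean = c(30, 30, 30), seed = 1
  )), "cell too small")
  # cell height outside the validity range
  expect_error(model_cell_spec(cell_semi_axes = c(12.5, 12.5, 10)), "40-60")
  expect_s3_class(model_cell_spec(cell_semi_axes = c(12.5, 12.5, 10),
                                  allow_any_height = TRUE),
                  "model_cell_spec")
})

test_that("generation is deterministic given the seed (byte-identical JSON)", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_model_json(generate_model_cell(model_cell_spec(seed = 9)), f1)
  write_model_json(generate_model_cell(model_cell_spec(seed = 9)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # different seed, different model
  f3 <- tempfile(fileext = ".json")
  write_model_json(generate_model_cell(model_cell_spec(seed = 10)), f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("peripheral-shell placement confines centers to an outer shell", {
  spec <- model_cell_spec(placement = "peripheral_shell", shell_thickness = 4,
                          seed = 3)
  m <- generate_model_cell(spec)
  R <- c(m$cell$rx, m$cell$ry, m$cell$rz)
  r_scaled <- sqrt(((m$particles$cx - m$cell$cx) / R[1])^2 +
                     ((m$particles$cy - m$cell$cy) / R[2])^2 +
                     ((m$particles$cz - m$cell$cz) / R[3])^2)
  expect_true(all(spheroid_contains(m$cell, m$particles)))
  expect_gt(min(r_scaled), 0.35)   # hollow core
})

test_that("non-overlapping placement rejects collisions or reports failure", {
  spec <- model_cell_spec(n_chloroplasts = 25, allow_overlap = FALSE, seed = 4)
  m <- generate_model_cell(spec)
  p <- m$particles
  for (i in seq_len(nrow(p) - 1)) {
    rest <- p[(i + 1):nrow(p), , drop = FALSE]
    d2 <- (rest$cx - p$cx[i])^2 + (rest$cy - p$cy[i])^2 + (rest$cz - p$cz[i])^2
    # conservative criterion used by the generator implies center separation
    expect_true(all(d2 > 0))
  }
  # impossible dense packing without overlap: bounded attempts then error
  expect_error(generate_model_cell(model_cell_spec(
    n_chloroplasts = 12, cell_semi_axes = c(5, 5, 20),
    chl_semi_axes_mean = c(2.5, 2.5, 2), allow_overlap = FALSE,
    allow_any_height = TRUE, seed = 4
  )), "attempt")
})

test_that("synthetic tissue respects containment, linkage and targets", {
  spec <- tissue_spec(domain = box3(c(0, 0, 0), c(150, 150, 250)),
                      n_cells = 50, chl_per_cell_mean = 40,
                      chl_per_cell_sd = 6, seed = 11)
  tm <- generate_tissue(spec)
  md <- tm$metadata
  expect_equal(md$n_cells, 50L)
  # particle totals near n * mean, every parent id valid
  expect_equal(md$n_particles, nrow(tm$particles))
  expect_lt(abs(md$n_particles - 50 * 40), 4 * sqrt(50) * 6 + 50)
  expect_true(all(tm$particles$parent_id %in% tm$cells$id))
  # chloroplasts inside their parent cells
  for (cid in sample(tm$cells$id, 8)) {
    kids <- tm$particles[tm$particles$parent_id == cid, , drop = FALSE]
    expect_true(all(spheroid_contains(tm$cells[tm$cells$id == cid, ], kids)))
  }
  # cells inside the mesophyll region, mesophyll region fraction on target
  lo <- tm$mesophyll$origin; hi <- lo + tm$mesophyll$size
  expect_true(all(tm$cells$cx - tm$cells$rx >= lo[1] &
                    tm$cells$cx + tm$cells$rx <= hi[1]))
  expect_true(all(tm$cells$cz - tm$cells$rz >= lo[3] &
                    tm$cells$cz + tm$cells$rz <= hi[3]))
  expect_lt(abs(md$mesophyll_fraction_realized - 0.72), 0.05)
  # non-overlap of cell bodies certified by the Minkowski criterion
  for (i in seq_len(nrow(tm$cells) - 1)) {
    rest <- tm$cells[(i + 1):nrow(tm$cells), , drop = FALSE]
    q <- ((rest$cx - tm$cells$cx[i]) / (tm$cells$rx[i] + rest$rx))^2 +
      ((rest$cy - tm$cells$cy[i]) / (tm$cells$ry[i] + rest$ry))^2 +
      ((rest$cz - tm$cells$cz[i]) / (tm$cells$rz[i] + rest$rz))^2
    expect_true(all(q > 1))
  }
})

test_that("tissue generation degenerates and errors sensibly", {
  # a single cell reduces to model-cell generation
  tm1 <- generate_tissue(tissue_spec(domain = box3(c(0, 0, 0), c(80, 80, 100)),
                                     n_cells = 1, chl_per_cell_mean = 30,
                                     chl_per_cell_sd = 0, seed = 12))
  expect_equal(tm1$metadata$n_cells, 1L)
  expect_equal(nrow(tm1$particles), tm1$metadata$chl_per_cell[1])
  # unreachable packing target
  expect_error(generate_tissue(tissue_spec(cell_packing = 0.8)),
               "unreachable")
  # dart placement works at sparse packing
  tmd <- generate_tissue(tissue_spec(domain = box3(c(0, 0, 0), c(150, 150, 200)),
                                     cell_packing = 0.1, placement = "dart",
                                     chl_per_cell_mean = 10,
                                     chl_per_cell_sd = 1, seed = 13))
  expect_gt(tmd$metadata$n_cells, 2L)
  expect_lt(tmd$metadata$cell_packing_realized, 0.15)
})

test_that("tissue generation is seed-deterministic", {
  sp <- tissue_spec(domain = box3(c(0, 0, 0), c(120, 120, 160)),
                    n_cells = 10, chl_per_cell_mean = 20,
                    chl_per_cell_sd = 2, seed = 14)
  t1 <- generate_tissue(sp); t2 <- generate_tissue(sp)
  expect_identical(t1$cells, t2$cells)
  expect_identical(t1$particles, t2$particles)
})

test_that("SUR positions follow offset + i * period within the extent", {
  expect_equal(sur_positions(30000, 3000, offset = 2000),
               seq(2000, 29000, by = 3000))
  expect_length(sur_positions(30000, 3000, offset = 2000), 10L)
  # period equal to the extent: exactly one section
  expect_length(sur_positions(5000, 5000, offset = 1000), 1L)
  expect_error(sur_positions(100, 200), "period")
  expect_error(sur_positions(100, -1), "period")
  # sixth-step dialect with the smallest admissible start: period/6 from the tip
  set.seed(15)
  repeat {
    p <- sur_positions(30000, 3000, dialect = "sixths")
    if (p[1] == 500) break
  }
  expect_equal(p, seq(500, 30000, by = 3000))
})

test_that("sixth-step SUR starts are uniform over the six admissible offsets", {
  set.seed(16)
  starts <- replicate(6000, sur_positions(6000, 3000, dialect = "sixths")[1])
  freq <- table(factor(starts, levels = (1:6) * 500))
  p0 <- 1 / 6
  sigma <- sqrt(p0 * (1 - p0) / 6000)
  expect_true(all(abs(freq / 6000 - p0) < 3 * sigma))
})
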