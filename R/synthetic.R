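empty_spheroid_set <- function() {
  out <- data.frame(id = integer(0), parent_id = integer(0),
                    cx = numeric(0), cy = numeric(0), cz = numeric(0),
                    rx = numeric(0), ry = numeric(0), rz = numeric(0),
                    role = character(0), stringsAsFactors = FALSE)
  class(out) <- c("spheroid_set", "data.frame")
  out
}

bind_spheroids <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  as_spheroid_set(out)
}

#' Specification of the model mesophyll cell
#'
#' Defaults reproduce the simplified mesophyll cell used throughout the
#' package's demonstrations: 210 spheroidal chloroplasts with mean semi-axes
#' (2.5, 2.5, 2.0) um (z-caliper 4 um) placed uniformly inside a spheroidal
#' cell body whose z semi-axis 24.5 um gives a 49 um z-caliper, inside the
#' 40-60 um range typical of conifer mesophyll cells.
#'
#' @param n_chloroplasts number of particles (>= 0).
#' @param cell_semi_axes cell body semi-axes `(rx, ry, rz)` (um).
#' @param chl_semi_axes_mean mean particle semi-axes (um).
#' @param chl_semi_axes_cv coefficient of variation of each particle
#'   semi-axis (independent Gaussian scatter, truncated at 5% of the mean).
#' @param placement `"uniform"` (default; volume-uniform inside the cell) or
#'   `"peripheral_shell"` (centers confined to an outer shell).
#' @param shell_thickness shell thickness (um) for `"peripheral_shell"`.
#' @param allow_overlap may particles overlap each other (default `TRUE`;
#'   counting rules are id-based, not morphology-based).
#' @param allow_any_height bypass the declared 40-60 um validity range of the
#'   cell z-caliper.
#' @param seed integer seed for reproducible generation, or `NULL`.
#' @return A `model_cell_spec` list.
#' @export
model_cell_spec <- function(n_chloroplasts = 210,
                            cell_semi_axes = c(12.5, 12.5, 24.5),
                            chl_semi_axes_mean = c(2.5, 2.5, 2.0),
                            chl_semi_axes_cv = 0.1,
                            placement = c("uniform", "peripheral_shell"),
                            shell_thickness = 5,
                            allow_overlap = TRUE,
                            allow_any_height = FALSE,
                            seed = NULL) {
  placement <- match.arg(placement)
  check_scalar(n_chloroplasts, "n_chloroplasts")
  if (n_chloroplasts < 0) stop("`n_chloroplasts` must be >= 0", call. = FALSE)
  check_len3_pos(cell_semi_axes, "cell_semi_axes")
  check_len3_pos(chl_semi_axes_mean, "chl_semi_axes_mean")
  check_scalar(chl_semi_axes_cv, "chl_semi_axes_cv")
  caliper <- 2 * cell_semi_axes[3]
  if (!allow_any_height && (caliper < 40 || caliper > 60))
    stop(sprintf(paste0("cell z-caliper %g um is outside the declared 40-60 um",
                        " validity range (set allow_any_height = TRUE to override)"),
                 caliper), call. = FALSE)
  structure(list(n_chloroplasts = as.integer(n_chloroplasts),
                 cell_semi_axes = cell_semi_axes,
                 chl_semi_axes_mean = chl_semi_axes_mean,
                 chl_semi_axes_cv = chl_semi_axes_cv,
                 placement = placement, shell_thickness = shell_thickness,
                 allow_overlap = allow_overlap,
                 allow_any_height = allow_any_height, seed = seed),
            class = "model_cell_spec")
}

# Place n particle spheroids wholly inside a cell body (one row of a
# spheroid_set). Containment is enforced with the conservative axis-scaling
# test, so particles stay strictly interior. Uniform placement samples
# volume-uniformly in the admissible (scaled) ball; peripheral_shell confines
# centers to an outer shell of the admissible region.
place_particles_in_cell <- function(cell, n, mean_axes, cv,
                                    placement = "uniform",
                                    shell_thickness = 5,
                                    allow_overlap = TRUE,
                                    id_start = 1L,
                                    max_attempts = 200L) {
  if (n == 0L) return(empty_spheroid_set())
  R <- c(cell$rx, cell$ry, cell$rz)
  draw_axes <- function(m) {
    ax <- matrix(rnorm(3 * m, 1, cv), m, 3)
    ax <- pmax(ax, 0.05)
    sweep(ax, 2, mean_axes, "*")
  }
  draw_centers <- function(axes) {
    m <- nrow(axes)
    amax <- pmax(axes[, 1] / R[1], axes[, 2] / R[2], axes[, 3] / R[3])
    if (any(amax >= 1))
      stop(sprintf(paste0("cell too small: a particle with max scaled semi-axis",
                          " %.3f cannot fit inside the cell body"), max(amax)),
           call. = FALSE)
    dir <- matrix(rnorm(3 * m), m, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    rhi <- 1 - amax
    if (placement == "peripheral_shell") {
      rlo <- pmax(0, rhi - shell_thickness / min(R))
      rad <- (rlo^3 + runif(m) * (rhi^3 - rlo^3))^(1 / 3)
    } else {
      rad <- rhi * runif(m)^(1 / 3)
    }
    sweep(dir * rad, 2, R, "*") +
      matrix(c(cell$cx, cell$cy, cell$cz), m, 3, byrow = TRUE)
  }
  if (allow_overlap) {
    axes <- draw_axes(n)
    cen <- draw_centers(axes)
    return(spheroids(id = id_start + seq_len(n) - 1L, center = cen,
                     semi_axes = axes, role = "particle",
                     parent_id = cell$id))
  }
  # bounded-rejection placement without particle overlap
  placed <- empty_spheroid_set()
  attempts_left <- max_attempts * n
  for (i in seq_len(n)) {
    ok <- FALSE
    while (attempts_left > 0L) {
      attempts_left <- attempts_left - 1L
      axes <- draw_axes(1L)
      cen <- draw_centers(axes)
      cand <- spheroids(id = id_start + i - 1L, center = cen[1, ],
                        semi_axes = axes[1, ], role = "particle",
                        parent_id = cell$id)
      if (nrow(placed) == 0L ||
          all(spheroids_surely_disjoint(as.list(cand[1, ]), placed))) {
        placed <- bind_spheroids(placed, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(paste0("non-overlapping placement failed after the %d-attempt",
                          " limit (%d of %d particles placed)"),
                   max_attempts * n, i - 1L, n), call. = FALSE)
  }
  placed
}

#' Generate the model mesophyll cell
#'
#' Builds the geometric ground truth of the model-cell experiment: a
#' spheroidal cell body hosting `n_chloroplasts` spheroidal particles, each
#' wholly inside the cell (closed containment via the conservative
#' axis-scaling test). Deterministic given `spec$seed`.
#'
#' @param spec a [model_cell_spec()].
#' @return A `cell_model`: list with `cell` (one-row `spheroid_set`),
#'   `particles` (`spheroid_set`), `spec` and `seed`.
#' @examples
#' m <- generate_model_cell(model_cell_spec(seed = 1))
#' nrow(m$particles)  # 210
#' @export
generate_model_cell <- function(spec = model_cell_spec()) {
  stopifnot(inherits(spec, "model_cell_spec"))
  with_seed(spec$seed, {
    cell <- spheroids(1L, c(0, 0, 0), spec$cell_semi_axes, role = "cell_body")
    particles <- place_particles_in_cell(
      cell = as.list(cell[1, ]), n = spec$n_chloroplasts,
      mean_axes = spec$chl_semi_axes_mean, cv = spec$chl_semi_axes_cv,
      placement = spec$placement, shell_thickness = spec$shell_thickness,
      allow_overlap = spec$allow_overlap, id_start = 2L
    )
    structure(list(cell = cell, particles = particles, spec = spec,
                   seed = spec$seed),
              class = "cell_model")
  })
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> %d particles in a cell of z-caliper %g um\n",
              nrow(x$particles), 2 * x$cell$rz[1]))
  invisible(x)
}

#' Specification of a needle-like synthetic tissue
#'
#' The tissue block stands in for a segment of needle: an axis-aligned domain
#' box containing a centred inner mesophyll region occupying
#' `mesophyll_fraction` of the domain volume (the fraction that
#' point counting would measure, including intercellular space), with
#' non-overlapping mesophyll cell bodies packed inside the mesophyll region
#' at `cell_packing`, each hosting its own chloroplast population. The z axis
#' is the needle/optical axis along which sections are taken.
#'
#' @param domain a [box3()] tissue block (um).
#' @param cell_caliper_mean,cell_caliper_sd cell z-caliper (height) mean and
#'   sd (um).
#' @param cell_lateral_mean,cell_lateral_sd lateral cell semi-axis mean and
#'   sd (um).
#' @param n_cells exact number of cells to place, or `NULL` to fill the
#'   lattice at the packing target.
#' @param cells_per_volume target cell numerical density (um^-3), or `NULL`;
#'   converted to a packing fraction of the mesophyll region.
#' @param chl_per_cell_mean,chl_per_cell_sd per-cell chloroplast count mean
#'   and sd (Gaussian, rounded, truncated at 0).
#' @param chl_semi_axes_mean,chl_semi_axes_cv chloroplast semi-axes mean (um)
#'   and per-axis coefficient of variation.
#' @param mesophyll_fraction target fraction of domain volume occupied by the
#'   mesophyll region.
#' @param cell_packing target fraction of the mesophyll region occupied by
#'   cell bodies (lattice placement; at most ~0.73).
#' @param placement `"lattice"` (jittered, affinely scaled FCC; default) or
#'   `"dart"` (uniform rejection sampling, for sparse tissues).
#' @param seed integer seed or `NULL`.
#' @return A `tissue_spec` list.
#' @export
tissue_spec <- function(domain = box3(c(0, 0, 0), c(200, 200, 400)),
                        cell_caliper_mean = 40, cell_caliper_sd = 2,
                        cell_lateral_mean = 12.5, cell_lateral_sd = 0.6,
                        n_cells = NULL, cells_per_volume = NULL,
                        chl_per_cell_mean = 210, chl_per_cell_sd = 21,
                        chl_semi_axes_mean = c(2.5, 2.5, 2.0),
                        chl_semi_axes_cv = 0.1,
                        mesophyll_fraction = 0.72,
                        cell_packing = 0.60,
                        placement = c("lattice", "dart"),
                        seed = NULL) {
  placement <- match.arg(placement)
  stopifnot(inherits(domain, "box3"))
  check_scalar(cell_caliper_mean, "cell_caliper_mean", positive = TRUE)
  check_scalar(cell_lateral_mean, "cell_lateral_mean", positive = TRUE)
  check_scalar(chl_per_cell_mean, "chl_per_cell_mean", positive = TRUE)
  check_len3_pos(chl_semi_axes_mean, "chl_semi_axes_mean")
  check_scalar(mesophyll_fraction, "mesophyll_fraction", positive = TRUE)
  if (mesophyll_fraction > 1)
    stop("`mesophyll_fraction` must be <= 1", call. = FALSE)
  check_scalar(cell_packing, "cell_packing", positive = TRUE)
  structure(list(domain = domain,
                 cell_caliper_mean = cell_caliper_mean,
                 cell_caliper_sd = cell_caliper_sd,
                 cell_lateral_mean = cell_lateral_mean,
                 cell_lateral_sd = cell_lateral_sd,
                 n_cells = n_cells, cells_per_volume = cells_per_volume,
                 chl_per_cell_mean = chl_per_cell_mean,
                 chl_per_cell_sd = chl_per_cell_sd,
                 chl_semi_axes_mean = chl_semi_axes_mean,
                 chl_semi_axes_cv = chl_semi_axes_cv,
                 mesophyll_fraction = mesophyll_fraction,
                 cell_packing = cell_packing,
                 placement = placement, seed = seed),
            class = "tissue_spec")
}

# FCC lattice sites (scaled coordinates) covering a box of dims L, with
# nearest-neighbour distance gamma and a uniform-random phase: the tissue
# sits at an arbitrary position relative to any later probe frame, which is
# what makes fixed-frame probe counts unbiased over replicate tissues.
fcc_sites <- function(L, gamma, phase = stats::runif(3)) {
  a <- gamma * sqrt(2)
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5)) * a
  idx <- expand.grid(i = -1:(ceiling(L[1] / a) + 1L),
                     j = -1:(ceiling(L[2] / a) + 1L),
                     k = -1:(ceiling(L[3] / a) + 1L))
  corners <- sweep(as.matrix(idx) * a, 2, phase * a, "+")
  sites <- do.call(rbind, lapply(seq_len(nrow(basis)), function(b) {
    sweep(corners, 2, basis[b, ], "+")
  }))
  sites[sites[, 1] >= 0 & sites[, 1] <= L[1] &
          sites[, 2] >= 0 & sites[, 2] <= L[2] &
          sites[, 3] >= 0 & sites[, 3] <= L[3], , drop = FALSE]
}

#' Generate a synthetic needle-like tissue
#'
#' Places non-overlapping cell bodies inside the mesophyll region of the
#' domain and fills each cell with its chloroplast population; every
#' chloroplast lies wholly inside its parent cell, every cell wholly inside
#' the mesophyll region. The default placement is a jittered, affinely scaled
#' face-centred-cubic lattice (mesophyll cells form tightly connected layers;
#' random sequential placement cannot reach realistic packing). Cell-size
#' scatter and jitter are bounded by the packing slack, so at high packing
#' targets the scatter is automatically damped. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [tissue_spec()].
#' @return A `tissue_model`: list with `cells` and `particles`
#'   (`spheroid_set`s), `domain` and `mesophyll` ([box3()]s), `spec`, and
#'   `metadata` (realized mesophyll fraction, realized packing, per-cell
#'   counts, realized mean calipers, seed).
#' @examples
#' tm <- generate_tissue(tissue_spec(
#'   domain = box3(c(0, 0, 0), c(120, 120, 160)),
#'   n_cells = 8, chl_per_cell_mean = 30, chl_per_cell_sd = 3, seed = 1
#' ))
#' tm$metadata$n_cells
#' @export
generate_tissue <- function(spec = tissue_spec()) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_seed(spec$seed, {
    dom <- spec$domain
    f_ax <- spec$mesophyll_fraction^(1 / 3)
    mes_size <- dom$size * f_ax
    mes_lo <- box3_lo(dom) + (dom$size - mes_size) / 2
    mes <- box3(mes_lo, mes_size)

    A <- c(spec$cell_lateral_mean, spec$cell_lateral_mean,
           spec$cell_caliper_mean / 2)           # nominal semi-axes
    v_cell <- 4 / 3 * pi * prod(A)
    v_mes <- prod(mes_size)
    phi <- spec$cell_packing
    if (!is.null(spec$cells_per_volume)) {
      phi <- spec$cells_per_volume * prod(dom$size) * v_cell / v_mes
    }
    phi_max <- 0.73
    if (phi > phi_max)
      stop(sprintf(paste0("cell density target unreachable: requested packing",
                          " fraction %.3f of the mesophyll region exceeds the",
                          " achievable %.2f"), phi, phi_max), call. = FALSE)

    L <- mes_size / (2 * A)                      # scaled mesophyll dims
    if (spec$placement == "lattice") {
      gamma <- (0.7405 / phi)^(1 / 3)
      sites <- fcc_sites(L, gamma)
      m <- nrow(sites)
      # per-cell semi-axes, scatter capped by the packing slack
      lat <- pmax(0.2 * A[1],
                  spec$cell_lateral_mean + spec$cell_lateral_sd * rnorm(m))
      zax <- pmax(0.2 * A[3],
                  (spec$cell_caliper_mean + spec$cell_caliper_sd * rnorm(m)) / 2)
      axes <- cbind(lat, lat, zax)
      sc <- sweep(axes, 2, 2 * A, "/")           # scaled semi-axes
      s <- 2 * pmax(sc[, 1], sc[, 2], sc[, 3])   # scaled diameters
      too_big <- s > 0.999 * gamma
      if (any(too_big)) {
        shrink <- 0.999 * gamma / s[too_big]
        axes[too_big, ] <- axes[too_big, ] * shrink
        sc[too_big, ] <- sc[too_big, ] * shrink
        s[too_big] <- 0.999 * gamma
      }
      jr <- 0.45 * max(0, gamma - max(s))
      dir <- matrix(rnorm(3 * m), m, 3)
      dir <- dir / sqrt(rowSums(dir^2))
      jit <- dir * (jr * runif(m)^(1 / 3))
      cen_s <- sites + jit
      fits <- cen_s[, 1] - sc[, 1] >= 0 & cen_s[, 1] + sc[, 1] <= L[1] &
        cen_s[, 2] - sc[, 2] >= 0 & cen_s[, 2] + sc[, 2] <= L[2] &
        cen_s[, 3] - sc[, 3] >= 0 & cen_s[, 3] + sc[, 3] <= L[3]
      cen_s <- cen_s[fits, , drop = FALSE]
      axes <- axes[fits, , drop = FALSE]
      if (!is.null(spec$n_cells)) {
        if (spec$n_cells > nrow(cen_s))
          stop(sprintf(paste0("cell density target unreachable: %d cells",
                              " requested, lattice holds %d (achieved packing",
                              " fraction %.3f)"),
                       spec$n_cells, nrow(cen_s),
                       nrow(cen_s) * v_cell / v_mes), call. = FALSE)
        keep <- sort(sample.int(nrow(cen_s), spec$n_cells))
        cen_s <- cen_s[keep, , drop = FALSE]
        axes <- axes[keep, , drop = FALSE]
      }
      centers <- sweep(sweep(cen_s, 2, 2 * A, "*"), 2, mes_lo, "+")
    } else {
      n_target <- spec$n_cells %||% max(1L, floor(phi * v_mes / v_cell))
      centers <- matrix(NA_real_, 0, 3)
      axes <- matrix(NA_real_, 0, 3)
      attempts <- 0L
      limit <- 200L * n_target
      while (nrow(centers) < n_target && attempts < limit) {
        attempts <- attempts + 1L
        lat <- pmax(0.2 * A[1],
                    spec$cell_lateral_mean + spec$cell_lateral_sd * rnorm(1))
        zax <- pmax(0.2 * A[3],
                    (spec$cell_caliper_mean + spec$cell_caliper_sd * rnorm(1)) / 2)
        ax <- c(lat, lat, zax)
        lo <- box3_lo(mes) + ax; hi <- box3_hi(mes) - ax
        if (any(hi < lo)) next
        cen <- lo + runif(3) * (hi - lo)
        if (nrow(centers) > 0L) {
          cand <- list(cx = cen[1], cy = cen[2], cz = cen[3],
                       rx = ax[1], ry = ax[2], rz = ax[3])
          prev <- data.frame(cx = centers[, 1], cy = centers[, 2],
                             cz = centers[, 3], rx = axes[, 1],
                             ry = axes[, 2], rz = axes[, 3])
          if (!all(spheroids_surely_disjoint(cand, prev))) next
        }
        centers <- rbind(centers, cen)
        axes <- rbind(axes, ax)
      }
      if (nrow(centers) < n_target)
        stop(sprintf(paste0("cell density target unreachable by dart-throwing:",
                            " %d of %d cells placed (achieved packing fraction",
                            " %.3f)"), nrow(centers), n_target,
                     sum(4 / 3 * pi * apply(axes, 1, prod)) / v_mes),
             call. = FALSE)
    }

    n_cells <- nrow(centers)
    if (n_cells == 0L)
      stop("no cells could be placed in the mesophyll region", call. = FALSE)
    cells <- spheroids(id = seq_len(n_cells), center = centers,
                       semi_axes = axes, role = "cell_body")

    # defensive: construction must guarantee pairwise non-overlap
    if (n_cells > 1L) {
      for (i in seq_len(n_cells - 1L)) {
        rest <- cells[(i + 1L):n_cells, , drop = FALSE]
        if (!all(spheroids_surely_disjoint(as.list(cells[i, ]), rest)))
          stop("internal error: overlapping cell bodies generated")
      }
    }

    counts <- pmax(0L, as.integer(round(
      rnorm(n_cells, spec$chl_per_cell_mean, spec$chl_per_cell_sd))))
    id_next <- n_cells + 1L
    parts <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      parts[[i]] <- place_particles_in_cell(
        cell = as.list(cells[i, ]), n = counts[i],
        mean_axes = spec$chl_semi_axes_mean, cv = spec$chl_semi_axes_cv,
        id_start = id_next
      )
      id_next <- id_next + counts[i]
    }
    particles <- as_spheroid_set(do.call(rbind, c(list(empty_spheroid_set()),
                                                  lapply(parts, as.data.frame))))

    metadata <- list(
      n_cells = n_cells,
      n_particles = nrow(particles),
      chl_per_cell = counts,
      mean_chl_per_cell = if (n_cells) sum(counts) / n_cells else NA_real_,
      mesophyll_fraction_realized = prod(mes$size) / prod(dom$size),
      cell_packing_realized =
        sum(4 / 3 * pi * cells$rx * cells$ry * cells$rz) / v_mes,
      mean_cell_caliper = mean(2 * cells$rz),
      mean_chl_caliper = if (nrow(particles)) mean(2 * particles$rz) else NA_real_,
      seed = spec$seed
    )
    structure(list(cells = cells, particles = particles, domain = dom,
                   mesophyll = mes, spec = spec, metadata = metadata),
              class = "tissue_model")
  })
}

#' @export
print.tissue_model <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(paste0("<tissue_model> %d cells, %d chloroplasts",
                     " (%.1f per cell)\n"),
              md$n_cells, md$n_particles, md$mean_chl_per_cell))
  cat(sprintf("  domain %g x %g x %g um, mesophyll fraction %.3f, packing %.3f\n",
              x$domain$size[1], x$domain$size[2], x$domain$size[3],
              md$mesophyll_fraction_realized, md$cell_packing_realized))
  cat(sprintf("  mean calipers: cell %.1f um, chloroplast %.2f um\n",
              md$mean_cell_caliper, md$mean_chl_caliper))
  invisible(x)
}

#' Systematic uniform random (SUR) section positions
#'
#' A random start followed by fixed-period positions, giving every location
#' the same sampling probability. Two dialects of the random start: the
#' `"sixths"` dialect draws a random integer `k` in 0..5 and starts at
#' `(k + 1) * period / 6` (for a 3 mm period the first cross-section falls
#' 0.5, 1, ..., or 3 mm from the tip); the `"continuous"` dialect draws the
#' start uniformly in `(0, period]`.
#'
#' @param length sampled extent (um).
#' @param period sampling period `T` (um), `0 < period <= length`.
#' @param offset fixed first position (um), or `NULL` to draw it at random.
#' @param dialect `"sixths"` (integer sixth-steps of the period) or `"continuous"`.
#' @return Numeric vector of positions `offset + i * period` within
#'   `(0, length]`.
#' @examples
#' sur_positions(30000, 3000, offset = 2000)  # 2000, 5000, ..., 29000
#' @export
sur_positions <- function(length, period, offset = NULL,
                          dialect = c("sixths", "continuous")) {
  dialect <- match.arg(dialect)
  check_scalar(length, "length", positive = TRUE)
  check_scalar(period, "period", positive = TRUE)
  if (period > length)
    stop("`period` must satisfy 0 < period <= length", call. = FALSE)
  if (is.null(offset)) {
    offset <- if (dialect == "sixths") {
      (sample(0:5, 1L) + 1L) * period / 6
    } else {
      stats::runif(1, 0, period)
    }
  }
  check_scalar(offset, "offset", positive = TRUE)
  if (offset > length) return(numeric(0))
  seq(offset, length, by = period)
}

model_spheroids <- function(model, role = c("particle", "cell_body", "all")) {
  role <- match.arg(role)
  if (inherits(model, "cell_model")) {
    cells <- model$cell; parts <- model$particles
  } else if (inherits(model, "tissue_model")) {
    cells <- model$cells; parts <- model$particles
  } else if (inherits(model, "spheroid_set")) {
    s <- as_spheroid_set(model)
    cells <- s[s$role == "cell_body", , drop = FALSE]
    parts <- s[s$role == "particle", , drop = FALSE]
  } else {
    stop("`model` must be a cell_model, tissue_model or spheroid_set",
         call. = FALSE)
  }
  switch(role,
         particle = as_spheroid_set(parts),
         cell_body = as_spheroid_set(cells),
         all = bind_spheroids(parts, cells))
}

#' Section a model: 2D profiles at a given height
#'
#' Cuts the model with the plane at height `z` and returns one elliptical
#' profile per spheroid of the requested role whose z-extent contains `z`.
#'
#' @param model a `cell_model`, `tissue_model` or `spheroid_set`.
#' @param z section height (um).
#' @param role which spheroids to section: `"particle"` (default),
#'   `"cell_body"` or `"all"`.
#' @return A `profile_set` (see [plane_profile()]).
#' @export
section_profiles <- function(model, z,
                             role = c("particle", "cell_body", "all")) {
  plane_profile(model_spheroids(model, match.arg(role)), z)
}
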