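#' Specification of a labelled optical-section stack
#'
#' Describes a voxelized stand-in for a confocal acquisition: `n_sections`
#' label images of a `frame` (w x d um) field of view, `dz` um apart, with
#' square pixels of `pixel_size` um. Page 0 is the topmost plane (the
#' reference side of the disector browsing order): section `k` lies at
#' `z = z_top - k * dz`.
#'
#' @param origin `(x, y, z_top)` um: lower-left corner of the field of view
#'   and the height of the topmost section.
#' @param frame `(w, d)` um field-of-view extents.
#' @param n_sections number of optical sections (>= 1).
#' @param dz section spacing (um); 0.5 um for chloroplast stacks, 2 um for
#'   cell stacks in the calibration this package emulates.
#' @param pixel_size pixel edge (um).
#' @param channel which spheroids to render: `"chloroplasts"`, `"cells"` or
#'   `"both"`.
#' @return A `stack_spec` list.
#' @export
stack_spec <- function(origin, frame, n_sections, dz, pixel_size,
                       channel = c("chloroplasts", "cells", "both")) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(origin), length(origin) == 3L)
  stopifnot(is.numeric(frame), length(frame) == 2L, all(frame > 0))
  check_scalar(n_sections, "n_sections", positive = TRUE)
  check_scalar(dz, "dz", positive = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  structure(list(origin = as.numeric(origin), frame = as.numeric(frame),
                 n_sections = as.integer(n_sections), dz = dz,
                 pixel_size = pixel_size, channel = channel),
            class = "stack_spec")
}

#' Render a model into a labelled z-stack
#'
#' Voxelizes the model into 16-bit label images: a pixel carries a particle's
#' id when the pixel centre lies inside that particle's section ellipse; when
#' particles overlap, the highest id wins (particles are rasterized in
#' increasing id order, later ones overwriting). A warning is raised (and
#' blank pages returned) when the field of view lies outside the model.
#'
#' @param model a `cell_model`, `tissue_model` or `spheroid_set`.
#' @param spec a [stack_spec()].
#' @return A `label_stack`: list of integer label matrices (`pages`, row = y,
#'   column = x, page 1 = topmost section) plus `origin`, `z_top`, `dz`,
#'   `pixel_size`, `channel`.
#' @export
render_label_stack <- function(model, spec) {
  stopifnot(inherits(spec, "stack_spec"))
  role <- switch(spec$channel, chloroplasts = "particle",
                 cells = "cell_body", both = "all")
  s <- model_spheroids(model, role)
  if (any(s$id > 65535L))
    stop("labels exceed the 16-bit range", call. = FALSE)
  px <- spec$pixel_size
  nx <- max(1L, round(spec$frame[1] / px))
  ny <- max(1L, round(spec$frame[2] / px))
  xs <- spec$origin[1] + (seq_len(nx) - 0.5) * px
  ys <- spec$origin[2] + (seq_len(ny) - 0.5) * px

  if (nrow(s) > 0L) {
    inside <- any(s$cx + s$rx >= min(xs) & s$cx - s$rx <= max(xs) &
                    s$cy + s$ry >= min(ys) & s$cy - s$ry <= max(ys))
    if (!inside)
      warning("field of view lies outside the model: rendering blank pages",
              call. = FALSE)
  }

  pages <- vector("list", spec$n_sections)
  for (k in seq_len(spec$n_sections) - 1L) {
    z <- spec$origin[3] - k * spec$dz
    page <- matrix(0L, ny, nx)
    profs <- plane_profile(s, z)
    if (nrow(profs) > 0L) {
      profs <- profs[order(profs$particle_id), , drop = FALSE]
      for (r in seq_len(nrow(profs))) {
        p <- profs[r, ]
        jj <- which(abs(xs - p$cx) <= p$ax)
        ii <- which(abs(ys - p$cy) <= p$ay)
        if (!length(jj) || !length(ii)) next
        ex <- if (p$ax == 0) {
          outer(rep(0, length(ii)), rep(0, length(jj)), "+")
        } else {
          outer(rep(1, length(ii)), ((xs[jj] - p$cx) / p$ax)^2)
        }
        ey <- if (p$ay == 0) 0 else ((ys[ii] - p$cy) / p$ay)^2
        m <- ex + ey <= 1
        sub <- page[ii, jj, drop = FALSE]
        sub[m] <- p$particle_id
        page[ii, jj] <- sub
      }
    }
    pages[[k + 1L]] <- page
  }
  structure(list(pages = pages, origin = spec$origin[1:2],
                 z_top = spec$origin[3], dz = spec$dz,
                 pixel_size = px, channel = spec$channel),
            class = "label_stack")
}

#' @export
print.label_stack <- function(x, ...) {
  d <- dim(x$pages[[1]])
  cat(sprintf(paste0("<label_stack> %d sections of %d x %d px",
                     " (pixel %g um, dz %g um), channel %s\n"),
              length(x$pages), d[2], d[1], x$pixel_size, x$dz, x$channel))
  invisible(x)
}

#' Write / read a label stack as multi-page TIFF with JSON sidecar
#'
#' The stack is stored as an uncompressed 16-bit multi-page TIFF (page 0 =
#' topmost section) together with a `<path>.json` sidecar carrying the voxel
#' metadata (`pixel_size_um`, `dz_um`, `origin_um`, `z_top_um`, `channel`).
#'
#' @param stack a `label_stack`.
#' @param path TIFF file path.
#' @return `write_label_stack` returns `path` invisibly; `read_label_stack`
#'   returns the reconstructed `label_stack`.
#' @export
write_label_stack <- function(stack, path) {
  stopifnot(inherits(stack, "label_stack"))
  imgs <- lapply(stack$pages, function(m) m / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_um = stack$pixel_size, dz_um = stack$dz,
               origin_um = stack$origin, z_top_um = stack$z_top,
               channel = stack$channel, n_sections = length(stack$pages))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_label_stack
#' @export
read_label_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- lapply(imgs, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  structure(list(pages = pages, origin = as.numeric(meta$origin_um),
                 z_top = meta$z_top_um, dz = meta$dz_um,
                 pixel_size = meta$pixel_size_um, channel = meta$channel),
            class = "label_stack")
}
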