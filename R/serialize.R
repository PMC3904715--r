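#' Serialize a geometric model to JSON
#'
#' One JSON document per model: the spheroid tables (particles and cell
#' bodies), the domain geometry and the generation metadata, written at full
#' double precision so that write/read round-trips are exact.
#'
#' @param model a `cell_model` or `tissue_model`.
#' @param path output file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the reconstructed model.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "cell_model")) {
    doc <- list(type = "cell_model",
                cell = as.data.frame(model$cell),
                particles = as.data.frame(model$particles),
                spec = unclass(model$spec),
                seed = model$seed)
  } else if (inherits(model, "tissue_model")) {
    spec <- unclass(model$spec)
    spec$domain <- unclass(spec$domain)
    doc <- list(type = "tissue_model",
                cells = as.data.frame(model$cells),
                particles = as.data.frame(model$particles),
                domain = unclass(model$domain),
                mesophyll = unclass(model$mesophyll),
                spec = spec,
                metadata = model$metadata)
  } else {
    stop("`model` must be a cell_model or tissue_model", call. = FALSE)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null")
  invisible(path)
}

json_to_spheroids <- function(df) {
  if (is.null(df) || !length(df) || !NROW(df)) return(empty_spheroid_set())
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("cx", "cy", "cz", "rx", "ry", "rz"))
    df[[col]] <- as.numeric(df[[col]])
  df$id <- as.integer(df$id)
  df$parent_id <- suppressWarnings(as.integer(df$parent_id))
  as_spheroid_set(df[, c("id", "parent_id", "cx", "cy", "cz",
                         "rx", "ry", "rz", "role")])
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$type, "cell_model")) {
    spec <- doc$spec
    sp <- model_cell_spec(
      n_chloroplasts = spec$n_chloroplasts,
      cell_semi_axes = as.numeric(spec$cell_semi_axes),
      chl_semi_axes_mean = as.numeric(spec$chl_semi_axes_mean),
      chl_semi_axes_cv = spec$chl_semi_axes_cv,
      placement = spec$placement, shell_thickness = spec$shell_thickness,
      allow_overlap = spec$allow_overlap,
      allow_any_height = spec$allow_any_height,
      seed = spec$seed
    )
    structure(list(cell = json_to_spheroids(doc$cell),
                   particles = json_to_spheroids(doc$particles),
                   spec = sp, seed = doc$seed),
              class = "cell_model")
  } else if (identical(doc$type, "tissue_model")) {
    spec <- doc$spec
    sp <- tissue_spec(
      domain = box3(as.numeric(spec$domain$origin),
                    as.numeric(spec$domain$size)),
      cell_caliper_mean = spec$cell_caliper_mean,
      cell_caliper_sd = spec$cell_caliper_sd,
      cell_lateral_mean = spec$cell_lateral_mean,
      cell_lateral_sd = spec$cell_lateral_sd,
      n_cells = spec$n_cells, cells_per_volume = spec$cells_per_volume,
      chl_per_cell_mean = spec$chl_per_cell_mean,
      chl_per_cell_sd = spec$chl_per_cell_sd,
      chl_semi_axes_mean = as.numeric(spec$chl_semi_axes_mean),
      chl_semi_axes_cv = spec$chl_semi_axes_cv,
      mesophyll_fraction = spec$mesophyll_fraction,
      cell_packing = spec$cell_packing,
      placement = spec$placement, seed = spec$seed
    )
    md <- doc$metadata
    md$chl_per_cell <- as.integer(md$chl_per_cell)
    structure(list(cells = json_to_spheroids(doc$cells),
                   particles = json_to_spheroids(doc$particles),
                   domain = box3(as.numeric(doc$domain$origin),
                                 as.numeric(doc$domain$size)),
                   mesophyll = box3(as.numeric(doc$mesophyll$origin),
                                    as.numeric(doc$mesophyll$size)),
                   spec = sp, metadata = md),
              class = "tissue_model")
  } else {
    stop("unknown model type in JSON document", call. = FALSE)
  }
}
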