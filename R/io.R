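#' Read a colony plate table
#'
#' Reads plate colony sizes in either supported dialect and returns the
#' canonical long tibble. The *long* dialect is a TSV (or CSV) with
#' columns `plate_id, media, induced, replicate, row, col, strain_id,
#' size`. The *dense* dialect is a numeric size matrix (rows x cols,
#' header-less) with a sidecar strain map TSV of `row, col, strain_id`;
#' plate metadata then come from the arguments.
#'
#' @param path Path to the long table, or to the dense matrix when
#'   `strain_map` is given.
#' @param strain_map Optional path to the sidecar strain map (dense
#'   dialect).
#' @param plate_id,media,induced,replicate Metadata for the dense dialect.
#' @return Long plate tibble (see [score_relative_growth()] for the
#'   contract). Malformed rows abort with their line numbers; negative
#'   sizes are a validation error.
#' @export
read_plate_table <- function(path, strain_map = NULL, plate_id = "P1",
                             media = "rich", induced = FALSE,
                             replicate = 1L) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(strain_map)) {
    df <- read_delim_auto(path)
    required <- c("plate_id", "media", "induced", "replicate",
                  "row", "col", "strain_id", "size")
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      abort(paste0("missing required columns: ",
                   paste(missing, collapse = ", ")))
    }
    df <- df %>% mutate(
      induced = as.logical(.data$induced),
      replicate = as.integer(.data$replicate),
      row = as.integer(.data$row), col = as.integer(.data$col),
      size = as.numeric(.data$size)
    )
    bad <- which(is.na(df$size) | df$size < 0 | is.na(df$row) | is.na(df$col))
    if (length(bad)) {
      abort(sprintf("invalid size/position on data line(s): %s",
                    paste(head(bad, 10), collapse = ", ")))
    }
    as_tibble(df[required])
  } else {
    mat <- as.matrix(utils::read.table(path, sep = "\t"))
    smap <- read_delim_auto(strain_map)
    if (!all(c("row", "col", "strain_id") %in% names(smap))) {
      abort("strain map needs columns row, col, strain_id.")
    }
    if (any(smap$row > nrow(mat)) || any(smap$col > ncol(mat))) {
      abort("strain map positions fall outside the size matrix.")
    }
    sizes <- mat[cbind(smap$row, smap$col)]
    if (any(is.na(sizes) | sizes < 0)) {
      abort("size matrix holds negative or missing values at mapped positions.")
    }
    tibble(
      plate_id = plate_id, media = media, induced = induced,
      replicate = as.integer(replicate),
      row = as.integer(smap$row), col = as.integer(smap$col),
      strain_id = smap$strain_id, size = sizes
    )
  }
}

#' Write a plate table in the long TSV dialect
#'
#' @param plates Long plate tibble.
#' @param path Output path (tab-separated, UTF-8, header row).
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(plates, path) {
  readr::write_tsv(plates, path)
  invisible(path)
}

# TSV canonical; CSV accepted on read
read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read and write per-cell intensity tables
#'
#' TSV of `strain_id, condition, channel, cell_id, mean_intensity`.
#'
#' @param path File path.
#' @return Tibble of per-cell records.
#' @export
read_cell_table <- function(path) {
  df <- read_delim_auto(path)
  required <- c("strain_id", "condition", "channel", "cell_id",
                "mean_intensity")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(df$mean_intensity <= 0, na.rm = TRUE)) {
    abort("mean_intensity values must be positive.")
  }
  as_tibble(df[required])
}

#' @rdname read_cell_table
#' @param cells Tibble of per-cell records.
#' @export
write_cell_table <- function(cells, path) {
  readr::write_tsv(cells, path)
  invisible(path)
}

#' Read and write degradation time-course tables
#'
#' TSV of `strain_id, modality, replicate, time_min, signal`.
#'
#' @param path File path.
#' @return Tibble of time-course records.
#' @export
read_timecourse_table <- function(path) {
  df <- read_delim_auto(path)
  required <- c("strain_id", "modality", "replicate", "time_min", "signal")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  as_tibble(df[required])
}

#' @rdname read_timecourse_table
#' @param tc Tibble of time-course records.
#' @export
write_timecourse_table <- function(tc, path) {
  readr::write_tsv(tc, path)
  invisible(path)
}

#' Read and write single-channel grayscale images
#'
#' TIFF (8/16-bit grayscale) and PNG are supported by file extension.
#' Images are numeric matrices in integer camera units (not rescaled to
#' `[0, 1]`): a 16-bit TIFF reads as values in `[0, 65535]`.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("the png package is required to read PNG images.")
    }
    img <- png::readPNG(path) * 65535
  } else {
    abort(sprintf("unsupported image extension '%s'.", ext))
  }
  if (length(dim(img)) == 3L) img <- img[, , 1] # first channel
  img
}

#' @rdname read_image
#' @param image Numeric matrix in integer units.
#' @param bits Bits per sample (8 or 16) for TIFF output.
#' @export
write_image <- function(image, path, bits = 16L) {
  ext <- tolower(tools::file_ext(path))
  max_val <- 2^bits - 1
  scaled <- pmin(pmax(image / max_val, 0), 1)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("the png package is required to write PNG images.")
    }
    png::writePNG(scaled, path)
  } else {
    abort(sprintf("unsupported image extension '%s'.", ext))
  }
  invisible(path)
}

#' Read and write centroid tables
#'
#' TSV of `cell_id, row, col` (1-based pixel coordinates).
#'
#' @param path File path.
#' @return Tibble of centroid records.
#' @export
read_centroid_table <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("row", "col") %in% names(df))) {
    abort("centroid table needs `row` and `col` columns.")
  }
  if (!"cell_id" %in% names(df)) df$cell_id <- seq_len(nrow(df))
  as_tibble(df[c("cell_id", "row", "col")])
}

#' @rdname read_centroid_table
#' @param centroids Tibble of centroid records.
#' @export
write_centroid_table <- function(centroids, path) {
  readr::write_tsv(centroids, path)
  invisible(path)
}

#' Default run configuration
#'
#' All stage parameters with their defaults: the screen's published values
#' where one exists (growth thresholds 0.5 / 0.1, colony presence 50 A.U.,
#' 2-SD trimming and band, 65-px boxes on a 20 x 20 grid, 0.35%
#' saturation) and this package's documented choices elsewhere. Override
#' any subset via `...` or a YAML file ([read_run_config()]).
#'
#' @param ... Named overrides of the defaults (unknown names abort).
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # simulation
    n_strains = 96L, layout = c(8L, 12L), lethal_fraction = 0.1,
    effect_size = 0.05, noise_cv = 0.1, edge_boost = 1.2,
    n_cells = 200L, depletion_factor = 0.3,
    t50 = 45, plateau = 0.1, tc_noise_cv = 0.05, n_rep = 3L,
    # growth screen
    permissive = 0.5, stringent = 0.1, presence_threshold = 50,
    trim_outliers_k = 2,
    # fluorescence screen
    alpha = 0.05, min_effect = 0.75, death_fraction = 0.25, trim_k = 2,
    band_k = 2,
    # enrichment
    top_k = 3L,
    # montage
    box_size = 65L, grid_dims = c(20L, 20L), saturate_fraction = 0.0035
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, overrides)
  structure(cfg, class = c("run_config", "list"))
}

#' Read and write YAML run configurations
#'
#' @param path YAML file path.
#' @return A `run_config` list (unspecified fields filled with defaults).
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
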