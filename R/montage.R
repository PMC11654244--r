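#' Crop fixed boxes around cell centroids
#'
#' Extracts a square `box_size x box_size` crop centered on each centroid
#' (for an odd box the crop's center pixel is exactly the centroid pixel).
#' Regions falling outside the image frame are zero-padded; raw
#' intensities are copied unmodified. Centroids outside the frame are
#' skipped with a warning. Pixel coordinates are 1-based matrix indices
#' (row 1, col 1 at the top-left), matching how the centroid tables are
#' read and written.
#'
#' @param image Numeric matrix (single-channel image).
#' @param centroids Tibble with `row`, `col` (and optionally `cell_id`)
#'   columns in pixel coordinates of `image`.
#' @param box_size Crop side length in pixels (default 65).
#' @return Tibble of `cell_id, row, col` with a `pixels` list-column of
#'   `box_size x box_size` matrices; zero rows for an empty centroid list.
#' @examples
#' img <- sim_cell_image(1, image_size = 131, cell_radius = 5, seed = 1)
#' crops <- crop_cells(img$image, img$centroids)
#' dim(crops$pixels[[1]])
#' @export
crop_cells <- function(image, centroids, box_size = 65L) {
  if (!is.matrix(image)) abort("`image` must be a matrix.")
  if (box_size < 1L) abort("`box_size` must be >= 1.")
  half <- (box_size - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  if (!all(c("row", "col") %in% names(centroids))) {
    abort("`centroids` needs `row` and `col` columns.")
  }
  cents <- as_tibble(centroids)
  if (!"cell_id" %in% names(cents)) cents$cell_id <- seq_len(nrow(cents))
  # even-box convention: centroid sits at floor(box/2) + 1
  inside <- cents$row >= 1 & cents$row <= nr & cents$col >= 1 & cents$col <= nc
  if (any(!inside)) {
    warn(sprintf("%d centroid(s) outside the image frame were skipped.",
                 sum(!inside)))
    cents <- cents[inside, ]
  }
  crops <- purrr::pmap(list(cents$row, cents$col), function(r, c) {
    out <- matrix(0, box_size, box_size)
    rr <- (r - half):(r - half + box_size - 1L)
    cc <- (c - half):(c - half + box_size - 1L)
    src_r <- rr >= 1 & rr <= nr
    src_c <- cc >= 1 & cc <= nc
    out[which(src_r), which(src_c)] <- image[rr[src_r], cc[src_c]]
    out
  })
  tibble(cell_id = cents$cell_id, row = cents$row, col = cents$col,
         pixels = crops)
}

#' Assemble cell crops into a grid montage
#'
#' Lays crops out row-major on a `grid_dims` grid (default 20 x 20, up to
#' 400 cells), producing a canvas of `grid_dims * box_size` pixels
#' (1,300 x 1,300 for the defaults). Intensities are preserved verbatim at
#' this stage so expression levels remain comparable across cells and
#' timepoints; unplaced tiles are zero. Excess crops beyond the grid
#' capacity are truncated with a warning.
#'
#' @param crops Output of [crop_cells()] (or a bare list of equal-size
#'   square matrices).
#' @param grid_dims Integer vector `c(rows, cols)` of tiles.
#' @return An object of class `montage`: list with `pixels` (matrix),
#'   `grid_dims`, `box_size`, `n_cells_placed`, `contrast` (NULL until
#'   [adjust_contrast()]), `bit_depth`.
#' @examples
#' tiles <- replicate(4, matrix(1, 65, 65), simplify = FALSE)
#' m <- assemble_grid(tiles, grid_dims = c(2, 2))
#' dim(m$pixels) # 130 130
#' @export
assemble_grid <- function(crops, grid_dims = c(20L, 20L)) {
  tiles <- if (is.data.frame(crops)) crops$pixels else crops
  capacity <- prod(grid_dims)
  if (length(tiles) > capacity) {
    warn(sprintf("%d crops exceed the %d-tile grid; extras dropped.",
                 length(tiles), capacity))
    tiles <- tiles[seq_len(capacity)]
  }
  if (length(tiles) > 0L) {
    dims <- unique(purrr::map(tiles, dim))
    if (length(dims) != 1L || dims[[1]][1] != dims[[1]][2]) {
      abort("all crops must be square matrices of one size.")
    }
    box <- dims[[1]][1]
  } else {
    box <- 65L
  }
  canvas <- matrix(0, grid_dims[1] * box, grid_dims[2] * box)
  for (i in seq_along(tiles)) {
    tr <- (i - 1L) %/% grid_dims[2] # tile row, 0-based
    tc <- (i - 1L) %% grid_dims[2]
    canvas[tr * box + seq_len(box), tc * box + seq_len(box)] <- tiles[[i]]
  }
  structure(
    list(pixels = canvas, grid_dims = as.integer(grid_dims),
         box_size = as.integer(box), n_cells_placed = length(tiles),
         contrast = NULL, bit_depth = 16L),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf(
    "Cell-grid montage: %d x %d px (%d x %d tiles of %d px), %d cells, %d-bit%s\n",
    nrow(x$pixels), ncol(x$pixels), x$grid_dims[1], x$grid_dims[2],
    x$box_size, x$n_cells_placed, x$bit_depth,
    if (is.null(x$contrast)) "" else
      sprintf(", contrast-adjusted (%.2f%% saturation)",
              100 * x$contrast$saturate_fraction)))
  invisible(x)
}

#' Extract one tile from a montage
#'
#' Inverse of [assemble_grid()] placement: returns the pixels of the
#' `i`-th tile in row-major order.
#'
#' @param montage A `montage` object.
#' @param i Tile index (row-major, 1-based).
#' @return A `box_size x box_size` matrix.
#' @export
extract_tile <- function(montage, i) {
  box <- montage$box_size
  tr <- (i - 1L) %/% montage$grid_dims[2]
  tc <- (i - 1L) %% montage$grid_dims[2]
  montage$pixels[tr * box + seq_len(box), tc * box + seq_len(box)]
}

#' Adjust montage contrast by pixel-saturation fraction
#'
#' Linear contrast stretch clipped so that approximately
#' `saturate_fraction` of pixels saturate (default 0.35%): the upper clip
#' bound is the `1 - saturate_fraction` quantile, the lower bound is the
#' image minimum (bright-end saturation only, suiting fluorescence
#' visualization), and values are mapped linearly onto the full range of
#' the montage's bit depth. Pure function: the input is untouched. A
#' constant image is returned unchanged with a flag. Pixel ordering is
#' preserved wherever not clipped. The saturated fraction can exceed the
#' request by at most one quantization step (ties at the bound).
#'
#' @param montage A `montage` object.
#' @param saturate_fraction Target saturated-pixel fraction.
#' @param side `"top"` (default) anchors the lower bound at the minimum;
#'   `"both"` splits the fraction between tails.
#' @return A new `montage` with rescaled `pixels` and a `contrast` record
#'   (`saturate_fraction, lo, hi, constant`).
#' @export
adjust_contrast <- function(montage, saturate_fraction = 0.0035,
                            side = c("top", "both")) {
  side <- match.arg(side)
  check_fraction(saturate_fraction, "saturate_fraction")
  x <- montage$pixels
  max_val <- 2^montage$bit_depth - 1
  if (diff(range(x)) == 0) {
    montage$contrast <- list(saturate_fraction = saturate_fraction,
                             lo = min(x), hi = max(x), constant = TRUE)
    return(montage)
  }
  f_top <- if (side == "top") saturate_fraction else saturate_fraction / 2
  f_bot <- if (side == "top") 0 else saturate_fraction / 2
  hi <- quantile(x, 1 - f_top, type = 1, names = FALSE)
  lo <- if (f_bot > 0) quantile(x, f_bot, type = 1, names = FALSE) else min(x)
  if (hi <= lo) hi <- max(x)
  out <- (x - lo) / (hi - lo) * max_val
  out <- pmin(pmax(out, 0), max_val)
  montage$pixels <- matrix(out, nrow(x), ncol(x))
  montage$contrast <- list(saturate_fraction = saturate_fraction,
                           lo = lo, hi = hi, constant = FALSE)
  montage
}

#' Downscale a montage to 8 bits
#'
#' Linear min-max rescale onto `[0, 255]` with half-up rounding, used for
#' brightfield montages where intensity variations carry no information
#' and storage matters.
#'
#' @param montage A `montage` object (bit depth >= 8).
#' @return The montage with 8-bit `pixels` and `bit_depth = 8`.
#' @examples
#' m <- assemble_grid(list(matrix(c(0, 65535), 2, 2)), grid_dims = c(1, 1))
#' range(to_8bit(m)$pixels) # 0 255
#' @export
to_8bit <- function(montage) {
  if (montage$bit_depth < 8L) abort("input bit depth must be >= 8.")
  x <- montage$pixels
  rng <- range(x)
  out <- if (diff(rng) == 0) matrix(0, nrow(x), ncol(x)) else
    round_half_up((x - rng[1]) / (rng[2] - rng[1]) * 255)
  montage$pixels <- out
  montage$bit_depth <- 8L
  montage
}
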