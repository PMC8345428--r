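#' Open a whole-slide image
#'
#' Reads the header(s) of a (possibly multi-page pyramidal) TIFF and returns a
#' lightweight handle. Page 0 is taken as the full-resolution level; further
#' pages, if present, must be strictly decreasing in size and become pyramid
#' levels with downsample factor `width_px / width_level`. Pixel data are
#' decoded lazily on first tile access and cached on the handle.
#'
#' @param path path to a TIFF file (plain, multi-page, or pyramidal).
#' @param mpp optional microns-per-pixel of level 0 (not stored by the
#'   generic TIFF tags this reader exposes, so supplied by the caller).
#' @return an object of class `slide` with fields `width_px`, `height_px`,
#'   `levels` (downsample factors, level 0 = 1.0), `mpp`, `source_path`.
#' @examples
#' \donttest{
#' sl <- generate_slide(fixture_spec(width_px = 640, height_px = 640,
#'                                   n_clusters = 2, seed = 1),
#'                      dir = tempdir())
#' s <- open_slide(sl$slide_path)
#' s$width_px
#' }
#' @export
open_slide <- function(path, mpp = NA_real_) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read slide: file not found: ", path)
  info <- tryCatch(
    tiff::readTIFF(path, all = TRUE, payload = FALSE),
    error = function(e) stop("not a readable TIFF image: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  info <- as.data.frame(info)
  widths  <- info$width
  heights <- info$length
  levels <- widths[1] / widths
  if (any(diff(levels) <= 0))
    stop("pyramid pages must be strictly decreasing in size: ", path)
  s <- structure(list(
    width_px = as.integer(widths[1]),
    height_px = as.integer(heights[1]),
    levels = as.numeric(levels),
    level_dims = cbind(width = as.integer(widths),
                       height = as.integer(heights)),
    mpp = mpp,
    source_path = normalizePath(path),
    cache = new.env(parent = emptyenv())
  ), class = "slide")
  s
}

#' @export
print.slide <- function(x, ...) {
  cat(sprintf("<slide> %d x %d px, %d level(s) [x%s]%s\n  %s\n",
              x$width_px, x$height_px, length(x$levels),
              paste(format(x$levels, trim = TRUE), collapse = ", x"),
              if (is.na(x$mpp)) "" else sprintf(", %.3f um/px", x$mpp),
              x$source_path))
  invisible(x)
}

# decode a pyramid level once and cache it; returns integer array (or matrix
# for single-channel pages)
slide_page <- function(slide, level = 1L) {
  key <- paste0("L", level)
  if (!is.null(slide$cache[[key]])) return(slide$cache[[key]])
  pages <- tiff::readTIFF(slide$source_path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pg <- pages[[level]]
  # multi-channel pages come back as normalized doubles; 8-bit values are
  # recovered exactly because the writer rounds to nearest
  if (is.double(pg)) pg <- round(pg * 255)
  storage.mode(pg) <- "integer"
  slide$cache[[key]] <- pg
  pg
}

#' Hierarchical tile grid of a slide
#'
#' Partitions level 0 of a slide into non-overlapping `tile_px`-sized square
#' tiles (right/bottom edge tiles may be smaller). Every level-0 pixel belongs
#' to exactly one tile.
#'
#' @param slide a `slide` handle from [open_slide()], or any list with
#'   `width_px`/`height_px` fields.
#' @param tile_px tile side length in level-0 pixels (default 512, the
#'   network input size).
#' @return an object of class `tile_grid` with `n_cols`, `n_rows`, `tile_px`.
#' @export
tile_grid <- function(slide, tile_px = 512L) {
  tile_px <- as.integer(tile_px)
  if (is.na(tile_px) || tile_px < 1L)
    stop("tile_px must be a positive integer")
  structure(list(
    tile_px = tile_px,
    n_cols = as.integer(ceiling(slide$width_px / tile_px)),
    n_rows = as.integer(ceiling(slide$height_px / tile_px)),
    width_px = slide$width_px,
    height_px = slide$height_px
  ), class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles of %d px (%d total) over %d x %d px\n",
              x$n_cols, x$n_rows, x$tile_px, n_tiles(x),
              x$width_px, x$height_px))
  invisible(x)
}

#' Number of tiles in a grid
#' @param grid a `tile_grid`.
#' @export
n_tiles <- function(grid) grid$n_cols * grid$n_rows

#' Pixel bounds of one tile
#'
#' Bounds are 0-based half-open level-0 pixel intervals
#' `[x0, x1) x [y0, y1)`; x indexes columns, y rows.
#'
#' @param grid a `tile_grid`.
#' @param row,col 0-based tile indices.
#' @return a `tile_ref` list with `row`, `col`, `x0`, `y0`, `x1`, `y1`.
#' @export
tile_ref <- function(grid, row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (row < 0L || row >= grid$n_rows || col < 0L || col >= grid$n_cols)
    stop(sprintf("tile (%d,%d) outside grid %d x %d",
                 row, col, grid$n_rows, grid$n_cols))
  structure(list(
    row = row, col = col,
    x0 = col * grid$tile_px,
    y0 = row * grid$tile_px,
    x1 = min((col + 1L) * grid$tile_px, grid$width_px),
    y1 = min((row + 1L) * grid$tile_px, grid$height_px)
  ), class = "tile_ref")
}

#' All tiles of a grid, row-major
#' @param grid a `tile_grid`.
#' @return list of `tile_ref`.
#' @export
grid_tiles <- function(grid) {
  out <- vector("list", n_tiles(grid))
  k <- 1L
  for (r in seq_len(grid$n_rows) - 1L)
    for (cc in seq_len(grid$n_cols) - 1L) {
      out[[k]] <- tile_ref(grid, r, cc)
      k <- k + 1L
    }
  out
}

#' Read one tile from level 0
#'
#' Returns the pixel-exact region; edge tiles come back at their true
#' (smaller) size — padding to the network input is the caller's concern.
#'
#' @param slide a `slide` handle.
#' @param tile a `tile_ref`.
#' @return integer array `h x w x 3` with 8-bit RGB values (0–255).
#' @export
read_tile <- function(slide, tile) {
  if (tile$x1 > slide$width_px || tile$y1 > slide$height_px ||
      tile$x0 < 0L || tile$y0 < 0L || tile$x1 <= tile$x0 || tile$y1 <= tile$y0)
    stop("tile bounds outside slide")
  pg <- slide_page(slide, 1L)
  if (length(dim(pg)) == 2L) dim(pg) <- c(dim(pg), 1L)
  pg[(tile$y0 + 1L):tile$y1, (tile$x0 + 1L):tile$x1, , drop = FALSE]
}

#' Write / read a whole-slide label mask
#'
#' Masks are single-channel 8-bit TIFFs (LZW, lossless) in the level-0 frame
#' of their parent slide; the round trip is exact for labels 0–255.
#'
#' @param mask integer matrix of labels (0–255), `height_px x width_px`.
#' @param path output path.
#' @param width_px,height_px optional declared slide dimensions; if given,
#'   the mask must match them.
#' @return `path`, invisibly.
#' @export
write_slide_mask <- function(mask, path, width_px = NULL, height_px = NULL) {
  if (!is.matrix(mask)) stop("mask must be a matrix of labels")
  if (!is.null(width_px) && ncol(mask) != width_px)
    stop("mask width ", ncol(mask), " does not match slide width ", width_px)
  if (!is.null(height_px) && nrow(mask) != height_px)
    stop("mask height ", nrow(mask), " does not match slide height ", height_px)
  if (any(mask < 0L | mask > 255L)) stop("labels must be in 0..255")
  tiff::writeTIFF(mask / 255, path, bits.per.sample = 8L,
                  compression = "LZW")
  invisible(path)
}

#' @rdname write_slide_mask
#' @export
read_slide_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  storage.mode(m) <- "integer"
  m
}

# periodic symmetric (reflect) index extension: 1..n mirrored to length m
reflect_index <- function(n, m) {
  if (n >= m) return(seq_len(m))
  p <- c(seq_len(n), rev(seq_len(n)))
  p[((seq_len(m) - 1L) %% (2L * n)) + 1L]
}

# reflect-pad an h x w x c tile to target x target keeping the top-left corner
pad_tile_reflect <- function(img, target) {
  d <- dim(img)
  if (d[1] == target && d[2] == target) return(img)
  img[reflect_index(d[1], target), reflect_index(d[2], target), , drop = FALSE]
}
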