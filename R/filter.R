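#' Background-filter configuration
#'
#' Settings for the fast tissue detector that discards background-only tiles
#' before any network inference. Papanicolaou-stained material is colored on a
#' near-white background, so tissue is detected as HSV saturation above a
#' threshold with a brightness guard, on a small thumbnail.
#'
#' @param downsample thumbnail downsample factor relative to level 0
#'   (default 32).
#' @param saturation_floor either the string `"otsu"` (threshold derived from
#'   Otsu's method on the thumbnail saturation histogram) or a fixed
#'   saturation threshold in `[0, 1]`.
#' @param tissue_fraction_min minimum fraction of tissue pixels in a tile's
#'   thumbnail footprint for the tile to be kept (default 0.05).
#' @param brightness_max pixels at or above this HSV value are background
#'   regardless of saturation (default 250/255, the glass/air guard).
#' @param fallback_floor fixed saturation threshold used when the thumbnail
#'   is degenerate (all one value) and Otsu is undefined.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(downsample = 32, saturation_floor = "otsu",
                          tissue_fraction_min = 0.05,
                          brightness_max = 250 / 255,
                          fallback_floor = 25 / 255) {
  if (!(is.numeric(tissue_fraction_min) && tissue_fraction_min >= 0 &&
        tissue_fraction_min <= 1))
    stop("tissue_fraction_min must lie in [0, 1]")
  if (downsample < 1) stop("downsample must be >= 1")
  if (!identical(saturation_floor, "otsu") &&
      !(is.numeric(saturation_floor) && saturation_floor >= 0 &&
        saturation_floor <= 1))
    stop("saturation_floor must be \"otsu\" or a value in [0, 1]")
  structure(list(downsample = downsample,
                 saturation_floor = saturation_floor,
                 tissue_fraction_min = tissue_fraction_min,
                 brightness_max = brightness_max,
                 fallback_floor = fallback_floor),
            class = "filter_config")
}

# thumbnail of a slide at integer factor `ds`, as double array h x w x 3;
# reads the coarsest pyramid level whose factor divides ds, never level-0
# tiles individually
slide_thumbnail <- function(slide, ds) {
  ds <- as.integer(round(ds))
  lev <- which(slide$levels <= ds &
                 abs(ds / slide$levels - round(ds / slide$levels)) < 1e-9)
  lev <- if (length(lev)) max(lev) else 1L
  pg <- slide_page(slide, lev)
  if (length(dim(pg)) == 2L) dim(pg) <- c(dim(pg), 1L)
  rest <- as.integer(round(ds / slide$levels[lev]))
  x <- pg * 1.0
  dim(x) <- dim(pg)
  if (rest > 1L) x <- box_downsample_cpp(x, rest)
  x
}

#' Tissue mask of a slide
#'
#' Computes a boolean tissue mask on a thumbnail at `cfg$downsample`. A pixel
#' is tissue iff its HSV saturation exceeds the threshold (Otsu-derived when
#' `cfg$saturation_floor == "otsu"`) and its brightness (HSV value) is below
#' `cfg$brightness_max`. Deterministic for a fixed input; a degenerate
#' thumbnail (all one saturation value) falls back to `cfg$fallback_floor`
#' with a warning.
#'
#' @param slide a `slide` handle.
#' @param cfg a [filter_config()].
#' @return an object of class `tissue_mask`: logical matrix `mask`, the
#'   `downsample` factor, and the threshold actually used.
#' @export
tissue_mask <- function(slide, cfg = filter_config()) {
  thumb <- slide_thumbnail(slide, cfg$downsample)
  d <- dim(thumb)
  if (d[3] < 3L) stop("tissue detection needs an RGB slide")
  n <- d[1] * d[2]
  hsv <- rgb2hsv(r = as.vector(thumb[, , 1]), g = as.vector(thumb[, , 2]),
                 b = as.vector(thumb[, , 3]), maxColorValue = 255)
  s <- hsv[2L, ]; v <- hsv[3L, ]
  thr <- cfg$saturation_floor
  if (identical(thr, "otsu")) {
    if (diff(range(s)) < 1e-12) {
      warning("degenerate thumbnail (uniform saturation); using fixed floor ",
              signif(cfg$fallback_floor, 3))
      thr <- cfg$fallback_floor
    } else {
      thr <- EBImage::otsu(matrix(s, d[1], d[2]), range = c(0, 1),
                           levels = 256L)
    }
  }
  m <- matrix(s > thr & v < cfg$brightness_max, d[1], d[2])
  structure(list(mask = m, downsample = cfg$downsample, threshold = thr),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d x %d at x%g, threshold %.4f, tissue %.1f%%\n",
              nrow(x$mask), ncol(x$mask), x$downsample, x$threshold,
              100 * mean(x$mask)))
  invisible(x)
}

#' Fraction of tissue pixels in a tissue mask
#' @param tm a `tissue_mask`.
#' @export
tissue_fraction <- function(tm) mean(tm$mask)

#' Select tiles overlapping tissue
#'
#' A tile is kept iff the fraction of tissue pixels inside its (downsampled)
#' footprint is at least `cfg$tissue_fraction_min`. Kept plus discarded
#' always equals the grid's tile count.
#'
#' @param grid a [tile_grid()] over the same slide the mask came from.
#' @param tm a [tissue_mask()].
#' @param cfg a [filter_config()].
#' @return list with `kept` (list of `tile_ref`), `n_kept`, `n_discarded`,
#'   and `keep` (logical matrix `n_rows x n_cols`).
#' @export
select_tiles <- function(grid, tm, cfg = filter_config()) {
  ds <- tm$downsample
  m <- tm$mask
  keep <- matrix(FALSE, grid$n_rows, grid$n_cols)
  kept <- list()
  for (r in seq_len(grid$n_rows) - 1L) {
    for (cc in seq_len(grid$n_cols) - 1L) {
      tr <- tile_ref(grid, r, cc)
      rows <- (floor(tr$y0 / ds) + 1L):min(nrow(m), ceiling(tr$y1 / ds))
      cols <- (floor(tr$x0 / ds) + 1L):min(ncol(m), ceiling(tr$x1 / ds))
      frac <- mean(m[rows, cols])
      if (frac >= cfg$tissue_fraction_min) {
        keep[r + 1L, cc + 1L] <- TRUE
        kept[[length(kept) + 1L]] <- tr
      }
    }
  }
  list(kept = kept, n_kept = length(kept),
       n_discarded = n_tiles(grid) - length(kept), keep = keep)
}
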