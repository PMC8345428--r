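#' Stitch per-tile class maps into a whole-slide mask
#'
#' Each pixel takes the label of its unique tile; pixels not covered by any
#' tile get label 0 (background). Tiles must be pairwise non-overlapping and
#' inside the slide bounds.
#'
#' @param tiles list of `list(tile = <tile_ref>, map = <integer matrix>)`;
#'   each map must match its tile's true extent.
#' @param width_px,height_px level-0 slide dimensions.
#' @return integer label matrix `height_px x width_px`.
#' @export
stitch_tiles <- function(tiles, width_px, height_px) {
  mask <- matrix(0L, height_px, width_px)
  covered <- matrix(FALSE, height_px, width_px)
  for (tl in tiles) {
    tr <- tl$tile
    if (tr$x0 < 0L || tr$y0 < 0L || tr$x1 > width_px || tr$y1 > height_px)
      stop("tile outside slide bounds")
    rows <- (tr$y0 + 1L):tr$y1
    cols <- (tr$x0 + 1L):tr$x1
    if (!all(dim(tl$map) == c(length(rows), length(cols))))
      stop(sprintf("class map %s does not match tile extent %d x %d",
                   paste(dim(tl$map), collapse = " x "),
                   length(rows), length(cols)))
    if (any(covered[rows, cols]))
      stop(sprintf("overlapping tiles at (%d,%d)", tr$row, tr$col))
    covered[rows, cols] <- TRUE
    mask[rows, cols] <- tl$map
  }
  mask
}

#' Screen a whole slide for PTC
#'
#' The full screening pipeline: tile the slide at the network's input size,
#' discard background-only tiles with the fast tissue filter (discarded tiles
#' contribute label 0 *without* model evaluation — the pipeline's entire
#' speed claim), run the network on the kept tiles (edge tiles are
#' reflect-padded to the input size and the predictions cropped back), and
#' stitch the class maps into a whole-slide mask.
#'
#' @param slide a `slide` handle.
#' @param model an `fcn_network`; its `input_px` sets the tile size.
#' @param filter_cfg a [filter_config()].
#' @param mask_path optional path; when given, the stitched mask is written
#'   there as a single-channel TIFF.
#' @param report_path optional CSV path; the report row is appended (with a
#'   header when the file does not yet exist), so a cohort run accumulates a
#'   tile-count table.
#' @param no_filter if `TRUE`, every tile is scored (the filter is bypassed;
#'   used to verify that filtering only suppresses, never alters,
#'   predictions).
#' @param slide_id identifier used in the report (defaults to the file name).
#' @return an object of class `screening`: the stitched `mask` and a
#'   `report` data frame with `slide_id`, `total_tiles`, `kept_tiles`,
#'   `inferred_tiles`, `ptc_pixel_count`, `ptc_area_fraction` (of tissue),
#'   and `wall_seconds` (informational only).
#' @export
screen_slide <- function(slide, model, filter_cfg = filter_config(),
                         mask_path = NULL, report_path = NULL,
                         no_filter = FALSE, slide_id = NULL) {
  t0 <- proc.time()[["elapsed"]]
  px <- model$config$input_px
  grid <- tile_grid(slide, px)
  if (is.null(slide_id))
    slide_id <- sub("\\.[^.]*$", "", basename(slide$source_path))
  tm <- tissue_mask(slide, filter_cfg)
  if (no_filter) {
    kept <- grid_tiles(grid)
  } else {
    sel <- select_tiles(grid, tm, filter_cfg)
    kept <- sel$kept
  }
  n_eval <- 0L
  tiles <- vector("list", length(kept))
  for (k in seq_along(kept)) {
    tr <- kept[[k]]
    img <- read_tile(slide, tr)
    h <- tr$y1 - tr$y0; w <- tr$x1 - tr$x0
    img <- pad_tile_reflect(img, px)
    pred <- predict_tile(model, img)
    n_eval <- n_eval + 1L
    tiles[[k]] <- list(tile = tr,
                       map = pred$class_map[seq_len(h), seq_len(w),
                                            drop = FALSE])
  }
  mask <- stitch_tiles(tiles, slide$width_px, slide$height_px)
  ptc <- sum(mask == 2L)
  tissue_px <- sum(tm$mask) * tm$downsample^2
  report <- data.frame(
    slide_id = slide_id,
    total_tiles = n_tiles(grid),
    kept_tiles = length(kept),
    inferred_tiles = n_eval,
    ptc_pixel_count = ptc,
    ptc_area_fraction = if (tissue_px > 0) min(1, ptc / tissue_px) else 0,
    wall_seconds = proc.time()[["elapsed"]] - t0,
    stringsAsFactors = FALSE)
  if (!is.null(mask_path))
    write_slide_mask(mask, mask_path, slide$width_px, slide$height_px)
  if (!is.null(report_path))
    write.table(report, report_path, sep = ",", row.names = FALSE,
                col.names = !file.exists(report_path),
                append = file.exists(report_path))
  structure(list(mask = mask, report = report), class = "screening")
}

#' @export
print.screening <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<screening> %s: %d/%d tiles kept, %d inferred, ",
           "%s PTC px (%.1f%% of tissue), %.1f s\n"),
    r$slide_id, r$kept_tiles, r$total_tiles, r$inferred_tiles,
    format(r$ptc_pixel_count, big.mark = ","),
    100 * r$ptc_area_fraction, r$wall_seconds))
  invisible(x)
}
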