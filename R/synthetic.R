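#' Specification of a synthetic papanicolaou-like slide
#'
#' Describes a deterministic synthetic cytology slide: a bright near-white
#' background with scattered darker ellipsoidal cell-cluster blobs of two
#' tissue classes — PTC (dark violet, label 2) and benign cellular material
#' (pale blue, label 1) — with an exact per-pixel ground-truth mask recorded
#' at paint time. Colors are chosen so that HSV saturation separates clusters
#' from background by construction (the pale-blue benign color still sits
#' above the tissue-detection threshold), and the gray background jitter is
#' applied equally to all channels so background saturation stays exactly
#' zero.
#'
#' @param width_px,height_px canvas size in pixels.
#' @param n_clusters number of cell clusters.
#' @param ptc_fraction share of clusters labeled PTC (default 0.5).
#' @param cluster_radius inclusive range of ellipse semi-axes in pixels.
#' @param background_rgb background gray level (default 245).
#' @param background_jitter per-pixel gray jitter amplitude (default 5,
#'   giving 245 +/- 5).
#' @param ptc_rgb,benign_rgb cluster base colors (dark violet / pale blue).
#' @param noise_sd Gaussian texture noise inside clusters (default 8).
#' @param pyramid downsample factors of the pyramid levels written for the
#'   slide (default 1, 4, 16).
#' @param seed integer seed; the same seed reproduces bitwise-identical
#'   slides.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(width_px = 2048L, height_px = 2048L,
                         n_clusters = 8L, ptc_fraction = 0.5,
                         cluster_radius = c(60, 180),
                         background_rgb = c(245, 245, 245),
                         background_jitter = 5,
                         ptc_rgb = c(110, 50, 140),
                         benign_rgb = c(165, 200, 235),
                         noise_sd = 8, pyramid = c(1, 4, 16), seed = 1L) {
  if (ptc_fraction < 0 || ptc_fraction > 1)
    stop("ptc_fraction must lie in [0, 1]")
  if (length(cluster_radius) != 2L || cluster_radius[1] > cluster_radius[2])
    stop("cluster_radius must be an increasing range")
  if (2 * cluster_radius[2] >= min(width_px, height_px))
    stop("largest cluster does not fit the canvas")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_clusters = as.integer(n_clusters),
                 ptc_fraction = ptc_fraction,
                 cluster_radius = cluster_radius,
                 background_rgb = background_rgb,
                 background_jitter = background_jitter,
                 ptc_rgb = ptc_rgb, benign_rgb = benign_rgb,
                 noise_sd = noise_sd, pyramid = pyramid,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

clip8 <- function(x) {
  d <- dim(x)
  y <- pmin(255L, pmax(0L, as.integer(round(x))))
  dim(y) <- d
  y
}

# paint spec into memory: image (H x W x 3 integer), truth (H x W integer),
# manifest (cluster table + label pixel counts)
render_fixture <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  H <- spec$height_px; W <- spec$width_px
  jit <- sample.int(2L * spec$background_jitter + 1L, H * W,
                    replace = TRUE) - spec$background_jitter - 1L
  img <- array(0L, dim = c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- clip8(spec$background_rgb[ch] + jit)
  truth <- matrix(0L, H, W)
  n_ptc <- round(spec$n_clusters * spec$ptc_fraction)
  labels <- c(rep(2L, n_ptc), rep(1L, spec$n_clusters - n_ptc))
  clusters <- list()
  placed <- matrix(numeric(0), 0, 4)  # cx, cy, rx, ry for overlap checks
  for (k in seq_len(spec$n_clusters)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      rx <- runif(1, spec$cluster_radius[1], spec$cluster_radius[2])
      ry <- runif(1, spec$cluster_radius[1], spec$cluster_radius[2])
      cx <- runif(1, rx + 1, W - rx)   # fully inside the canvas
      cy <- runif(1, ry + 1, H - ry)
      if (nrow(placed) == 0 ||
          all((abs(placed[, 1] - cx) > placed[, 3] + rx + 2) |
              (abs(placed[, 2] - cy) > placed[, 4] + ry + 2))) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place cluster ", k, " after bounded retries; ",
           "reduce n_clusters or cluster_radius for a ",
           spec$width_px, " x ", spec$height_px, " canvas")
    placed <- rbind(placed, c(cx, cy, rx, ry))
    xs <- max(1L, floor(cx - rx)):min(W, ceiling(cx + rx))
    ys <- max(1L, floor(cy - ry)):min(H, ceiling(cy + ry))
    inside <- outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, `+`) <= 1
    npx <- sum(inside)
    rgb0 <- if (labels[k] == 2L) spec$ptc_rgb else spec$benign_rgb
    tb <- truth[ys, xs, drop = FALSE]
    tb[inside] <- labels[k]
    truth[ys, xs] <- tb
    for (ch in 1:3) {
      blk <- img[ys, xs, ch, drop = TRUE]
      blk[inside] <- clip8(rgb0[ch] + rnorm(npx, sd = spec$noise_sd))
      img[ys, xs, ch] <- blk
    }
    clusters[[k]] <- data.frame(id = k, cx = cx, cy = cy, rx = rx, ry = ry,
                                label = labels[k], painted_px = npx)
  }
  lbl_px <- table(factor(truth, levels = 0:2))
  manifest <- list(
    width_px = W, height_px = H, seed = spec$seed,
    n_clusters = spec$n_clusters,
    clusters = if (length(clusters)) do.call(rbind, clusters)
               else data.frame(),
    label_px = as.list(setNames(as.integer(lbl_px), names(lbl_px))))
  list(image = img, truth = truth, manifest = manifest)
}

#' Generate a synthetic slide with ground truth
#'
#' Renders the slide described by `spec` and (when `dir` is given) writes a
#' pyramidal multi-page TIFF of the slide, a single-channel TIFF truth mask,
#' and a JSON manifest recording every cluster's center, radii, label, and
#' exact painted pixel count. The same seed yields bitwise-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed); `NULL` keeps everything
#'   in memory.
#' @param basename file stem (default `"synthetic_slide"`; files are
#'   labelled synthetic — they stand in for clinical slides that are not
#'   distributable).
#' @return an object of class `synthetic_slide`: `image`, `truth`,
#'   `manifest`, and (if written) `slide_path`, `truth_path`,
#'   `manifest_path`.
#' @export
generate_slide <- function(spec, dir = NULL, basename = "synthetic_slide") {
  fx <- render_fixture(spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    slide_path <- file.path(dir, paste0(basename, ".tiff"))
    truth_path <- file.path(dir, paste0(basename, "_truth.tiff"))
    manifest_path <- file.path(dir, paste0(basename, "_manifest.json"))
    pages <- lapply(spec$pyramid, function(f) {
      if (f == 1) return(fx$image / 255)
      x <- fx$image * 1.0
      dim(x) <- dim(fx$image)
      clip8(box_downsample_cpp(x, as.integer(f))) / 255
    })
    tiff::writeTIFF(pages, slide_path, bits.per.sample = 8L,
                    compression = "LZW")
    write_slide_mask(fx$truth, truth_path)
    jsonlite::write_json(fx$manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    fx$slide_path <- slide_path
    fx$truth_path <- truth_path
    fx$manifest_path <- manifest_path
  }
  structure(fx, class = "synthetic_slide")
}

#' @export
print.synthetic_slide <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<synthetic_slide> %d x %d px, %d cluster(s), seed %d\n",
              m$width_px, m$height_px, m$n_clusters, m$seed))
  invisible(x)
}

#' Generate ground-truthed training tiles
#'
#' Renders one slide from `spec` and cuts `n_tiles` tile-sized crops, each
#' guaranteed to contain at least one cluster pixel (crops are centered on a
#' uniformly chosen cluster with jitter, then clamped to the canvas). Labels
#' come from the exact truth mask; the focal cluster's label is recorded per
#' tile so class balance can be checked against `spec$ptc_fraction`.
#'
#' @param spec a [fixture_spec()]; the canvas must be at least
#'   `tile_px` on each side.
#' @param n_tiles number of tiles to cut.
#' @param tile_px crop side length (default 512, the network input).
#' @return list of training samples
#'   `list(image, label_map, focal_label)`, reproducible per seed.
#' @export
generate_training_tiles <- function(spec, n_tiles, tile_px = 512L) {
  if (n_tiles < 1L) stop("n_tiles must be >= 1")
  if (spec$width_px < tile_px || spec$height_px < tile_px)
    stop("canvas smaller than tile_px")
  if (spec$n_clusters < 1L)
    stop("need at least one cluster to cut tiles around")
  fx <- render_fixture(spec)
  cl <- fx$manifest$clusters
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 1L)
  out <- vector("list", n_tiles)
  for (t in seq_len(n_tiles)) {
    k <- sample.int(nrow(cl), 1L)
    jx <- runif(1, -tile_px / 4, tile_px / 4)
    jy <- runif(1, -tile_px / 4, tile_px / 4)
    x0 <- round(cl$cx[k] + jx - tile_px / 2)
    y0 <- round(cl$cy[k] + jy - tile_px / 2)
    x0 <- min(max(0, x0), spec$width_px - tile_px)
    y0 <- min(max(0, y0), spec$height_px - tile_px)
    rows <- (y0 + 1):(y0 + tile_px)
    cols <- (x0 + 1):(x0 + tile_px)
    out[[t]] <- list(image = fx$image[rows, cols, , drop = FALSE],
                     label_map = fx$truth[rows, cols, drop = FALSE],
                     focal_label = cl$label[k])
  }
  out
}
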