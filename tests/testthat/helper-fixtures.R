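# shared helpers: tiny-width network builders and geometry fixtures

tiny_cfg <- function(...) fcn_config(width_multiplier = 1 / 64, ...)

tiny_model <- function(seed = 1L, ...) {
  fcn_network(tiny_cfg(...), seed = seed, init = "random")
}

# conv8 zeroed with bias (0, 0, +1): every pixel is forced to class 2 (PTC)
forced_logit_model <- function(seed = 1L, bias = c(0, 0, 1)) {
  m <- tiny_model(seed)
  i <- which(vapply(m$layers, function(l) identical(l$name, "conv8"),
                    logical(1)))
  m$layers[[i]]$W[] <- 0
  m$layers[[i]]$b <- bias
  m
}

iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# plain white RGB canvas with optional saturated discs, written as a
# single-page TIFF so reader-side code paths are exercised
write_rgb_slide <- function(path, width, height, gray = 245,
                            discs = list()) {
  img <- array(gray / 255, dim = c(height, width, 3))
  for (d in discs) {
    xs <- max(1, floor(d$cx - d$r)):min(width, ceiling(d$cx + d$r))
    ys <- max(1, floor(d$cy - d$r)):min(height, ceiling(d$cy + d$r))
    inside <- outer((ys - d$cy)^2, (xs - d$cx)^2, `+`) <= d$r^2
    for (ch in 1:3) {
      blk <- img[ys, xs, ch]
      blk[inside] <- d$rgb[ch] / 255
      img[ys, xs, ch] <- blk
    }
  }
  tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "LZW")
  path
}

violet <- c(110, 50, 140)
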