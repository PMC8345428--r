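#' Network configuration for the padded-VGG16 segmenter
#'
#' Declarative description of the FCN-32s-style segmentation network: a
#' 100-px zero-padding layer, the VGG16 convolutional stack with a *valid*
#' first convolution and ceil-mode 2x2 max pooling, fully-connected layers
#' converted to 7x7/1x1 convolutions with dropout, a 3-channel scoring
#' convolution, a 64-kernel stride-32 transposed convolution, and a crop back
#' to the input frame. At `width_multiplier = 1` the channel widths are
#' 64,64,128,128,256x3,512x3,512x3,4096,4096,`n_classes`.
#'
#' @param n_classes number of output classes (default 3: 0 = background,
#'   1 = non-PTC cellular material, 2 = PTC).
#' @param width_multiplier factor in (0, 1] applied to every channel width
#'   (rounded up, minimum 1); spatial sizes are unaffected. Use small values
#'   (e.g. 1/64) for desk-scale work.
#' @param input_px side length of the square input tile (default 512).
#' @param crop_offset `"center"` (symmetric crop of the upsampled score map,
#'   offset 32 for input 512), `"fcn"` (the classical fixed offset 19), or an
#'   explicit non-negative integer.
#' @return an object of class `fcn_config`.
#' @export
fcn_config <- function(n_classes = 3L, width_multiplier = 1,
                       input_px = 512L, crop_offset = "center") {
  if (!(is.numeric(width_multiplier) && width_multiplier > 0 &&
        width_multiplier <= 1))
    stop("width_multiplier must lie in (0, 1]")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (input_px < 1L) stop("input_px must be positive")
  if (!(identical(crop_offset, "center") || identical(crop_offset, "fcn") ||
        (is.numeric(crop_offset) && crop_offset >= 0)))
    stop("crop_offset must be \"center\", \"fcn\", or a non-negative integer")
  cfg <- structure(list(
    n_classes = as.integer(n_classes),
    width_multiplier = width_multiplier,
    input_px = as.integer(input_px),
    crop_offset = crop_offset
  ), class = "fcn_config")
  cfg$layers <- fcn_layer_table(cfg)
  cfg
}

# width-scaled channel count
scale_ch <- function(base, wm) max(1L, as.integer(ceiling(base * wm)))

# the ordered layer stack; kernel/stride/pad per layer, ReLU and dropout
# fused onto the conv rows they follow
fcn_layer_table <- function(cfg) {
  wm <- cfg$width_multiplier
  L <- list()
  add <- function(name, kind, kernel = NA_integer_, stride = 1L,
                  pad = 0L, out_channels = NA_integer_, relu = FALSE,
                  dropout = FALSE) {
    L[[length(L) + 1L]] <<- list(name = name, kind = kind,
                                 kernel = kernel, stride = stride, pad = pad,
                                 out_channels = out_channels, relu = relu,
                                 dropout = dropout)
  }
  add("padding", "pad", pad = 100L)
  add("conv1_1", "conv", 3L, pad = 0L, out_channels = scale_ch(64, wm),
      relu = TRUE)  # valid: 712 -> 710
  add("conv1_2", "conv", 3L, pad = 1L, out_channels = scale_ch(64, wm),
      relu = TRUE)
  add("pool1", "pool", 2L, 2L)
  for (i in 1:2)
    add(paste0("conv2_", i), "conv", 3L, pad = 1L,
        out_channels = scale_ch(128, wm), relu = TRUE)
  add("pool2", "pool", 2L, 2L)
  for (i in 1:3)
    add(paste0("conv3_", i), "conv", 3L, pad = 1L,
        out_channels = scale_ch(256, wm), relu = TRUE)
  add("pool3", "pool", 2L, 2L)
  for (i in 1:3)
    add(paste0("conv4_", i), "conv", 3L, pad = 1L,
        out_channels = scale_ch(512, wm), relu = TRUE)
  add("pool4", "pool", 2L, 2L)
  for (i in 1:3)
    add(paste0("conv5_", i), "conv", 3L, pad = 1L,
        out_channels = scale_ch(512, wm), relu = TRUE)
  add("pool5", "pool", 2L, 2L)
  add("conv6", "conv", 7L, pad = 0L, out_channels = scale_ch(4096, wm),
      relu = TRUE, dropout = TRUE)
  add("conv7", "conv", 1L, pad = 0L, out_channels = scale_ch(4096, wm),
      relu = TRUE, dropout = TRUE)
  add("conv8", "conv", 1L, pad = 0L, out_channels = cfg$n_classes)
  add("deconv9", "deconv", 64L, 32L, out_channels = cfg$n_classes)
  add("cropping", "crop")
  L
}

resolve_crop_offset <- function(cfg, pre_px, input_px) {
  off <- switch(as.character(cfg$crop_offset[1]),
                center = (pre_px - input_px) %/% 2L,
                fcn = 19L,
                as.integer(cfg$crop_offset))
  if (off < 0L || off + input_px > pre_px)
    stop(sprintf(
      "cropping: offset %d with input %d exceeds upsampled size %d",
      off, input_px, pre_px))
  off
}

#' Analytic shape trace of the network
#'
#' Propagates spatial sizes and channel counts through the layer stack by
#' pure arithmetic (no tensors allocated): pad adds 100 per side; a valid
#' k x k convolution maps H to H - k + 1; pad-1 3x3 convolutions preserve H;
#' pooling maps H to ceil(H / 2); the transposed convolution maps H to
#' (H - 1) * 32 + 64; the crop returns to `input_px`. For input 512 this
#' reproduces the size chain 712, 710, 355, 178, 89, 45, 23, 17, 576, 512.
#'
#' @param cfg an [fcn_config()].
#' @param input_px input side length (defaults to `cfg$input_px`).
#' @return data frame with columns `layer`, `height`, `width`, `channels`.
#' @export
shape_trace <- function(cfg, input_px = cfg$input_px) {
  h <- as.integer(input_px); ch <- 3L
  rows <- list(list(layer = "input", height = h, width = h, channels = 3L))
  for (ly in cfg$layers) {
    h <- switch(ly$kind,
      pad = h + 2L * ly$pad,
      conv = h + 2L * ly$pad - ly$kernel + 1L,
      pool = (h + 1L) %/% 2L,
      deconv = (h - 1L) * ly$stride + ly$kernel,
      crop = {
        off <- resolve_crop_offset(cfg, h, as.integer(input_px))
        as.integer(input_px)
      })
    if (h < 1L)
      stop("layer ", ly$name, " produces a non-positive feature size")
    if (!is.na(ly$out_channels)) ch <- ly$out_channels
    rows[[length(rows) + 1L]] <-
      list(layer = ly$name, height = h, width = h, channels = ch)
  }
  rows[[length(rows) + 1L]] <-
    list(layer = "output", height = h, width = h, channels = 1L)
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Build the segmentation network
#'
#' Instantiates the layer stack of [fcn_config()] with initialized weights.
#' Weight initialization is delegated to [init_weights()] and is
#' deterministic given `seed`.
#'
#' @param cfg an [fcn_config()].
#' @param seed integer seed for weight initialization.
#' @param init `"random"` (He-normal convolutions, bilinear transposed
#'   convolution) or `"pretrained_backbone"` (copy VGG16 convolution weights
#'   from `weights_file` where shapes permit, zero conv8, bilinear deconv9;
#'   falls back to random with a warning when no weight file is available).
#' @param weights_file optional RDS file of named VGG16 weights for
#'   `init = "pretrained_backbone"`.
#' @return an object of class `fcn_network`: the config plus a layer list
#'   carrying weight matrices.
#' @export
fcn_network <- function(cfg = fcn_config(), seed = 1L, init = "random",
                        weights_file = NULL) {
  model <- structure(list(config = cfg, seed = as.integer(seed),
                          layers = cfg$layers),
                     class = "fcn_network")
  in_ch <- 3L
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$kind == "conv") {
      model$layers[[i]]$in_channels <- in_ch
      in_ch <- ly$out_channels
    } else if (ly$kind == "deconv") {
      model$layers[[i]]$in_channels <- in_ch
      in_ch <- ly$out_channels
    }
  }
  init_weights(model, scheme = init, seed = seed, weights_file = weights_file)
}

#' Number of trainable parameters
#' @param model an `fcn_network`.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(ly)
    length(ly$W) + length(ly$b), numeric(1)))
}

#' @export
print.fcn_network <- function(x, ...) {
  cat(sprintf(
    "<fcn_network> padded-VGG16 FCN-32s: %d classes, input %d px, width x%g\n",
    x$config$n_classes, x$config$input_px, x$config$width_multiplier))
  cat(sprintf("  %d layers, %s parameters, seed %d\n",
              length(x$layers), format(n_params(x), big.mark = ","), x$seed))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epoch(s), final mean loss %.6g\n",
                length(x$history), x$history[length(x$history)]))
  invisible(x)
}

#' @export
summary.fcn_network <- function(object, ...) {
  tr <- shape_trace(object$config)
  cat("Layer shape trace (input ", object$config$input_px, " px):\n", sep = "")
  print(tr, row.names = FALSE)
  invisible(tr)
}

# forward pass; returns scores (pre-softmax, input_px^2 x n_classes) and,
# when cache = TRUE, everything the backward pass needs
fcn_forward <- function(model, tile, train = FALSE, dropout = 0.5,
                        cache = FALSE) {
  px <- model$config$input_px
  d <- dim(tile)
  if (is.null(d) || length(d) != 3L || d[1] != px || d[2] != px || d[3] != 3L)
    stop(sprintf("tile must be %d x %d x 3, got %s", px, px,
                 paste(d, collapse = " x ")))
  # stain-darkness representation: 0 = bare glass, 1 = maximal absorption
  # (bright-field convention; keeps stained material on the active side of
  # the first ReLU)
  a <- array(1 - as.numeric(tile) / 255, dim = d)
  caches <- if (cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$kind == "pad") {
      d0 <- dim(a); p <- ly$pad
      out <- array(0, dim = c(d0[1] + 2L * p, d0[2] + 2L * p, d0[3]))
      out[p + seq_len(d0[1]), p + seq_len(d0[2]), ] <- a
      if (cache) caches[[i]] <- list(dims = d0)
      a <- out
    } else if (ly$kind == "conv") {
      xin <- a
      a <- conv_forward_cpp(a, ly$W, ly$b, ly$kernel, ly$kernel, ly$pad,
                            ly$relu)
      if (cache) caches[[i]] <- list(x = xin, y = if (ly$relu) a else NULL)
      if (ly$dropout && train && dropout > 0) {
        mask <- array((runif(length(a)) >= dropout) / (1 - dropout),
                      dim = dim(a))
        a <- a * mask
        if (cache) caches[[i]]$mask <- mask
      }
    } else if (ly$kind == "pool") {
      if (cache) din <- dim(a)
      r <- maxpool_forward_cpp(a)
      if (cache) caches[[i]] <- list(idx = r$idx, dims = din)
      a <- r$y
    } else if (ly$kind == "deconv") {
      xin <- a
      a <- deconv_forward_cpp(a, ly$W, ly$b, ly$stride, ly$out_channels)
      if (cache) caches[[i]] <- list(x = xin)
    } else if (ly$kind == "crop") {
      pre <- dim(a)
      off <- resolve_crop_offset(model$config, pre[1], px)
      if (cache) caches[[i]] <- list(dims = pre, off = off)
      a <- a[off + seq_len(px), off + seq_len(px), , drop = FALSE]
    }
  }
  list(scores = a, caches = caches)
}

# gradients of all parameters given d(loss)/d(scores)
fcn_backward <- function(model, caches, dscores) {
  g <- dscores
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    cc <- caches[[i]]
    if (ly$kind == "crop") {
      full <- array(0, dim = cc$dims)
      full[cc$off + seq_len(dim(g)[1]), cc$off + seq_len(dim(g)[2]), ] <- g
      g <- full
    } else if (ly$kind == "deconv") {
      bw <- deconv_backward_cpp(cc$x, ly$W, g, ly$stride, ly$out_channels)
      grads[[i]] <- list(dW = bw$dW, db = as.numeric(bw$db))
      g <- bw$dx
    } else if (ly$kind == "pool") {
      g <- maxpool_backward_cpp(cc$idx, g, cc$dims[1], cc$dims[2])
    } else if (ly$kind == "conv") {
      if (!is.null(cc$mask)) g <- g * cc$mask
      if (ly$relu) g <- g * (cc$y > 0)
      bw <- conv_backward_cpp(cc$x, ly$W, g, ly$kernel, ly$kernel, ly$pad)
      grads[[i]] <- list(dW = bw$dW, db = as.numeric(bw$db))
      g <- bw$dx
    } else if (ly$kind == "pad") {
      p <- ly$pad
      g <- g[p + seq_len(cc$dims[1]), p + seq_len(cc$dims[2]), ,
             drop = FALSE]
    }
  }
  grads
}

#' Segment one tile
#'
#' Runs the network on a single tile (dropout disabled) and returns the
#' per-pixel class map and the pre-softmax score planes. Argmax ties break
#' toward the lowest class index, so exact ties favor background.
#'
#' @param model an `fcn_network`.
#' @param tile 8-bit RGB array `input_px x input_px x 3` (values 0–255);
#'   smaller edge tiles must be padded by the caller.
#' @return list with `class_map` (integer matrix, labels
#'   `0 .. n_classes-1`) and `scores` (`input_px x input_px x n_classes`).
#' @export
predict_tile <- function(model, tile) {
  fw <- fcn_forward(model, tile, train = FALSE)
  sc <- fw$scores
  d <- dim(sc)
  cm <- matrix(max.col(matrix(sc, ncol = d[3]), ties.method = "first") - 1L,
               d[1], d[2])
  list(class_map = cm, scores = sc)
}

#' @export
#' @rdname predict_tile
#' @param object an `fcn_network`.
#' @param newdata a tile as in `tile`.
#' @param ... unused.
predict.fcn_network <- function(object, newdata, ...) {
  predict_tile(object, newdata)
}

# coarse (pre-upsampling) score map from the scoring convolution, used to
# study stride-granularity behavior
coarse_scores <- function(model, tile) {
  px <- model$config$input_px
  a <- array(1 - as.numeric(tile) / 255, dim = dim(tile))
  for (ly in model$layers) {
    if (ly$kind == "pad") {
      d0 <- dim(a); p <- ly$pad
      out <- array(0, dim = c(d0[1] + 2L * p, d0[2] + 2L * p, d0[3]))
      out[p + seq_len(d0[1]), p + seq_len(d0[2]), ] <- a
      a <- out
    } else if (ly$kind == "conv") {
      a <- conv_forward_cpp(a, ly$W, ly$b, ly$kernel, ly$kernel, ly$pad,
                            ly$relu)
    } else if (ly$kind == "pool") {
      a <- maxpool_forward_cpp(a)$y
    } else if (ly$kind == "deconv") {
      break
    }
  }
  a
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single RDS file holding the weights, with a JSON
#' sidecar (`<path>.json`) recording the network configuration and seed.
#'
#' @param model an `fcn_network`.
#' @param path checkpoint path (e.g. `model.ckpt`).
#' @return `path` (save) or the restored `fcn_network` (load).
#' @export
save_fcn <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(input_px = model$config$input_px,
                  n_classes = model$config$n_classes,
                  width_multiplier = model$config$width_multiplier,
                  crop_offset = model$config$crop_offset,
                  seed = model$seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_fcn
#' @export
load_fcn <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "fcn_network")) stop("not an fcn_network checkpoint: ", path)
  m
}
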