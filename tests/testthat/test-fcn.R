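test_that("shape trace reproduces the published 512-px feature chain", {
  tr <- shape_trace(fcn_config())
  chain <- setNames(tr$height, tr$layer)
  expect_identical(chain[["input"]], 512L)
  expect_identical(chain[["padding"]], 712L)
  expect_identical(chain[["conv1_1"]], 710L)
  expect_identical(chain[["conv1_2"]], 710L)
  expect_identical(chain[["pool1"]], 355L)
  expect_identical(chain[["pool2"]], 178L)
  expect_identical(chain[["pool3"]], 89L)
  expect_identical(chain[["pool4"]], 45L)
  expect_identical(chain[["pool5"]], 23L)
  expect_identical(chain[["conv6"]], 17L)
  expect_identical(chain[["conv7"]], 17L)
  expect_identical(chain[["conv8"]], 17L)
  expect_identical(chain[["deconv9"]], 576L)
  expect_identical(chain[["cropping"]], 512L)
  expect_identical(chain[["output"]], 512L)
  expect_true(all(tr$height == tr$width))
  ch <- setNames(tr$channels, tr$layer)
  expect_identical(unname(ch[c("conv1_1", "conv2_1", "conv3_1", "conv4_1",
                               "conv5_1", "conv6", "conv7", "conv8",
                               "deconv9", "output")]),
                   c(64L, 128L, 256L, 512L, 512L, 4096L, 4096L, 3L, 3L, 1L))
})

test_that("shape rules propagate any input size, not just 512", {
  tr <- shape_trace(fcn_config(), input_px = 160)
  chain <- setNames(tr$height, tr$layer)
  expect_identical(unname(chain[c("padding", "conv1_1", "pool1", "pool2",
                                  "pool3", "pool4", "pool5", "conv6",
                                  "deconv9", "cropping")]),
                   c(360L, 358L, 179L, 90L, 45L, 23L, 12L, 6L, 224L, 160L))
})

test_that("width multiplier scales channels but never spatial sizes", {
  tr1 <- shape_trace(fcn_config())
  tr64 <- shape_trace(tiny_cfg())
  expect_identical(tr1$height, tr64$height)
  expect_identical(tr1$width, tr64$width)
  ch <- setNames(tr64$channels, tr64$layer)
  expect_identical(unname(ch[c("conv1_1", "conv2_1", "conv3_1", "conv4_1",
                               "conv6", "conv7", "conv8", "deconv9")]),
                   c(1L, 2L, 4L, 8L, 64L, 64L, 3L, 3L))
})

test_that("config validation rejects impossible settings", {
  expect_error(fcn_config(width_multiplier = 0), "width_multiplier")
  expect_error(fcn_config(width_multiplier = 2), "width_multiplier")
  expect_error(fcn_config(n_classes = 1), "n_classes")
  expect_error(shape_trace(fcn_config(input_px = 512, crop_offset = 200)),
               "cropping")
})

test_that("empirical forward shapes match the analytic trace", {
  m <- tiny_model(seed = 3)
  set.seed(1)
  tile <- array(sample(0:255, 512 * 512 * 3, TRUE), c(512, 512, 3))
  p <- predict_tile(m, tile)
  expect_identical(dim(p$scores), c(512L, 512L, 3L))
  expect_identical(dim(p$class_map), c(512L, 512L))
  expect_true(all(p$class_map %in% 0:2))
  cs <- ptcscreen:::coarse_scores(m, tile)
  expect_identical(dim(cs), c(17L, 17L, 3L))
})

test_that("two builds with the same seed have identical weights", {
  m1 <- tiny_model(seed = 11)
  m2 <- tiny_model(seed = 11)
  expect_identical(m1$layers, m2$layers)
  m3 <- tiny_model(seed = 12)
  expect_false(identical(m1$layers, m3$layers))
})

test_that("forced conv8 logits drive the class map", {
  set.seed(2)
  tile <- array(sample(0:255, 512 * 512 * 3, TRUE), c(512, 512, 3))
  # bias +1 on class 2 with zero weights: everything is PTC
  m2 <- forced_logit_model(seed = 1, bias = c(0, 0, 1))
  expect_true(all(predict_tile(m2, tile)$class_map == 2L))
  # all-equal scores: argmax ties break to the lowest class (background)
  m0 <- forced_logit_model(seed = 1, bias = c(0, 0, 0))
  expect_true(all(predict_tile(m0, tile)$class_map == 0L))
})

test_that("inference is deterministic and rejects wrong tile sizes", {
  m <- tiny_model(seed = 5)
  set.seed(4)
  tile <- array(sample(0:255, 512 * 512 * 3, TRUE), c(512, 512, 3))
  p1 <- predict_tile(m, tile)
  p2 <- predict_tile(m, tile)
  expect_identical(p1$class_map, p2$class_map)
  expect_identical(p1$scores, p2$scores)
  expect_error(predict_tile(m, tile[1:100, 1:100, ]), "512 x 512 x 3")
})

test_that("a 32-px shift moves the coarse score peak by one cell", {
  m <- tiny_model(seed = 8)
  mk <- function(cx, cy) {
    img <- array(245L, c(512, 512, 3))
    xs <- (cx - 40):(cx + 40); ys <- (cy - 40):(cy + 40)
    inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= 40^2
    for (ch in 1:3) {
      blk <- img[ys, xs, ch]
      blk[inside] <- violet[ch]
      img[ys, xs, ch] <- blk
    }
    img
  }
  # difference against a blob-free canvas cancels the border response of
  # the 100-px zero pad; what remains is the blob's coarse-grid footprint
  blank <- ptcscreen:::coarse_scores(m, array(245L, c(512, 512, 3)))
  peak <- function(img) {
    cs <- ptcscreen:::coarse_scores(m, img)
    dev <- apply(abs(cs - blank), c(1, 2), sum)
    which(dev == max(dev), arr.ind = TRUE)[1, ]
  }
  p0 <- peak(mk(224, 256))
  px <- peak(mk(224 + 32, 256))
  expect_identical(px["col"] - p0["col"], c(col = 1L))
  expect_identical(px["row"], p0["row"])
})

test_that("checkpoints round-trip through disk with their sidecar", {
  m <- tiny_model(seed = 2)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_fcn(m, f)
  m2 <- load_fcn(f)
  expect_identical(m$layers, m2$layers)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_identical(side$input_px, 512L)
  expect_identical(side$n_classes, 3L)
  expect_equal(side$width_multiplier, 1 / 64)
})
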