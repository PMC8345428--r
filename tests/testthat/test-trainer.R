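test_that("cross-entropy matches closed forms", {
  # saturated one-hot logits: essentially zero loss
  H <- 4; W <- 4; C <- 3
  lab <- matrix(sample(0:2, H * W, TRUE), H, W)
  s <- array(-20, c(H, W, C))
  for (i in 1:H) for (j in 1:W) s[i, j, lab[i, j] + 1] <- 20
  expect_lt(pixel_cross_entropy(s, lab, "sum"), 1e-6 * H * W)

  # uniform softmax: summed loss is exactly N * ln(3)
  z <- array(0, c(H, W, C))
  expect_equal(pixel_cross_entropy(z, lab, "sum"), H * W * log(3))
  expect_equal(pixel_cross_entropy(z, lab, "mean"), log(3))

  # ignore label removes pixels from loss and gradient
  lab2 <- lab; lab2[1, ] <- 255L
  expect_equal(pixel_cross_entropy(z, lab2, "sum"), (H * W - W) * log(3))
  all_ig <- matrix(255L, H, W)
  ce <- pixel_cross_entropy(z, all_ig, "sum", grad = TRUE)
  expect_equal(ce$loss, 0)
  expect_true(all(ce$grad == 0))

  expect_error(pixel_cross_entropy(z, matrix(7L, H, W)), "labels outside")
})

test_that("analytic cross-entropy gradient matches numerical differentiation", {
  set.seed(21)
  s <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  lab <- matrix(c(0L, 2L, 255L, 1L), 2, 2)
  for (red in c("sum", "mean")) {
    ce <- pixel_cross_entropy(s, lab, red, grad = TRUE)
    h <- 1e-6
    num <- vapply(seq_along(s), function(i) {
      s1 <- s; s2 <- s
      s1[i] <- s1[i] + h; s2[i] <- s2[i] - h
      (pixel_cross_entropy(s1, lab, red) -
         pixel_cross_entropy(s2, lab, red)) / (2 * h)
    }, numeric(1))
    denom <- pmax(abs(num), 1e-8)
    expect_lt(max(abs(num - as.vector(ce$grad)) / denom), 1e-4)
  }
})

test_that("random init builds the closed-form bilinear deconvolution", {
  bk <- bilinear_kernel(64)
  w1 <- 1 - abs(0:63 - 31.5) / 32
  expect_equal(bk, outer(w1, w1))
  expect_equal(max(bk), (63 / 64)^2)

  m <- tiny_model(seed = 6)
  i <- which(vapply(m$layers, function(l) identical(l$name, "deconv9"),
                    logical(1)))
  W <- m$layers[[i]]$W  # kh x kw x (outC * inC), slice = oc + outC * ic
  outC <- m$layers[[i]]$out_channels
  for (oc in 0:(outC - 1)) for (ic in 0:(outC - 1)) {
    sl <- W[, , oc + outC * ic + 1]
    if (oc == ic) expect_equal(sl, bk) else expect_true(all(sl == 0))
  }
})

test_that("pretrained-backbone init falls back gracefully offline", {
  expect_warning(m <- fcn_network(tiny_cfg(), seed = 1,
                                  init = "pretrained_backbone"),
                 "falling back to random")
  i <- which(vapply(m$layers, function(l) identical(l$name, "conv8"),
                    logical(1)))
  expect_true(all(m$layers[[i]]$W == 0))
  expect_true(all(m$layers[[i]]$b == 0))
})

test_that("a zero learning rate leaves weights untouched", {
  m <- tiny_model(seed = 9)
  sm <- list(list(image = array(128L, c(512, 512, 3)),
                  label_map = matrix(1L, 512, 512)))
  fit <- fcn_train(m, sm, training_config(learning_rate = 0, epochs = 2,
                                          seed = 1, loss_reduction = "mean"))
  expect_identical(fit$layers, m$layers)
})

test_that("one step with zero data gradient shrinks weights by 1 - lr*decay", {
  m <- tiny_model(seed = 10)
  # all-ignore labels: loss and data gradient are exactly zero
  sm <- list(list(image = array(100L, c(512, 512, 3)),
                  label_map = matrix(255L, 512, 512)))
  lr <- 0.1; decay <- 0.01
  fit <- fcn_train(m, sm, training_config(learning_rate = lr,
                                          weight_decay = decay,
                                          momentum = 0.9, epochs = 1,
                                          seed = 1))
  expect_equal(fit$history, 0)
  for (i in seq_along(m$layers)) {
    if (is.null(m$layers[[i]]$W)) next
    expect_equal(as.vector(fit$layers[[i]]$W),
                 as.vector(m$layers[[i]]$W) * (1 - lr * decay),
                 tolerance = 1e-12)
  }
})

test_that("training is deterministic and reduces loss on a toy problem", {
  spec <- fixture_spec(width_px = 1024, height_px = 1024, n_clusters = 3,
                       cluster_radius = c(80, 150), seed = 31)
  tiles <- generate_training_tiles(spec, 2)
  m <- tiny_model(seed = 13)
  tc <- training_config(learning_rate = 0.01, momentum = 0.9,
                        loss_reduction = "mean", epochs = 3, seed = 13,
                        dropout = 0.5)
  f1 <- fcn_train(m, tiles, tc)
  f2 <- fcn_train(m, tiles, tc)
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history[3], f1$history[1])
  expect_s3_class(f1, "fcn_fit")
})

test_that("training configuration defaults carry the published recipe", {
  tc <- training_config()
  expect_equal(tc$learning_rate, 1e-10)
  expect_equal(tc$dropout, 0.5)
  expect_equal(tc$weight_decay, 5e-4)
  expect_identical(tc$loss_reduction, "sum")
  expect_error(training_config(dropout = 1), "dropout")
})
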