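#' Training configuration
#'
#' Defaults follow the screening network's published recipe: stochastic
#' gradient descent with learning rate 1e-10, dropout ratio 0.5, and weight
#' decay 0.0005, with per-image *summed* cross-entropy (the classical FCN
#' convention — a learning rate of 1e-10 is only sensible against a summed
#' loss). Momentum, batch size and epoch count are not part of that recipe;
#' the defaults here are the heavy-momentum FCN convention (0.99), one tile
#' per step, and a caller-chosen epoch count.
#'
#' @param learning_rate SGD learning rate (default 1e-10).
#' @param dropout dropout ratio for the fc-converted layers (default 0.5).
#' @param weight_decay L2 penalty coefficient, applied inside the SGD update
#'   (coupled decay; default 5e-4).
#' @param momentum classical momentum (default 0.99).
#' @param loss_reduction `"sum"` (default) or `"mean"` per-image reduction.
#' @param epochs number of passes over the samples.
#' @param seed integer seed governing dropout masks (and weight init when a
#'   model is built from this config).
#' @param init weight scheme, `"pretrained_backbone"` or `"random"`; see
#'   [init_weights()].
#' @return an object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-10, dropout = 0.5,
                            weight_decay = 5e-4, momentum = 0.99,
                            loss_reduction = c("sum", "mean"), epochs = 10L,
                            seed = 1L, init = c("pretrained_backbone",
                                                "random")) {
  loss_reduction <- match.arg(loss_reduction)
  init <- match.arg(init)
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  structure(list(learning_rate = learning_rate, dropout = dropout,
                 weight_decay = weight_decay, momentum = momentum,
                 loss_reduction = loss_reduction,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 init = init),
            class = "training_config")
}

#' Pixel-wise softmax cross-entropy
#'
#' Numerically stable softmax cross-entropy summed (or averaged) over valid
#' pixels; pixels carrying `ignore_label` contribute neither loss nor
#' gradient. With all-zero logits over `C` classes and `N` valid pixels the
#' summed loss is exactly `N * log(C)`.
#'
#' @param scores array `H x W x C` of pre-softmax scores.
#' @param labels integer matrix `H x W` with values in `0 .. C-1` or
#'   `ignore_label`.
#' @param reduction `"sum"` or `"mean"` over valid pixels.
#' @param ignore_label label excluded from the loss (default 255).
#' @param grad if `TRUE`, also return `d(loss)/d(scores)`.
#' @return the loss, or (with `grad = TRUE`) `list(loss, grad, n_valid)`.
#' @export
pixel_cross_entropy <- function(scores, labels, reduction = c("sum", "mean"),
                                ignore_label = 255L, grad = FALSE) {
  reduction <- match.arg(reduction)
  d <- dim(scores)
  if (length(d) != 3L) stop("scores must be H x W x C")
  if (!all(dim(labels) == d[1:2]))
    stop("labels must match the spatial frame of scores")
  C <- d[3]
  lab <- as.integer(labels)
  valid <- lab != as.integer(ignore_label)
  bad <- valid & (lab < 0L | lab >= C)
  if (any(bad))
    stop("labels outside 0..", C - 1L, " (and != ignore label): ",
         paste(unique(lab[bad]), collapse = ", "))
  S <- matrix(scores, ncol = C)
  mx <- S[, 1]
  for (j in seq_len(C)[-1]) mx <- pmax(mx, S[, j])
  E <- exp(S - mx)
  Z <- rowSums(E)
  n <- sum(valid)
  iv <- which(valid)
  ll <- (S[cbind(iv, lab[iv] + 1L)] - mx[iv]) - log(Z[iv])
  loss <- -sum(ll)
  if (reduction == "mean") loss <- if (n > 0L) loss / n else 0
  if (n == 0L) loss <- 0
  if (!grad) return(loss)
  G <- E / Z
  G[cbind(iv, lab[iv] + 1L)] <- G[cbind(iv, lab[iv] + 1L)] - 1
  G[!valid, ] <- 0
  if (reduction == "mean" && n > 0L) G <- G / n
  if (n == 0L) G[] <- 0
  list(loss = loss, grad = array(G, dim = d), n_valid = n)
}

#' Separable bilinear upsampling kernel
#'
#' Closed-form 2-D kernel used to initialize the stride-32 transposed
#' convolution: the outer product of the 1-D triangle
#' `w[i] = 1 - |i - c| / f` with `f = ceil(k / 2)` and
#' `c = (k - 1) / 2`, the standard bilinear-interpolation filter for
#' upsampling factor `f`.
#'
#' @param kernel_px kernel side length (64 for the stride-32 deconvolution).
#' @return `kernel_px x kernel_px` numeric matrix.
#' @export
bilinear_kernel <- function(kernel_px) {
  f <- ceiling(kernel_px / 2)
  ctr <- (kernel_px - 1) / 2
  w <- 1 - abs(seq_len(kernel_px) - 1 - ctr) / f
  outer(w, w)
}

#' Initialize network weights
#'
#' `scheme = "random"`: He-normal convolution weights
#' (`sd = sqrt(2 / fan_in)`), zero biases, bilinear transposed-convolution
#' kernel (identity across matching class channels, zero across others).
#' `scheme = "pretrained_backbone"`: copies published VGG16 convolution
#' weights from `weights_file` (an RDS list named by layer) into conv1–conv7
#' where shapes permit, zero-initializes the scoring convolution conv8, and
#' bilinear-initializes deconv9; when no weight file is available the
#' backbone falls back to the random scheme with a warning (never a hard
#' failure). Deterministic per `seed` either way.
#'
#' @param model an `fcn_network`.
#' @param scheme `"random"` or `"pretrained_backbone"`.
#' @param seed integer seed.
#' @param weights_file optional RDS file with named entries
#'   `list(conv1_1 = list(W = ..., b = ...), ...)` whose `W` are
#'   `(kh*kw*inC) x outC` matrices.
#' @return the model with weights set.
#' @export
init_weights <- function(model, scheme = c("random", "pretrained_backbone"),
                         seed = 1L, weights_file = NULL) {
  scheme <- match.arg(scheme)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  pretrained <- NULL
  if (scheme == "pretrained_backbone") {
    if (!is.null(weights_file) && file.exists(weights_file)) {
      pretrained <- readRDS(weights_file)
    } else {
      warning("pretrained VGG16 weights unavailable; ",
              "falling back to random backbone initialization")
    }
  }
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$kind == "conv") {
      k <- ly$kernel
      fan_in <- k * k * ly$in_channels
      if (identical(ly$name, "conv8") && scheme == "pretrained_backbone") {
        W <- matrix(0, fan_in, ly$out_channels)
      } else if (!is.null(pretrained) && !is.null(pretrained[[ly$name]]) &&
                 all(dim(pretrained[[ly$name]]$W) ==
                       c(fan_in, ly$out_channels))) {
        W <- pretrained[[ly$name]]$W
      } else {
        W <- matrix(rnorm(fan_in * ly$out_channels, sd = sqrt(2 / fan_in)),
                    fan_in, ly$out_channels)
        # the first convolution unmixes stain darkness; absorbance
        # combinations are non-negative (Beer-Lambert), and keeping the
        # draw half-normal preserves stain contrast through narrow widths
        if (identical(ly$name, "conv1_1")) W <- abs(W)
      }
      # ReLU-bearing layers start with a small positive bias so no unit is
      # born dead; the linear scoring layer (conv8) starts at zero
      b <- if (!is.null(pretrained) && !is.null(pretrained[[ly$name]]) &&
               length(pretrained[[ly$name]]$b) == ly$out_channels &&
               !identical(ly$name, "conv8"))
        as.numeric(pretrained[[ly$name]]$b)
      else if (ly$relu) rep(0.1, ly$out_channels)
      else numeric(ly$out_channels)
      model$layers[[i]]$W <- W
      model$layers[[i]]$b <- b
    } else if (ly$kind == "deconv") {
      k <- ly$kernel
      outC <- ly$out_channels; inC <- ly$in_channels
      W <- array(0, dim = c(k, k, outC * inC))
      bk <- bilinear_kernel(k)
      for (cidx in seq_len(min(outC, inC)))
        W[, , (cidx - 1L) + outC * (cidx - 1L) + 1L] <- bk
      model$layers[[i]]$W <- W
      model$layers[[i]]$b <- numeric(outC)
    }
  }
  model
}

# one coupled-decay momentum-SGD step over all parameters; `vel` is an
# environment holding per-layer velocity arrays
sgd_step <- function(model, grads, vel, lr, momentum, decay) {
  for (i in seq_along(model$layers)) {
    if (is.null(grads[[i]])) next
    ly <- model$layers[[i]]
    gW <- grads[[i]]$dW + decay * ly$W
    gb <- grads[[i]]$db + decay * ly$b
    kW <- paste0("W", i); kb <- paste0("b", i)
    vW <- if (is.null(vel[[kW]])) gW else momentum * vel[[kW]] + gW
    vb <- if (is.null(vel[[kb]])) gb else momentum * vel[[kb]] + gb
    vel[[kW]] <- vW; vel[[kb]] <- vb
    W <- ly$W - lr * vW
    if (!is.null(dim(ly$W))) dim(W) <- dim(ly$W)
    model$layers[[i]]$W <- W
    model$layers[[i]]$b <- ly$b - lr * vb
  }
  model
}

#' Train the segmentation network
#'
#' Full-image stochastic gradient descent (one tile per step, in sample
#' order) with classical momentum and coupled L2 weight decay, optimizing the
#' pixel-wise cross-entropy of [pixel_cross_entropy()]. Deterministic given
#' `cfg$seed`: two runs with the same seed, model, and samples produce
#' bitwise-equal loss traces.
#'
#' @param model an `fcn_network`.
#' @param samples list of training samples, each
#'   `list(image = <px x px x 3 RGB>, label_map = <px x px integer matrix>)`
#'   (labels in the class set, optional ignore label 255).
#' @param cfg a [training_config()].
#' @return the trained model, classed `c("fcn_fit", "fcn_network")`, with a
#'   `history` vector of per-epoch mean losses.
#' @export
fcn_train <- function(model, samples, cfg = training_config()) {
  if (!length(samples)) stop("need at least one training sample")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  vel <- new.env(parent = emptyenv())
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    total <- 0
    for (s in samples) {
      fw <- fcn_forward(model, s$image, train = TRUE, dropout = cfg$dropout,
                        cache = TRUE)
      ce <- pixel_cross_entropy(fw$scores, s$label_map,
                                reduction = cfg$loss_reduction, grad = TRUE)
      if (!is.finite(ce$loss))
        stop("non-finite loss at epoch ", epoch, "; lower the learning rate")
      total <- total + ce$loss
      grads <- fcn_backward(model, fw$caches, ce$grad)
      model <- sgd_step(model, grads, vel, cfg$learning_rate, cfg$momentum,
                        cfg$weight_decay)
    }
    history[epoch] <- total / length(samples)
  }
  model$history <- history
  class(model) <- unique(c("fcn_fit", class(model)))
  model
}

#' @export
print.fcn_fit <- function(x, ...) {
  NextMethod()
  invisible(x)
}

#' @export
#' @importFrom graphics plot
plot.fcn_fit <- function(x, ...) {
  plot(seq_along(x$history), x$history, type = "b", xlab = "epoch",
       ylab = "mean per-image loss", main = "training loss", ...)
  invisible(x)
}
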