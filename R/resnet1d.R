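# 1D preactivation residual network over 120-sample heartbeats.
#
# The full-size variant follows the canonical ResNet-50 table with the 2D
# convolutions replaced by 1D ones (stage layout 3-4-6-3 bottleneck blocks,
# widths 64/128/256/512 with 4x expansion, stem kernel 7, block kernel 3,
# stride-2 temporal downsampling per stage; input length 120 -> final
# feature length 4). Every block applies batch normalization and a
# rectifier before each convolution (preactivation ordering). A ResNet-18
# basic-block variant shares all the pipeline code and trains in minutes on
# a CPU. Forward and backward passes are explicit; see nn_layers.R.

#' Network architecture specification
#'
#' @param variant `"resnet50_1d"` (bottleneck blocks, 3-4-6-3) or
#'   `"resnet18_1d"` (basic blocks, 2-2-2-2).
#' @param input_length Beat length in samples.
#' @param num_classes Number of output classes.
#' @return An object of class `network_spec`.
#' @export
resnet_spec <- function(variant = c("resnet50_1d", "resnet18_1d"),
                        input_length = 120L, num_classes = 2L) {
  variant <- match.arg(variant)
  if (variant == "resnet50_1d") {
    block <- "bottleneck"; layout <- c(3L, 4L, 6L, 3L); expansion <- 4L
  } else {
    block <- "basic"; layout <- c(2L, 2L, 2L, 2L); expansion <- 1L
  }
  structure(list(variant = variant, block = block, layout = layout,
                 widths = c(64L, 128L, 256L, 512L), strides = c(1L, 2L, 2L, 2L),
                 expansion = expansion, stem_width = 64L, stem_kernel = 7L,
                 kernel = 3L, input_length = as.integer(input_length),
                 in_channels = 1L, num_classes = as.integer(num_classes)),
            class = "network_spec")
}

#' Count of weighted layers (convolutions + final fully connected)
#'
#' Projection shortcuts are not counted, matching the conventional depth
#' naming (ResNet-50 has 50 weighted layers).
#'
#' @param spec A [resnet_spec()].
#' @return Integer layer count.
#' @export
weighted_layer_count <- function(spec) {
  per_block <- if (spec$block == "bottleneck") 3L else 2L
  1L + sum(spec$layout) * per_block + 1L
}

# Channel bookkeeping: returns for each stage/block the in/out channels and
# whether a projection shortcut is needed.
block_plan <- function(spec) {
  plan <- list()
  c_in <- spec$stem_width
  for (s in seq_along(spec$layout)) {
    width <- spec$widths[s]
    c_out <- width * spec$expansion
    for (b in seq_len(spec$layout[s])) {
      stride <- if (b == 1L) spec$strides[s] else 1L
      plan[[length(plan) + 1L]] <- list(
        stage = s, block = b, prefix = sprintf("stage%d.block%d", s, b),
        c_in = c_in, width = width, c_out = c_out, stride = stride,
        project = (stride != 1L || c_in != c_out))
      c_in <- c_out
    }
  }
  plan
}

he_init <- function(k, c_in, c_out) {
  matrix(stats::rnorm(k * c_in * c_out, sd = sqrt(2 / (k * c_in))), k * c_in, c_out)
}

new_bn <- function(C, params, buffers, prefix) {
  params[[paste0(prefix, ".gamma")]] <- rep(1, C)
  params[[paste0(prefix, ".beta")]] <- rep(0, C)
  buffers[[paste0(prefix, ".mean")]] <- rep(0, C)
  buffers[[paste0(prefix, ".var")]] <- rep(1, C)
  list(params = params, buffers = buffers)
}

#' Build and randomly initialize a network
#'
#' Convolutions use He-normal initialization; batch-norm scales start at 1
#' and shifts at 0. Identical spec and seed give bitwise-identical weights.
#'
#' @param spec A [resnet_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A model: list with `spec`, `params` (named trainable arrays),
#'   `buffers` (batch-norm running statistics), `frozen_stages` (0 = none).
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(seed)
  params <- list(); buffers <- list()
  params[["stem.conv.W"]] <- he_init(spec$stem_kernel, spec$in_channels, spec$stem_width)
  for (bp in block_plan(spec)) {
    p <- bp$prefix
    if (spec$block == "bottleneck") {
      r <- new_bn(bp$c_in, params, buffers, paste0(p, ".bn1")); params <- r$params; buffers <- r$buffers
      params[[paste0(p, ".conv1.W")]] <- he_init(1L, bp$c_in, bp$width)
      r <- new_bn(bp$width, params, buffers, paste0(p, ".bn2")); params <- r$params; buffers <- r$buffers
      params[[paste0(p, ".conv2.W")]] <- he_init(spec$kernel, bp$width, bp$width)
      r <- new_bn(bp$width, params, buffers, paste0(p, ".bn3")); params <- r$params; buffers <- r$buffers
      params[[paste0(p, ".conv3.W")]] <- he_init(1L, bp$width, bp$c_out)
    } else {
      r <- new_bn(bp$c_in, params, buffers, paste0(p, ".bn1")); params <- r$params; buffers <- r$buffers
      params[[paste0(p, ".conv1.W")]] <- he_init(spec$kernel, bp$c_in, bp$c_out)
      r <- new_bn(bp$c_out, params, buffers, paste0(p, ".bn2")); params <- r$params; buffers <- r$buffers
      params[[paste0(p, ".conv2.W")]] <- he_init(spec$kernel, bp$c_out, bp$c_out)
    }
    if (bp$project)
      params[[paste0(p, ".shortcut.W")]] <- he_init(1L, bp$c_in, bp$c_out)
  }
  c_final <- spec$widths[length(spec$widths)] * spec$expansion
  r <- new_bn(c_final, params, buffers, "final.bn"); params <- r$params; buffers <- r$buffers
  params[["fc.W"]] <- matrix(stats::rnorm(c_final * spec$num_classes, sd = sqrt(2 / c_final)),
                             c_final, spec$num_classes)
  params[["fc.b"]] <- rep(0, spec$num_classes)
  structure(list(spec = spec, params = params, buffers = buffers, frozen_stages = 0L),
            class = "resnet1d")
}

#' @export
print.resnet1d <- function(x, ...) {
  cat(sprintf("<resnet1d %s: %d weighted layers, %s parameters, frozen stages: %d>\n",
              x$spec$variant, weighted_layer_count(x$spec),
              format(sum(vapply(x$params, length, 1L)), big.mark = ","),
              x$frozen_stages))
  invisible(x)
}

#' Names of trainable parameters given a frozen-stage prefix
#'
#' Freezing covers the stem and stages `1..frozen_stages` (their
#' convolutions and batch-norm scale/shift); the remaining stages, the
#' final batch norm and the classification head stay trainable.
#'
#' @param model A `resnet1d` model.
#' @param frozen_stages Number of leading residual stages frozen.
#' @return Character vector of frozen parameter names.
#' @export
frozen_param_names <- function(model, frozen_stages = model$frozen_stages) {
  nm <- names(model$params)
  if (frozen_stages <= 0) return(character(0))
  pref <- c("stem.", sprintf("stage%d.", seq_len(frozen_stages)))
  nm[Reduce(`|`, lapply(pref, function(p) startsWith(nm, p)))]
}

# bn helper: frozen stages run in eval mode during training so their
# running statistics stay bitwise unchanged.
bn_is_training <- function(training, prefix, frozen_stages) {
  if (!training) return(FALSE)
  if (frozen_stages <= 0) return(TRUE)
  for (s in seq_len(frozen_stages))
    if (startsWith(prefix, sprintf("stage%d.", s))) return(FALSE)
  TRUE
}

bn_apply <- function(x, params, buffers, prefix, training) {
  bn_forward(x, params[[paste0(prefix, ".gamma")]], params[[paste0(prefix, ".beta")]],
             buffers[[paste0(prefix, ".mean")]], buffers[[paste0(prefix, ".var")]],
             training = training)
}

residual_block_forward <- function(x, model, bp, training, buffers) {
  p <- model$params; spec <- model$spec; pre <- bp$prefix
  cache <- list(prefix = pre, bp = bp)
  tr1 <- bn_is_training(training, pre, model$frozen_stages)
  r <- bn_apply(x, p, buffers, paste0(pre, ".bn1"), tr1)
  buffers[[paste0(pre, ".bn1.mean")]] <- r$rmean; buffers[[paste0(pre, ".bn1.var")]] <- r$rvar
  cache$bn1 <- r$cache
  a1 <- relu_forward(r$out); cache$relu1 <- a1$cache
  shortcut_in <- if (bp$project) a1$out else x
  if (spec$block == "bottleneck") {
    c1 <- conv1d_forward(a1$out, p[[paste0(pre, ".conv1.W")]], 1L, 1L, 0L); cache$conv1 <- c1$cache
    r <- bn_apply(c1$out, p, buffers, paste0(pre, ".bn2"), tr1)
    buffers[[paste0(pre, ".bn2.mean")]] <- r$rmean; buffers[[paste0(pre, ".bn2.var")]] <- r$rvar
    cache$bn2 <- r$cache
    a2 <- relu_forward(r$out); cache$relu2 <- a2$cache
    c2 <- conv1d_forward(a2$out, p[[paste0(pre, ".conv2.W")]], spec$kernel,
                         bp$stride, spec$kernel %/% 2L); cache$conv2 <- c2$cache
    r <- bn_apply(c2$out, p, buffers, paste0(pre, ".bn3"), tr1)
    buffers[[paste0(pre, ".bn3.mean")]] <- r$rmean; buffers[[paste0(pre, ".bn3.var")]] <- r$rvar
    cache$bn3 <- r$cache
    a3 <- relu_forward(r$out); cache$relu3 <- a3$cache
    c3 <- conv1d_forward(a3$out, p[[paste0(pre, ".conv3.W")]], 1L, 1L, 0L); cache$conv3 <- c3$cache
    branch <- c3$out
  } else {
    c1 <- conv1d_forward(a1$out, p[[paste0(pre, ".conv1.W")]], spec$kernel,
                         bp$stride, spec$kernel %/% 2L); cache$conv1 <- c1$cache
    r <- bn_apply(c1$out, p, buffers, paste0(pre, ".bn2"), tr1)
    buffers[[paste0(pre, ".bn2.mean")]] <- r$rmean; buffers[[paste0(pre, ".bn2.var")]] <- r$rvar
    cache$bn2 <- r$cache
    a2 <- relu_forward(r$out); cache$relu2 <- a2$cache
    c2 <- conv1d_forward(a2$out, p[[paste0(pre, ".conv2.W")]], spec$kernel, 1L,
                         spec$kernel %/% 2L); cache$conv2 <- c2$cache
    branch <- c2$out
  }
  if (bp$project) {
    sc <- conv1d_forward(shortcut_in, p[[paste0(pre, ".shortcut.W")]], 1L, bp$stride, 0L)
    cache$shortcut <- sc$cache
    short <- sc$out
  } else short <- x
  list(out = branch + short, cache = cache, buffers = buffers)
}

residual_block_backward <- function(dout, model, cache) {
  p <- model$params; spec <- model$spec; pre <- cache$prefix; bp <- cache$bp
  grads <- list()
  dbranch <- dout
  if (spec$block == "bottleneck") {
    cb <- conv1d_backward(dbranch, p[[paste0(pre, ".conv3.W")]], cache$conv3)
    grads[[paste0(pre, ".conv3.W")]] <- cb$dW
    da3 <- relu_backward(cb$dx, cache$relu3)
    bb <- bn_backward(da3, p[[paste0(pre, ".bn3.gamma")]], cache$bn3)
    grads[[paste0(pre, ".bn3.gamma")]] <- bb$dgamma; grads[[paste0(pre, ".bn3.beta")]] <- bb$dbeta
    cb <- conv1d_backward(bb$dx, p[[paste0(pre, ".conv2.W")]], cache$conv2)
    grads[[paste0(pre, ".conv2.W")]] <- cb$dW
    da2 <- relu_backward(cb$dx, cache$relu2)
    bb <- bn_backward(da2, p[[paste0(pre, ".bn2.gamma")]], cache$bn2)
    grads[[paste0(pre, ".bn2.gamma")]] <- bb$dgamma; grads[[paste0(pre, ".bn2.beta")]] <- bb$dbeta
    cb <- conv1d_backward(bb$dx, p[[paste0(pre, ".conv1.W")]], cache$conv1)
    grads[[paste0(pre, ".conv1.W")]] <- cb$dW
    da1 <- cb$dx
  } else {
    cb <- conv1d_backward(dbranch, p[[paste0(pre, ".conv2.W")]], cache$conv2)
    grads[[paste0(pre, ".conv2.W")]] <- cb$dW
    da2 <- relu_backward(cb$dx, cache$relu2)
    bb <- bn_backward(da2, p[[paste0(pre, ".bn2.gamma")]], cache$bn2)
    grads[[paste0(pre, ".bn2.gamma")]] <- bb$dgamma; grads[[paste0(pre, ".bn2.beta")]] <- bb$dbeta
    cb <- conv1d_backward(bb$dx, p[[paste0(pre, ".conv1.W")]], cache$conv1)
    grads[[paste0(pre, ".conv1.W")]] <- cb$dW
    da1 <- cb$dx
  }
  if (bp$project) {
    sb <- conv1d_backward(dout, p[[paste0(pre, ".shortcut.W")]], cache$shortcut)
    grads[[paste0(pre, ".shortcut.W")]] <- sb$dW
    da1 <- da1 + sb$dx      # shortcut taps the shared preactivation
    dpre <- relu_backward(da1, cache$relu1)
    bb <- bn_backward(dpre, p[[paste0(pre, ".bn1.gamma")]], cache$bn1)
    grads[[paste0(pre, ".bn1.gamma")]] <- bb$dgamma; grads[[paste0(pre, ".bn1.beta")]] <- bb$dbeta
    dx <- bb$dx
  } else {
    dpre <- relu_backward(da1, cache$relu1)
    bb <- bn_backward(dpre, p[[paste0(pre, ".bn1.gamma")]], cache$bn1)
    grads[[paste0(pre, ".bn1.gamma")]] <- bb$dgamma; grads[[paste0(pre, ".bn1.beta")]] <- bb$dbeta
    dx <- bb$dx + dout      # identity shortcut
  }
  list(dx = dx, grads = grads)
}

#' Forward pass
#'
#' @param model A `resnet1d` model.
#' @param x Beat batch: an `n x input_length` matrix (one beat per row) or
#'   an `[n, L, 1]` array.
#' @param training Use batch statistics and update running statistics
#'   (frozen stages always run in evaluation mode).
#' @param collect Keep layer caches for a subsequent backward pass.
#' @return List with `logits`, `probs` (n x classes), `features` (pooled
#'   final features, n x C), `feature_map` (last residual stage output,
#'   `[n, 4, C]`), `buffers` (updated running stats), and `cache` when
#'   `collect = TRUE`.
#' @export
nn_forward <- function(model, x, training = FALSE, collect = FALSE) {
  stopifnot(inherits(model, "resnet1d"))
  if (is.matrix(x)) {
    if (ncol(x) != model$spec$input_length)
      stop("beat length ", ncol(x), " does not match the network input length ",
           model$spec$input_length)
    x <- array(x, c(nrow(x), ncol(x), 1L))
  }
  if (dim(x)[2] != model$spec$input_length)
    stop("beat length does not match the network input length")
  p <- model$params; buffers <- model$buffers
  cache <- list()
  st <- conv1d_forward(x, p[["stem.conv.W"]], model$spec$stem_kernel, 2L,
                       model$spec$stem_kernel %/% 2L)
  cache$stem <- st$cache
  mp <- maxpool_forward(st$out, 3L, 2L, 1L)
  cache$maxpool <- mp$cache
  h <- mp$out
  plan <- block_plan(model$spec)
  cache$blocks <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    rb <- residual_block_forward(h, model, plan[[i]], training, buffers)
    h <- rb$out; buffers <- rb$buffers
    cache$blocks[[i]] <- if (collect) rb$cache else NULL
  }
  feature_map <- h
  trf <- if (training) TRUE else FALSE
  r <- bn_apply(h, p, buffers, "final.bn", trf)
  buffers[["final.bn.mean"]] <- r$rmean; buffers[["final.bn.var"]] <- r$rvar
  cache$final_bn <- r$cache
  a <- relu_forward(r$out); cache$final_relu <- a$cache
  g <- gap_forward(a$out); cache$gap <- g$cache
  features <- g$out
  fc <- linear_forward(features, p[["fc.W"]], p[["fc.b"]])
  cache$fc <- fc$cache
  out <- list(logits = fc$out, probs = softmax_probs(fc$out), features = features,
              feature_map = feature_map, buffers = buffers)
  if (collect) out$cache <- cache
  out
}

# Backward through the classification head only; returns the gradient at
# the last residual stage output plus head parameter grads.
head_backward <- function(model, cache, dlogits) {
  p <- model$params
  lb <- linear_backward(dlogits, p[["fc.W"]], cache$fc)
  grads <- list(fc.W = lb$dW, fc.b = lb$db)
  dg <- gap_backward(lb$dx, cache$gap)
  dr <- relu_backward(dg, cache$final_relu)
  bb <- bn_backward(dr, p[["final.bn.gamma"]], cache$final_bn)
  grads[["final.bn.gamma"]] <- bb$dgamma; grads[["final.bn.beta"]] <- bb$dbeta
  list(d_feature = bb$dx, grads = grads)
}

#' Backward pass
#'
#' @param model A `resnet1d` model.
#' @param cache Cache from [nn_forward()] with `collect = TRUE`.
#' @param dlogits Gradient of the loss with respect to the logits.
#' @return List with `grads` (named, matching `model$params`) and
#'   `d_feature` (gradient at the last residual stage output).
#' @export
nn_backward <- function(model, cache, dlogits) {
  hb <- head_backward(model, cache, dlogits)
  grads <- hb$grads
  dh <- hb$d_feature
  for (i in rev(seq_along(cache$blocks))) {
    rb <- residual_block_backward(dh, model, cache$blocks[[i]])
    grads <- c(grads, rb$grads)
    dh <- rb$dx
  }
  dmp <- maxpool_backward(dh, cache$maxpool)
  sb <- conv1d_backward(dmp, model$params[["stem.conv.W"]], cache$stem)
  grads[["stem.conv.W"]] <- sb$dW
  list(grads = grads, d_feature = hb$d_feature)
}

#' Predict class probabilities for a beat matrix
#'
#' Evaluation mode (frozen batch statistics), batched so memory stays flat;
#' duplicated beats therefore always give identical probabilities.
#'
#' @param model A `resnet1d` model.
#' @param X `n x input_length` beat matrix.
#' @param batch_size Beats per forward pass.
#' @return `n x num_classes` probability matrix (rows sum to 1).
#' @export
predict_proba <- function(model, X, batch_size = 256L) {
  n <- nrow(X)
  out <- matrix(0, n, model$spec$num_classes)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    out[i:j, ] <- nn_forward(model, X[i:j, , drop = FALSE], training = FALSE)$probs
    i <- j + 1L
  }
  out
}

#' Pooled last-stage features for a beat matrix
#'
#' The global-average-pooled activations feeding the classification layer;
#' the inputs to the t-SNE embedding.
#'
#' @inheritParams predict_proba
#' @return `n x C` feature matrix.
#' @export
nn_features <- function(model, X, batch_size = 256L) {
  n <- nrow(X)
  cfin <- model$spec$widths[4] * model$spec$expansion
  out <- matrix(0, n, cfin)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    out[i:j, ] <- nn_forward(model, X[i:j, , drop = FALSE], training = FALSE)$features
    i <- j + 1L
  }
  out
}

#' Last-layer feature maps and their class-score gradients
#'
#' Runs one beat forward in evaluation mode and differentiates the chosen
#' class's logit with respect to the final residual stage's feature maps —
#' the two ingredients of Grad-CAM.
#'
#' @param model A `resnet1d` model.
#' @param beat Numeric vector of length `input_length`.
#' @param class_index 1-based class index (1 = normokalemia, 2 =
#'   hyperkalemia under the package's label encoding).
#' @return List with `activations` and `gradients`, both `C x L` matrices.
#' @export
feature_maps_and_grads <- function(model, beat, class_index) {
  if (class_index < 1 || class_index > model$spec$num_classes)
    stop("class_index out of range")
  fw <- nn_forward(model, matrix(beat, 1L), training = FALSE, collect = TRUE)
  dlog <- matrix(0, 1L, model$spec$num_classes)
  dlog[1L, class_index] <- 1
  hb <- head_backward(model, fw$cache, dlog)
  A <- t(matrix(fw$feature_map[1L, , ], dim(fw$feature_map)[2], dim(fw$feature_map)[3]))
  G <- t(matrix(hb$d_feature[1L, , ], dim(fw$feature_map)[2], dim(fw$feature_map)[3]))
  list(activations = A, gradients = G)
}
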