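# Model interpretation: Grad-CAM saliency over single beats and a 2D
# t-SNE embedding of the pooled last-stage features.

#' Grad-CAM saliency for one beat
#'
#' Channel weights are the temporal average of the class-score gradients at
#' the last residual stage; the map is the rectified weighted sum of the
#' channel activations, linearly interpolated from the coarse feature
#' length (4 for 120-sample beats) to the beat length, and max-normalized
#' to `[0, 1]`. An all-zero map (e.g. zero head weights) is returned
#' unnormalized.
#'
#' @param model A `resnet1d` model.
#' @param beat Numeric beat of length `input_length`.
#' @param class_index 1-based class (2 = hyperkalemia).
#' @return Numeric saliency of length `input_length`, values in `[0, 1]`.
#' @export
grad_cam <- function(model, beat, class_index = 2L) {
  fg <- feature_maps_and_grads(model, beat, class_index)
  w <- rowMeans(fg$gradients)                  # per-channel weight
  coarse <- pmax(colSums(fg$activations * w), 0)
  n_out <- model$spec$input_length
  if (length(coarse) == 1) {
    map <- rep(coarse, n_out)
  } else {
    map <- stats::approx(x = seq(1, n_out, length.out = length(coarse)),
                         y = coarse, xout = seq_len(n_out))$y
  }
  mx <- max(map)
  if (mx > 0) map <- map / mx
  map
}

#' Class-average beat curves
#'
#' Pointwise mean beat per class, as plotted against Grad-CAM maps.
#'
#' @param X `n x L` beat matrix.
#' @param labels Character labels (`"hyper"` / `"normo"`), both present.
#' @return List with numeric vectors `hyper` and `normo`, each of length L.
#' @export
average_class_beats <- function(X, labels) {
  if (!all(c("hyper", "normo") %in% labels))
    stop("both classes must be present")
  list(hyper = colMeans(X[labels == "hyper", , drop = FALSE]),
       normo = colMeans(X[labels == "normo", , drop = FALSE]))
}

#' t-SNE embedding of feature vectors
#'
#' Exact (quadratic-cost) t-distributed stochastic neighbor embedding:
#' per-point bandwidths found by bisection to match the target perplexity,
#' symmetrized input affinities, Student-t low-dimensional kernel,
#' gradient descent with momentum, adaptive gains and early exaggeration.
#' Deterministic given the seed.
#'
#' @param X `n x d` feature matrix (e.g. [nn_features()] output).
#' @param perplexity Target perplexity; requires `n > 3 * perplexity`.
#' @param seed RNG seed for the initial layout.
#' @param n_iter Gradient-descent iterations.
#' @param eta Learning rate.
#' @return `n x 2` embedding matrix.
#' @export
embed_tsne <- function(X, perplexity = 30, seed = 1L, n_iter = 500L, eta = 100) {
  n <- nrow(X)
  if (n <= 3 * perplexity) stop("perplexity too large: need n > 3 * perplexity")
  P <- tsne_affinities(X, perplexity)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  exag <- 4; stop_exag <- 100L
  Pe <- P * exag
  for (it in seq_len(n_iter)) {
    if (it == stop_exag + 1L) Pe <- P
    # Student-t kernel on the current layout
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (it < 20L) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# symmetrized, perplexity-calibrated input affinities
tsne_affinities <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  sumX <- rowSums(X^2)
  D <- outer(sumX, sumX, "+") - 2 * tcrossprod(X)
  D[D < 0] <- 0
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1; betamin <- -Inf; betamax <- Inf
    for (tries in seq_len(50)) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sump) + beta * sum(di * p) / sump
        p <- p / sump
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { betamin <- beta; beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2 }
      else { betamax <- beta; beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}
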