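#' Training configuration
#'
#' @param epochs number of passes over the training split.
#' @param batch_size minibatch size.
#' @param learning_rate initial SGD learning rate (cosine-decayed to 0).
#' @param momentum SGD momentum.
#' @param rotation_degrees augmentation: random rotation in
#'   \code{[-rotation_degrees, rotation_degrees]} (0 disables).
#' @param horizontal_flip_prob augmentation: probability of a left-right flip.
#' @param clip_grad_norm cap on the global L2 norm of the gradient; batches
#'   whose gradient exceeds it are rescaled (Inf disables). Guards the early
#'   epochs of the batch-norm-free residual encoder against blow-ups.
#' @param normalize logical; standardize inputs by the training-split mean and
#'   standard deviation (computed at fit time, never hard-coded).
#' @param shuffle logical; reshuffle minibatches every epoch.
#' @param verbose print per-epoch progress.
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(epochs = 14L, batch_size = 32L, learning_rate = 0.02,
                         momentum = 0.9, rotation_degrees = 0,
                         horizontal_flip_prob = 0, clip_grad_norm = 5,
                         normalize = TRUE, shuffle = TRUE, verbose = FALSE) {
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (horizontal_flip_prob < 0 || horizontal_flip_prob > 1)
    stopf("horizontal_flip_prob must be in [0, 1]")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 rotation_degrees = rotation_degrees,
                 horizontal_flip_prob = horizontal_flip_prob,
                 clip_grad_norm = clip_grad_norm,
                 normalize = isTRUE(normalize), shuffle = isTRUE(shuffle),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Horizontally flip an image
#'
#' Left-right mirror; applying it twice restores the original.
#' @param img matrix (H x W) or array [H, W, C].
#' @export
flip_image <- function(img) {
  if (is.matrix(img)) img[, rev(seq_len(ncol(img))), drop = FALSE]
  else img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
}

#' Rotate an image about its center
#'
#' Bilinear interpolation; pixels sampled outside the frame take the value
#' \code{fill}.
#' @param img matrix (H x W).
#' @param degrees rotation angle (counter-clockwise).
#' @param fill out-of-frame value, default 0.
#' @export
rotate_image <- function(img, degrees, fill = 0) {
  if (degrees == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- rep(seq_len(H), times = W) - cy
  gx <- rep(seq_len(W), each = H) - cx
  sy <- cos(th) * gy - sin(th) * gx + cy
  sx <- sin(th) * gy + cos(th) * gx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  pix <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- rep(fill, length(yy))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  v <- (1 - fy) * (1 - fx) * pix(y0, x0) + (1 - fy) * fx * pix(y0, x0 + 1) +
    fy * (1 - fx) * pix(y0 + 1, x0) + fy * fx * pix(y0 + 1, x0 + 1)
  matrix(v, H, W)
}

#' Augment a batch of images
#'
#' Applies, in order: random rotation within \code{rotation_degrees}, a
#' horizontal flip with the configured probability, then standardization by
#' \code{norm_mean}/\code{norm_sd}. Deterministic under a fixed RNG seed.
#'
#' @param x image array [H, W, C, N] (or [H, W, N]).
#' @param cfg a \code{\link{train_config}}.
#' @param norm_mean,norm_sd normalization statistics (defaults leave pixel
#'   units untouched).
#' @return array of the same shape.
#' @export
augment <- function(x, cfg, norm_mean = 0, norm_sd = 1) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d[1L], d[2L], 1L, d[3L])
  d <- dim(x)
  N <- d[4L]
  if (cfg$rotation_degrees > 0) {
    angles <- runif(N, -cfg$rotation_degrees, cfg$rotation_degrees)
    for (n in seq_len(N)) for (c in seq_len(d[3L]))
      x[, , c, n] <- rotate_image(x[, , c, n], angles[n])
  }
  if (cfg$horizontal_flip_prob > 0) {
    do_flip <- runif(N) < cfg$horizontal_flip_prob
    for (n in which(do_flip)) x[, , , n] <- x[, rev(seq_len(d[2L])), , n]
  }
  (x - norm_mean) / norm_sd
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

# mean cross-entropy and gradient wrt logits
ce_loss <- function(logits, labels) {
  P <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dP <- P
  dP[idx] <- dP[idx] - 1
  list(loss = loss, dlogits = dP / n)
}

#' Fit a hybrid Euclidean/Lorentz convolutional classifier
#'
#' The main fitting entry point. Builds a model (or continues from one),
#' computes normalization statistics from the training images, and trains by
#' minibatch SGD with momentum and cosine learning-rate decay under
#' cross-entropy loss. All trainable parameters use Euclidean
#' reparameterizations (curvature as log k; hyperbolic hyperplanes as tangent
#' directions plus scalar offsets), so the constraint k > 0 holds at every
#' step by construction.
#'
#' @param x images: array [H, W, N] or [H, W, C, N], raw pixel units in [0, 1].
#' @param y labels: integer vector (1..n_classes) or factor of length N.
#' @param geometry "lorentz" or "euclidean" (ignored when \code{config} given).
#' @param config a \code{\link{model_config}}; defaults to a tiny-encoder
#'   config inferred from the data.
#' @param control a \code{\link{train_config}}.
#' @param seed integer seed governing initialization, shuffling, augmentation.
#' @param model optionally, an existing \code{hcnn} to (continue) train(ing).
#' @return a fitted object of class \code{hcnn}, with a per-epoch training log
#'   (\code{$log}: epoch, loss, top1).
#' @export
hcnn <- function(x, y, geometry = c("lorentz", "euclidean"), config = NULL,
                 control = train_config(), seed = 1L, model = NULL) {
  y <- as_labels(y)
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d[1L], d[2L], 1L, d[3L])
  if (is.null(model)) {
    if (is.null(config)) {
      geometry <- match.arg(geometry)
      config <- model_config(geometry, n_classes = max(y),
                             image_size = dim(x)[1L], in_channels = dim(x)[3L])
    }
    model <- build_model(config, seed = seed)
  }
  train_model(model, x, y, control, seed = seed)
}

as_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (any(is.na(y)) || any(y < 1L)) stopf("labels must be positive integers or a factor")
  y
}

#' @rdname hcnn
#' @export
train_model <- function(model, x, y, control = train_config(), seed = 1L) {
  y <- as_labels(y)
  x <- as_image_batch(x, model$config)
  tab <- table(y)
  if (length(tab) < 2L || any(tab < 2L))
    stopf("training data needs >= 2 classes with >= 2 images each")
  if (max(y) > model$config$n_classes)
    stopf("label %d exceeds n_classes = %d", max(y), model$config$n_classes)
  set.seed(seed + 1L)
  if (control$normalize) {
    model$norm <- list(mean = mean(x), sd = max(sd(x), 1e-8))
  }
  params <- param_tree(model)
  vel <- tree_map(function(p) p * 0, params)
  N <- dim(x)[4L]
  n_batches <- ceiling(N / control$batch_size)
  log <- data.frame(epoch = integer(), loss = numeric(), top1 = numeric())
  for (epoch in seq_len(control$epochs)) {
    lr <- control$learning_rate *
      0.5 * (1 + cos(pi * (epoch - 1) / control$epochs))
    ord <- if (control$shuffle) sample.int(N) else seq_len(N)
    ep_loss <- 0; ep_correct <- 0
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1L) * control$batch_size + 1L):min(b * control$batch_size, N)]
      xb <- augment(x[, , , idx, drop = FALSE], control,
                    model$norm$mean, model$norm$sd)
      yb <- y[idx]
      fp <- forward_pass(model, xb, keep_cache = TRUE)
      l <- ce_loss(fp$logits, yb)
      if (!is.finite(l$loss))
        stopf("training diverged (non-finite loss) at epoch %d, batch %d", epoch, b)
      bp <- backward_pass(model, fp, l$dlogits)
      grads <- bp$grads
      if (is.finite(control$clip_grad_norm)) {
        gn <- sqrt(sum(vapply(tree_flatten(grads), function(g) sum(g * g), 1.0)))
        if (gn > control$clip_grad_norm)
          grads <- tree_map(function(g) g * (control$clip_grad_norm / gn), grads)
      }
      vel <- tree_map(function(v, g) control$momentum * v - lr * g, vel, grads)
      params <- tree_map(function(p, v) p + v, params, vel)
      model <- set_param_tree(model, params)
      ep_loss <- ep_loss + l$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(fp$logits, ties.method = "first") == yb)
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = ep_loss / N,
                                 top1 = 100 * ep_correct / N))
    if (control$verbose)
      message(sprintf("epoch %d: loss %.4f, top1 %.1f%%", epoch,
                      ep_loss / N, 100 * ep_correct / N))
  }
  model$fitted <- TRUE
  model$log <- log
  model$control <- control
  model
}

#' Top-k accuracy
#'
#' Fraction (in percent) of rows whose true label is among the k largest
#' logits. Ties are broken in favour of the lowest class index, so a label
#' tied at the k-th position counts only if its index wins the tie.
#'
#' @param logits matrix (n x n_classes).
#' @param labels integer vector in 1..n_classes.
#' @param k integer, 1 <= k <= n_classes.
#' @return percentage in [0, 100].
#' @export
topk_accuracy <- function(logits, labels, k) {
  labels <- as_labels(labels)
  C <- ncol(logits)
  if (k < 1L || k > C) stopf("k must be in 1..%d", C)
  if (any(labels > C)) stopf("label out of range (> %d classes)", C)
  hit <- vapply(seq_len(nrow(logits)), function(i) {
    topk <- order(-logits[i, ], seq_len(C))[seq_len(k)]
    labels[i] %in% topk
  }, TRUE)
  100 * mean(hit)
}

#' Evaluate a model on a labelled split
#'
#' Computes cross-entropy loss, Top-1 and Top-5 accuracy (Top-5 capped at the
#' class count), and per-class accuracy, with no parameter updates.
#'
#' @param model a fitted \code{hcnn}.
#' @param x images (raw pixel units).
#' @param y labels.
#' @param batch_size forward-pass batch size.
#' @return an object of class \code{metrics_report}.
#' @export
evaluate <- function(model, x, y, batch_size = 256L) {
  y <- as_labels(y)
  if (length(y) == 0L) stopf("evaluate: empty split")
  logits <- predict(model, x, type = "logit", batch_size = batch_size)
  l <- ce_loss(logits, y)
  k5 <- min(5L, ncol(logits))
  per_class <- vapply(seq_len(model$config$n_classes), function(cl) {
    sel <- y == cl
    if (!any(sel)) NA_real_
    else 100 * mean(max.col(logits[sel, , drop = FALSE], ties.method = "first") == cl)
  }, 1.0)
  structure(list(cross_entropy = l$loss,
                 top1 = topk_accuracy(logits, y, 1L),
                 top5 = topk_accuracy(logits, y, k5),
                 per_class = per_class, n_eval = length(y)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d: cross-entropy %.4f, Top-1 %.2f%%, Top-5 %.2f%%\n",
              x$n_eval, x$cross_entropy, x$top1, x$top5))
  invisible(x)
}
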