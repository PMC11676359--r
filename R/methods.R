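#' Predict from a fitted classifier
#'
#' @param object a fitted \code{hcnn}.
#' @param x images, array [H, W, N] or [H, W, C, N] in raw pixel units.
#' @param type "class" (integer labels), "prob" (softmax probabilities),
#'   "logit" (head scores), or "embedding" (penultimate features).
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @export
predict.hcnn <- function(object, x, type = c("class", "prob", "logit", "embedding"),
                         batch_size = 256L, ...) {
  type <- match.arg(type)
  x <- as_image_batch(x, object$config)
  x <- (x - object$norm$mean) / object$norm$sd
  N <- dim(x)[4L]
  out <- NULL
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    fp <- forward_pass(object, x[, , , idx, drop = FALSE])
    piece <- if (type == "embedding") fp$embeddings else fp$logits
    out <- rbind(out, piece)
  }
  switch(type,
         class = max.col(out, ties.method = "first"),
         prob = softmax_rows(out),
         logit = out,
         embedding = out)
}

#' @export
print.hcnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s classifier (%s encoder, %dx%d input, %d classes, %d-dim embedding)\n",
              if (x$geometry == "lorentz") "Euclidean-Lorentz hybrid" else "Euclidean",
              cfg$encoder_scale, cfg$image_size, cfg$image_size,
              cfg$n_classes, cfg$embedding_dim))
  cat(sprintf("trainable parameters: %d%s\n", param_count(x),
              if (x$geometry == "lorentz")
                sprintf("; curvature k = %.4g (learnable), clip radius %.3g",
                        exp(x$head$logk), cfg$clip_radius) else ""))
  if (x$fitted) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("fitted: %d epochs, final training loss %.4f, Top-1 %.1f%%\n",
                last$epoch, last$loss, last$top1))
  } else cat("not fitted\n")
  invisible(x)
}

#' @export
summary.hcnn <- function(object, ...) {
  print(object)
  if (object$fitted) {
    cat("\ntraining log:\n")
    print(object$log, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.hcnn <- function(object, ...) {
  param_tree(object)
}

#' Plot the training loss curve
#' @param x a fitted \code{hcnn}.
#' @param ... passed to \code{plot}.
#' @export
plot.hcnn <- function(x, ...) {
  if (!x$fitted) stopf("model is not fitted")
  plot(x$log$epoch, x$log$loss, type = "b", xlab = "epoch",
       ylab = "training cross-entropy", ...)
  invisible(x)
}
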