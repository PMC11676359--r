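#' PGD attack configuration
#'
#' Hyperparameters of a projected-gradient-descent adversarial attack under
#' the sup-norm. Epsilon and the step size are expressed in normalized input
#' units (the units the model consumes after standardization); the valid
#' pixel range is given in raw units and mapped internally.
#'
#' Two epsilon presets from the robustness protocol ship with the package:
#' \code{pgd_epsilon_presets} — "text" (0.03, 0.06, 0.12) and "table"
#' (0.003, 0.006, 0.012).
#'
#' @param epsilon sup-norm budget (>= 0; 0 yields the identity attack).
#' @param step_size gradient-sign step, default epsilon/4; must not exceed
#'   epsilon.
#' @param n_iter iterations, default 20.
#' @param random_start start from a uniform point inside the epsilon ball.
#' @param pixel_range valid raw pixel range, default c(0, 1).
#' @param seed RNG seed for the random start.
#' @return an object of class \code{attack_config}.
#' @export
attack_config <- function(epsilon, step_size = epsilon / 4, n_iter = 20L,
                          random_start = TRUE, pixel_range = c(0, 1),
                          seed = 1L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stopf("epsilon must be a nonnegative scalar")
  if (epsilon > 0 && (step_size <= 0 || step_size > epsilon))
    stopf("step_size must be in (0, epsilon]")
  if (n_iter < 1L) stopf("n_iter must be >= 1")
  structure(list(epsilon = epsilon, step_size = step_size,
                 n_iter = as.integer(n_iter), random_start = isTRUE(random_start),
                 pixel_range = pixel_range, seed = as.integer(seed)),
            class = "attack_config")
}

#' @rdname attack_config
#' @export
pgd_epsilon_presets <- list(text = c(0.03, 0.06, 0.12),
                            table = c(0.003, 0.006, 0.012))

# gradient of mean cross-entropy wrt the normalized input batch
input_gradient <- function(model, x_norm, labels) {
  fp <- forward_pass(model, x_norm, keep_cache = TRUE)
  l <- ce_loss(fp$logits, labels)
  bp <- backward_pass(model, fp, l$dlogits, need_dx = TRUE)
  bp$dx
}

#' Projected gradient descent adversarial attack
#'
#' Iteratively ascends the sign of the cross-entropy input gradient by
#' \code{step_size}, after each step projecting onto the sup-norm ball of
#' radius epsilon around the original (normalized) inputs and clipping to the
#' valid pixel range. With epsilon = 0 the input is returned exactly. The
#' perturbation bound \eqn{\|x_{adv} - x\|_\infty \le \epsilon} holds in
#' normalized units.
#'
#' @param model a fitted \code{hcnn} (evaluation mode; no parameters change).
#' @param x images in raw pixel units.
#' @param labels true labels the attack tries to contradict.
#' @param cfg an \code{\link{attack_config}}.
#' @return adversarial images in raw pixel units, same shape as \code{x}.
#' @export
pgd_attack <- function(model, x, labels, cfg) {
  if (!inherits(cfg, "attack_config")) stopf("cfg must be an attack_config")
  labels <- as_labels(labels)
  din <- dim(x)
  x <- as_image_batch(x, model$config)
  if (cfg$epsilon == 0) { dim(x) <- din; return(x) }
  mu <- model$norm$mean; sdv <- model$norm$sd
  xn0 <- (x - mu) / sdv
  lo <- (cfg$pixel_range[1L] - mu) / sdv
  hi <- (cfg$pixel_range[2L] - mu) / sdv
  set.seed(cfg$seed)
  xn <- xn0
  if (cfg$random_start)
    xn <- xn + array(runif(length(xn), -cfg$epsilon, cfg$epsilon), dim = dim(xn))
  xn <- pmin(pmax(xn, lo), hi)
  for (it in seq_len(cfg$n_iter)) {
    g <- input_gradient(model, xn, labels)
    xn <- xn + cfg$step_size * sign(g)
    xn <- pmin(pmax(xn, xn0 - cfg$epsilon), xn0 + cfg$epsilon)
    xn <- pmin(pmax(xn, lo), hi)
  }
  out <- xn * sdv + mu
  dim(out) <- din
  out
}

#' Robust accuracy across an epsilon sweep
#'
#' Attacks the evaluation set at each configuration (ordered by epsilon) and
#' reports Top-1/Top-5 accuracy on the adversarial inputs; epsilon = 0 rows
#' equal clean accuracy.
#'
#' @param model a fitted \code{hcnn}.
#' @param x,labels evaluation images and labels.
#' @param sweep list of \code{\link{attack_config}}s, or a numeric vector of
#'   epsilons (expanded with default attack settings).
#' @param seed seed passed to attacks built from a numeric sweep.
#' @return data.frame (epsilon, top1, top5, n).
#' @export
robust_accuracy <- function(model, x, labels, sweep, seed = 1L) {
  if (is.numeric(sweep))
    sweep <- lapply(sweep, function(e)
      if (e == 0) attack_config(0, step_size = 0, random_start = FALSE, seed = seed)
      else attack_config(e, seed = seed))
  if (length(sweep) == 0L) stopf("empty attack sweep")
  eps <- vapply(sweep, `[[`, 1.0, "epsilon")
  sweep <- sweep[order(eps)]
  labels <- as_labels(labels)
  rows <- lapply(sweep, function(cfg) {
    xa <- pgd_attack(model, x, labels, cfg)
    logits <- predict(model, xa, type = "logit")
    data.frame(epsilon = cfg$epsilon,
               top1 = topk_accuracy(logits, labels, 1L),
               top5 = topk_accuracy(logits, labels, min(5L, ncol(logits))),
               n = length(labels))
  })
  do.call(rbind, rows)
}
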