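#' Model configuration
#'
#' Describes a classifier: a shared residual convolutional encoder with either
#' a Euclidean affine head or a Lorentz head (feature clipping, exponential
#' map onto the hyperboloid, hyperbolic multinomial-logistic decoder with
#' learnable curvature).
#'
#' @param geometry "euclidean" or "lorentz".
#' @param n_classes number of classes (>= 2).
#' @param embedding_dim penultimate embedding dimension; defaults to
#'   \code{n_classes}, matching the convention that the evaluation embedding
#'   space has one dimension per class.
#' @param encoder_scale "tiny" (stride-2 3x3 stem, two residual stages of
#'   width 16/32, global average pool) or "resnet18" (ResNet-18 width/depth:
#'   3x3 stem, stages 64/128/256/512 with two blocks each).
#' @param image_size input spatial size (square), default 32.
#' @param in_channels input channels, default 1 (grayscale).
#' @param clip_radius feature-clipping radius for the Lorentz head, default 1.
#' @param k_init initial curvature magnitude, default 1.
#' @return an object of class \code{model_config}.
#' @export
model_config <- function(geometry = c("lorentz", "euclidean"), n_classes,
                         embedding_dim = n_classes,
                         encoder_scale = c("tiny", "resnet18"),
                         image_size = 32L, in_channels = 1L,
                         clip_radius = 1, k_init = 1) {
  geometry <- match.arg(geometry)
  encoder_scale <- match.arg(encoder_scale)
  n_classes <- as.integer(n_classes)
  embedding_dim <- as.integer(embedding_dim)
  if (n_classes < 2L) stopf("n_classes must be >= 2")
  if (embedding_dim < 2L) stopf("embedding_dim must be >= 2")
  if (clip_radius <= 0 || k_init <= 0) stopf("clip_radius and k_init must be > 0")
  structure(list(geometry = geometry, n_classes = n_classes,
                 embedding_dim = embedding_dim, encoder_scale = encoder_scale,
                 image_size = as.integer(image_size),
                 in_channels = as.integer(in_channels),
                 clip_radius = as.numeric(clip_radius),
                 k_init = as.numeric(k_init)),
            class = "model_config")
}

#' Build an (untrained) classifier
#'
#' Encoder weights are drawn first from the seeded RNG stream, so two models
#' built with the same seed and config but different geometries share
#' bitwise-identical encoder initializations. The Lorentz head carries exactly
#' one more trainable scalar than the Euclidean head at equal dimensions: the
#' log-curvature.
#'
#' @param config a \code{\link{model_config}}.
#' @param seed integer seed for the initialization RNG.
#' @return an object of class \code{hcnn} (unfitted).
#' @export
build_model <- function(config, seed = 1L) {
  if (!inherits(config, "model_config")) stopf("config must be a model_config")
  set.seed(seed)
  enc <- encoder_init(config$encoder_scale, config$in_channels)
  fc <- list(w = matrix(rnorm(enc$out_channels * config$embedding_dim,
                              sd = sqrt(2 / enc$out_channels)),
                        nrow = enc$out_channels),
             b = rep(0, config$embedding_dim))
  d <- config$embedding_dim; C <- config$n_classes
  dirs <- matrix(rnorm(C * d, sd = 1 / sqrt(d)), nrow = C)
  head <- if (config$geometry == "euclidean") {
    list(W = dirs, b = rep(0, C))
  } else {
    list(Z = dirs, a = rep(0, C), logk = log(config$k_init))
  }
  structure(list(config = config, geometry = config$geometry,
                 encoder = enc, fc = fc, head = head,
                 norm = list(mean = 0, sd = 1),
                 fitted = FALSE, log = NULL, seed = as.integer(seed)),
            class = "hcnn")
}

param_tree <- function(model) {
  strip <- function(x) x[!vapply(x, is.null, TRUE)]
  enc <- model$encoder
  enc$out_channels <- NULL
  enc$stem$stride <- NULL
  enc$blocks <- lapply(enc$blocks, function(b) strip(list(a = b$a, b = b$b, proj = b$proj)))
  list(encoder = enc, fc = model$fc, head = model$head)
}

set_param_tree <- function(model, tree) {
  model$encoder$stem$w <- tree$encoder$stem$w
  model$encoder$stem$b <- tree$encoder$stem$b
  for (i in seq_along(model$encoder$blocks)) {
    for (part in c("a", "b", "proj")) {
      if (!is.null(model$encoder$blocks[[i]][[part]]))
        model$encoder$blocks[[i]][[part]][c("w", "b")] <-
          tree$encoder$blocks[[i]][[part]][c("w", "b")]
    }
  }
  model$fc <- tree$fc
  model$head <- tree$head
  model
}

#' Number of trainable parameters
#'
#' @param model an \code{hcnn} model.
#' @return integer count; the lorentz variant of a config exceeds its
#'   euclidean twin by exactly 1 (the curvature scalar).
#' @export
param_count <- function(model) {
  sum(vapply(tree_flatten(param_tree(model)), length, 1L))
}

#' Euclidean classification head
#'
#' Affine map \eqn{W z + b} applied row-wise.
#'
#' @param z embedding matrix (batch x embedding_dim).
#' @param head list with \code{W} (n_classes x dim) and \code{b}.
#' @return logits matrix (batch x n_classes).
#' @export
euclidean_logits <- function(z, head) {
  if (ncol(z) != ncol(head$W)) stopf("embedding dim %d != head dim %d",
                                     ncol(z), ncol(head$W))
  z %*% t(head$W) + matrix(head$b, nrow(z), length(head$b), byrow = TRUE)
}

# Lorentz multinomial-logistic head.
# Per class j: direction z_j in R^d, offset a_j. With s = sqrt(k), the
# hyperplane normal is v_j = (sinh(s a_j)||z_j||, cosh(s a_j) z_j), which is
# spacelike with ||v_j||_L = ||z_j||; the logit is the norm-scaled signed
# geodesic distance of the embedded point x to the hyperplane:
#   logit_j = (||z_j|| / s) * asinh( s * alpha_j / ||z_j|| ),
#   alpha_j = cosh(s a_j) <z_j, x_space> - sinh(s a_j) ||z_j|| x_time.
lorentz_head_forward <- function(E, head, clip_radius, keep_cache = FALSE) {
  k <- exp(head$logk); s <- sqrt(k); r <- clip_radius
  n <- sqrt(rowSums(E * E))
  clip_scale <- ifelse(n > r, r / pmax(n, .Machine$double.xmin), 1)
  Cm <- E * clip_scale                       # clipped tangent features
  mm <- n * clip_scale                       # ||c||
  t <- s * mm
  xt <- cosh(t) / s                          # time coordinate
  g <- sinhc(t)                              # x_space = Cm * g
  Xs <- Cm * g
  u <- sqrt(rowSums(head$Z^2))               # per-class ||z_j||
  u <- pmax(u, 1e-12)
  ca <- cosh(s * head$a); sa <- sinh(s * head$a)
  A <- (Xs %*% t(head$Z)) * rep(ca, each = nrow(E)) -
    outer(xt, u * sa)                        # alpha, batch x C
  Q <- sweep(A * s, 2L, u, "/")              # q = s*alpha/u
  L <- sweep(asinh(Q), 2L, u / s, "*")
  if (!all(is.finite(L)))
    stopf("lorentz head produced non-finite logits (k = %g)", k)
  if (!keep_cache) return(list(logits = L))
  list(logits = L,
       cache = list(E = E, n = n, clip_scale = clip_scale, Cm = Cm, mm = mm,
                    t = t, xt = xt, g = g, Xs = Xs, u = u, ca = ca, sa = sa,
                    A = A, Q = Q, s = s, k = k, r = r))
}

# d sinhc / dt
dsinhc <- function(t) ifelse(abs(t) < 1e-4, t / 3, (cosh(t) * t - sinh(t)) / t^2)

lorentz_head_backward <- function(dL, head, cache) {
  with(cache, {
    B <- nrow(dL)
    sq <- sqrt(1 + Q^2)
    # dL/dalpha (through asinh only): (u/s)*(1/sq)*(s/u) = 1/sq
    dA <- dL / sq
    # head direction gradients: L = (u/s) asinh(s A / u); through u as well
    # dL/du_j = (1/s) asinh(q) - (A/u)/sq
    dL_du <- colSums(dL * (asinh(Q) / s - sweep(A, 2L, u, "/") / sq))
    # dA/dz_j = ca_j * Xs_row - sa_j * xt * z_j/u_j  (per sample, summed)
    dZ <- t(dA * rep(ca, each = B)) %*% Xs -
      (head$Z / u) * (colSums(dA * outer(xt, rep(1, length(u)))) * sa)
    dZ <- dZ + (head$Z / u) * dL_du
    # dA/da_j = s*( sa_j <z_j, Xs> - ca_j u_j xt )
    ZXs <- Xs %*% t(head$Z)                  # batch x C of <z_j, x_space>
    da <- colSums(dA * (sweep(ZXs, 2L, s * sa, "*") - outer(xt, s * ca * u)))
    # gradients to the embedded point
    dXs <- (dA * rep(ca, each = B)) %*% head$Z
    dxt <- -as.vector(dA %*% (u * sa))
    # back through expmap0: Xs = Cm*g(mm), xt = cosh(s mm)/s
    # d xt/d Cm = sinh(s mm) * Cm/mm ; d g/d Cm = g'(t)*s*Cm/mm
    gp <- dsinhc(t)                          # dg/dt
    dot_dXs_Cm <- rowSums(dXs * Cm)
    safe_mm <- pmax(mm, .Machine$double.xmin)
    dCm <- dXs * g +
      Cm * ((dot_dXs_Cm * gp * s + dxt * sinh(t)) / safe_mm)
    # back through clipping: Cm = E * clip_scale
    # unclipped rows: identity; clipped rows: c = r*E/n, Jacobian (r/n)(I - ee^T/n^2)
    dE <- dCm * clip_scale
    clipped <- clip_scale < 1
    if (any(clipped)) {
      dot <- rowSums(dCm * E)
      dE[clipped, ] <- dE[clipped, , drop = FALSE] -
        (E * (clip_scale * dot / n^2))[clipped, , drop = FALSE]
    }
    # curvature gradient via s (k = s^2, dk->dlogk = k, ds/dlogk = s/2)
    # L depends on s explicitly, through t = s*mm (xt, g), and through ca/sa.
    dL_ds_alpha_fixed <- sum(dL * (-asinh(Q) * rep(u, each = B) / s^2 +
                                     A / (s * sq)))
    dxt_ds <- mm * sinh(t) / s - cosh(t) / s^2
    dXs_ds <- Cm * (gp * mm)
    # alpha's explicit s-dependence through ca/sa:
    dA_ds_head <- sweep(ZXs, 2L, head$a * sa, "*") - outer(xt, u * head$a * ca)
    ds_total <- dL_ds_alpha_fixed +
      sum(dA * dA_ds_head) +
      sum(dXs * dXs_ds) + sum(dxt * dxt_ds)
    dlogk <- ds_total * s / 2
    list(dE = dE, dhead = list(Z = dZ, a = da, logk = dlogk))
  })
}

#' Lorentz head logits
#'
#' Clips the embeddings to the configured radius, exp-maps them onto the
#' hyperboloid of curvature \code{exp(head$logk)}, and scores each class by
#' the norm-scaled signed geodesic distance to that class's learnable
#' hyperbolic hyperplane (Lorentz multinomial logistic regression).
#'
#' @param z embedding matrix (batch x embedding_dim).
#' @param head list with \code{Z} (n_classes x dim directions), \code{a}
#'   (offsets) and \code{logk} (log-curvature).
#' @param m a \code{\link{lorentz_manifold}} supplying the clip radius (its
#'   \code{k} is ignored in favour of the head's learnable curvature unless
#'   the head lacks one).
#' @return logits matrix (batch x n_classes).
#' @export
lorentz_logits <- function(z, head, m) {
  if (ncol(z) != ncol(head$Z)) stopf("embedding dim %d != head dim %d",
                                     ncol(z), ncol(head$Z))
  if (is.null(head$logk)) head$logk <- log(m$k)
  lorentz_head_forward(z, head, m$clip_radius)$logits
}

# full forward pass; x already normalized, layout [H,W,C,N]
forward_pass <- function(model, x, keep_cache = FALSE) {
  ef <- encoder_forward(model$encoder, x, keep_cache)
  hdim <- dim(ef$out)
  G <- gap_forward(ef$out)                    # N x C_feat
  E <- G %*% model$fc$w + matrix(model$fc$b, nrow(G), length(model$fc$b), byrow = TRUE)
  if (model$geometry == "euclidean") {
    logits <- euclidean_logits(E, model$head)
    hc <- NULL
  } else {
    hf <- lorentz_head_forward(E, model$head, model$config$clip_radius, keep_cache)
    logits <- hf$logits
    hc <- hf$cache
  }
  out <- list(embeddings = E, logits = logits)
  if (keep_cache) out$cache <- list(enc = ef$cache, hdim = hdim, G = G, head = hc)
  out
}

# dlogits: batch x C gradient; returns list(grads, dx)
backward_pass <- function(model, fp, dlogits, need_dx = FALSE) {
  cache <- fp$cache
  if (model$geometry == "euclidean") {
    dhead <- list(W = t(dlogits) %*% fp$embeddings, b = colSums(dlogits))
    dE <- dlogits %*% model$head$W
  } else {
    hb <- lorentz_head_backward(dlogits, model$head, cache$head)
    dhead <- hb$dhead
    dE <- hb$dE
  }
  dfc <- list(w = t(cache$G) %*% dE, b = colSums(dE))
  dG <- dE %*% t(model$fc$w)
  dh <- gap_backward(dG, cache$hdim)
  eb <- encoder_backward(model$encoder, cache$enc, dh, need_dx)
  list(grads = list(encoder = eb$grads, fc = dfc, head = dhead),
       dx = eb$dx)
}

#' Penultimate embeddings for a batch of images
#'
#' Returns the pre-clipping Euclidean encoder outputs (the penultimate
#' n-dimensional features before the classification head), for either
#' geometry. Deterministic in evaluation mode.
#'
#' @param model an \code{hcnn} model.
#' @param x image array \code{[H, W, N]} or \code{[H, W, C, N]} in raw pixel
#'   units; the model's stored normalization is applied.
#' @return matrix (batch x embedding_dim).
#' @export
forward_embeddings <- function(model, x) {
  x <- as_image_batch(x, model$config)
  x <- (x - model$norm$mean) / model$norm$sd
  forward_pass(model, x)$embeddings
}

as_image_batch <- function(x, config) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stopf("images must be an [H,W,N] or [H,W,C,N] array")
  if (length(d) == 3L) {
    dim(x) <- c(d[1L], d[2L], 1L, d[3L])
    d <- dim(x)
  }
  if (d[1L] != config$image_size || d[2L] != config$image_size ||
      d[3L] != config$in_channels)
    stopf("image batch is %dx%dx%d but the model expects %dx%dx%d",
          d[1L], d[2L], d[3L], config$image_size, config$image_size,
          config$in_channels)
  x
}
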