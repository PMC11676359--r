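test_that("lorentz and euclidean twins share encoder init and differ by one parameter", {
  for (scale in c("tiny", "resnet18")) {
    for (n_cls in c(4L, 6L)) {
      ce <- model_config("euclidean", n_classes = n_cls, encoder_scale = scale)
      cl <- model_config("lorentz", n_classes = n_cls, encoder_scale = scale)
      me <- build_model(ce, seed = 21)
      ml <- build_model(cl, seed = 21)
      expect_identical(me$encoder, ml$encoder)   # bitwise-shared initialization
      expect_identical(me$fc, ml$fc)
      expect_equal(param_count(ml) - param_count(me), 1L)
    }
  }
})

test_that("tiny encoder parameter count matches a layer-by-layer audit", {
  mdl <- build_model(tiny_config("euclidean", n_classes = 6L, dim = 6L), seed = 1)
  # stem 3x3 1->16 (+16), block1 16->16 (two 3x3 convs), block2 16->32
  # stride 2 (two 3x3 convs + 1x1 projection), fc 32->6, head 6x6+6
  stem <- 3 * 3 * 1 * 16 + 16
  b1 <- 2 * (3 * 3 * 16 * 16 + 16)
  b2 <- (3 * 3 * 16 * 32 + 32) + (3 * 3 * 32 * 32 + 32) + (1 * 1 * 16 * 32 + 32)
  fc <- 32 * 6 + 6
  head <- 6 * 6 + 6
  expect_equal(param_count(mdl), stem + b1 + b2 + fc + head)
})

test_that("forward embeddings are deterministic with the expected shape", {
  mdl <- build_model(tiny_config(), seed = 2)
  one <- tiny_batch(1)
  four <- array(rep(one, 4), dim = c(8, 8, 1, 4))
  E <- forward_embeddings(mdl, four)
  expect_equal(dim(E), c(4L, 5L))
  expect_equal(E[1, ], E[3, ])                       # identical inputs
  expect_identical(E, forward_embeddings(mdl, four)) # bitwise repeatable
  expect_error(forward_embeddings(mdl, tiny_batch(2, size = 16)), "expects")
})

test_that("euclidean logits equal an independent affine oracle", {
  mdl <- build_model(tiny_config("euclidean"), seed = 3)
  z <- matrix(rnorm(6 * 5), 6, 5)
  L <- euclidean_logits(z, mdl$head)
  oracle <- matrix(0, 6, 4)
  for (i in 1:6) for (j in 1:4)
    oracle[i, j] <- sum(mdl$head$W[j, ] * z[i, ]) + mdl$head$b[j]
  expect_equal(L, oracle, tolerance = 1e-12)
  expect_equal(euclidean_logits(matrix(0, 2, 5), list(W = mdl$head$W, b = rep(0, 4))),
               matrix(0, 2, 4))
})

test_that("lorentz logits behave as signed distances to per-class hyperplanes", {
  mdl <- build_model(tiny_config("lorentz"), seed = 4)
  m <- lorentz_manifold(exp(mdl$head$logk), mdl$config$clip_radius)
  # zero embeddings: every row identical (depends on head parameters only)
  L0 <- lorentz_logits(matrix(0, 3, 5), mdl$head, m)
  expect_equal(L0[1, ], L0[2, ])
  expect_equal(L0[2, ], L0[3, ])
  # finite under extreme inputs thanks to clipping
  z <- matrix(runif(8 * 5, -1e4, 1e4), 8, 5)
  expect_true(all(is.finite(lorentz_logits(z, mdl$head, m))))
  # perturbing one class's offset changes only that class's logit column
  z2 <- matrix(rnorm(6 * 5), 6, 5)
  L1 <- lorentz_logits(z2, mdl$head, m)
  head2 <- mdl$head; head2$a[3] <- head2$a[3] * 2 + 0.5
  L2 <- lorentz_logits(z2, head2, m)
  expect_equal(L1[, -3], L2[, -3], tolerance = 1e-12)
  expect_gt(max(abs(L1[, 3] - L2[, 3])), 1e-6)
})

test_that("both heads are permutation-equivariant in the class index", {
  perm <- c(3, 1, 4, 2)
  z <- matrix(rnorm(5 * 5), 5, 5)
  me <- build_model(tiny_config("euclidean"), seed = 6)
  he <- me$head
  he_p <- list(W = he$W[perm, ], b = he$b[perm])
  expect_equal(euclidean_logits(z, he_p), euclidean_logits(z, he)[, perm])
  ml <- build_model(tiny_config("lorentz"), seed = 6)
  m <- lorentz_manifold(exp(ml$head$logk), ml$config$clip_radius)
  hl <- ml$head
  hl_p <- list(Z = hl$Z[perm, ], a = hl$a[perm], logk = hl$logk)
  expect_equal(lorentz_logits(z, hl_p, m), lorentz_logits(z, hl, m)[, perm])
})

test_that("analytic gradients match finite differences for both geometries", {
  set.seed(31)
  xb <- array(runif(8 * 8 * 1 * 5) * 3, c(8, 8, 1, 5))  # mixes clipped rows
  yb <- c(1L, 2L, 3L, 4L, 2L)
  h <- 1e-5
  for (geom in c("euclidean", "lorentz")) {
    mdl <- build_model(tiny_config(geom, k_init = 1.7), seed = 7)
    fp <- lorentznet:::forward_pass(mdl, xb, keep_cache = TRUE)
    l <- lorentznet:::ce_loss(fp$logits, yb)
    bp <- lorentznet:::backward_pass(mdl, fp, l$dlogits, need_dx = TRUE)
    lossfun <- function(m)
      lorentznet:::ce_loss(lorentznet:::forward_pass(m, xb)$logits, yb)$loss
    fd_vs <- function(set, get, n_probe = 4L) {
      for (i in sample(length(get(mdl)), n_probe)) {
        mp <- set(mdl, i, h); mm <- set(mdl, i, -h)
        fd <- (lossfun(mp) - lossfun(mm)) / (2 * h)
        expect_equal(fd, get(bp$grads)[i], tolerance = 1e-4)
      }
    }
    fd_vs(function(m, i, d) { m$head[[1]][i] <- m$head[[1]][i] + d; m },
          function(o) o$head[[1]])
    fd_vs(function(m, i, d) { m$fc$w[i] <- m$fc$w[i] + d; m },
          function(o) o$fc$w)
    fd_vs(function(m, i, d) { m$encoder$stem$w[i] <- m$encoder$stem$w[i] + d; m },
          function(o) o$encoder$stem$w)
    if (geom == "lorentz") {
      fd_vs(function(m, i, d) { m$head$a[i] <- m$head$a[i] + d; m },
            function(o) o$head$a)
      fd_vs(function(m, i, d) { m$head$logk <- m$head$logk + d; m },
            function(o) o$head$logk, n_probe = 1L)
    }
    # input gradient (drives the adversarial attack)
    for (i in sample(length(xb), 5)) {
      xp <- xb; xp[i] <- xp[i] + h; xm <- xb; xm[i] <- xm[i] - h
      fd <- (lossfun2 <- function(x) lorentznet:::ce_loss(
        lorentznet:::forward_pass(mdl, x)$logits, yb)$loss)(xp) - lossfun2(xm)
      expect_equal(fd / (2 * h), bp$dx[i], tolerance = 1e-4)
    }
  }
})
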