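test_that("lorentz inner product matches a sign-flipped dot-product oracle", {
  expect_equal(lorentz_inner(c(1, 0, 0), c(1, 0, 0)), -1)
  expect_equal(lorentz_inner(c(0, 1, 0), c(0, 0, 1)), 0)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(4); y <- rnorm(4)
    oracle <- sum(c(-1, 1, 1, 1) * x * y)
    expect_equal(lorentz_inner(x, y), oracle, tolerance = 1e-12)
  }
  expect_error(lorentz_inner(1:3, 1:4), "lengths differ")
})

test_that("feature clipping bounds the norm and preserves direction", {
  v <- c(1.2, -1.6)                     # norm 2
  expect_equal(clip_features(v, 1), v / 2)
  v2 <- c(0.3, 0.4)                     # norm 0.5, inside the ball
  expect_identical(clip_features(v2, 1), v2)
  expect_identical(clip_features(c(0, 0), 1), c(0, 0))
  set.seed(2)
  V <- matrix(rnorm(1000 * 6, sd = 4), ncol = 6)
  W <- clip_features(V, 1)
  expect_lte(max(sqrt(rowSums(W^2))), 1 + 1e-12)
  # directions untouched
  i <- which(sqrt(rowSums(V^2)) > 1)[1:50]
  cs <- rowSums(V[i, ] * W[i, ]) / (sqrt(rowSums(V[i, ]^2)) * sqrt(rowSums(W[i, ]^2)))
  expect_equal(cs, rep(1, 50), tolerance = 1e-12)
})

test_that("expmap0 lands on the hyperboloid and is a radial isometry", {
  for (k in c(0.1, 0.5, 1, 2, 10)) {
    m <- lorentz_manifold(k)
    o <- lorentz_origin(m, 3)
    expect_equal(lorentz_inner(o, o), -1 / k, tolerance = 1e-9)
    expect_equal(expmap0(c(0, 0, 0), m), o)
    set.seed(7)
    V <- random_tangent(50, 3, max_norm = 15)
    X <- expmap0(V, m)
    expect_lt(max(lorentznet:::manifold_residual(X, m)), 1e-6)
    d <- geodesic_distance(X, lorentznet:::sweep_origin(m, 3, 50), m)
    expect_equal(d, sqrt(rowSums(V^2)), tolerance = 1e-6)
  }
  # spot value: ||(0.3, -0.7)|| at k = 2
  m2 <- lorentz_manifold(2)
  x <- expmap0(c(0.3, -0.7), m2)
  expect_equal(geodesic_distance(x, lorentz_origin(m2, 2), m2),
               sqrt(0.3^2 + 0.7^2), tolerance = 1e-9)
  expect_error(expmap0(c(1, NA), m2), "non-finite")
})

test_that("logmap0 and expmap0 are mutual inverses", {
  for (k in c(0.5, 1, 2)) {
    m <- lorentz_manifold(k)
    set.seed(11)
    V <- random_tangent(100, 4, max_norm = 10)
    back <- logmap0(expmap0(V, m), m)
    expect_lt(max(abs(back - V)), 1e-5)
    # reverse round trip on on-manifold points
    X <- expmap0(random_tangent(50, 4, max_norm = 5), m)
    X2 <- expmap0(logmap0(X, m), m)
    expect_lt(max(abs(X2 - X) / pmax(1, abs(X))), 1e-5)
  }
  m <- lorentz_manifold(1)
  expect_equal(logmap0(lorentz_origin(m, 3), m), c(0, 0, 0))
  expect_error(logmap0(c(5, 0, 0), m), "off the hyperboloid")
})

test_that("geodesic distance is a metric on random triples", {
  m <- lorentz_manifold(1.5)
  set.seed(13)
  X <- expmap0(random_tangent(300, 3, max_norm = 6), m)
  i <- sample(300, 200, TRUE); j <- sample(300, 200, TRUE); l <- sample(300, 200, TRUE)
  dij <- geodesic_distance(X[i, ], X[j, ], m, check = FALSE)
  dil <- geodesic_distance(X[i, ], X[l, ], m, check = FALSE)
  dlj <- geodesic_distance(X[l, ], X[j, ], m, check = FALSE)
  expect_true(all(dij >= 0))
  expect_lte(max(dij - (dil + dlj)), 1e-9)                       # triangle
  expect_equal(dij, geodesic_distance(X[j, ], X[i, ], m, check = FALSE))
  expect_equal(geodesic_distance(X[1, ], X[1, ], m), 0)
})

test_that("projection restores the hyperboloid constraint", {
  m <- lorentz_manifold(1)
  x <- project_to_hyperboloid(c(999, 0.3, 0.4), m)
  expect_equal(x[1], sqrt(1.25), tolerance = 1e-12)
  ok <- expmap0(c(0.5, -0.2), m)
  expect_equal(project_to_hyperboloid(ok, m), ok, tolerance = 1e-12)
  set.seed(17)
  X <- expmap0(random_tangent(100, 3, max_norm = 4), m)
  Xp <- project_to_hyperboloid(X + matrix(rnorm(400, sd = 0.05), 100, 4), m)
  expect_lt(max(lorentznet:::manifold_residual(Xp, m)), 1e-9)
})

test_that("riemannian step stays on the manifold and descends", {
  m <- lorentz_manifold(2)
  target <- expmap0(c(0.4, -0.3, 0.8), m)
  x <- lorentz_origin(m, 3)
  # gradient of 0.5*d(x,target)^2 pulled back as a Euclidean gradient via FD
  fd_grad <- function(x) {
    f <- function(p) 0.5 * geodesic_distance(project_to_hyperboloid(p, m), target, m)^2
    vapply(seq_along(x), function(i) {
      h <- 1e-6; xp <- x; xp[i] <- xp[i] + h; xm <- x; xm[i] <- xm[i] - h
      (f(xp) - f(xm)) / (2 * h)
    }, 1.0)
  }
  d0 <- geodesic_distance(x, target, m)
  for (it in 1:40) x <- riemannian_step(x, fd_grad(x), 0.3, m)
  expect_lt(max(lorentznet:::manifold_residual(x, m)), 1e-9)
  expect_lt(geodesic_distance(x, target, m), 0.01 * d0)
})
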