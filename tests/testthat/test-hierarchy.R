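test_that("class centroids equal a group-by-mean oracle", {
  set.seed(51)
  E <- matrix(rnorm(30 * 4), 30, 4)
  lab <- sample(1:3, 30, TRUE)
  cen <- class_centroids(E, lab)
  oracle <- t(sapply(1:3, function(cl) colMeans(E[lab == cl, , drop = FALSE])))
  expect_equal(cen, oracle, tolerance = 1e-12)
  expect_equal(class_centroids(matrix(1:4, 2, 2, byrow = TRUE), c(1L, 2L)),
               matrix(1:4, 2, 2, byrow = TRUE))       # one sample per class
  expect_equal(class_centroids(rbind(c(1, 2), c(-1, -2)), c(1L, 1L)),
               matrix(0, 1, 2))                       # symmetric pair
  expect_error(class_centroids(E, lab, n_classes = 5L), "class\\(es\\): 4, 5")
})

test_that("model distance matrices match scalar oracles in both geometries", {
  cen <- matrix(c(0, 1, 3), ncol = 1)
  cen2 <- cbind(cen, 0)
  De <- model_distance_matrix(cen2, "euclidean")
  expect_equal(De[1, 2], 1); expect_equal(De[2, 3], 2); expect_equal(De[1, 3], 3)
  expect_symmetric_zero_diag(De)
  m <- lorentz_manifold(1.7)
  set.seed(52)
  cenL <- matrix(rnorm(5 * 3, sd = 0.5), 5, 3)
  Dl <- model_distance_matrix(cenL, "lorentz", m)
  X <- expmap0(cenL, m)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(Dl[i, j], geodesic_distance(X[i, ], X[j, ], m), tolerance = 1e-9)
  expect_symmetric_zero_diag(Dl)
  expect_equal(max(model_distance_matrix(matrix(1, 3, 2), "euclidean")), 0)
  expect_error(model_distance_matrix(cenL, "lorentz"), "requires a lorentz_manifold")
})

test_that("ground-truth matrix equals weighted descriptor-mismatch enumeration", {
  desc <- data.frame(class_id = paste0("c", 1:6),
                     modality = c("MRI", "MRI", "MRI", "CT", "CT", "CT"),
                     disease = c("a", "a", "b", "c", "d", "d"),
                     subtype = c("a1", "a2", "b1", "c1", "d1", "d2"))
  w <- c(4, 2, 1)
  D <- ground_truth_matrix(desc, w)
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    oracle[i, j] <- 4 * (desc$modality[i] != desc$modality[j]) +
      2 * (desc$disease[i] != desc$disease[j]) +
      1 * (desc$subtype[i] != desc$subtype[j])
  expect_equal(unclass(D), oracle, ignore_attr = TRUE)
  expect_equal(D[1, 2], 1)   # same modality/disease, different subtype
  expect_equal(D[1, 1], 0)
  expect_error(ground_truth_matrix(rbind(desc, desc[1, ]), w), "duplicate")
  expect_error(ground_truth_matrix(desc, c(0, 0, 0)), "not all zero")
})

test_that("normalization scales the max off-diagonal to one and is idempotent", {
  D <- lorentznet:::new_distance_matrix(matrix(c(0, 2, 4, 2, 0, 2, 4, 2, 0), 3), "x")
  N1 <- normalize_matrix(D)
  expect_equal(max(N1[row(N1) != col(N1)]), 1)
  expect_equal(N1[1, 2], 0.5)
  expect_equal(unclass(normalize_matrix(N1)), unclass(N1))
  expect_error(normalize_matrix(lorentznet:::new_distance_matrix(matrix(0, 2, 2), "x")),
               "degenerate")
})

test_that("mean absolute difference matches hand enumeration with a sane bootstrap", {
  Dm <- lorentznet:::new_distance_matrix(
    matrix(c(0, 0.2, 1, 0.2, 0, 0.6, 1, 0.6, 0), 3), "m")
  Dg <- lorentznet:::new_distance_matrix(
    matrix(c(0, 0.5, 1, 0.5, 0, 0.25, 1, 0.25, 0), 3), "g")
  r <- mean_absolute_difference(Dm, Dg, n_boot = 500, seed = 9)
  expect_equal(r$mad, mean(c(abs(0.2 - 0.5), abs(1 - 1), abs(0.6 - 0.25))))
  expect_lte(r$ci[1], r$mad); expect_gte(r$ci[2], r$mad)
  expect_equal(mean_absolute_difference(Dg, Dg, n_boot = 10)$mad, 0)
  # identical seeds give identical intervals
  r2 <- mean_absolute_difference(Dm, Dg, n_boot = 500, seed = 9)
  expect_identical(r$ci, r2$ci)
})

test_that("spearman alignment matches the rank-formula oracle and is label-invariant", {
  set.seed(53)
  D5 <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  G5 <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  sp <- spearman_alignment(D5, G5)
  a <- D5[upper.tri(D5)]; b <- G5[upper.tri(G5)]
  d <- rank(a) - rank(b); n <- length(a)
  expect_equal(sp$rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)), tolerance = 1e-12)
  expect_equal(spearman_alignment(G5, G5)$rho, 1)
  expect_equal(spearman_alignment(max(G5) - G5 + diag(max(G5), 5), G5)$rho, -1)
  # permuting class order leaves rho unchanged
  p <- c(3, 5, 1, 4, 2)
  expect_equal(spearman_alignment(D5[p, p], G5[p, p])$rho, sp$rho)
  expect_error(spearman_alignment(matrix(1, 3, 3) - diag(3), G5[1:3, 1:3]),
               "constant")
})

test_that("the model-comparison t-test is a Welch test with expected symmetries", {
  set.seed(54)
  a <- rnorm(50, 0.1, 0.01); b <- rnorm(50, 0.3, 0.01)
  r <- compare_models_ttest(a, b)
  expect_lt(r$p, 1e-4)
  oracle <- t.test(a, b)
  expect_equal(r$t, unname(oracle$statistic))
  flipped <- compare_models_ttest(b, a)
  expect_equal(flipped$t, -r$t)
  expect_equal(flipped$p, r$p)
  same <- compare_models_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("dendrograms merge tight pairs first with monotone heights", {
  cen <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  hc <- embedding_dendrogram(cen, "euclidean")
  expect_equal(nrow(hc$merge), 2L)
  expect_equal(sort(hc$merge[1, ]), c(-2L, -1L))    # tight pair merges first
  set.seed(55)
  cen2 <- matrix(rnorm(16), 8, 2)
  hc2 <- embedding_dendrogram(cen2, "euclidean")
  expect_equal(nrow(hc2$merge), 7L)
  expect_true(all(diff(hc2$height) >= -1e-12))
})
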