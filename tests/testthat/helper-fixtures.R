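# Shared fixtures: tiny models and datasets, built in code at test time.

tiny_config <- function(geometry = "lorentz", n_classes = 4L, dim = 5L,
                        image_size = 8L, ...) {
  model_config(geometry, n_classes = n_classes, embedding_dim = dim,
               image_size = image_size, ...)
}

tiny_batch <- function(n = 6L, size = 8L, seed = 3L, scale = 1) {
  set.seed(seed)
  array(runif(size * size * n) * scale, dim = c(size, size, 1L, n))
}

# a quickly-trainable 4-class dataset (used by training/robustness tests)
quick_dataset <- function(seed = 5L, n_per_class = 30L) {
  tax <- build_taxonomy(c(2, 2))
  generate_dataset(tax, synthetic_spec(image_size = 16L, n_per_class = n_per_class),
                   seed = seed)
}

# train a small model once per session and reuse it across tests
quick_model_env <- new.env(parent = emptyenv())
quick_model <- function(geometry = "lorentz") {
  key <- paste0("m_", geometry)
  if (is.null(quick_model_env[[key]])) {
    ds <- quick_dataset()
    tr <- dataset_split(ds, "train")
    cfg <- model_config(geometry, n_classes = 4L, image_size = 16L)
    quick_model_env[[key]] <- hcnn(tr$images, tr$labels, config = cfg,
                                   control = train_config(epochs = 6L),
                                   seed = 5L)
  }
  quick_model_env[[key]]
}

expect_symmetric_zero_diag <- function(D, tol = 1e-9) {
  expect_lt(max(abs(D - t(D))), tol)
  expect_lt(max(abs(diag(D))), tol)
}

random_tangent <- function(n, d, max_norm = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(n * d), n, d)
  v * (runif(n) * max_norm / sqrt(rowSums(v * v)))
}
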