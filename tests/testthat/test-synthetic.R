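test_that("taxonomy construction: leaf counts, unique descriptors, sibling structure", {
  tax <- build_taxonomy(c(2, 3, 2))
  expect_equal(tax$n_classes, 12L)
  desc <- taxonomy_ground_truth_labels(tax)
  expect_equal(dim(desc), c(12L, 4L))  # class_id + 3 levels
  expect_false(anyDuplicated(desc[, -1]) > 0)
  # siblings (consecutive leaves under one disease node) differ only at the
  # last level
  expect_equal(desc$modality[1], desc$modality[2])
  expect_equal(desc$category[1], desc$category[2])
  expect_false(desc$disease[1] == desc$disease[2])
  flat <- build_taxonomy(42)
  expect_equal(flat$n_classes, 42L)
  expect_equal(length(flat$levels), 1L)
  expect_error(build_taxonomy(integer(0)), "non-empty")
})

test_that("generated images carry the taxonomy's correlation structure", {
  tax <- build_taxonomy(c(2, 2))
  ds <- generate_dataset(tax, synthetic_spec(image_size = 16L, n_per_class = 20L),
                         seed = 3)
  expect_equal(dim(ds$images), c(16L, 16L, 80L))
  expect_true(all(ds$images >= 0 & ds$images <= 1))
  # noise_sd -> 0 limit: images within a class identical
  ds0 <- generate_dataset(tax, synthetic_spec(image_size = 16L, n_per_class = 3L,
                                              noise_sd = 1e-9), seed = 3)
  expect_equal(ds0$images[, , 1], ds0$images[, , 2], tolerance = 1e-6)
  # within-class pixel correlation beats between-class correlation
  flat <- t(matrix(ds$images, 16 * 16))
  cm <- cor(t(flat))
  same <- outer(ds$labels, ds$labels, "==") & upper.tri(cm)
  diff <- outer(ds$labels, ds$labels, "!=") & upper.tri(cm)
  expect_gt(mean(cm[same]), mean(cm[diff]))
  # sibling prototypes more alike than cross-branch prototypes
  p <- sapply(ds$prototypes, c)
  pc <- cor(p)
  expect_gt(pc[1, 2], pc[1, 3])  # classes 1,2 share the modality; 3 does not
  expect_gt(pc[1, 2], pc[1, 4])
})

test_that("dataset generation is seed-reproducible with stratified splits", {
  tax <- build_taxonomy(c(2, 2))
  spec <- synthetic_spec(image_size = 16L, n_per_class = 20L)
  d1 <- generate_dataset(tax, spec, seed = 10)
  d2 <- generate_dataset(tax, spec, seed = 10)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$manifest, d2$manifest)
  s <- summarize_manifest(d1$manifest)
  expect_equal(unname(as.vector(s$per_split)), c(64L, 8L, 8L))
  expect_true(all(table(d1$manifest$split, d1$manifest$class_id)["val", ] == 2))
})

test_that("patient cohorts honor positivity rules and reproduce under a seed", {
  tax <- build_taxonomy(c(2, 2))
  spec <- synthetic_spec(image_size = 16L)
  none <- generate_patient_cohort(5L, 4L, positive_fraction = 0, tax, spec, seed = 2)
  expect_true(all(!vapply(none, `[[`, TRUE, "patient_positive")))
  expect_true(all(!unlist(lapply(none, `[[`, "slice_positive"))))
  co <- generate_patient_cohort(20L, 6L, positive_fraction = 0.5, tax, spec, seed = 2)
  expect_length(co, 20L)
  pos <- vapply(co, `[[`, TRUE, "patient_positive")
  expect_equal(sum(pos), 10L)
  for (s in co)  # patient truth is the OR of slice truths
    expect_identical(s$patient_positive, any(s$slice_positive))
  expect_true(all(vapply(co[pos], function(s) sum(s$slice_positive) >= 1L, TRUE)))
  co2 <- generate_patient_cohort(20L, 6L, positive_fraction = 0.5, tax, spec, seed = 2)
  expect_identical(lapply(co, `[[`, "images"), lapply(co2, `[[`, "images"))
})

test_that("outcome cohort bookkeeping matches the requested composition", {
  coh <- generate_outcome_cohort(436L, 40L, seed = 4)
  expect_equal(nrow(coh), 436L)
  expect_equal(sum(coh$positive), 40L)
  expect_equal(sum(!coh$positive), 396L)
})

test_that("descriptor tables and PNG datasets survive a write/read round trip", {
  tax <- build_taxonomy(c(2, 2))
  desc <- taxonomy_ground_truth_labels(tax)
  f <- tempfile(fileext = ".csv")
  write.csv(desc, f, row.names = FALSE)
  expect_identical(read.csv(f, stringsAsFactors = FALSE), desc)
  ds <- generate_dataset(tax, synthetic_spec(image_size = 8L, n_per_class = 3L),
                         seed = 5)
  dir <- tempfile()
  write_dataset(ds, dir)
  m <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 12L)
  imgs <- read_images(m, dir)
  # PNG is 8/16-bit quantized; round trip is near-exact
  expect_lt(max(abs(imgs - ds$images)), 1 / 255)
  unlink(dir, recursive = TRUE)
})
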