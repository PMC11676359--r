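#' Build a balanced class taxonomy
#'
#' Constructs the tree of categorical class descriptors that the synthetic
#' generator shares with the ground-truth distance matrix: each taxonomy
#' level (e.g. modality, disease category, disease, subtype) splits every
#' node into a fixed number of children, and each leaf is one image class
#' carrying one categorical value per level.
#'
#' @param branching integer vector: number of children per node at each
#'   level; the leaf count is \code{prod(branching)}.
#' @param levels optional character vector of level names (defaults to
#'   modality/category/disease/subtype truncated or extended to match).
#' @return an object of class \code{class_taxonomy} with a descriptor table
#'   (one row per leaf, one column per level) and unique class ids.
#' @export
build_taxonomy <- function(branching, levels = NULL) {
  branching <- as.integer(branching)
  if (length(branching) == 0L) stopf("branching must be non-empty")
  if (any(branching < 1L)) stopf("branching entries must be >= 1")
  L <- length(branching)
  if (is.null(levels)) {
    base <- c("modality", "category", "disease", "subtype")
    levels <- if (L <= 4L) base[seq_len(L)] else
      c(base, paste0("level", 5:L))[seq_len(L)]
  }
  if (length(levels) != L) stopf("levels must name each branching entry")
  grid <- expand.grid(rev(lapply(branching, seq_len)), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(L)), drop = FALSE]   # level 1 varies slowest
  desc <- as.data.frame(lapply(seq_len(L), function(l) {
    # descriptor value = path prefix up to this level, a stable string
    apply(grid[, seq_len(l), drop = FALSE], 1L, function(p)
      paste0(levels[l], "_", paste(p, collapse = ".")))
  }), stringsAsFactors = FALSE)
  names(desc) <- levels
  n_leaves <- prod(branching)
  desc <- cbind(class_id = sprintf("class_%02d", seq_len(n_leaves)), desc,
                stringsAsFactors = FALSE)
  structure(list(levels = levels, branching = branching, descriptors = desc,
                 n_classes = n_leaves),
            class = "class_taxonomy")
}

#' @export
print.class_taxonomy <- function(x, ...) {
  cat(sprintf("class taxonomy: %d levels (%s), branching %s, %d leaf classes\n",
              length(x$levels), paste(x$levels, collapse = "/"),
              paste(x$branching, collapse = "x"), x$n_classes))
  invisible(x)
}

#' Descriptor table of a taxonomy
#'
#' One row per class with its categorical value at every level; the input to
#' \code{\link{ground_truth_matrix}}.
#' @param tax a \code{\link{build_taxonomy}} result.
#' @export
taxonomy_ground_truth_labels <- function(tax) {
  tax$descriptors
}

#' Synthetic image generation settings
#'
#' The generative model: each class prototype is a sum of smooth random
#' spatial patterns, one shared by all classes under the same ancestor at
#' each taxonomy level (amplitude decaying from coarse to fine) plus one
#' unique to the leaf; each image is its class prototype plus i.i.d. Gaussian
#' pixel noise, clamped to [0, 1].
#'
#' @param image_size square image side, default 32.
#' @param n_per_class images per class, default 100.
#' @param level_amplitudes numeric vector (one per taxonomy level) of pattern
#'   amplitudes, coarse to fine; default geometric decay 0.3 * 0.6^(l-1).
#' @param leaf_amplitude amplitude of the leaf-unique pattern, default 0.15.
#' @param noise_sd pixel noise standard deviation (> 0), default 0.1.
#' @param pattern_res resolution of the low-frequency pattern grid that is
#'   bilinearly upsampled to image size, default 8.
#' @return an object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(image_size = 32L, n_per_class = 100L,
                           level_amplitudes = NULL, leaf_amplitude = 0.15,
                           noise_sd = 0.1, pattern_res = 8L) {
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  if (leaf_amplitude < 0) stopf("amplitudes must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 n_per_class = as.integer(n_per_class),
                 level_amplitudes = level_amplitudes,
                 leaf_amplitude = leaf_amplitude, noise_sd = noise_sd,
                 pattern_res = as.integer(pattern_res)),
            class = "synthetic_spec")
}

# bilinear upsample of a small matrix to size S x S
upsample <- function(p, S) {
  r <- nrow(p)
  # sample coordinates mapped into [1, r]
  co <- (seq_len(S) - 0.5) / S * (r - 1) + 1
  i0 <- pmin(floor(co), r - 1); f <- co - i0
  rows0 <- p[i0, i0, drop = FALSE]
  rows1 <- p[i0 + 1, i0, drop = FALSE]
  cols0 <- rows0 * (1 - f) + rows1 * f            # interp rows
  rows0b <- p[i0, i0 + 1, drop = FALSE]
  rows1b <- p[i0 + 1, i0 + 1, drop = FALSE]
  cols1 <- rows0b * (1 - f) + rows1b * f
  cols0 * rep(1 - f, each = S) + cols1 * rep(f, each = S)
}

random_pattern <- function(S, res) {
  upsample(matrix(rnorm(res * res), res, res), S)
}

# prototypes for every leaf: base 0.5 + sum of level patterns + leaf pattern
taxonomy_prototypes <- function(tax, spec) {
  L <- length(tax$levels)
  amps <- spec$level_amplitudes
  if (is.null(amps)) amps <- 0.3 * 0.6^(seq_len(L) - 1)
  if (length(amps) != L) stopf("level_amplitudes must have one entry per level")
  if (any(amps < 0)) stopf("amplitudes must be >= 0")
  S <- spec$image_size
  protos <- vector("list", tax$n_classes)
  pat_cache <- new.env(parent = emptyenv())
  level_pattern <- function(l, value) {
    key <- paste0(l, "|", value)
    if (!is.null(pat_cache[[key]])) return(pat_cache[[key]])
    pat_cache[[key]] <- random_pattern(S, spec$pattern_res)
    pat_cache[[key]]
  }
  # deterministic order: iterate levels then distinct ancestor values
  for (l in seq_len(L)) {
    for (v in unique(tax$descriptors[[tax$levels[l]]])) level_pattern(l, v)
  }
  leaf_pats <- lapply(seq_len(tax$n_classes), function(i) random_pattern(S, spec$pattern_res))
  for (i in seq_len(tax$n_classes)) {
    img <- matrix(0.5, S, S)
    for (l in seq_len(L)) {
      img <- img + amps[l] * level_pattern(l, tax$descriptors[i, tax$levels[l]])
    }
    img <- img + spec$leaf_amplitude * leaf_pats[[i]]
    protos[[i]] <- img
  }
  protos
}

#' Generate a synthetic hierarchical image dataset
#'
#' Draws class prototypes from the taxonomy (level-shared patterns plus a
#' leaf-unique pattern), then one image per sample as prototype plus Gaussian
#' pixel noise, clamped to [0, 1]. Splits are assigned stratified by class
#' (80/10/10 train/val/test by default).
#'
#' @param tax a \code{\link{build_taxonomy}} result.
#' @param spec a \code{\link{synthetic_spec}}.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param split_fractions train/val/test fractions summing to 1.
#' @return an object of class \code{synthetic_dataset}: \code{images}
#'   (array [S, S, N]), \code{labels} (integer), \code{manifest}
#'   (data.frame: path, class_id, one column per level, split),
#'   \code{taxonomy}, \code{prototypes}.
#' @export
generate_dataset <- function(tax, spec = synthetic_spec(), seed = 1L,
                             split_fractions = c(train = 0.8, val = 0.1, test = 0.1)) {
  if (abs(sum(split_fractions) - 1) > 1e-8) stopf("split fractions must sum to 1")
  set.seed(seed)
  protos <- taxonomy_prototypes(tax, spec)
  S <- spec$image_size; npc <- spec$n_per_class; C <- tax$n_classes
  N <- npc * C
  images <- array(0, dim = c(S, S, N))
  labels <- integer(N)
  rows <- vector("list", C)
  for (i in seq_len(C)) {
    idx <- ((i - 1L) * npc + 1L):(i * npc)
    noise <- array(rnorm(S * S * npc, sd = spec$noise_sd), dim = c(S, S, npc))
    images[, , idx] <- pmin(1, pmax(0, c(protos[[i]]) + noise))
    labels[idx] <- i
    n_tr <- round(split_fractions[[1L]] * npc)
    n_va <- round(split_fractions[[2L]] * npc)
    split <- c(rep("train", n_tr), rep("val", n_va),
               rep("test", npc - n_tr - n_va))
    rows[[i]] <- data.frame(
      path = sprintf("%s/img_%05d.png", tax$descriptors$class_id[i], seq_len(npc)),
      class_id = tax$descriptors$class_id[i],
      tax$descriptors[i, tax$levels, drop = FALSE],
      split = split, row.names = NULL, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(images = images, labels = labels, manifest = manifest,
                 taxonomy = tax, prototypes = protos, spec = spec, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic dataset: %d images (%dx%d) across %d classes, noise sd %g\n",
              length(x$labels), x$spec$image_size, x$spec$image_size,
              x$taxonomy$n_classes, x$spec$noise_sd))
  invisible(x)
}

#' Subset a synthetic dataset by split
#' @param ds a \code{synthetic_dataset}.
#' @param split "train", "val" or "test".
#' @return list(images, labels).
#' @export
dataset_split <- function(ds, split) {
  sel <- ds$manifest$split == split
  list(images = ds$images[, , sel, drop = FALSE], labels = ds$labels[sel])
}

#' Generate a synthetic patient cohort for zero-shot evaluation
#'
#' Emulates the emergency-stroke setting: every patient contributes an
#' ordered stack of axial slices. Negative slices are drawn from the trained
#' "normal" class; positive slices come from an unseen disease synthesized as
#' the normal prototype plus a localized hyperdense blob (a lesion never seen
#' in training). Every positive patient is guaranteed at least one positive
#' slice; the patient-level truth is the OR of the slice truths.
#'
#' @param n_patients number of patients.
#' @param slices_per_patient slices in each series.
#' @param positive_fraction fraction of patients with disease (in [0, 1]).
#' @param tax,spec taxonomy and generation settings used for the normal class.
#' @param normal_class leaf index serving as the "normal" class, default 1.
#' @param prototype optional normal-class prototype image. Supply
#'   \code{dataset$prototypes[[normal_class]]} so the cohort's negative slices
#'   come from the very class the model was trained on; when NULL a fresh
#'   prototype is derived from \code{tax}/\code{spec} under \code{seed}.
#' @param lesion_amplitude,lesion_radius blob intensity and radius (pixels).
#' @param positive_slice_prob probability that any further slice of a
#'   positive patient is positive (the first is forced positive).
#' @param seed integer seed.
#' @return list of \code{patient_series} objects (patient_id, images
#'   [S, S, n_slices], slice_positive, patient_positive).
#' @export
generate_patient_cohort <- function(n_patients, slices_per_patient = 8L,
                                    positive_fraction = 0.5, tax,
                                    spec = synthetic_spec(), normal_class = 1L,
                                    prototype = NULL,
                                    lesion_amplitude = 0.4, lesion_radius = 4,
                                    positive_slice_prob = 0.3, seed = 1L) {
  if (positive_fraction < 0 || positive_fraction > 1)
    stopf("positive_fraction must be in [0, 1]")
  set.seed(seed)
  proto <- if (is.null(prototype)) taxonomy_prototypes(tax, spec)[[normal_class]]
           else prototype
  S <- spec$image_size
  n_pos <- round(positive_fraction * n_patients)
  is_pos_patient <- c(rep(TRUE, n_pos), rep(FALSE, n_patients - n_pos))
  lapply(seq_len(n_patients), function(p) {
    flags <- rep(FALSE, slices_per_patient)
    if (is_pos_patient[p]) {
      flags <- runif(slices_per_patient) < positive_slice_prob
      flags[sample.int(slices_per_patient, 1L)] <- TRUE
    }
    imgs <- array(0, dim = c(S, S, slices_per_patient))
    for (sl in seq_len(slices_per_patient)) {
      img <- proto + matrix(rnorm(S * S, sd = spec$noise_sd), S, S)
      if (flags[sl]) {
        cy <- runif(1, lesion_radius + 1, S - lesion_radius)
        cx <- runif(1, lesion_radius + 1, S - lesion_radius)
        gy <- rep(seq_len(S), times = S); gx <- rep(seq_len(S), each = S)
        blob <- exp(-((gy - cy)^2 + (gx - cx)^2) / (2 * (lesion_radius / 1.5)^2))
        img <- img + lesion_amplitude * matrix(blob, S, S)
      }
      imgs[, , sl] <- pmin(1, pmax(0, img))
    }
    structure(list(patient_id = sprintf("patient_%03d", p), images = imgs,
                   slice_positive = flags, patient_positive = any(flags)),
              class = "patient_series")
  })
}

#' Generate a synthetic out-of-sample outcome cohort
#'
#' Bookkeeping emulation of a single-slice-per-subject cohort with a binary
#' outcome (e.g. disease-positive by a cognitive-score threshold): returns
#' per-subject truth flags with exactly the requested composition.
#'
#' @param n_subjects total subjects.
#' @param n_positive number of outcome-positive subjects.
#' @param seed seed for the (reproducible) subject ordering.
#' @return data.frame (subject_id, positive) with
#'   \code{sum(positive) == n_positive}.
#' @export
generate_outcome_cohort <- function(n_subjects, n_positive, seed = 1L) {
  if (n_positive > n_subjects) stopf("n_positive exceeds n_subjects")
  set.seed(seed)
  pos <- rep(FALSE, n_subjects)
  pos[sample.int(n_subjects, n_positive)] <- TRUE
  data.frame(subject_id = sprintf("subject_%04d", seq_len(n_subjects)),
             positive = pos, stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to disk as PNGs plus a CSV manifest
#'
#' Images land in class-named directories under \code{dir}; the manifest
#' gains no columns and is written as \code{manifest.csv}.
#' @param ds a \code{synthetic_dataset}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(ds$manifest))) {
    p <- file.path(dir, ds$manifest$path[i])
    dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
    png::writePNG(ds$images[, , i], p)
  }
  mp <- file.path(dir, "manifest.csv")
  write.csv(ds$manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read images listed in a manifest back into an array
#' @param manifest a manifest data.frame (paths relative to \code{dir}).
#' @param dir dataset root directory.
#' @return array [H, W, N] in the manifest's row order.
#' @export
read_images <- function(manifest, dir) {
  imgs <- lapply(manifest$path, function(p) {
    img <- png::readPNG(file.path(dir, p))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  })
  array(unlist(imgs), dim = c(nrow(imgs[[1L]]), ncol(imgs[[1L]]), length(imgs)))
}
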