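#' Load and validate a dataset manifest
#'
#' A manifest is one CSV row per image with at least \code{path},
#' \code{class_id} and \code{split} columns (plus optional taxonomy-level
#' descriptor columns, \code{patient_id} and \code{slice_positive}).
#' Validation is total and reports every violation at once: missing required
#' columns, duplicated paths, unknown split values, and class ids whose
#' descriptor rows are inconsistent.
#'
#' @param x path to a CSV file, or a data.frame.
#' @param required_levels optional character vector of descriptor columns
#'   that must be present.
#' @return the validated manifest (class \code{dataset_manifest}).
#' @export
load_manifest <- function(x, required_levels = NULL) {
  m <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else as.data.frame(x)
  problems <- character()
  required <- c("path", "class_id", "split", required_levels)
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols))
    problems <- c(problems, sprintf("missing column(s): %s",
                                    paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols)) {
    dup <- unique(m$path[duplicated(m$path)])
    if (length(dup))
      problems <- c(problems, sprintf("duplicated path(s): %s",
                                      paste(head(dup, 5L), collapse = ", ")))
    bad_split <- setdiff(unique(m$split), c("train", "val", "test"))
    if (length(bad_split))
      problems <- c(problems, sprintf("unknown split value(s): %s",
                                      paste(bad_split, collapse = ", ")))
    level_cols <- setdiff(names(m), c("path", "class_id", "split",
                                      "patient_id", "slice_positive"))
    if (length(level_cols)) {
      per_class <- unique(m[c("class_id", level_cols)])
      dup_desc <- per_class$class_id[duplicated(per_class$class_id)]
      if (length(dup_desc))
        problems <- c(problems,
                      sprintf("class(es) with inconsistent descriptors: %s",
                              paste(unique(dup_desc), collapse = ", ")))
    }
  }
  if (length(problems))
    stopf("invalid manifest:\n  - %s", paste(problems, collapse = "\n  - "))
  class(m) <- c("dataset_manifest", "data.frame")
  m
}

#' Summarize a manifest
#'
#' @param m a manifest (validated or raw data.frame with the same columns).
#' @return list(n_images, n_classes, per_class, per_split); per-class counts
#'   always sum to the total.
#' @export
summarize_manifest <- function(m) {
  per_class <- table(m$class_id)
  list(n_images = nrow(m),
       n_classes = length(per_class),
       per_class = per_class,
       per_split = table(factor(m$split, levels = c("train", "val", "test"))))
}

#' @export
print.dataset_manifest <- function(x, ...) {
  s <- summarize_manifest(x)
  cat(sprintf("dataset manifest: %d images, %d classes (train/val/test = %s)\n",
              s$n_images, s$n_classes, paste(s$per_split, collapse = "/")))
  invisible(x)
}

#' Expand a per-class count table into a full manifest
#'
#' Utility for bookkeeping checks: given rows of (class, images), emits one
#' manifest row per image with synthetic unique paths.
#'
#' @param counts data.frame with columns \code{class} and \code{images}.
#' @param split split value assigned to every row, default "train".
#' @return a validated \code{dataset_manifest}.
#' @export
expand_counts_manifest <- function(counts, split = "train") {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$images[i]
    cid <- gsub("[^A-Za-z0-9]+", "_", counts$class[i])
    data.frame(path = sprintf("%s/img_%06d.png", cid, seq_len(n)),
               class_id = counts$class[i], split = split,
               stringsAsFactors = FALSE)
  })
  load_manifest(do.call(rbind, rows))
}
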