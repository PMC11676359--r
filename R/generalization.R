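#' Class-to-outcome mapping
#'
#' Maps predicted class ids onto a binary outcome: predictions in
#' \code{positive_classes} count as positive calls, predictions in
#' \code{negative_classes} as negative calls. Predictions in neither set
#' follow the unmapped policy ("count_as_error" or "exclude").
#'
#' @param positive_classes,negative_classes disjoint vectors of class ids
#'   (integers or class-id strings).
#' @param unmapped "count_as_error" (default) or "exclude".
#' @return an object of class \code{class_mapping}.
#' @export
class_mapping <- function(positive_classes, negative_classes,
                          unmapped = c("count_as_error", "exclude")) {
  unmapped <- match.arg(unmapped)
  if (length(intersect(positive_classes, negative_classes)))
    stopf("positive and negative class sets overlap")
  structure(list(positive = positive_classes, negative = negative_classes,
                 unmapped = unmapped),
            class = "class_mapping")
}

map_call <- function(pred, mapping) {
  ifelse(pred %in% mapping$positive, "pos",
         ifelse(pred %in% mapping$negative, "neg", "unmapped"))
}

#' Percentile bootstrap confidence interval
#'
#' @param values sample vector.
#' @param statistic function of a vector, default \code{mean}.
#' @param n_resamples resamples with replacement, default 1000.
#' @param level confidence level, default 0.95.
#' @param seed RNG seed; the same seed reproduces the interval exactly.
#' @return numeric c(lo, hi).
#' @export
bootstrap_ci <- function(values, statistic = mean, n_resamples = 1000L,
                         level = 0.95, seed = 1L) {
  if (length(values) == 0L) stopf("bootstrap_ci: empty input")
  if (n_resamples < 1L || level <= 0 || level >= 1)
    stopf("invalid bootstrap configuration")
  set.seed(seed)
  n <- length(values)
  stats <- vapply(seq_len(n_resamples), function(i)
    statistic(values[sample.int(n, n, replace = TRUE)]), 1.0)
  unname(quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
}

#' Binary outcome accuracy under a class mapping
#'
#' Each subject's predicted class is mapped to a positive or negative call;
#' accuracy is the fraction of subjects whose call matches the truth flag.
#' Unmapped predictions count as errors or are excluded per the mapping
#' policy. The bootstrap resamples subjects.
#'
#' @param predicted_classes per-subject predicted class ids.
#' @param true_flags per-subject logical truth.
#' @param mapping a \code{\link{class_mapping}}.
#' @param n_boot,level,seed bootstrap settings.
#' @return list(accuracy, ci, n, n_unmapped).
#' @export
binary_outcome_accuracy <- function(predicted_classes, true_flags, mapping,
                                    n_boot = 1000L, level = 0.95, seed = 1L) {
  if (length(predicted_classes) != length(true_flags))
    stopf("prediction and truth lengths differ")
  call <- map_call(predicted_classes, mapping)
  correct <- (call == "pos" & true_flags) | (call == "neg" & !true_flags)
  keep <- rep(TRUE, length(call))
  if (mapping$unmapped == "exclude") keep <- call != "unmapped"
  vals <- as.numeric(correct[keep])
  if (!length(vals)) stopf("no subjects left after applying the mapping")
  list(accuracy = mean(vals),
       ci = bootstrap_ci(vals, mean, n_resamples = n_boot, level = level, seed = seed),
       n = length(vals), n_unmapped = sum(call == "unmapped"))
}

#' Zero-shot image-level accuracy
#'
#' True positive: a truth-positive image predicted into the positive class
#' set. True negative: a truth-negative image predicted into the negative
#' set. Accuracy = (TP + TN) / N over all images.
#'
#' @param per_image_preds predicted class ids.
#' @param per_image_truth logical truth per image.
#' @param mapping a \code{\link{class_mapping}}.
#' @return list(accuracy, tp, tn, n).
#' @export
zero_shot_image_accuracy <- function(per_image_preds, per_image_truth, mapping) {
  if (length(per_image_preds) != length(per_image_truth))
    stopf("prediction and truth lengths differ")
  call <- map_call(per_image_preds, mapping)
  tp <- sum(call == "pos" & per_image_truth)
  tn <- sum(call == "neg" & !per_image_truth)
  list(accuracy = (tp + tn) / length(per_image_preds), tp = tp, tn = tn,
       n = length(per_image_preds))
}

#' Patient-level identification rate
#'
#' A patient is identified when at least one of their truth-positive images
#' is predicted into the positive class set; the rate is identified / total
#' patients (displayed to two decimals, stored at full precision). The order
#' of images within a series does not matter.
#'
#' @param series list of \code{patient_series} objects (fields
#'   \code{patient_id}, \code{slice_positive}).
#' @param per_image_preds predicted class ids for every image of every
#'   series, concatenated in series order; or a list parallel to
#'   \code{series}.
#' @param mapping a \code{\link{class_mapping}}.
#' @return list(identified, n_patients, rate, rate_display).
#' @export
patient_identification_rate <- function(series, per_image_preds, mapping) {
  counts <- vapply(series, function(s) length(s$slice_positive), 1L)
  if (is.list(per_image_preds)) {
    if (length(per_image_preds) != length(series))
      stopf("prediction list does not match the series list")
    preds <- per_image_preds
  } else {
    if (length(per_image_preds) != sum(counts)) {
      stopf("predictions missing for patient(s): %s",
            paste(vapply(series, `[[`, "", "patient_id"), collapse = ", "))
    }
    ends <- cumsum(counts)
    starts <- ends - counts + 1L
    preds <- lapply(seq_along(series), function(i) per_image_preds[starts[i]:ends[i]])
  }
  identified <- vapply(seq_along(series), function(i) {
    s <- series[[i]]
    if (length(preds[[i]]) != length(s$slice_positive))
      stopf("predictions missing for patient(s): %s", s$patient_id)
    any(s$slice_positive & preds[[i]] %in% mapping$positive)
  }, TRUE)
  rate <- sum(identified) / length(series)
  list(identified = sum(identified), n_patients = length(series),
       rate = rate, rate_display = sprintf("%.2f", rate))
}
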