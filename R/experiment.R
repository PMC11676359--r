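#' Experiment configuration
#'
#' Bundles every stage setting of the full comparison pipeline: synthetic
#' data generation, training of both geometries from a shared encoder
#' initialization, hierarchy alignment, the PGD epsilon sweep, and the
#' zero-shot patient cohort.
#'
#' @param branching taxonomy branching, default c(2, 3, 2) (12 classes over
#'   3 levels).
#' @param spec a \code{\link{synthetic_spec}}.
#' @param control a \code{\link{train_config}}.
#' @param encoder_scale encoder size for both models.
#' @param epsilons PGD sweep epsilons (normalized units), default the
#'   \code{pgd_epsilon_presets$text} values.
#' @param n_patients,slices_per_patient,positive_fraction zero-shot cohort
#'   composition (0 patients disables the stage).
#' @param level_weights ground-truth hierarchy level weights.
#' @param n_boot bootstrap resamples.
#' @param seed global seed; each stage derives its own seed as seed + stage
#'   index, so stages are independently reproducible.
#' @param output_dir optional directory for the JSON/CSV report bundle.
#' @return an object of class \code{experiment_config}.
#' @export
experiment_config <- function(branching = c(2, 3, 2), spec = synthetic_spec(),
                              control = train_config(), encoder_scale = "tiny",
                              epsilons = pgd_epsilon_presets$text,
                              n_patients = 20L, slices_per_patient = 8L,
                              positive_fraction = 0.5, level_weights = NULL,
                              n_boot = 1000L, seed = 1L, output_dir = NULL) {
  structure(list(branching = branching, spec = spec, control = control,
                 encoder_scale = encoder_scale, epsilons = epsilons,
                 n_patients = as.integer(n_patients),
                 slices_per_patient = as.integer(slices_per_patient),
                 positive_fraction = positive_fraction,
                 level_weights = level_weights, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "experiment_config")
}

#' Run the full comparison experiment
#'
#' Generates the synthetic taxonomy dataset, trains the Euclidean and
#' Lorentz models from a shared encoder initialization, evaluates both,
#' computes hierarchy alignment against the taxonomy ground truth (with the
#' two-model Welch test), runs the PGD robustness sweep, and evaluates the
#' zero-shot patient cohort. Rerunning with the same config reproduces every
#' number.
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @return an \code{experiment_report}: list with dataset summary, per-model
#'   metrics, hierarchy, robustness and zero-shot results, the resolved
#'   config and all stage seeds. Written as JSON/CSV under
#'   \code{cfg$output_dir} when set.
#' @export
run_experiment <- function(cfg = experiment_config()) {
  stage_seed <- function(i) cfg$seed + i
  tax <- build_taxonomy(cfg$branching)
  ds <- generate_dataset(tax, cfg$spec, seed = stage_seed(1L))
  tr <- dataset_split(ds, "train"); va <- dataset_split(ds, "val")
  te <- dataset_split(ds, "test")

  mc <- function(geometry) model_config(geometry, n_classes = tax$n_classes,
                                        encoder_scale = cfg$encoder_scale,
                                        image_size = cfg$spec$image_size)
  models <- list()
  metrics <- list()
  for (g in c("euclidean", "lorentz")) {
    fit <- hcnn(tr$images, tr$labels, config = mc(g), control = cfg$control,
                seed = stage_seed(2L))
    models[[g]] <- fit
    metrics[[g]] <- list(val = evaluate(fit, va$images, va$labels),
                         test = evaluate(fit, te$images, te$labels))
  }

  desc <- taxonomy_ground_truth_labels(tax)
  # centroids are averaged over the whole dataset, the lowest-noise estimate
  # of each class's mean embedding position
  hier <- lapply(models, function(mdl)
    hierarchy_alignment(mdl, ds$images, ds$labels, desc,
                        level_weights = cfg$level_weights,
                        n_boot = cfg$n_boot, seed = stage_seed(3L)))
  hier_test <- compare_models_ttest(hier$euclidean$diffs, hier$lorentz$diffs)

  robust <- lapply(models, function(mdl)
    robust_accuracy(mdl, te$images, te$labels, cfg$epsilons,
                    seed = stage_seed(4L)))

  zero_shot <- NULL
  if (cfg$n_patients > 0L) {
    cohort <- generate_patient_cohort(cfg$n_patients, cfg$slices_per_patient,
                                      cfg$positive_fraction, tax, cfg$spec,
                                      prototype = ds$prototypes[[1L]],
                                      seed = stage_seed(5L))
    normal_id <- desc$class_id[1L]
    mapping <- class_mapping(setdiff(desc$class_id, normal_id), normal_id)
    zero_shot <- lapply(models, function(mdl) {
      preds <- lapply(cohort, function(s)
        desc$class_id[predict(mdl, s$images, type = "class")])
      truth <- unlist(lapply(cohort, `[[`, "slice_positive"))
      img_acc <- zero_shot_image_accuracy(unlist(preds), truth, mapping)
      pat <- patient_identification_rate(cohort, preds, mapping)
      list(image = img_acc, patient = pat)
    })
  }

  report <- structure(list(
    dataset = summarize_manifest(ds$manifest),
    taxonomy = tax,
    metrics = metrics,
    hierarchy = lapply(hier, function(h) h[c("mad", "mad_ci", "rho", "rho_p")]),
    hierarchy_ttest = hier_test,
    robustness = robust,
    zero_shot = zero_shot,
    config = cfg,
    stage_seeds = setNames(cfg$seed + 1:5,
                           c("data", "train", "hierarchy", "attack", "cohort")),
    models = models),
    class = "experiment_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment: %d classes, %d images (seed %d)\n",
              x$dataset$n_classes, x$dataset$n_images, x$config$seed))
  for (g in names(x$metrics))
    cat(sprintf("  %-9s val Top-1 %.1f%%, test Top-1 %.1f%%; MAD %.3f, rho %.3f\n",
                g, x$metrics[[g]]$val$top1, x$metrics[[g]]$test$top1,
                x$hierarchy[[g]]$mad, x$hierarchy[[g]]$rho))
  invisible(x)
}

#' Write an experiment report bundle to disk
#'
#' JSON summary (metrics, hierarchy, zero-shot, config, seeds) plus
#' per-model robustness CSVs; every report embeds the resolved configuration
#' and all stage seeds.
#'
#' @param report an \code{experiment_report}.
#' @param dir output directory.
#' @return dir, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strip <- report[c("dataset", "metrics", "hierarchy", "hierarchy_ttest",
                    "stage_seeds")]
  strip$zero_shot <- if (!is.null(report$zero_shot))
    lapply(report$zero_shot, function(z)
      list(image_accuracy = z$image$accuracy,
           patient_rate = z$patient$rate,
           identified = z$patient$identified,
           n_patients = z$patient$n_patients))
  strip$config <- report$config[c("branching", "encoder_scale", "epsilons",
                                  "n_patients", "seed")]
  strip$dataset$per_class <- as.list(strip$dataset$per_class)
  strip$dataset$per_split <- as.list(strip$dataset$per_split)
  jsonlite::write_json(strip, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (g in names(report$robustness))
    write.csv(report$robustness[[g]],
              file.path(dir, sprintf("robustness_%s.csv", g)), row.names = FALSE)
  invisible(dir)
}
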