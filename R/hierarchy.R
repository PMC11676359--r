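#' Embedding set for hierarchy evaluation
#'
#' Collects the canonical evaluation embeddings of a fitted model over a set
#' of labelled images. For the euclidean geometry these are the penultimate
#' features; for the lorentz geometry they are the post-clip tangent features
#' (so exponential maps and geodesic distances are recomputable from the
#' stored rows).
#'
#' @param model a fitted \code{hcnn}.
#' @param x images.
#' @param labels integer or factor labels.
#' @return an object of class \code{embedding_set}: matrix, labels, geometry,
#'   and for lorentz models the manifold (learned curvature + clip radius).
#' @export
embedding_set <- function(model, x, labels) {
  labels <- as_labels(labels)
  E <- forward_embeddings(model, x)
  if (nrow(E) != length(labels)) stopf("row count != label count")
  m <- NULL
  if (model$geometry == "lorentz") {
    m <- lorentz_manifold(exp(model$head$logk), model$config$clip_radius)
    E <- clip_features(E, m$clip_radius)
  }
  structure(list(embeddings = E, labels = labels, geometry = model$geometry,
                 manifold = m),
            class = "embedding_set")
}

#' Per-class average embeddings
#'
#' Arithmetic mean of the stored rows per class. For the lorentz geometry the
#' stored rows are tangent-space features, so this is the tangent-space mean;
#' it is exp-mapped later, inside \code{\link{model_distance_matrix}}.
#'
#' @param emb an \code{\link{embedding_set}}, or a plain matrix (then
#'   \code{labels} must be given).
#' @param labels labels when \code{emb} is a matrix.
#' @param n_classes expected class count; every class must be present.
#' @return matrix (n_classes x dim), row i the centroid of class i.
#' @export
class_centroids <- function(emb, labels = NULL, n_classes = NULL) {
  if (inherits(emb, "embedding_set")) {
    labels <- emb$labels
    E <- emb$embeddings
  } else E <- emb
  labels <- as_labels(labels)
  if (is.null(n_classes)) n_classes <- max(labels)
  missing <- setdiff(seq_len(n_classes), unique(labels))
  if (length(missing))
    stopf("no samples for class(es): %s", paste(missing, collapse = ", "))
  out <- matrix(0, n_classes, ncol(E))
  for (cl in seq_len(n_classes))
    out[cl, ] <- colMeans(E[labels == cl, , drop = FALSE])
  out
}

new_distance_matrix <- function(D, provenance) {
  dimnames(D) <- NULL
  structure(D, provenance = provenance, class = c("distance_matrix", "matrix", "array"))
}

#' Pairwise class-distance matrix of centroids
#'
#' Euclidean geometry: pairwise L2 distances. Lorentz geometry: tangent
#' centroids are exp-mapped onto the hyperboloid and pairwise geodesic
#' distances are taken there.
#'
#' @param centroids matrix (n_classes x dim).
#' @param geometry "euclidean" or "lorentz".
#' @param m a \code{\link{lorentz_manifold}} (required for lorentz geometry).
#' @return a symmetric zero-diagonal \code{distance_matrix}.
#' @export
model_distance_matrix <- function(centroids, geometry = c("euclidean", "lorentz"),
                                  m = NULL) {
  geometry <- match.arg(geometry)
  if (geometry == "euclidean") {
    D <- as.matrix(stats::dist(centroids))
    return(new_distance_matrix(D, "model_euclidean"))
  }
  if (is.null(m)) stopf("lorentz geometry requires a lorentz_manifold")
  X <- expmap0(centroids, m)
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    d <- geodesic_distance(X[rest, , drop = FALSE], X[i, ], m, check = FALSE)
    D[i, rest] <- d
    D[rest, i] <- d
  }
  new_distance_matrix(D, "model_lorentz")
}

#' Ground-truth hierarchy distance matrix from class descriptors
#'
#' Entry (i, j) is the weighted count of taxonomy levels at which the two
#' classes' categorical descriptors differ:
#' \eqn{D_{ij} = \sum_l w_l [desc_l(i) \ne desc_l(j)]}.
#'
#' @param descriptors data.frame with one row per class; a \code{class_id}
#'   column (if present) is excluded from the levels.
#' @param level_weights nonnegative weights, one per level, coarse to fine;
#'   default L, L-1, ..., 1 so coarse disagreements dominate.
#' @return a symmetric zero-diagonal \code{distance_matrix}.
#' @export
ground_truth_matrix <- function(descriptors, level_weights = NULL) {
  cols <- setdiff(names(descriptors), "class_id")
  L <- length(cols)
  if (is.null(level_weights)) level_weights <- rev(seq_len(L))
  if (length(level_weights) != L) stopf("need one weight per level (%d)", L)
  if (any(level_weights < 0) || all(level_weights == 0))
    stopf("level weights must be nonnegative and not all zero")
  if (anyDuplicated(descriptors[cols]))
    stopf("duplicate class descriptor rows")
  n <- nrow(descriptors)
  D <- matrix(0, n, n)
  for (l in seq_len(L)) {
    v <- descriptors[[cols[l]]]
    D <- D + level_weights[l] * outer(v, v, "!=")
  }
  new_distance_matrix(D, "ground_truth")
}

#' Normalize a distance matrix by its largest off-diagonal entry
#'
#' After normalization the maximum off-diagonal entry is exactly 1;
#' re-applying the operation is the identity.
#'
#' @param D a symmetric nonnegative matrix with zero diagonal.
#' @return the rescaled \code{distance_matrix}.
#' @export
normalize_matrix <- function(D) {
  off <- D[row(D) != col(D)]
  mx <- max(off)
  if (mx <= 0) stopf("degenerate distance matrix: no positive off-diagonal entry")
  new_distance_matrix(D / mx, attr(D, "provenance"))
}

upper_tri_vec <- function(D) D[upper.tri(D)]

#' Mean absolute difference between two normalized distance matrices
#'
#' Mean of |Dm - Dg| over the strict upper triangle, with a percentile
#' bootstrap confidence interval obtained by resampling class-pair entries
#' with replacement.
#'
#' @param Dm,Dg conforming normalized distance matrices.
#' @param n_boot bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return list(mad, ci = c(lo, hi), diffs) where \code{diffs} is the
#'   per-pair absolute-difference vector (used by the model-comparison test).
#' @export
mean_absolute_difference <- function(Dm, Dg, n_boot = 1000L, level = 0.95,
                                     seed = 1L) {
  if (!all(dim(Dm) == dim(Dg))) stopf("distance matrices differ in shape")
  diffs <- abs(upper_tri_vec(Dm) - upper_tri_vec(Dg))
  ci <- bootstrap_ci(diffs, mean, n_resamples = n_boot, level = level, seed = seed)
  list(mad = mean(diffs), ci = ci, diffs = diffs)
}

#' Spearman rank alignment between two distance matrices
#'
#' Tie-corrected Spearman correlation between the strict-upper-triangle
#' vectors of the two matrices, with a two-sided p-value.
#'
#' @param Dm,Dg conforming distance matrices over >= 3 classes.
#' @return list(rho, p).
#' @export
spearman_alignment <- function(Dm, Dg) {
  if (nrow(Dm) < 3L) stopf("need >= 3 classes")
  a <- upper_tri_vec(Dm); b <- upper_tri_vec(Dg)
  if (sd(a) == 0 || sd(b) == 0)
    stopf("constant distance vector: Spearman correlation undefined")
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Welch two-sample t-test comparing per-pair alignment errors of two models
#'
#' @param diffs_a,diffs_b the \code{diffs} vectors from
#'   \code{\link{mean_absolute_difference}} for the two models (length >= 2).
#' @return list(t, p, df).
#' @export
compare_models_ttest <- function(diffs_a, diffs_b) {
  if (length(diffs_a) < 2L || length(diffs_b) < 2L) stopf("need >= 2 values per model")
  if (sd(diffs_a) == 0 && sd(diffs_b) == 0)
    stopf("zero variance in both difference vectors")
  tt <- t.test(diffs_a, diffs_b)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Hierarchical-clustering dendrogram of class centroids
#'
#' Agglomerative clustering (average linkage) on the model's class-distance
#' matrix; returns the standard \code{hclust} merge structure (n - 1 merges
#' with heights).
#'
#' @param centroids matrix (n_classes x dim).
#' @param geometry "euclidean" or "lorentz".
#' @param m manifold for lorentz geometry.
#' @param labels optional class labels for the leaves.
#' @return an \code{hclust} object.
#' @export
embedding_dendrogram <- function(centroids, geometry = c("euclidean", "lorentz"),
                                 m = NULL, labels = NULL) {
  D <- model_distance_matrix(centroids, geometry, m)
  hc <- hclust(as.dist(D), method = "average")
  if (!is.null(labels)) hc$labels <- labels
  hc
}

#' Full hierarchy-alignment analysis for one fitted model
#'
#' Centroids, model distance matrix, normalization, and comparison with the
#' taxonomy ground truth: mean absolute difference (with bootstrap CI) and
#' Spearman rank alignment.
#'
#' @param model fitted \code{hcnn}.
#' @param x,labels evaluation images and labels.
#' @param descriptors taxonomy descriptor table.
#' @param level_weights see \code{\link{ground_truth_matrix}}.
#' @param n_boot,seed bootstrap settings.
#' @return list(mad, mad_ci, rho, rho_p, diffs, D_model, D_truth, dendrogram).
#' @export
hierarchy_alignment <- function(model, x, labels, descriptors,
                                level_weights = NULL, n_boot = 1000L, seed = 1L) {
  es <- embedding_set(model, x, labels)
  cen <- class_centroids(es, n_classes = model$config$n_classes)
  Dm <- normalize_matrix(model_distance_matrix(cen, es$geometry, es$manifold))
  Dg <- normalize_matrix(ground_truth_matrix(descriptors, level_weights))
  madr <- mean_absolute_difference(Dm, Dg, n_boot = n_boot, seed = seed)
  sp <- spearman_alignment(Dm, Dg)
  list(mad = madr$mad, mad_ci = madr$ci, rho = sp$rho, rho_p = sp$p,
       diffs = madr$diffs, D_model = Dm, D_truth = Dg,
       dendrogram = embedding_dendrogram(cen, es$geometry, es$manifold,
                                         labels = descriptors$class_id))
}
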