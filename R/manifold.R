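#' Lorentz model of hyperbolic space
#'
#' Constructs a manifold descriptor for the upper sheet of the hyperboloid
#' \eqn{\{x : \langle x, x\rangle_L = -1/k,\ x_0 > 0\}} in Minkowski space,
#' where \eqn{\langle x, y\rangle_L = -x_0 y_0 + \sum_{i\ge 1} x_i y_i} and
#' \eqn{k > 0} is the curvature magnitude. The time coordinate comes first,
#' a convention fixed throughout the package.
#'
#' @param k positive curvature magnitude; the decoder learns \code{log(k)} so
#'   positivity can never be violated by an optimizer step.
#' @param clip_radius maximum Euclidean norm allowed for tangent features
#'   before the exponential map (the feature-clipping stabilizer); default 1.
#' @param learnable_k logical flag recorded for model construction.
#' @return an object of class \code{lorentz_manifold}.
#' @export
lorentz_manifold <- function(k = 1, clip_radius = 1, learnable_k = TRUE) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stopf("curvature k must be a positive finite scalar")
  if (!is.numeric(clip_radius) || length(clip_radius) != 1L || clip_radius <= 0)
    stopf("clip_radius must be a positive scalar")
  structure(list(k = as.numeric(k), clip_radius = as.numeric(clip_radius),
                 learnable_k = isTRUE(learnable_k)),
            class = "lorentz_manifold")
}

#' @export
print.lorentz_manifold <- function(x, ...) {
  cat(sprintf("Lorentz manifold: k = %g (self-product -1/k = %g), clip radius = %g\n",
              x$k, -1 / x$k, x$clip_radius))
  invisible(x)
}

#' Lorentz (Minkowski) inner product
#'
#' \eqn{\langle x, y\rangle_L = -x_0 y_0 + \sum_{i \ge 1} x_i y_i}.
#'
#' @param x,y numeric vectors of equal length \eqn{\ge 2}, time coordinate first.
#' @return a scalar.
#' @export
lorentz_inner <- function(x, y) {
  if (length(x) != length(y)) stopf("lorentz_inner: lengths differ (%d vs %d)",
                                    length(x), length(y))
  if (length(x) < 2L) stopf("lorentz_inner: need length >= 2")
  -x[1L] * y[1L] + sum(x[-1L] * y[-1L])
}

#' Origin of the hyperboloid
#'
#' @param m a \code{\link{lorentz_manifold}}.
#' @param dim spatial dimension d; the returned point has length d + 1.
#' @return the point \eqn{(1/\sqrt k, 0, \dots, 0)}.
#' @export
lorentz_origin <- function(m, dim) {
  c(1 / sqrt(m$k), rep(0, dim))
}

#' Clip tangent features to a maximum norm
#'
#' Rescales \code{v} to \code{v * min(1, r / ||v||)}: direction preserved,
#' output norm never exceeds \code{r}. The zero vector is returned unchanged.
#' Operates row-wise when given a matrix.
#'
#' @param v numeric vector (one tangent vector) or matrix (rows are vectors).
#' @param r positive clip radius.
#' @export
clip_features <- function(v, r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stopf("clip radius must be > 0")
  if (is.matrix(v)) {
    n <- sqrt(rowSums(v * v))
    s <- ifelse(n > r, r / n, 1)
    return(v * s)
  }
  n <- sqrt(sum(v * v))
  if (n > r) v * (r / n) else v
}

# sinh(t)/t with a series branch near zero
sinhc <- function(t) ifelse(abs(t) < 1e-6, 1 + t * t / 6, sinh(t) / t)

#' Exponential map at the origin
#'
#' Maps a tangent vector at the hyperboloid origin (time component implicitly
#' zero, so only the d space components are supplied) to the manifold:
#' \deqn{\exp_o(v) = \cosh(\sqrt k \|v\|)\, o + \frac{\sinh(\sqrt k \|v\|)}{\sqrt k \|v\|} (0, v).}
#' The geodesic distance from the origin to the image equals \eqn{\|v\|_2}
#' (radial isometry). A Taylor branch handles \eqn{\|v\| \to 0}.
#'
#' @param v numeric vector of length d, or a matrix with d columns (row-wise).
#' @param m a \code{\link{lorentz_manifold}}.
#' @return vector of length d + 1, or matrix with d + 1 columns.
#' @export
expmap0 <- function(v, m) {
  s <- sqrt(m$k)
  if (is.matrix(v)) {
    if (!all(is.finite(v))) stopf("expmap0: non-finite input")
    nv <- sqrt(rowSums(v * v))
    t <- s * nv
    cbind(cosh(t) / s, v * sinhc(t))
  } else {
    if (!all(is.finite(v))) stopf("expmap0: non-finite input")
    nv <- sqrt(sum(v * v))
    t <- s * nv
    c(cosh(t) / s, v * sinhc(t))
  }
}

# constraint residual |k<x,x> + 1| scaled by the conditioning of the
# cancellation (~ k x0^2); used for on-manifold validation
manifold_residual <- function(x, m) {
  if (is.matrix(x)) {
    ip <- -x[, 1L]^2 + rowSums(x[, -1L, drop = FALSE]^2)
    abs(m$k * ip + 1) / pmax(1, m$k * x[, 1L]^2)
  } else {
    ip <- lorentz_inner(x, x)
    abs(m$k * ip + 1) / max(1, m$k * x[1L]^2)
  }
}

check_on_manifold <- function(x, m, tol = 1e-6, what = "point") {
  bad <- manifold_residual(x, m) > tol
  if (any(bad)) stopf("%s off the hyperboloid (scaled residual > %g)", what, tol)
  tneg <- if (is.matrix(x)) any(x[, 1L] <= 0) else x[1L] <= 0
  if (tneg) stopf("%s has non-positive time coordinate", what)
  invisible(TRUE)
}

#' Logarithmic map at the origin
#'
#' Left inverse of \code{\link{expmap0}}: recovers the tangent vector whose
#' exponential image is \code{x}, i.e. \code{logmap0(expmap0(v, m), m) == v}.
#'
#' @param x point(s) on the hyperboloid: vector of length d + 1 or matrix
#'   with d + 1 columns.
#' @param m a \code{\link{lorentz_manifold}}.
#' @param tol scaled tolerance for the on-manifold check.
#' @return tangent vector of length d (or matrix with d columns).
#' @export
logmap0 <- function(x, m, tol = 1e-4) {
  check_on_manifold(x, m, tol, "logmap0 input")
  if (is.matrix(x)) {
    xs <- x[, -1L, drop = FALSE]
    ns <- sqrt(rowSums(xs * xs))
    d <- geodesic_distance(x, sweep_origin(m, ncol(xs), nrow(x)), m)
    scl <- ifelse(ns > 0, d / ns, 0)
    xs * scl
  } else {
    xs <- x[-1L]
    ns <- sqrt(sum(xs * xs))
    if (ns == 0) return(rep(0, length(xs)))
    d <- geodesic_distance(x, lorentz_origin(m, length(xs)), m)
    xs * (d / ns)
  }
}

sweep_origin <- function(m, dim, n) {
  matrix(rep(lorentz_origin(m, dim), each = n), nrow = n)
}

#' Geodesic distance on the hyperboloid
#'
#' \eqn{d(x, y) = \frac{1}{\sqrt k} \mathrm{arccosh}(-k \langle x, y\rangle_L)},
#' with the arccosh argument floored at 1 so that rounding can never produce
#' NaN for coincident points.
#'
#' @param x,y points (vectors of length d + 1, or conforming matrices of row
#'   points; one may be a single point).
#' @param m a \code{\link{lorentz_manifold}}.
#' @param check validate that inputs lie on the hyperboloid (default TRUE).
#' @return nonnegative distance(s).
#' @export
geodesic_distance <- function(x, y, m, check = TRUE) {
  if (check) {
    check_on_manifold(x, m, 1e-4, "geodesic_distance x")
    check_on_manifold(y, m, 1e-4, "geodesic_distance y")
  }
  if (is.matrix(x) || is.matrix(y)) {
    x <- if (is.matrix(x)) x else matrix(x, nrow = NROW(y), ncol = length(x), byrow = TRUE)
    y <- if (is.matrix(y)) y else matrix(y, nrow = nrow(x), ncol = length(y), byrow = TRUE)
    ip <- -x[, 1L] * y[, 1L] + rowSums(x[, -1L, drop = FALSE] * y[, -1L, drop = FALSE])
    acosh(pmax(1, -m$k * ip)) / sqrt(m$k)
  } else {
    ip <- lorentz_inner(x, y)
    acosh(max(1, -m$k * ip)) / sqrt(m$k)
  }
}

#' Re-project a drifted point onto the hyperboloid
#'
#' Keeps the space components and recomputes the time coordinate as
#' \eqn{\sqrt{1/k + \|x_{space}\|^2}}, restoring the constraint exactly.
#'
#' @param u numeric vector of length d + 1 (or matrix with d + 1 columns)
#'   whose space components are finite.
#' @param m a \code{\link{lorentz_manifold}}.
#' @export
project_to_hyperboloid <- function(u, m) {
  if (is.matrix(u)) {
    xs <- u[, -1L, drop = FALSE]
    if (!all(is.finite(xs))) stopf("project_to_hyperboloid: non-finite space components")
    cbind(sqrt(1 / m$k + rowSums(xs * xs)), xs)
  } else {
    xs <- u[-1L]
    if (!all(is.finite(xs))) stopf("project_to_hyperboloid: non-finite space components")
    c(sqrt(1 / m$k + sum(xs * xs)), xs)
  }
}

#' One Riemannian gradient step on the hyperboloid
#'
#' The manifold-parameter update contract: a Euclidean gradient is converted
#' to the Riemannian gradient (metric correction: flip the sign of the time
#' component), projected onto the tangent space at \code{x}, and the point is
#' retracted along the geodesic via the exponential map at \code{x}. The
#' result lies on the hyperboloid to machine accuracy.
#'
#' @param x point on the hyperboloid (length d + 1).
#' @param egrad Euclidean gradient of the loss at \code{x} (length d + 1).
#' @param lr positive step size.
#' @param m a \code{\link{lorentz_manifold}}.
#' @return the updated point.
#' @export
riemannian_step <- function(x, egrad, lr, m) {
  check_on_manifold(x, m, 1e-4, "riemannian_step x")
  h <- egrad
  h[1L] <- -h[1L]                          # inverse metric
  v <- h + m$k * lorentz_inner(x, h) * x   # tangent projection at x
  v <- -lr * v
  nv2 <- lorentz_inner(v, v)               # tangent vectors are spacelike
  nv <- sqrt(max(0, nv2))
  t <- sqrt(m$k) * nv
  out <- cosh(t) * x + sinhc(t) * v        # sinh(t)/(sqrt(k)||v||) = sinh(t)/t
  project_to_hyperboloid(out, m)
}
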